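# Readers and writers for every external table the pipeline touches.
# All tables are tab-separated with a header row; missing values are "NA".
# Genomic coordinates are 1-based inclusive internally (GFF3 convention).

CHLOROTYPE_LEVELS <- c("PB", "PT", "OTHER", "MISSING")
TRAIT_LEVELS <- c("gsw", "PhiPSII", "Fs", "Fm", "ETR", "d13C", "Npct")

#' Read a sample metadata table
#'
#' Reads the tab-separated sample table (one row per sampled genotype) and
#' validates it: `sample_id` (unique), `contact_zone`, `lat`/`lon` in
#' decimal degrees, `chlorotype` in `PB`/`PT`/`OTHER`/`MISSING`, and
#' `nuclear_q`, the proportion of P. trichocarpa nuclear ancestry in
#' \[0, 1\] (admixture Q). Unknown extra columns are dropped with a warning.
#'
#' @param path Path to a TSV file with a header.
#' @return A `data.frame` with columns `sample_id`, `contact_zone`, `lat`,
#'   `lon`, `chlorotype`, `nuclear_q`, `genotype_id`, row order preserved.
#' @export
read_sample_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA", check.names = FALSE)
  required <- c("sample_id", "contact_zone", "lat", "lon", "chlorotype",
                "nuclear_q", "genotype_id")
  assert_columns(df, required, "sample table")
  extra <- setdiff(names(df), required)
  if (length(extra) > 0) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  df <- df[required]
  df$sample_id <- as.character(df$sample_id)
  df$genotype_id <- as.character(df$genotype_id)
  validate_sample_table(df)
  df
}

validate_sample_table <- function(df) {
  bad <- which(!is.na(df$lat) & (df$lat < -90 | df$lat > 90))
  if (length(bad) > 0) {
    stop_validation("latitude out of [-90, 90] at row %d", bad[1])
  }
  bad <- which(!is.na(df$lon) & (df$lon < -180 | df$lon > 180))
  if (length(bad) > 0) {
    stop_validation("longitude out of [-180, 180] at row %d", bad[1])
  }
  bad <- which(!is_proportion(df$nuclear_q))
  if (length(bad) > 0) {
    stop_validation("nuclear_q out of [0, 1] at row %d", bad[1])
  }
  bad <- which(!df$chlorotype %in% CHLOROTYPE_LEVELS)
  if (length(bad) > 0) {
    stop_validation("unknown chlorotype '%s' at row %d",
                    df$chlorotype[bad[1]], bad[1])
  }
  if (anyDuplicated(df$sample_id)) {
    stop_validation("duplicate sample_id: %s",
                    df$sample_id[duplicated(df$sample_id)][1])
  }
  invisible(df)
}

#' Read a haplotype-level local-ancestry matrix
#'
#' The TSV has one row per phased haplotype (id column `haplotype_id`, two
#' rows per individual distinguished by a suffix, `_1`/`_2` by default) and
#' one column per variant position named `chromosome:position` (1-based).
#' Cells are 0 (P. balsamifera ancestry) or 1 (P. trichocarpa ancestry).
#'
#' @param path Path to the TSV.
#' @param suffix_pattern Regex (with one capture group) stripped from
#'   haplotype ids to recover the individual id.
#' @return An object of class `ancestry_matrix`: a list with `values`
#'   (binary matrix, haplotypes x positions), `haplotype_ids`,
#'   `individual_ids`, and `positions` (data.frame `chromosome`, `position`).
#' @export
read_ancestry_matrix <- function(path, suffix_pattern = "_([12])$") {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  assert_columns(df, "haplotype_id", "ancestry matrix")
  hap_ids <- as.character(df$haplotype_id)
  values <- as.matrix(df[setdiff(names(df), "haplotype_id")])
  storage.mode(values) <- "numeric"
  rownames(values) <- hap_ids
  ancestry_matrix(values, suffix_pattern = suffix_pattern)
}

#' Construct and validate an ancestry matrix
#'
#' @param values Binary matrix, haplotype rows x position columns; column
#'   names `chromosome:position`.
#' @param suffix_pattern Regex identifying the haplotype suffix.
#' @return An `ancestry_matrix` object.
#' @export
ancestry_matrix <- function(values, suffix_pattern = "_([12])$") {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_validation("ancestry matrix needs haplotype row names and position column names")
  }
  if (!all(values %in% c(0, 1))) {
    stop_validation("ancestry matrix cells must be 0 or 1")
  }
  hap_ids <- rownames(values)
  ind_ids <- sub(suffix_pattern, "", hap_ids)
  counts <- table(ind_ids)
  if (any(counts != 2)) {
    bad <- names(counts)[counts != 2][1]
    stop_validation("individual '%s' has %d haplotype row(s); expected exactly 2",
                    bad, counts[[bad]])
  }
  parts <- strsplit(colnames(values), ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop_validation("position columns must be named 'chromosome:position'")
  }
  positions <- data.frame(
    chromosome = vapply(parts, `[`, "", 1),
    position = as.integer(vapply(parts, `[`, "", 2)),
    stringsAsFactors = FALSE
  )
  for (chr in unique(positions$chromosome)) {
    p <- positions$position[positions$chromosome == chr]
    if (any(diff(p) <= 0)) {
      stop_validation("positions not strictly increasing on %s", chr)
    }
  }
  structure(
    list(values = values, haplotype_ids = hap_ids,
         individual_ids = unique(ind_ids), positions = positions),
    class = "ancestry_matrix"
  )
}

#' Write an ancestry matrix to TSV
#' @param x An `ancestry_matrix`.
#' @param path Output path.
#' @export
write_ancestry_matrix <- function(x, path) {
  df <- data.frame(haplotype_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations from GFF3 or BED
#'
#' Records are normalized to 1-based inclusive coordinates regardless of
#' dialect (BED input is 0-based half-open on disk).
#'
#' @param path Path to the annotation file.
#' @param dialect `"GFF3"` or `"BED"`.
#' @param feature_type For GFF3, keep only features of this type
#'   (default `"gene"`); `NULL` keeps everything.
#' @return A `data.frame` with `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotations <- function(path, dialect = c("GFF3", "BED"),
                                  feature_type = "gene") {
  dialect <- toupper(dialect[1])
  if (!dialect %in% c("GFF3", "BED")) {
    stop_validation("unknown annotation dialect '%s' (use GFF3 or BED)", dialect)
  }
  gr <- rtracklayer::import(path,
                            format = if (dialect == "GFF3") "gff3" else "bed")
  if (dialect == "GFF3") {
    meta <- S4Vectors::mcols(gr)
    if (!is.null(feature_type) && "type" %in% names(meta)) {
      gr <- gr[as.character(meta$type) %in% feature_type]
      meta <- S4Vectors::mcols(gr)
    }
    id <- if ("ID" %in% names(meta) && !all(is.na(meta$ID))) {
      as.character(meta$ID)
    } else if ("Name" %in% names(meta)) as.character(meta$Name) else NULL
  } else {
    id <- as.character(S4Vectors::mcols(gr)$name)
  }
  if (is.null(id) || anyNA(id)) {
    stop_validation("annotation records lack gene identifiers")
  }
  ann <- data.frame(
    gene_id = id,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  if (any(ann$start > ann$end)) {
    stop_validation("annotation with start > end: %s",
                    ann$gene_id[ann$start > ann$end][1])
  }
  if (anyDuplicated(ann$gene_id)) {
    stop_validation("duplicate gene_id: %s",
                    ann$gene_id[duplicated(ann$gene_id)][1])
  }
  rownames(ann) <- NULL
  ann
}

#' Read a per-sample climate table
#'
#' Columns: `sample_id` plus the six climate normals used for chlorotype
#' association — continentality `TD` (degrees C), mean annual temperature
#' `MAT` (degrees C), mean annual precipitation `MAP` (mm), climate
#' moisture deficit `CMD` (mm), relative humidity `RH` (%), and
#' precipitation as snow `PAS` (mm).
#'
#' @param path Path to the TSV.
#' @return Validated `data.frame`.
#' @export
read_climate_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA")
  assert_columns(df, c("sample_id", "TD", "MAT", "MAP", "CMD", "RH", "PAS"),
                 "climate table")
  df$sample_id <- as.character(df$sample_id)
  if (any(!is.na(df$RH) & (df$RH < 0 | df$RH > 100))) {
    stop_validation("RH out of [0, 100]")
  }
  for (v in c("MAP", "PAS", "CMD")) {
    if (any(!is.na(df[[v]]) & df[[v]] < 0)) {
      stop_validation("%s must be non-negative", v)
    }
  }
  df
}

#' Read a common-garden trait table
#'
#' One row per measured ramet: `genotype_id`, `garden` (VT or VA), `block`,
#' `trait_name`, `value`. At most one value per
#' (genotype, garden, block, trait) cell.
#'
#' @param path Path to the TSV.
#' @return Validated `data.frame`.
#' @export
read_trait_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA")
  assert_columns(df, c("genotype_id", "garden", "block", "trait_name", "value"),
                 "trait table")
  df$genotype_id <- as.character(df$genotype_id)
  df$block <- as.character(df$block)
  if (any(!df$garden %in% c("VT", "VA"))) {
    stop_validation("garden must be VT or VA")
  }
  if (any(!df$trait_name %in% TRAIT_LEVELS)) {
    stop_validation("unknown trait_name '%s'",
                    df$trait_name[!df$trait_name %in% TRAIT_LEVELS][1])
  }
  key <- paste(df$genotype_id, df$garden, df$block, df$trait_name)
  if (anyDuplicated(key)) {
    stop_validation("duplicate trait cell: %s", key[duplicated(key)][1])
  }
  df
}

#' Write a result table to TSV or JSON
#'
#' Column order is taken from the input and is deterministic; numeric
#' columns are serialized with 6 significant digits; re-reading the TSV
#' recovers the declared fields.
#'
#' @param records A `data.frame`.
#' @param path Output path.
#' @param format `"TSV"` or `"JSON"`.
#' @export
write_results <- function(records, path, format = c("TSV", "JSON")) {
  format <- toupper(format[1])
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (format == "TSV") {
    out <- records
    for (j in seq_along(out)) {
      if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
        out[[j]] <- signif(out[[j]], 6)
      }
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  } else if (format == "JSON") {
    jsonlite::write_json(records, path, dataframe = "rows", digits = 6,
                         na = "null", auto_unbox = FALSE)
  } else {
    stop_validation("unknown output format '%s'", format)
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path Input path.
#' @param format `"TSV"` or `"JSON"`.
#' @return A `data.frame`.
#' @export
read_results <- function(path, format = c("TSV", "JSON")) {
  format <- toupper(format[1])
  if (format == "TSV") {
    read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = "NA")
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
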