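# Co-introgression classification of nuclear-encoded chloroplast-
# interacting (N-cp) genes: a gene co-introgresses with the chloroplast
# when its cline center and width both fall inside the chloroplast
# reference's support intervals but not both inside the nuclear
# reference's, with constrained-model likelihood-ratio tests against
# each reference center.

#' Per-gene ancestry proportions from a haplotype ancestry matrix
#'
#' For each annotated gene, averages the binary local-ancestry calls over
#' all variant positions within the gene body plus a flanking region, per
#' haplotype, then averages the two haplotypes of each individual; the
#' result is the per-individual proportion of P. trichocarpa ancestry at
#' that gene.
#'
#' @param ancestry An [ancestry_matrix()].
#' @param annotations Gene annotation `data.frame`
#'   (see [read_gene_annotations()]).
#' @param flank Flanking region in bp added to both sides of each gene.
#' @return Matrix of proportions, individuals x genes. Genes with no
#'   variant position in range are dropped with a warning.
#' @export
gene_ancestry_proportions <- function(ancestry, annotations, flank = 100) {
  stopifnot(inherits(ancestry, "ancestry_matrix"))
  pos <- ancestry$positions
  inds <- ancestry$individual_ids
  hap_ind <- sub("_[12]$", "", rownames(ancestry$values))
  cols <- lapply(seq_len(nrow(annotations)), function(i) {
    which(pos$chromosome == annotations$chromosome[i] &
            pos$position >= annotations$start[i] - flank &
            pos$position <= annotations$end[i] + flank)
  })
  empty <- lengths(cols) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d gene(s) with no variant in range: %s",
                    sum(empty),
                    paste(head(annotations$gene_id[empty], 5), collapse = ", ")),
            call. = FALSE)
  }
  keep <- which(!empty)
  out <- matrix(NA_real_, length(inds), length(keep),
                dimnames = list(inds, annotations$gene_id[keep]))
  for (j in seq_along(keep)) {
    hap_mean <- rowMeans(ancestry$values[, cols[[keep[j]]], drop = FALSE])
    out[, j] <- vapply(inds, function(id) mean(hap_mean[hap_ind == id]),
                       numeric(1))
  }
  out
}

#' Build a reference cline with support intervals
#'
#' @param label `"chloroplast"` or `"nuclear_mean"`.
#' @param data The [cline_data()] the reference is fitted on.
#' @param variants,n_starts,seed Passed to [select_cline_model()].
#' @param delta Support-interval log-likelihood drop.
#' @return A `reference_cline`: list with `label`, `fit`, `center_ci`,
#'   `width_ci`.
#' @export
reference_cline <- function(label = c("chloroplast", "nuclear_mean"), data,
                            variants = NULL, n_starts = 20, seed = 1L,
                            delta = 2.0) {
  label <- match.arg(label)
  fit <- select_cline_model(data, variants = variants, n_starts = n_starts,
                            seed = seed)
  fit <- add_support_intervals(data, fit, c("center", "width"), delta)
  structure(
    list(label = label, fit = fit,
         center_ci = as.numeric(fit$support_intervals$center),
         width_ci = as.numeric(fit$support_intervals$width)),
    class = "reference_cline"
  )
}

in_interval <- function(v, ci) v >= ci[1] & v <= ci[2]

#' Classify one gene against the chloroplast and nuclear references
#'
#' A gene overlaps a reference when BOTH its center and width point
#' estimates lie inside that reference's support intervals. The gene is
#' `co_introgressing` if it overlaps the chloroplast reference but not
#' the nuclear one, `ambiguous` if it overlaps both, `independent`
#' otherwise, and `unevaluable` if its fit did not converge.
#'
#' @param gene_fit The gene's selected [fit_cline()] result.
#' @param cp_ref,nuc_ref [reference_cline()] objects.
#' @return List with `overlap_cp`, `overlap_nuc`, `classification`.
#' @export
classify_gene <- function(gene_fit, cp_ref, nuc_ref) {
  if (!gene_fit$converged) {
    return(list(overlap_cp = NA, overlap_nuc = NA,
                classification = "unevaluable"))
  }
  ctr <- gene_fit$spec$center
  w <- gene_fit$spec$width
  overlap_cp <- in_interval(ctr, cp_ref$center_ci) &&
    in_interval(w, cp_ref$width_ci)
  overlap_nuc <- in_interval(ctr, nuc_ref$center_ci) &&
    in_interval(w, nuc_ref$width_ci)
  classification <- if (overlap_cp && !overlap_nuc) "co_introgressing"
                    else if (overlap_cp && overlap_nuc) "ambiguous"
                    else "independent"
  list(overlap_cp = overlap_cp, overlap_nuc = overlap_nuc,
       classification = classification)
}

#' Constrained-model likelihood-ratio test against a reference center
#'
#' Refits the gene's selected model variant with the cline center
#' bound-constrained to the reference's center support interval (the best
#' achievable likelihood with the center inside the interval), and
#' compares it to the free fit: statistic = 2 (lnL_free - lnL_constrained),
#' chi-square with 1 df.
#'
#' @param gene_data The gene's [cline_data()].
#' @param gene_fit The gene's free (selected) fit.
#' @param reference_ci `c(lo, hi)` center interval of the reference.
#' @param n_starts,seed,maxit Optimization controls for the constrained
#'   refit.
#' @return List with `statistic` (>= 0) and `p_value`.
#' @export
constrained_lrt <- function(gene_data, gene_fit, reference_ci,
                            n_starts = 10, seed = 1L, maxit = 200L) {
  con <- fit_cline(gene_data, gene_fit$spec$scaling, gene_fit$spec$tails,
                   n_starts = n_starts, seed = seed, maxit = maxit,
                   center_bounds = reference_ci)
  if (!con$converged) {
    # narrow center intervals can stall the line search; retry once with
    # more starts and a longer iteration budget before giving up
    retry <- fit_cline(gene_data, gene_fit$spec$scaling, gene_fit$spec$tails,
                       n_starts = 2L * n_starts, seed = seed + 1L,
                       maxit = 4L * maxit, center_bounds = reference_ci)
    if (retry$converged) con <- retry
  }
  if (!con$converged) {
    stop_validation("constrained fit did not converge (center in [%.4f, %.4f])",
                    reference_ci[1], reference_ci[2])
  }
  stat <- max(0, 2 * (gene_fit$loglik - con$loglik))
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Scan all genes for co-introgression with the chloroplast
#'
#' Fits the chloroplast and mean-nuclear reference clines, then, for each
#' gene, fits its cline, classifies it against both references, and runs
#' the two constrained LRTs.
#'
#' @param gene_props Matrix of per-individual, per-gene P. trichocarpa
#'   ancestry proportions (rows = individuals, columns = genes), e.g.
#'   from [gene_ancestry_proportions()].
#' @param x Scaled transect distance per individual (row order of
#'   `gene_props`).
#' @param cp_y Binary chlorotype per individual (1 = PT).
#' @param variants Cline variants tried per fit; default: the three
#'   scaling variants with no tails.
#' @param n_starts,seed Optimization controls; per-gene seeds are derived
#'   from the gene id, so gene order does not affect any verdict.
#' @param delta Support-interval drop for the reference CIs.
#' @return A `cointro_scan` object: list with `verdicts` (one row per
#'   gene), `summary`, `cp_ref`, `nuc_ref`.
#' @export
cointro_scan <- function(gene_props, x, cp_y, variants = NULL,
                         n_starts = 20, seed = 1L, delta = 2.0) {
  if (is.null(variants)) {
    variants <- data.frame(scaling = c("none", "fixed", "free"),
                           tails = "none", stringsAsFactors = FALSE)
  }
  if (ncol(gene_props) == 0) {
    # no genes: no nuclear-mean signal exists, so no references are fitted
    return(scan_genes(gene_props, x, cp_ref = NULL, nuc_ref = NULL,
                      variants = variants, n_starts = n_starts, seed = seed))
  }
  cp_data <- cline_data(x, cp_y, "bernoulli")
  nuc_mean <- rowMeans(gene_props, na.rm = TRUE)
  nuc_data <- cline_data(x, pmin(pmax(nuc_mean, 0), 1), "gaussian")
  cp_ref <- reference_cline("chloroplast", cp_data, variants = variants,
                            n_starts = n_starts,
                            seed = child_seed(seed, "cp_ref"), delta = delta)
  nuc_ref <- reference_cline("nuclear_mean", nuc_data, variants = variants,
                             n_starts = n_starts,
                             seed = child_seed(seed, "nuc_ref"), delta = delta)
  scan_genes(gene_props, x, cp_ref, nuc_ref, variants = variants,
             n_starts = n_starts, seed = seed)
}

# Per-gene fitting, classification and LRTs against prebuilt references.
scan_genes <- function(gene_props, x, cp_ref, nuc_ref, variants,
                       n_starts = 20, seed = 1L) {
  genes <- colnames(gene_props)
  rows <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    p <- gene_props[, g]
    keep <- !is.na(p)
    gseed <- child_seed(seed, genes[g])
    gdata <- if (all(p[keep] %in% c(0, 0.5, 1))) {
      cline_data(x[keep], 2 * p[keep], "binomial2")
    } else {
      cline_data(x[keep], p[keep], "gaussian")
    }
    gfit <- tryCatch(
      select_cline_model(gdata, variants = variants, n_starts = n_starts,
                         seed = gseed),
      error = function(e) NULL)
    if (is.null(gfit)) {
      rows[[g]] <- data.frame(
        gene_id = genes[g], center = NA_real_, width = NA_real_,
        scaling = NA_character_, tails = NA_character_, converged = FALSE,
        overlap_cp = NA, overlap_nuc = NA, classification = "unevaluable",
        lrt_cp_stat = NA_real_, lrt_cp_p = NA_real_,
        lrt_nuc_stat = NA_real_, lrt_nuc_p = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    cls <- classify_gene(gfit, cp_ref, nuc_ref)
    lrt_cp <- lrt_nuc <- list(statistic = NA_real_, p_value = NA_real_)
    if (gfit$converged) {
      lrt_cp <- tryCatch(
        constrained_lrt(gdata, gfit, cp_ref$center_ci,
                        seed = child_seed(gseed, "lrt_cp")),
        error = function(e) list(statistic = NA_real_, p_value = NA_real_))
      lrt_nuc <- tryCatch(
        constrained_lrt(gdata, gfit, nuc_ref$center_ci,
                        seed = child_seed(gseed, "lrt_nuc")),
        error = function(e) list(statistic = NA_real_, p_value = NA_real_))
    }
    rows[[g]] <- data.frame(
      gene_id = genes[g], center = gfit$spec$center, width = gfit$spec$width,
      scaling = gfit$spec$scaling, tails = gfit$spec$tails,
      converged = gfit$converged,
      overlap_cp = cls$overlap_cp, overlap_nuc = cls$overlap_nuc,
      classification = cls$classification,
      lrt_cp_stat = lrt_cp$statistic, lrt_cp_p = lrt_cp$p_value,
      lrt_nuc_stat = lrt_nuc$statistic, lrt_nuc_p = lrt_nuc$p_value,
      stringsAsFactors = FALSE)
  }
  verdicts <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(gene_id = character(0), center = numeric(0),
               width = numeric(0), scaling = character(0),
               tails = character(0), converged = logical(0),
               overlap_cp = logical(0), overlap_nuc = logical(0),
               classification = character(0), lrt_cp_stat = numeric(0),
               lrt_cp_p = numeric(0), lrt_nuc_stat = numeric(0),
               lrt_nuc_p = numeric(0), stringsAsFactors = FALSE)
  }
  counts <- table(factor(verdicts$classification,
                         levels = c("co_introgressing", "independent",
                                    "ambiguous", "unevaluable")))
  structure(
    list(verdicts = verdicts,
         summary = list(
           n_genes = length(genes),
           n_evaluated = length(genes) - unname(counts[["unevaluable"]]),
           n_co_introgressing = unname(counts[["co_introgressing"]]),
           n_independent = unname(counts[["independent"]]),
           n_ambiguous = unname(counts[["ambiguous"]]),
           n_unevaluable = unname(counts[["unevaluable"]])),
         cp_ref = cp_ref, nuc_ref = nuc_ref),
    class = "cointro_scan"
  )
}

#' @export
print.cointro_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<cointro_scan> %d of %d evaluated genes co-introgressing (%d independent, %d ambiguous, %d unevaluable)\n",
    s$n_co_introgressing, s$n_evaluated, s$n_independent, s$n_ambiguous,
    s$n_unevaluable))
  invisible(x)
}
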