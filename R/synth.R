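# Synthetic hybrid-zone data with recorded ground truth. The generators
# emulate the statistical structure the pipeline consumes: diploid local
# ancestry drawn from per-locus clines along a 0-1 transect, Bernoulli
# chlorotype from a chloroplast cline, climate covariates monotone in
# transect distance, clonally replicated common-garden phenotypes with
# block/garden variance components, and a two-group chloroplast
# alignment with planted fixed differences. All randomness flows from a
# single seed through named substreams.

#' Default hybrid-zone generator configuration
#'
#' Defaults echo the study setting for the steep contact zone: a
#' chloroplast cline at center 0.43 with width 0.05, a nuclear background
#' cline displaced toward the interior, and a small fraction of
#' co-introgressing genes sharing the chloroplast cline.
#'
#' @param n_samples Individuals along the transect.
#' @param n_genes Nuclear genes.
#' @param snps_per_gene Variant positions per gene.
#' @param cointro_fraction Fraction of genes planted on the chloroplast
#'   cline.
#' @param cp_center,cp_width Chloroplast cline truth.
#' @param nuc_center,nuc_width Nuclear background cline truth.
#' @param center_jitter_sd SD of per-gene center jitter.
#' @param zone Contact-zone label.
#' @return Named list of generator settings.
#' @export
hybrid_zone_config <- function(n_samples = 300, n_genes = 100,
                               snps_per_gene = 5, cointro_fraction = 0.1,
                               cp_center = 0.43, cp_width = 0.05,
                               nuc_center = 0.68, nuc_width = 0.05,
                               center_jitter_sd = 0.0, zone = "Cassiar") {
  list(n_samples = n_samples, n_genes = n_genes,
       snps_per_gene = snps_per_gene, cointro_fraction = cointro_fraction,
       cp_center = cp_center, cp_width = cp_width,
       nuc_center = nuc_center, nuc_width = nuc_width,
       center_jitter_sd = center_jitter_sd, zone = zone)
}

#' Generate a synthetic hybrid zone
#'
#' Samples are placed uniformly on the scaled transect (geographically, a
#' constant-latitude line so that Haversine scaling recovers the planted
#' positions); chlorotype is Bernoulli in the chloroplast cline
#' probability; each gene's two haplotype ancestries are independent
#' Bernoulli draws in that gene's cline probability (Hardy-Weinberg at
#' the local frequency), constant across the gene's variant positions.
#'
#' @param config See [hybrid_zone_config()].
#' @param seed Integer seed.
#' @return List with `samples` (sample table), `ancestry`
#'   ([ancestry_matrix()]), `annotations` (gene table), `truth` (all
#'   generator parameters, including the per-gene co-introgression flag).
#' @export
generate_hybrid_zone <- function(config = hybrid_zone_config(), seed = 1L) {
  if (config$n_samples < 10) {
    stop_validation("n_samples must be >= 10 to support cline fitting")
  }
  with_seed(child_seed(seed, "hybrid_zone"), {
    n <- config$n_samples
    x <- sort(runif(n))
    ids <- sprintf("S%03d", seq_len(n))
    lat <- rep(55, n)
    lon <- -131 + x * 10

    cp_spec <- cline_spec(config$cp_center, config$cp_width)
    cp <- rbinom(n, 1, cline_probability(x, cp_spec))

    n_cointro <- round(config$cointro_fraction * config$n_genes)
    cointro <- rep(c(TRUE, FALSE),
                   c(n_cointro, config$n_genes - n_cointro))
    centers <- ifelse(cointro, config$cp_center, config$nuc_center)
    if (config$center_jitter_sd > 0) {
      centers <- pmin(pmax(centers + rnorm(config$n_genes, 0,
                                           config$center_jitter_sd),
                           0.02), 0.98)
    }
    widths <- ifelse(cointro, config$cp_width, config$nuc_width)
    gene_ids <- sprintf("G%03d", seq_len(config$n_genes))

    gene_len <- config$snps_per_gene * 100L
    starts <- (seq_len(config$n_genes) - 1L) * (gene_len + 1000L) + 1L
    annotations <- data.frame(
      gene_id = gene_ids, chromosome = "Chr01",
      start = starts, end = starts + gene_len - 1L,
      strand = "+", stringsAsFactors = FALSE)

    hap_ids <- as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2")))
    values <- matrix(0, nrow = 2 * n,
                     ncol = config$n_genes * config$snps_per_gene)
    colpos <- integer(0)
    for (g in seq_len(config$n_genes)) {
      p <- cline_probability(x, cline_spec(centers[g], widths[g]))
      hap1 <- rbinom(n, 1, p)
      hap2 <- rbinom(n, 1, p)
      cols <- (g - 1L) * config$snps_per_gene + seq_len(config$snps_per_gene)
      values[seq(1, 2 * n, by = 2), cols] <- hap1
      values[seq(2, 2 * n, by = 2), cols] <- hap2
      colpos <- c(colpos, starts[g] + round(seq(10, gene_len - 10,
                                                length.out = config$snps_per_gene)))
    }
    rownames(values) <- hap_ids
    colnames(values) <- paste0("Chr01:", colpos)
    ancestry <- ancestry_matrix(values)

    hap_mean <- rowMeans(values)
    nuclear_q <- (hap_mean[seq(1, 2 * n, by = 2)] +
                    hap_mean[seq(2, 2 * n, by = 2)]) / 2
    samples <- data.frame(
      sample_id = ids, contact_zone = config$zone, lat = lat, lon = lon,
      chlorotype = ifelse(cp == 1, "PT", "PB"),
      nuclear_q = round(unname(nuclear_q), 6), genotype_id = ids,
      stringsAsFactors = FALSE)

    list(samples = samples, ancestry = ancestry, annotations = annotations,
         truth = list(seed = seed, x = x,
                      cp_cline = cp_spec,
                      nuclear_cline = cline_spec(config$nuc_center,
                                                 config$nuc_width),
                      gene_centers = centers, gene_widths = widths,
                      cointro = setNames(cointro, gene_ids),
                      config = config))
  })
}

#' Generate common-garden trait data
#'
#' One observation per genotype x garden x block (a randomized complete
#' block design with `blocks_per_garden` replicates per genotype):
#' y = mu + bN N + bC C + bNxC N C + bE 1(garden = VA) + G + R + eps with
#' genotype effect G ~ N(0, V_G), block-within-garden effect
#' R ~ N(0, V_block) and residual eps ~ N(0, V_eps).
#'
#' @param config List with `mu`, `beta_N`, `beta_C`, `beta_NxC`,
#'   `beta_E`, `V_G`, `V_block`, `V_eps`, `gardens`, `blocks_per_garden`,
#'   `trait_name` (missing entries take the defaults below).
#' @param seed Integer seed.
#' @param sample_table Sample table supplying `genotype_id`, `nuclear_q`
#'   and `chlorotype` (rows with chlorotype other than PB/PT are skipped).
#' @return List with `traits` (trait table) and `truth`.
#' @export
generate_traits <- function(config = list(), seed = 1L, sample_table) {
  cfg <- utils::modifyList(
    list(mu = 1, beta_N = 0, beta_C = 0, beta_NxC = 0, beta_E = 0,
         V_G = 0, V_block = 0.1, V_eps = 0.1,
         gardens = c("VT", "VA"), blocks_per_garden = 3L,
         trait_name = "PhiPSII"),
    config)
  if (cfg$V_eps <= 0) stop_validation("V_eps must be > 0")
  st <- sample_table[sample_table$chlorotype %in% c("PB", "PT") &
                       !is.na(sample_table$nuclear_q), , drop = FALSE]
  with_seed(child_seed(seed, "traits"), {
    g_eff <- setNames(rnorm(nrow(st), 0, sqrt(cfg$V_G)), st$genotype_id)
    rows <- list()
    for (garden in cfg$gardens) {
      blocks <- sprintf("B%d", seq_len(cfg$blocks_per_garden))
      b_eff <- setNames(rnorm(length(blocks), 0, sqrt(cfg$V_block)), blocks)
      for (b in blocks) {
        nuc <- st$nuclear_q
        cp <- as.numeric(st$chlorotype == "PT")
        y <- cfg$mu + cfg$beta_N * nuc + cfg$beta_C * cp +
          cfg$beta_NxC * nuc * cp + cfg$beta_E * (garden == "VA") +
          g_eff[st$genotype_id] + b_eff[b] +
          rnorm(nrow(st), 0, sqrt(cfg$V_eps))
        rows[[length(rows) + 1L]] <- data.frame(
          genotype_id = st$genotype_id, garden = garden, block = b,
          trait_name = cfg$trait_name, value = unname(y),
          stringsAsFactors = FALSE)
      }
    }
    list(traits = do.call(rbind, rows),
         truth = list(seed = seed, config = cfg,
                      genotype_effects = g_eff))
  })
}

#' Generate a per-sample climate table
#'
#' Each climate variable is a linear trend in scaled transect distance
#' plus gaussian noise. Default trends mimic a coast-to-interior
#' gradient: warmer/wetter/less continental near the coast.
#'
#' @param config Named list of per-variable `c(intercept, slope, sd)`
#'   triplets (any of TD, MAT, MAP, CMD, RH, PAS; missing variables take
#'   the defaults).
#' @param seed Integer seed.
#' @param sample_table Sample table with coordinates.
#' @return List with `climate` (climate table) and `truth` (the trend
#'   parameters and the scaled distances used).
#' @export
generate_climate <- function(config = list(), seed = 1L, sample_table) {
  defaults <- list(TD = c(10, 15, 1), MAT = c(6, -6, 0.5),
                   MAP = c(900, -500, 40), CMD = c(100, 200, 15),
                   RH = c(72, -10, 1), PAS = c(50, 150, 10))
  cfg <- utils::modifyList(defaults, config)
  tr <- scale_transect(sample_table)
  x <- tr$distance_scaled
  with_seed(child_seed(seed, "climate"), {
    climate <- data.frame(sample_id = sample_table$sample_id,
                          stringsAsFactors = FALSE)
    for (v in names(defaults)) {
      p <- cfg[[v]]
      val <- p[1] + p[2] * x + rnorm(length(x), 0, p[3])
      if (v %in% c("MAP", "CMD", "PAS")) val <- pmax(val, 0)
      if (v == "RH") val <- pmin(pmax(val, 0), 100)
      climate[[v]] <- val
    }
    list(climate = climate,
         truth = list(seed = seed, trends = cfg, x = x))
  })
}

#' Generate a two-chlorotype chloroplast alignment with planted truth
#'
#' Builds a random reference genome with in-frame CDS blocks, plants the
#' requested numbers of synonymous, nonsynonymous and noncoding fixed
#' differences between the two groups (honoring codon structure: planted
#' synonymous changes hit four-fold degenerate third positions; planted
#' nonsynonymous changes hit first positions), and sprinkles each group
#' with private within-group polymorphisms at non-planted positions so
#' they cannot create spurious fixed differences.
#'
#' @param config List with `genome_length`, `n_per_group`, `n_cds`,
#'   `cds_length`, `n_synonymous`, `n_nonsynonymous`, `n_noncoding`,
#'   `n_polymorphisms` (per group).
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector, groups
#'   `PT_*`/`PB_*`), `cds` (CDS annotation table), `reference`
#'   (the group-A reference string), `truth` (planted positions,
#'   alleles, effects).
#' @export
generate_cp_alignment <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(
    list(genome_length = 6000L, n_per_group = 4L, n_cds = 8L,
         cds_length = 300L, n_synonymous = 30L, n_nonsynonymous = 9L,
         n_noncoding = 23L, n_polymorphisms = 10L),
    config)
  stopifnot(cfg$cds_length %% 3 == 0)
  with_seed(child_seed(seed, "cp_alignment"), {
    nuc <- c("A", "C", "G", "T")
    L <- cfg$genome_length
    ref <- sample(nuc, L, replace = TRUE)

    gap <- (L - cfg$n_cds * cfg$cds_length) %/% (cfg$n_cds + 1L)
    cds_start <- gap + (seq_len(cfg$n_cds) - 1L) * (cfg$cds_length + gap) + 1L
    cds <- data.frame(
      gene_id = sprintf("cds%02d", seq_len(cfg$n_cds)),
      chromosome = "plastome", start = cds_start,
      end = cds_start + cfg$cds_length - 1L,
      strand = rep(c("+", "-"), length.out = cfg$n_cds),
      stringsAsFactors = FALSE)

    in_cds <- unlist(Map(seq, cds$start, cds$end))
    codon_starts <- unlist(Map(function(s, e) seq(s, e - 2, by = 3),
                               cds$start, cds$end))
    need_codons <- cfg$n_synonymous + cfg$n_nonsynonymous
    if (need_codons > length(codon_starts)) {
      stop_validation("requested %d coding differences but only %d codons available",
                      need_codons, length(codon_starts))
    }
    picked <- sample(codon_starts, need_codons)
    syn_codons <- picked[seq_len(cfg$n_synonymous)]
    nsyn_codons <- picked[cfg$n_synonymous + seq_len(cfg$n_nonsynonymous)]

    alt <- ref
    planted <- list()
    # Synonymous: plant GGN (Gly; four-fold) and change the third base.
    for (s in syn_codons) {
      strand <- cds$strand[cds$start <= s & cds$end >= s]
      if (strand == "+") {
        ref[s:(s + 1)] <- c("G", "G"); alt[s:(s + 1)] <- c("G", "G")
        third <- s + 2L
        ref[third] <- "A"; alt[third] <- "C"
      } else {
        # on -, the codon read 5'->3' uses complemented bases in reverse
        ref[(s + 1):(s + 2)] <- c("C", "C"); alt[(s + 1):(s + 2)] <- c("C", "C")
        third <- s
        ref[third] <- "T"; alt[third] <- "G"
      }
      planted[[length(planted) + 1L]] <-
        data.frame(position = third, allele_A = ref[third],
                   allele_B = alt[third], effect = "synonymous",
                   stringsAsFactors = FALSE)
    }
    # Nonsynonymous: plant AAA (Lys) -> GAA (Glu) at the first base.
    for (s in nsyn_codons) {
      strand <- cds$strand[cds$start <= s & cds$end >= s]
      if (strand == "+") {
        ref[s:(s + 2)] <- c("A", "A", "A"); alt[s:(s + 2)] <- c("A", "A", "A")
        first <- s
        alt[first] <- "G"
      } else {
        ref[s:(s + 2)] <- c("T", "T", "T"); alt[s:(s + 2)] <- c("T", "T", "T")
        first <- s + 2L
        alt[first] <- "C"
      }
      planted[[length(planted) + 1L]] <-
        data.frame(position = first, allele_A = ref[first],
                   allele_B = alt[first], effect = "nonsynonymous",
                   stringsAsFactors = FALSE)
    }
    # Noncoding differences outside any CDS.
    noncoding_pool <- setdiff(seq_len(L), in_cds)
    nc <- sample(noncoding_pool, cfg$n_noncoding)
    for (pos in nc) {
      alt[pos] <- sample(setdiff(nuc, ref[pos]), 1)
      planted[[length(planted) + 1L]] <-
        data.frame(position = pos, allele_A = ref[pos],
                   allele_B = alt[pos], effect = "noncoding",
                   stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, planted)
    planted <- planted[order(planted$position), , drop = FALSE]
    rownames(planted) <- NULL

    make_group <- function(base, prefix) {
      seqs <- matrix(rep(base, cfg$n_per_group), nrow = cfg$n_per_group,
                     byrow = TRUE)
      rownames(seqs) <- sprintf("%s_%d", prefix, seq_len(cfg$n_per_group))
      pool <- setdiff(seq_len(L), planted$position)
      poly <- sample(pool, cfg$n_polymorphisms)
      for (pos in poly) {
        i <- sample(cfg$n_per_group, 1)
        seqs[i, pos] <- sample(setdiff(nuc, base[pos]), 1)
      }
      list(seqs = seqs, poly = poly)
    }
    ga <- make_group(ref, "PT")
    gb <- make_group(alt, "PB")
    all_seqs <- rbind(ga$seqs, gb$seqs)
    sequences <- setNames(apply(all_seqs, 1, paste, collapse = ""),
                          rownames(all_seqs))

    list(sequences = sequences, cds = cds,
         reference = paste(ref, collapse = ""),
         truth = list(seed = seed, config = cfg, planted = planted,
                      polymorphic_positions = sort(c(ga$poly, gb$poly))))
  })
}

#' Generate aligned sequences with a known derived group
#'
#' Simulates an ancestral sequence; group A keeps the ancestral state,
#' group B carries shared derived substitutions, and each outgroup
#' accumulates independent substitutions. Used to validate polarization:
#' the planted ancestral group is A.
#'
#' @param length Alignment length.
#' @param n_a,n_b,n_out Sequences per chlorotype group and outgroups.
#' @param derived_rate Per-site probability of a shared derived
#'   substitution in group B.
#' @param outgroup_rate Per-site substitution probability per outgroup.
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector: `A_*`, `B_*`,
#'   `OUT_*`) and `truth` (`ancestral_group = "A"`).
#' @export
generate_polarized_alignment <- function(length = 300L, n_a = 2L, n_b = 2L,
                                         n_out = 2L, derived_rate = 0.05,
                                         outgroup_rate = 0.02, seed = 1L) {
  with_seed(child_seed(seed, "polarize"), {
    nuc <- c("A", "C", "G", "T")
    anc <- sample(nuc, length, replace = TRUE)
    mutate <- function(base, rate) {
      hit <- runif(length) < rate
      out <- base
      out[hit] <- vapply(base[hit],
                         function(b) sample(setdiff(nuc, b), 1), "")
      out
    }
    derived <- mutate(anc, derived_rate)
    seqs <- c(
      setNames(replicate(n_a, paste(anc, collapse = "")),
               sprintf("A_%d", seq_len(n_a))),
      setNames(replicate(n_b, paste(derived, collapse = "")),
               sprintf("B_%d", seq_len(n_b))),
      setNames(vapply(seq_len(n_out),
                      function(i) paste(mutate(anc, outgroup_rate),
                                        collapse = ""), ""),
               sprintf("OUT_%d", seq_len(n_out))))
    list(sequences = seqs, truth = list(ancestral_group = "A", seed = seed))
  })
}
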