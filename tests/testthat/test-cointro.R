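make_ref <- function(center_ci, width_ci, center = mean(center_ci),
                     width = mean(width_ci), converged = TRUE) {
  structure(list(label = "ref", center = center, width = width,
                 center_ci = center_ci, width_ci = width_ci,
                 converged = converged),
            class = "reference_cline")
}

fake_fit <- function(center, width, converged = TRUE) {
  structure(list(spec = cline_spec(center, width), converged = converged),
            class = "cline_fit")
}

test_that("classification implements the both-parameter overlap rule", {
  cp <- make_ref(c(0.40, 0.46), c(0.03, 0.08))
  nuc <- make_ref(c(0.64, 0.72), c(0.03, 0.08))

  # inside cp on both parameters, outside nuclear center -> co_introgressing
  expect_equal(classify_gene(fake_fit(0.43, 0.05), cp, nuc)$classification,
               "co_introgressing")
  # inside nuclear only -> independent
  expect_equal(classify_gene(fake_fit(0.68, 0.05), cp, nuc)$classification,
               "independent")
  # overlapping both references -> ambiguous
  wide_nuc <- make_ref(c(0.30, 0.80), c(0.01, 0.2))
  expect_equal(classify_gene(fake_fit(0.43, 0.05), cp, wide_nuc)$classification,
               "ambiguous")
  # center inside cp interval but width outside -> not co_introgressing
  expect_equal(classify_gene(fake_fit(0.43, 0.50), cp, nuc)$classification,
               "independent")
  # matching neither -> independent
  expect_equal(classify_gene(fake_fit(0.90, 0.05), cp, nuc)$classification,
               "independent")
  # unconverged gene fit -> unevaluable
  expect_equal(classify_gene(fake_fit(0.43, 0.05,
                                        converged = FALSE), cp, nuc)$classification,
               "unevaluable")
})

test_that("constrained LRT is zero when unconstrained optimum satisfies it", {
  d <- sim_cline_bernoulli(200, 0.5, 0.1, seed = 14)
  f <- fit_cline(d, n_starts = 10, seed = 14)
  # constraint interval generously containing the MLE -> statistic ~ 0
  res <- constrained_lrt(d, f, c(0.2, 0.8), seed = 14)
  expect_gte(res$statistic, 0)
  expect_lt(res$statistic, 1e-6)
  expect_gt(res$p_value, 0.99)
  # constraint far from the MLE -> large statistic, small p
  res2 <- constrained_lrt(d, f, c(0.90, 0.95), seed = 14)
  expect_gt(res2$statistic, 10)
  expect_lt(res2$p_value, 0.01)
  expect_equal(res2$p_value,
               pchisq(res2$statistic, df = 1, lower.tail = FALSE))
})

test_that("gene ancestry proportions average haplotypes over gene + flank", {
  vals <- matrix(0L, 4, 4,
                 dimnames = list(c("A_1", "A_2", "B_1", "B_2"),
                                 paste0("Chr01:", c(50, 150, 260, 5000))))
  vals["A_1", ] <- 1L  # A is heterozygous everywhere
  vals["B_1", 4] <- 1L; vals["B_2", 4] <- 1L
  am <- ancestry_matrix(vals)
  ann <- data.frame(gene_id = c("g1", "g2"), chromosome = "Chr01",
                    start = c(100L, 4950L), end = c(200L, 5100L),
                    strand = "+", stringsAsFactors = FALSE)
  # flank 100 pulls positions 50 and 260 into g1 (window 0..300)
  gp <- gene_ancestry_proportions(am, ann, flank = 100)
  expect_equal(dim(gp), c(2L, 2L))
  expect_equal(gp["A", "g1"], 0.5)
  expect_equal(gp["B", "g1"], 0)
  expect_equal(gp["B", "g2"], 1)
  # flank 0 keeps only position 150 for g1; values unchanged here
  gp0 <- gene_ancestry_proportions(am, ann, flank = 0)
  expect_equal(gp0["A", "g1"], 0.5)
  # gene with no covered SNPs is dropped with a warning
  ann2 <- rbind(ann, data.frame(gene_id = "g3", chromosome = "Chr01",
                                start = 9000L, end = 9100L, strand = "+"))
  expect_warning(gp3 <- gene_ancestry_proportions(am, ann2), "g3")
  expect_equal(colnames(gp3), c("g1", "g2"))
})

test_that("scan verdicts are invariant to gene order and summary partitions", {
  cfg <- hybrid_zone_config(n_samples = 120, n_genes = 8, snps_per_gene = 3,
                            cointro_fraction = 0.25)
  hz <- generate_hybrid_zone(cfg, seed = 77)
  gp <- gene_ancestry_proportions(hz$ancestry, hz$annotations)
  x <- hz$truth$x
  y <- as.integer(hz$samples$chlorotype == "PT")
  s1 <- cointro_scan(gp, x, y, n_starts = 6, seed = 4)
  s2 <- cointro_scan(gp[, rev(colnames(gp))], x, y, n_starts = 6, seed = 4)
  v1 <- s1$verdicts[order(s1$verdicts$gene_id), ]
  v2 <- s2$verdicts[order(s2$verdicts$gene_id), ]
  rownames(v1) <- rownames(v2) <- NULL
  expect_equal(v1, v2)
  # summary counts partition the gene list
  sm <- s1$summary
  expect_equal(sm$n_genes,
               sm$n_co_introgressing + sm$n_independent +
                 sm$n_ambiguous + sm$n_unevaluable)
})

test_that("scanning zero genes yields an empty verdict table with zero counts", {
  cfg <- hybrid_zone_config(n_samples = 60, n_genes = 2, snps_per_gene = 2,
                            cointro_fraction = 0)
  hz <- generate_hybrid_zone(cfg, seed = 5)
  gp <- gene_ancestry_proportions(hz$ancestry, hz$annotations)
  s <- cointro_scan(gp[, 0, drop = FALSE], hz$truth$x,
                    as.integer(hz$samples$chlorotype == "PT"),
                    n_starts = 4, seed = 1)
  expect_equal(nrow(s$verdicts), 0L)
  expect_equal(s$summary$n_genes, 0L)
  expect_equal(s$summary$n_co_introgressing, 0L)
})
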