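test_that("hybrid zone generation is deterministic and bookkeeps truth", {
  cfg <- hybrid_zone_config(n_samples = 60, n_genes = 10, snps_per_gene = 2,
                            cointro_fraction = 0.2)
  hz1 <- generate_hybrid_zone(cfg, seed = 3)
  hz2 <- generate_hybrid_zone(cfg, seed = 3)
  expect_identical(hz1$samples, hz2$samples)
  expect_identical(hz1$ancestry$values, hz2$ancestry$values)
  hz3 <- generate_hybrid_zone(cfg, seed = 4)
  expect_false(identical(hz1$samples$chlorotype, hz3$samples$chlorotype))

  expect_equal(sum(hz1$truth$cointro), 2L)
  expect_equal(length(hz1$truth$gene_centers), 10L)
  expect_equal(unname(hz1$truth$gene_centers[hz1$truth$cointro]),
               rep(cfg$cp_center, 2))
  expect_equal(unname(hz1$truth$gene_centers[!hz1$truth$cointro]),
               rep(cfg$nuc_center, 8))
  expect_equal(nrow(hz1$samples), 60L)
  expect_equal(ncol(hz1$ancestry$values), 20L)
  expect_equal(nrow(hz1$ancestry$values), 120L)
})

test_that("sample geography reproduces the transect after scaling", {
  cfg <- hybrid_zone_config(n_samples = 100)
  hz <- generate_hybrid_zone(cfg, seed = 7)
  tr <- scale_transect(hz$samples)
  # samples sit on a constant-latitude line, so min-max scaled distance
  # recovers the planted transect coordinate up to the slight
  # nonlinearity of great-circle distance across a 10-degree span
  want <- (hz$truth$x - min(hz$truth$x)) / diff(range(hz$truth$x))
  expect_equal(tr$distance_scaled, want, tolerance = 2e-3)
})

test_that("nuclear_q equals the mean haplotype ancestry", {
  cfg <- hybrid_zone_config(n_samples = 30, n_genes = 5, snps_per_gene = 3)
  hz <- generate_hybrid_zone(cfg, seed = 11)
  v <- hz$ancestry$values
  manual <- (rowMeans(v)[seq(1, nrow(v), 2)] +
               rowMeans(v)[seq(2, nrow(v), 2)]) / 2
  expect_equal(hz$samples$nuclear_q, round(unname(manual), 6))
})

test_that("chlorotype frequency transitions across the planted center", {
  cfg <- hybrid_zone_config(n_samples = 400)
  hz <- generate_hybrid_zone(cfg, seed = 13)
  x <- hz$truth$x
  pt <- hz$samples$chlorotype == "PT"
  left <- mean(pt[x < cfg$cp_center - 2 * cfg$cp_width])
  right <- mean(pt[x > cfg$cp_center + 2 * cfg$cp_width])
  expect_lt(left, 0.1)
  expect_gt(right, 0.9)
})

test_that("gene ancestry proportions from the generator are diploid fractions", {
  cfg <- hybrid_zone_config(n_samples = 40, n_genes = 6, snps_per_gene = 4)
  hz <- generate_hybrid_zone(cfg, seed = 17)
  gp <- gene_ancestry_proportions(hz$ancestry, hz$annotations)
  expect_true(all(gp %in% c(0, 0.5, 1)))
  expect_equal(dim(gp), c(40L, 6L))
})

test_that("climate trends have the planted sign and strength", {
  cfg <- hybrid_zone_config(n_samples = 150)
  hz <- generate_hybrid_zone(cfg, seed = 19)
  cl <- generate_climate(list(), seed = 19, sample_table = hz$samples)
  x <- cl$truth$x
  expect_lt(cor(cl$climate$MAT, x), -0.9)
  expect_gt(cor(cl$climate$TD, x), 0.9)
  expect_true(all(cl$climate$RH >= 0 & cl$climate$RH <= 100))
  cl2 <- generate_climate(list(), seed = 19, sample_table = hz$samples)
  expect_identical(cl$climate, cl2$climate)
})

test_that("trait generation is balanced, deterministic and validates", {
  cfg <- hybrid_zone_config(n_samples = 25)
  hz <- generate_hybrid_zone(cfg, seed = 23)
  tr <- generate_traits(list(blocks_per_garden = 2L), seed = 23,
                        sample_table = hz$samples)
  # 25 genotypes x 2 gardens x 2 blocks
  expect_equal(nrow(tr$traits), 100L)
  expect_equal(as.vector(table(tr$traits$garden)), c(50L, 50L))
  tr2 <- generate_traits(list(blocks_per_garden = 2L), seed = 23,
                         sample_table = hz$samples)
  expect_identical(tr$traits, tr2$traits)
  expect_error(generate_traits(list(V_eps = 0), seed = 1,
                               sample_table = hz$samples), "V_eps")
  expect_error(generate_hybrid_zone(hybrid_zone_config(n_samples = 5),
                                    seed = 1), "10")
})

test_that("cp alignment generator plants the requested differences", {
  cp <- generate_cp_alignment(list(genome_length = 1500L, n_cds = 3L,
                                   cds_length = 150L, n_synonymous = 5L,
                                   n_nonsynonymous = 2L, n_noncoding = 4L,
                                   n_polymorphisms = 3L), seed = 9)
  expect_equal(nrow(cp$truth$planted), 11L)
  expect_equal(sum(cp$truth$planted$effect == "nonsynonymous"), 2L)
  expect_equal(nchar(cp$reference), 1500L)
  expect_equal(length(cp$sequences), 8L)
  # planted positions never collide with within-group polymorphisms
  expect_length(intersect(cp$truth$planted$position,
                          cp$truth$polymorphic_positions), 0)
  cp2 <- generate_cp_alignment(list(genome_length = 1500L, n_cds = 3L,
                                    cds_length = 150L, n_synonymous = 5L,
                                    n_nonsynonymous = 2L, n_noncoding = 4L,
                                    n_polymorphisms = 3L), seed = 9)
  expect_identical(cp$sequences, cp2$sequences)
})

test_that("child seeds give independent but reproducible substreams", {
  s1 <- child_seed(42, "a")
  s2 <- child_seed(42, "b")
  expect_false(s1 == s2)
  expect_identical(s1, child_seed(42, "a"))
  a <- with_seed(s1, runif(3))
  b <- with_seed(s1, runif(3))
  expect_identical(a, b)
  # with_seed restores the RNG state of the caller
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(with_seed(99, runif(10))); after <- runif(1)
  expect_identical(before, after)
})
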