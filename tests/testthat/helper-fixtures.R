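# Shared fixture builders; everything is generated in code at test time.

make_sample_df <- function(n = 5, zone = "Cassiar") {
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    contact_zone = zone,
    lat = 55 + seq_len(n) * 0.01,
    lon = -130 + seq_len(n) * 0.5,
    chlorotype = rep(c("PB", "PT"), length.out = n),
    nuclear_q = seq(0, 1, length.out = n),
    genotype_id = sprintf("S%02d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

write_sample_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Simulate bernoulli cline observations at given truth.
sim_cline_bernoulli <- function(n, center, width, seed) {
  withr::with_seed(seed, {
    x <- runif(n)
    y <- rbinom(n, 1, cline_probability(x, cline_spec(center, width)))
    cline_data(x, y, "bernoulli")
  })
}

# Simulate diploid (binomial2) cline observations.
sim_cline_binomial2 <- function(n, center, width, seed) {
  withr::with_seed(seed, {
    x <- runif(n)
    y <- rbinom(n, 2, cline_probability(x, cline_spec(center, width)))
    cline_data(x, y, "binomial2")
  })
}
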