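aln4 <- function(a1, a2, b1, b2, out = NULL) {
  x <- c(A1 = a1, A2 = a2, B1 = b1, B2 = b2)
  if (!is.null(out)) x <- c(x, O1 = out)
  x
}

test_that("fixed differences require within-group monomorphism, clean columns", {
  #            123456789
  aln <- aln4("ACGTACGTA",
              "ACGTACGTA",
              "AGGTACCTA",   # pos 2 C->G fixed, pos 7 G->C fixed
              "AGGTACCTA")
  fd <- find_fixed_differences(aln, c("A1", "A2"), c("B1", "B2"))
  expect_equal(fd$position, c(2L, 7L))
  expect_equal(fd$allele_A, c("C", "G"))
  expect_equal(fd$allele_B, c("G", "C"))

  # polymorphism within a group cancels the call; gaps/ambiguity mask it
  aln2 <- aln4("ACGTACGTA",
               "AAGTACGTA",   # pos 2 polymorphic in A
               "AGGTAC-TA",   # pos 7 gap in B
               "AGGTACCTA")
  fd2 <- find_fixed_differences(aln2, c("A1", "A2"), c("B1", "B2"))
  expect_equal(nrow(fd2), 0L)
  expect_true(7L %in% attr(fd2, "masked_columns"))

  expect_error(find_fixed_differences(aln, c("A1", "A2"), c("A2", "B1")),
               "overlap")
  expect_error(find_fixed_differences(aln, "A1", c("B1", "B2")), ">= 2")
})

test_that("effect classification translates with the plastid code, both strands", {
  # reference: one + strand CDS at 1..6, one - strand CDS at 10..15
  ref <- paste0("AAAGGA", "TAT", "TTTCCC", "T")
  cds <- data.frame(gene_id = c("p", "m"), start = c(1L, 10L),
                    end = c(6L, 15L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  fd <- data.frame(position = c(1L, 6L, 8L, 15L),
                   allele_A = c("A", "A", "A", "C"),
                   allele_B = c("G", "G", "C", "T"),
                   stringsAsFactors = FALSE)
  res <- classify_effect(fd, cds, ref)
  # pos 1: AAA -> GAA, K -> E nonsynonymous
  expect_equal(res$effect[1], "nonsynonymous")
  expect_equal(res$aa_A[1], "K"); expect_equal(res$aa_B[1], "E")
  # pos 6: GGA -> GGG, both glycine (4-fold third position)
  expect_equal(res$effect[2], "synonymous")
  # pos 8: outside both CDS
  expect_equal(res$effect[3], "noncoding")
  expect_true(is.na(res$gene_id[3]))
  # pos 15 on the minus strand is the first codon base read 5'->3'
  expect_equal(res$region[4], "coding")
  expect_equal(res$gene_id[4], "m")
  expect_equal(res$codon_index[4], 1L)
  # verify against manual translation of the reverse complement
  g <- strsplit(ref, "")[[1]]
  span <- 13:15
  ca <- g[span]; cb <- ca; cb[3] <- "T"
  rc <- function(v) rev(c(A = "T", C = "G", G = "C", T = "A")[v])
  code <- Biostrings::getGeneticCode("11")
  expect_equal(res$aa_A[4], unname(code[paste(rc(ca), collapse = "")]))
  expect_equal(res$aa_B[4], unname(code[paste(rc(cb), collapse = "")]))
})

test_that("two fixed differences in one codon are classified jointly", {
  ref <- "TTAGGG"
  cds <- data.frame(gene_id = "g", start = 1L, end = 6L, strand = "+",
                    stringsAsFactors = FALSE)
  # TTA (Leu) -> CTG: site 1 T->C alone is synonymous-ish? CTA is Leu;
  # site 3 A->G alone gives TTG Leu; jointly CTG is still Leu -> synonymous
  fd <- data.frame(position = c(1L, 3L), allele_A = c("T", "A"),
                   allele_B = c("C", "G"), stringsAsFactors = FALSE)
  res <- classify_effect(fd, cds, ref)
  expect_true(all(res$multi_site))
  expect_equal(unique(res$effect), "synonymous")
  expect_equal(unique(res$aa_A), "L")
  expect_equal(unique(res$aa_B), "L")
  # jointly nonsynonymous: TTA (L) -> GCA (A)
  fd2 <- data.frame(position = c(1L, 2L), allele_A = c("T", "T"),
                    allele_B = c("G", "C"), stringsAsFactors = FALSE)
  res2 <- classify_effect(fd2, cds, ref)
  expect_equal(unique(res2$effect), "nonsynonymous")
  # CDS length not a multiple of 3 errors
  bad <- data.frame(gene_id = "g", start = 1L, end = 5L, strand = "+")
  expect_error(classify_effect(fd, bad, ref), "multiple of 3")
})

test_that("planted alignment scan is exact", {
  cp <- generate_cp_alignment(seed = 101)
  ids <- names(cp$sequences)
  fd <- find_fixed_differences(cp$sequences, grep("^PT", ids, value = TRUE),
                               grep("^PB", ids, value = TRUE))
  expect_equal(nrow(fd), 62L)
  res <- classify_effect(fd, cp$cds, cp$reference)
  expect_equal(sum(res$effect == "nonsynonymous"), 9L)
  expect_equal(sum(res$effect == "synonymous"), 30L)
  expect_equal(sum(res$effect == "noncoding"), 23L)
  # site-by-site match against planted truth
  truth <- cp$truth$planted
  m <- merge(res, truth, by = "position", suffixes = c("", ".t"))
  expect_equal(nrow(m), 62L)
  expect_equal(m$effect, m$effect.t)
  expect_equal(m$allele_A, m$allele_A.t)
  expect_equal(m$allele_B, m$allele_B.t)
})

test_that("JC distance matches the closed form and its edge cases", {
  expect_equal(jc_distance("ACGT", "ACGT"), 0)
  # 1 mismatch in 4 sites: p = 0.25
  expect_equal(jc_distance("ACGT", "ACGA"),
               -0.75 * log(1 - 4 / 3 * 0.25), tolerance = 1e-12)
  # ambiguous/gap columns are excluded from the denominator
  expect_equal(jc_distance("ACGTN-", "ACGA??"),
               -0.75 * log(1 - 4 / 3 * 0.25), tolerance = 1e-12)
  expect_error(jc_distance("ACGT", "TGCA"), "0.75")
  expect_error(jc_distance("AC", "ACG"), "unequal")
  expect_error(jc_distance("NN", "AC"), "pairwise-complete")
})

test_that("NJ reconstructs random additive trees exactly", {
  reconstruct_ok <- sapply(1:20, function(s) withr::with_seed(900 + s, {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, rooted = FALSE,
                       br = function(k) runif(k, 0.05, 1))
    true$tip.label <- sort(true$tip.label)
    d <- cophenetic(true)
    est <- nj_tree(d)
    topo_ok <- ape::dist.topo(ape::unroot(true), ape::unroot(est)) == 0
    d_ok <- max(abs(cophenetic(est)[rownames(d), colnames(d)] - d)) < 1e-8
    topo_ok && d_ok
  }))
  expect_true(all(reconstruct_ok))
})

test_that("NJ validates its input and clamps negative branches", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), ">= 3")
  d3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3), "asymmetric")
  # near-degenerate distances can produce negative NJ branches; result
  # must have none, and total tree length must be preserved
  dd <- matrix(c(0, 0.1, 0.11, 0.2,
                 0.1, 0, 0.01, 0.1,
                 0.11, 0.01, 0, 0.1,
                 0.2, 0.1, 0.1, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(as.dist(dd))
  tr <- nj_tree(dd)
  expect_true(all(tr$edge.length >= 0))
  expect_equal(sum(tr$edge.length), sum(raw$edge.length), tolerance = 1e-12)
})

test_that("polarization calls the planted ancestral group", {
  pa <- generate_polarized_alignment(seed = 55)
  ids <- names(pa$sequences)
  res <- polarize(pa$sequences, grep("^A_", ids, value = TRUE),
                  grep("^B_", ids, value = TRUE),
                  grep("^OUT_", ids, value = TRUE))
  expect_equal(res$ancestral_group, pa$truth$ancestral_group)
  expect_match(res$method_note, "monophyletic")
})

test_that("polarization degenerates to unresolved, never to a wrong call", {
  # identical groups carry no signal
  s <- c(A1 = "ACGTACGTAA", A2 = "ACGTACGTAA",
         B1 = "ACGTACGTAA", B2 = "ACGTACGTAA",
         O1 = "ACGAACGTAA", O2 = "ACGAACGTAA")
  res <- polarize(s, c("A1", "A2"), c("B1", "B2"), c("O1", "O2"))
  expect_equal(res$ancestral_group, "unresolved")
  # saturated outgroup
  s2 <- c(A1 = "AAAAAAAA", A2 = "AAAAAAAA",
          B1 = "AAAACCCC", B2 = "AAAACCCC",
          O1 = "GGGGGGGG")
  res2 <- polarize(s2, c("A1", "A2"), c("B1", "B2"), "O1")
  expect_equal(res2$ancestral_group, "unresolved")
  expect_error(polarize(s, c("A1", "A2"), c("B1", "B2"), character(0)),
               "outgroup")
})
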