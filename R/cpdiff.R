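# Chloroplast divergence scan: fixed inter-chlorotype differences from a
# multi-sequence alignment, codon-level effect classification (plastid
# translation table 11), and polarization of substitutions with
# neighbour-joining gene trees on Jukes-Cantor distances.

# Coerce an alignment to a character matrix (sequences x columns).
as_alignment_matrix <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1 &&
      file.exists(alignment)) {
    alignment <- Biostrings::readDNAStringSet(alignment)
  }
  if (inherits(alignment, "DNAStringSet")) {
    m <- as.matrix(alignment)
  } else if (is.matrix(alignment)) {
    m <- alignment
  } else if (is.character(alignment)) {
    if (is.null(names(alignment))) stop_validation("alignment needs sequence names")
    if (length(unique(nchar(alignment))) != 1) {
      stop_validation("alignment sequences have unequal lengths")
    }
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(m) <- names(alignment)
  } else {
    stop_validation("unsupported alignment type")
  }
  toupper(m)
}

#' Find fixed differences between two chlorotype groups
#'
#' A column is a fixed difference when every group-A sequence carries one
#' nucleotide, every group-B sequence carries a different nucleotide, and
#' no sequence in either group carries a gap or ambiguity code there
#' (strict missing-data rule). Indel/ambiguous columns are reported
#' separately via the `"masked_columns"` attribute, not counted.
#'
#' @param alignment Multi-sequence alignment: `DNAStringSet`, named
#'   character vector, character matrix, or FASTA path.
#' @param group_a_ids,group_b_ids Sequence ids of the two chlorotype
#'   groups; disjoint, each with >= 2 sequences.
#' @return `data.frame` with `position` (1-based alignment column),
#'   `allele_A`, `allele_B`.
#' @export
find_fixed_differences <- function(alignment, group_a_ids, group_b_ids) {
  m <- as_alignment_matrix(alignment)
  if (length(intersect(group_a_ids, group_b_ids)) > 0) {
    stop_validation("groups overlap")
  }
  if (length(group_a_ids) < 2 || length(group_b_ids) < 2) {
    stop_validation("each group needs >= 2 sequences")
  }
  missing_ids <- setdiff(c(group_a_ids, group_b_ids), rownames(m))
  if (length(missing_ids) > 0) {
    stop_validation("id(s) not in alignment: %s",
                    paste(missing_ids, collapse = ", "))
  }
  a <- m[group_a_ids, , drop = FALSE]
  b <- m[group_b_ids, , drop = FALSE]
  nuc <- c("A", "C", "G", "T")
  clean <- apply(rbind(a, b), 2, function(col) all(col %in% nuc))
  a_fixed <- apply(a, 2, function(col) length(unique(col)) == 1)
  b_fixed <- apply(b, 2, function(col) length(unique(col)) == 1)
  fixed <- clean & a_fixed & b_fixed & (a[1, ] != b[1, ])
  out <- data.frame(position = which(fixed),
                    allele_A = unname(a[1, fixed]),
                    allele_B = unname(b[1, fixed]),
                    stringsAsFactors = FALSE)
  attr(out, "masked_columns") <- which(!clean)
  out
}

GENETIC_CODE_PLASTID <- Biostrings::getGeneticCode("11")

translate_codon <- function(codon) {
  unname(GENETIC_CODE_PLASTID[paste(codon, collapse = "")])
}

revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[x]))
}

#' Classify coding effects of fixed differences
#'
#' Locates each fixed difference within the CDS annotations, extracts the
#' containing codon from the reference sequence, substitutes the two
#' group alleles (minus-strand codons are reverse-complemented before
#' translation, plastid genetic code, table 11), and calls the
#' substitution synonymous or nonsynonymous. Two or more fixed
#' differences falling in one codon are classified jointly and flagged
#' `multi_site`.
#'
#' @param fixed_diffs Output of [find_fixed_differences()].
#' @param cds_annotations `data.frame` with `gene_id`, `start`, `end`
#'   (1-based inclusive), `strand`; CDS lengths must be multiples of 3.
#' @param reference_sequence The aligned reference the coordinates refer
#'   to (character string or `DNAString`).
#' @return `fixed_diffs` with added columns `region`, `gene_id`,
#'   `codon_index`, `effect` (`synonymous`, `nonsynonymous`,
#'   `noncoding`), `aa_A`, `aa_B`, `multi_site`.
#' @export
classify_effect <- function(fixed_diffs, cds_annotations, reference_sequence) {
  ref <- strsplit(toupper(as.character(reference_sequence)), "")[[1]]
  n <- nrow(fixed_diffs)
  out <- fixed_diffs
  out$region <- "noncoding"
  out$gene_id <- NA_character_
  out$codon_index <- NA_integer_
  out$effect <- "noncoding"
  out$aa_A <- NA_character_
  out$aa_B <- NA_character_
  out$multi_site <- FALSE
  if (n == 0) return(out)

  for (i in seq_len(n)) {
    pos <- out$position[i]
    hit <- which(cds_annotations$start <= pos & cds_annotations$end >= pos)
    if (length(hit) == 0) next
    hit <- hit[1]
    len <- cds_annotations$end[hit] - cds_annotations$start[hit] + 1
    if (len %% 3 != 0) {
      stop_validation("CDS %s length %d is not a multiple of 3",
                      cds_annotations$gene_id[hit], len)
    }
    out$region[i] <- "coding"
    out$gene_id[i] <- cds_annotations$gene_id[hit]
    offset <- if (cds_annotations$strand[hit] == "+") {
      pos - cds_annotations$start[hit]
    } else {
      cds_annotations$end[hit] - pos
    }
    out$codon_index[i] <- offset %/% 3 + 1L
  }

  coding <- which(out$region == "coding")
  for (key in unique(paste(out$gene_id[coding], out$codon_index[coding]))) {
    idx <- coding[paste(out$gene_id[coding], out$codon_index[coding]) == key]
    hit <- match(out$gene_id[idx[1]], cds_annotations$gene_id)
    strand <- cds_annotations$strand[hit]
    ci <- out$codon_index[idx[1]]
    codon_span <- if (strand == "+") {
      cds_annotations$start[hit] + (ci - 1L) * 3L + 0:2
    } else {
      cds_annotations$end[hit] - (ci - 1L) * 3L - 2:0
    }
    codon_a <- codon_b <- ref[codon_span]
    within <- match(out$position[idx], codon_span)
    codon_a[within] <- out$allele_A[idx]
    codon_b[within] <- out$allele_B[idx]
    if (strand == "-") {
      codon_a <- revcomp_chars(codon_a)
      codon_b <- revcomp_chars(codon_b)
    }
    aa_a <- translate_codon(codon_a)
    aa_b <- translate_codon(codon_b)
    out$aa_A[idx] <- aa_a
    out$aa_B[idx] <- aa_b
    out$effect[idx] <- if (identical(aa_a, aa_b)) "synonymous" else "nonsynonymous"
    out$multi_site[idx] <- length(idx) > 1
  }
  out
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' d = -(3/4) ln(1 - (4/3) p-hat), with p-hat the mismatch proportion
#' over pairwise-complete sites (columns where both sequences carry an
#' unambiguous nucleotide).
#'
#' @param seq1,seq2 Equal-length aligned sequences (character strings or
#'   character vectors).
#' @return Substitutions per site.
#' @export
jc_distance <- function(seq1, seq2) {
  s1 <- if (length(seq1) == 1) strsplit(toupper(as.character(seq1)), "")[[1]] else toupper(seq1)
  s2 <- if (length(seq2) == 1) strsplit(toupper(as.character(seq2)), "")[[1]] else toupper(seq2)
  if (length(s1) != length(s2)) stop_validation("sequences have unequal length")
  nuc <- c("A", "C", "G", "T")
  ok <- s1 %in% nuc & s2 %in% nuc
  if (!any(ok)) stop_validation("no pairwise-complete sites")
  p <- mean(s1[ok] != s2[ok])
  if (p >= 0.75) {
    stop_validation("Jukes-Cantor distance undefined: mismatch proportion %.3f >= 0.75", p)
  }
  -3 / 4 * log(1 - 4 / 3 * p)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour-joining agglomeration (via ape) with two
#' conventions for determinism and interpretability: taxa are processed
#' in lexicographic label order, and negative branch lengths are clamped
#' to zero with the deficit transferred to the sister branch.
#'
#' @param distance_matrix Symmetric matrix with zero diagonal.
#' @param taxon_labels Labels; default from the matrix dimnames.
#' @return An unrooted `phylo` tree; use [ape::write.tree()] for newick.
#' @export
nj_tree <- function(distance_matrix, taxon_labels = NULL) {
  d <- as.matrix(distance_matrix)
  if (!is.null(taxon_labels)) dimnames(d) <- list(taxon_labels, taxon_labels)
  if (is.null(rownames(d))) stop_validation("distance matrix needs taxon labels")
  if (nrow(d) < 3) stop_validation("neighbour-joining needs >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop_validation("distance matrix is asymmetric")
  if (max(abs(diag(d))) > 1e-12) stop_validation("distance matrix diagonal must be zero")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tree <- ape::nj(as.dist(d))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    sisters <- setdiff(which(tree$edge[, 1] == tree$edge[e, 1]), e)
    if (length(sisters) > 0) {
      tree$edge.length[sisters[1]] <- tree$edge.length[sisters[1]] + deficit
    }
  }
  tree
}

#' Polarize a substitution with outgroups
#'
#' Builds a neighbour-joining tree from Jukes-Cantor distances over the
#' two chlorotype groups and the outgroups; the ancestral chlorotype is
#' the one that clusters with the outgroups, i.e. the OTHER group forms
#' its own clade relative to the outgroups and the candidate ancestral
#' group is strictly closer to the outgroups on average. Anything short
#' of that (saturated distances, split outgroups, zero divergence) is
#' returned as `unresolved`.
#'
#' @param alignment Aligned sequences (codon or gene scale); any type
#'   accepted by [find_fixed_differences()].
#' @param group_a_ids,group_b_ids Chlorotype group sequence ids.
#' @param outgroup_ids Outgroup sequence ids (>= 1).
#' @return List with `ancestral_group` (`"A"`, `"B"`, or `"unresolved"`)
#'   and `method_note`.
#' @export
polarize <- function(alignment, group_a_ids, group_b_ids, outgroup_ids) {
  if (length(outgroup_ids) < 1) stop_validation("need at least one outgroup")
  m <- as_alignment_matrix(alignment)
  ids <- c(group_a_ids, group_b_ids, outgroup_ids)
  missing_ids <- setdiff(ids, rownames(m))
  if (length(missing_ids) > 0) {
    stop_validation("id(s) not in alignment: %s",
                    paste(missing_ids, collapse = ", "))
  }
  m <- m[ids, , drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- tryCatch(jc_distance(m[i, ], m[j, ]), error = function(e) NA_real_)
      if (is.na(dij)) {
        return(list(ancestral_group = "unresolved",
                    method_note = "saturated or undefined pairwise distance"))
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  da <- mean(d[group_a_ids, outgroup_ids])
  db <- mean(d[group_b_ids, outgroup_ids])
  tree <- tryCatch(nj_tree(d), error = function(e) NULL)
  if (is.null(tree)) {
    return(list(ancestral_group = "unresolved",
                method_note = "tree construction failed"))
  }
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup_ids[1], resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(rooted)) {
    return(list(ancestral_group = "unresolved",
                method_note = "could not root on outgroup"))
  }
  mono_a <- ape::is.monophyletic(rooted, group_a_ids)
  mono_b <- ape::is.monophyletic(rooted, group_b_ids)
  if (mono_b && da < db) {
    list(ancestral_group = "A",
         method_note = sprintf("B monophyletic; mean JC to outgroups A=%.4f < B=%.4f", da, db))
  } else if (mono_a && db < da) {
    list(ancestral_group = "B",
         method_note = sprintf("A monophyletic; mean JC to outgroups B=%.4f < A=%.4f", db, da))
  } else {
    list(ancestral_group = "unresolved",
         method_note = sprintf("no clean grouping (monoA=%s monoB=%s, dA=%.4f dB=%.4f)",
                               mono_a, mono_b, da, db))
  }
}
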