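# Quantitative genetics of cytonuclear effects in the common gardens:
# broad-sense heritability from a genotype + block random-effects model
# per garden, and the cytonuclear trait model with fixed nuclear (N),
# chloroplast (C), N x C interaction and garden effects plus a random
# block-within-garden intercept. REML fits via lme4/lmerTest.

#' Broad-sense heritability from clonal replicates in one garden
#'
#' Fits `value ~ (1 | genotype) + (1 | block)` by REML within a garden
#' and computes H2 = V_G / (V_G + V_E + V_eps), the fraction of
#' phenotypic variance attributable to total genotypic variance among
#' clones.
#'
#' @param trait_records Trait table (see [read_trait_table()]).
#' @param garden Garden to analyse (`"VT"` or `"VA"`).
#' @param trait_name Trait to analyse; `NULL` allowed only when the table
#'   holds a single trait.
#' @return A `variance_components` object: `V_G`, `V_E`, `V_eps`, `H2`,
#'   `boundary` (TRUE when a variance component was estimated at its
#'   zero bound), `n_genotypes`, `n_obs`.
#' @export
estimate_h2 <- function(trait_records, garden, trait_name = NULL) {
  df <- trait_records[trait_records$garden == garden, , drop = FALSE]
  if (!is.null(trait_name)) {
    df <- df[df$trait_name == trait_name, , drop = FALSE]
  } else if (length(unique(df$trait_name)) > 1) {
    stop_validation("multiple traits present; give trait_name")
  }
  df <- df[!is.na(df$value), , drop = FALSE]
  if (length(unique(df$genotype_id)) < 2) {
    stop_validation("need at least 2 genotypes to estimate H2")
  }
  if (var(df$value) == 0) {
    stop_validation("trait has zero variance; H2 undefined")
  }
  fit <- suppressMessages(lme4::lmer(
    value ~ 1 + (1 | genotype_id) + (1 | block), data = df, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_g <- vc$vcov[vc$grp == "genotype_id"]
  v_e <- vc$vcov[vc$grp == "block"]
  v_eps <- vc$vcov[vc$grp == "Residual"]
  h2 <- v_g / (v_g + v_e + v_eps)
  structure(
    list(V_G = v_g, V_E = v_e, V_eps = v_eps, H2 = h2,
         boundary = any(c(v_g, v_e) < 1e-8),
         n_genotypes = length(unique(df$genotype_id)), n_obs = nrow(df),
         garden = garden, trait_name = trait_name),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> V_G=%.4f V_E=%.4f V_eps=%.4f  H2=%.3f%s\n",
    x$V_G, x$V_E, x$V_eps, x$H2,
    if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Cytonuclear interaction trait model
#'
#' Fits the mixed model
#' `value ~ N + C + N:C + garden + (1 | garden:block)` by REML, where N
#' is continuous P. trichocarpa nuclear ancestry in \[0, 1\] and C is the
#' chlorotype coded 0 (PB) / 1 (PT). Reports Wald (Satterthwaite) tests
#' per fixed effect and marginal/conditional R-squared, where the
#' marginal value is the variance explained by fixed effects alone and
#' the conditional value additionally includes the block variance.
#' Rows with chlorotype `OTHER`/`MISSING` or missing ancestry are
#' excluded (count reported in the result).
#'
#' @param trait_records Trait table (see [read_trait_table()]), one trait.
#' @param sample_ancestry `data.frame` with `genotype_id`, `nuclear_q`,
#'   `chlorotype`.
#' @param trait_name Trait to model; `NULL` allowed for single-trait
#'   tables.
#' @param full_model If `TRUE`, also includes C x garden and the
#'   three-way N x C x garden interaction.
#' @return A `cytonuclear_fit` object: `beta_N`, `beta_C`, `beta_NxC`,
#'   `beta_E`, `wald_p`, `V_block`, `V_eps`, `r2_marginal`,
#'   `r2_conditional`, `n_obs`, `n_excluded`.
#' @export
fit_cytonuclear <- function(trait_records, sample_ancestry,
                            trait_name = NULL, full_model = FALSE) {
  df <- trait_records
  if (!is.null(trait_name)) {
    df <- df[df$trait_name == trait_name, , drop = FALSE]
  } else if (length(unique(df$trait_name)) > 1) {
    stop_validation("multiple traits present; give trait_name")
  }
  df <- merge(df, sample_ancestry[c("genotype_id", "nuclear_q", "chlorotype")],
              by = "genotype_id")
  n0 <- nrow(df)
  df <- df[df$chlorotype %in% c("PB", "PT") & !is.na(df$nuclear_q) &
             !is.na(df$value), , drop = FALSE]
  n_excluded <- n0 - nrow(df)
  if (length(unique(df$chlorotype)) < 2) {
    stop_validation("chlorotype is constant after filtering; C effect inestimable")
  }
  df$C <- as.numeric(df$chlorotype == "PT")
  df$N <- df$nuclear_q
  df$garden <- factor(df$garden)
  df$block_in_garden <- interaction(df$garden, df$block, drop = TRUE)

  fixed <- if (full_model) value ~ N * C * garden else value ~ N * C + garden
  X <- stats::model.matrix(fixed, df)

  # Exact-interpolation data (residual variance ~ 0) cannot be fitted by
  # REML; fall back to the fixed-effects least-squares solution.
  ls_fit <- stats::lm.fit(X, df$value)
  if (var(ls_fit$residuals) < 1e-16 * max(var(df$value), 1)) {
    beta <- ls_fit$coefficients
    v_fixed <- var(drop(X %*% beta))
    v_eps <- var(ls_fit$residuals)
    wald_p <- setNames(rep(NA_real_, length(beta)), names(beta))
    r2_den <- v_fixed + v_eps
    return(new_cytonuclear_fit(beta, wald_p, V_block = 0, V_eps = v_eps,
                               r2_marginal = v_fixed / r2_den,
                               r2_conditional = v_fixed / r2_den,
                               n_obs = nrow(df), n_excluded = n_excluded,
                               fit = NULL))
  }

  form <- stats::update(fixed, . ~ . + (1 | block_in_garden))
  fit <- suppressMessages(lmerTest::lmer(form, data = df, REML = TRUE))
  sm <- stats::coef(summary(fit))
  beta <- sm[, "Estimate"]
  wald_p <- sm[, "Pr(>|t|)"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_block <- vc$vcov[vc$grp == "block_in_garden"]
  v_eps <- vc$vcov[vc$grp == "Residual"]
  v_fixed <- var(drop(X %*% beta))
  den <- v_fixed + v_block + v_eps
  new_cytonuclear_fit(beta, wald_p, V_block = v_block, V_eps = v_eps,
                      r2_marginal = v_fixed / den,
                      r2_conditional = (v_fixed + v_block) / den,
                      n_obs = nrow(df), n_excluded = n_excluded, fit = fit)
}

new_cytonuclear_fit <- function(beta, wald_p, V_block, V_eps, r2_marginal,
                                r2_conditional, n_obs, n_excluded, fit) {
  garden_terms <- grep("^garden", names(beta), value = TRUE)
  structure(
    list(beta_N = unname(beta["N"]),
         beta_C = unname(beta["C"]),
         beta_NxC = unname(beta["N:C"]),
         beta_E = if (length(garden_terms)) unname(beta[garden_terms[1]]) else NA_real_,
         coefficients = beta, wald_p = wald_p,
         V_block = V_block, V_eps = V_eps,
         r2_marginal = r2_marginal, r2_conditional = r2_conditional,
         n_obs = n_obs, n_excluded = n_excluded, fit = fit),
    class = "cytonuclear_fit"
  )
}

#' @export
print.cytonuclear_fit <- function(x, ...) {
  cat(sprintf(
    "<cytonuclear_fit> beta_N=%.4f beta_C=%.4f beta_NxC=%.4f beta_E=%.4f\n",
    x$beta_N, x$beta_C, x$beta_NxC, x$beta_E))
  cat(sprintf("  V_block=%.4f V_eps=%.4f  R2 marginal=%.3f conditional=%.3f (n=%d)\n",
              x$V_block, x$V_eps, x$r2_marginal, x$r2_conditional, x$n_obs))
  invisible(x)
}
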