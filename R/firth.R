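# Firth bias-reduced logistic regression, the association model used to
# relate chlorotype to climate gradients. The penalized log-likelihood
#   l*(beta) = l(beta) + 1/2 log det I(beta)
# has a finite maximizer even under complete separation; it is maximized
# by Newton steps on the modified score
#   U*(beta) = X' (y - p + h (1/2 - p)),
# where h are the hat values of the weighted design.

#' Firth penalized-likelihood logistic regression
#'
#' @param design Numeric design matrix including an intercept column.
#' @param response Binary 0/1 response vector.
#' @param tol Convergence tolerance on the modified score (max absolute
#'   component).
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `firth_fit`: `coefficients`,
#'   `standard_errors` (Wald, from the inverse penalized information),
#'   `penalized_loglik`, `n_iter`, `converged`, and `trace` (the
#'   penalized log-likelihood after each accepted step).
#' @export
firth_fit <- function(design, response, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  if (!all(y %in% c(0, 1))) stop_validation("response must be binary 0/1")
  if (nrow(X) != length(y)) stop_validation("design/response length mismatch")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_validation("design matrix is rank deficient; dependent column(s): %s",
                    paste(dep, collapse = ", "))
  }
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)) - 1L)
  }

  pen_ll <- function(beta) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    info <- crossprod(X * (p * (1 - p)), X)
    sum(y * log(p) + (1 - y) * log(1 - p)) +
      0.5 * determinant(info, logarithm = TRUE)$modulus[1]
  }

  beta <- rep(0, ncol(X))
  ll <- pen_ll(beta)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- stats::plogis(drop(X %*% beta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    w <- p * (1 - p)
    info <- crossprod(X * w, X)
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * X) * w
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    step <- drop(info_inv %*% score)
    new_ll <- pen_ll(beta + step)
    halvings <- 0L
    while (new_ll < ll && halvings < 5L) {  # step-halving on non-increase
      step <- step / 2
      new_ll <- pen_ll(beta + step)
      halvings <- halvings + 1L
    }
    beta <- beta + step
    ll <- new_ll
    trace <- c(trace, ll)
  }
  p <- stats::plogis(drop(X %*% beta))
  info <- crossprod(X * (p * (1 - p)), X)
  se <- sqrt(diag(solve(info)))
  structure(
    list(coefficients = setNames(drop(beta), colnames(X)),
         standard_errors = setNames(se, colnames(X)),
         penalized_loglik = ll, n_iter = iter, converged = converged,
         trace = trace),
    class = "firth_fit"
  )
}

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf("<firth_fit> penalized logLik = %.4f (%d iterations%s)\n",
              x$penalized_loglik, x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  print(data.frame(estimate = x$coefficients, se = x$standard_errors))
  invisible(x)
}

#' Per-zone, per-variable chlorotype-climate association scan
#'
#' For every contact zone and climate variable, fits a univariate Firth
#' logistic regression of chlorotype (PT = 1, PB = 0; other chlorotypes
#' excluded) on the variable in its natural units, so slopes read as
#' log-odds per degree C, per %, or per mm.
#'
#' @param samples Sample table (see [read_sample_table()]).
#' @param climate Climate table (see [read_climate_table()]).
#' @param zones Contact zones to scan; `NULL` means all present.
#' @param variables Climate variables to test.
#' @param min_n Minimum samples per zone after chlorotype filtering.
#' @return `data.frame` with `contact_zone`, `variable`, `n`, `slope`,
#'   `se`, `p_value`, `converged`, `status` (`ok`, `monomorphic`,
#'   `too_few`, or `rank_deficient`).
#' @export
climate_scan <- function(samples, climate, zones = NULL,
                         variables = c("TD", "MAT", "MAP", "CMD", "RH", "PAS"),
                         min_n = 5L) {
  df <- merge(samples, climate, by = "sample_id")
  df <- df[df$chlorotype %in% c("PB", "PT"), , drop = FALSE]
  if (is.null(zones)) zones <- sort(unique(df$contact_zone))
  rows <- list()
  for (z in zones) {
    dz <- df[df$contact_zone == z, , drop = FALSE]
    y <- as.numeric(dz$chlorotype == "PT")
    for (v in variables) {
      keep <- !is.na(dz[[v]])
      n <- sum(keep)
      row <- data.frame(contact_zone = z, variable = v, n = n,
                        slope = NA_real_, se = NA_real_, p_value = NA_real_,
                        converged = NA, status = "ok",
                        stringsAsFactors = FALSE)
      if (n < min_n) {
        row$status <- "too_few"
      } else if (length(unique(y[keep])) < 2) {
        row$status <- "monomorphic"
      } else if (sd(dz[[v]][keep]) == 0) {
        row$status <- "rank_deficient"
      } else {
        X <- cbind(`(Intercept)` = 1, dz[[v]][keep])
        colnames(X)[2] <- v
        fit <- tryCatch(firth_fit(X, y[keep]), error = function(e) NULL)
        if (is.null(fit)) {
          row$status <- "rank_deficient"
        } else {
          z_stat <- fit$coefficients[2] / fit$standard_errors[2]
          row$slope <- unname(fit$coefficients[2])
          row$se <- unname(fit$standard_errors[2])
          row$p_value <- 2 * stats::pnorm(-abs(z_stat))
          row$converged <- fit$converged
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
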