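# The geographic cline model family: a tanh sigmoid with optional
# exponential introgression tails and optional frequency scaling.
#
#   Psi_sig(x) = (1 + tanh(2 (x - c) / w)) / 2
#   left tail (x < c - dL):  Psi(x) = Psi_sig(c - dL) * exp(4 tL (x - (c - dL)) / w)
#   right tail (x > c + dR): Psi(x) = 1 - (1 - Psi_sig(c + dR)) * exp(-4 tR (x - (c + dR)) / w)
#   p(x) = pmin + (pmax - pmin) * Psi(x)
#
# The width w is 1 / maximum slope of Psi, so for an unscaled tail-less
# cline the slope at the center is exactly 1/w.

SCALING_LEVELS <- c("none", "fixed", "free")
TAIL_LEVELS <- c("none", "left", "right", "mirror", "both")

#' Specify a geographic cline model
#'
#' @param center Cline center c, the scaled transect position where the
#'   sigmoid crosses its midpoint; in (0, 1).
#' @param width Cline width w > 0, the inverse of the maximum slope.
#' @param scaling `"none"` (pmin = 0, pmax = 1), `"fixed"` (end
#'   frequencies taken from the data, not estimated), or `"free"`
#'   (pmin/pmax estimated).
#' @param tails Which exponential tails are present: `"none"`, `"left"`,
#'   `"right"`, `"mirror"` (both sides, shared delta/tau), `"both"`
#'   (both sides, independent).
#' @param pmin,pmax End frequencies in \[0, 1\] with pmin < pmax.
#' @param delta_l,delta_r Tail offsets (distance from the center at which
#'   each tail takes over), >= 0.
#' @param tau_l,tau_r Tail decay rates in (0, 1\].
#' @return An object of class `cline_spec`.
#' @export
cline_spec <- function(center, width, scaling = "none", tails = "none",
                       pmin = 0, pmax = 1,
                       delta_l = 0, tau_l = 1, delta_r = 0, tau_r = 1) {
  scaling <- match.arg(scaling, SCALING_LEVELS)
  tails <- match.arg(tails, TAIL_LEVELS)
  if (center <= 0 || center >= 1) stop_validation("center must be in (0, 1)")
  if (width <= 0) stop_validation("width must be > 0")
  if (scaling == "none") {
    pmin <- 0; pmax <- 1
  }
  if (pmin < 0 || pmax > 1 || pmin >= pmax) {
    stop_validation("need 0 <= pmin < pmax <= 1")
  }
  if (tails == "mirror") {
    delta_r <- delta_l
    tau_r <- tau_l
  }
  if (delta_l < 0 || delta_r < 0) stop_validation("tail offsets must be >= 0")
  if (tau_l <= 0 || tau_l > 1 || tau_r <= 0 || tau_r > 1) {
    stop_validation("tail rates must be in (0, 1]")
  }
  structure(
    list(center = center, width = width, scaling = scaling, tails = tails,
         pmin = pmin, pmax = pmax, delta_l = delta_l, tau_l = tau_l,
         delta_r = delta_r, tau_r = tau_r),
    class = "cline_spec"
  )
}

# Number of estimated parameters for AIC.
n_params <- function(spec) {
  2L + (if (spec$scaling == "free") 2L else 0L) +
    switch(spec$tails, none = 0L, left = 2L, right = 2L, mirror = 2L, both = 4L)
}

#' Evaluate the cline ancestry probability
#'
#' @param x Scaled transect positions.
#' @param spec A [cline_spec()].
#' @return p(x) in \[pmin, pmax\], continuous and non-decreasing.
#' @export
cline_probability <- function(x, spec) {
  ctr <- spec$center; w <- spec$width
  psi_sig <- function(z) (1 + tanh(2 * (z - ctr) / w)) / 2
  psi <- psi_sig(x)
  has_left <- spec$tails %in% c("left", "mirror", "both")
  has_right <- spec$tails %in% c("right", "mirror", "both")
  if (has_left) {
    jl <- ctr - spec$delta_l
    i <- x < jl
    psi[i] <- psi_sig(jl) * exp(4 * spec$tau_l * (x[i] - jl) / w)
  }
  if (has_right) {
    jr <- ctr + spec$delta_r
    i <- x > jr
    psi[i] <- 1 - (1 - psi_sig(jr)) * exp(-4 * spec$tau_r * (x[i] - jr) / w)
  }
  spec$pmin + (spec$pmax - spec$pmin) * psi
}

#' Bundle observations for cline fitting
#'
#' @param x Scaled transect positions in \[0, 1\].
#' @param y Observations: binary 0/1 (`"bernoulli"`, e.g. chlorotype),
#'   diploid ancestry counts 0/1/2 (`"binomial2"`), or continuous mean
#'   ancestry in \[0, 1\] (`"gaussian"`).
#' @param likelihood_kind One of `"bernoulli"`, `"binomial2"`, `"gaussian"`.
#' @return An object of class `cline_data`.
#' @export
cline_data <- function(x, y, likelihood_kind = c("bernoulli", "binomial2",
                                                 "gaussian")) {
  likelihood_kind <- match.arg(likelihood_kind)
  if (length(x) != length(y)) stop_validation("x and y lengths differ")
  if (length(x) == 0) stop_validation("empty cline data")
  ok <- switch(likelihood_kind,
               bernoulli = all(y %in% c(0, 1)),
               binomial2 = all(y %in% c(0, 1, 2)),
               gaussian = all(y >= 0 & y <= 1))
  if (!ok) stop_validation("y inconsistent with likelihood_kind '%s'",
                           likelihood_kind)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 likelihood_kind = likelihood_kind),
            class = "cline_data")
}

#' Cline model log-likelihood
#'
#' Bernoulli and binomial likelihoods clamp p to \[1e-9, 1 - 1e-9\] before
#' taking logs; the gaussian residual variance is profiled out analytically.
#'
#' @param data A [cline_data()].
#' @param spec A [cline_spec()].
#' @return The log-likelihood at `spec`.
#' @export
cline_loglik <- function(data, spec) {
  p <- cline_probability(data$x, spec)
  y <- data$y
  switch(data$likelihood_kind,
    bernoulli = {
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      sum(y * log(p) + (1 - y) * log(1 - p))
    },
    binomial2 = {
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      sum(log(choose(2, y)) + y * log(p) + (2 - y) * log(1 - p))
    },
    gaussian = {
      n <- length(y)
      s2 <- mean((y - p)^2)
      s2 <- max(s2, 1e-12)
      -n / 2 * (log(2 * pi * s2) + 1)
    })
}

#' @export
print.cline_spec <- function(x, ...) {
  cat(sprintf("<cline_spec> center=%.4f width=%.4f scaling=%s tails=%s\n",
              x$center, x$width, x$scaling, x$tails))
  if (x$scaling != "none") {
    cat(sprintf("  pmin=%.4f pmax=%.4f\n", x$pmin, x$pmax))
  }
  if (x$tails != "none") {
    cat(sprintf("  delta_l=%.4f tau_l=%.4f delta_r=%.4f tau_r=%.4f\n",
                x$delta_l, x$tau_l, x$delta_r, x$tau_r))
  }
  invisible(x)
}
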