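#' Quantile-based knot placement
#'
#' Places K knots at the j/(K+1) empirical quantiles of `x`, j = 1..K — the
#' standard default for penalized mixed-model splines. Knots must be strictly
#' increasing; exact ties between quantiles (possible with heavily discrete
#' covariates) are separated by a deterministic machine-scale perturbation.
#'
#' @param x Numeric covariate values.
#' @param K Number of knots (>= 1).
#' @return Strictly increasing numeric vector of length K.
#' @export
spline_knots <- function(x, K) {
  x <- x[!is.na(x)]
  if (K < 1L) abort("'K' must be at least 1")
  if (length(unique(x)) <= K) {
    abort("too few distinct values to place knots", class = "multipoll_degenerate_error")
  }
  kn <- quantile(x, probs = seq_len(K) / (K + 1), names = FALSE, type = 7)
  if (any(diff(kn) <= 0)) {
    eps <- max(abs(kn), 1) * .Machine$double.eps^0.5
    kn <- kn + seq_len(K) * eps  # deterministic tie-break
    if (any(diff(kn) <= 0)) abort("could not separate tied knots")
  }
  kn
}

#' Low-rank thin-plate spline specification
#'
#' A smooth term s(x) = alpha * x + sum_k b_k |x - kappa_k|^3 with radial
#' cubic basis functions at fixed knots. The basis coefficients `b` are
#' penalized (shrunk to zero) through a common precision with a Gamma
#' hyperprior, giving the mixed-model representation of a penalized spline.
#'
#' @param name Label for the smoothed covariate (for example `"time"`).
#' @param knots Strictly increasing knot locations.
#' @param alpha Linear coefficient (default 0).
#' @param b Basis coefficients, one per knot (default all 0).
#' @param smooth_precision Positive prior precision scale for `b` (default 1).
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(name, knots, alpha = 0, b = numeric(length(knots)),
                        smooth_precision = 1) {
  knots <- as.numeric(knots)
  if (is.unsorted(knots, strictly = TRUE)) abort("'knots' must be strictly increasing")
  if (length(b) != length(knots)) abort("'b' must have one entry per knot")
  if (smooth_precision <= 0) abort("'smooth_precision' must be positive")
  structure(list(name = name, knots = knots, alpha = alpha, b = as.numeric(b),
                 smooth_precision = smooth_precision),
            class = "spline_spec")
}

#' Evaluate a thin-plate spline term
#'
#' @param spec A [spline_spec()].
#' @param x Numeric values at which to evaluate.
#' @return Numeric vector s(x) = alpha * x + sum_k b_k |x - kappa_k|^3.
#' @export
spline_eval <- function(spec, x) {
  drop(spec$alpha * x + tps_basis(x, spec$knots) %*% spec$b)
}

# Radial cubic basis |x - kappa|^3, one column per knot.
tps_basis <- function(x, knots) {
  abs(outer(x, knots, `-`))^3
}

# Centered basis for model fitting: each column has sample mean zero so the
# smooth term is identifiable next to the model intercept.
tps_basis_centered <- function(x, knots) {
  Z <- tps_basis(x, knots)
  sweep(Z, 2, colMeans(Z), `-`)
}
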