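#' Continuous dose-response model families
#'
#' The pipeline models the median fold induction at concentration `x` as
#' \deqn{\mu(x) = a \, [1 + (c - 1) F(x; b, d)]}
#' where `a > 0` is the background response (fold induction of the solvent
#' control, close to 1), `c > 1` is the maximum fold change over background
#' (so the plateau is `a c`), `b > 0` sets the concentration scale and
#' `d > 0` the steepness. `F` is a family-specific saturating function with
#' `F(0) = 0`, `F(Inf) = 1`, strictly increasing, so every family rises from
#' `a` to `a c`.
#'
#' The eight families and their `F`:
#' \describe{
#'   \item{exponential}{`1 - exp(-(x/b)^d)`}
#'   \item{inv_exponential}{`exp(-(x/b)^-d)`}
#'   \item{hill}{`x^d / (b^d + x^d)` (log-logistic)}
#'   \item{lognormal}{`pnorm(d * log(x/b))`}
#'   \item{gamma}{`pgamma(x/b, shape = d)` (regularised incomplete gamma)}
#'   \item{quad_exponential}{`1 - exp(-(x/b) - d (x/b)^2)`}
#'   \item{probit}{normal CDF in `x`, truncated so that `F(0) = 0`:
#'     `(pnorm(d (x - b)) - pnorm(-d b)) / (1 - pnorm(-d b))`}
#'   \item{logit}{as probit with the logistic CDF}
#' }
#'
#' The first six depend on the concentration only through `x/b` (scale
#' families); probit and logit are location-scale in `x` and truncated at
#' zero dose.
#'
#' @return `drc_families()` returns the character vector of family names.
#' @export
drc_families <- function() {
  c("exponential", "inv_exponential", "hill", "lognormal",
    "gamma", "quad_exponential", "probit", "logit")
}

# F(x; b, d) for each family; vectorized in x. All return 0 at x = 0.
.fam_F <- function(family) {
  switch(family,
    exponential      = function(x, b, d) 1 - exp(-(x / b)^d),
    inv_exponential  = function(x, b, d) ifelse(x <= 0, 0, exp(-(x / b)^(-d))),
    hill             = function(x, b, d) x^d / (b^d + x^d),
    lognormal        = function(x, b, d) ifelse(x <= 0, 0, stats::pnorm(d * log(x / b))),
    gamma            = function(x, b, d) stats::pgamma(x / b, shape = d),
    quad_exponential = function(x, b, d) 1 - exp(-(x / b) - d * (x / b)^2),
    probit           = function(x, b, d) {
      F0 <- stats::pnorm(-d * b)
      (stats::pnorm(d * (x - b)) - F0) / (1 - F0)
    },
    logit            = function(x, b, d) {
      F0 <- stats::plogis(-d * b)
      (stats::plogis(d * (x - b)) - F0) / (1 - F0)
    },
    stop("unknown dose-response family: ", family)
  )
}

# Inverse of F at level t in (0,1): the unique x with F(x) = t, closed form.
.fam_Finv <- function(family) {
  switch(family,
    exponential      = function(t, b, d) b * (-log(1 - t))^(1 / d),
    inv_exponential  = function(t, b, d) b * (-log(t))^(-1 / d),
    hill             = function(t, b, d) b * (t / (1 - t))^(1 / d),
    lognormal        = function(t, b, d) b * exp(stats::qnorm(t) / d),
    gamma            = function(t, b, d) b * stats::qgamma(t, shape = d),
    quad_exponential = function(t, b, d) {
      # solve d u^2 + u + log(1 - t) = 0 for u = x/b, positive root
      b * (-1 + sqrt(1 - 4 * d * log(1 - t))) / (2 * d)
    },
    probit           = function(t, b, d) {
      F0 <- stats::pnorm(-d * b)
      b + stats::qnorm(t * (1 - F0) + F0) / d
    },
    logit            = function(t, b, d) {
      F0 <- stats::plogis(-d * b)
      b + stats::qlogis(t * (1 - F0) + F0) / d
    },
    stop("unknown dose-response family: ", family)
  )
}

#' Median response of a dose-response candidate
#'
#' @param family one of [drc_families()].
#' @param x concentration vector (same units as `b`, conventionally uM).
#' @param a background response at dose 0.
#' @param b concentration-scale parameter (> 0).
#' @param c maximum fold change over background (> 1).
#' @param d steepness parameter (> 0).
#' @return vector of median responses.
#' @export
drc_median <- function(family, x, a, b, c, d) {
  stopifnot(a > 0, b > 0, c > 1, d > 0, all(x >= 0))
  a * (1 + (c - 1) * .fam_F(family)(x, b, d))
}

#' Benchmark dose of a model candidate by root finding
#'
#' Finds the smallest concentration at which the candidate's median response
#' equals `bmr` times its background response, i.e. solves
#' `mu(x) = bmr * mu(0)`. The root is located numerically (bracket expansion
#' followed by [stats::uniroot()]) to a relative tolerance of 1e-8, so the
#' same code path serves every family. Returns `NA_real_` (not reached) when
#' the plateau fold change `c` does not exceed `bmr`.
#'
#' @param candidate list with elements `family` and `parameters`
#'   (named `a`, `b`, `c`, `d`; a noise sd `sigma` may be present and is
#'   ignored here).
#' @param bmr benchmark response as a ratio to background (default 1.5).
#' @return concentration at the benchmark response, or `NA_real_`.
#' @export
bmd_from_params <- function(candidate, bmr = 1.5) {
  stopifnot(bmr > 1)
  p <- as.list(candidate$parameters)
  if (p$c <= bmr) return(NA_real_)
  t <- (bmr - 1) / (p$c - 1)
  Ff <- .fam_F(candidate$family)
  g <- function(x) Ff(x, p$b, p$d) - t
  # bracket: expand upper bound geometrically from the scale parameter
  lo <- 0
  hi <- p$b
  for (i in 1:200) {
    if (g(hi) > 0) break
    hi <- hi * 2
  }
  if (g(hi) <= 0) return(NA_real_)
  r <- stats::uniroot(g, c(lo, hi), tol = .Machine$double.eps^0.5)
  # polish to relative tolerance 1e-8
  stats::uniroot(g, c(max(0, r$root * (1 - 1e-4)), r$root * (1 + 1e-4)),
                 tol = r$root * 1e-10)$root
}

# Closed-form BMD used for per-draw evaluation inside the MCMC (vectorized
# over parameter draws; must agree with bmd_from_params, which is tested).
.bmd_closed <- function(family, a, b, c, d, bmr) {
  t <- (bmr - 1) / (c - 1)
  out <- rep(NA_real_, length(b))
  ok <- c > bmr
  if (any(ok)) {
    fi <- .fam_Finv(family)
    out[ok] <- fi(t[ok], b[ok], d[ok])
  }
  out[!is.finite(out) | out < 0] <- NA_real_
  out
}

# Solve the scale parameter b so that the curve passes through
# mu(true_bmd) = bmr * a given d (used by the simulator).
.b_for_bmd <- function(family, true_bmd, t, d) {
  if (family %in% c("probit", "logit")) {
    Ff <- .fam_F(family)
    g <- function(b) Ff(true_bmd, b, d) - t
    # F is decreasing in b; bracket
    lo <- true_bmd * 1e-6
    hi <- true_bmd
    while (g(hi) > 0) hi <- hi * 2
    stats::uniroot(g, c(lo, hi), tol = true_bmd * 1e-12)$root
  } else {
    # scale family: F(x) = F0(x / b), so b = true_bmd / F0^{-1}(t)
    u <- .fam_Finv(family)(t, 1, d)
    true_bmd / u
  }
}
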