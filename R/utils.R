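## Shared numerical helpers.

## Gas constant in kcal/(mol*K); used for all free-energy <-> fold-change
## conversions (exp(ddG/RT)).
RGAS <- 1.9872e-3

#' Gas constant used by the package
#'
#' Returns the molar gas constant in kcal/(mol K) used for every
#' free-energy to affinity conversion in the package.
#'
#' @return Numeric scalar, 1.9872e-3 kcal/(mol K).
#' @export
gasConstantKcal <- function() RGAS

## log(sum(exp(x))) with overflow protection.
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a per-stream sub-seed from a global seed
#'
#' Every stochastic generator in the package draws from its own stream,
#' seeded by a deterministic hash of the global seed and a stream label.
#' Adding a new generator therefore never perturbs the draws of an
#' existing one.
#'
#' @param seed Integer global seed.
#' @param stream Character label of the random stream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
subSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(paste(stream, collapse = "/"))) {
    h <- (h * 31 + ch) %% 1000000007
  }
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147483646) + 1L
}

## Trapezoidal integral of (times, values) over [t0, t1], with linear
## interpolation at off-grid endpoints.  Irregular spacing (e.g. instrument
## gaps) is handled naturally: the trapezoid across a gap IS the linear
## interpolation across it.
trapzWindow <- function(times, values, t0, t1) {
  if (t1 < t0) stop("integration window has t1 < t0")
  eps <- sqrt(.Machine$double.eps) * max(1, abs(t1))
  if (t0 < min(times) - eps || t1 > max(times) + eps) {
    stop(sprintf("window [%g, %g] outside trace support [%g, %g]",
                 t0, t1, min(times), max(times)))
  }
  if (t1 == t0) return(0)
  inner <- times > t0 & times < t1
  tt <- c(t0, times[inner], t1)
  vv <- c(stats::approx(times, values, xout = t0, rule = 2)$y,
          values[inner],
          stats::approx(times, values, xout = t1, rule = 2)$y)
  pracma::trapz(tt, vv)
}

## Linear interpolation of the time at which a series crosses `level`
## between samples i and i+1.
crossingTime <- function(t1, v1, t2, v2, level) {
  if (v2 == v1) return((t1 + t2) / 2)
  t1 + (level - v1) * (t2 - t1) / (v2 - v1)
}
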