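#' Random draw source used by the optimizer operators
#'
#' Every stochastic operator takes an \code{rng} argument: a list with
#' functions \code{unif(n)} (i.i.d. Uniform(0,1)) and \code{norm(n)}
#' (i.i.d. standard normal). The default draws from R's global RNG, so a
#' single \code{set.seed()} makes a whole run reproducible. Supplying a
#' custom source lets callers replay a recorded draw sequence through an
#' operator (each operator documents its draw order) or probe edge cases
#' with adversarial draws.
#'
#' @return list with elements \code{unif} and \code{norm}.
#' @examples
#' set.seed(1)
#' rng <- defaultRNG()
#' rng$unif(3)
#' @export
defaultRNG <- function() {
    list(unif = function(n = 1L) stats::runif(n),
         norm = function(n = 1L) stats::rnorm(n))
}

# one index uniform on 1..n
sampleIndex <- function(rng, n) {
    min(n, 1L + floor(rng$unif(1L) * n))
}

# one index uniform on 1..n excluding `excl`
sampleIndexExcluding <- function(rng, n, excl) {
    if (n < 2L) stop("cannot draw an index distinct from ", excl,
                     " out of ", n)
    j <- min(n - 1L, 1L + floor(rng$unif(1L) * (n - 1L)))
    if (j >= excl) j + 1L else j
}

clip01 <- function(x) pmin(1, pmax(0, x))

# round half away from zero (for positive inputs: floor(x + 0.5))
roundHalfUp <- function(x) floor(x + 0.5)
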