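#' Heavy-tailed Levy flight steps (Mantegna algorithm)
#'
#' Draws approximately Levy-stable step sizes with stability exponent
#' \code{exponent} via Mantegna's method: \eqn{u/|v|^{1/\beta}} with
#' \eqn{u \sim N(0,\sigma_u^2)}, \eqn{v \sim N(0,1)} and
#' \deqn{\sigma_u = \left[\frac{\Gamma(1+\beta)\sin(\pi\beta/2)}
#'   {\Gamma((1+\beta)/2)\,\beta\,2^{(\beta-1)/2}}\right]^{1/\beta}.}
#' The resulting distribution mixes many small adjustments with occasional
#' large jumps, which the optimizer uses to escape stagnation.
#'
#' Draw order: \code{n} normals for \eqn{u}, then \code{n} normals for
#' \eqn{v}.
#'
#' @param n number of steps (0 gives an empty vector).
#' @param exponent stability exponent in (1, 2].
#' @param rng draw source, see \code{\link{defaultRNG}}.
#' @return numeric vector of length \code{n}.
#' @export
levySteps <- function(n, exponent = 1.5, rng = defaultRNG()) {
    if (exponent <= 1 || exponent > 2)
        stop("exponent must lie in (1, 2]")
    if (n == 0L) return(numeric(0))
    beta <- exponent
    sigmaU <- (gamma(1 + beta) * sin(pi * beta / 2) /
               (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
    u <- rng$norm(n) * sigmaU
    v <- rng$norm(n)
    u / abs(v)^(1 / beta)
}
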