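#' Decode a continuous position into a fixed-size gene subset
#'
#' A candidate is a vector in \eqn{[0,1]^D}; its gene subset is the set of
#' indices of the k largest components, ties broken in favour of the lower
#' index. Returned sorted ascending, which also serves as the cache key for
#' fitness evaluations.
#'
#' @param position numeric vector in \eqn{[0,1]^D}.
#' @param k subset size, \code{1 <= k <= length(position)}.
#' @return integer vector of k distinct 1-based gene indices, ascending.
#' @examples
#' decodeSubset(c(0.9, 0.1, 0.8, 0.2), 2)  # 1 3
#' @export
decodeSubset <- function(position, k) {
    D <- length(position)
    if (k < 1L || k > D)
        stop("k must lie in 1..", D, " (got ", k, ")")
    ord <- order(-position, seq_len(D), method = "radix")
    sort(ord[seq_len(k)])
}

#' Fission mutation factors
#'
#' Two discrete mutation scales: \code{Pnes = round(rand + 1)} in
#' \{1, 2\} for subaltern fission products and \code{Pnee = round(rand + 2)}
#' in \{2, 3\} for essential ones, each from an independent uniform draw,
#' rounding half away from zero.
#'
#' Draw order: one uniform for \code{Pnes}, one for \code{Pnee}.
#'
#' @param rng draw source, see \code{\link{defaultRNG}}.
#' @return list with integers \code{Pnes} and \code{Pnee}.
#' @export
mutationFactors <- function(rng = defaultRNG()) {
    list(Pnes = as.integer(roundHalfUp(rng$unif(1L) + 1)),
         Pnee = as.integer(roundHalfUp(rng$unif(1L) + 2)))
}

#' Fission step sizes
#'
#' The Gaussian dispersion of the fission perturbation shrinks as the
#' search advances: \eqn{\sigma_1 = (\log g / g)\,\|X_i - X_{best}\|} and
#' \eqn{\sigma_2 = (\log g / g)\,\|X_r - X_{best}\|} (Euclidean norms). At
#' generation 1 both are exactly 0 (\eqn{\log 1 = 0}), so first-generation
#' fission perturbs only through the neutron term.
#'
#' @param xi current position.
#' @param xr a random peer position.
#' @param xbest best-known position.
#' @param g generation index, \code{>= 1}.
#' @return list with non-negative scalars \code{sigma1} and \code{sigma2}.
#' @export
fissionStepSizes <- function(xi, xr, xbest, g) {
    if (g < 1L) stop("generation index must be >= 1")
    sc <- log(g) / g
    list(sigma1 = sc * sqrt(sum((xi - xbest)^2)),
         sigma2 = sc * sqrt(sum((xr - xbest)^2)))
}

#' Fission operator: exploration by Gaussian perturbation
#'
#' Produces a new candidate around either the best-known solution (the
#' "subaltern" branch, taken when the branch draw is <= \code{pBeta}) or
#' the current solution (the "essential" branch):
#' \deqn{X^{Fi} = \begin{cases}
#'   \mathcal N(X_{best}, \sigma_1) + z\,(X_{best} - P_{nes}\,Nei) &
#'     u \le P_\beta\\
#'   \mathcal N(X_i, \sigma_2) + z\,(X_{best} - P_{nee}\,Nei) &
#'     u > P_\beta\end{cases}}
#' where the Gaussian is per-component with the common scalar sigma of
#' \code{\link{fissionStepSizes}}, \eqn{z} is one scalar standard-normal
#' draw, and the heated neutron \eqn{Nei} combines two random distinct
#' peers (element-wise mean by default; \code{cfg@neutron = "product"}
#' selects the element-wise product). The first peer doubles as the random
#' solution \eqn{X_r} in \eqn{\sigma_2}. The result is clipped to
#' \eqn{[0,1]^D} and carries no fitness.
#'
#' Draw order: 1 uniform (branch), 2 uniforms (peer indices), 2 uniforms
#' (mutation factors, see \code{\link{mutationFactors}}), D normals
#' (Gaussian), 1 normal (z).
#'
#' @param xi current position.
#' @param xbest best-known position.
#' @param population numeric matrix, one candidate position per row
#'   (at least 3 rows).
#' @param g generation index, \code{>= 1}.
#' @param cfg a \linkS4class{GNRConfig}.
#' @param rng draw source.
#' @return numeric position in \eqn{[0,1]^D}.
#' @export
fission <- function(xi, xbest, population, g, cfg = gnrConfig(),
                    rng = defaultRNG()) {
    N <- nrow(population)
    if (is.null(N) || N < 3L)
        stop("fission needs a population of at least 3 candidates")
    D <- length(xi)
    u <- rng$unif(1L)
    i1 <- sampleIndex(rng, N)
    i2 <- sampleIndexExcluding(rng, N, i1)
    mf <- mutationFactors(rng)
    nei <- if (cfg@neutron == "mean")
        (population[i1, ] + population[i2, ]) / 2
    else population[i1, ] * population[i2, ]
    ss <- fissionStepSizes(xi, population[i1, ], xbest, g)
    gz <- rng$norm(D)
    z <- rng$norm(1L)
    pos <- if (u <= cfg@pBeta)
        xbest + ss$sigma1 * gz + z * (xbest - mf$Pnes * nei)
    else
        xi + ss$sigma2 * gz + z * (xbest - mf$Pnee * nei)
    clip01(pos)
}

#' Ionization operator: difference-vector perturbation with Levy fallback
#'
#' Perturbs a fission product with component-wise differences between two
#' random distinct peers of the fission population:
#' \deqn{X^{Ion}_d = X^{Fi}_{r1,d} \pm u_d\,(X^{Fi}_{r2,d} - X^{Fi}_{i,d})}
#' with the sign chosen per component (plus when the branch draw is
#' <= 0.5). When the whole difference vector
#' \eqn{\|X^{Fi}_{r2} - X^{Fi}_i\|} falls below
#' \code{cfg@stagnationEpsilon} the search would stall, so a Levy flight is
#' applied instead:
#' \eqn{X^{Ion} = X^{Fi}_i + \alpha\,L(\beta) \odot (X^{Fi}_i -
#' X^{Fi}_{best})}. Output clipped to \eqn{[0,1]^D}.
#'
#' Draw order: 2 uniforms (peer indices); then either D uniforms (branch)
#' followed by D uniforms (multipliers), or 2D normals for the Levy steps
#' (see \code{\link{levySteps}}).
#'
#' @param xiFis fission product of the current candidate.
#' @param fissionPop numeric matrix of fission products (>= 3 rows).
#' @param xbestFis reference best of the fission population (used by the
#'   Levy fallback).
#' @param cfg a \linkS4class{GNRConfig}.
#' @param rng draw source.
#' @return numeric position in \eqn{[0,1]^D}.
#' @export
ionization <- function(xiFis, fissionPop, xbestFis, cfg = gnrConfig(),
                       rng = defaultRNG()) {
    N <- nrow(fissionPop)
    if (is.null(N) || N < 3L)
        stop("ionization needs a fission population of at least 3")
    D <- length(xiFis)
    i1 <- sampleIndex(rng, N)
    i2 <- sampleIndexExcluding(rng, N, i1)
    diffVec <- fissionPop[i2, ] - xiFis
    if (sqrt(sum(diffVec^2)) < cfg@stagnationEpsilon) {
        lev <- levySteps(D, cfg@levyExponent, rng)
        pos <- xiFis + cfg@levyAlpha * lev * (xiFis - xbestFis)
    } else {
        branch <- rng$unif(D)
        mult <- rng$unif(D)
        base <- fissionPop[i1, ]
        pos <- ifelse(branch <= 0.5, base + mult * diffVec,
                      base - mult * diffVec)
    }
    clip01(pos)
}

#' Fusion operator: best-guided recombination or Levy escape
#'
#' When diversity is sufficient, pulls the ionized candidate along the
#' directions of two ionized peers relative to the best solution:
#' \deqn{X^{Fu} = X^{Ion}_i + u_1 (X^{Ion}_{r1} - X_{best}) +
#'       u_2 (X^{Ion}_{r2} - X_{best})}
#' with independent scalar uniforms \eqn{u_1, u_2}. When diversity is
#' insufficient (\code{diversityOk = FALSE}) a Levy escape is used
#' instead: \eqn{X^{Fu} = X^{Ion}_i + \alpha\,L(\beta) \odot
#' (X^{Ion}_i - X_{best})}, where \code{xbest} is then the best of the
#' ionized population. Output clipped to \eqn{[0,1]^D}.
#'
#' Draw order: 2 uniforms (guided branch) or 2D normals (Levy branch).
#'
#' @param xiIon ionized position of the current candidate.
#' @param xr1Ion,xr2Ion ionized positions of two random peers.
#' @param xbest guiding position (global best for the guided branch, best
#'   ionized candidate for the Levy branch).
#' @param diversityOk logical, whether the guided form is applicable.
#' @param cfg a \linkS4class{GNRConfig}.
#' @param rng draw source.
#' @return numeric position in \eqn{[0,1]^D}.
#' @export
fusion <- function(xiIon, xr1Ion, xr2Ion, xbest, diversityOk = TRUE,
                   cfg = gnrConfig(), rng = defaultRNG()) {
    D <- length(xiIon)
    if (length(xr1Ion) != D || length(xr2Ion) != D || length(xbest) != D)
        stop("fusion inputs must share one dimension")
    if (diversityOk) {
        u1 <- rng$unif(1L)
        u2 <- rng$unif(1L)
        pos <- xiIon + u1 * (xr1Ion - xbest) + u2 * (xr2Ion - xbest)
    } else {
        lev <- levySteps(D, cfg@levyExponent, rng)
        pos <- xiIon + cfg@levyAlpha * lev * (xiIon - xbest)
    }
    clip01(pos)
}

#' Uniform crossover with the best solution
#'
#' Component-wise genetic recombination: each component is inherited from
#' the best parent with probability \code{pInheritBest} and from the random
#' parent otherwise.
#'
#' Draw order: D uniforms, one per component.
#'
#' @param xbest best-known position.
#' @param xrand a random peer position.
#' @param pInheritBest inheritance probability in [0,1].
#' @param rng draw source.
#' @return numeric position (no clipping needed: parents are in range).
#' @export
uniformCrossover <- function(xbest, xrand, pInheritBest = 0.8,
                             rng = defaultRNG()) {
    D <- length(xbest)
    if (length(xrand) != D)
        stop("crossover parents must share one dimension")
    u <- rng$unif(D)
    ifelse(u < pInheritBest, xbest, xrand)
}

#' Crossover-gated fusion step
#'
#' The defining move of the genetic-embedded variant: one uniform gate draw
#' decides, with probability \code{cfg@pCrossover}, whether the fusion step
#' is replaced by a \code{\link{uniformCrossover}} between the best
#' solution and a random peer (drawn from the ionized population excluding
#' the best candidate's slot). Otherwise ordinary \code{\link{fusion}} is
#' applied — the guided form when the search is progressing, the Levy
#' escape when it is stagnant.
#'
#' Draw order: 1 uniform (gate); crossover path: 1 uniform (peer index) +
#' D uniforms; fusion path: 2 uniforms (peer indices) + fusion draws.
#'
#' @param xiIon ionized position of the current candidate.
#' @param ionPop numeric matrix of ionized candidates.
#' @param xbest global best position.
#' @param bestIdx row index of the best candidate's slot in \code{ionPop}.
#' @param stagnant logical, whether the run is currently stagnant (selects
#'   the Levy form of fusion).
#' @param cfg a \linkS4class{GNRConfig}.
#' @param rng draw source.
#' @return numeric position in \eqn{[0,1]^D}.
#' @export
gnrFusionGate <- function(xiIon, ionPop, xbest, bestIdx, stagnant = FALSE,
                          cfg = gnrConfig(), rng = defaultRNG()) {
    N <- nrow(ionPop)
    if (is.null(N) || N < 2L)
        stop("gate needs a population of at least 2")
    gate <- rng$unif(1L)
    if (gate < cfg@pCrossover) {
        j <- sampleIndexExcluding(rng, N, bestIdx)
        return(uniformCrossover(xbest, ionPop[j, ], cfg@pInheritBest, rng))
    }
    r1 <- sampleIndex(rng, N)
    r2 <- sampleIndexExcluding(rng, N, r1)
    if (!stagnant)
        fusion(xiIon, ionPop[r1, ], ionPop[r2, ], xbest, TRUE, cfg, rng)
    else
        fusion(xiIon, ionPop[r1, ], ionPop[r2, ], ionPop[bestIdx, ], FALSE,
               cfg, rng)
}
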