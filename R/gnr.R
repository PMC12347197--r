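#' Build a GNR configuration
#'
#' Defaults follow the published study conditions: population 500, at most
#' 30 generations, early stop after 5 consecutive non-improving
#' generations, 30 independent runs, crossover gate probability 0.3,
#' inheritance-from-best probability 0.8, subset sizes 2..25. The fission
#' branch probability (0.5), Levy scale (0.01) and Levy exponent (1.5) are
#' conventional choices for quantities the method leaves open; see the
#' package vignette.
#'
#' @param populationSize candidates per generation.
#' @param maxGenerations generation cap.
#' @param patience consecutive non-improving generations before stopping.
#' @param nRuns independent restarts (experiment harness).
#' @param pCrossover probability the fusion step is replaced by crossover.
#' @param pInheritBest per-component inheritance probability.
#' @param subsetSizes gene subset sizes swept by the harness.
#' @param pBeta fission branch probability.
#' @param levyAlpha Levy flight scale.
#' @param levyExponent Levy stability exponent in (1,2].
#' @param stagnationEpsilon degenerate-difference threshold.
#' @param targetFitness stop once the best fitness reaches this value; the
#'   LOOCV-accuracy objective cannot exceed 1.
#' @param neutron \code{"mean"} (default) or \code{"product"} combination
#'   of the two neutron peers.
#' @param seed RNG seed for a single run, or NA.
#' @return A validated \linkS4class{GNRConfig}.
#' @examples
#' cfg <- gnrConfig(populationSize = 50, maxGenerations = 20, seed = 1)
#' @export
gnrConfig <- function(populationSize = 500L, maxGenerations = 30L,
                      patience = 5L, nRuns = 30L, pCrossover = 0.3,
                      pInheritBest = 0.8, subsetSizes = 2:25, pBeta = 0.5,
                      levyAlpha = 0.01, levyExponent = 1.5,
                      stagnationEpsilon = 1e-12, targetFitness = 1.0,
                      neutron = c("mean", "product"), seed = NA) {
    neutron <- match.arg(neutron)
    new("GNRConfig",
        populationSize = as.integer(populationSize),
        maxGenerations = as.integer(maxGenerations),
        patience = as.integer(patience),
        nRuns = as.integer(nRuns),
        pCrossover = pCrossover,
        pInheritBest = pInheritBest,
        subsetSizes = as.integer(subsetSizes),
        pBeta = pBeta,
        levyAlpha = levyAlpha,
        levyExponent = levyExponent,
        stagnationEpsilon = stagnationEpsilon,
        targetFitness = targetFitness,
        neutron = neutron,
        seed = as.integer(seed))
}

setMethod("show", "GNRConfig", function(object) {
    cat("GNRConfig: population", object@populationSize,
        "| generations <=", object@maxGenerations,
        "| patience", object@patience, "\n")
    cat("  pCrossover", object@pCrossover,
        "| pInheritBest", object@pInheritBest,
        "| pBeta", object@pBeta, "\n")
    cat("  subset sizes", paste(range(object@subsetSizes), collapse = ".."),
        "| runs", object@nRuns,
        "| seed", object@seed, "\n")
    invisible(NULL)
})

#' Run the GNR search for one subset size
#'
#' The full search loop: a population of continuous candidates in
#' \eqn{[0,1]^D} is initialized uniformly and evaluated (each candidate's
#' fitness is the score of its decoded k-gene subset); every generation
#' then applies \code{\link{fission}} to each candidate, then
#' \code{\link{ionization}}, then the crossover-gated fusion
#' (\code{\link{gnrFusionGate}}). After each phase every candidate's
#' product is accepted greedily — it replaces the candidate when its
#' fitness is at least as good — which is the selection scheme of the
#' nuclear-reaction optimizer lineage and is what lets the population
#' concentrate around good subsets instead of diffusing (see the
#' vignette). The best-known solution is updated only on strictly greater
#' fitness. A generation-level no-improvement counter drives both early
#' stopping (counter reaches \code{patience}) and the stagnation flag
#' that switches fusion to its Levy form (counter >= 2). The run also
#' stops when the best fitness reaches \code{cfg@targetFitness} or the
#' generation cap.
#'
#' Fitness values are cached per decoded subset, so repeated evaluation of
#' the same gene set costs nothing.
#'
#' @param ds a \linkS4class{GeneExpressionSet} (typically the filtered
#'   pool), used to build the default LOOCV-SVM fitness; alternatively a
#'   single integer giving the search dimension D when a custom
#'   \code{fitnessFn} is supplied.
#' @param k gene subset size; every candidate decodes to exactly k genes.
#' @param cfg a \linkS4class{GNRConfig}; \code{cfg@seed} (when not NA)
#'   seeds the run.
#' @param fitnessFn optional function(subset indices) -> fitness in [0,1];
#'   defaults to LOOCV accuracy of a linear SVM (C = 1) on \code{ds}
#'   restricted to the subset.
#' @return A \linkS4class{GNRTrajectory}.
#' @seealso \code{\link{loocvFitness}}, \code{\link{runExperiment}}
#' @export
runGNR <- function(ds, k, cfg = gnrConfig(), fitnessFn = NULL) {
    if (is(ds, "GeneExpressionSet")) {
        D <- nGenes(ds)
        if (is.null(fitnessFn))
            fitnessFn <- function(subset) loocvFitness(ds, subset)$accuracy
    } else if (is.numeric(ds) && length(ds) == 1L) {
        D <- as.integer(ds)
        if (is.null(fitnessFn))
            stop("a fitness function is required when only D is given")
    } else {
        stop("ds must be a GeneExpressionSet or an integer dimension")
    }
    if (k < 1L || k > D)
        stop("subset size k must lie in 1..", D, " (got ", k, ")")
    if (!is.na(cfg@seed)) set.seed(cfg@seed)
    rng <- defaultRNG()
    N <- cfg@populationSize

    cache <- new.env(parent = emptyenv())
    evalSubset <- function(subset) {
        key <- paste(subset, collapse = ",")
        hit <- cache[[key]]
        if (!is.null(hit)) return(hit)
        val <- fitnessFn(subset)
        if (length(val) != 1L || !is.finite(val))
            stop("fitness function returned a non-finite value")
        cache[[key]] <- val
        val
    }

    pop <- matrix(rng$unif(N * D), nrow = N, ncol = D)
    fit <- vapply(seq_len(N),
                  function(i) evalSubset(decodeSubset(pop[i, ], k)),
                  numeric(1))
    bestSlot <- which.max(fit)
    xbest <- pop[bestSlot, ]
    bestFit <- fit[bestSlot]
    initialBest <- bestFit

    traj <- numeric(0)
    improvedAt <- integer(0)
    prevBest <- -Inf   # first recorded generation counts as improvement
    noImprove <- 0L
    stopReason <- "max_generations"
    g <- 0L

    # generate a phase's products from the current population snapshot,
    # then accept each product greedily (>=: neutral drift is allowed)
    acceptPhase <- function(products) {
        for (i in seq_len(N)) {
            nf <- evalSubset(decodeSubset(products[i, ], k))
            if (nf >= fit[i]) {
                pop[i, ] <<- products[i, ]
                fit[i] <<- nf
            }
        }
        bestSlot <<- which.max(fit)
    }

    while (g < cfg@maxGenerations) {
        if (bestFit >= cfg@targetFitness) { stopReason <- "target"; break }
        g <- g + 1L
        stagnant <- noImprove >= 2L

        fisPop <- matrix(0, nrow = N, ncol = D)
        for (i in seq_len(N))
            fisPop[i, ] <- fission(pop[i, ], xbest, pop, g, cfg, rng)
        acceptPhase(fisPop)

        ionPop <- matrix(0, nrow = N, ncol = D)
        for (i in seq_len(N))
            ionPop[i, ] <- ionization(pop[i, ], pop, pop[bestSlot, ], cfg,
                                      rng)
        acceptPhase(ionPop)

        fuPop <- matrix(0, nrow = N, ncol = D)
        for (i in seq_len(N))
            fuPop[i, ] <- gnrFusionGate(pop[i, ], pop, xbest,
                                        bestSlot, stagnant, cfg, rng)
        acceptPhase(fuPop)

        if (fit[bestSlot] > bestFit) {     # strictly greater: elitist
            bestFit <- fit[bestSlot]
            xbest <- pop[bestSlot, ]
        }
        traj[g] <- bestFit
        if (bestFit > prevBest) {
            noImprove <- 0L
            improvedAt <- c(improvedAt, g)
        } else {
            noImprove <- noImprove + 1L
        }
        prevBest <- bestFit
        if (noImprove >= cfg@patience) { stopReason <- "patience"; break }
        if (bestFit >= cfg@targetFitness) { stopReason <- "target"; break }
    }

    new("GNRTrajectory",
        bestFitness = traj,
        generationsExecuted = g,
        stoppedEarly = stopReason != "max_generations",
        stopReason = stopReason,
        bestPosition = xbest,
        bestSubset = decodeSubset(xbest, k),
        bestFitnessValue = bestFit,
        subsetSize = as.integer(k),
        improvedAt = improvedAt,
        initialBest = initialBest)
}

#' @describeIn runGNR best-so-far fitness after each executed generation.
#' @param x a \linkS4class{GNRTrajectory}.
#' @export
setMethod("bestFitness", "GNRTrajectory", function(x) x@bestFitness)

#' @describeIn runGNR decoded gene indices of the best candidate.
#' @export
setMethod("bestSubset", "GNRTrajectory", function(x) x@bestSubset)

setMethod("show", "GNRTrajectory", function(object) {
    cat("GNRTrajectory: k =", object@subsetSize, "|",
        object@generationsExecuted, "generations | best fitness",
        format(object@bestFitnessValue, digits = 6), "\n")
    cat("  stop:", object@stopReason,
        if (object@stoppedEarly) "(early)" else "", "\n")
    invisible(NULL)
})

#' Export a trajectory as JSON
#'
#' Per-generation best fitness, stopping reason, and the best subset's
#' gene identifiers (when the pool dataset is supplied).
#'
#' @param traj a \linkS4class{GNRTrajectory}.
#' @param path output file path.
#' @param ds optional \linkS4class{GeneExpressionSet} to translate gene
#'   indices to identifiers.
#' @return \code{path}, invisibly.
#' @export
writeTrajectoryJSON <- function(traj, path, ds = NULL) {
    out <- list(subset_size = traj@subsetSize,
                generations_executed = traj@generationsExecuted,
                stopped_early = traj@stoppedEarly,
                stop_reason = traj@stopReason,
                best_fitness_per_generation = traj@bestFitness,
                initial_best = traj@initialBest,
                best_fitness = traj@bestFitnessValue,
                best_subset_indices = traj@bestSubset)
    if (!is.null(ds))
        out$best_subset_genes <- geneIds(ds)[traj@bestSubset]
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
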