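# shared fixtures and RNG harnesses for the test suite

# 6-sample, 2-gene toy: g1 separates (1,2,3) vs (5,6,7), g2 is constant
toyBinary <- function() {
    m <- cbind(g1 = c(1, 2, 3, 5, 6, 7), g2 = rep(1, 6))
    GeneExpressionSet(m, labels = rep(c("pos", "neg"), each = 3))
}

# linearly separable two-class set: one gene at -5 / +5 plus noise genes
separableSet <- function(n = 20, nNoise = 3, seed = 42) {
    set.seed(seed)
    half <- n %/% 2
    sig <- c(rnorm(half, -5, 0.3), rnorm(n - half, 5, 0.3))
    m <- cbind(sig, matrix(rnorm(n * nNoise), n, nNoise))
    colnames(m) <- paste0("g", seq_len(nNoise + 1))
    GeneExpressionSet(m, labels = c(rep("a", half), rep("b", n - half)))
}

# draw source replaying fixed sequences; errors if a sequence runs dry
stubRNG <- function(unif = numeric(0), norm = numeric(0)) {
    env <- new.env()
    env$ui <- 0L
    env$ni <- 0L
    list(unif = function(n = 1L) {
             if (n == 0L) return(numeric(0))
             out <- unif[env$ui + seq_len(n)]
             if (anyNA(out)) stop("stub unif sequence exhausted")
             env$ui <- env$ui + n
             out
         },
         norm = function(n = 1L) {
             if (n == 0L) return(numeric(0))
             out <- norm[env$ni + seq_len(n)]
             if (anyNA(out)) stop("stub norm sequence exhausted")
             env$ni <- env$ni + n
             out
         })
}

# draw source with constant values (hostile-edge probing)
constantRNG <- function(u = 0, z = 0) {
    list(unif = function(n = 1L) rep(u, n),
         norm = function(n = 1L) rep(z, n))
}

# records every draw from the global RNG so an independent transcription
# can replay the exact sequence
recordingRNG <- function() {
    env <- new.env()
    env$unif <- numeric(0)
    env$norm <- numeric(0)
    list(unif = function(n = 1L) {
             x <- stats::runif(n)
             env$unif <- c(env$unif, x)
             x
         },
         norm = function(n = 1L) {
             x <- stats::rnorm(n)
             env$norm <- c(env$norm, x)
             x
         },
         draws = function() list(unif = env$unif, norm = env$norm))
}

# index sampling rules shared by the oracle transcriptions (documented
# draw mapping: one uniform -> index on 1..n, second maps over 1..n-1
# skipping the excluded slot)
oracleIndex <- function(u, n) min(n, 1L + floor(u * n))
oracleIndexExcl <- function(u, n, excl) {
    j <- min(n - 1L, 1L + floor(u * (n - 1L)))
    if (j >= excl) j + 1L else j
}

clip01o <- function(x) pmin(1, pmax(0, x))

# literal transcription of the Mantegna Levy generator
oracleLevy <- function(nu, nv, beta) {
    sigmaU <- (gamma(1 + beta) * sin(pi * beta / 2) /
        (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
    (nu * sigmaU) / abs(nv)^(1 / beta)
}
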