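#' @include regression.R
NULL

#' Genetic-algorithm configuration
#'
#' Settings of the real-coded genetic algorithm used to minimise the
#' relative-error objective over the box-constrained weight vector.
#' Defaults follow the common defaults of R genetic-algorithm packages:
#' population 50, 100 generations, crossover rate 0.8, mutation rate 0.1,
#' elitism 2. Candidates are kept inside the open box (0, 1) by clipping to
#' [1e-6, 1 - 1e-6] after crossover/mutation. Mutation is Gaussian with a
#' standard deviation that decays geometrically from
#' \code{mutationSdStart} to \code{mutationSdEnd} across generations, which
#' gives broad early exploration and fine late refinement.
#'
#' @param populationSize number of candidate weight vectors (>= 10).
#' @param generations number of generations.
#' @param crossoverRate probability a child is produced by blend crossover.
#' @param mutationRate per-gene mutation probability.
#' @param elitism number of best candidates copied unchanged (>= 1).
#' @param mutationSdStart,mutationSdEnd Gaussian mutation scale schedule.
#' @param seed RNG seed for the training split and the GA run.
#' @return A list of class \code{ga_config}.
#' @export
gaConfig <- function(populationSize = 50L, generations = 100L,
                     crossoverRate = 0.8, mutationRate = 0.1,
                     elitism = 2L, mutationSdStart = 0.15,
                     mutationSdEnd = 0.01, seed = 1L) {
  stopifnot(populationSize >= 10, generations >= 1,
            crossoverRate >= 0, crossoverRate <= 1,
            mutationRate >= 0, mutationRate <= 1,
            elitism >= 1, elitism < populationSize)
  structure(list(populationSize = as.integer(populationSize),
                 generations = as.integer(generations),
                 crossoverRate = crossoverRate, mutationRate = mutationRate,
                 elitism = as.integer(elitism),
                 mutationSdStart = mutationSdStart,
                 mutationSdEnd = mutationSdEnd,
                 seed = as.integer(seed)),
            class = "ga_config")
}

## real-coded GA minimising the mean relative prediction error over the
## active weight columns; relies on the caller having seeded the RNG
.gaMinimize <- function(features, targets, interceptWc, config) {
  k <- ncol(features)
  eps <- 1e-6
  pop <- config$populationSize
  evalPop <- function(P) {
    pred <- features %*% t(P) + interceptWc        # n x pop
    colMeans(abs(pred - targets) / targets)
  }
  P <- matrix(stats::runif(pop * k, eps, 1 - eps), pop, k)
  obj <- evalPop(P)
  trace <- numeric(config$generations)
  decay <- (config$mutationSdEnd / config$mutationSdStart)^
    (1 / max(1, config$generations - 1))
  sdMut <- config$mutationSdStart
  for (g in seq_len(config$generations)) {
    ord <- order(obj)
    elite <- P[ord[seq_len(config$elitism)], , drop = FALSE]
    ## tournament selection, size 3
    nOff <- pop - config$elitism
    pick <- function()
      P[apply(matrix(sample.int(pop, 3 * nOff, replace = TRUE), nOff, 3),
              1, function(ix) ix[which.min(obj[ix])]), , drop = FALSE]
    p1 <- pick(); p2 <- pick()
    ## blend (BLX-style) crossover
    doCx <- stats::runif(nOff) < config$crossoverRate
    u <- matrix(stats::runif(nOff * k, -0.25, 1.25), nOff, k)
    child <- ifelse(matrix(doCx, nOff, k), u * p1 + (1 - u) * p2, p1)
    ## Gaussian mutation with decaying scale
    mut <- matrix(stats::runif(nOff * k) < config$mutationRate, nOff, k)
    child <- child + mut * matrix(stats::rnorm(nOff * k, 0, sdMut), nOff, k)
    child <- pmin(pmax(child, eps), 1 - eps)
    P <- rbind(elite, child)
    obj <- evalPop(P)
    trace[g] <- min(obj)
    sdMut <- sdMut * decay
  }
  best <- which.min(obj)
  list(weights = P[best, ], objective = obj[best], trace = trace)
}
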