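# Wright-Fisher engine: binary genomes, additive log-fitness, symmetric
# per-site mutation, multinomial resampling at constant population size N.

#' Simulation parameters
#'
#' Bundles the parameters of a forward Wright-Fisher run. Note `mu` is the
#' per-site mutation probability per generation; the genomic rate is `mu * L`.
#'
#' @param N positive integer; constant population size.
#' @param L positive integer; number of genomic sites.
#' @param mu per-site mutation probability per generation, in `[0, 1]`.
#' @param f_in initial frequency of the less-fit allele, in `[0, 1]`.
#' @param generations non-negative integer; number of generations to run.
#' @param n_replicates positive integer; ensemble size for [run_ensemble()].
#' @param seed integer master seed. Replicate `r` of an ensemble runs with
#'   seed `seed + r - 1`.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(N = 1e4, L = 100, mu = 5e-4, f_in = 0.2,
                       generations = 100, n_replicates = 20, seed = 1) {
  stopifnot(N >= 1, L >= 1, mu >= 0, mu <= 1, f_in >= 0, f_in <= 1,
            generations >= 0, n_replicates >= 1)
  structure(list(N = as.integer(N), L = as.integer(L), mu = mu, f_in = f_in,
                 generations = as.integer(generations),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "Wright-Fisher parameters: N = %d, L = %d, mu = %g (genomic muL = %g),\n  f_in = %g, generations = %d, replicates = %d, seed = %d\n",
    x$N, x$L, x$mu, x$mu * x$L, x$f_in, x$generations, x$n_replicates, x$seed))
  invisible(x)
}

#' Initialize a population
#'
#' Each of the `N * L` occupancy entries is independently 1 (less-fit allele)
#' with probability `f_in`, emulating a diverse population newly exposed to a
#' changed environment.
#'
#' @param params a [sim_params()] object.
#' @return Integer `N x L` matrix with entries in `{0, 1}` (class `population`).
#' @export
initialize_population <- function(params) {
  pop <- matrix(stats::rbinom(params$N * params$L, 1L, params$f_in),
                nrow = params$N, ncol = params$L)
  class(pop) <- c("population", class(pop))
  pop
}

#' Additive log-fitness of a genome
#'
#' `W = -sum(s_i * K_i)`: each less-fit allele (`K_i = 1`) subtracts its cost
#' `s_i`. The fitness weight used in resampling is `exp(W)`, so the all-zero
#' (best-fit) genome has `W = 0`.
#'
#' @param genome binary vector of length `L`, or an `N x L` binary matrix
#'   (one genome per row).
#' @param profile a `selection_profile` of matching length.
#' @return numeric: `W` per genome (scalar for a vector input).
#' @export
genome_fitness <- function(genome, profile) {
  s <- as.numeric(profile)
  if (is.matrix(genome)) {
    if (ncol(genome) != length(s))
      stop("genome matrix has ", ncol(genome), " sites but profile has ",
           length(s), call. = FALSE)
    return(-as.vector(genome %*% s))
  }
  if (length(genome) != length(s))
    stop("genome length ", length(genome), " does not match profile length ",
         length(s), call. = FALSE)
  -sum(s * genome)
}

#' Mutate a population
#'
#' Symmetric per-site flips: every occupancy entry toggles `0 <-> 1`
#' independently with probability `mu`. Implemented by drawing the binomial
#' flip count and placing flips uniformly, which is distributionally identical
#' to entrywise Bernoulli flips.
#'
#' @param pop binary population matrix.
#' @param mu per-site mutation probability in `[0, 1]`.
#' @return mutated population matrix, same dimensions.
#' @export
mutate_population <- function(pop, mu) {
  stopifnot(mu >= 0, mu <= 1)
  if (mu == 0) return(pop)
  n_cells <- length(pop)
  k <- stats::rbinom(1L, n_cells, mu)
  if (k > 0L) {
    idx <- sample.int(n_cells, k)
    pop[idx] <- 1L - pop[idx]
  }
  pop
}

#' Selection and multinomial resampling
#'
#' Draws `N` offspring with replacement, each parent chosen with probability
#' proportional to `exp(W)`; the offspring counts are therefore multinomial.
#' Weights are computed relative to the fittest genome present for numerical
#' stability (`exp(W - max(W))`), which leaves the multinomial probabilities
#' unchanged.
#'
#' @param pop binary population matrix (any number of rows `> 0`).
#' @param profile a `selection_profile`.
#' @param N number of offspring to draw (defaults to `nrow(pop)`).
#' @return binary matrix with exactly `N` rows.
#' @export
select_and_resample <- function(pop, profile, N = nrow(pop)) {
  if (nrow(pop) == 0L) stop("population is empty", call. = FALSE)
  W <- genome_fitness(pop, profile)
  w <- exp(W - max(W))
  parents <- sample.int(nrow(pop), N, replace = TRUE, prob = w)
  out <- pop[parents, , drop = FALSE]
  class(out) <- c("population", "matrix", "array")
  out
}

#' Run one Wright-Fisher simulation
#'
#' One generation = mutation, then selection with multinomial resampling.
#' Generation 0 is the initialized state. Per-site less-fit allele frequencies
#' (column means of the occupancy matrix) are recorded at `record_times`.
#'
#' @param params a [sim_params()] object. `params$seed` is applied unless
#'   `use_seed = FALSE` (as when called from [run_ensemble()], which manages
#'   per-replicate seeds itself).
#' @param profile a `selection_profile` of length `params$L`.
#' @param record_times sorted integer vector of generations at which to record
#'   frequencies; must lie in `[0, generations]`.
#' @param checkpoint_times integer vector of generations at which to store
#'   the full population matrix (for FASTA export); must be recorded times.
#' @param keep_final if `TRUE`, the final population matrix is attached.
#' @param use_seed set the RNG from `params$seed` before running.
#' @return An object of class `trajectory`: list with `times`,
#'   `site_frequencies` (times x L matrix), `mean_fitness` (per recorded time),
#'   optionally `checkpoints` (named list of population matrices) and
#'   `final_population`.
#' @export
run_simulation <- function(params, profile, record_times = 0:params$generations,
                           checkpoint_times = integer(0),
                           keep_final = FALSE, use_seed = TRUE) {
  stopifnot(length(profile) == params$L)
  record_times <- as.integer(record_times)
  if (is.unsorted(record_times, strictly = TRUE) ||
      any(record_times < 0L) || any(record_times > params$generations))
    stop("`record_times` must be strictly increasing within [0, generations]",
         call. = FALSE)
  checkpoint_times <- as.integer(checkpoint_times)
  if (!all(checkpoint_times %in% record_times))
    stop("`checkpoint_times` must be a subset of `record_times`", call. = FALSE)
  if (use_seed) set.seed(params$seed)

  pop <- initialize_population(params)
  freqs <- matrix(NA_real_, nrow = length(record_times), ncol = params$L)
  mean_W <- numeric(length(record_times))
  checkpoints <- list()
  record <- function(rec, g) {
    freqs[rec, ] <<- colMeans(pop)
    mean_W[rec] <<- mean(genome_fitness(pop, profile))
    if (g %in% checkpoint_times) checkpoints[[as.character(g)]] <<- pop
  }
  rec <- 1L
  if (length(record_times) && record_times[1L] == 0L) {
    record(1L, 0L)
    rec <- 2L
  }
  if (params$generations > 0L) {
    for (g in seq_len(params$generations)) {
      pop <- mutate_population(pop, params$mu)
      pop <- select_and_resample(pop, profile, params$N)
      if (rec <= length(record_times) && record_times[rec] == g) {
        record(rec, g)
        rec <- rec + 1L
      }
    }
  }
  out <- list(times = record_times, site_frequencies = freqs,
              mean_fitness = mean_W, profile = as.numeric(profile))
  if (length(checkpoints)) out$checkpoints <- checkpoints
  if (keep_final) out$final_population <- pop
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d recorded times (t = %d..%d), L = %d sites\n",
              length(x$times), min(x$times), max(x$times),
              ncol(x$site_frequencies)))
  invisible(x)
}

#' Run an ensemble of replicate simulations
#'
#' `n_replicates` independent runs sharing the same selection profile.
#' Replicate `r` uses seed `params$seed + r - 1`, so the ensemble is
#' bit-reproducible from the master seed and any replicate can be re-run in
#' isolation.
#'
#' @inheritParams run_simulation
#' @param keep_final attach each replicate's final population (for FASTA
#'   export of sampled sequences).
#' @return list of `trajectory` objects, length `params$n_replicates`.
#' @export
run_ensemble <- function(params, profile, record_times = 0:params$generations,
                         checkpoint_times = integer(0), keep_final = FALSE) {
  lapply(seq_len(params$n_replicates), function(r) {
    set.seed(params$seed + r - 1L)
    run_simulation(params, profile, record_times,
                   checkpoint_times = checkpoint_times,
                   keep_final = keep_final, use_seed = FALSE)
  })
}

#' Trajectory frequencies as a tidy table
#'
#' @param trajectories a `trajectory` or list of them.
#' @return data.frame with columns `replicate`, `time`, `site` (1-based),
#'   `s`, `frequency`.
#' @export
trajectory_table <- function(trajectories) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  do.call(rbind, lapply(seq_along(trajectories), function(r) {
    tr <- trajectories[[r]]
    L <- ncol(tr$site_frequencies)
    data.frame(
      replicate = r,
      time = rep(tr$times, each = L),
      site = rep(seq_len(L), times = length(tr$times)),
      s = rep(tr$profile, times = length(tr$times)),
      frequency = as.vector(t(tr$site_frequencies))
    )
  }))
}
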