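#' Time to population collapse
#'
#' Runs the stochastic engine until the collapse criterion first holds or the
#' horizon \code{max_time} is reached. \code{"f0_zero"} (default) declares
#' collapse when no cell retains damage exactly \code{epsilon} — the loss of
#' the initial-level class that precedes the rapid rise of mean damage — or
#' when the population is fully damaged; \code{"all_damage_one"} waits for
#' absorption into the all-ones state. Times are measured at elementary-step
#' resolution (\code{t_steps / N} time units).
#'
#' @param params a [damage_model()]; \code{params$seed} seeds the run.
#' @param criterion \code{"f0_zero"} or \code{"all_damage_one"}.
#' @param max_time censoring horizon in time units.
#' @return Object of class \code{"collapse_result"}: \code{tau},
#'   \code{censored}, \code{criterion}, \code{seed}.
#' @export
collapse_time <- function(params, criterion = c("f0_zero", "all_damage_one"),
                          max_time = 1e5) {
  criterion <- match.arg(criterion)
  tr <- run_simulation(params, max_time_units = max_time,
                       stop_criterion = criterion, record = FALSE)
  structure(list(tau = if (tr$collapsed) tr$collapse_time else max_time,
                 censored = !tr$collapsed,
                 criterion = criterion,
                 seed = params$seed),
            class = "collapse_result")
}

#' @export
#' @method print collapse_result
print.collapse_result <- function(x, ...) {
  cat(sprintf("Collapse time (%s, seed %d): %s%g time units\n",
              x$criterion, x$seed, if (x$censored) "> " else "", x$tau))
  invisible(x)
}

#' Median collapse time over replicates
#'
#' Runs \code{n_reps} independent replicates with seeds
#' \code{base_seed + 0:(n_reps-1)} and reports their median collapse time.
#' Censored replicates enter the median at their lower bound \code{max_time};
#' if at least half the replicates are censored the median itself is only a
#' lower bound and is reported as \code{Inf} with \code{median_censored =
#' TRUE} (read: "> max_time").
#'
#' @inheritParams collapse_time
#' @param n_reps number of replicates (>= 1).
#' @param base_seed base replicate seed; defaults to \code{params$seed}.
#' @return One-row data.frame: mode, topology, N, epsilon, p, delta,
#'   criterion, n_reps, n_censored, median_tau, median_censored.
#' @export
median_collapse_time <- function(params, n_reps = 20, base_seed = params$seed,
                                 criterion = c("f0_zero", "all_damage_one"),
                                 max_time = 1e5) {
  criterion <- match.arg(criterion)
  stopifnot(n_reps >= 1)
  taus <- numeric(n_reps)
  cens <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    pr <- params
    pr$seed <- as.integer(base_seed + r - 1L)
    cr <- collapse_time(pr, criterion = criterion, max_time = max_time)
    taus[r] <- cr$tau
    cens[r] <- cr$censored
  }
  if (any(cens))
    warning(sprintf("%d of %d replicates censored at max_time = %g",
                    sum(cens), n_reps, max_time), call. = FALSE)
  half_censored <- sum(cens) >= n_reps / 2
  data.frame(mode = params$mode, topology = params$topology, N = params$N,
             epsilon = params$epsilon, p = params$p, delta = params$delta,
             criterion = criterion, n_reps = n_reps, n_censored = sum(cens),
             median_tau = if (half_censored) Inf else stats::median(taus),
             median_censored = half_censored,
             stringsAsFactors = FALSE)
}

#' Median collapse time over a (p, delta) grid
#'
#' Full factorial sweep of the mutation probability and fragility for both
#' partitioning modes: the numerical counterpart of the stability heat maps.
#' Collapse time decreases with \code{p} and — counterintuitively — increases
#' with the fragility \code{delta}, because highly damaged cells are removed
#' more efficiently.
#'
#' @param params_base a [damage_model()] supplying all other fields.
#' @param p_grid,delta_grid numeric grids (non-empty).
#' @param n_reps replicates per grid point.
#' @param modes character vector of partitioning modes to sweep.
#' @inheritParams median_collapse_time
#' @return data.frame with one row per (mode, p, delta) combination.
#' @export
sweep_fragility_mutation <- function(params_base, p_grid, delta_grid,
                                     n_reps = 20,
                                     modes = c("symmetric", "asymmetric"),
                                     criterion = "f0_zero", max_time = 1e5) {
  stopifnot(length(p_grid) >= 1, length(delta_grid) >= 1)
  grid <- expand.grid(mode = modes, p = p_grid, delta = delta_grid,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pr <- params_base
    pr$mode <- grid$mode[i]
    pr$p <- grid$p[i]
    pr$delta <- grid$delta[i]
    median_collapse_time(pr, n_reps = n_reps, criterion = criterion,
                         max_time = max_time)
  })
  do.call(rbind, rows)
}

#' Median collapse time versus system size
#'
#' Sweeps the population size for the requested mode/topology variants and
#' reports, per variant, the successive-median ratio
#' \code{median_tau(N[i+1]) / median_tau(N[i])}: well-mixed populations show a
#' steeply growing ratio (collapse time diverges with N), ring populations a
#' ratio approaching 1 (each cell sees only an effective local system, so the
#' collapse time saturates).
#'
#' @param params_base a [damage_model()] supplying epsilon, p, delta.
#' @param N_grid increasing vector of population sizes.
#' @param n_reps replicates per point.
#' @param modes,topologies variants to sweep (default: all four).
#' @inheritParams median_collapse_time
#' @return data.frame with one row per (mode, topology, N); column
#'   \code{ratio_to_prev} holds the successive-median ratio within a variant.
#' @export
sweep_system_size <- function(params_base, N_grid, n_reps = 20,
                              modes = c("symmetric", "asymmetric"),
                              topologies = c("well_mixed", "ring_1d"),
                              criterion = "f0_zero", max_time = 1e5) {
  stopifnot(all(diff(N_grid) > 0), length(N_grid) >= 1)
  out <- list()
  for (mo in modes) for (to in topologies) {
    prev <- NA_real_
    for (N in N_grid) {
      pr <- params_base
      pr$mode <- mo; pr$topology <- to; pr$N <- as.integer(N)
      row <- median_collapse_time(pr, n_reps = n_reps, criterion = criterion,
                                  max_time = max_time)
      row$ratio_to_prev <- row$median_tau / prev
      prev <- row$median_tau
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Nearest-neighbour damage correlation on the ring
#'
#' Pearson correlation between the damage levels at ring positions \eqn{i} and
#' \eqn{i+1 \pmod N}, together with a permutation null: the same statistic on
#' \code{n_perm} random permutations of the vector. Clusters of damaged cells
#' make the observed correlation exceed the null.
#'
#' @param damages numeric damage vector (ring order, length >= 3).
#' @param n_perm number of permutations for the null distribution.
#' @return List: \code{correlation}, \code{null} (permutation statistics),
#'   \code{p_value} (upper tail, with the +1 continuity convention),
#'   \code{degenerate} (TRUE when the vector is constant; correlation then
#'   reported as 0).
#' @export
neighbor_correlation <- function(damages, n_perm = 1000) {
  stopifnot(length(damages) >= 3)
  nn_cor <- function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    stats::cor(v, v[c(2:length(v), 1)])
  }
  obs <- nn_cor(damages)
  if (is.na(obs)) {
    return(list(correlation = 0, null = rep(0, n_perm), p_value = NA_real_,
                degenerate = TRUE))
  }
  null <- vapply(seq_len(n_perm), function(i) nn_cor(sample(damages)),
                 numeric(1))
  list(correlation = obs, null = null,
       p_value = (sum(null >= obs) + 1) / (n_perm + 1),
       degenerate = FALSE)
}
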