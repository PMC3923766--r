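#' Initialise a population
#'
#' All \code{N} cells start at damage level \code{epsilon} with zero recorded
#' mutational increments, at elapsed time 0.
#'
#' @param params a [damage_model()] object.
#' @return An object of class \code{"population"}: list with \code{damages},
#'   \code{increments}, \code{t_steps} and \code{params}.
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "damage_model"))
  structure(list(damages = rep(params$epsilon, params$N),
                 increments = rep(0L, params$N),
                 t_steps = 0,
                 params = params),
            class = "population")
}

#' Advance a population by elementary steps
#'
#' Executes \code{n_steps} elementary steps (one random cell selection each)
#' using the current R RNG stream (seed it with \code{set.seed()} for
#' reproducibility). One time unit of the model corresponds to \code{N}
#' elementary steps, so that on average each cell is selected once per unit.
#'
#' @param pop a \code{"population"} object.
#' @param n_steps number of elementary steps to run (default 1).
#' @return The advanced \code{"population"}.
#' @export
step_population <- function(pop, n_steps = 1) {
  stopifnot(inherits(pop, "population"))
  p <- pop$params
  res <- .engine_run(pop$damages, pop$increments, pop$t_steps,
                     p$epsilon, p$p, p$delta,
                     .mode_int(p$mode), .topology_int(p$topology),
                     as.numeric(n_steps), record_every = 0L,
                     stop_criterion = 0L, record_kymograph = FALSE,
                     n_hist_bins = 1L)
  pop$damages <- res$damages
  pop$increments <- res$increments
  pop$t_steps <- res$t_steps
  pop
}

#' Summary statistics of a population
#'
#' @param pop a \code{"population"} object.
#' @return List with \code{t} (time units, \code{t_steps/N}),
#'   \code{mean_damage}, \code{f0} (fraction of cells whose damage equals
#'   \code{epsilon} exactly; unmutated lineages copy \code{epsilon} bit-exactly
#'   so the equality test is safe) and \code{histogram} (named vector of
#'   increment-count fractions).
#' @export
summarize_population <- function(pop) {
  stopifnot(inherits(pop, "population"))
  p <- pop$params
  h <- table(factor(pop$increments, levels = 0:max(pop$increments)))
  list(t = pop$t_steps / p$N,
       mean_damage = mean(pop$damages),
       f0 = mean(pop$damages == p$epsilon),
       histogram = as.numeric(h) / p$N)
}

#' Run the stochastic simulation
#'
#' Runs \code{N * max_time_units} elementary steps from the all-\code{epsilon}
#' initial state, recording summary statistics once per time unit. Stops early
#' (flagged) when a collapse criterion is met.
#'
#' @param params a [damage_model()]; \code{params$seed} seeds the run.
#' @param max_time_units time horizon in time units (> 0).
#' @param record_kymograph logical; record the full damage vector each time
#'   unit (rows = time units, columns = cell index) — the 1D analogue of a
#'   space-time heat map.
#' @param stop_criterion \code{"none"} (run to the horizon), \code{"f0_zero"}
#'   (stop when no cell retains damage exactly \code{epsilon}, or the
#'   population is fully damaged), or \code{"all_damage_one"}.
#' @param record logical; set \code{FALSE} to skip per-unit recording (faster
#'   collapse searches).
#' @param n_hist_bins number of increment-count bins recorded (counts beyond
#'   the last bin are lumped into it).
#' @return An object of class \code{"damage_trajectory"}: list with
#'   \code{summary} (data.frame \code{t}, \code{mean_damage}, \code{f0}),
#'   \code{hist} (matrix of increment-count fractions per recorded unit),
#'   \code{kymograph} (matrix or \code{NULL}), \code{collapsed},
#'   \code{collapse_time} (time units, \code{NA} if not collapsed),
#'   \code{final} (the final \code{"population"}), and \code{params}.
#' @examples
#' m <- damage_model(N = 50, epsilon = 0.1, p = 0.1, delta = 0.2, seed = 1)
#' tr <- run_simulation(m, max_time_units = 20)
#' head(tr$summary)
#' @export
run_simulation <- function(params, max_time_units,
                           record_kymograph = FALSE,
                           stop_criterion = c("none", "f0_zero", "all_damage_one"),
                           record = TRUE, n_hist_bins = 64L) {
  stopifnot(inherits(params, "damage_model"), max_time_units > 0)
  stop_criterion <- match.arg(stop_criterion)
  crit_int <- match(stop_criterion, c("none", "f0_zero", "all_damage_one")) - 1L
  pop <- init_population(params)
  set.seed(params$seed)
  res <- .engine_run(pop$damages, pop$increments, 0,
                     params$epsilon, params$p, params$delta,
                     .mode_int(params$mode), .topology_int(params$topology),
                     as.numeric(params$N) * max_time_units,
                     record_every = if (record) params$N else 0L,
                     stop_criterion = crit_int,
                     record_kymograph = record && record_kymograph,
                     n_hist_bins = as.integer(n_hist_bins))
  .as_trajectory(res, params, record, record_kymograph)
}

.as_trajectory <- function(res, params, record, record_kymograph) {
  s <- res$summary
  summary_df <- if (record && res$n_rec > 0) {
    data.frame(t = s[, 1], mean_damage = s[, 2], f0 = s[, 3])
  } else {
    data.frame(t = numeric(0), mean_damage = numeric(0), f0 = numeric(0))
  }
  hist <- if (record && res$n_rec > 0) {
    colnames(res$hist) <- paste0("k", seq_len(ncol(res$hist)) - 1L)
    res$hist
  } else NULL
  final <- structure(list(damages = res$damages, increments = res$increments,
                          t_steps = res$t_steps, params = params),
                     class = "population")
  structure(list(summary = summary_df,
                 hist = hist,
                 kymograph = if (record && record_kymograph) res$kymograph else NULL,
                 collapsed = res$collapsed,
                 collapse_time = if (res$collapsed) res$collapse_t_steps / params$N else NA_real_,
                 final = final,
                 params = params),
            class = "damage_trajectory")
}

#' Simulate trajectories from a damage model
#'
#' \code{stats::simulate} method: runs [run_simulation()] \code{nsim} times with
#' replicate seeds \code{seed + 0:(nsim-1)}.
#'
#' @param object a [damage_model()].
#' @param nsim number of replicate trajectories.
#' @param seed base seed; defaults to \code{object$seed}.
#' @param max_time_units time horizon in time units.
#' @param ... passed to [run_simulation()].
#' @return A single \code{"damage_trajectory"} if \code{nsim = 1}, else a list
#'   of them.
#' @export
simulate.damage_model <- function(object, nsim = 1, seed = NULL,
                                  max_time_units = 100, ...) {
  base_seed <- if (is.null(seed)) object$seed else seed
  out <- lapply(seq_len(nsim) - 1L, function(k) {
    pk <- object
    pk$seed <- as.integer(base_seed + k)
    run_simulation(pk, max_time_units = max_time_units, ...)
  })
  if (nsim == 1) out[[1]] else out
}

#' @export
#' @method print damage_trajectory
print.damage_trajectory <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf("Damage trajectory: %d recorded time units (N = %d, %s, %s)\n",
              n, x$params$N, x$params$mode, x$params$topology))
  if (x$collapsed)
    cat(sprintf("  collapsed at t = %.4g time units\n", x$collapse_time))
  else
    cat("  did not collapse within the horizon\n")
  if (n > 0) {
    last <- x$summary[n, ]
    cat(sprintf("  last record: t = %g, <d> = %.4f, f0 = %.4f\n",
                last$t, last$mean_damage, last$f0))
  }
  invisible(x)
}

#' @export
#' @method summary damage_trajectory
summary.damage_trajectory <- function(object, plateau = NULL, ...) {
  s <- object$summary
  out <- list(params = object$params, collapsed = object$collapsed,
              collapse_time = object$collapse_time)
  if (!is.null(plateau) && nrow(s) > 0) {
    w <- s$t >= plateau[1] & s$t <= plateau[2]
    out$plateau_mean_damage <- mean(s$mean_damage[w])
    out$plateau_f0 <- mean(s$f0[w])
  }
  out
}

#' @export
#' @method plot damage_trajectory
plot.damage_trajectory <- function(x, which = c("summary", "kymograph"), ...) {
  which <- match.arg(which)
  s <- x$summary
  if (which == "kymograph") {
    if (is.null(x$kymograph)) stop("no kymograph recorded", call. = FALSE)
    graphics::image(x = s$t, y = seq_len(x$params$N), z = x$kymograph,
                    xlab = "time (units)", ylab = "cell index",
                    main = "Damage kymograph", ...)
  } else {
    graphics::plot(s$t, s$mean_damage, type = "l", ylim = c(0, 1),
                   xlab = "time (units)", ylab = "",
                   main = sprintf("N = %d, %s, %s", x$params$N, x$params$mode,
                                  x$params$topology), ...)
    graphics::lines(s$t, s$f0, lty = 2)
    graphics::legend("topright", legend = c("mean damage", "f0"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
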