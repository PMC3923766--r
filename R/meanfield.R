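#' Mean-field hierarchy right-hand side
#'
#' Time derivative of the fractions of cells having received \eqn{k} mutational
#' increments, for the well-mixed system. A class-\eqn{k} cell has damage
#' \eqn{d_k = \epsilon + k s} with \eqn{s = \Delta/2} (symmetric partitioning)
#' or \eqn{s = \Delta} (asymmetric), clamped at 1. The hierarchy is closed
#' through the population mean damage \eqn{\langle d\rangle = \sum_k d_k x_k}:
#' \deqn{\dot x_k = -d_k x_k + (1-2p)\langle d\rangle x_k +
#'       2p\langle d\rangle x_{k-1} \quad \mathrm{(symmetric)}}
#' \deqn{\dot a_j = -d_j a_j + (1-p)\langle d\rangle a_j +
#'       p\langle d\rangle a_{j-1} \quad \mathrm{(asymmetric)}}
#' In the symmetric case a mutated division removes the parent from class
#' \eqn{k} and creates two class-\eqn{k+1} daughters, hence the factor 2; in
#' the asymmetric case one daughter stays in class \eqn{j}, so only the
#' promotion to \eqn{j+1} appears. Both conserve total fraction exactly.
#'
#' @param x numeric vector of class fractions, index \code{0:(length(x)-1)}.
#' @param params a [damage_model()] (only \code{epsilon}, \code{p},
#'   \code{delta} are used; must be well-mixed).
#' @param mode partitioning mode; defaults to \code{params$mode}.
#' @param split symmetric-split reading: \code{"half"} (each daughter gets
#'   \code{delta/2}; the default model convention) or \code{"full"} (each
#'   daughter gets \code{delta}). Exposed as a robustness knob: the steady
#'   state mean damage is identical under either reading, only the increment
#'   lattice and hence the Poisson mean differ by a factor 2.
#' @return Numeric vector of the same length: d/dt of each fraction.
#' @export
meanfield_rhs <- function(x, params, mode = params$mode, split = c("half", "full")) {
  split <- match.arg(split)
  stopifnot(is.numeric(x), length(x) >= 1, all(is.finite(x)))
  s <- if (mode == "symmetric" && split == "half") params$delta / 2 else params$delta
  k <- seq_along(x) - 1
  d_k <- pmin(params$epsilon + k * s, 1)
  dbar <- sum(d_k * x)
  p <- params$p
  K <- length(x)
  xm1 <- c(0, x[-K])
  # the top class is lumped ("K or more"): promotion out of it stays in it,
  # so total fraction is conserved exactly for any state, not only when the
  # tail is empty
  out <- if (mode == "symmetric") {
    r <- -d_k * x + (1 - 2 * p) * dbar * x + 2 * p * dbar * xm1
    r[K] <- r[K] + 2 * p * dbar * x[K]
    r
  } else {
    r <- -d_k * x + (1 - p) * dbar * x + p * dbar * xm1
    r[K] <- r[K] + p * dbar * x[K]
    r
  }
  out
}

#' Integrate the mean-field hierarchy to its stationary point
#'
#' Fixed-step 4th-order Runge-Kutta integration (step 0.01 time units, via
#' \pkg{deSolve}) of the truncated hierarchy from the all-in-class-0 initial
#' condition, until \code{max|rhs| < tol} or the time horizon is exhausted.
#' The truncation index doubles automatically whenever the tail mass at the
#' last class exceeds \code{1e-8}.
#'
#' @inheritParams meanfield_rhs
#' @param k_max initial truncation index (classes \code{0:k_max}).
#' @param tol stationarity tolerance on \code{max|rhs|}.
#' @param t_max integration horizon in time units.
#' @return List of class \code{"meanfield_state"}: \code{x} (fractions),
#'   \code{k_max}, \code{mode}, \code{mean_damage}, \code{converged},
#'   \code{max_rhs}, \code{norm_error}.
#' @export
meanfield_integrate <- function(params, mode = params$mode, k_max = 40,
                                tol = 1e-10, t_max = 2000,
                                split = c("half", "full")) {
  split <- match.arg(split)
  deriv <- function(t, y, parms) list(meanfield_rhs(y, params, mode, split))
  x <- c(1, rep(0, k_max))
  t_done <- 0
  chunk <- 20
  converged <- FALSE
  drift <- 0
  # The constant-total-fraction manifold is invariant but transversally
  # unstable (off it, the total grows at rate <d>), so roundoff must not be
  # allowed to accumulate: renormalise after every chunk and track the drift.
  while (t_done < t_max) {
    times <- seq(0, chunk, by = 0.01)
    sol <- deSolve::rk4(y = x, times = times, func = deriv, parms = NULL)
    x <- as.numeric(sol[nrow(sol), -1])
    drift <- drift + abs(sum(x) - 1)
    x <- x / sum(x)
    t_done <- t_done + chunk
    if (x[length(x)] > 1e-8) {  # truncation inadequate: double and restart
      k_max <- 2 * k_max
      x <- c(1, rep(0, k_max))
      t_done <- 0
      drift <- 0
      next
    }
    if (max(abs(meanfield_rhs(x, params, mode, split))) < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(x = x, k_max = k_max, mode = mode, split = split,
                 mean_damage = sum(pmin(params$epsilon + (seq_along(x) - 1) *
                   (if (mode == "symmetric" && split == "half") params$delta / 2
                    else params$delta), 1) * x),
                 converged = converged,
                 max_rhs = max(abs(meanfield_rhs(x, params, mode, split))),
                 norm_error = drift),
            class = "meanfield_state")
}

#' Analytic transient steady state
#'
#' Closed-form quasi-stationary state of the well-mixed hierarchy. Setting the
#' class-0 balance to zero gives the steady-state mean damage
#' \eqn{d^* = \epsilon/(1-2p)} (symmetric) or \eqn{d^* = \epsilon/(1-p)}
#' (asymmetric); the recurrence over classes then yields a Poisson distribution
#' of increment counts with mean \eqn{\lambda = 4 p d^*/\Delta} (symmetric,
#' \eqn{\Delta/2} lattice) or \eqn{\lambda = p d^*/\Delta} (asymmetric), and
#' the fraction of cells still at the initial damage level is
#' \eqn{x_0 = e^{-\lambda}}. The state exists only when the denominator is
#' positive and \eqn{0 < d^* \le 1}.
#'
#' With \code{generation >= 1} the post-collapse steady states are returned:
#' once the initial-level class is lost, the same analysis applies with the
#' base level shifted up one lattice step per generation
#' (\eqn{\epsilon \to \epsilon + g\Delta/2} symmetric,
#' \eqn{\epsilon \to \epsilon + g\Delta} asymmetric), giving successively
#' larger \eqn{\lambda} and hence less stable states.
#'
#' @inheritParams meanfield_rhs
#' @param generation non-negative integer; 0 is the primary steady state.
#' @return Object of class \code{"steady_state"}: \code{d_star},
#'   \code{lambda}, \code{x0}, \code{mode}, \code{exists}, \code{base_level},
#'   \code{generation}.
#' @examples
#' m <- damage_model(100, 0.1, 0.1, 0.2)
#' steady_state(m)                        # d* = 0.125, lambda = 0.25
#' steady_state(m, mode = "asymmetric")   # d* = 0.1111, lambda = 0.0556
#' @export
steady_state <- function(params, mode = params$mode, generation = 0,
                         split = c("half", "full")) {
  split <- match.arg(split)
  stopifnot(generation >= 0, generation == round(generation))
  s_latt <- if (mode == "symmetric" && split == "half") params$delta / 2 else params$delta
  base <- params$epsilon + generation * s_latt
  denom <- if (mode == "symmetric") 1 - 2 * params$p else 1 - params$p
  exists <- denom > 0
  d_star <- if (exists) base / denom else NA_real_
  if (exists && (d_star <= 0 || d_star > 1)) exists <- FALSE
  lambda <- if (exists) {
    if (mode == "symmetric") {
      if (split == "half") 4 * params$p * d_star / params$delta
      else 2 * params$p * d_star / params$delta
    } else params$p * d_star / params$delta
  } else NA_real_
  structure(list(d_star = d_star, lambda = lambda,
                 x0 = if (exists) exp(-lambda) else NA_real_,
                 mode = mode, exists = exists,
                 base_level = base, generation = generation),
            class = "steady_state")
}

#' Post-collapse steady states
#'
#' Convenience wrapper: [steady_state()] with \code{generation >= 1}.
#' @inheritParams steady_state
#' @export
post_collapse_state <- function(params, mode = params$mode, generation = 1) {
  steady_state(params, mode = mode, generation = generation)
}

#' @export
#' @method print steady_state
print.steady_state <- function(x, ...) {
  if (!x$exists) {
    cat(sprintf("Transient steady state (%s): does not exist (base level %g)\n",
                x$mode, x$base_level))
  } else {
    cat(sprintf("Transient steady state (%s%s):\n", x$mode,
                if (x$generation > 0) sprintf(", post-collapse generation %d",
                                              x$generation) else ""))
    cat(sprintf("  d* = %.6g   lambda = %.6g   x0 = exp(-lambda) = %.6g\n",
                x$d_star, x$lambda, x$x0))
  }
  invisible(x)
}

#' Truncated Poisson probability vector
#'
#' @param lambda Poisson mean (>= 0).
#' @param k_max last class index retained.
#' @return Normalised probabilities over \code{0:k_max}; the truncation mass
#'   that was renormalised away is attached as attribute \code{"renorm_error"}.
#' @export
poisson_pmf <- function(lambda, k_max) {
  stopifnot(lambda >= 0, k_max >= 0)
  p <- stats::dpois(0:k_max, lambda)
  err <- 1 - sum(p)
  out <- p / sum(p)
  attr(out, "renorm_error") <- err
  out
}

#' Compare symmetric and asymmetric steady states
#'
#' Evaluates both closed forms at the same \eqn{(\epsilon, p, \Delta)} and
#' reports the orderings: asymmetric partitioning always yields a lower steady
#' state damage level and a larger unmutated fraction whenever both states
#' exist.
#'
#' @param params a [damage_model()].
#' @return List with both steady states and the logical checks
#'   \code{d_star_asym_lower}, \code{x0_asym_higher} (ties allowed only at
#'   \code{p = 0}).
#' @export
compare_modes <- function(params) {
  ss <- steady_state(params, mode = "symmetric")
  sa <- steady_state(params, mode = "asymmetric")
  if (!ss$exists || !sa$exists)
    stop("steady state does not exist for both modes at these parameters",
         call. = FALSE)
  list(symmetric = ss, asymmetric = sa,
       d_star_asym_lower = if (params$p == 0) sa$d_star == ss$d_star
                           else sa$d_star < ss$d_star,
       x0_asym_higher = if (params$p == 0) sa$x0 == ss$x0 else sa$x0 > ss$x0)
}
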