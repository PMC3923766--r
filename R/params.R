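#' Define a damage-segregation tissue model
#'
#' Constructs the parameter object for the stochastic model of damage
#' accumulation in a homeostatic tissue of \code{N} cells. Each cell carries a
#' damage level in \eqn{[0,1]} (here interpreted as the load of mitochondrial
#' DNA mutations) which doubles as its per-selection apoptosis probability.
#' Apoptotic cells are replaced by the division of another cell; with
#' probability \code{p} a division adds \code{delta} new damage, split equally
#' between the daughters (\code{mode = "symmetric"}, \code{delta/2} each) or
#' given entirely to one daughter (\code{mode = "asymmetric"}). Damage is
#' irreversible and capped at 1.
#'
#' @param N integer number of cells (homeostatic, constant); must be >= 2 so an
#'   apoptotic cell always has another cell available to divide.
#' @param epsilon initial damage level of every cell, in \eqn{[0,1]}.
#' @param p probability that a division transmits newly acquired damage, in
#'   \eqn{[0,1]}.
#' @param delta damage increment per mutated division ("fragility"), > 0.
#' @param mode damage partitioning at mutated divisions: \code{"symmetric"}
#'   (both daughters get \code{delta/2}) or \code{"asymmetric"} (one daughter
#'   gets all of \code{delta}).
#' @param topology \code{"well_mixed"} (any cell may replace the apoptotic one)
#'   or \code{"ring_1d"} (1D lattice with periodic boundaries; only the two
#'   neighbours may divide into the vacancy).
#' @param seed non-negative integer RNG seed used by [simulate.damage_model()].
#'
#' @return An immutable object of class \code{"damage_model"}: a list with the
#'   seven validated fields.
#'
#' @examples
#' m <- damage_model(N = 100, epsilon = 0.1, p = 0.1, delta = 0.2)
#' m
#' @seealso [simulate.damage_model()], [steady_state()], [collapse_time()]
#' @export
damage_model <- function(N, epsilon, p, delta,
                         mode = c("symmetric", "asymmetric"),
                         topology = c("well_mixed", "ring_1d"),
                         seed = 0L) {
  mode <- match.arg(mode)
  topology <- match.arg(topology)
  chk_num <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    as.numeric(x)
  }
  N <- chk_num(N, "N"); epsilon <- chk_num(epsilon, "epsilon")
  p <- chk_num(p, "p"); delta <- chk_num(delta, "delta")
  seed <- chk_num(seed, "seed")
  if (N != round(N) || N < 2) stop("N must be >= 2 (an integer)", call. = FALSE)
  if (epsilon < 0 || epsilon > 1) stop("epsilon out of range [0,1]", call. = FALSE)
  if (p < 0 || p > 1) stop("p out of range [0,1]", call. = FALSE)
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (seed != round(seed) || seed < 0)
    stop("seed must be a non-negative integer", call. = FALSE)
  if (epsilon == 0)
    warning("epsilon = 0: apoptosis can never occur, dynamics are frozen",
            call. = FALSE)
  if (epsilon == 1)
    warning("epsilon = 1: the population starts in the absorbing all-ones state",
            call. = FALSE)
  obj <- list(N = as.integer(N), epsilon = epsilon, p = p, delta = delta,
              mode = mode, topology = topology, seed = as.integer(seed))
  class(obj) <- "damage_model"
  obj
}

#' Validate a raw parameter mapping
#'
#' Accepts a flat named list (e.g. parsed from a JSON config, keys \code{n},
#' \code{epsilon}, \code{p}, \code{delta}, \code{mode}, \code{topology},
#' \code{seed}) and returns a validated [damage_model()].
#'
#' @param raw named list with the seven model fields (case-insensitive \code{n}).
#' @return A \code{"damage_model"} object.
#' @export
validate_params <- function(raw) {
  stopifnot(is.list(raw))
  nm <- names(raw)
  nm[nm == "n"] <- "N"
  names(raw) <- nm
  required <- c("N", "epsilon", "p", "delta", "mode", "topology", "seed")
  missing <- setdiff(required, nm)
  if (length(missing))
    stop("missing field(s): ", paste(missing, collapse = ", "), call. = FALSE)
  do.call(damage_model, raw[required])
}

#' @export
#' @method print damage_model
print.damage_model <- function(x, ...) {
  cat("Damage-segregation tissue model\n")
  cat(sprintf("  N = %d cells, topology = %s\n", x$N, x$topology))
  cat(sprintf("  epsilon = %g, p = %g, delta = %g, mode = %s, seed = %d\n",
              x$epsilon, x$p, x$delta, x$mode, x$seed))
  ss <- steady_state(x)
  if (ss$exists)
    cat(sprintf("  mean-field steady state: d* = %.6g, lambda = %.6g, x0 = %.6g\n",
                ss$d_star, ss$lambda, ss$x0))
  else
    cat("  mean-field steady state: does not exist for these parameters\n")
  invisible(x)
}

#' Per-selection apoptosis probability
#'
#' The apoptosis probability of a selected cell is proportional to its damage
#' level; the proportionality constant is 1 (damage already lives on
#' \eqn{[0,1]}), so the probability equals the damage level itself.
#'
#' @param d damage level(s) in \eqn{[0,1]} (vectorised).
#' @return The apoptosis probability, equal to \code{d}.
#' @export
apoptosis_prob <- function(d) {
  if (any(d < 0 | d > 1)) stop("damage level outside [0,1]", call. = FALSE)
  d
}

#' Daughter damage levels at division
#'
#' Implements irreversible inheritance: each daughter receives at least the
#' parent's damage. An unmutated division copies the parent level exactly. A
#' mutated division adds \code{delta} in total: split \code{delta/2} per
#' daughter under symmetric partitioning, or all to one daughter under
#' asymmetric partitioning. Each daughter is clamped at 1 after the increment.
#'
#' @param d_parent parent damage level in \eqn{[0,1]}.
#' @param mutated logical; did this division transmit new damage?
#' @param mode \code{"symmetric"} or \code{"asymmetric"}.
#' @param delta damage increment (> 0).
#' @return Named numeric vector \code{c(d_high, d_low)} with
#'   \code{d_high >= d_low}, both in \code{[d_parent, 1]}.
#' @examples
#' daughter_damages(0.3, TRUE, "asymmetric", 0.2)  # c(0.5, 0.3)
#' daughter_damages(0.3, TRUE, "symmetric", 0.2)   # c(0.4, 0.4)
#' @export
daughter_damages <- function(d_parent, mutated, mode = c("symmetric", "asymmetric"),
                             delta) {
  mode <- match.arg(mode)
  stopifnot(length(d_parent) == 1L, d_parent >= 0, d_parent <= 1, delta > 0)
  if (!mutated) {
    out <- c(d_parent, d_parent)
  } else if (mode == "symmetric") {
    v <- min(d_parent + delta / 2, 1)
    out <- c(v, v)
  } else {
    out <- c(min(d_parent + delta, 1), d_parent)
  }
  names(out) <- c("d_high", "d_low")
  out
}

# internal enum coders shared with the C++ engine
.mode_int <- function(mode) match(mode, c("symmetric", "asymmetric")) - 1L
.topology_int <- function(topology) match(topology, c("well_mixed", "ring_1d")) - 1L

# per-daughter damage-lattice spacing for a partitioning mode
.lattice_step <- function(mode, delta) if (mode == "symmetric") delta / 2 else delta
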