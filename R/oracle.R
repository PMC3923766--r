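# Exact Markov-chain analysis of tiny instances. The reachable damage values
# are generated by the same repeated floating-point addition the engine
# performs (d <- d + delta/2 or d + delta, clamped at 1), so exact-equality
# bookkeeping matches the simulation bit for bit.

.damage_levels <- function(params, mode = params$mode) {
  s <- .lattice_step(mode, params$delta)
  if (params$epsilon >= 1) return(1)
  levels <- params$epsilon
  v <- params$epsilon
  repeat {
    v <- v + s
    if (v >= 1) { levels <- c(levels, 1); break }
    levels <- c(levels, v)
  }
  levels
}

.key_counts <- function(counts) paste(counts, collapse = ",")

.ring_canonical <- function(x) {
  n <- length(x)
  best <- NULL
  for (v in list(x, rev(x))) {
    for (r in 0:(n - 1)) {
      cand <- c(v[(r + 1):n], if (r > 0) v[1:r])
      if (is.null(best) ||
          {cmp <- cand - best; nz <- which(cmp != 0); length(nz) > 0 && cmp[nz[1]] < 0})
        best <- cand
    }
  }
  best
}

# transitions from one state; returns list(keys = character, probs = numeric)
# including the self-loop. Well-mixed states are count vectors over levels;
# ring states are canonical level-index tuples.
.transitions_from <- function(state, params, L) {
  p <- params$p
  N <- params$N
  vals <- attr(state, "levels")
  succ <- function(l) min(l + 1L, L)
  acc <- new.env(parent = emptyenv())
  add <- function(key, pr) {
    if (pr <= 0) return()
    cur <- if (is.null(acc[[key]])) 0 else acc[[key]]
    acc[[key]] <- cur + pr
  }
  if (params$topology == "well_mixed") {
    c0 <- state
    self <- 0
    for (a in seq_len(L)) {
      if (c0[a] == 0) next
      self <- self + (c0[a] / N) * (1 - vals[a])
      p_death <- (c0[a] / N) * vals[a]
      if (p_death == 0) next
      for (b in seq_len(L)) {
        avail <- c0[b] - (a == b)
        if (avail <= 0) next
        p_div <- p_death * avail / (N - 1)
        # unmutated: remove apoptotic a, divider b yields two copies of b
        nu <- c0; nu[a] <- nu[a] - 1L; nu[b] <- nu[b] + 1L
        add(.key_counts(nu), p_div * (1 - p))
        # mutated
        if (p > 0) {
          nm <- c0; nm[a] <- nm[a] - 1L
          if (params$mode == "symmetric") {
            nm[b] <- nm[b] - 1L
            nm[succ(b)] <- nm[succ(b)] + 2L
          } else {
            nm[succ(b)] <- nm[succ(b)] + 1L
          }
          add(.key_counts(nm), p_div * p)
        }
      }
    }
    add(.key_counts(c0), self)
  } else {
    x0 <- as.integer(state)
    self <- 0
    for (i in seq_len(N)) {
      v <- vals[x0[i]]
      self <- self + (1 / N) * (1 - v)
      p_death <- v / N
      if (p_death == 0) next
      for (j in c(if (i == 1) N else i - 1L, if (i == N) 1L else i + 1L)) {
        p_div <- p_death / 2
        y <- x0; y[i] <- x0[j]
        add(.key_counts(.ring_canonical(y)), p_div * (1 - p))
        if (p > 0) {
          if (params$mode == "symmetric") {
            y <- x0; y[i] <- succ(x0[j]); y[j] <- succ(x0[j])
            add(.key_counts(.ring_canonical(y)), p_div * p)
          } else {
            y1 <- x0; y1[i] <- succ(x0[j])               # high daughter fills vacancy
            y2 <- x0; y2[i] <- x0[j]; y2[j] <- succ(x0[j]) # high daughter on divider slot
            add(.key_counts(.ring_canonical(y1)), p_div * p / 2)
            add(.key_counts(.ring_canonical(y2)), p_div * p / 2)
          }
        }
      }
    }
    add(.key_counts(.ring_canonical(x0)), self)
  }
  keys <- ls(acc)
  list(keys = keys, probs = vapply(keys, function(k) acc[[k]], numeric(1)))
}

#' Enumerate the reachable state space of a tiny instance
#'
#' Breadth-first closure of the one-step dynamics from the all-\code{epsilon}
#' state. Well-mixed states are stored as multisets (count vectors over the
#' clamped damage lattice; the dynamics are exchangeable), ring states as
#' tuples up to rotation and reflection.
#'
#' @param params a [damage_model()].
#' @param max_states enumeration bound; exceeded state counts raise an error
#'   (use a smaller \code{N} or a larger \code{delta}).
#' @return Object of class \code{"state_space"}: \code{states} (list of count
#'   vectors or canonical tuples), \code{keys}, \code{levels} (damage values),
#'   \code{initial} (index of the all-epsilon state), \code{absorbing_all_one}
#'   (indices), \code{params}.
#' @export
enumerate_states <- function(params, max_states = 20000) {
  stopifnot(inherits(params, "damage_model"))
  levels <- .damage_levels(params)
  L <- length(levels)
  if (params$topology == "well_mixed" &&
      choose(params$N + L - 1, L - 1) > max_states)
    stop("state space bound exceeded; use smaller N or larger delta",
         call. = FALSE)
  init <- if (params$topology == "well_mixed") {
    c0 <- integer(L); c0[1] <- params$N; c0
  } else rep(1L, params$N)
  attr(init, "levels") <- levels
  states <- list(init)
  keys <- .key_counts(if (params$topology == "well_mixed") init
                      else .ring_canonical(init))
  seen <- new.env(parent = emptyenv())
  seen[[keys[1]]] <- 1L
  queue <- 1L
  while (length(queue)) {
    idx <- queue[1]; queue <- queue[-1]
    st <- states[[idx]]
    attr(st, "levels") <- levels
    tr <- .transitions_from(st, params, L)
    for (k in tr$keys) {
      if (is.null(seen[[k]])) {
        if (length(states) + 1L > max_states)
          stop("state space bound exceeded; use smaller N or larger delta",
               call. = FALSE)
        newstate <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
        states[[length(states) + 1L]] <- newstate
        keys <- c(keys, k)
        seen[[k]] <- length(states)
        queue <- c(queue, length(states))
      }
    }
  }
  all_one <- vapply(states, function(s) {
    if (params$topology == "well_mixed") s[L] == params$N else all(s == L)
  }, logical(1))
  structure(list(states = states, keys = keys, levels = levels,
                 initial = 1L, absorbing_all_one = which(all_one),
                 params = params),
            class = "state_space")
}

#' Exact one-step transition matrix
#'
#' Row-stochastic matrix of the elementary-step dynamics on an enumerated
#' state space; the self-loop mass includes all apoptosis-failed selections.
#'
#' @param space a [enumerate_states()] result.
#' @param params the same [damage_model()] used for the enumeration.
#' @return A sparse \code{dgCMatrix} with rows summing to 1.
#' @export
transition_matrix <- function(space, params = space$params) {
  n <- length(space$states)
  L <- length(space$levels)
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(n)) idx[[space$keys[i]]] <- i
  ii <- jj <- integer(0); pp <- numeric(0)
  for (i in seq_len(n)) {
    st <- space$states[[i]]
    attr(st, "levels") <- space$levels
    tr <- .transitions_from(st, params, L)
    ii <- c(ii, rep(i, length(tr$keys)))
    jj <- c(jj, vapply(tr$keys, function(k) idx[[k]], integer(1)))
    pp <- c(pp, tr$probs)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = pp, dims = c(n, n))
}

#' Exact expected absorption time
#'
#' Solves the fundamental linear system \eqn{(I - Q)\,t = 1} over the
#' transient states and returns the expected time to collapse from the
#' all-\code{epsilon} state, converted from elementary steps to time units
#' (divide by \code{N}). Under \code{"all_damage_one"} the absorbing set is
#' the fully damaged state; under \code{"f0_zero"} every state without a cell
#' at the initial damage level (or fully damaged) is treated as absorbed.
#'
#' @param space a [enumerate_states()] result.
#' @param P the matching [transition_matrix()].
#' @param params the same [damage_model()].
#' @param criterion \code{"all_damage_one"} or \code{"f0_zero"}.
#' @return List: \code{expected_tau} (time units; \code{Inf} when absorption
#'   is impossible), \code{expected_steps}, \code{finite}, \code{criterion}.
#' @export
expected_absorption_time <- function(space, P, params = space$params,
                                     criterion = c("all_damage_one", "f0_zero")) {
  criterion <- match.arg(criterion)
  n <- length(space$states)
  L <- length(space$levels)
  absorbed <- vapply(seq_len(n), function(i) {
    s <- space$states[[i]]
    all_one <- if (params$topology == "well_mixed") s[L] == params$N
               else all(s == L)
    if (criterion == "all_damage_one") all_one
    else {
      n_eps <- if (params$topology == "well_mixed") s[1] else sum(s == 1L)
      (params$epsilon < 1 && n_eps == 0) || all_one
    }
  }, logical(1))
  if (absorbed[space$initial])
    return(list(expected_tau = 0, expected_steps = 0, finite = TRUE,
                criterion = criterion))
  if (params$p == 0 || params$epsilon == 0 || !any(absorbed))
    return(list(expected_tau = Inf, expected_steps = Inf, finite = FALSE,
                criterion = criterion))
  trans <- which(!absorbed)
  Q <- P[trans, trans, drop = FALSE]
  t_steps <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Diagonal(length(trans)) - Q,
                             rep(1, length(trans)))),
    error = function(e) NULL)
  if (is.null(t_steps))
    return(list(expected_tau = Inf, expected_steps = Inf, finite = FALSE,
                criterion = criterion))
  steps <- t_steps[match(space$initial, trans)]
  list(expected_tau = steps / params$N, expected_steps = steps, finite = TRUE,
       criterion = criterion)
}

#' Empirical one-step transition frequencies
#'
#' Samples \code{n_samples} independent elementary steps from a fixed state
#' via the simulation engine and tabulates the resulting states on the keys of
#' an enumerated state space — an exactness check of the engine against the
#' analytic transition matrix.
#'
#' @param space a [enumerate_states()] result.
#' @param state_index index of the source state in \code{space}.
#' @param n_samples number of independent one-step draws.
#' @param params the same [damage_model()]; \code{params$seed} seeds the draws.
#' @return Named numeric vector of frequencies over \code{space$keys}.
#' @export
one_step_frequencies <- function(space, state_index, n_samples,
                                 params = space$params) {
  st <- space$states[[state_index]]
  damages <- if (params$topology == "well_mixed") {
    rep(space$levels, st)
  } else space$levels[st]
  set.seed(params$seed)
  out <- .engine_one_step_samples(damages, rep(0L, params$N),
                                  params$epsilon, params$p, params$delta,
                                  .mode_int(params$mode),
                                  .topology_int(params$topology),
                                  as.integer(n_samples))
  lvl_of <- function(v) match(v, space$levels)
  keys <- vapply(seq_len(nrow(out)), function(r) {
    li <- lvl_of(out[r, ])
    if (params$topology == "well_mixed") {
      cnt <- tabulate(li, nbins = length(space$levels))
      .key_counts(cnt)
    } else .key_counts(.ring_canonical(li))
  }, character(1))
  tab <- table(factor(keys, levels = space$keys))
  fr <- as.numeric(tab) / n_samples
  names(fr) <- space$keys
  fr
}
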