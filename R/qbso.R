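#' Search configuration for the Q-learning bee swarm optimiser
#'
#' Houses the search hyper-parameters: `flip` controls both
#' the number of candidate solutions per strategy and the number of bits each
#' candidate flips (`n/flip`); `n_bees` bees explore the search areas;
#' `max_iteration` outer rounds; `local_iteration` Q-learning steps per bee;
#' `gamma` the discount applied to stored Q values; `init_fraction` the
#' fraction of features set in a fresh random reference solution.
#'
#' @param flip positive integer (default 5).
#' @param n_bees positive integer (default 10).
#' @param max_iteration positive integer (default 10).
#' @param local_iteration positive integer (default 10).
#' @param gamma discount in \[0, 1\] (default 0.1).
#' @param init_fraction fraction in (0, 1) (default 0.2).
#' @param seed integer seed for the search's randomness.
#' @return list of class `search_config`.
#' @export
search_config <- function(flip = 5, n_bees = 10, max_iteration = 10,
                          local_iteration = 10, gamma = 0.1,
                          init_fraction = 0.2, seed = 1) {
  stopifnot(flip >= 1, n_bees >= 1, max_iteration >= 1, local_iteration >= 1,
            gamma >= 0, gamma <= 1, init_fraction > 0, init_fraction < 1)
  structure(list(flip = as.integer(flip), n_bees = as.integer(n_bees),
                 max_iteration = as.integer(max_iteration),
                 local_iteration = as.integer(local_iteration),
                 gamma = gamma, init_fraction = init_fraction,
                 seed = as.integer(seed)),
            class = "search_config")
}

#' Q-table with zero default
#'
#' Stores learned values for (solution, bit-flip) pairs; any pair never
#' written reads as 0. The state key is the canonical 0/1 encoding of the
#' solution mask.
#'
#' @return an empty Q-table (environment-backed).
#' @export
new_qtable <- function() new.env(parent = emptyenv())

#' @rdname new_qtable
#' @param qtable a Q-table.
#' @param mask 0/1 solution mask (the state).
#' @param action bit index flipped (the action).
#' @export
q_value <- function(qtable, mask, action) {
  key <- mask_key(mask)
  if (exists(key, envir = qtable, inherits = FALSE))
    get(key, envir = qtable)[action]
  else 0
}

# per-state storage: one numeric vector of action values, zero-initialised
q_state <- function(qtable, key, n) {
  if (exists(key, envir = qtable, inherits = FALSE)) get(key, envir = qtable)
  else numeric(n)
}

#' Random initial reference solution
#'
#' Draws a solution with `round(fraction * n_features)` bits set (at least
#' one), chosen uniformly without replacement. Uses the current RNG stream.
#'
#' @param n_features mask length.
#' @param fraction fraction of bits to set, in (0, 1); the reference setting
#'   starts from 20% of the features.
#' @return integer 0/1 mask of length `n_features`.
#' @export
initial_reference <- function(n_features, fraction = 0.2) {
  stopifnot(n_features >= 1, fraction > 0, fraction < 1)
  n_set <- max(1L, round(fraction * n_features))
  mask <- integer(n_features)
  mask[sample.int(n_features, n_set)] <- 1L
  mask
}

#' Candidate solutions around a reference (the search area)
#'
#' Generates `flip` candidates from a reference solution. Under strategy 1,
#' candidate k (k = 1..flip) flips the interleaved bits k, k+flip, k+2*flip,
#' ... Under strategy 2, candidate k flips a contiguous block of
#' `floor(n/flip)` bits starting at position (k-1)*floor(n/flip)+1; when
#' `flip` does not divide n the final block absorbs the remainder. Each
#' candidate differs from the reference exactly at its flipped bits, and the
#' flipped sets partition the bit positions.
#'
#' @param refsol 0/1 reference mask.
#' @param flip number of candidates (and the stride/block divisor).
#' @param strategy 1 (interleaved) or 2 (contiguous blocks).
#' @return list of `flip` masks.
#' @export
search_area <- function(refsol, flip, strategy = 1) {
  n <- length(refsol)
  if (flip > n) stop("flip cannot exceed the mask length")
  stopifnot(flip >= 1, strategy %in% c(1, 2))
  sets <- flip_sets(n, flip, strategy)
  lapply(sets, function(s) {
    out <- as.integer(refsol)
    out[s] <- 1L - out[s]
    out
  })
}

# the bit positions each candidate flips (1-based)
flip_sets <- function(n, flip, strategy) {
  if (strategy == 1) {
    lapply(seq_len(flip), function(k) seq(k, n, by = flip))
  } else {
    m <- n %/% flip
    lapply(seq_len(flip), function(k) {
      if (k < flip) ((k - 1L) * m + 1L):(k * m) else ((flip - 1L) * m + 1L):n
    })
  }
}

#' Reward for moving between feature subsets
#'
#' The reward for a transition compares held-out accuracies first: an
#' improvement earns the new accuracy, a deterioration the (negative)
#' accuracy difference. At equal accuracy the subset sizes break the tie:
#' moving to fewer features earns half the new accuracy, to more features
#' minus half; equal accuracy and equal size earn 0.
#'
#' @param acc_t,acc_t1 accuracies in \[0, 1\] of the current and next state.
#' @param nfeat_t,nfeat_t1 number of selected features in the two states.
#' @return the scalar reward.
#' @export
qbso_reward <- function(acc_t, acc_t1, nfeat_t, nfeat_t1) {
  if (acc_t < acc_t1) return(acc_t1)
  if (acc_t > acc_t1) return(acc_t1 - acc_t)
  if (nfeat_t > nfeat_t1) return(acc_t1 / 2)
  if (nfeat_t < nfeat_t1) return(-acc_t1 / 2)
  0
}

#' Discounted Q-value update
#'
#' `Q_new = r + gamma * Q_prev` with the table zero-initialised, so the first
#' update of a pair stores the bare reward.
#'
#' @param q_prev previously stored value (0 if never written).
#' @param r reward from [qbso_reward()].
#' @param gamma discount in \[0, 1\].
#' @return the updated value.
#' @export
q_update <- function(q_prev, r, gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  r + gamma * q_prev
}

#' Q-learning local search from one starting solution
#'
#' For `local_iteration` steps: enumerate every single-bit-flip neighbour of
#' the current solution (a flip that would empty the mask is skipped), score
#' each neighbour's reward against the current state, update the Q entry of
#' the (current state, flipped bit) pair, then move greedily to the neighbour
#' with the largest updated Q (ties to the lowest bit index). Returns the
#' best-fitness solution visited; the Q-table is updated in place.
#'
#' @param start non-empty 0/1 mask.
#' @param qtable a [new_qtable()]; modified in place.
#' @param fitness_fn function(mask) -> accuracy in \[0, 1\].
#' @param config a [search_config()] (`local_iteration` and `gamma` used).
#' @return list with `solution`, `fitness` (best visited), `q` (largest
#'   updated Q value observed) and `qtable`.
#' @export
local_search <- function(start, qtable, fitness_fn, config = search_config()) {
  n <- length(start)
  if (sum(start) == 0) stop("local_search requires a non-empty starting mask")
  cur <- as.integer(start)
  cur_fit <- fitness_fn(cur)
  best <- cur; best_fit <- cur_fit
  max_q <- -Inf
  for (step in seq_len(config$local_iteration)) {
    nf_cur <- sum(cur)
    key <- mask_key(cur)
    qvec <- q_state(qtable, key, n)
    best_j <- 0L; best_q <- -Inf; best_nb_fit <- NA_real_
    for (j in seq_len(n)) {
      if (nf_cur == 1L && cur[j] == 1L) next   # move would empty the mask
      nb <- cur
      nb[j] <- 1L - nb[j]
      f <- fitness_fn(nb)
      r <- qbso_reward(cur_fit, f, nf_cur, nf_cur + 1L - 2L * cur[j])
      qn <- q_update(qvec[j], r, config$gamma)
      qvec[j] <- qn
      if (qn > best_q) { best_q <- qn; best_j <- j; best_nb_fit <- f }
      if (f > best_fit) { best <- nb; best_fit <- f }
    }
    assign(key, qvec, envir = qtable)
    if (best_j == 0L) break   # degenerate single-bit mask: no legal move
    max_q <- max(max_q, best_q)
    cur[best_j] <- 1L - cur[best_j]
    cur_fit <- best_nb_fit
  }
  list(solution = best, fitness = best_fit, q = max_q, qtable = qtable)
}

#' Bee swarm feature-subset search guided by Q-learning
#'
#' Runs `max_iteration` rounds. Each round derives candidate starting
#' solutions from the reference solution with the two flip strategies
#' (bees alternate between the interleaved and the contiguous-block search
#' areas; if more bees than candidates are requested, additional candidates
#' are generated on a freshly permuted bit order), runs the Q-learning
#' [local_search()] for every bee against one shared Q-table, and takes the
#' solution of the bee with the largest observed Q value as the next
#' reference. If a round's maximum Q falls below the previous round's, the
#' next round instead restarts from a fresh random solution (diversification).
#' The best-fitness solution ever visited is returned, so the recorded best
#' fitness is non-decreasing across rounds.
#'
#' Fitness values are memoised by mask, which leaves results unchanged but
#' avoids re-scoring revisited subsets.
#'
#' @param fitness_fn function(mask) -> accuracy in \[0, 1\]; must be
#'   deterministic.
#' @param n_features mask length.
#' @param config a [search_config()].
#' @return list with `solution` (best mask), `fitness`, `history`
#'   (data.frame: iteration, best_fitness, n_features) and `qtable`.
#' @export
qbso_select <- function(fitness_fn, n_features, config = search_config()) {
  stopifnot(n_features >= 1)
  if (config$flip > n_features) stop("flip cannot exceed the number of features")
  cache <- new.env(parent = emptyenv())
  fit_memo <- function(mask) {
    key <- mask_key(mask)
    if (exists(key, envir = cache, inherits = FALSE))
      return(get(key, envir = cache))
    val <- fitness_fn(mask)
    assign(key, val, envir = cache)
    val
  }
  with_local_seed(config$seed, {
    qtable <- new_qtable()
    refsol <- initial_reference(n_features, config$init_fraction)
    best <- refsol
    best_fit <- fit_memo(refsol)
    prev_q <- -Inf
    diversify <- FALSE
    hist_it <- integer(config$max_iteration)
    hist_fit <- numeric(config$max_iteration)
    hist_nf <- integer(config$max_iteration)
    for (it in seq_len(config$max_iteration)) {
      if (diversify)
        refsol <- initial_reference(n_features, config$init_fraction)
      starts <- bee_starts(refsol, config$flip, config$n_bees)
      round_q <- -Inf
      next_ref <- refsol
      for (b in seq_len(config$n_bees)) {
        res <- local_search(starts[[b]], qtable, fit_memo, config)
        if (res$fitness > best_fit) { best <- res$solution; best_fit <- res$fitness }
        if (res$q > round_q) { round_q <- res$q; next_ref <- res$solution }
      }
      hist_it[it] <- it; hist_fit[it] <- best_fit; hist_nf[it] <- sum(best)
      diversify <- round_q < prev_q
      if (!diversify) refsol <- next_ref
      prev_q <- round_q
    }
    list(solution = best, fitness = best_fit,
         history = data.frame(iteration = hist_it, best_fitness = hist_fit,
                              n_features = hist_nf),
         qtable = qtable)
  })
}

# Starting solutions for the bees: interleave the two strategies' candidates;
# generate further candidates on a permuted bit order if more bees than
# candidates. An empty candidate falls back to the reference solution.
bee_starts <- function(refsol, flip, n_bees) {
  n <- length(refsol)
  pool <- list()
  while (length(pool) < n_bees) {
    if (length(pool) == 0L) {
      s1 <- search_area(refsol, flip, 1)
      s2 <- search_area(refsol, flip, 2)
    } else {
      perm <- sample.int(n)
      inv <- order(perm)
      permute_back <- function(m) m[inv]
      s1 <- lapply(search_area(refsol[perm], flip, 1), permute_back)
      s2 <- lapply(search_area(refsol[perm], flip, 2), permute_back)
    }
    inter <- vector("list", 2L * flip)
    inter[seq(1, 2 * flip, by = 2)] <- s1
    inter[seq(2, 2 * flip, by = 2)] <- s2
    pool <- c(pool, inter)
  }
  lapply(pool[seq_len(n_bees)], function(m) if (sum(m) == 0L) refsol else m)
}
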