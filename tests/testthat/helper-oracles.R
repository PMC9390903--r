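# Independent oracles used by the unit and acceptance tests. Everything here
# is written as plain, slow, direct evaluation of the definitions, on purpose:
# none of it calls into the package's implementation paths.

# --- hybrid k-NN imputation, brute force ------------------------------------
# Direct evaluation: for a missing cell (a, i), distance to each other row b
# over the features observed in both rows (0/1 mismatch for discrete ones),
# reciprocal-distance weighted mean for continuous targets, neighbour-set mode
# for discrete ones (ties: smallest summed distance, then smallest category).
brute_impute <- function(values, kinds, k) {
  n <- nrow(values)
  out <- values
  for (a in seq_len(n)) {
    for (i in seq_len(ncol(values))) {
      if (!is.na(values[a, i])) next
      d <- rep(NA_real_, n)
      for (b in seq_len(n)) {
        if (b == a) next
        shared <- which(!is.na(values[a, ]) & !is.na(values[b, ]))
        if (!length(shared)) next
        s <- 0
        for (j in shared) {
          diff <- if (kinds[j] == "discrete") {
            if (values[a, j] != values[b, j]) 1 else 0
          } else values[a, j] - values[b, j]
          s <- s + diff^2
        }
        d[b] <- sqrt(s)
      }
      cand <- which(!is.na(d) & !is.na(values[, i]))
      stopifnot(length(cand) > 0)
      nb <- cand[order(d[cand], cand)]
      nb <- nb[seq_len(min(k, length(nb)))]
      dnb <- pmax(d[nb], 1e-12)
      if (kinds[i] == "discrete") {
        vals <- values[nb, i]
        counts <- table(vals)
        top <- as.numeric(names(counts)[counts == max(counts)])
        if (length(top) > 1) {
          dsum <- sapply(top, function(v) sum(dnb[vals == v]))
          top <- top[dsum == min(dsum)]
        }
        out[a, i] <- min(top)
      } else {
        w <- 1 / dnb
        out[a, i] <- sum(w * values[nb, i]) / sum(w)
      }
    }
  }
  out
}

# random small mixed-type table with guaranteed imputability
random_mixed_table <- function(n, p, miss = 0.2) {
  kinds <- sample(c("continuous", "discrete"), p, replace = TRUE)
  x <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    x[, j] <- if (kinds[j] == "discrete") sample(0:2, n, replace = TRUE)
    else round(rnorm(n), 3)
  }
  holes <- matrix(runif(n * p) < miss, n, p)
  # keep every column mostly observed and every row partly observed
  for (j in seq_len(p)) if (sum(!holes[, j]) < 2) holes[seq_len(2), j] <- FALSE
  for (i in seq_len(n)) if (all(holes[i, ])) holes[i, 1] <- FALSE
  x[holes] <- NA
  list(values = x, kinds = kinds)
}

# --- ridge objective, iterative minimiser -----------------------------------
# BFGS on  J(b) = sum (y - X b)^2 + lambda ||b||^2  with its analytic
# gradient; independent of the closed-form solve.
ridge_iterative <- function(x, y, lambda) {
  obj <- function(b) sum((y - x %*% b)^2) + lambda * sum(b^2)
  grad <- function(b) drop(-2 * t(x) %*% (y - x %*% b) + 2 * lambda * b)
  par <- rep(0, ncol(x))
  for (restart in 1:4)      # restarts polish past BFGS stalls
    par <- stats::optim(par, obj, grad, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-16))$par
  par
}

# --- AUROC as the Mann-Whitney rank statistic -------------------------------
auroc_rank <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# --- step-by-step re-simulation of the swarm search -------------------------
# A literal transcription of the search rules for tiny masks with a
# tabulated fitness: two flip strategies interleaved across bees, greedy
# Q-learning local search (reward by accuracy comparison, size tie-break;
# Q <- r + gamma * Q, zero-initialised; ties to the lowest bit), best-Q bee
# becomes the next reference, diversification restart when the round's
# maximum Q drops. Mirrors the package's seeding so trajectories can be
# compared exactly, but shares no code with it.
resim_qbso <- function(fitness_tab, n, flip, n_bees, max_iter, local_iter,
                       gamma, init_fraction, seed) {
  fitness <- function(mask)
    fitness_tab[[paste(mask, collapse = "")]]
  rand_ref <- function() {
    mask <- integer(n)
    mask[sample.int(n, max(1, round(init_fraction * n)))] <- 1L
    mask
  }
  strat_sets <- function(strategy) {
    if (strategy == 1) lapply(seq_len(flip), function(k) seq(k, n, by = flip))
    else {
      m <- n %/% flip
      lapply(seq_len(flip), function(k)
        if (k < flip) ((k - 1) * m + 1):(k * m) else ((flip - 1) * m + 1):n)
    }
  }
  qtab <- list()
  qkey <- function(mask, j) paste0(paste(mask, collapse = ""), "@", j)
  qget <- function(mask, j) {
    v <- qtab[[qkey(mask, j)]]
    if (is.null(v)) 0 else v
  }
  trajectory <- list()
  set.seed(seed)
  refsol <- rand_ref()
  best <- refsol; best_fit <- fitness(refsol)
  prev_q <- -Inf; diversify <- FALSE
  for (it in seq_len(max_iter)) {
    if (diversify) refsol <- rand_ref()
    s1 <- strat_sets(1); s2 <- strat_sets(2)
    starts <- list()
    for (k in seq_len(flip)) {
      starts <- c(starts, list(s1[[k]]), list(s2[[k]]))
    }
    starts <- lapply(starts[seq_len(n_bees)], function(set) {
      m <- refsol; m[set] <- 1L - m[set]
      if (sum(m) == 0) refsol else m
    })
    round_q <- -Inf; next_ref <- refsol
    for (b in seq_len(n_bees)) {
      cur <- starts[[b]]; cur_fit <- fitness(cur)
      bee_best <- cur; bee_best_fit <- cur_fit
      bee_q <- -Inf
      for (step in seq_len(local_iter)) {
        qs <- rep(-Inf, n); fs <- rep(NA_real_, n)
        for (j in seq_len(n)) {
          nb <- cur; nb[j] <- 1L - nb[j]
          if (sum(nb) == 0) next
          f <- fitness(nb)
          r <- if (cur_fit < f) f
          else if (cur_fit > f) f - cur_fit
          else if (sum(cur) > sum(nb)) f / 2
          else if (sum(cur) < sum(nb)) -f / 2
          else 0
          qn <- r + gamma * qget(cur, j)
          qtab[[qkey(cur, j)]] <- qn
          qs[j] <- qn; fs[j] <- f
          if (f > bee_best_fit) { bee_best <- nb; bee_best_fit <- f }
        }
        if (all(!is.finite(qs))) break
        j_star <- which.max(qs)          # which.max takes the lowest index tie
        bee_q <- max(bee_q, qs[j_star])
        cur[j_star] <- 1L - cur[j_star]
        cur_fit <- fs[j_star]
      }
      if (bee_best_fit > best_fit) { best <- bee_best; best_fit <- bee_best_fit }
      if (bee_q > round_q) { round_q <- bee_q; next_ref <- bee_best }
    }
    trajectory[[it]] <- list(iteration = it, best_fitness = best_fit,
                             n_features = sum(best))
    diversify <- round_q < prev_q
    if (!diversify) refsol <- next_ref
    prev_q <- round_q
  }
  list(solution = best, fitness = best_fit,
       history = do.call(rbind, lapply(trajectory, as.data.frame)))
}

# exhaustive fitness table over all masks of n bits, random but seeded
tabulate_fitness <- function(n, seed) {
  set.seed(seed)
  masks <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  vals <- round(runif(nrow(masks)), 3)
  tab <- as.list(vals)
  names(tab) <- apply(masks, 1, paste, collapse = "")
  tab
}
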