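test_that("initial reference solutions have the right size and are uniform", {
  set.seed(1)
  expect_equal(sum(initial_reference(20, 0.2)), 4)
  expect_equal(sum(initial_reference(3, 0.2)), 1)    # floor guard
  draws <- replicate(1000, initial_reference(10, 0.2))
  freq <- rowMeans(draws)
  expect_true(all(abs(freq - 0.2) < 0.05))
})

test_that("flip strategies generate disjoint covering candidate sets", {
  ref <- example_reference()
  for (strategy in 1:2) {
    cands <- search_area(ref, 5, strategy)
    expect_length(cands, 5)
    flipped <- lapply(cands, function(m) which(m != ref))
    expect_equal(sort(unlist(flipped)), 1:20)          # partition of all bits
    expect_true(all(lengths(flipped) == 4))
  }
  # non-divisible n: strategy 1 strides cover everything, strategy 2's last
  # block absorbs the remainder
  ref7 <- rep(0L, 7)
  f1 <- lapply(search_area(ref7, 3, 1), function(m) which(m != ref7))
  expect_equal(sort(unlist(f1)), 1:7)
  f2 <- lapply(search_area(ref7, 3, 2), function(m) which(m != ref7))
  expect_equal(f2[[3]], 5:7)
  expect_equal(sort(unlist(f2)), 1:7)
  expect_error(search_area(ref7, 8, 1), "exceed")
})

test_that("reward branches are total and exact", {
  expect_equal(qbso_reward(0.6, 0.8, 5, 5), 0.8)       # improvement
  expect_equal(qbso_reward(0.8, 0.6, 5, 5), -0.2)      # deterioration
  expect_equal(qbso_reward(0.7, 0.7, 10, 8), 0.35)     # same acc, fewer
  expect_equal(qbso_reward(0.7, 0.7, 8, 10), -0.35)    # same acc, more
  expect_equal(qbso_reward(0.7, 0.7, 8, 8), 0)         # full tie
  set.seed(2)
  for (i in 1:50) {
    a <- round(runif(2), 2); nf <- sample(1:10, 2, replace = TRUE)
    r <- qbso_reward(a[1], a[2], nf[1], nf[2])
    expected <- if (a[1] < a[2]) a[2]
    else if (a[1] > a[2]) a[2] - a[1]
    else if (nf[1] > nf[2]) a[2] / 2
    else if (nf[1] < nf[2]) -a[2] / 2 else 0
    expect_identical(r, expected)
  }
})

test_that("Q updates follow the discounted recurrence and stay bounded", {
  expect_equal(q_update(0, 0.7, 0.1), 0.7)
  expect_equal(q_update(0.5, 0.2, 0.1), 0.25)
  set.seed(3)
  for (chain in 1:20) {
    q <- 0; gamma <- 0.1
    for (t in 1:200) q <- q_update(q, runif(1, -1, 1), gamma)
    expect_lte(abs(q), 1 / (1 - gamma))
  }
})

test_that("unseen state-action pairs read as zero", {
  qt <- new_qtable()
  expect_equal(q_value(qt, c(1L, 0L, 1L), 2), 0)
})

test_that("constant fitness drives the search toward fewer features", {
  qt <- new_qtable()
  flat <- function(mask) 0.5
  res <- local_search(c(1L, 1L, 0L), qt, flat,
                      search_config(local_iteration = 1, flip = 1, n_bees = 1))
  # dropping a bit rewards +0.25, adding one -0.25 (half the accuracy)
  expect_equal(q_value(qt, c(1L, 1L, 0L), 1), 0.25)
  expect_equal(q_value(qt, c(1L, 1L, 0L), 2), 0.25)
  expect_equal(q_value(qt, c(1L, 1L, 0L), 3), -0.25)
  expect_equal(res$q, 0.25)
  # the move went to the lowest-index fewer-feature neighbour: a second
  # iteration must therefore update entries of state (0,1,0)
  qt2 <- new_qtable()
  local_search(c(1L, 1L, 0L), qt2, flat,
               search_config(local_iteration = 2, flip = 1, n_bees = 1))
  expect_equal(q_value(qt2, c(0L, 1L, 0L), 3), -0.25)
})

test_that("a maximum one flip away is found immediately", {
  target <- c(1L, 0L, 1L, 0L)
  fitness <- function(mask) if (all(mask == target)) 1 else 0.4
  res <- local_search(c(1L, 0L, 0L, 0L), new_qtable(), fitness,
                      search_config(local_iteration = 1, flip = 1, n_bees = 1))
  expect_equal(res$solution, target)
  expect_equal(res$fitness, 1)
})

test_that("the swarm finds a planted high-fitness feature", {
  fitness <- function(mask) if (mask[3] == 1) 1 else 0.5
  cfg <- search_config(flip = 3, n_bees = 4, max_iteration = 3,
                       local_iteration = 3, seed = 9)
  res <- qbso_select(fitness, 6, cfg)
  expect_equal(res$solution[3], 1L)
  expect_equal(res$fitness, 1)
})

test_that("history is bounded, monotone and reproducible", {
  tab <- tabulate_fitness(4, seed = 21)
  fitness <- function(mask) tab[[paste(mask, collapse = "")]]
  cfg <- search_config(flip = 2, n_bees = 4, max_iteration = 5,
                       local_iteration = 4, seed = 13)
  r1 <- qbso_select(fitness, 4, cfg)
  r2 <- qbso_select(fitness, 4, cfg)
  expect_identical(r1$solution, r2$solution)
  expect_identical(r1$history, r2$history)
  expect_lte(nrow(r1$history), cfg$max_iteration)
  expect_true(all(diff(r1$history$best_fitness) >= 0))
})

test_that("the search trajectory matches an independent re-simulation", {
  for (case in 1:4) {
    tab <- tabulate_fitness(4, seed = 100 + case)
    fitness <- function(mask) tab[[paste(mask, collapse = "")]]
    cfg <- search_config(flip = 2, n_bees = 4, max_iteration = 4,
                         local_iteration = 3, gamma = 0.1,
                         init_fraction = 0.3, seed = case)
    got <- qbso_select(fitness, 4, cfg)
    want <- resim_qbso(tab, n = 4, flip = 2, n_bees = 4, max_iter = 4,
                       local_iter = 3, gamma = 0.1, init_fraction = 0.3,
                       seed = case)
    expect_equal(got$solution, want$solution)
    expect_equal(got$fitness, want$fitness)
    expect_equal(got$history$best_fitness, want$history$best_fitness)
    expect_equal(got$history$n_features, want$history$n_features)
  }
})
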