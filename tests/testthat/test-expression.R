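test_that("burst schedules alternate OFF/ON with the configured exponential means", {
  ex <- expression_params()  # t_ON = 240 s, t_OFF = 144 s
  set.seed(42)
  on <- off <- numeric(0)
  for (k in 1:110) {
    sch <- sample_burst_schedule(ex, horizon = 4e4)
    w <- sch$intervals
    expect_true(all(w$end > w$start))
    expect_true(all(diff(w$start) > 0))          # disjoint, increasing
    expect_true(all(w$end <= 4e4 + 1e-9))        # truncated at horizon
    expect_gt(w$start[1], 0)                     # starts with an OFF draw
    on <- c(on, (w$end - w$start)[-nrow(w)])     # drop truncated last window
    off <- c(off, w$start[1], w$start[-1] - w$end[-nrow(w)])
  }
  expect_gt(length(on), 1e4)
  expect_lt(abs(mean(on) - 240), 3 * sd(on) / sqrt(length(on)))
  expect_lt(abs(mean(off) - 144), 3 * sd(off) / sqrt(length(off)))
  # renewal limit: fraction of time ON = t_ON / (t_ON + t_OFF) = 0.625
  set.seed(7)
  frac <- mean(replicate(200, {
    w <- sample_burst_schedule(ex, horizon = 2e4)$intervals
    sum(w$end - w$start) / 2e4
  }))
  expect_lt(abs(frac - 0.625), 0.01)
})

test_that("a tiny horizon almost surely holds no ON window", {
  ex <- expression_params(mean_t_off = 600)
  set.seed(1)
  n_on <- replicate(50, nrow(sample_burst_schedule(ex, 0.001)$intervals))
  expect_true(all(n_on == 0))
  expect_error(sample_burst_schedule(ex, 0), "positive")
  expect_error(expression_params(mean_t_on = -1), "positive")
})

test_that("transcription completes only transcripts that fit in the window", {
  ex <- expression_params(mrna_rate_on = 1, txn_elongation_time = 0.5,
                          mean_mrna_lifetime = 120)
  # window shorter than the elongation time yields nothing
  short <- simulate_transcription(data.frame(start = 0, end = 0.4), ex)
  expect_identical(nrow(short), 0L)
  # window [0, 4], rate 1/s, elongation 0.5 s: initiations at 0,1,2,3
  set.seed(5)
  m <- simulate_transcription(data.frame(start = 0, end = 4), ex)
  expect_identical(nrow(m), 4L)
  expect_equal(m$birth, c(0.5, 1.5, 2.5, 3.5))
  # long window: count tracks rate * (L - elongation)
  long <- simulate_transcription(data.frame(start = 0, end = 1000), ex)
  expect_lt(abs(nrow(long) - 1 * (1000 - 0.5)), 1.5)
  # seeded determinism is bit-exact
  set.seed(11); a <- simulate_transcription(data.frame(start = 0, end = 50), ex)
  set.seed(11); b <- simulate_transcription(data.frame(start = 0, end = 50), ex)
  expect_identical(a, b)
})

test_that("translation follows the single-ribosome floor rule", {
  ex <- expression_params(tln_time_per_protein = 10, mean_protein_lifetime = 1800)
  # lifetime 0.4 tau: the only protein in progress is lost
  p0 <- simulate_translation(data.frame(birth = 0, death = 4), ex)
  expect_identical(nrow(p0), 0L)
  # lifetime exactly 3.5 tau: 3 complete proteins
  set.seed(2)
  p3 <- simulate_translation(data.frame(birth = 0, death = 35), ex)
  expect_identical(nrow(p3), 3L)
  expect_equal(p3$birth, c(10, 20, 30))
  # operon: each round emits one copy of every step species, simultaneously
  set.seed(3)
  p2 <- simulate_translation(data.frame(birth = 5, death = 28), ex, n_steps = 3)
  expect_identical(nrow(p2), 6L)  # 2 rounds x 3 steps
  expect_equal(sort(unique(p2$step)), 1:3)
  expect_equal(p2$birth[p2$step == 1], p2$birth[p2$step == 2])
})

test_that("mean proteins per mRNA matches the geometric-sum closed form", {
  # P(L >= k tau) summed: 1 / (exp(tau / mean) - 1), with mean = 10 tau
  ex <- expression_params(tln_time_per_protein = 10, mean_mrna_lifetime = 120,
                          mean_protein_lifetime = 1800)
  set.seed(8)
  n <- 1e5
  life <- rexp(n, 1 / 100)  # mean 10 tau
  prot <- simulate_translation(data.frame(birth = 0, death = life), ex)
  expected <- 1 / (exp(10 / 100) - 1)
  se <- sd(floor(life / 10)) / sqrt(n)
  expect_lt(abs(nrow(prot) / n - expected), 4 * se)
})

test_that("enzyme trajectories count live molecules exactly", {
  # births at 1, 2 and a death at 3: counts 0, 1, 2, 1
  ev <- data.frame(birth = c(1, 2), death = c(3, 100))
  tr <- build_enzyme_trajectory(ev, inherited = 0, horizon = 10)
  expect_equal(tr$breakpoints, c(0, 1, 2, 3, 10))
  expect_equal(tr$counts, c(0, 1, 2, 1))
  expect_equal(trajectory_at(tr, c(0.5, 1, 2.5, 3, 9)), c(0, 1, 2, 1, 1))
  # no events, immortal inherited molecules: constant trajectory
  none <- data.frame(birth = numeric(0), death = numeric(0))
  tr5 <- build_enzyme_trajectory(none, inherited = 5, horizon = 100)
  expect_equal(tr5$counts, 5)
  expect_error(build_enzyme_trajectory(none, inherited = -1, horizon = 1),
               ">= 0")
})

test_that("trajectory integral equals the per-molecule overlap sum", {
  set.seed(21)
  for (rep in 1:20) {
    nb <- sample(5:40, 1)
    ev <- data.frame(birth = runif(nb, 0, 80))
    ev$death <- ev$birth + rexp(nb, 1 / 30)
    H <- 60
    tr <- build_enzyme_trajectory(ev, inherited = 0, horizon = H)
    integral <- sum(tr$counts * diff(tr$breakpoints))
    overlap <- sum(pmax(0, pmin(ev$death, H) - pmin(ev$birth, H)))
    expect_equal(integral, overlap, tolerance = 1e-10)
    # integer, non-negative, +-1 jumps only
    expect_true(all(tr$counts >= 0))
    expect_true(all(tr$counts == round(tr$counts)))
    expect_true(all(abs(diff(tr$counts)) >= 1 - 1e-12))
  }
})

test_that("immortal proteins give non-decreasing trajectories", {
  set.seed(4)
  ev <- data.frame(birth = sort(runif(30, 0, 50)), death = Inf)
  tr <- build_enzyme_trajectory(ev, inherited = 3, horizon = 50)
  expect_true(all(diff(tr$counts) >= 0))
})

test_that("the full expression realisation is reproducible bit-exactly", {
  cfg <- growth_config(plan = quick_plan(0, 1))
  st <- new_cell_state(3, 3, prot = matrix(10, 3, 3), mrna = rep(2, 3))
  set.seed(99); a <- stogrow:::.generate_expression(cfg, st, 2000)
  set.seed(99); b <- stogrow:::.generate_expression(cfg, st, 2000)
  expect_identical(a, b)
  # continuation keeps the original prefix untouched
  set.seed(99); a2 <- stogrow:::.generate_expression(cfg, st, 2000)
  a2 <- stogrow:::.extend_expression(a2, cfg, 4000)
  for (i in 1:3) {
    expect_identical(a$mrna[[i]], a2$mrna[[i]][seq_len(nrow(a$mrna[[i]])), ])
    expect_identical(a$schedules[[i]]$durations,
                     a2$schedules[[i]]$durations[
                       seq_along(a$schedules[[i]]$durations)])
  }
})
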