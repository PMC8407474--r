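test_that("division targets implement the Adder and Sizer rules", {
  sizer <- division_rule("sizer", 2e7)
  adder <- division_rule("adder", 1e7)
  # sizer: the balance amount; born at 1e7, must reach the absolute 2e7
  expect_equal(division_targets(sizer, c(1e7, 1e7)), c(2e7, 2e7))
  # sizer born above threshold: divide-ready immediately on that pathway
  expect_equal(division_targets(sizer, c(3e7, 1e7)), c(3e7, 2e7))
  # adder: a fixed amount on top of whatever was inherited
  expect_equal(division_targets(adder, c(0, 5e6)), c(1e7, 1.5e7))
  # per-pathway thresholds recycle
  expect_equal(division_targets(division_rule("sizer", c(1e7, 3e7)),
                                c(0, 0)), c(1e7, 3e7))
})

test_that("division halves every pool exactly and conserves totals", {
  st <- new_cell_state(2, 2, S = 10, P = matrix(c(2e7, 2e7, 1e7, 3e7), 2, 2),
                       mrna = c(3, 5), prot = matrix(c(11, 7, 2, 9), 2, 2))
  kids <- divide_cell(st)
  expect_equal(kids$A$S, 5)
  expect_equal(kids$A$P, st$P / 2)
  expect_equal(kids$A$S + kids$B$S, st$S)
  expect_equal(kids$A$P + kids$B$P, st$P)
  expect_equal(kids$A$mrna + kids$B$mrna, st$mrna)
  expect_equal(kids$A$prot + kids$B$prot, st$prot)
  expect_equal(kids$A$Q, c(0, 0))  # exchange counters reset
  expect_equal(kids$A$birth_pools, st$P[, 2] / 2)
  # calling divide on a non-dividing state is an error
  expect_error(divide_cell(st, targets = c(9e7, 9e7)), "non-dividing")
})

test_that("a Sizer cell dividing at threshold reproduces the Adder increment", {
  # daughters born at threshold/2 must produce threshold/2 more: the same
  # per-cycle production requirement the Adder imposes with its threshold
  thr <- 2e7
  sizer <- division_rule("sizer", thr)
  adder <- division_rule("adder", thr / 2)
  st <- new_cell_state(1, 1, P = matrix(thr, 1, 1))
  kid <- divide_cell(st)$A
  need_sizer <- division_targets(sizer, kid$birth_pools) - kid$birth_pools
  need_adder <- division_targets(adder, kid$birth_pools) - kid$birth_pools
  expect_equal(need_sizer, need_adder)
  expect_equal(need_sizer, thr / 2)
})

test_that("doubling time follows the size-ratio identity", {
  expect_equal(doubling_time(30, 2, 1), 30)   # ratio 2: T_mu = T_div
  expect_equal(doubling_time(30, 4, 1), 15)   # log2(4) = 2
  # ratio -> 1+ diverges
  expect_gt(doubling_time(30, 1 + 1e-9, 1), 1e10)
  expect_error(doubling_time(30, 1, 2), "exceed")
  expect_error(doubling_time(30, 2, 0), "positive")
})

test_that("the Sizer trigger pathway doubles its pool over one cycle", {
  cfg <- det_config(E = 40, burn = 6)
  st <- burn_in(cfg)
  cyc <- simulate_cycle(st, cfg, 1)
  i <- cyc$event_pathway
  ratio <- cyc$state_div$P[i, cfg$kinetics$n] / st$P[i, cfg$kinetics$n]
  expect_equal(ratio, 2, tolerance = 1e-6)
  # non-triggering pathways end at or above their targets
  expect_true(all(cyc$state_div$P[, cfg$kinetics$n] >=
                    cyc$targets * (1 - 1e-6)))
  # and hence doubling time equals generation time
  expect_equal(doubling_time(cyc$generation_time, ratio, 1),
               cyc$generation_time, tolerance = 1e-5)
})

test_that("inherited-count rounding is immaterial at realistic copy numbers", {
  # identical config, one lineage started from integer counts and one from
  # half-integer counts: generation-time statistics agree closely
  cfg <- growth_config(plan = quick_plan(0, 1), seed = 5)
  st_int <- new_cell_state(3, 3, S = 2e7, P = matrix(1e7, 3, 3),
                           mrna = rep(2, 3), prot = matrix(14, 3, 3))
  st_half <- new_cell_state(3, 3, S = 2e7, P = matrix(1e7, 3, 3),
                            mrna = rep(2.5, 3), prot = matrix(14.5, 3, 3))
  g1 <- vapply(1:40, function(k) simulate_cycle(st_int, cfg, k)$generation_time,
               numeric(1))
  g2 <- vapply(1:40, function(k) simulate_cycle(st_half, cfg, k)$generation_time,
               numeric(1))
  expect_lt(abs(mean(g1) - mean(g2)) / mean(g1), 0.05)
})
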