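test_that("knockout flux redistribution raises per-pathway inflow exactly", {
  kin <- kinetic_params(p = 3, s_in = 9000)
  intact <- per_pathway_inflow(kin)
  ko <- per_pathway_inflow(kin, exchange_params(3, feed_rate = c(0, 0, 100),
                                                knockout = c(FALSE, FALSE, TRUE)))
  expect_equal(intact, 9000)
  expect_equal(ko / intact, 1.5)  # p/(p-1) with p = 3: exactly +50%
  expect_error(per_pathway_inflow(kin, exchange_params(3, feed_rate = 1,
                                                       knockout = TRUE)),
               "all pathways")
})

test_that("mean secretion rate matches the closed form for a constant cell", {
  # deterministic cell, sigma = 0.5 on pathway 1: secretion rate is half the
  # final-step throughput, itself the per-pathway production requirement
  # divided by the cycle time
  cfg <- growth_config(kinetics = kinetic_params(),
                       exchange = exchange_params(3, secretion_ratio = c(0.5, 0, 0)),
                       plan = quick_plan(8, 3), constant_enzymes = 40)
  lin <- simulate_lineage(cfg)
  rate <- mean_secretion_rate(lin, 1)
  # at steady cycling the retained production is 1e7 per cycle, so the
  # total production is 1e7/(1-sigma) and secretion sigma/(1-sigma)*1e7/T
  Tdiv <- mean(generation_times(lin))
  expect_equal(rate, 0.5 / 0.5 * 1e7 / Tdiv, tolerance = 1e-3)
  expect_equal(mean_secretion_rate(lin, 2), 0)  # sigma = 0 pathway
  expect_error(mean_secretion_rate(lin, 9), "no secretion record")
})

test_that("feasibility classification applies both conditions", {
  pts <- data.frame(feed_rate = c(120, 100, 100, 100),
                    mean_secretion_rate = c(100, 120, 120, 120),
                    growth_rate = c(2e-4, 2e-4, 0.5e-4, 1e-4),
                    baseline_prototroph_rate = 1e-4)
  out <- classify_feasibility(pts)
  # below the diagonal; feasible; too slow; exactly at baseline (strict)
  expect_identical(out$feasible, c(FALSE, TRUE, FALSE, FALSE))
  expect_error(classify_feasibility(pts[, 1:3]), "baseline")
})

test_that("scenario validation rejects impossible configurations", {
  base <- growth_config(plan = quick_plan(2, 2))
  expect_error(scenario_spec("auxotroph", config = base, feed_rate = 0),
               "must be fed")
  expect_error(growth_config(kinetics = kinetic_params(p = 2, s_in = 0)),
               "never divide")
  expect_error(scenario_spec("uptake", config = base, p = c(2, 3)),
               "baseline")
})

test_that("a scenario manifest carries matched baselines and moments", {
  base <- growth_config(plan = quick_plan(6, 5), constant_enzymes = 40)
  man <- run_scenario(scenario_spec("uptake", config = base,
                                    feed_rate = c(1000, 4000)))
  expect_identical(nrow(man), 2L)
  expect_true(all(c("growth_rate", "baseline_rate", "rel_change",
                    "mean_generation_time", "cv") %in% names(man)))
  expect_equal(man$rel_change,
               (man$growth_rate - man$baseline_rate) / man$baseline_rate)
  # feeding a deterministic cell can only help
  expect_true(all(man$rel_change >= -1e-9))
  expect_true(all(diff(man$growth_rate) >= -1e-9))
})

test_that("the auxotroph advantage shrinks as bottlenecks multiply", {
  # percentage gain from losing one of p pathways, saturating feed,
  # nutrient-poor medium where the redistributed flux dominates
  plan <- quick_plan(12, 5)
  gains <- vapply(2:4, function(p) {
    base <- growth_config(kinetics = kinetic_params(p = p, s_in = 1000),
                          plan = plan, seed = 31)
    spec <- scenario_spec("auxotroph", config = base, s_in = 1000,
                          feed_rate = 20000)
    man <- run_scenario(spec)
    man$rel_change
  }, numeric(1))
  expect_true(all(gains > 0))
  expect_true(all(diff(gains) < 0))
})

test_that("the cross-feeder proxy wires overexpression, secretion and feed", {
  base <- growth_config(plan = quick_plan(4, 5), seed = 3)
  spec <- scenario_spec("crossfeeder", config = base, feed_rate = 5000)
  cfg <- stogrow:::.scenario_config(spec, 9000, 3, 5000, 0.5)
  expect_equal(cfg$kinetics$kcat_multiplier, c(2, 1, 1))
  expect_equal(cfg$exchange$secretion_ratio, c(0.5, 0, 0))
  expect_equal(cfg$exchange$feed_rate, c(0, 0, 5000))
  expect_identical(cfg$exchange$knockout, c(FALSE, FALSE, TRUE))
  man <- run_scenario(spec)
  expect_gt(man$mean_secretion_rate, 0)
  fz <- classify_feasibility(man)
  expect_type(fz$feasible, "logical")
})
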