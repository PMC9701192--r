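test_that("default spec generates pure intact populations deterministically", {
  pop <- simulate_population(simulation_spec(), 1000, seed = 51)
  expect_equal(nrow(pop), 1000)
  expect_true(all(pop$particle_class == "intact"))
  expect_true(all(pop$mass_pg > 0))
  again <- simulate_population(simulation_spec(), 1000, seed = 51)
  expect_identical(pop$mass_pg, again$mass_pg)
})

test_that("generated masses recover the spec moments at large n", {
  spec <- simulation_spec(mean_mass = 60, cv = 0.35, noise_sd = 0)
  pop <- simulate_population(spec, 1e5, seed = 52)
  expect_lt(abs(mean(pop$mass_pg) / 60 - 1), 0.02)
  cv_hat <- sd(pop$mass_pg) / mean(pop$mass_pg)
  expect_lt(abs(cv_hat / 0.35 - 1), 0.05)
})

test_that("class mean masses are ordered aggregate > intact > permeable > debris", {
  spec <- simulation_spec(class_weights = c(intact = 0.7, permeable = 0.1,
                                            aggregate = 0.1, debris = 0.1))
  pop <- simulate_population(spec, 20000, seed = 53)
  means <- tapply(pop$mass_pg, pop$particle_class, mean)
  expect_gt(means[["aggregate"]], means[["intact"]])
  expect_gt(means[["intact"]], means[["permeable"]])
  expect_gt(means[["permeable"]], means[["debris"]])
})

test_that("spec validation rejects malformed inputs before sampling", {
  expect_error(simulation_spec(class_weights = c(intact = 0.5)), "sum to 1")
  expect_error(simulation_spec(cv = -1))
  expect_error(simulation_spec(class_weights = c(blob = 1)), "unknown class")
})

test_that("uniform shift links the simulator to the statistic", {
  pop <- simulate_population(simulation_spec(), 20000, seed = 54)
  shifted <- apply_moa(pop, moa_effect("uniform_shift", shift = 0.10))
  expect_equal(mass_response(shifted$mass_pg, pop$mass_pg)$value, 0.10,
               tolerance = 1e-12)
})

test_that("arrest effects move the mean and consolidate the distribution", {
  pop <- simulate_population(simulation_spec(), 20000, seed = 55)
  g1 <- apply_moa(pop, moa_effect("g1_arrest"))
  g2 <- apply_moa(pop, moa_effect("g2_arrest"))
  expect_lt(mean(g1$mass_pg), mean(pop$mass_pg))
  expect_gt(mean(g2$mass_pg), mean(pop$mass_pg))
  cv <- function(x) sd(x) / mean(x)
  expect_equal(cv(g1$mass_pg) / cv(pop$mass_pg), 0.6, tolerance = 0.02)
  expect_equal(mean(g2$mass_pg) / mean(pop$mass_pg), 1.4, tolerance = 0.02)
})

test_that("metabolic skews are pure mean scalings", {
  pop <- simulate_population(simulation_spec(), 5000, seed = 56)
  expect_equal(apply_moa(pop, moa_effect("catabolic"))$mass_pg,
               pop$mass_pg * 0.90)
  expect_equal(apply_moa(pop, moa_effect("anabolic"))$mass_pg,
               pop$mass_pg * 1.10)
})

test_that("membrane loss moves the affected fraction to a low-mass permeable mode", {
  pop <- simulate_population(simulation_spec(), 20000, seed = 57)
  lost <- apply_moa(pop, moa_effect("membrane_loss", fraction = 0.40),
                    seed = 58)
  frac <- mean(lost$particle_class == "permeable")
  expect_lt(abs(frac - 0.40), 0.02)
  hit <- lost$particle_class == "permeable"
  expect_equal(lost$mass_pg[hit], pop$mass_pg[hit] * 0.35)
  expect_equal(lost$mass_pg[!hit], pop$mass_pg[!hit])
})

test_that("population mixing respects the requested fractions", {
  a <- simulate_population(simulation_spec(), 1000, seed = 59,
                           condition_id = "A")
  b <- simulate_population(simulation_spec(), 1000, seed = 60,
                           condition_id = "B")
  only_a <- mix_populations(list(a, b), c(1, 0), n = 500, seed = 61)
  expect_true(all(only_a$condition_id == "A"))
  half <- mix_populations(list(a, b), c(0.5, 0.5), n = 600, seed = 62)
  expect_equal(sum(half$condition_id == "A"), 300)
  expect_error(mix_populations(list(a, b), c(0.7, 0.7)), "sum to 1")
})

test_that("simulated experiments have the reference-first control-last design", {
  rec <- simulate_experiment(simulation_spec(),
                             effects = list(drugA = NULL, drugB = NULL),
                             n_per_condition = 300, seed = 63)
  exp_set <- build_experiment(rec)
  expect_named(exp_set$tests, c("drugA", "drugB"))
  t_ref <- unique(rec$t_meas_s[rec$role == "reference"])
  t_ctl <- unique(rec$t_meas_s[rec$role == "control"])
  expect_equal(t_ref, 0)
  expect_equal(t_ctl, 3 * 3600)
  expect_true(all(rec$t_meas_s[rec$role == "test"] > t_ref &
                    rec$t_meas_s[rec$role == "test"] < t_ctl))
})

test_that("a null experiment yields theta near zero", {
  rec <- simulate_experiment(simulation_spec(),
                             effects = list(drugA = NULL),
                             n_per_condition = 2500, seed = 64)
  exp_set <- build_experiment(rec)
  th <- theta_stat(exp_set$tests$drugA, exp_set$control, exp_set$reference)
  expect_lt(abs(th), 0.02)
})

test_that("drift is linear in time and guards against mass sign flips", {
  spec <- simulation_spec()
  rec0 <- simulate_experiment(spec, list(drugA = NULL), drift_rate = 0,
                              n_per_condition = 500, seed = 65)
  rec <- simulate_experiment(spec, list(drugA = NULL), drift_rate = 0.04,
                             n_per_condition = 500, seed = 65)
  # control measured at 3 h: masses scaled by 1 - 0.04 * 3 = 0.88
  expect_equal(rec$mass_pg[rec$role == "control"],
               rec0$mass_pg[rec0$role == "control"] * 0.88, tolerance = 1e-12)
  expect_error(simulate_experiment(spec, list(drugA = NULL), drift_rate = 0.5,
                                   n_per_condition = 100, seed = 65),
               "non-positive")
})

test_that("baseline noise falls with cell count at the root-n rate", {
  scan <- noise_vs_n_scan(simulation_spec(), n_values = c(250, 1000, 4000),
                          reps = 300, seed = 66)
  expect_true(all(diff(scan$mean_response) < 0))
  slope <- coef(lm(log(scan$mean_response) ~ log(scan$n)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})
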