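test_that("a well-formed table loads with every row preserved", {
  rec <- tiny_records()
  path <- write_fixture_table(rec)
  loaded <- load_measurements(path)
  expect_equal(nrow(loaded), 9)
  expect_equal(attr(loaded, "n_rejected"), 0)
  expect_equal(loaded$mass_pg, rec$mass_pg)
  expect_equal(loaded$condition_id, rec$condition_id)
})

test_that("rows with invalid mass are rejected and counted", {
  df <- data.frame(mass_pg = c("50", "-1.0", "60", "oops"),
                   particle_class = "intact",
                   condition_id = "c1", role = "test", t_meas_s = 0,
                   instrument_id = "I1")
  path <- write_fixture_table(df)
  loaded <- suppressMessages(load_measurements(path))
  expect_equal(nrow(loaded), 2)
  expect_equal(attr(loaded, "n_rejected"), 2)
  expect_equal(loaded$mass_pg, c(50, 60))
})

test_that("missing required columns raise a schema error", {
  df <- data.frame(mass_pg = 50, condition_id = "c1", role = "test")
  path <- write_fixture_table(df)
  expect_error(load_measurements(path), "missing required columns")
  expect_error(load_measurements(tempfile()), "not found")
})

test_that("unknown classes and missing roles are repaired with warnings", {
  df <- data.frame(mass_pg = c(50, 60), particle_class = c("blob", "intact"),
                   condition_id = "c1", role = c("test", ""),
                   t_meas_s = 0, instrument_id = NA)
  path <- write_fixture_table(df)
  expect_warning(expect_warning(loaded <- load_measurements(path),
                                "unclassified"), "defaulted to 'test'")
  expect_equal(loaded$particle_class[1], "unclassified")
  expect_equal(loaded$role[2], "test")
})

test_that("write/load round-trip preserves masses to full precision", {
  set.seed(5)
  rec <- mass_records(rlnorm(50, log(60), 0.3),
                      sample(c("intact", "debris"), 50, replace = TRUE),
                      condition_id = rep(c("REF", "CTL"), 25),
                      role = rep(c("reference", "control"), 25),
                      t_meas = runif(50, 0, 100))
  for (sep in c(",", "\t")) {
    path <- write_fixture_table(rec[0, ])
    write_measurements(rec, if (sep == "\t") sub("csv$", "tsv", path) else path)
    back <- load_measurements(if (sep == "\t") sub("csv$", "tsv", path) else path)
    expect_identical(back$mass_pg, rec$mass_pg)
    expect_identical(back$particle_class, rec$particle_class)
    expect_identical(back$t_meas_s, rec$t_meas_s)
  }
})

test_that("build_experiment groups conditions and sorts masses", {
  rec <- tiny_records()
  rec2 <- rbind(rec, mass_records(c(90, 85), "intact", "drugB", "test", 5400))
  exp_set <- build_experiment(rec2)
  expect_s3_class(exp_set, "experiment_set")
  expect_named(exp_set$tests, c("drugA", "drugB"))
  expect_equal(exp_set$reference$condition_id, "REF")
  expect_equal(exp_set$tests$drugB$masses, c(85, 90))
  expect_false(is.unsorted(exp_set$reference$masses))
})

test_that("build_experiment is invariant to input row order", {
  rec <- tiny_records()
  set.seed(3)
  shuffled <- rec[sample(nrow(rec)), ]
  a <- build_experiment(rec)
  b <- build_experiment(shuffled)
  expect_equal(a$reference$masses, b$reference$masses)
  expect_equal(a$tests$drugA$masses, b$tests$drugA$masses)
})

test_that("experiment structure errors are raised", {
  rec <- tiny_records()
  expect_error(build_experiment(rec[rec$role != "control", ]),
               "exactly one control")
  dup <- rbind(rec, mass_records(50, "intact", "REF2", "reference", 0))
  expect_error(build_experiment(dup), "exactly one reference")
})

test_that("out-of-order measurement times produce a warning, not an error", {
  rec <- tiny_records()
  rec$t_meas_s[rec$condition_id == "REF"] <- 9000 # reference measured last
  expect_warning(build_experiment(rec), "reference-first")
})

test_that("inference config validates its parameters", {
  cfg <- inference_config()
  expect_equal(cfg$theta0, 0.03)
  expect_equal(cfg$N, 2500L)
  expect_equal(cfg$r_inner, 19L)
  expect_error(inference_config(theta0 = 0), "theta0")
  expect_error(inference_config(ci_level = 1.2), "ci_level")
})

test_that("config JSON round-trips through read_config", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(theta0 = 0.05, R_test = 199, ci_level = 0.95),
                       path, auto_unbox = TRUE)
  cfg <- read_config(path)
  expect_equal(cfg$theta0, 0.05)
  expect_equal(cfg$R_test, 199L)
  expect_equal(cfg$alpha, 0.05) # default fills in
})

test_that("report writing round-trips results including the call enum", {
  set.seed(7)
  z <- rlnorm(300, log(60), 0.3)
  res <- bootstrap_t_test(z * 1.4, z * 1.12, z, fast_config(),
                          condition_id = "drugX", seed = 11)
  expect_equal(res$call, "inconclusive") # 12% control drift
  paths <- write_report(list(res), file.path(tempdir(), "rep"),
                        config = fast_config())
  back <- read_report(paths[["json"]])
  expect_equal(back$call, "inconclusive")
  expect_equal(back$p_value, res$p_value)
  expect_equal(back$theta_hat, res$theta_hat, tolerance = 1e-12)
  expect_true(file.exists(paths[["csv"]]))
  csv <- read.csv(paths[["csv"]])
  expect_equal(csv$condition_id, "drugX")
})
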