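test_that("curation filters by accepted class and never alters masses", {
  rec <- mass_records(c(rep(60, 10), rep(8, 5)),
                      c(rep("intact", 10), rep("debris", 5)),
                      condition_id = "c1")
  samples <- curate(rec, curation_policy())
  expect_length(samples, 1)
  expect_equal(samples$c1$n, 10)
  expect_equal(samples$c1$masses, rep(60, 10))
  removed <- attr(samples, "removed_by_class")
  expect_equal(unname(removed[["debris"]]), 5)

  all_intact <- mass_records(rlnorm(20, log(60), 0.3), "intact", "c2")
  out <- curate(all_intact, curation_policy(), as_records = TRUE)
  expect_equal(out$mass_pg, all_intact$mass_pg) # identity on clean input
})

test_that("unclassified handling and strict policies work", {
  rec <- mass_records(c(60, 61, 62), c("intact", "permeable", "unclassified"),
                      condition_id = "c1")
  expect_equal(curate(rec, curation_policy())$c1$n, 2)
  expect_equal(curate(rec, curation_policy(treat_unclassified = "accept"))$c1$n, 3)
  expect_equal(curate(rec, curation_policy("intact"))$c1$n, 1)
  expect_error(curation_policy("blob"), "unknown particle class")
})

test_that("curating away an entire condition names it in the error", {
  rec <- rbind(mass_records(60, "intact", "good"),
               mass_records(8, "debris", "junk_only"))
  expect_error(curate(rec, curation_policy()), "junk_only")
})

test_that("curation moves a contaminated sample mean toward the intact mean", {
  spec <- simulation_spec(class_weights = c(intact = 0.7, permeable = 0.1,
                                            aggregate = 0.1, debris = 0.1))
  pop <- simulate_population(spec, 6000, seed = 31)
  cur <- curate(pop, curation_policy("intact"), as_records = TRUE)
  intact_mean <- mean(pop$mass_pg[pop$particle_class == "intact"])
  expect_lt(abs(mean(cur$mass_pg) - intact_mean),
            abs(mean(pop$mass_pg) - intact_mean))
})

test_that("sampling error is deterministic and validates the subset size", {
  set.seed(32)
  z <- rlnorm(3000, log(60), 0.35)
  ref <- rlnorm(2500, log(60), 0.35)
  a <- sampling_error(z, ref, subset_size = 500, reps = 50, seed = 12)
  b <- sampling_error(z, ref, subset_size = 500, reps = 50, seed = 12)
  expect_identical(a$sd, b$sd)
  expect_identical(a$mean, b$mean)
  expect_error(sampling_error(z[1:100], ref, subset_size = 500), "fewer cells")
})

test_that("subset sampling error sits near the baseline noise floor", {
  # homogeneous population: the subset dispersion must be comparable to the
  # independent-pair noise SD at the same n (same order, not several-fold off)
  spec <- simulation_spec()
  pop <- simulate_population(spec, 8000, seed = 33)
  ref <- simulate_population(spec, 2500, seed = 34)
  se <- sampling_error(pop$mass_pg, ref$mass_pg, subset_size = 1000,
                       reps = 100, seed = 35)
  scan <- noise_vs_n_scan(spec, n_values = 1000, reps = 300, seed = 36)
  expect_lt(se$sd, 3 * scan$sd_response)
  expect_gt(se$sd, scan$sd_response / 3)
})

test_that("label confusion emulation reproduces the specified error rates", {
  spec <- simulation_spec(class_weights = c(intact = 0.55, permeable = 0.15,
                                            aggregate = 0.15, debris = 0.15))
  pop <- simulate_population(spec, 20000, seed = 37)

  perfect <- apply_confusion(pop, confusion_spec(diag = 1), seed = 1)
  expect_identical(perfect$particle_class, perfect$class_true)
  pr <- precision_recall(perfect)
  expect_true(all(pr$precision[pr$support > 0] == 1))
  expect_true(all(pr$recall[pr$support > 0] == 1))

  noisy <- apply_confusion(pop, confusion_spec(diag = 0.97), seed = 2)
  pr <- precision_recall(noisy)
  expect_true(all(abs(pr$recall - 0.97) < 0.02)) # law of large numbers

  force_mat <- diag(4); force_mat[4, ] <- c(1, 0, 0, 0) # debris -> intact
  forced <- apply_confusion(pop, confusion_spec(force_mat), seed = 3)
  expect_true(all(forced$particle_class[forced$class_true == "debris"] ==
                    "intact"))
})

test_that("confusion specs must be row-stochastic", {
  bad <- diag(4); bad[1, 1] <- 0.5
  expect_error(confusion_spec(bad), "sum to 1")
  expect_error(confusion_spec(matrix(2, 4, 4)), "lie in")
})

test_that("precision and recall match a hand-built confusion table", {
  # 9 true intact called intact, 1 debris called intact (FP),
  # 1 true intact called debris (FN): precision = recall = 0.9
  rec <- mass_records(rep(60, 11), rep("intact", 11), "c1")
  rec$class_true <- c(rep("intact", 10), "debris")
  rec$particle_class <- c(rep("intact", 9), "debris", "intact")
  pr <- precision_recall(rec)
  expect_equal(pr$precision[pr$class == "intact"], 0.9)
  expect_equal(pr$recall[pr$class == "intact"], 0.9)
  # permeable absent from truth: recall undefined, reported NA
  expect_true(is.na(pr$recall[pr$class == "permeable"]))
  expect_error(precision_recall(mass_records(60, "intact", "c")), "true labels")
})

test_that("curation reduces subset sampling error on contaminated populations", {
  # reduced paired-seed version of the fidelity-benefit study: 20%
  # aggregate+debris contamination, 1000-cell subsets vs a curated reference
  spec <- simulation_spec(class_weights = c(intact = 0.7, permeable = 0.1,
                                            aggregate = 0.1, debris = 0.1))
  wins <- vapply(1:20, function(i) {
    pop <- simulate_population(spec, 4000, seed = 4000 + i)
    ref <- curate(simulate_population(spec, 4000, seed = 8000 + i),
                  curation_policy(), as_records = TRUE)
    cur <- curate(pop, curation_policy(), as_records = TRUE)
    se_cur <- sampling_error(cur$mass_pg, ref$mass_pg, 1000, reps = 60,
                             seed = i)
    se_unc <- sampling_error(pop$mass_pg, ref$mass_pg, 1000, reps = 60,
                             seed = i)
    se_cur$sd < se_unc$sd
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
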