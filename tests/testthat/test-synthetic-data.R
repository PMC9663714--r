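test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_patients = 120, seed = 99)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$labs, b$labs)
  expect_identical(a$prescriptions, b$prescriptions)
  expect_identical(a$diagnoses, b$diagnoses)
  expect_identical(a$demographics, b$demographics)
  c <- simulate_population(sim_config(n_patients = 120, seed = 100))
  expect_false(identical(a$labs, c$labs))
})

test_that("configuration is validated", {
  expect_error(sim_config(regimen_catalog = data.frame()), "regimen")
  expect_error(sim_config(outcome_noise_sd = 0))
  bad <- data.frame(regimen = "notadrug", true_effect = -1)
  expect_error(sim_config(regimen_catalog = bad), "notadrug")
  six <- data.frame(
    regimen = regimen_string(default_drug_classes()[1:6]), true_effect = -1)
  expect_error(sim_config(regimen_catalog = six), "1-5")
  expect_error(sim_config(missingness_rates = list(egfr = 1.4)), "\\[0, 1\\]")
})

test_that("zero confounding makes assignment independent of covariates", {
  pop <- simulate_population(sim_config(
    n_patients = 3000, regimen_catalog = catalog_three(),
    confounding_strength = 0, labs_per_patient = c(2, 2), seed = 11))
  sn <- build_snapshots(pop)
  ## split on a strong covariate (comorbidity count) and compare regimen
  ## frequencies across the halves
  grp <- sn$cci >= stats::median(sn$cci)
  tab <- table(grp, sn$regimen)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("noise-free covariate-free outcomes equal the true effects", {
  cat3 <- catalog_three()
  pop <- simulate_population(sim_config(
    n_patients = 400, regimen_catalog = cat3, confounding_strength = 0,
    outcome_confounding = 0, outcome_noise_sd = 1e-12,
    labs_per_patient = c(2, 2), seed = 21))
  sn <- build_snapshots(pop)
  mean_delta <- tapply(sn$delta_hba1c, sn$regimen, mean)
  truth <- setNames(cat3$true_effect, cat3$regimen)
  for (r in names(mean_delta))
    expect_equal(unname(mean_delta[r]), unname(truth[r]), tolerance = 1e-9)
})

test_that("stored assignment model matches empirical frequencies", {
  pop <- simulate_population(sim_config(
    n_patients = 4000, regimen_catalog = catalog_three(),
    confounding_strength = 0.5, labs_per_patient = c(2, 2), seed = 31))
  gt <- pop$ground_truth
  probs <- as.matrix(gt$snapshots[, gt$catalog$regimen])
  expected <- colSums(probs)
  observed <- table(factor(gt$snapshots$regimen,
                           levels = gt$catalog$regimen))
  ## Monte-Carlo error: binomial SD per regimen
  for (k in seq_along(expected)) {
    sdk <- sqrt(sum(probs[, k] * (1 - probs[, k])))
    expect_lt(abs(observed[k] - expected[k]), 4 * sdk)
  }
  ## all stored propensities are proper probabilities
  expect_true(all(probs > 0 & probs < 1))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)),
               tolerance = 1e-8)
})

test_that("confounding biases the naive difference-in-means detectably", {
  hits <- 0L
  for (s in 1:5) {
    pop <- simulate_population(sim_config(
      n_patients = 1800, regimen_catalog = catalog_three(),
      confounding_strength = 0.8, outcome_confounding = 0.4,
      labs_per_patient = c(2, 2), seed = 40 + s))
    sn <- suppressWarnings(build_snapshots(pop))
    sel <- sn$regimen %in% catalog_three()$regimen[1:2]
    tt <- as.integer(sn$regimen[sel] == catalog_three()$regimen[2])
    y <- sn$delta_hba1c[sel]
    dim_est <- naive_ate(y, tt)
    se <- sqrt(stats::var(y[tt == 1]) / sum(tt == 1) +
               stats::var(y[tt == 0]) / sum(tt == 0))
    truth <- catalog_three()$true_effect[2] - catalog_three()$true_effect[1]
    if (abs(dim_est - truth) > 2 * se) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})

test_that("tables round-trip losslessly through write/read", {
  pop <- simulate_population(sim_config(n_patients = 25, seed = 5))
  dir <- withr::local_tempdir()
  write_tables(pop, dir)
  back <- read_tables(dir)
  for (nm in c("labs", "prescriptions", "diagnoses", "demographics")) {
    expect_equal(back[[nm]], pop[[nm]], tolerance = 1e-12)
  }
  ## ground-truth sidecar survives too
  expect_equal(back$ground_truth$catalog$true_effect,
               pop$ground_truth$catalog$true_effect)
  expect_equal(unname(back$ground_truth$assign_coef),
               unname(pop$ground_truth$assign_coef), tolerance = 1e-12)
})

test_that("single patient event counts are as constructed", {
  pop <- simulate_population(sim_config(
    n_patients = 1, labs_per_patient = c(2, 2), seed = 3))
  h <- patient_history(pop, pop$demographics$patient_id[1])
  expect_equal(sum(h$labs$test_name == "hba1c"), 2L)
  dir <- withr::local_tempdir()
  write_tables(pop, dir)
  labs <- utils::read.csv(file.path(dir, "labs.csv"))
  expect_equal(sum(labs$test_name == "hba1c"), 2L)
  ## a patient without prescriptions writes zero rows without error
  pop$prescriptions <- pop$prescriptions[0, , drop = FALSE]
  expect_silent(write_tables(pop, dir))
  expect_equal(nrow(utils::read.csv(file.path(dir, "prescriptions.csv"))), 0L)
})
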