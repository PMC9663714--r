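test_that("snapshot construction follows the duration and index rules", {
  pop <- make_fixture_population()
  pop <- apply_exclusions(pop)
  sn <- build_snapshots(pop)
  ## hand enumeration: only p1 contributes, with durations 100 and 200
  expect_equal(nrow(sn), 2L)
  expect_equal(sn$patient_id, c("p1", "p1"))
  expect_equal(sn$terminal_day - sn$index_day, c(100, 200))
  log <- attr(sn, "filter_log")
  expect_equal(unname(log["duration"]), 1L)        # p2 gap of 60
  expect_equal(unname(log["single_lab"]), 1L)      # p3
  expect_equal(unname(log["index_below_threshold"]), 1L)  # p4
  expect_equal(unname(log["no_treatment"]), 1L)    # p7 untreated
  ## snapshot invariants hold for everything retained
  expect_true(all(sn$index_hba1c >= 9))
  expect_true(all(sn$delta_hba1c == sn$terminal_hba1c - sn$index_hba1c))
  expect_false(anyNA(sn$regimen))
})

test_that("exclusion filters drop flagged patients and minors", {
  pop <- make_fixture_population()
  out <- apply_exclusions(pop)
  log <- attr(out, "exclusion_log")
  expect_setequal(log$patient_id, c("p5", "p6"))
  expect_true("cystic_fibrosis" %in% log$reason)
  expect_true("under_18" %in% log$reason)
  expect_false(any(c("p5", "p6") %in% out$demographics$patient_id))
  ## no flags -> untouched
  clean <- pop
  keep <- !clean$diagnoses$condition_category %in% "cystic_fibrosis"
  clean$diagnoses <- clean$diagnoses[keep, , drop = FALSE]
  clean$demographics$birth_day[6] <- -round(30 * 365.25)
  out2 <- apply_exclusions(clean)
  expect_equal(nrow(out2$demographics), 7L)
})

test_that("treatment attribution honors the 30-day grace period", {
  rx <- data.frame(fill_day = 0, drug_class = "metformin", days_supply = 90)
  expect_equal(attribute_treatment(rx, 100), "metformin")   # 0+90+30 > 100
  rx$days_supply <- 60
  expect_true(is.na(attribute_treatment(rx, 100)))          # 0+60+30 <= 100
  expect_equal(attribute_treatment(rx, 89), "metformin")    # boundary: < 90
  expect_true(is.na(attribute_treatment(rx, 90)))           # day 90 excluded
  both <- data.frame(fill_day = c(0, 10),
                     drug_class = c("metformin", "sulfonylurea"),
                     days_supply = c(90, 90))
  expect_equal(attribute_treatment(both, 50), "metformin+sulfonylurea")
  expect_error(attribute_treatment(
    data.frame(fill_day = 0, drug_class = "x", days_supply = -1), 5),
    "nonnegative")
})

test_that("regimen change during a snapshot is attributed to the new regimen", {
  pop <- make_fixture_population()
  sn <- build_snapshots(apply_exclusions(pop))
  ## p1's first interval starts on insulin (prior) but ends on metformin
  expect_equal(sn$regimen[1], "metformin")
  expect_equal(sn$prior_regimen[1], "insulin")
  expect_true(sn$insulin_at_index[1])
  ## second interval: combination at the terminal lab
  expect_equal(sn$regimen[2], "metformin+sulfonylurea")
  expect_false(sn$insulin_at_index[2])
})

test_that("comorbidity count is distinct categories as of the index day", {
  dg <- data.frame(day = c(-100, -50, -50, 150),
                   condition_category = c("renal_disease",
                                          "chronic_pulmonary_disease",
                                          "chronic_pulmonary_disease",
                                          "congestive_heart_failure"))
  expect_equal(compute_cci(dg[0, , drop = FALSE], 0), 0L)
  expect_equal(compute_cci(dg, 0), 2L)     # repeat counts once
  expect_equal(compute_cci(dg, 300), 3L)   # later category now included
  ## non-Charlson categories never count
  dg2 <- rbind(dg, data.frame(day = -5, condition_category = "type1_diabetes"))
  expect_equal(compute_cci(dg2, 0), 2L)
})

test_that("cohort assignment partitions all boundary combinations", {
  expect_equal(assign_cohort(FALSE, 54, 2), "A")
  expect_equal(assign_cohort(FALSE, 40, 3), "B")
  expect_equal(assign_cohort(FALSE, 40, 5), "C")
  expect_equal(assign_cohort(FALSE, 65.0, 0), "D")  # >= 65 boundary
  expect_equal(assign_cohort(FALSE, 64.9, 0), "A")
  expect_equal(assign_cohort(FALSE, 70, 5), "E")
  expect_equal(assign_cohort(TRUE, 54, 2), "F")
  expect_equal(assign_cohort(TRUE, 54, 4), "G")
  expect_equal(assign_cohort(TRUE, 54, 5), "H")
  expect_equal(assign_cohort(TRUE, 70, 4), "I")
  expect_equal(assign_cohort(TRUE, 70, 6), "J")
  ## totality: every (insulin, age, cci) cell maps to exactly one label
  grid <- expand.grid(ins = c(TRUE, FALSE), age = c(20, 64, 65, 90),
                      cci = 0:8)
  labs <- assign_cohort(grid$ins, grid$age, grid$cci)
  expect_true(all(labs %in% LETTERS[1:10]))
  expect_equal(length(labs), nrow(grid))
})

test_that("confounder assembly imputes to training means with indicators", {
  pop <- simulate_population(sim_config(
    n_patients = 200, missingness_rates = list(egfr = 0.3, creatinine = 0.2,
                                               zcta_income = 0.1),
    seed = 17))
  sn <- build_snapshots(pop)
  X <- assemble_confounders(pop, sn)
  expect_true(anyNA(X[, "egfr"]))
  imp <- impute_to_means(X)
  expect_false(anyNA(imp$X))
  expect_true(all(paste0("miss_", c("egfr", "creatinine")) %in%
                  colnames(imp$X)))
  miss <- is.na(X[, "egfr"])
  expect_equal(unname(imp$X[miss, "egfr"][1]),
               mean(X[, "egfr"], na.rm = TRUE))
  expect_equal(unname(imp$X[, "miss_egfr"]), unname(1 * miss))
  ## reusing training means on a "test" matrix imputes the same value
  imp2 <- impute_to_means(X[1:50, , drop = FALSE], means = imp$means)
  if (anyNA(X[1:50, "egfr"]))
    expect_equal(unname(imp2$X[is.na(X[1:50, "egfr"]), "egfr"][1]),
                 unname(imp$means[["egfr"]]))
  ## age/sex must always be present
  bad <- pop
  bad$demographics$birth_day[1] <- NA
  expect_error(assemble_confounders(bad, sn), "age and sex")
})

test_that("duplicate same-day HbA1c keeps the last value with a warning", {
  pop <- make_fixture_population()
  extra <- data.frame(patient_id = "p1", day = 0, test_name = "hba1c",
                      value = 11.0)
  pop$labs <- rbind(pop$labs, extra)
  expect_warning(sn <- build_snapshots(apply_exclusions(pop)), "duplicate")
  expect_equal(sn$index_hba1c[1], 11.0)
})

test_that("train/test split has the right sizes and is reproducible", {
  pop <- simulate_population(sim_config(n_patients = 300, seed = 23))
  sn <- suppressWarnings(build_snapshots(pop))
  sp1 <- split_train_test(sn, fraction = 0.8, seed = 5)
  sp2 <- split_train_test(sn, fraction = 0.8, seed = 5)
  expect_identical(sp1$train, sp2$train)
  expect_equal(length(sp1$train), round(0.8 * nrow(sn)))
  expect_equal(sort(c(sp1$train, sp1$test)), seq_len(nrow(sn)))
  ## patient-level split never leaks a patient across sets
  sp3 <- split_train_test(sn, fraction = 0.8, seed = 5, by_patient = TRUE)
  expect_length(intersect(sn$patient_id[sp3$train],
                          sn$patient_id[sp3$test]), 0)
})

test_that("split halves are covariate-balanced on a large simulation", {
  pop <- simulate_population(sim_config(n_patients = 4000,
                                        labs_per_patient = c(2, 2),
                                        seed = 29))
  sn <- suppressWarnings(build_snapshots(pop))
  X <- impute_to_means(assemble_confounders(pop, sn))$X
  sp <- split_train_test(sn, fraction = 0.8, seed = 7, X = X)
  expect_true(all(sp$smd_report$smd < 0.1))
})
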