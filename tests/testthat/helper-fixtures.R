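# Shared fixtures, built in code at test time.

# A directly specified two-arm observational study with known truth:
# logistic assignment on three covariates, linear outcome model, additive
# treatment effect. Cheaper than a full claims simulation for propensity
# and bootstrap experiments.
make_two_arm_study <- function(n = 1000, effect = -0.5, confounding = 0.8,
                               noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rbinom(n, 1, 0.4))
  ps <- plogis(confounding * (X[, 1] - X[, 2] + X[, 3]))
  t <- rbinom(n, 1, ps)
  ## outcome coefficients aligned with the assignment score so the
  ## confounding biases add up rather than cancel
  y <- -1 + effect * t + 0.6 * X[, 1] - 0.5 * X[, 2] + 0.4 * X[, 3] +
    rnorm(n, 0, noise_sd)
  list(X = X, t = t, y = y, ps = ps, effect = effect)
}

# Small regimen catalogs for generator-based experiments.
catalog_three <- function() {
  data.frame(
    regimen = c("metformin", "glp1_agonist+metformin", "insulin+metformin"),
    true_effect = c(-1.0, -1.8, -1.3), stringsAsFactors = FALSE)
}

# Twelve regimens whose true effects are well separated so the estimated
# ranking should recover the true order at the top and bottom.
catalog_graded <- function() {
  cat12 <- default_regimen_catalog()
  cat12$true_effect <- seq(-2.6, -0.4, length.out = 12)[rank(
    cat12$true_effect, ties.method = "first")]
  cat12
}

# A hand-built population for filter-fidelity checks: every event placed
# explicitly so snapshot counts and cohort labels can be enumerated by
# hand.
make_fixture_population <- function() {
  labs <- rbind(
    # p1: three HbA1c labs (gaps 100, 200) -> 2 snapshots
    data.frame(patient_id = "p1", day = c(0, 100, 300), test_name = "hba1c",
               value = c(9.5, 10.0, 9.2)),
    # p2: gap 60 -> too short, no snapshot
    data.frame(patient_id = "p2", day = c(0, 60), test_name = "hba1c",
               value = c(9.5, 9.8)),
    # p3: single lab -> none
    data.frame(patient_id = "p3", day = 0, test_name = "hba1c", value = 9.5),
    # p4: index 8.5 < 9 -> none
    data.frame(patient_id = "p4", day = c(0, 100), test_name = "hba1c",
               value = c(8.5, 10.0)),
    # p5: valid pair but flagged cystic fibrosis -> excluded
    data.frame(patient_id = "p5", day = c(0, 100), test_name = "hba1c",
               value = c(9.5, 9.0)),
    # p6: 17 years old at index -> excluded
    data.frame(patient_id = "p6", day = c(0, 100), test_name = "hba1c",
               value = c(9.5, 9.0)),
    # p7: valid pair, no prescriptions -> snapshot dropped (untreated)
    data.frame(patient_id = "p7", day = c(0, 100), test_name = "hba1c",
               value = c(9.5, 9.0)))
  prescriptions <- rbind(
    # p1 interval 1: metformin fills covering day 100 (terminal) and a
    # prior insulin fill covering day 0 only
    data.frame(patient_id = "p1", fill_day = -20, drug_class = "insulin",
               days_supply = 10),
    data.frame(patient_id = "p1", fill_day = 5, drug_class = "metformin",
               days_supply = 95),
    # p1 interval 2: metformin + sulfonylurea covering day 300
    data.frame(patient_id = "p1", fill_day = 150,
               drug_class = c("metformin", "sulfonylurea"),
               days_supply = 130),
    data.frame(patient_id = c("p2", "p4", "p5", "p6"), fill_day = 0,
               drug_class = "metformin", days_supply = 400))
  diagnoses <- rbind(
    # p1: two Charlson categories before day 0, a third only by day 300,
    # plus a repeat (counts once)
    data.frame(patient_id = "p1", day = c(-100, -50, -50, 150),
               condition_category = c("renal_disease",
                                      "chronic_pulmonary_disease",
                                      "chronic_pulmonary_disease",
                                      "congestive_heart_failure")),
    data.frame(patient_id = "p5", day = -10,
               condition_category = "cystic_fibrosis"))
  demographics <- data.frame(
    patient_id = paste0("p", 1:7),
    birth_day = c(-round(54 * 365.25), -round(70 * 365.25),
                  -round(40 * 365.25), -round(40 * 365.25),
                  -round(40 * 365.25), -round(17.5 * 365.25),
                  -round(40 * 365.25)),
    sex = c("F", "M", "F", "M", "F", "M", "F"),
    zcta_income = 55000, zcta_white = 0.6, zcta_black = 0.25,
    zcta_asian = 0.15, stringsAsFactors = FALSE)
  structure(list(labs = labs, prescriptions = prescriptions,
                 diagnoses = diagnoses, demographics = demographics,
                 ground_truth = NULL, config = NULL),
            class = "glyco_population")
}

# An nma_posterior built directly from draws, for ranking contracts.
make_posterior <- function(d, tau = rep(0, nrow(d)), baseline = colnames(d)[1]) {
  structure(list(d = d, tau = tau, rhat = c(d = 1), converged = TRUE,
                 regimens = colnames(d), baseline = baseline,
                 n_chains = 1L, n_iter = nrow(d)),
            class = "nma_posterior")
}

fast_bcaus <- function(seed = 1, nu = 1) {
  bcaus_config(hidden_width = 16L, max_epochs = 100L, seed = seed, nu = nu)
}
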