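# Synthetic longitudinal claims generator with known ground truth.
#
# Emulates the statistical structure the downstream analysis assumes:
# HbA1c trajectories with high index values, multi-class drug regimens,
# confounded treatment assignment driven by covariates, and known additive
# per-regimen effects on HbA1c change. Ground truth (assignment model,
# outcome model, per-interval propensities) is carried in a sidecar object
# that the analysis pipeline never reads.

#' Default antihyperglycemic drug classes
#' @return character vector of drug-class identifiers.
#' @export
default_drug_classes <- function() {
  c("metformin", "sulfonylurea", "dpp4_inhibitor", "sglt2_inhibitor",
    "glp1_agonist", "thiazolidinedione", "insulin")
}

#' Default regimen catalog with true additive HbA1c effects
#'
#' Twelve regimens spanning monotherapy to a five-class combination.
#' `true_effect` is the additive change in HbA1c percentage points a regimen
#' causes over one observation period (negative = reduction); the spread
#' (about -0.8 to -2.2) is of the order seen for antihyperglycemic
#' combinations over a ~6-month window.
#'
#' @return data.frame with columns `regimen` (canonical string) and
#'   `true_effect` (percentage points).
#' @export
default_regimen_catalog <- function() {
  reg <- list(
    c("metformin"),
    c("glp1_agonist"),
    c("sulfonylurea"),
    c("insulin"),
    c("metformin", "glp1_agonist"),
    c("metformin", "sulfonylurea"),
    c("metformin", "sglt2_inhibitor"),
    c("metformin", "insulin"),
    c("metformin", "dpp4_inhibitor"),
    c("metformin", "glp1_agonist", "sglt2_inhibitor"),
    c("metformin", "sulfonylurea", "dpp4_inhibitor"),
    c("metformin", "insulin", "sulfonylurea", "sglt2_inhibitor",
      "thiazolidinedione")
  )
  effect <- c(-1.0, -1.4, -0.8, -1.1, -2.0, -1.3, -1.7, -1.5, -1.2,
              -2.2, -1.1, -0.9)
  data.frame(regimen = vapply(reg, regimen_string, character(1)),
             true_effect = effect, stringsAsFactors = FALSE)
}

#' Configuration for the synthetic claims generator
#'
#' @param n_patients number of patients to simulate.
#' @param drug_classes drug-class identifiers available to regimens.
#' @param regimen_catalog data.frame with `regimen` (canonical string of 1-5
#'   classes drawn from `drug_classes`) and `true_effect` (additive change in
#'   HbA1c percentage points, negative = reduction).
#' @param confounding_strength nonnegative scale of the covariate
#'   coefficients in the multinomial-logistic treatment assignment model;
#'   0 means assignment is independent of covariates.
#' @param outcome_confounding scale of the linear covariate terms in the
#'   outcome model; together with `confounding_strength > 0` this creates
#'   genuine confounding.
#' @param outcome_noise_sd positive Gaussian noise SD on terminal HbA1c
#'   (percentage points).
#' @param labs_per_patient integer range (length-2) of HbA1c labs per
#'   patient.
#' @param inter_lab_gap_days integer range of days between consecutive
#'   HbA1c labs.
#' @param index_hba1c_range range the first HbA1c value is drawn from (%).
#' @param missingness_rates named list of probabilities in [0,1] for
#'   injecting missingness into `egfr`, `creatinine`, `zcta_income`.
#' @param age_range adult age range (years) at simulation epoch.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       drug_classes = default_drug_classes(),
                       regimen_catalog = default_regimen_catalog(),
                       confounding_strength = 0.5,
                       outcome_confounding = 0.3,
                       outcome_noise_sd = 0.8,
                       labs_per_patient = c(2L, 4L),
                       inter_lab_gap_days = c(90L, 365L),
                       index_hba1c_range = c(9, 12.5),
                       missingness_rates = list(egfr = 0.1, creatinine = 0.1,
                                                zcta_income = 0.05),
                       age_range = c(21, 85),
                       seed = 1L) {
  if (is.null(regimen_catalog) || nrow(regimen_catalog) == 0L)
    stop("regimen_catalog must contain at least one regimen", call. = FALSE)
  stopifnot(n_patients >= 1, outcome_noise_sd > 0, confounding_strength >= 0,
            length(labs_per_patient) == 2, length(inter_lab_gap_days) == 2)
  sizes <- vapply(regimen_catalog$regimen,
                  function(r) length(regimen_classes(r)), integer(1))
  if (any(sizes < 1L | sizes > 5L))
    stop("every regimen must contain 1-5 drug classes", call. = FALSE)
  unknown <- setdiff(unlist(lapply(regimen_catalog$regimen, regimen_classes)),
                     drug_classes)
  if (length(unknown))
    stop("regimen classes not in drug_classes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  rates <- unlist(missingness_rates)
  if (any(rates < 0 | rates > 1))
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients), drug_classes = drug_classes,
    regimen_catalog = regimen_catalog,
    confounding_strength = confounding_strength,
    outcome_confounding = outcome_confounding,
    outcome_noise_sd = outcome_noise_sd,
    labs_per_patient = as.integer(labs_per_patient),
    inter_lab_gap_days = as.integer(inter_lab_gap_days),
    index_hba1c_range = index_hba1c_range,
    missingness_rates = missingness_rates,
    age_range = age_range, seed = as.integer(seed)),
    class = "sim_config")
}

# sample() collapses to 1:x for a scalar first argument; this keeps
# degenerate ranges (a == b) safe.
.sample_range <- function(a, b, n) {
  if (a == b) rep(as.integer(a), n)
  else sample(seq.int(a, b), n, replace = TRUE)
}

# Covariates entering the assignment and outcome models, standardized with
# fixed population constants so the generative models are scale-free.
.sim_covariate_names <- c("age", "sex", "n_conditions", "log_income",
                          "egfr", "index_hba1c")

.standardize_sim_covariates <- function(age, sex01, ncond, income, egfr,
                                        hba1c) {
  cbind(age = (age - 55) / 12,
        sex = sex01 - 0.5,
        n_conditions = (ncond - 2) / 1.3,
        log_income = (log(income) - log(55000)) / 0.4,
        egfr = (egfr - 94) / 15,
        index_hba1c = (hba1c - 10.5) / 1.0)
}

# Background prevalences of the chronic-condition categories.
.condition_prevalence <- c(
  myocardial_infarction = 0.10, congestive_heart_failure = 0.15,
  peripheral_vascular_disease = 0.08, cerebrovascular_disease = 0.10,
  dementia = 0.03, chronic_pulmonary_disease = 0.20,
  rheumatic_disease = 0.05, peptic_ulcer_disease = 0.05,
  mild_liver_disease = 0.08, diabetes_with_complication = 0.30,
  hemiplegia = 0.02, renal_disease = 0.25, malignancy = 0.07,
  moderate_severe_liver_disease = 0.02, metastatic_solid_tumor = 0.02,
  aids_hiv = 0.01)

#' Simulate a population of longitudinal claims-like patient histories
#'
#' Generates, per patient: demographics with area-level income and
#' race-fraction proxies; dated chronic-condition diagnoses; baseline EGFR
#' and creatinine labs; a series of dated HbA1c labs; and prescriptions
#' whose fill dates and days-supply cover each terminal lab for the regimen
#' assigned to that interval. Assignment follows a multinomial logistic
#' model over standardized covariates with coefficients drawn once from a
#' seeded normal scaled by `confounding_strength`. Terminal HbA1c =
#' index HbA1c + true effect of the assigned regimen + linear covariate
#' terms + Gaussian noise.
#'
#' @param config a [sim_config()].
#' @return object of class `glyco_population`: a list with data.frames
#'   `labs`, `prescriptions`, `diagnoses`, `demographics`, plus
#'   `ground_truth` (assignment/outcome coefficients and per-interval true
#'   propensities, keyed by `patient_id` and `index_day`) and the `config`.
#'   Dates are integer day offsets from the simulation epoch.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_population_impl(config))
}

.simulate_population_impl <- function(config) {
  n <- config$n_patients
  cat_df <- config$regimen_catalog
  K <- nrow(cat_df)
  pid <- sprintf("P%05d", seq_len(n))

  ## demographics
  age0 <- runif(n, config$age_range[1], config$age_range[2])
  birth_day <- -round(age0 * 365.25)
  sex <- ifelse(runif(n) < 0.5, "F", "M")
  income <- round(exp(rnorm(n, log(55000), 0.4)))
  g <- cbind(rgamma(n, 6, 1), rgamma(n, 2, 1), rgamma(n, 1, 1))
  race <- g / rowSums(g)

  ## chronic conditions (diagnosed before the first lab)
  prev <- .condition_prevalence
  has_cond <- matrix(runif(n * length(prev)) < rep(prev, each = n), nrow = n)
  colnames(has_cond) <- names(prev)

  ## lab schedule
  n_labs <- .sample_range(config$labs_per_patient[1],
                          config$labs_per_patient[2], n)
  first_day <- sample.int(200L, n, replace = TRUE)
  max_int <- max(n_labs) - 1L
  gap <- matrix(NA_integer_, n, max(max_int, 1L))
  for (j in seq_len(max_int)) {
    need <- n_labs > j
    gap[need, j] <- .sample_range(config$inter_lab_gap_days[1],
                                  config$inter_lab_gap_days[2], sum(need))
  }
  lab_day <- matrix(NA_integer_, n, max(n_labs))
  lab_day[, 1] <- first_day
  for (j in seq_len(max_int))
    lab_day[, j + 1L] <- lab_day[, j] + gap[, j]

  ## ground-truth model coefficients (drawn once per simulation)
  p <- length(.sim_covariate_names)
  Gamma <- matrix(rnorm(K * p, 0, config$confounding_strength), K, p,
                  dimnames = list(cat_df$regimen, .sim_covariate_names))
  intercept <- rnorm(K, 0, 0.3)
  beta_out <- rnorm(p, 0, config$outcome_confounding)
  names(beta_out) <- .sim_covariate_names

  ncond <- rowSums(has_cond)
  egfr_true <- rnorm(n, 94, 15)
  creat_true <- pmax(0.4, rnorm(n, 0.9, 0.2))
  sex01 <- as.numeric(sex == "F")

  ## HbA1c trajectory + per-interval assignment (sequential in interval idx,
  ## vectorized across patients)
  hba1c <- matrix(NA_real_, n, max(n_labs))
  hba1c[, 1] <- runif(n, config$index_hba1c_range[1],
                      config$index_hba1c_range[2])
  assigned <- matrix(NA_integer_, n, max(max_int, 1L))
  prop_list <- vector("list", max_int)
  for (j in seq_len(max_int)) {
    idx <- which(n_labs > j)
    age_j <- (lab_day[idx, j] - birth_day[idx]) / 365.25
    Z <- .standardize_sim_covariates(age_j, sex01[idx], ncond[idx],
                                     income[idx], egfr_true[idx],
                                     hba1c[idx, j])
    eta <- sweep(Z %*% t(Gamma), 2, intercept, "+")
    eta <- eta - apply(eta, 1, max)
    pr <- exp(eta) / rowSums(exp(eta))
    u <- runif(length(idx))
    k <- max.col(u < t(apply(pr, 1, cumsum)), ties.method = "first")
    assigned[idx, j] <- k
    pr_df <- as.data.frame(pr)
    names(pr_df) <- cat_df$regimen
    prop_list[[j]] <- cbind(
      data.frame(patient_id = pid[idx], index_day = lab_day[idx, j],
                 interval = j, regimen = cat_df$regimen[k],
                 stringsAsFactors = FALSE),
      pr_df)
    hba1c[idx, j + 1L] <- hba1c[idx, j] + cat_df$true_effect[k] +
      as.vector(Z %*% beta_out) +
      rnorm(length(idx), 0, config$outcome_noise_sd)
  }

  ## labs table
  rate <- config$missingness_rates
  keep_egfr <- runif(n) >= (rate$egfr %||% 0)
  keep_creat <- runif(n) >= (rate$creatinine %||% 0)
  lab_rows <- list(
    data.frame(patient_id = rep(pid, n_labs),
               day = as.integer(t(lab_day))[!is.na(t(lab_day))],
               test_name = "hba1c",
               value = as.numeric(t(hba1c))[!is.na(t(hba1c))],
               stringsAsFactors = FALSE),
    data.frame(patient_id = pid[keep_egfr],
               day = first_day[keep_egfr] - 7L, test_name = "egfr",
               value = round(egfr_true[keep_egfr], 1),
               stringsAsFactors = FALSE),
    data.frame(patient_id = pid[keep_creat],
               day = first_day[keep_creat] - 7L, test_name = "creatinine",
               value = round(creat_true[keep_creat], 2),
               stringsAsFactors = FALSE))
  labs <- do.call(rbind, lab_rows)
  labs <- labs[order(labs$patient_id, labs$day), , drop = FALSE]
  rownames(labs) <- NULL

  ## prior regimen covering only the first lab (sets insulin status at the
  ## first index without covering later labs)
  Z0 <- .standardize_sim_covariates((first_day - birth_day) / 365.25, sex01,
                                    ncond, income, egfr_true, hba1c[, 1])
  eta0 <- sweep(Z0 %*% t(Gamma), 2, intercept, "+")
  eta0 <- eta0 - apply(eta0, 1, max)
  pr0 <- exp(eta0) / rowSums(exp(eta0))
  k0 <- max.col(runif(n) < t(apply(pr0, 1, cumsum)), ties.method = "first")

  rx_rows <- list()
  prior_classes <- lapply(cat_df$regimen[k0], regimen_classes)
  rx_rows[[1]] <- data.frame(
    patient_id = rep(pid, lengths(prior_classes)),
    fill_day = rep(first_day - 20L, lengths(prior_classes)),
    drug_class = unlist(prior_classes),
    days_supply = 10L, stringsAsFactors = FALSE)
  for (j in seq_len(max_int)) {
    idx <- which(n_labs > j)
    cls <- lapply(cat_df$regimen[assigned[idx, j]], regimen_classes)
    rx_rows[[j + 1L]] <- data.frame(
      patient_id = rep(pid[idx], lengths(cls)),
      fill_day = rep(lab_day[idx, j] + 1L, lengths(cls)),
      drug_class = unlist(cls),
      days_supply = rep(gap[idx, j], lengths(cls)),
      stringsAsFactors = FALSE)
  }
  prescriptions <- do.call(rbind, rx_rows)
  prescriptions <- prescriptions[order(prescriptions$patient_id,
                                       prescriptions$fill_day), , drop = FALSE]
  rownames(prescriptions) <- NULL

  ## diagnoses
  cond_idx <- which(has_cond, arr.ind = TRUE)
  diagnoses <- data.frame(
    patient_id = pid[cond_idx[, 1]],
    day = first_day[cond_idx[, 1]] -
      sample.int(1825L, nrow(cond_idx), replace = TRUE),
    condition_category = colnames(has_cond)[cond_idx[, 2]],
    stringsAsFactors = FALSE)
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$day), ,
                         drop = FALSE]
  rownames(diagnoses) <- NULL

  demographics <- data.frame(
    patient_id = pid, birth_day = birth_day, sex = sex,
    zcta_income = ifelse(runif(n) < (rate$zcta_income %||% 0), NA_real_,
                         income),
    zcta_white = round(race[, 1], 4), zcta_black = round(race[, 2], 4),
    zcta_asian = round(race[, 3], 4), stringsAsFactors = FALSE)

  truth_snap <- if (max_int > 0L) do.call(rbind, prop_list) else NULL
  if (!is.null(truth_snap)) rownames(truth_snap) <- NULL
  ground_truth <- list(
    catalog = cat_df, assign_coef = Gamma, assign_intercept = intercept,
    outcome_coef = beta_out, covariate_names = .sim_covariate_names,
    snapshots = truth_snap)

  structure(list(labs = labs, prescriptions = prescriptions,
                 diagnoses = diagnoses, demographics = demographics,
                 ground_truth = ground_truth, config = config),
            class = "glyco_population")
}

#' @export
print.glyco_population <- function(x, ...) {
  cat("<glyco_population>", nrow(x$demographics), "patients,",
      sum(x$labs$test_name == "hba1c"), "HbA1c labs,",
      nrow(x$prescriptions), "prescription fills\n")
  invisible(x)
}

#' Extract one patient's history from a population
#' @param population a `glyco_population`.
#' @param patient_id patient identifier.
#' @return list of the four per-patient event tables.
#' @export
patient_history <- function(population, patient_id) {
  pick <- function(df) {
    out <- df[df$patient_id == patient_id, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(labs = pick(population$labs),
       prescriptions = pick(population$prescriptions),
       diagnoses = pick(population$diagnoses),
       demographics = pick(population$demographics))
}

#' True pairwise propensity between two regimens
#'
#' From the stored assignment model, the probability of the case regimen
#' given assignment to one of the two regimens: P(case)/(P(case)+P(comp)).
#'
#' @param ground_truth the `ground_truth` element of a population.
#' @param patient_id,index_day snapshot key vectors (recycled together).
#' @param case_regimen,comparator_regimen canonical regimen strings.
#' @return numeric vector of true propensities in (0,1).
#' @export
true_pairwise_propensity <- function(ground_truth, patient_id, index_day,
                                     case_regimen, comparator_regimen) {
  ts <- ground_truth$snapshots
  key <- paste(ts$patient_id, ts$index_day)
  i <- match(paste(patient_id, index_day), key)
  pa <- ts[i, case_regimen]
  pb <- ts[i, comparator_regimen]
  pa / (pa + pb)
}

#' Write a population to the four-table delimited schema
#'
#' Emits `labs.csv`, `prescriptions.csv`, `diagnoses.csv`,
#' `demographics.csv` under `path`, plus a `ground_truth.json` sidecar that
#' the analysis pipeline never reads.
#'
#' @param population a `glyco_population`.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_tables <- function(population, path) {
  if (nrow(population$demographics) == 0L)
    stop("population has no patients", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("labs", "prescriptions", "diagnoses", "demographics"))
    utils::write.csv(population[[nm]], file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE)
  gt <- population$ground_truth
  if (!is.null(gt)) {
    gt$assign_coef <- as.data.frame(gt$assign_coef, row.names = FALSE)
    rownames(gt$assign_coef) <- NULL
    jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                         dataframe = "columns", digits = NA)
  }
  invisible(path)
}

#' Read the four-table schema back into a population object
#'
#' The inverse of [write_tables()]; the ground-truth sidecar is loaded only
#' if present and is never used by the analysis stages.
#'
#' @param path directory holding the four CSV tables.
#' @return a `glyco_population` (with `ground_truth = NULL` if no sidecar).
#' @export
read_tables <- function(path) {
  rd <- function(nm) utils::read.csv(file.path(path, paste0(nm, ".csv")),
                                     stringsAsFactors = FALSE)
  out <- list(labs = rd("labs"), prescriptions = rd("prescriptions"),
              diagnoses = rd("diagnoses"), demographics = rd("demographics"),
              ground_truth = NULL, config = NULL)
  gt_path <- file.path(path, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt$catalog <- as.data.frame(gt$catalog, stringsAsFactors = FALSE)
    gt$assign_coef <- as.matrix(as.data.frame(gt$assign_coef))
    rownames(gt$assign_coef) <- gt$catalog$regimen
    gt$outcome_coef <- unlist(gt$outcome_coef)
    if (!is.null(gt$snapshots))
      gt$snapshots <- as.data.frame(gt$snapshots, check.names = FALSE,
                                    stringsAsFactors = FALSE)
    out$ground_truth <- gt
  }
  structure(out, class = "glyco_population")
}
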