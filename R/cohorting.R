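# Snapshot construction and clinical cohort stratification.
#
# A snapshot is a pair of consecutive HbA1c lab events for one patient:
# the index lab (value >= 9%) and the terminal lab 90-365 days later. The
# change in HbA1c over the observation period is attributed to the regimen
# covering the terminal lab; insulin status and all confounders are
# measured at the index lab.

#' Apply patient-level clinical exclusions
#'
#' Removes patients flagged with type-1 diabetes, gestational diabetes,
#' diabetic ketoacidosis, cystic fibrosis or a solid-organ transplant, and
#' patients under 18 years of age at any HbA1c lab. Snapshot-level rules
#' (no treatment, duration, index value) are applied in
#' [build_snapshots()].
#'
#' @param population a `glyco_population`.
#' @return the filtered population, with an `exclusion_log` attribute
#'   (data.frame of `patient_id`, `reason`).
#' @export
apply_exclusions <- function(population) {
  dem <- population$demographics
  dg <- population$diagnoses
  flagged <- dg[dg$condition_category %in% EXCLUSION_CATEGORIES, , drop = FALSE]
  log <- data.frame(patient_id = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(flagged))
    log <- unique(data.frame(patient_id = flagged$patient_id,
                             reason = flagged$condition_category,
                             stringsAsFactors = FALSE))
  hb <- population$labs[population$labs$test_name == "hba1c", , drop = FALSE]
  if (nrow(hb)) {
    age <- (hb$day - dem$birth_day[match(hb$patient_id, dem$patient_id)]) /
      365.25
    minors <- unique(hb$patient_id[age < 18])
    if (length(minors))
      log <- rbind(log, data.frame(patient_id = minors, reason = "under_18",
                                   stringsAsFactors = FALSE))
  }
  drop <- unique(log$patient_id)
  out <- population
  for (nm in c("labs", "prescriptions", "diagnoses", "demographics")) {
    out[[nm]] <- out[[nm]][!out[[nm]]$patient_id %in% drop, , drop = FALSE]
    rownames(out[[nm]]) <- NULL
  }
  attr(out, "exclusion_log") <- log
  out
}

#' Attribute a treatment regimen at a given day
#'
#' A drug class covers a day if any prescription satisfies
#' `fill_day <= day < fill_day + days_supply + 30`; the 30-day grace period
#' absorbs imperfect adherence. The regimen is the set of all covering
#' classes.
#'
#' @param prescriptions data.frame with `fill_day`, `drug_class`,
#'   `days_supply` (one patient's fills).
#' @param at_day integer day to attribute at.
#' @param grace_days grace period appended to each supply (days).
#' @return canonical regimen string, or `NA_character_` if no class covers
#'   the day.
#' @export
#' @examples
#' rx <- data.frame(fill_day = 0, drug_class = "metformin", days_supply = 90)
#' attribute_treatment(rx, 100)  # covered: 0 + 90 + 30 > 100
attribute_treatment <- function(prescriptions, at_day, grace_days = 30L) {
  if (nrow(prescriptions) == 0L) return(NA_character_)
  if (any(prescriptions$days_supply < 0))
    stop("days_supply must be nonnegative", call. = FALSE)
  cover <- prescriptions$fill_day <= at_day &
    at_day < prescriptions$fill_day + prescriptions$days_supply + grace_days
  regimen_string(prescriptions$drug_class[cover])
}

# Vectorized attribution for many (patient, day) queries against the full
# prescriptions table.
.attribute_many <- function(prescriptions, patient_id, day, grace_days = 30L) {
  if (any(prescriptions$days_supply < 0))
    stop("days_supply must be nonnegative", call. = FALSE)
  out <- rep(NA_character_, length(patient_id))
  rx_split <- split(prescriptions[c("fill_day", "drug_class", "days_supply")],
                    prescriptions$patient_id)
  q_split <- split(seq_along(patient_id), patient_id)
  for (pid in names(q_split)) {
    rx <- rx_split[[pid]]
    if (is.null(rx)) next
    for (i in q_split[[pid]]) {
      cover <- rx$fill_day <= day[i] &
        day[i] < rx$fill_day + rx$days_supply + grace_days
      out[i] <- regimen_string(rx$drug_class[cover])
    }
  }
  out
}

#' Unweighted Charlson comorbidity count
#'
#' Number of distinct Charlson comorbidity categories diagnosed on or
#' before `as_of_day`; each category contributes 1 regardless of repeats.
#'
#' @param diagnoses data.frame with `day`, `condition_category` (one
#'   patient's diagnoses).
#' @param as_of_day integer cutoff day.
#' @return nonnegative integer.
#' @export
compute_cci <- function(diagnoses, as_of_day) {
  if (nrow(diagnoses) == 0L) return(0L)
  hit <- diagnoses$condition_category %in% CHARLSON_CATEGORIES &
    diagnoses$day <= as_of_day
  length(unique(diagnoses$condition_category[hit]))
}

#' Assign a snapshot to one of the ten clinical cohorts
#'
#' Cohorts partition (insulin status at index) x (age) x (comorbidity
#' count): non-users under 65 split at CCI <=2 / 3-4 / >=5 (A/B/C),
#' non-users 65+ at CCI <5 / >=5 (D/E); insulin users mirror these as
#' F/G/H and I/J.
#'
#' @param insulin_user logical: insulin class in the regimen covering the
#'   index lab.
#' @param age_years age at the index lab.
#' @param cci unweighted Charlson count.
#' @return character vector of labels "A".."J" (vectorized, total).
#' @export
assign_cohort <- function(insulin_user, age_years, cci) {
  n <- max(length(insulin_user), length(age_years), length(cci))
  insulin_user <- rep_len(as.logical(insulin_user), n)
  age_years <- rep_len(age_years, n)
  cci <- rep_len(cci, n)
  young <- age_years < 65
  lab <- ifelse(!insulin_user,
    ifelse(young,
           ifelse(cci <= 2, "A", ifelse(cci < 5, "B", "C")),
           ifelse(cci < 5, "D", "E")),
    ifelse(young,
           ifelse(cci <= 2, "F", ifelse(cci < 5, "G", "H")),
           ifelse(cci < 5, "I", "J")))
  lab
}

#' Build analysis snapshots from patient histories
#'
#' Pairs each patient's consecutive HbA1c labs, retains pairs with
#' duration in [90, 365] days and index value >= 9%, attributes the
#' regimen at the terminal lab (changes during a snapshot count toward the
#' new regimen) and the prior regimen at the index lab, and assigns each
#' snapshot to a clinical cohort. Patients with a single HbA1c lab yield
#' no snapshots; snapshots with no covering regimen are dropped. Duplicate
#' same-day HbA1c values keep the last recorded, with a warning.
#'
#' @param population a `glyco_population` (after [apply_exclusions()]).
#' @param min_duration,max_duration inclusive observation-period bounds
#'   (days).
#' @param min_index_hba1c inclusion threshold on the index value (%).
#' @return data.frame of snapshots (`snapshot_id`, `patient_id`,
#'   `index_day`, `terminal_day`, `index_hba1c`, `terminal_hba1c`,
#'   `delta_hba1c`, `regimen`, `prior_regimen`, `insulin_at_index`,
#'   `age_years`, `cci`, `cohort`), with a `filter_log` attribute counting
#'   drops by reason.
#' @export
build_snapshots <- function(population, min_duration = 90L,
                            max_duration = 365L, min_index_hba1c = 9.0) {
  labs <- population$labs
  hb <- labs[labs$test_name == "hba1c", , drop = FALSE]
  hb <- hb[order(hb$patient_id, hb$day), , drop = FALSE]
  dup <- duplicated(hb[c("patient_id", "day")], fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate same-day HbA1c value(s); keeping the last",
            call. = FALSE)
    hb <- hb[!dup, , drop = FALSE]
  }
  bad <- hb$value <= 3 | hb$value >= 20 | !is.finite(hb$value)
  if (any(bad)) {
    warning(sum(bad), " implausible HbA1c value(s) outside (3, 20) dropped",
            call. = FALSE)
    hb <- hb[!bad, , drop = FALSE]
  }
  n <- nrow(hb)
  log <- c(single_lab = 0L, duration = 0L, index_below_threshold = 0L,
           no_treatment = 0L)
  empty <- data.frame()
  if (n < 2L) return(structure(empty, filter_log = log))

  same <- hb$patient_id[-n] == hb$patient_id[-1]
  cand <- data.frame(
    patient_id = hb$patient_id[-n][same],
    index_day = hb$day[-n][same], terminal_day = hb$day[-1][same],
    index_hba1c = hb$value[-n][same], terminal_hba1c = hb$value[-1][same],
    stringsAsFactors = FALSE)
  n_pairs_per_patient <- table(cand$patient_id)
  log["single_lab"] <- length(setdiff(unique(hb$patient_id),
                                      names(n_pairs_per_patient)))

  dur <- cand$terminal_day - cand$index_day
  keep_dur <- dur >= min_duration & dur <= max_duration
  log["duration"] <- sum(!keep_dur)
  cand <- cand[keep_dur, , drop = FALSE]

  keep_idx <- cand$index_hba1c >= min_index_hba1c
  log["index_below_threshold"] <- sum(!keep_idx)
  cand <- cand[keep_idx, , drop = FALSE]
  if (nrow(cand) == 0L) return(structure(empty, filter_log = log))

  rx <- population$prescriptions
  cand$regimen <- .attribute_many(rx, cand$patient_id, cand$terminal_day)
  cand$prior_regimen <- .attribute_many(rx, cand$patient_id, cand$index_day)

  keep_rx <- !is.na(cand$regimen)
  log["no_treatment"] <- sum(!keep_rx)
  cand <- cand[keep_rx, , drop = FALSE]
  if (nrow(cand) == 0L) return(structure(empty, filter_log = log))

  cand$delta_hba1c <- cand$terminal_hba1c - cand$index_hba1c
  cand$insulin_at_index <- vapply(cand$prior_regimen, function(r)
    "insulin" %in% regimen_classes(if (is.na(r)) NA_character_ else r),
    logical(1))

  dem <- population$demographics
  birth <- dem$birth_day[match(cand$patient_id, dem$patient_id)]
  cand$age_years <- (cand$index_day - birth) / 365.25

  dg <- population$diagnoses
  dg_split <- split(dg[c("day", "condition_category")], dg$patient_id)
  cand$cci <- mapply(function(pid, day) {
    d <- dg_split[[pid]]
    if (is.null(d)) 0L else compute_cci(d, day)
  }, cand$patient_id, cand$index_day, USE.NAMES = FALSE)

  cand$cohort <- assign_cohort(cand$insulin_at_index, cand$age_years,
                               cand$cci)
  cand$snapshot_id <- paste(cand$patient_id, cand$index_day, sep = "_")
  rownames(cand) <- NULL
  cols <- c("snapshot_id", "patient_id", "index_day", "terminal_day",
            "index_hba1c", "terminal_hba1c", "delta_hba1c", "regimen",
            "prior_regimen", "insulin_at_index", "age_years", "cci",
            "cohort")
  structure(cand[cols], filter_log = log)
}

#' Assemble the confounder matrix for a set of snapshots
#'
#' One row per snapshot: Charlson category indicator flags as of the index
#' day, most recent EGFR and creatinine at or before the index day
#' (unbounded lookback), age, sex, area-level income and race-fraction
#' proxies, and the index HbA1c. Numeric fields may be missing (`NA`);
#' impute with [impute_to_means()]. Age and sex are never imputable and
#' must be present.
#'
#' @param population a `glyco_population`.
#' @param snapshots data.frame from [build_snapshots()].
#' @return numeric matrix (rows = snapshots, named columns), possibly with
#'   `NA` entries.
#' @export
assemble_confounders <- function(population, snapshots) {
  n <- nrow(snapshots)
  dem <- population$demographics
  di <- match(snapshots$patient_id, dem$patient_id)
  if (anyNA(di) || anyNA(dem$birth_day[di]) || anyNA(dem$sex[di]))
    stop("age and sex must be present for every snapshot", call. = FALSE)

  dg <- population$diagnoses
  dg <- dg[dg$condition_category %in% CHARLSON_CATEGORIES, , drop = FALSE]
  cm <- matrix(0, n, length(CHARLSON_CATEGORIES),
               dimnames = list(NULL, paste0("cc_", CHARLSON_CATEGORIES)))
  if (nrow(dg)) {
    dg_split <- split(dg[c("day", "condition_category")], dg$patient_id)
    for (i in seq_len(n)) {
      d <- dg_split[[snapshots$patient_id[i]]]
      if (is.null(d)) next
      present <- unique(d$condition_category[d$day <= snapshots$index_day[i]])
      cm[i, paste0("cc_", present)] <- 1
    }
  }

  most_recent <- function(test) {
    lb <- population$labs[population$labs$test_name == test, , drop = FALSE]
    lb <- lb[order(lb$patient_id, lb$day), , drop = FALSE]
    lb_split <- split(lb[c("day", "value")], lb$patient_id)
    vapply(seq_len(n), function(i) {
      l <- lb_split[[snapshots$patient_id[i]]]
      if (is.null(l)) return(NA_real_)
      ok <- l$day <= snapshots$index_day[i]
      if (!any(ok)) NA_real_ else l$value[max(which(ok))]
    }, numeric(1))
  }

  X <- cbind(
    cm,
    egfr = most_recent("egfr"),
    creatinine = most_recent("creatinine"),
    age = snapshots$age_years,
    sex = as.numeric(dem$sex[di] == "F"),
    zcta_income = dem$zcta_income[di],
    zcta_white = dem$zcta_white[di],
    zcta_black = dem$zcta_black[di],
    zcta_asian = dem$zcta_asian[di],
    index_hba1c = snapshots$index_hba1c)
  rownames(X) <- snapshots$snapshot_id
  X
}

#' Impute missing confounders to training-set means
#'
#' Replaces `NA` entries column-wise by the supplied means (typically
#' computed on the training split) and appends a 0/1 missingness indicator
#' column for every field that had any missing value. When `means` is
#' `NULL` they are computed from `X` itself; a column that is entirely
#' missing is imputed to 0 with a warning.
#'
#' @param X confounder matrix from [assemble_confounders()].
#' @param means named vector of imputation means, or `NULL`.
#' @return list with `X` (complete matrix, indicators appended), `means`
#'   (the means used, for reuse on a test split).
#' @export
impute_to_means <- function(X, means = NULL) {
  if (is.null(means)) {
    means <- colMeans(X, na.rm = TRUE)
    if (anyNA(means) || any(!is.finite(means))) {
      warning("column(s) entirely missing; imputed to 0", call. = FALSE)
      means[!is.finite(means)] <- 0
    }
  }
  miss_cols <- colnames(X)[colSums(is.na(X)) > 0]
  ind <- NULL
  if (length(miss_cols)) {
    ind <- 1 * is.na(X[, miss_cols, drop = FALSE])
    colnames(ind) <- paste0("miss_", miss_cols)
    for (j in miss_cols) X[is.na(X[, j]), j] <- means[[j]]
  }
  list(X = if (is.null(ind)) X else cbind(X, ind), means = means)
}

#' Split snapshots into training and test sets
#'
#' Random snapshot-level split by default (patients may span both sets);
#' `by_patient = TRUE` keeps all of a patient's snapshots together. A
#' standardized-mean-difference report comparing train vs test on the
#' confounders is attached when `X` is supplied.
#'
#' @param snapshots snapshot data.frame.
#' @param fraction training fraction.
#' @param seed integer seed.
#' @param by_patient split at the patient level instead.
#' @param X optional confounder matrix (rows aligned with `snapshots`) for
#'   the balance report.
#' @return list with `train`, `test` (integer row indices) and
#'   `smd_report` (data.frame or NULL).
#' @export
split_train_test <- function(snapshots, fraction = 0.8, seed = 1L,
                             by_patient = FALSE, X = NULL) {
  stopifnot(nrow(snapshots) > 0, fraction > 0, fraction < 1)
  n <- nrow(snapshots)
  idx <- with_seed(seed, {
    if (by_patient) {
      pats <- unique(snapshots$patient_id)
      tr_p <- sample(pats, round(fraction * length(pats)))
      which(snapshots$patient_id %in% tr_p)
    } else sample.int(n, round(fraction * n))
  })
  train <- sort(idx)
  test <- setdiff(seq_len(n), train)
  rep <- NULL
  if (!is.null(X)) {
    grp <- rep(0L, n)
    grp[train] <- 1L
    rep <- check_balance(X, grp, rep(1, n), threshold = 0.1)
  }
  list(train = train, test = test, smd_report = rep)
}

#' Summarize snapshot cohorts
#'
#' One row per clinical cohort: snapshots, distinct patients, and distinct
#' treatment regimens observed.
#'
#' @param snapshots snapshot data.frame.
#' @return data.frame with `cohort`, `n_snapshots`, `n_patients`,
#'   `n_treatments`.
#' @export
cohort_summary <- function(snapshots) {
  sp <- split(snapshots, snapshots$cohort)
  out <- data.frame(
    cohort = names(sp),
    n_snapshots = vapply(sp, nrow, integer(1)),
    n_patients = vapply(sp, function(d) length(unique(d$patient_id)),
                        integer(1)),
    n_treatments = vapply(sp, function(d) length(unique(d$regimen)),
                          integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
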