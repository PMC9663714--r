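#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the Mersenne-Twister generator, runs
#' `expr`, and restores the previous state so library code never perturbs the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Deterministic per-stage substream derivation from one pipeline seed.
# Stage indices are fixed so stages can be rerun independently.
derive_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, cohort = 2L, rank = 3L, validate = 4L)
  idx <- stages[[stage]]
  as.integer((as.numeric(seed) * 7919 + idx * 104729) %% 2147483647)
}

#' Canonical string form of a treatment regimen
#'
#' A regimen is an unordered set of drug-class names; its canonical form is
#' the sorted `+`-joined string, so set equality is string equality.
#'
#' @param classes character vector of drug-class identifiers.
#' @return length-1 character string, or `NA_character_` for an empty set.
#' @export
#' @examples
#' regimen_string(c("sulfonylurea", "metformin"))
regimen_string <- function(classes) {
  classes <- unique(classes[!is.na(classes) & nzchar(classes)])
  if (length(classes) == 0L) return(NA_character_)
  paste(sort(classes), collapse = "+")
}

#' Split a canonical regimen string back into its classes
#' @param regimen canonical regimen string.
#' @return character vector of class names.
#' @export
regimen_classes <- function(regimen) {
  if (is.na(regimen)) return(character(0))
  strsplit(regimen, "+", fixed = TRUE)[[1]]
}

# Charlson comorbidity categories (unweighted index: each counts 1).
CHARLSON_CATEGORIES <- c(
  "myocardial_infarction", "congestive_heart_failure",
  "peripheral_vascular_disease", "cerebrovascular_disease", "dementia",
  "chronic_pulmonary_disease", "rheumatic_disease", "peptic_ulcer_disease",
  "mild_liver_disease", "diabetes_with_complication", "hemiplegia",
  "renal_disease", "malignancy", "moderate_severe_liver_disease",
  "metastatic_solid_tumor", "aids_hiv"
)

# Condition categories that trigger patient-level exclusion.
EXCLUSION_CATEGORIES <- c(
  "type1_diabetes", "gestational_diabetes", "diabetic_ketoacidosis",
  "cystic_fibrosis", "solid_organ_transplant"
)
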