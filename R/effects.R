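# Confounder-adjusted average treatment effects on HbA1c change.
#
# Every unordered pair of eligible regimens within a clinical cohort forms
# one case-comparator observational study: a propensity model is fit on
# the snapshots of the two regimens, the ATE is the Hajek (normalized)
# IPTW difference of weighted mean delta-HbA1c, and uncertainty comes from
# a stratified bootstrap over snapshots.

#' Hajek IPTW average treatment effect
#'
#' Weighted mean outcome difference between arms:
#' `sum(w*y)[case]/sum(w)[case] - sum(w*y)[comp]/sum(w)[comp]`.
#' Negative values mean the case regimen lowers HbA1c more.
#'
#' @param y outcome vector (change in HbA1c, percentage points).
#' @param t 0/1 arm labels (1 = case).
#' @param w positive weights.
#' @return the ATE (scalar).
#' @export
iptw_ate <- function(y, t, w) {
  stopifnot(length(y) == length(t), length(t) == length(w))
  t <- as.integer(t)
  i1 <- t == 1L; i0 <- t == 0L
  if (!any(i1) || !any(i0))
    stop("both arms must be non-empty", call. = FALSE)
  sum(w[i1] * y[i1]) / sum(w[i1]) - sum(w[i0] * y[i0]) / sum(w[i0])
}

#' Unadjusted difference in arm means
#' @inheritParams iptw_ate
#' @return the naive ATE (scalar).
#' @export
naive_ate <- function(y, t) {
  t <- as.integer(t)
  mean(y[t == 1L]) - mean(y[t == 0L])
}

#' Bootstrap standard error and CI for one case-comparator study
#'
#' Resamples snapshots with replacement within each arm (so both arms
#' always survive) `B` times. In the default `"weights"` refit mode each
#' replicate reuses the fitted propensity model's scores on the resampled
#' rows and recomputes the Hajek weights and ATE; `"full"` retrains the
#' propensity model per replicate. The point estimate comes from the full
#' data; `se` is the SD of replicates and `ci95` their 2.5/97.5
#' percentiles.
#'
#' @param y outcomes, `t` arm labels, `X` confounder matrix (rows aligned).
#' @param t 0/1 arm labels.
#' @param X confounder matrix.
#' @param config a [bcaus_config()].
#' @param B number of bootstrap replicates (must be >= 1).
#' @param seed integer seed.
#' @param refit `"weights"` (default) or `"full"`.
#' @param fit optional pre-computed `bcaus_fit` on (`X`, `t`).
#' @return object of class `pairwise_effect`: list with `ate`, `se`,
#'   `ci95`, `n_case`, `n_comp`, `all_balanced`, `fit`.
#' @export
bootstrap_effect <- function(y, t, X, config = bcaus_config(), B = 200L,
                             seed = 1L, refit = c("weights", "full"),
                             fit = NULL) {
  refit <- match.arg(refit)
  if (B < 1L) stop("B must be a positive integer", call. = FALSE)
  t <- as.integer(t)
  if (is.null(fit)) fit <- fit_bcaus(X, t, config)
  ate <- iptw_ate(y, t, fit$weights)
  i1 <- which(t == 1L); i0 <- which(t == 0L)
  reps <- with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- c(sample(i1, length(i1), replace = TRUE),
             sample(i0, length(i0), replace = TRUE))
    tb <- t[idx]
    if (refit == "full") {
      cfg_b <- config
      cfg_b$seed <- config$seed + b
      fb <- fit_bcaus(X[idx, , drop = FALSE], tb, cfg_b)
      wb <- fb$weights
    } else {
      wb <- compute_weights(fit, e = fit$e[idx], t = tb)
    }
    iptw_ate(y[idx], tb, wb)
  }, numeric(1)))
  structure(list(ate = ate, se = stats::sd(reps),
                 ci95 = unname(stats::quantile(reps, c(0.025, 0.975))),
                 n_case = length(i1), n_comp = length(i0),
                 all_balanced = fit$all_balanced, fit = fit,
                 replicates = reps),
            class = "pairwise_effect")
}

#' Run every pairwise case-comparator study within a cohort
#'
#' For each unordered pair of eligible regimens, restricts to snapshots on
#' exactly one of the two, fits the propensity model, and estimates the
#' bootstrap ATE. The first regimen of the pair (earlier in sort order) is
#' the case arm. Studies that cannot be fit are recorded with a reason
#' instead of failing the run.
#'
#' @param snapshots snapshot data.frame for one cohort.
#' @param X confounder matrix aligned with `snapshots` rows.
#' @param eligible_regimens character vector of regimens to compare (e.g.
#'   those with cohort count > 35); defaults to all observed.
#' @param config a [bcaus_config()].
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @param refit bootstrap refit mode, see [bootstrap_effect()].
#' @return data.frame with one row per completed study (`cohort`, `case`,
#'   `comparator`, `ate`, `se`, `lo`, `hi`, `n_case`, `n_comp`,
#'   `all_balanced`) and a `failures` attribute (data.frame of skipped
#'   pairs with reasons).
#' @export
run_all_pairs <- function(snapshots, X, eligible_regimens = NULL,
                          config = bcaus_config(), B = 200L, seed = 1L,
                          refit = "weights") {
  regs <- sort(eligible_regimens %||% unique(snapshots$regimen))
  cohort <- if (nrow(snapshots)) snapshots$cohort[1] else NA_character_
  if (length(regs) < 2L) {
    warning("fewer than 2 eligible regimens; no studies to run",
            call. = FALSE)
    return(structure(data.frame(), failures = data.frame()))
  }
  pairs <- utils::combn(regs, 2L)
  rows <- list(); fails <- list()
  for (k in seq_len(ncol(pairs))) {
    case <- pairs[1, k]; comp <- pairs[2, k]
    sel <- snapshots$regimen %in% c(case, comp)
    tt <- as.integer(snapshots$regimen[sel] == case)
    res <- tryCatch(
      bootstrap_effect(snapshots$delta_hba1c[sel], tt,
                       X[sel, , drop = FALSE], config, B = B,
                       seed = seed + k, refit = refit),
      glycorank_small_arm = function(e) e, error = function(e) e)
    if (inherits(res, "condition")) {
      fails[[length(fails) + 1L]] <- data.frame(
        cohort = cohort, case = case, comparator = comp,
        reason = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cohort = cohort, case = case, comparator = comp, ate = res$ate,
      se = res$se, lo = res$ci95[1], hi = res$ci95[2],
      n_case = res$n_case, n_comp = res$n_comp,
      all_balanced = res$all_balanced, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(out) <- NULL
  structure(out,
            failures = if (length(fails)) do.call(rbind, fails)
                       else data.frame())
}
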