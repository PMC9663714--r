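# Ranking validation: do top-ranked regimens causally outperform others?
#
# Snapshots are split by concordance (prescribed regimen equals one of the
# top-3 ranked regimens for its cohort), group means are compared by a
# Welch two-sample t-test, and when the difference is significant a
# confounder-adjusted case-comparator study is run with concordance as the
# binary "treatment". A tiered sensitivity analysis (ranks 1-3 / 4-10 /
# 11+) probes internal consistency, and rank-trajectory descriptives
# summarize switching behavior across a patient's consecutive snapshots.

#' Split snapshots into concordant and non-concordant groups
#'
#' A snapshot is concordant when its regimen equals (set equality, via the
#' canonical string) one of the top `top_k` regimens of the ranking.
#' Regimens absent from the ranking table (e.g. arms below the node-size
#' cutoff) are non-concordant.
#'
#' @param snapshots snapshot data.frame.
#' @param ranking a [sucra_ranks()] table.
#' @param top_k number of top-ranked regimens counting as concordant.
#' @return logical vector, TRUE = concordant, aligned with `snapshots`.
#' @export
concordance_split <- function(snapshots, ranking, top_k = 3L) {
  if (is.null(ranking) || nrow(ranking) == 0L)
    stop("ranking table is empty", call. = FALSE)
  top <- ranking$regimen[ranking$rank <= top_k]
  snapshots$regimen %in% top
}

#' Evaluate the concordance effect for one cohort
#'
#' Welch two-sample t-test of delta-HbA1c between concordant and
#' non-concordant snapshots; if `p < alpha`, a confounder-adjusted
#' case-comparator study (concordance as treatment) is run and the IPTW
#' ATE with bootstrap CI reported.
#'
#' @param snapshots snapshot data.frame for one cohort and one dataset
#'   (train or test).
#' @param X confounder matrix aligned with `snapshots`.
#' @param ranking a [sucra_ranks()] table.
#' @param dataset label ("train"/"test") carried into the result.
#' @param config a [bcaus_config()] for the adjusted study.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @param alpha significance gate for the adjusted study.
#' @param top_k concordance depth.
#' @return one-row data.frame: `cohort`, `dataset`, `n_concordant`,
#'   `n_nonconcordant`, `mean_concordant`, `mean_nonconcordant`,
#'   `t_statistic`, `p_value`, `significant`, `adjusted_ate`, `ci_lo`,
#'   `ci_hi` (adjusted fields `NA` unless significant), `reason`.
#' @export
evaluate_concordance <- function(snapshots, X, ranking, dataset = "train",
                                 config = bcaus_config(), B = 200L,
                                 seed = 1L, alpha = 0.05, top_k = 3L) {
  conc <- concordance_split(snapshots, ranking, top_k)
  cohort <- if (nrow(snapshots)) snapshots$cohort[1] else NA_character_
  base <- data.frame(
    cohort = cohort, dataset = dataset,
    n_concordant = sum(conc), n_nonconcordant = sum(!conc),
    mean_concordant = NA_real_, mean_nonconcordant = NA_real_,
    t_statistic = NA_real_, p_value = NA_real_, significant = FALSE,
    adjusted_ate = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
    reason = NA_character_, stringsAsFactors = FALSE)
  if (sum(conc) < 2L || sum(!conc) < 2L) {
    base$reason <- "a concordance group has fewer than 2 snapshots"
    return(base)
  }
  y <- snapshots$delta_hba1c
  base$mean_concordant <- mean(y[conc])
  base$mean_nonconcordant <- mean(y[!conc])
  tt <- stats::t.test(y[conc], y[!conc], var.equal = FALSE)
  base$t_statistic <- unname(tt$statistic)
  base$p_value <- tt$p.value
  base$significant <- tt$p.value < alpha
  if (base$significant) {
    eff <- bootstrap_effect(y, as.integer(conc), X, config, B = B,
                            seed = seed)
    base$adjusted_ate <- eff$ate
    base$ci_lo <- eff$ci95[1]
    base$ci_hi <- eff$ci95[2]
  }
  base
}

#' Tiered sensitivity analysis of the ranking
#'
#' Splits snapshots into "top" (regimen ranked 1-3), "middle" (4-10) and
#' "bottom" (11+) concordance tiers and reports confounder-adjusted ATEs
#' for top-vs-bottom and middle-vs-bottom. With fewer than 11 ranked
#' regimens the bottom tier may be empty and a comparison is skipped with
#' a reason. Snapshots on unranked regimens fall in the bottom tier.
#'
#' @inheritParams evaluate_concordance
#' @return data.frame with one row per comparison: `comparison`, `ate`,
#'   `se`, `ci_lo`, `ci_hi`, `n_case`, `n_comp`, `skipped`, `reason`.
#' @export
sensitivity_tiers <- function(snapshots, X, ranking,
                              config = bcaus_config(), B = 200L,
                              seed = 1L) {
  if (nrow(ranking) < 11L)
    warning("ranking has ", nrow(ranking),
            " entries; tiers truncate", call. = FALSE)
  tier_of <- function(reg) {
    r <- ranking$rank[match(reg, ranking$regimen)]
    ifelse(is.na(r) | r >= 11, "bottom",
           ifelse(r <= 3, "top", "middle"))
  }
  tier <- tier_of(snapshots$regimen)
  one <- function(case_tier) {
    sel <- tier %in% c(case_tier, "bottom")
    tt <- as.integer(tier[sel] == case_tier)
    out <- data.frame(comparison = paste0(case_tier, "_vs_bottom"),
                      ate = NA_real_, se = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, n_case = sum(tt == 1L),
                      n_comp = sum(tt == 0L), skipped = TRUE,
                      reason = NA_character_, stringsAsFactors = FALSE)
    if (sum(tt == 1L) < 2L || sum(tt == 0L) < 2L) {
      out$reason <- "a tier has fewer than 2 snapshots"
      return(out)
    }
    eff <- tryCatch(
      bootstrap_effect(snapshots$delta_hba1c[sel], tt,
                       X[sel, , drop = FALSE], config, B = B, seed = seed),
      error = function(e) e)
    if (inherits(eff, "error")) {
      out$reason <- conditionMessage(eff)
      return(out)
    }
    out$ate <- eff$ate; out$se <- eff$se
    out$ci_lo <- eff$ci95[1]; out$ci_hi <- eff$ci95[2]
    out$skipped <- FALSE
    out
  }
  rbind(one("top"), one("middle"))
}

#' Rank-trajectory descriptives across consecutive snapshots
#'
#' Assigns each snapshot its regimen's rank in the cohort ranking
#' (unranked regimens get `NA`) and summarizes, over consecutive
#' same-patient snapshot pairs: the switching incidence, and among
#' switches with both ranks known, the fractions improving/worsening rank
#' and the mean rank movement (positive = improvement, i.e. toward rank
#' 1).
#'
#' @param snapshots snapshot data.frame (one cohort), any order; sorted
#'   internally by patient and index day.
#' @param ranking a [sucra_ranks()] table for the cohort.
#' @return list: `mean_rank`, `n_pairs`, `switch_incidence`,
#'   `frac_improved`, `frac_worsened`, `mean_rank_change`,
#'   `mean_improvement`, `mean_worsening`.
#' @export
rank_trajectories <- function(snapshots, ranking) {
  sn <- snapshots[order(snapshots$patient_id, snapshots$index_day), ,
                  drop = FALSE]
  rk <- ranking$rank[match(sn$regimen, ranking$regimen)]
  n <- nrow(sn)
  same <- if (n > 1) sn$patient_id[-n] == sn$patient_id[-1] else logical(0)
  prev <- which(same)
  switched <- sn$regimen[prev] != sn$regimen[prev + 1L]
  move <- rk[prev] - rk[prev + 1L]  # positive = moved toward rank 1
  move <- move[switched & !is.na(move)]
  list(mean_rank = mean(rk, na.rm = TRUE),
       n_pairs = length(prev),
       switch_incidence = if (length(prev)) mean(switched) else NA_real_,
       frac_improved = if (length(move)) mean(move > 0) else NA_real_,
       frac_worsened = if (length(move)) mean(move < 0) else NA_real_,
       mean_rank_change = if (length(move)) mean(move) else NA_real_,
       mean_improvement = if (any(move > 0)) mean(move[move > 0])
                          else NA_real_,
       mean_worsening = if (any(move < 0)) mean(abs(move[move < 0]))
                        else NA_real_)
}
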