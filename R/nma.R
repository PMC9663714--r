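# Bayesian random-effects network meta-analysis and SUCRA ranking.
#
# Per cohort, pairwise IPTW ATEs form a network: nodes are regimens with
# more than 35 snapshots, edges are studies in which all confounders were
# balanced after weighting. A random-effects model is fit by MCMC:
#
#   ate_e ~ Normal(theta_e, se_e^2)
#   theta_e ~ Normal(d_case(e) - d_comp(e), tau^2)
#   d_k ~ Normal(0, 10^2),  d_baseline = 0,  tau ~ HalfNormal(5)
#
# where d_k is the network-synthesized change in HbA1c of regimen k
# relative to the baseline (metformin monotherapy). SUCRA scores are
# normalized mean ranks over posterior-predictive draws.

#' Build the per-cohort evidence network
#'
#' Nodes are regimens with cohort snapshot count strictly greater than
#' `min_arm`; edges are balanced studies whose endpoints are both
#' retained. If the resulting graph is disconnected, only the component
#' containing the baseline is analyzed; the remainder is reported under
#' `excluded`.
#'
#' @param effects pairwise-effect table from [run_all_pairs()] (one
#'   cohort).
#' @param counts named integer vector: snapshots per regimen in the
#'   cohort.
#' @param baseline baseline regimen; if absent from the retained nodes,
#'   the largest-arm regimen is substituted and the substitution recorded.
#' @param min_arm nodes require count strictly greater than this.
#' @return object of class `evidence_network`: `nodes` (data.frame
#'   `regimen`, `n`), `edges`, `baseline`, `baseline_substituted`,
#'   `excluded` (list of dropped nodes/edges with reasons).
#' @export
build_network <- function(effects, counts, baseline = "metformin",
                          min_arm = 35L) {
  cohort <- if (nrow(effects)) effects$cohort[1] else NA_character_
  excluded <- list()
  keep_reg <- names(counts)[counts > min_arm]
  excluded$small_nodes <- setdiff(names(counts), keep_reg)

  ed <- effects
  if (nrow(ed)) {
    drop_unbal <- !ed$all_balanced
    excluded$unbalanced_edges <- ed[drop_unbal, c("case", "comparator"),
                                    drop = FALSE]
    ed <- ed[!drop_unbal, , drop = FALSE]
    keep_e <- ed$case %in% keep_reg & ed$comparator %in% keep_reg
    ed <- ed[keep_e, , drop = FALSE]
    ed <- ed[ed$case != ed$comparator, , drop = FALSE]
  }
  nodes <- data.frame(regimen = keep_reg,
                      n = as.integer(counts[keep_reg]),
                      stringsAsFactors = FALSE)

  baseline_substituted <- FALSE
  if (!baseline %in% nodes$regimen && nrow(nodes)) {
    baseline <- nodes$regimen[which.max(nodes$n)]
    baseline_substituted <- TRUE
  }

  if (nrow(ed)) {
    g <- igraph::graph_from_data_frame(
      ed[c("case", "comparator")], directed = FALSE,
      vertices = nodes$regimen)
    comp <- igraph::components(g)
    base_comp <- comp$membership[[baseline]]
    in_comp <- names(comp$membership)[comp$membership == base_comp]
    excluded$disconnected_nodes <- setdiff(nodes$regimen, in_comp)
    nodes <- nodes[nodes$regimen %in% in_comp, , drop = FALSE]
    ed <- ed[ed$case %in% in_comp & ed$comparator %in% in_comp, ,
             drop = FALSE]
  } else {
    excluded$disconnected_nodes <-
      setdiff(nodes$regimen, baseline)
    nodes <- nodes[nodes$regimen == baseline, , drop = FALSE]
  }
  rownames(nodes) <- rownames(ed) <- NULL
  structure(list(cohort = cohort, nodes = nodes, edges = ed,
                 baseline = baseline,
                 baseline_substituted = baseline_substituted,
                 excluded = excluded),
            class = "evidence_network")
}

#' @export
print.evidence_network <- function(x, ...) {
  cat("<evidence_network>", x$cohort %||% "", "-", nrow(x$nodes),
      "regimens,", nrow(x$edges), "edges, baseline", x$baseline,
      if (x$baseline_substituted) "(substituted)" else "", "\n")
  invisible(x)
}

#' Fit the Bayesian random-effects NMA by MCMC
#'
#' @param network an [build_network()] result with >= 2 nodes and >= 1
#'   edge.
#' @param n_chains,n_warmup,n_iter MCMC settings (per chain).
#' @param seed integer seed; chains get derived sub-seeds, so results are
#'   deterministic given `seed` and the sampler settings.
#' @param d_prior_sd prior SD of the basic parameters (percentage points).
#' @param tau_prior_sd scale of the half-normal heterogeneity prior.
#' @param fixed_tau optional fixed heterogeneity SD (e.g. 0 for a
#'   common-effect model); overrides the prior.
#' @return object of class `nma_posterior`: `d` (draws matrix, one column
#'   per regimen, baseline identically 0), `tau` (draws), `rhat` (named,
#'   split-chain), `converged` (all rhat <= 1.05), `regimens`, `baseline`.
#' @export
fit_nma <- function(network, n_chains = 4L, n_warmup = 2000L,
                    n_iter = 2500L, seed = 1L, d_prior_sd = 10,
                    tau_prior_sd = 5, fixed_tau = NULL) {
  nodes <- network$nodes$regimen
  K <- length(nodes)
  if (K < 2L || nrow(network$edges) == 0L)
    stop("network needs >= 2 connected regimens and >= 1 edge",
         call. = FALSE)
  ## baseline first so d[1] == 0
  nodes <- c(network$baseline, setdiff(nodes, network$baseline))
  ed <- network$edges
  a <- match(ed$case, nodes); b <- match(ed$comparator, nodes)

  fixed <- !is.null(fixed_tau)
  ## the per-edge random effect theta_e ~ Normal(d_a - d_b, tau^2) is
  ## marginalized analytically (y_e ~ Normal(d_a - d_b, se_e^2 + tau^2)),
  ## which is exactly equivalent and avoids the tau -> 0 funnel
  model_str <- paste0(
    "model {\n",
    "  for (s in 1:S) {\n",
    "    prec[s] <- 1 / (sigma2[s] + tau * tau)\n",
    "    y[s] ~ dnorm(d[a[s]] - d[b[s]], prec[s])\n",
    "  }\n",
    "  d[1] <- 0\n",
    "  for (k in 2:K) { d[k] ~ dnorm(0, ", 1 / d_prior_sd^2, ") }\n",
    if (fixed) "" else paste0(
      "  tau ~ dnorm(0, ", 1 / tau_prior_sd^2, ") T(0,)\n"),
    "}\n")
  data <- list(S = nrow(ed), K = K, a = a, b = b, y = ed$ate,
               sigma2 = ed$se^2)
  if (fixed) data$tau <- fixed_tau

  inits <- lapply(seq_len(n_chains), function(ch) {
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = as.integer(seed) * 100L + ch)
  })
  jm <- rjags::jags.model(textConnection(model_str), data = data,
                          inits = inits, n.chains = n_chains, quiet = TRUE)
  stats::update(jm, n_warmup, progress.bar = "none")
  vars <- if (fixed) "d" else c("d", "tau")
  samp <- rjags::coda.samples(jm, vars, n.iter = n_iter,
                              progress.bar = "none")

  mat <- do.call(rbind, lapply(samp, as.matrix))
  d_cols <- grep("^d\\[", colnames(mat))
  d <- mat[, d_cols, drop = FALSE]
  ord <- order(as.integer(gsub("d\\[|\\]", "", colnames(mat)[d_cols])))
  d <- d[, ord, drop = FALSE]
  colnames(d) <- nodes
  tau <- if (fixed) rep(fixed_tau, nrow(d)) else mat[, "tau"]

  ## split-chain potential scale reduction on the free parameters
  free <- setdiff(colnames(as.matrix(samp[[1]])), "d[1]")
  rhat <- vapply(free, function(v) {
    ch <- lapply(samp, function(s) as.matrix(s)[, v])
    .split_rhat(ch)
  }, numeric(1))
  names(rhat)[grepl("^d\\[", names(rhat))] <-
    nodes[as.integer(gsub("d\\[|\\]", "",
                          grep("^d\\[", names(rhat), value = TRUE)))]

  structure(list(d = d, tau = as.numeric(tau), rhat = rhat,
                 converged = all(is.finite(rhat) & rhat <= 1.05),
                 regimens = nodes, baseline = network$baseline,
                 n_chains = n_chains, n_iter = n_iter),
            class = "nma_posterior")
}

# Split-chain potential scale reduction factor (each chain halved).
.split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    m <- length(x) %/% 2L
    list(x[seq_len(m)], x[m + seq_len(m)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.nma_posterior <- function(x, ...) {
  cat("<nma_posterior>", length(x$regimens), "regimens vs", x$baseline,
      "| tau median", round(stats::median(x$tau), 3),
      "|", if (x$converged) "converged" else
        paste0("NOT converged (max rhat ", round(max(x$rhat), 3), ")"),
      "\n")
  invisible(x)
}

#' SUCRA treatment ranking from an NMA posterior
#'
#' For each draw, the predictive ATE vs baseline of every regimen is
#' sampled (`d_k` plus, by default, a new-study heterogeneity draw
#' `Normal(0, tau^2)`; the baseline's ATE is 0) and regimens are ranked in
#' ascending order of ATE (most negative — largest HbA1c reduction — is
#' rank 1, ties averaged). The SUCRA score is the normalized mean rank,
#' `(T - mean_rank)/(T - 1)`, so 1 means always best and 0 always worst.
#'
#' @param posterior an `nma_posterior`.
#' @param network the matching `evidence_network` (for per-regimen `n`);
#'   optional.
#' @param n_draws number of ranking draws (capped at the posterior size).
#' @param seed integer seed for the predictive draws.
#' @param include_tau include the heterogeneity draw in the predictive
#'   ATE; `FALSE` ranks on the posterior `d_k` draws directly.
#' @param force rank even if the posterior is flagged unconverged.
#' @return data.frame sorted by descending SUCRA: `rank`, `regimen`,
#'   `sucra`, `d_mean`, `d_lo`, `d_hi`, `n`.
#' @export
sucra_ranks <- function(posterior, network = NULL, n_draws = 4000L,
                        seed = 1L, include_tau = TRUE, force = FALSE) {
  if (!posterior$converged && !force)
    stop("posterior flagged as unconverged; pass force = TRUE to rank ",
         "anyway", call. = FALSE)
  Tn <- length(posterior$regimens)
  if (Tn < 2L) stop("ranking needs >= 2 treatments", call. = FALSE)
  n_avail <- nrow(posterior$d)
  use <- with_seed(seed, {
    idx <- if (n_draws >= n_avail) seq_len(n_avail)
           else sample.int(n_avail, n_draws)
    ate <- posterior$d[idx, , drop = FALSE]
    if (include_tau) {
      noise <- matrix(stats::rnorm(length(idx) * Tn, 0,
                                   rep(posterior$tau[idx], Tn)),
                      ncol = Tn)
      noise[, 1] <- 0  # baseline ATE is identically 0
      ate <- ate + noise
    }
    ate
  })
  ranks <- t(apply(use, 1, rank, ties.method = "average"))
  mean_rank <- colMeans(ranks)
  sucra <- (Tn - mean_rank) / (Tn - 1)
  qs <- apply(posterior$d, 2, stats::quantile, c(0.025, 0.975))
  out <- data.frame(regimen = posterior$regimens, sucra = unname(sucra),
                    d_mean = unname(colMeans(posterior$d)),
                    d_lo = unname(qs[1, ]), d_hi = unname(qs[2, ]),
                    stringsAsFactors = FALSE)
  out$n <- if (!is.null(network))
    network$nodes$n[match(out$regimen, network$nodes$regimen)]
  else NA_integer_
  out <- out[order(-out$sucra), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[c("rank", "regimen", "sucra", "d_mean", "d_lo", "d_hi", "n")]
}
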