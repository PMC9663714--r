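edge <- function(case, comp, ate, se, balanced = TRUE, cohort = "A") {
  data.frame(cohort = cohort, case = case, comparator = comp, ate = ate,
             se = se, lo = ate - 2 * se, hi = ate + 2 * se, n_case = 100,
             n_comp = 100, all_balanced = balanced, stringsAsFactors = FALSE)
}

test_that("network construction enforces the >35 node rule and trimming", {
  eff <- rbind(edge("T1", "metformin", -0.5, 0.1),
               edge("T2", "metformin", -0.8, 0.1),
               edge("T2", "T1", -0.3, 0.12, balanced = FALSE))
  counts <- c(metformin = 100, T1 = 36, T2 = 35)
  net <- build_network(eff, counts)
  expect_setequal(net$nodes$regimen, c("metformin", "T1"))  # T2 at 35 is out
  expect_equal(nrow(net$edges), 1L)
  counts2 <- c(metformin = 100, T1 = 36, T2 = 36)
  net2 <- build_network(eff, counts2)
  expect_setequal(net2$nodes$regimen, c("metformin", "T1", "T2"))
  ## the unbalanced T2-T1 edge is trimmed but T2 stays estimable via the
  ## two-edge path through metformin
  expect_equal(nrow(net2$edges), 2L)
  expect_false(any(!net2$edges$all_balanced))
  ## all edges unbalanced -> empty network
  eff3 <- eff; eff3$all_balanced <- FALSE
  net3 <- build_network(eff3, counts2)
  expect_equal(nrow(net3$edges), 0L)
})

test_that("disconnected components outside the baseline are excluded", {
  eff <- rbind(edge("T1", "metformin", -0.5, 0.1),
               edge("T3", "T2", -0.2, 0.1))
  counts <- c(metformin = 100, T1 = 50, T2 = 50, T3 = 50)
  net <- build_network(eff, counts)
  expect_setequal(net$nodes$regimen, c("metformin", "T1"))
  expect_setequal(net$excluded$disconnected_nodes, c("T2", "T3"))
  ## absent baseline falls back to the largest arm, recorded
  net2 <- build_network(edge("T3", "T2", -0.2, 0.1),
                        c(T2 = 80, T3 = 50), baseline = "metformin")
  expect_true(net2$baseline_substituted)
  expect_equal(net2$baseline, "T2")
})

test_that("single-edge posterior matches the conjugate-normal closed form", {
  net <- build_network(edge("T", "metformin", -0.5, 0.1),
                       c(metformin = 100, T = 100))
  post <- fit_nma(net, seed = 31, fixed_tau = 0)
  ## closed form: prior N(0, 10^2), likelihood N(d_T; -0.5, 0.1^2)
  v <- 1 / (1 / 100 + 1 / 0.01)
  m <- v * (-0.5 / 0.01)
  nd <- length(post$d[, "T"])
  mcse_mean <- sqrt(v / nd) * sqrt(post$n_chains)  # conservative
  expect_lt(abs(mean(post$d[, "T"]) - m), 3 * max(mcse_mean, 5e-3))
  expect_equal(stats::sd(post$d[, "T"]), sqrt(v), tolerance = 0.1)
  expect_true(all(post$d[, "metformin"] == 0))
})

test_that("consistent triangle recovers the basic parameters", {
  d_true <- c(T1 = -0.5, T2 = -0.9)
  eff <- rbind(edge("T1", "metformin", d_true["T1"], 0.08),
               edge("T2", "metformin", d_true["T2"], 0.08),
               edge("T2", "T1", d_true["T2"] - d_true["T1"], 0.1))
  net <- build_network(eff, c(metformin = 100, T1 = 100, T2 = 100))
  post <- fit_nma(net, seed = 7)
  expect_true(post$converged)
  for (k in names(d_true)) {
    expect_lt(abs(mean(post$d[, k]) - d_true[[k]]),
              2 * stats::sd(post$d[, k]))
  }
  expect_true(all(post$tau >= 0))
})

test_that("indirect-only estimates agree with direct ones when consistent", {
  d_true <- c(T1 = -0.4, T2 = -1.0)
  eff_full <- rbind(edge("T1", "metformin", d_true["T1"], 0.08),
                    edge("T2", "metformin", d_true["T2"], 0.08),
                    edge("T2", "T1", -0.6, 0.1))
  counts <- c(metformin = 100, T1 = 100, T2 = 100)
  direct <- fit_nma(build_network(eff_full, counts), seed = 11)
  indirect <- fit_nma(build_network(eff_full[-2, ], counts), seed = 11)
  pooled <- sqrt(stats::sd(direct$d[, "T2"])^2 +
                 stats::sd(indirect$d[, "T2"])^2)
  expect_lt(abs(mean(direct$d[, "T2"]) - mean(indirect$d[, "T2"])),
            2 * pooled)
})

test_that("relabeling the baseline leaves pairwise contrasts invariant", {
  eff <- rbind(edge("T1", "metformin", -0.5, 0.08),
               edge("T2", "metformin", -0.9, 0.08),
               edge("T2", "T1", -0.4, 0.1))
  counts <- c(metformin = 100, T1 = 100, T2 = 100)
  p_m <- fit_nma(build_network(eff, counts, baseline = "metformin"),
                 seed = 3)
  p_1 <- fit_nma(build_network(eff, counts, baseline = "T1"), seed = 3)
  c_m <- mean(p_m$d[, "T2"]) - mean(p_m$d[, "T1"])
  c_1 <- mean(p_1$d[, "T2"]) - mean(p_1$d[, "T1"])
  se <- sqrt(stats::sd(p_m$d[, "T2"] - p_m$d[, "T1"])^2 / nrow(p_m$d)) +
    0.02
  expect_lt(abs(c_m - c_1), 4 * se)
})

test_that("SUCRA endpoints, symmetry and ordering behave as defined", {
  set.seed(1)
  ## T_best more negative than everything in every draw -> sucra 1;
  ## T_worst always last -> sucra 0
  d <- cbind(metformin = rep(0, 500),
             T_best = rnorm(500, -3, 0.05), T_mid = rnorm(500, -1, 0.05),
             T_worst = rnorm(500, 2, 0.05))
  post <- make_posterior(d)
  rk <- sucra_ranks(post, n_draws = 500, seed = 2, include_tau = FALSE)
  expect_equal(rk$sucra[rk$regimen == "T_best"], 1)
  expect_equal(rk$sucra[rk$regimen == "T_worst"], 0)
  expect_equal(rk$regimen, c("T_best", "T_mid", "metformin", "T_worst"))
  expect_true(all(diff(rk$sucra) <= 0))
  ## mean ranks sum to T(T+1)/2, so sucra sums to T/2 exactly
  expect_equal(sum(rk$sucra), 4 / 2, tolerance = 1e-12)
  ## exchangeable treatments: all sucra near 0.5
  d2 <- matrix(rnorm(4000 * 3, -1, 0.3), ncol = 3,
               dimnames = list(NULL, c("A", "B", "C")))
  rk2 <- sucra_ranks(make_posterior(d2), n_draws = 4000, seed = 5,
                     include_tau = FALSE)
  expect_true(all(abs(rk2$sucra - 0.5) < 0.05))
  ## contract errors
  expect_error(sucra_ranks(make_posterior(d[, 1, drop = FALSE])), ">= 2")
})

test_that("unconverged posteriors are refused unless forced", {
  d <- cbind(metformin = rep(0, 100), T1 = rnorm(100))
  post <- make_posterior(d)
  post$converged <- FALSE
  expect_error(sucra_ranks(post, seed = 1), "unconverged")
  expect_silent(rk <- sucra_ranks(post, seed = 1, force = TRUE))
  expect_equal(nrow(rk), 2L)
})
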