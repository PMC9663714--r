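# Balance-regularized neural propensity scoring (BCAUS).
#
# A single-hidden-layer network maps standardized confounders to a
# propensity score e = P(case arm | x). Training minimizes
#
#   L_TOTAL = L_BCE + nu * mu * L_BIAS
#
# where L_BCE is the mean binary cross-entropy of arm prediction, L_BIAS is
# the mean squared IPTW-weighted standardized mean difference across
# covariates, and mu = L_BCE / L_BIAS is recomputed (and detached) each
# epoch so the two terms contribute at comparable magnitude; nu alone sets
# the user-facing trade-off. The returned model is the epoch checkpoint
# with the most balanced covariates (ties broken by lower L_BCE), so
# balance is never selected to worsen relative to initialization.

#' Configuration for the balance-regularized propensity model
#'
#' @param hidden_width hidden-layer width.
#' @param nu nonnegative weight of the balance loss; 0 gives a plain
#'   cross-entropy propensity classifier.
#' @param learning_rate Adam step size.
#' @param max_epochs full-batch training epochs.
#' @param propensity_clip `(lo, hi)` clipping bounds applied to reported
#'   propensities before weighting, bounding IPTW variance.
#' @param balance_threshold absolute weighted-SMD threshold below which a
#'   covariate counts as balanced (standardized-difference units).
#' @param seed integer seed for weight initialization.
#' @return object of class `bcaus_config`.
#' @export
bcaus_config <- function(hidden_width = 32L, nu = 1, learning_rate = 0.01,
                         max_epochs = 200L, propensity_clip = c(0.01, 0.99),
                         balance_threshold = 0.1, seed = 1L) {
  stopifnot(hidden_width >= 1, nu >= 0, learning_rate > 0, max_epochs >= 1,
            balance_threshold > 0, length(propensity_clip) == 2,
            propensity_clip[1] > 0, propensity_clip[2] < 1,
            propensity_clip[1] < propensity_clip[2])
  structure(list(hidden_width = as.integer(hidden_width), nu = nu,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 propensity_clip = propensity_clip,
                 balance_threshold = balance_threshold,
                 seed = as.integer(seed)),
            class = "bcaus_config")
}

#' Weighted standardized mean differences between arms
#'
#' For each covariate, `|weighted mean(case) - weighted mean(comparator)| /
#' pooled unweighted SD`. Zero-variance covariates get SMD 0 and count as
#' balanced.
#'
#' @param X covariate matrix.
#' @param t 0/1 arm labels (1 = case).
#' @param w positive weights.
#' @param threshold balanced-flag threshold on |SMD|.
#' @return data.frame (`covariate`, `smd`, `balanced`) with an
#'   `all_balanced` logical attribute.
#' @export
check_balance <- function(X, t, w, threshold = 0.1) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(t), length(t) == length(w))
  t <- as.integer(t)
  i1 <- t == 1L; i0 <- t == 0L
  s <- sqrt((apply(X[i1, , drop = FALSE], 2, stats::var) +
             apply(X[i0, , drop = FALSE], 2, stats::var)) / 2)
  m1 <- colSums(X[i1, , drop = FALSE] * w[i1]) / sum(w[i1])
  m0 <- colSums(X[i0, , drop = FALSE] * w[i0]) / sum(w[i0])
  smd <- abs(m1 - m0) / s
  smd[!is.finite(smd) | s < 1e-12] <- 0
  out <- data.frame(covariate = colnames(X) %||% paste0("x", seq_along(smd)),
                    smd = unname(smd), balanced = unname(smd) < threshold,
                    stringsAsFactors = FALSE)
  attr(out, "all_balanced") <- all(out$balanced)
  out
}

# Forward pass of the propensity network on an already-standardized matrix.
.bcaus_forward <- function(par, Xs) {
  Z1 <- sweep(Xs %*% par$W1, 2, par$b1, "+")
  A1 <- pmax(Z1, 0)
  z <- as.vector(A1 %*% par$W2) + par$b2
  list(Z1 = Z1, A1 = A1, z = z, e = stats::plogis(z))
}

#' Fit the balance-regularized neural propensity model
#'
#' @param X confounder matrix (finite; standardized internally).
#' @param t 0/1 or logical arm labels (1/TRUE = case).
#' @param config a [bcaus_config()].
#' @return object of class `bcaus_fit`: network parameters at the selected
#'   checkpoint, standardization constants, clipped propensities `e`, IPTW
#'   `weights`, a per-epoch training `trace` (`l_bce`, `l_bias`, `mu`,
#'   `n_balanced`), the selected `checkpoint_epoch`, and `small_arms`
#'   (TRUE when either arm has fewer than 36 snapshots).
#' @export
fit_bcaus <- function(X, t, config = bcaus_config()) {
  X <- as.matrix(X)
  t <- as.integer(as.logical(t))
  if (!all(is.finite(X)))
    stop("non-finite covariates; impute before fitting", call. = FALSE)
  n1 <- sum(t == 1L); n0 <- sum(t == 0L)
  if (n1 < 2L || n0 < 2L)
    stop2_small_arm(n1, n0)
  n <- nrow(X)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")

  i1 <- t == 1L; i0 <- !i1
  s_pool <- sqrt((apply(Xs[i1, , drop = FALSE], 2, stats::var) +
                  apply(Xs[i0, , drop = FALSE], 2, stats::var)) / 2)
  active <- is.finite(s_pool) & s_pool > 1e-12
  J <- max(sum(active), 1L)

  p <- ncol(Xs); h <- config$hidden_width
  par <- with_seed(config$seed, list(
    W1 = matrix(stats::rnorm(p * h, 0, sqrt(2 / p)), p, h),
    b1 = rep(0, h),
    W2 = matrix(stats::rnorm(h, 0, sqrt(2 / h)), h, 1),
    b2 = 0))
  mom <- lapply(par, function(x) x * 0)
  vel <- lapply(par, function(x) x * 0)
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  clip <- config$propensity_clip
  thr <- config$balance_threshold

  eval_epoch <- function(par) {
    fw <- .bcaus_forward(par, Xs)
    e <- fw$e
    ec <- pmin(pmax(e, 1e-7), 1 - 1e-7)
    l_bce <- -mean(t * log(ec) + (1 - t) * log(1 - ec))
    ecl <- pmin(pmax(e, clip[1]), clip[2])
    w <- ifelse(i1, 1 / ecl, 1 / (1 - ecl))
    bal <- check_balance(Xs[, active, drop = FALSE], t, w, thr)
    list(fw = fw, e = e, l_bce = l_bce, w = w, bal = bal,
         n_balanced = sum(bal$balanced))
  }

  trace <- vector("list", config$max_epochs + 1L)
  ev <- eval_epoch(par)
  best <- list(par = par, n_balanced = ev$n_balanced, l_bce = ev$l_bce,
               epoch = 0L)
  trace[[1]] <- c(epoch = 0, l_bce = ev$l_bce, l_bias = NA, mu = NA,
                  n_balanced = ev$n_balanced)

  for (epoch in seq_len(config$max_epochs)) {
    fw <- ev$fw
    e <- fw$e
    ## balance loss on softly-bounded propensities (gradient masked where
    ## the bound binds)
    eb <- pmin(pmax(e, 0.005), 0.995)
    inb <- e > 0.005 & e < 0.995
    w1v <- 1 / eb; w0v <- 1 / (1 - eb)
    S1 <- sum(w1v[i1]); S0 <- sum(w0v[i0])
    m1 <- colSums(Xs[i1, , drop = FALSE] * w1v[i1]) / S1
    m0 <- colSums(Xs[i0, , drop = FALSE] * w0v[i0]) / S0
    D <- ((m1 - m0) / s_pool)
    D[!active] <- 0
    l_bias <- sum(D^2) / J
    mu <- if (l_bias > 1e-12) ev$l_bce / l_bias else 0

    ## dL_BIAS / de
    Ds <- D / s_pool
    Ds[!active] <- 0
    g_bias <- numeric(n)
    proj1 <- as.vector(sweep(Xs[i1, , drop = FALSE], 2, m1) %*% Ds)
    proj0 <- as.vector(sweep(Xs[i0, , drop = FALSE], 2, m0) %*% Ds)
    g_bias[i1] <- (2 / J) * proj1 / S1 * (-1 / eb[i1]^2)
    g_bias[i0] <- -(2 / J) * proj0 / S0 * (1 / (1 - eb[i0])^2)
    g_bias[!inb] <- 0

    ec <- pmin(pmax(e, 1e-7), 1 - 1e-7)
    delta <- (ec - t) / n + config$nu * mu * g_bias * e * (1 - e)

    gW2 <- crossprod(fw$A1, delta)
    gb2 <- sum(delta)
    dA1 <- delta %*% t(par$W2)
    dZ1 <- dA1 * (fw$Z1 > 0)
    gW1 <- crossprod(Xs, dZ1)
    gb1 <- colSums(dZ1)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)

    for (nm in names(par)) {
      mom[[nm]] <- b1a * mom[[nm]] + (1 - b1a) * grads[[nm]]
      vel[[nm]] <- b2a * vel[[nm]] + (1 - b2a) * grads[[nm]]^2
      mhat <- mom[[nm]] / (1 - b1a^epoch)
      vhat <- vel[[nm]] / (1 - b2a^epoch)
      par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }

    ev <- eval_epoch(par)
    trace[[epoch + 1L]] <- c(epoch = epoch, l_bce = ev$l_bce,
                             l_bias = l_bias, mu = mu,
                             n_balanced = ev$n_balanced)
    if (ev$n_balanced > best$n_balanced ||
        (ev$n_balanced == best$n_balanced && ev$l_bce < best$l_bce)) {
      best <- list(par = par, n_balanced = ev$n_balanced, l_bce = ev$l_bce,
                   epoch = epoch)
    }
  }

  ev <- eval_epoch(best$par)
  ecl <- pmin(pmax(ev$e, clip[1]), clip[2])
  w <- ifelse(i1, 1 / ecl, 1 / (1 - ecl))
  bal_full <- check_balance(X, t, w, thr)
  structure(list(
    par = best$par, center = center, scale = scale,
    covariates = colnames(X), t = t, e = ecl, e_raw = ev$e, weights = w,
    balance = bal_full, all_balanced = attr(bal_full, "all_balanced"),
    trace = as.data.frame(do.call(rbind, trace)),
    checkpoint_epoch = best$epoch, config = config,
    small_arms = min(n1, n0) < 36L), class = "bcaus_fit")
}

stop2_small_arm <- function(n1, n0) {
  cond <- structure(class = c("glycorank_small_arm", "error", "condition"),
                    list(message = sprintf(
                      "each arm needs >= 2 snapshots (case %d, comparator %d)",
                      n1, n0), call = NULL))
  stop(cond)
}

#' Predict clipped propensities for new snapshots
#' @param fit a `bcaus_fit`.
#' @param X confounder matrix with the columns the model was trained on.
#' @return numeric vector of propensities within the configured clip range.
#' @export
predict_propensity <- function(fit, X) {
  X <- as.matrix(X)[, fit$covariates, drop = FALSE]
  Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  e <- .bcaus_forward(fit$par, Xs)$e
  clip <- fit$config$propensity_clip
  pmin(pmax(e, clip[1]), clip[2])
}

#' Inverse-probability-of-treatment weights from a fitted propensity model
#'
#' `w = 1/e` for the case arm and `w = 1/(1-e)` for the comparator arm,
#' with `e` already clipped to the configured range.
#'
#' @param fit a `bcaus_fit`.
#' @param e optional propensity vector overriding the fit's.
#' @param t optional arm labels overriding the fit's.
#' @return positive finite weight vector.
#' @export
compute_weights <- function(fit, e = NULL, t = NULL) {
  e <- e %||% fit$e
  t <- as.integer(t %||% fit$t)
  clip <- fit$config$propensity_clip
  e <- pmin(pmax(e, clip[1]), clip[2])
  ifelse(t == 1L, 1 / e, 1 / (1 - e))
}

#' @export
print.bcaus_fit <- function(x, ...) {
  cat("<bcaus_fit> n =", length(x$t), " (case", sum(x$t == 1),
      "/ comparator", sum(x$t == 0), ")\n",
      "checkpoint epoch", x$checkpoint_epoch, "-",
      sum(x$balance$balanced), "of", nrow(x$balance),
      "covariates balanced\n")
  invisible(x)
}
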