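# Random-intercept mixed model for one screening week: rods nested in fish,
# one fixed (cell-mean) effect per treatment group. Estimated from scratch
# by restricted maximum likelihood with the variance ratio profiled out.
#
# Model: y_ij = beta_{t(i)} + b_i + e_ij, b_i ~ N(0, tau2), e_ij ~ N(0,
# sigma2), fish i nested in treatment t(i). Writing theta = tau2/sigma2,
# the GLS weight of fish i is w_i = n_i / (1 + theta n_i) and everything
# reduces to per-fish summaries (n_i, mean, within-fish SS), so fits are
# O(#fish) per objective evaluation regardless of rod counts.

# Per-fish sufficient statistics for one week/metric.
fish_summaries <- function(measurements, metric) {
  col <- paste0("d_", metric, "_um")
  x <- measurements[!is.na(measurements[[col]]), , drop = FALSE]
  if (nrow(x) == 0) stop("no non-missing values for metric ", metric)
  if (length(unique(x$week_id)) > 1)
    stop("fit_random_intercept expects a single week; got ",
         paste(unique(x$week_id), collapse = ", "))
  by_fish <- unique(x[, c("fish_id", "compound_id", "treatment_role")])
  if (anyDuplicated(by_fish$fish_id))
    stop("lineage error: fish appearing under more than one treatment: ",
         paste(by_fish$fish_id[duplicated(by_fish$fish_id)], collapse = ", "))
  f <- factor(x$fish_id, levels = by_fish$fish_id)
  list(week_id = unique(x$week_id),
       n = as.vector(tapply(x[[col]], f, length)),
       ybar = as.vector(tapply(x[[col]], f, mean)),
       ss = as.vector(tapply(x[[col]], f,
                             function(v) sum((v - mean(v))^2))),
       compound = by_fish$compound_id,
       role = by_fish$treatment_role)
}

# -2 restricted log-likelihood profiled over (beta, sigma2) at a given
# variance ratio theta; returns the criterion and the implied estimates.
reml_profile <- function(theta, n, ybar, ss, group) {
  w <- n / (1 + theta * n)
  W <- as.vector(tapply(w, group, sum))
  beta <- as.vector(tapply(w * ybar, group, sum)) / W
  N <- sum(n); p <- nlevels(group)
  Q <- sum(ss) + sum(w * (ybar - beta[as.integer(group)])^2)
  sigma2 <- Q / (N - p)
  crit <- (N - p) * log(2 * pi * sigma2) + sum(log1p(theta * n)) +
    sum(log(W)) + (N - p)
  list(crit = crit, beta = beta, W = W, sigma2 = sigma2)
}

# Analytic derivative of the profiled criterion w.r.t. theta. Uses
# dw/dtheta = -w^2 and the GLS orthogonality sum_i w_i (ybar_i - beta) = 0
# within each treatment, which kills the beta' term of dQ/dtheta.
reml_profile_deriv <- function(theta, n, ybar, ss, group) {
  w <- n / (1 + theta * n)
  W <- as.vector(tapply(w, group, sum))
  beta <- as.vector(tapply(w * ybar, group, sum)) / W
  N <- sum(n); p <- nlevels(group)
  resid <- ybar - beta[as.integer(group)]
  Q <- sum(ss) + sum(w * resid^2)
  dQ <- -sum(w^2 * resid^2)
  W2 <- as.vector(tapply(w^2, group, sum))
  (N - p) * dQ / Q + sum(w) - sum(W2 / W)
}

# -2 restricted log-likelihood at arbitrary (sigma2, tau2); used for the
# observed information behind Satterthwaite degrees of freedom.
reml_deviance <- function(sigma2, tau2, n, ybar, ss, group) {
  theta <- tau2 / sigma2
  w <- n / (1 + theta * n)
  W <- as.vector(tapply(w, group, sum))
  beta <- as.vector(tapply(w * ybar, group, sum)) / W
  N <- sum(n); p <- nlevels(group)
  Q <- sum(ss) + sum(w * (ybar - beta[as.integer(group)])^2)
  (N - p) * log(2 * pi * sigma2) + sum(log1p(theta * n)) + sum(log(W)) +
    Q / sigma2
}

#' Fit the per-week random-intercept model
#'
#' Fits, by restricted maximum likelihood, the model `distance ~ treatment`
#' with a random intercept per fish, to one week's measurements of one
#' metric. The variance ratio `theta = tau2/sigma2` is profiled and
#' minimized by 1-D bounded search (golden section with parabolic
#' refinement) on `[0, 1e6]` with tolerance 1e-10; fixed effects are then
#' generalized-least-squares cell means at the optimum. A negative
#' between-fish component is truncated at zero (flagged). Each treatment
#' estimate is the precision-weighted combination of its fish means.
#'
#' @param measurements One week's measurement rows (see
#'   [read_measurements()]).
#' @param metric `"growth"` or `"shed"`.
#' @return An object of class `ros_model_fit` with the treatment levels
#'   (control first when present), fixed estimates and covariance, variance
#'   components `var_fish` (tau2) and `var_resid` (sigma2), per-fish
#'   summaries, convergence flags and the restricted log-likelihood.
#' @export
fit_random_intercept <- function(measurements, metric = c("growth", "shed")) {
  metric <- match.arg(metric)
  check_measurement_frame(measurements)
  fs <- fish_summaries(measurements, metric)

  control <- unique(fs$compound[fs$role == "control"])
  if (length(control) > 1)
    stop("more than one control group in week ", fs$week_id)
  levels_ <- c(control, setdiff(unique(fs$compound), control))
  group <- factor(fs$compound, levels = levels_)

  N <- sum(fs$n); p <- length(levels_)
  if (N - p < 1)
    stop("degenerate design: no residual degrees of freedom (", N,
         " rods, ", p, " treatment levels)")

  pr0 <- reml_profile(0, fs$n, fs$ybar, fs$ss, group)
  degenerate <- pr0$sigma2 < 1e-20
  if (degenerate) {
    # zero residual variance (all rods equal within groups): variance
    # floor, treatment means exact
    pr <- pr0
    pr$sigma2 <- 1e-10
    theta_hat <- 0
    crit <- NA_real_
    converged <- TRUE
    tau_zero <- TRUE
  } else {
    obj <- function(th) reml_profile(th, fs$n, fs$ybar, fs$ss, group)$crit
    gr <- function(th) reml_profile_deriv(th, fs$n, fs$ybar, fs$ss, group)
    opt <- stats::optimize(obj, interval = c(0, 1e6), tol = 1e-10)
    theta_hat <- opt$minimum
    # polish with the analytic gradient: the line search localizes the
    # optimum, the root of the derivative pins it to full precision
    lo <- max(theta_hat / 4, 1e-14); hi <- min(theta_hat * 4, 1e6)
    glo <- gr(lo); ghi <- gr(hi)
    if (is.finite(glo) && is.finite(ghi) && glo < 0 && ghi > 0) {
      theta_hat <- stats::uniroot(gr, c(lo, hi), f.lower = glo,
                                  f.upper = ghi,
                                  tol = 1e-12 * max(1, theta_hat))$root
    }
    crit0 <- pr0$crit
    tau_zero <- gr(0) >= 0 || crit0 <= obj(theta_hat)
    theta_hat <- if (tau_zero) 0 else theta_hat
    pr <- reml_profile(theta_hat, fs$n, fs$ybar, fs$ss, group)
    crit <- pr$crit
    converged <- TRUE
  }

  vcov_ <- diag(pr$sigma2 / pr$W, nrow = p)
  dimnames(vcov_) <- list(levels_, levels_)
  estimates <- stats::setNames(pr$beta, levels_)

  structure(list(
    metric = metric,
    week_id = fs$week_id,
    treatment_levels = levels_,
    control_level = if (length(control) == 1) control else NA_character_,
    fixed_estimates = estimates,
    fixed_covariance = vcov_,
    var_fish = theta_hat * pr$sigma2,
    var_resid = pr$sigma2,
    theta = theta_hat,
    group_weights = stats::setNames(pr$W, levels_),
    n_rods = N,
    n_fish = length(fs$n),
    fish = list(n = fs$n, ybar = fs$ybar, ss = fs$ss, group = group),
    tau_truncated = tau_zero,
    degenerate = degenerate,
    converged = converged,
    log_restricted_likelihood = -crit / 2,
    reml_criterion = crit
  ), class = "ros_model_fit")
}

#' @export
print.ros_model_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept fit [%s, week %s]: %d levels, %d fish, %d rods\n",
    x$metric, x$week_id, length(x$treatment_levels), x$n_fish, x$n_rods))
  cat(sprintf("  var components: fish %.4f, residual %.4f (REML%s)\n",
              x$var_fish, x$var_resid,
              if (x$tau_truncated) ", fish component truncated at 0" else ""))
  print(round(x$fixed_estimates, 4))
  invisible(x)
}

#' Contrasts of every compound against the weekly control
#'
#' For each non-control treatment level, returns the estimated difference
#' from the control mean, its standard error from the fixed-effect
#' covariance, and the full correlation matrix of the contrasts. Because
#' each group's estimate is independent given the variance components, the
#' many-to-one correlations have the classical product form
#' `lambda_i * lambda_j` with `lambda_i = sqrt(v_0 / (v_i + v_0))`, `v`
#' being estimate variances and 0 the control.
#'
#' @param fit A `ros_model_fit` with a control level present.
#' @return An object of class `ros_contrasts`: a list with a `table` data
#'   frame (compound_id, estimate, se, control_mean, treated_mean), the
#'   contrast `correlation` matrix, and the parent `fit`.
#' @export
contrast_control <- function(fit) {
  stopifnot(inherits(fit, "ros_model_fit"))
  if (is.na(fit$control_level) || length(fit$control_level) == 0)
    stop("no control: week ", fit$week_id, " has no control group")
  others <- setdiff(fit$treatment_levels, fit$control_level)
  k <- length(others)
  v <- fit$var_resid / fit$group_weights       # var of each group mean
  v0 <- v[[fit$control_level]]
  est <- fit$fixed_estimates[others] - fit$fixed_estimates[[fit$control_level]]
  se <- sqrt(pmax(v[others] + v0, 1e-24))      # guard exact-zero variance
  lambda <- sqrt(v0 / (v[others] + v0))
  correlation <- tcrossprod(lambda)
  diag(correlation) <- 1
  dimnames(correlation) <- list(others, others)
  structure(list(
    table = data.frame(compound_id = others,
                       estimate = as.vector(est),
                       se = as.vector(se),
                       control_mean = fit$fixed_estimates[[fit$control_level]],
                       treated_mean = as.vector(fit$fixed_estimates[others]),
                       stringsAsFactors = FALSE, row.names = NULL),
    correlation = correlation,
    lambda = stats::setNames(as.vector(lambda), others),
    fit = fit
  ), class = "ros_contrasts")
}

#' @export
print.ros_contrasts <- function(x, ...) {
  cat(sprintf("Control contrasts [%s, week %s]: %d compound(s)\n",
              x$fit$metric, x$fit$week_id, nrow(x$table)))
  print(cbind(x$table[, c("compound_id", "estimate", "se")]))
  invisible(x)
}

# Analytic variance of a control contrast as a function of (sigma2, tau2):
# var = 1/S_j + 1/S_0 with S_t = sum_{fish in t} n_i / (sigma2 + tau2 n_i),
# plus its gradient. Returns list(value, grad = c(d/dsigma2, d/dtau2)).
contrast_variance_fun <- function(fit, level) {
  g <- fit$fish$group
  n0 <- fit$fish$n[g == fit$control_level]
  nj <- fit$fish$n[g == level]
  function(sigma2, tau2) {
    d0 <- sigma2 + tau2 * n0
    dj <- sigma2 + tau2 * nj
    S0 <- sum(n0 / d0); Sj <- sum(nj / dj)
    value <- 1 / Sj + 1 / S0
    dS0 <- c(-sum(n0 / d0^2), -sum(n0^2 / d0^2))
    dSj <- c(-sum(nj / dj^2), -sum(nj^2 / dj^2))
    grad <- -dSj / Sj^2 - dS0 / S0^2
    list(value = value, grad = grad)
  }
}

#' Satterthwaite effective degrees of freedom for control contrasts
#'
#' Approximates the degrees of freedom of each compound-vs-control contrast
#' by matching moments of the estimated contrast variance: `df = 2 v^2 /
#' Var(v)`, with `Var(v)` obtained from the analytic gradient of the
#' contrast variance with respect to `(sigma2, tau2)` and the inverse
#' observed REML information (central-difference Hessian of the exact
#' restricted deviance). At the `tau2 = 0` boundary the model collapses to
#' ordinary least squares and `df = n_rods - n_levels`; a singular
#' information matrix falls back to the fish-level `n_fish - n_levels`
#' (flagged via attribute `fallback`). Degrees of freedom are floored at 1.
#'
#' @param fit A `ros_model_fit`.
#' @param contrasts Optional `ros_contrasts` from [contrast_control()];
#'   computed from `fit` if missing.
#' @return Named numeric vector of df, one per non-control level.
#' @export
satterthwaite_df <- function(fit, contrasts = NULL) {
  stopifnot(inherits(fit, "ros_model_fit"))
  if (!isTRUE(fit$converged)) stop("satterthwaite_df requires a converged fit")
  if (is.null(contrasts)) contrasts <- contrast_control(fit)
  others <- contrasts$table$compound_id
  N <- fit$n_rods; p <- length(fit$treatment_levels)

  if (fit$theta <= 1e-8 || fit$degenerate) {
    # boundary: no usable between-fish component, OLS residual df
    return(stats::setNames(rep(N - p, length(others)), others))
  }

  s2 <- fit$var_resid; t2 <- fit$var_fish
  dev <- function(par) reml_deviance(par[1], par[2], fit$fish$n,
                                     fit$fish$ybar, fit$fish$ss,
                                     fit$fish$group)
  h <- c(1e-4 * s2, 1e-4 * max(t2, 1e-3 * s2))
  H <- matrix(NA_real_, 2, 2)
  par <- c(s2, t2)
  for (a in 1:2) {
    ea <- replace(numeric(2), a, h[a])
    H[a, a] <- (dev(par + ea) - 2 * dev(par) + dev(par - ea)) / h[a]^2
    for (b in seq_len(a - 1)) {
      eb <- replace(numeric(2), b, h[b])
      H[a, b] <- H[b, a] <-
        (dev(par + ea + eb) - dev(par + ea - eb) -
           dev(par - ea + eb) + dev(par - ea - eb)) / (4 * h[a] * h[b])
    }
  }
  vcov_vc <- tryCatch(2 * solve(H), error = function(e) NULL)
  fallback <- is.null(vcov_vc) || any(!is.finite(vcov_vc)) ||
    any(diag(vcov_vc) <= 0)
  if (fallback) {
    df <- stats::setNames(rep(max(1, fit$n_fish - p), length(others)), others)
    attr(df, "fallback") <- TRUE
    return(df)
  }
  df <- vapply(others, function(lv) {
    cv <- contrast_variance_fun(fit, lv)(s2, t2)
    denom <- as.numeric(t(cv$grad) %*% vcov_vc %*% cv$grad)
    if (denom <= 0) return(max(1, fit$n_fish - p))
    max(1, 2 * cv$value^2 / denom)
  }, numeric(1))
  stats::setNames(df, others)
}
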