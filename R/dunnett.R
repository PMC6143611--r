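# Single-step Dunnett many-to-one adjustment, implemented from scratch.
#
# For contrasts T_1..T_k jointly multivariate t (common denominator, given
# correlation R and df nu), the two-sided adjusted p of contrast i is
#   p_adj_i = 1 - Pr(max_j |T_j| <= |t_i|).
# Many-to-one correlation matrices have the one-factor form R = ll' with
# unit diagonal, so conditioning on the shared factor U ~ N(0,1) and the
# scale s = sqrt(chi2_nu / nu) makes the orthant probability a smooth
# 2-dimensional integral, evaluated by randomized-Halton quasi-Monte-Carlo
# with a reported Monte-Carlo error. General PSD correlation matrices fall
# back to a (noisier) simulation of max |T| from the same point set.

# Cache of Halton/van der Corput sequences, keyed by "n.base".
.halton_cache <- new.env(parent = emptyenv())

van_der_corput <- function(n, base) {
  key <- paste(n, base, sep = ".")
  if (!is.null(.halton_cache[[key]])) return(.halton_cache[[key]])
  i <- seq_len(n)
  r <- numeric(n)
  denom <- base
  while (any(i > 0)) {
    r <- r + (i %% base) / denom
    i <- i %/% base
    denom <- denom * base
  }
  .halton_cache[[key]] <- r
  r
}

halton_matrix <- function(n, dim) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47)
  if (dim > length(primes)) stop("Halton dimension too large")
  vapply(primes[seq_len(dim)], function(b) van_der_corput(n, b),
         numeric(n))
}

# Extract the one-factor loadings lambda (R = ll' off-diagonal), or NULL if
# the matrix does not have product structure.
factor_loadings <- function(R) {
  k <- nrow(R)
  if (k == 1) return(0)
  if (k == 2) {
    r <- R[1, 2]
    if (r < 0) return(NULL)
    return(rep(sqrt(r), 2))
  }
  lambda <- numeric(k)
  for (i in seq_len(k)) {
    jk <- setdiff(seq_len(k), i)[1:2]
    denom <- R[jk[1], jk[2]]
    if (abs(denom) < 1e-12) return(NULL)
    l2 <- R[i, jk[1]] * R[i, jk[2]] / denom
    if (l2 < 0 || l2 > 1) return(NULL)
    lambda[i] <- sqrt(l2)
  }
  if (max(abs(tcrossprod(lambda) + diag(1 - lambda^2) - R)) > 1e-6)
    return(NULL)
  lambda
}

# Pr(max_j |T_j| <= c) for each threshold c, one-factor structure.
# u, s: QMC draws of the shared normal factor and the chi scale.
max_abs_cdf_factor <- function(cs, lambda, u, s) {
  eta <- sqrt(pmax(1 - lambda^2, 1e-12))
  vapply(cs, function(c0) {
    acc <- rep(1, length(u))
    for (j in seq_along(lambda)) {
      up <- (c0 * s - lambda[j] * u) / eta[j]
      lo <- (-c0 * s - lambda[j] * u) / eta[j]
      acc <- acc * (stats::pnorm(up) - stats::pnorm(lo))
    }
    mean(acc)
  }, numeric(1))
}

#' Dunnett-adjusted p-values for many-to-one contrasts
#'
#' Computes two-sided single-step adjusted p-values for each
#' compound-vs-control contrast under the joint central multivariate t
#' distribution with the supplied correlation matrix and common degrees of
#' freedom. The equicoordinate probability is evaluated by seeded
#' randomized quasi-Monte-Carlo (shifted Halton points in batches); the
#' half-width of a 95% interval on each adjusted p is returned as
#' `mc_error`. For `df > 500` the multivariate normal limit is used. Raw
#' p-values come from the univariate t distribution. Identical inputs and
#' seed reproduce identical output to the last bit; the caller's RNG
#' stream is left untouched.
#'
#' @param contrasts A `ros_contrasts` object from [contrast_control()], or
#'   a data frame with columns `estimate` and `se` (optionally
#'   `compound_id`, `control_mean`, `treated_mean`).
#' @param correlation Contrast correlation matrix (symmetric PSD, unit
#'   diagonal); defaults to the one stored in `contrasts`.
#' @param df Common effective degrees of freedom (scalar, >= 1); typically
#'   the minimum Satterthwaite df across the week's contrasts.
#' @param n_points Total quasi-Monte-Carlo points (default 2e5).
#' @param seed Seed for the randomizing shifts (default 1).
#' @param n_batches Number of randomized batches used for the error
#'   estimate.
#' @return A data frame of class `ros_comparisons` with columns
#'   `compound_id`, `estimate`, `se`, `df`, `t_stat`, `p_raw`, `p_adj`,
#'   `mc_error`, `tier`, plus `control_mean`, `treated_mean` and
#'   `percent_change` when group means are available.
#' @export
dunnett_adjust <- function(contrasts, correlation = NULL, df,
                           n_points = 2e5, seed = 1L, n_batches = 8L) {
  if (inherits(contrasts, "ros_contrasts")) {
    if (is.null(correlation)) correlation <- contrasts$correlation
    tab <- contrasts$table
  } else {
    tab <- as.data.frame(contrasts)
    stopifnot(all(c("estimate", "se") %in% names(tab)))
  }
  k <- nrow(tab)
  if (k == 0) return(empty_comparisons())
  if (is.null(correlation)) {
    if (k > 1) stop("correlation matrix required for k > 1 contrasts")
    correlation <- matrix(1, 1, 1)
  }
  correlation <- as.matrix(correlation)
  stopifnot(nrow(correlation) == k, ncol(correlation) == k)
  if (max(abs(correlation - t(correlation))) > 1e-8 ||
      max(abs(diag(correlation) - 1)) > 1e-8)
    stop("correlation matrix must be symmetric with unit diagonal")
  if (min(eigen(correlation, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("correlation matrix is not positive semi-definite")
  stopifnot(length(df) == 1, df >= 1)

  tval <- tab$estimate / tab$se
  p_raw <- 2 * stats::pt(-abs(tval), df)
  use_normal <- df > 500

  if (k == 1) {
    p_adj <- p_raw
    mc_error <- rep(0, k)
  } else {
    lambda <- factor_loadings(correlation)
    n_batches <- as.integer(n_batches)
    n_b <- ceiling(n_points / n_batches)
    cs <- abs(tval)
    ord <- order(cs)
    shifts_dim <- if (is.null(lambda)) k + 1 else 2
    shifts <- with_local_seed(seed,
                              matrix(stats::runif(n_batches * shifts_dim),
                                     nrow = n_batches))
    F_batches <- matrix(NA_real_, n_batches, k)
    if (is.null(lambda)) {
      # general PSD correlation: simulate max |T| from shifted Halton points
      L <- t(chol(correlation + diag(1e-10, k)))
      H <- halton_matrix(n_b, k + 1)
      for (b in seq_len(n_batches)) {
        U <- (H + matrix(shifts[b, ], n_b, k + 1, byrow = TRUE)) %% 1
        U <- pmin(pmax(U, 1e-12), 1 - 1e-12)
        Z <- stats::qnorm(U[, seq_len(k), drop = FALSE]) %*% t(L)
        s <- if (use_normal) 1
             else sqrt(stats::qchisq(U[, k + 1], df) / df)
        mx <- apply(abs(Z), 1, max) / s
        F_batches[b, ] <- vapply(cs, function(c0) mean(mx <= c0), numeric(1))
      }
    } else {
      H <- halton_matrix(n_b, 2)
      for (b in seq_len(n_batches)) {
        U <- (H + matrix(shifts[b, ], n_b, 2, byrow = TRUE)) %% 1
        U <- pmin(pmax(U, 1e-12), 1 - 1e-12)
        u <- stats::qnorm(U[, 1])
        s <- if (use_normal) rep(1, n_b)
             else sqrt(stats::qchisq(U[, 2], df) / df)
        F_batches[b, ] <- max_abs_cdf_factor(cs, lambda, u, s)
      }
    }
    Fbar <- colMeans(F_batches)
    mc_error <- 1.96 * apply(F_batches, 2, stats::sd) / sqrt(n_batches)
    p_adj <- pmin(pmax(1 - Fbar, 0), 1)
    # enforce monotonicity in |t| (QMC noise could produce microscopic
    # inversions between near-identical statistics)
    p_adj[ord] <- rev(cummax(rev(p_adj[ord])))
  }

  out <- data.frame(
    compound_id = if ("compound_id" %in% names(tab)) tab$compound_id
                  else sprintf("contrast%d", seq_len(k)),
    estimate = tab$estimate,
    se = tab$se,
    df = df,
    t_stat = tval,
    p_raw = p_raw,
    p_adj = p_adj,
    mc_error = mc_error,
    stringsAsFactors = FALSE)
  if (all(c("control_mean", "treated_mean") %in% names(tab))) {
    out$control_mean <- tab$control_mean
    out$treated_mean <- tab$treated_mean
    out$percent_change <- percent_change(tab$treated_mean, tab$control_mean)
  }
  out$tier <- significance_tier(out$p_adj)
  class(out) <- c("ros_comparisons", "data.frame")
  out
}

empty_comparisons <- function() {
  out <- data.frame(compound_id = character(), estimate = numeric(),
                    se = numeric(), df = numeric(), t_stat = numeric(),
                    p_raw = numeric(), p_adj = numeric(),
                    mc_error = numeric(), tier = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("ros_comparisons", "data.frame")
  out
}

#' Significance tier of an adjusted p-value
#'
#' The screen's significance ladder: `"***"` for p < 0.001, `"**"` for
#' p < 0.01, `"*"` for p < 0.05, `"ns"` otherwise. Boundaries are strict
#' (exclusive), so p = 0.05 is `"ns"`.
#'
#' @param p_adj Adjusted p-value(s) in \[0, 1\].
#' @return Character vector of tier labels.
#' @export
significance_tier <- function(p_adj) {
  stopifnot(is.numeric(p_adj), all(p_adj >= 0 & p_adj <= 1, na.rm = TRUE))
  ifelse(is.na(p_adj), NA_character_,
         ifelse(p_adj < 0.001, "***",
                ifelse(p_adj < 0.01, "**",
                       ifelse(p_adj < 0.05, "*", "ns"))))
}
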