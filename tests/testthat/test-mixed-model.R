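test_that("negative between-fish moment truncates to zero, pooled mean", {
  # fish means {5, 6}: MSB = 1.0 < MSW = 2.0, so tau2 = 0 and the
  # estimate is the pooled mean 5.5 with sigma2 = Q/(N-p) = 5/3
  m <- make_week(list(DMSO = list(c(4, 6), c(5, 7))))
  fit <- fit_random_intercept(m, "growth")
  expect_equal(fit$var_fish, 0)
  expect_true(fit$tau_truncated)
  expect_equal(unname(fit$fixed_estimates["DMSO"]), 5.5)
  expect_equal(fit$var_resid, 5 / 3, tolerance = 1e-10)
})

test_that("with no fish variance the fit collapses to group means", {
  m <- make_noisy_week(c(DMSO = 5, C1 = 4, C2 = 6), nf = 3, n = 15,
                       fish_sd = 0, rod_sd = 1, seed = 8,
                       unbalanced = TRUE)
  fit <- fit_random_intercept(m, "growth")
  ols <- tapply(m$d_growth_um, m$compound_id, mean)
  tol <- if (fit$var_fish == 0) 1e-8 else 1e-2
  expect_equal(unname(fit$fixed_estimates[names(ols)]), as.vector(ols),
               tolerance = tol)
})

test_that("balanced designs reproduce the classical ANOVA REML forms", {
  for (seed in c(21, 22, 23)) {
    m <- make_noisy_week(c(DMSO = 5, C1 = 4.4, C2 = 5.8), nf = 3, n = 12,
                         fish_sd = 0.5, rod_sd = 1, seed = seed)
    fit <- fit_random_intercept(m, "growth")
    oracle <- balanced_reml_oracle(m, "growth")
    if (oracle$tau2 > 0) {
      expect_equal(fit$var_fish, oracle$tau2, tolerance = 1e-8)
      expect_equal(fit$var_resid, oracle$sigma2, tolerance = 1e-8)
    } else {
      expect_equal(fit$var_fish, 0)
    }
  }
})

test_that("fits agree with an established mixed-model reference", {
  skip_if_not_installed("lme4")
  set.seed(99)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    means <- runif(k, 3, 7)
    names(means) <- c("DMSO", paste0("C", seq_len(k - 1)))
    m <- make_noisy_week(means, nf = sample(3:4, 1), n = sample(8:25, 1),
                         fish_sd = runif(1, 0.1, 0.8),
                         rod_sd = runif(1, 0.5, 1.5),
                         seed = 1000 + i, unbalanced = TRUE)
    fit <- fit_random_intercept(m, "growth")
    lf <- suppressMessages(lme4::lmer(
      d_growth_um ~ 0 + compound_id + (1 | fish_id), data = m,
      REML = TRUE))
    fe <- lme4::fixef(lf)
    names(fe) <- sub("^compound_id", "", names(fe))
    expect_equal(fit$fixed_estimates[names(fe)], fe, tolerance = 1e-4)
    se <- sqrt(diag(as.matrix(vcov(lf))))
    names(se) <- sub("^compound_id", "", names(se))
    expect_equal(sqrt(diag(fit$fixed_covariance))[names(se)], se,
                 tolerance = 1e-4)
    vc <- as.data.frame(lme4::VarCorr(lf))
    expect_equal(fit$var_fish, vc$vcov[1], tolerance = 1e-3)
    expect_equal(fit$var_resid, vc$vcov[2], tolerance = 1e-3)
  }
})

test_that("REML criterion is optimal against the profile endpoints", {
  for (seed in c(5, 6)) {
    m <- make_noisy_week(c(DMSO = 5, C1 = 5.5), nf = 3, n = 10,
                         fish_sd = 0.6, rod_sd = 1, seed = seed)
    fit <- fit_random_intercept(m, "growth")
    fs <- fit$fish
    crit <- function(th) rosrenew:::reml_profile(th, fs$n, fs$ybar, fs$ss,
                                                 fs$group)$crit
    expect_lte(fit$reml_criterion, crit(0) + 1e-8)
    expect_lte(fit$reml_criterion, crit(100) + 1e-8)
  }
})

test_that("estimates are equivariant under translation", {
  m <- make_noisy_week(c(DMSO = 5, C1 = 4.2), nf = 3, n = 10,
                       fish_sd = 0.4, rod_sd = 1, seed = 13)
  m2 <- m
  m2$d_growth_um <- m2$d_growth_um + 3
  f1 <- fit_random_intercept(m, "growth")
  f2 <- fit_random_intercept(m2, "growth")
  expect_equal(f2$fixed_estimates, f1$fixed_estimates + 3, tolerance = 1e-6)
  expect_equal(f2$var_fish, f1$var_fish, tolerance = 1e-6)
  expect_equal(f2$var_resid, f1$var_resid, tolerance = 1e-6)
})

test_that("variance components are recovered without systematic bias", {
  tau2 <- 0.36; sigma2 <- 1
  est <- replicate(200, {
    m <- make_noisy_week(c(DMSO = 5, C1 = 5), nf = 5, n = 20,
                         fish_sd = sqrt(tau2), rod_sd = sqrt(sigma2),
                         seed = sample.int(1e6, 1))
    fit <- fit_random_intercept(m, "growth")
    c(fit$var_fish, fit$var_resid)
  })
  set.seed(555)  # replicate() above consumed the stream; pin for reruns
  expect_lt(abs(median(est[1, ]) - tau2) / tau2, 0.10)
  expect_lt(abs(median(est[2, ]) - sigma2) / sigma2, 0.10)
})

test_that("contrasts against the control have the classical structure", {
  # noise-free: contrast equals the difference of group means
  m <- make_week(list(DMSO = list(c(4, 4), c(4, 4)),
                      C1 = list(c(5, 5), c(5, 5))))
  fit <- fit_random_intercept(m, "growth")
  ct <- contrast_control(fit)
  expect_equal(ct$table$estimate, 1, tolerance = 1e-9)
  expect_true(all(ct$table$se >= 0))

  # balanced equal-n many-to-one correlations are exactly 0.5
  mb <- make_noisy_week(c(DMSO = 5, C1 = 4.5, C2 = 5.5, C3 = 6), nf = 3,
                        n = 10, fish_sd = 0.4, rod_sd = 1, seed = 17)
  fb <- fit_random_intercept(mb, "growth")
  cb <- contrast_control(fb)
  off <- cb$correlation[upper.tri(cb$correlation)]
  expect_equal(off, rep(0.5, length(off)), tolerance = 1e-10)

  # single contrast: 1x1 unit correlation
  m1 <- make_noisy_week(c(DMSO = 5, C1 = 4.5), nf = 3, n = 8, seed = 18)
  c1 <- contrast_control(fit_random_intercept(m1, "growth"))
  expect_equal(unname(c1$correlation), matrix(1, 1, 1))

  # no control present
  mnc <- make_week(list(A = list(c(4, 5)), B = list(c(5, 6))), control = "Z")
  mnc$treatment_role <- "compound"
  expect_error(contrast_control(fit_random_intercept(mnc, "growth")),
               "no control")
})

test_that("Satterthwaite df tracks the dominant variance level", {
  # tau2 = 0: collapses to the OLS residual df, rods - levels
  m0 <- make_noisy_week(c(DMSO = 5, C1 = 5.4), nf = 3, n = 10,
                        fish_sd = 0, rod_sd = 1, seed = 41)
  f0 <- fit_random_intercept(m0, "growth")
  if (f0$theta <= 1e-8) {
    expect_equal(unname(satterthwaite_df(f0)[1]), f0$n_rods - 2)
  }

  # dominant fish variance, 3 fish per group, 2 groups: fish-level df = 4
  mf <- make_noisy_week(c(DMSO = 5, C1 = 5.5), nf = 3, n = 40,
                        fish_sd = 2, rod_sd = 0.05, seed = 42)
  ff <- fit_random_intercept(mf, "growth")
  expect_equal(unname(satterthwaite_df(ff)[1]), 4, tolerance = 0.15)

  # df is non-increasing as the variance ratio grows, all else fixed
  base <- fit_random_intercept(
    make_noisy_week(c(DMSO = 5, C1 = 5.5), nf = 3, n = 20,
                    fish_sd = 0.5, rod_sd = 1, seed = 43), "growth")
  dfs <- vapply(c(0.02, 0.1, 0.5, 2, 10), function(th) {
    forged <- base
    forged$theta <- th
    forged$var_fish <- th * forged$var_resid
    unname(satterthwaite_df(forged)[1])
  }, numeric(1))
  expect_true(all(diff(dfs) <= 1e-6))
})

test_that("degenerate and malformed inputs are rejected or flagged", {
  # a fish listed under two treatments
  bad <- make_week(list(DMSO = list(c(4, 5)), C1 = list(c(5, 6))))
  bad$fish_id <- "shared_fish"
  expect_error(fit_random_intercept(bad, "growth"), "lineage")

  # all values identical: flagged degenerate with a variance floor
  flat <- make_week(list(DMSO = list(c(5, 5), c(5, 5)),
                         C1 = list(c(5, 5), c(5, 5))))
  ff <- fit_random_intercept(flat, "growth")
  expect_true(ff$degenerate)
  expect_gt(ff$var_resid, 0)
  expect_equal(unname(ff$fixed_estimates), c(5, 5))
})
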