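# Fixtures built in code: small measurement frames with known structure.

# One week of measurements from explicit per-fish rod values.
# groups: named list, name = compound id, value = list of numeric vectors
# (one per fish). `control` names the control group.
make_week <- function(groups, control = names(groups)[1], week = "W001",
                      metric = "growth") {
  col <- paste0("d_", metric, "_um")
  other <- setdiff(c("d_growth_um", "d_shed_um"), col)
  rows <- list()
  for (g in names(groups)) {
    for (f in seq_along(groups[[g]])) {
      v <- groups[[g]][[f]]
      r <- data.frame(
        week_id = week, compound_id = g,
        treatment_role = if (g == control) "control" else "compound",
        fish_id = sprintf("%s_f%d", g, f),
        rod_id = sprintf("r%03d", seq_along(v)),
        stringsAsFactors = FALSE)
      r[[col]] <- v
      r[[other]] <- NA_real_
      rows[[length(rows) + 1]] <- r
    }
  }
  do.call(rbind, rows)
}

# A week with normal noise at chosen variance components, group means given
# as named vector (first name = control), nf fish per group, n rods/fish.
make_noisy_week <- function(means, nf = 3, n = 20, fish_sd = 0.3,
                            rod_sd = 1.0, week = "W001", seed = 1,
                            unbalanced = FALSE) {
  set.seed(seed)
  groups <- lapply(seq_along(means), function(i) {
    lapply(seq_len(nf), function(f) {
      ni <- if (unbalanced) sample(max(2, n - 5):(n + 5), 1) else n
      rnorm(ni, means[i] + rnorm(1, 0, fish_sd), rod_sd)
    })
  })
  names(groups) <- names(means)
  make_week(groups, control = names(means)[1], week = week)
}

# Classical balanced-nested ANOVA REML closed forms (oracle).
balanced_reml_oracle <- function(measurements, metric = "growth") {
  col <- paste0("d_", metric, "_um")
  x <- measurements[!is.na(measurements[[col]]), ]
  f <- factor(x$fish_id)
  g <- factor(x$compound_id)
  n <- as.vector(table(f))
  stopifnot(length(unique(n)) == 1)
  n0 <- n[1]
  fish_means <- tapply(x[[col]], f, mean)
  fish_group <- tapply(as.character(x$compound_id), f, function(s) s[1])
  treat_means <- tapply(fish_means, fish_group, mean)
  msw <- sum(tapply(x[[col]], f, function(v) sum((v - mean(v))^2))) /
    (nrow(x) - nlevels(f))
  msb <- n0 * sum((fish_means - treat_means[fish_group])^2) /
    (nlevels(f) - nlevels(g))
  tau2 <- max(0, (msb - msw) / n0)
  sigma2 <- if (tau2 > 0) msw else NA  # at the boundary REML refits sigma2
  list(sigma2 = sigma2, tau2 = tau2, msw = msw, msb = msb)
}
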