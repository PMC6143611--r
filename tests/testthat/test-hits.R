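thr <- hit_thresholds()

test_that("distance calls combine biological and statistical thresholds", {
  expect_equal(call_distance_hit(list(percent_change = 34, p_adj = 5e-10),
                                 thr), "primary-increase")
  expect_equal(call_distance_hit(list(percent_change = -36, p_adj = 1e-16),
                                 thr), "primary-decrease")
  expect_equal(call_distance_hit(list(percent_change = 26, p_adj = 0.00101),
                                 thr), "tiered-increase")
  # strong p but below the biological threshold: not primary
  expect_equal(call_distance_hit(list(percent_change = 19, p_adj = 1e-9),
                                 thr), "tiered-increase")
  # boundaries: percent is non-strict, p is strict
  expect_equal(call_distance_hit(list(percent_change = 20, p_adj = 9.99e-4),
                                 thr), "primary-increase")
  expect_equal(call_distance_hit(list(percent_change = 25, p_adj = 0.001),
                                 thr), "tiered-increase")
  expect_equal(call_distance_hit(list(percent_change = 10, p_adj = 0.2),
                                 thr), "none")
  # same-target follow-up requires some significance tier
  expect_equal(call_distance_hit(list(percent_change = 15, p_adj = 0.03),
                                 thr, same_target_primary_exists = TRUE),
               "same-target-followup")
  expect_equal(call_distance_hit(list(percent_change = 15, p_adj = 0.3),
                                 thr, same_target_primary_exists = TRUE),
               "none")
  expect_error(hit_thresholds(p_primary = 0.05, p_tertiary = 0.001),
               "p_primary")
})

test_that("qualitative hits follow the at-least-one-image rule", {
  expect_true(qualitative_hit(c(FALSE, FALSE, TRUE)))
  expect_false(qualitative_hit(c(FALSE, FALSE, FALSE)))
  expect_true(qualitative_hit(TRUE))   # single CMZ image
  expect_error(qualitative_hit(logical(0)), "no image flags")
  expect_error(qualitative_hit(c(TRUE, NA)), "TRUE/FALSE")
})

test_that("pathway tallies count matching calls deterministically", {
  hits <- data.frame(
    compound_id = c("A", "B", "C", "D"),
    pathway = c("Neuronal Signaling", "Neuronal Signaling", "Cell Cycle",
                NA),
    dg_call = c("primary-increase", "primary-increase", "primary-increase",
                "tiered-increase"),
    ds_call = "none",
    phagosome_hit = c(TRUE, FALSE, FALSE, TRUE),
    misloc_hit = FALSE, cmz_hit = FALSE,
    lethal = FALSE, stringsAsFactors = FALSE)
  tg <- tally_by_pathway(hits, "growth-increase")
  expect_equal(tg$pathway, c("Neuronal Signaling", "Cell Cycle"))
  expect_equal(tg$count, c(2L, 1L))
  # tiered calls are not counted in the distance areas
  expect_false("unannotated" %in% tg$pathway)
  tp <- tally_by_pathway(hits, "phagosome")
  expect_equal(tp$pathway, c("Neuronal Signaling", "unannotated"))
  expect_equal(tally_by_pathway(hits[0, ], "cmz")$count, integer(0))
})

test_that("a noise-free +34% compound yields exactly one primary call", {
  cfg <- simulation_config(n_weeks = 1, compounds_per_week = c(3, 3),
                           rods_per_fish_dg = c(6, 6),
                           rods_per_fish_ds = c(5, 5),
                           week_sd = 0, fish_sd = 0, rod_sd = 0,
                           lethality_prob = 0, seed = 1)
  eff <- compound_effects(c("HIT", "N1", "N2"),
                          growth_multiplier = c(1.34, 1, 1))
  scr <- simulate_screen(cfg, eff)
  rep_ <- suppressWarnings(build_report(scr$measurements, scr$annotations,
                                        scr$qualitative,
                                        dunnett_points = 2e4))
  expect_equal(rep_$hits$dg_call[rep_$hits$compound_id == "HIT"],
               "primary-increase")
  expect_equal(sum(grepl("^primary", rep_$hits$dg_call)), 1)
  expect_true(all(rep_$hits$ds_call == "none"))
})

test_that("printed group means reproduce the reported percent change", {
  # two-group week with means pinned at 5.88 (treated) and 4.40 (control)
  spread <- c(-0.2, 0, 0.2)
  m <- make_week(list(DMSO = lapply(c(0, 0, 0), function(o) 4.40 + o + spread),
                      ETO = lapply(c(0, 0, 0), function(o) 5.88 + o + spread)))
  rep_ <- build_report(m, dunnett_points = 2e4)
  pc <- rep_$comparisons$percent_change[
    rep_$comparisons$compound_id == "ETO"]
  expect_equal(round_percent(pc), 34)
})

test_that("calls are invariant to compound order within a week", {
  cfg <- simulation_config(n_weeks = 1, compounds_per_week = c(4, 4),
                           rods_per_fish_dg = c(10, 20),
                           rods_per_fish_ds = c(8, 15),
                           lethality_prob = 0, seed = 60)
  eff <- compound_effects(c("A", "B", "C", "D"),
                          growth_multiplier = c(1.4, 1, 0.7, 1))
  scr <- simulate_screen(cfg, eff)
  m <- scr$measurements
  shuffled <- m[rev(seq_len(nrow(m))), ]
  r1 <- build_report(m, dunnett_points = 4e4)
  r2 <- build_report(shuffled, dunnett_points = 4e4)
  c1 <- r1$comparisons[order(r1$comparisons$compound_id,
                             r1$comparisons$metric), ]
  c2 <- r2$comparisons[order(r2$comparisons$compound_id,
                             r2$comparisons$metric), ]
  expect_equal(c1$p_adj, c2$p_adj,
               tolerance = max(c1$mc_error + c2$mc_error, 1e-6))
  h1 <- r1$hits[order(r1$hits$compound_id), ]
  h2 <- r2$hits[order(r2$hits$compound_id), ]
  expect_equal(h1$dg_call, h2$dg_call)
})

test_that("raising the biological threshold never adds primary calls", {
  cfg <- simulation_config(n_weeks = 1, compounds_per_week = c(5, 5),
                           rods_per_fish_dg = c(10, 20),
                           rods_per_fish_ds = c(8, 15),
                           lethality_prob = 0, seed = 61)
  eff <- compound_effects(sprintf("C%d", 1:5),
                          growth_multiplier = c(1.5, 1.25, 1, 0.7, 0.85))
  scr <- simulate_screen(cfg, eff)
  n_primary <- vapply(c(20, 30, 40, 60), function(pct) {
    r <- build_report(scr$measurements, scr$annotations,
                      thresholds = hit_thresholds(pct_threshold = pct),
                      dunnett_points = 2e4)
    sum(grepl("^primary", r$hits$dg_call) | grepl("^primary", r$hits$ds_call))
  }, numeric(1))
  expect_true(all(diff(n_primary) <= 0))
})

test_that("same-target companions are promoted to follow-up calls", {
  cfg <- simulation_config(n_weeks = 1, compounds_per_week = c(3, 3),
                           rods_per_fish_dg = c(30, 30),
                           rods_per_fish_ds = c(20, 20),
                           week_sd = 0, fish_sd = 0.05, rod_sd = 0.6,
                           lethality_prob = 0, seed = 62)
  # strong and weak effect on the same target, plus an unrelated null
  eff <- compound_effects(c("STRONG", "WEAK", "NULL1"),
                          growth_multiplier = c(1.5, 1.12, 1),
                          target = c("COX", "COX", "other"))
  scr <- simulate_screen(cfg, eff)
  r <- build_report(scr$measurements, scr$annotations,
                    dunnett_points = 2e4)
  h <- r$hits
  expect_equal(h$dg_call[h$compound_id == "STRONG"], "primary-increase")
  weak_call <- h$dg_call[h$compound_id == "WEAK"]
  # the weak companion is significant but sub-threshold: follow-up
  expect_true(weak_call %in% c("same-target-followup", "primary-increase"))
})

test_that("lethal compounds get no calls and a week needs its control", {
  m <- make_noisy_week(c(DMSO = 5, C1 = 5.2), nf = 3, n = 10, seed = 70)
  ann <- data.frame(compound_id = c("C1", "DEAD"), name = c("C1", "DEAD"),
                    target = NA, pathway = c("P1", "P2"),
                    stringsAsFactors = FALSE)
  r <- build_report(m, ann, dunnett_points = 2e4)
  expect_true(r$hits$lethal[r$hits$compound_id == "DEAD"])
  expect_equal(r$hits$dg_call[r$hits$compound_id == "DEAD"], "none")
  for (a in names(r$tallies))
    expect_false("P2" %in% r$tallies[[a]]$pathway)

  no_ctrl <- m[m$treatment_role == "compound", ]
  expect_error(build_report(no_ctrl), "W001")
})
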