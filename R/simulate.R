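# Hierarchical synthetic-screen generator: week baselines, fish intercepts,
# rod-level noise, unbalanced rod counts, lethality, and Bernoulli
# qualitative flags, with a recorded ground truth for recovery tests.

#' Configuration of a synthetic renewal screen
#'
#' Defaults encode the structure of the larval screen the package targets:
#' 8-32 compounds per week sharing one DMSO control, 3 fish per treatment,
#' 33-149 measured rods per fish for the growth distance and 24-105 with a
#' measurable shedding distance, and ~30% compound lethality. The variance
#' split (week 0.55 um, fish 0.35 um, rod 1.0 um on the distance scale) is
#' calibrated so the fish-level control SD pooled across weeks is ~0.65 um
#' and weekly control means span roughly 4-6.2 um; the split between week
#' and fish components is an assumption, tunable here.
#'
#' @param n_weeks Number of screening weeks.
#' @param compounds_per_week Integer range (length 2) of compounds per week.
#' @param fish_per_compound Fish per treatment group.
#' @param rods_per_fish_dg Integer range of rods per fish with a growth
#'   distance.
#' @param rods_per_fish_ds Integer range of rods per fish with a shedding
#'   distance (capped at the number of measured rods; the remainder are
#'   missing D^S).
#' @param week_sd Between-week SD of the weekly baseline, on the distance
#'   scale (um).
#' @param fish_sd SD of fish-level random intercepts (um).
#' @param rod_sd Rod-level residual SD (um).
#' @param lethality_prob Probability that a compound is lethal (no
#'   surviving fish).
#' @param control_label Label of the vehicle-control group.
#' @param base_growth_rate Control growth rate (um/day).
#' @param base_shed_rate Control shedding rate (um/day).
#' @param control_flag_prob Per-image probability of a qualitative flag in
#'   controls (background rate).
#' @param seed Integer seed; per-week child streams are derived from it so
#'   any week can be regenerated independently.
#' @param timeline A [study_timeline()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_weeks = 1,
                              compounds_per_week = c(8L, 32L),
                              fish_per_compound = 3L,
                              rods_per_fish_dg = c(33L, 149L),
                              rods_per_fish_ds = c(24L, 105L),
                              week_sd = 0.55,
                              fish_sd = 0.35,
                              rod_sd = 1.0,
                              lethality_prob = 0.3,
                              control_label = "DMSO",
                              base_growth_rate = 1.25,
                              base_shed_rate = 0.35,
                              control_flag_prob = 0.02,
                              seed = 1L,
                              timeline = study_timeline()) {
  cfg <- list(n_weeks = as.integer(n_weeks),
              compounds_per_week = as.integer(rep_len(compounds_per_week, 2)),
              fish_per_compound = as.integer(fish_per_compound),
              rods_per_fish_dg = as.integer(rep_len(rods_per_fish_dg, 2)),
              rods_per_fish_ds = as.integer(rep_len(rods_per_fish_ds, 2)),
              week_sd = week_sd, fish_sd = fish_sd, rod_sd = rod_sd,
              lethality_prob = lethality_prob,
              control_label = as.character(control_label),
              base_growth_rate = base_growth_rate,
              base_shed_rate = base_shed_rate,
              control_flag_prob = control_flag_prob,
              seed = as.integer(seed),
              timeline = timeline)
  stopifnot(cfg$n_weeks >= 1, cfg$fish_per_compound >= 1,
            inherits(timeline, "study_timeline"))
  if (any(c(cfg$week_sd, cfg$fish_sd, cfg$rod_sd) < 0))
    stop("all SDs must be >= 0")
  if (cfg$lethality_prob < 0 || cfg$lethality_prob > 1)
    stop("lethality_prob must be in [0, 1]")
  for (r in list(cfg$compounds_per_week, cfg$rods_per_fish_dg,
                 cfg$rods_per_fish_ds))
    if (r[1] > r[2] || r[1] < 1) stop("ranges must be non-empty and >= 1")
  if (cfg$base_growth_rate < 0 || cfg$base_shed_rate < 0)
    stop("baseline rates must be >= 0")
  if (cfg$control_flag_prob < 0 || cfg$control_flag_prob > 1)
    stop("control_flag_prob must be in [0, 1]")
  structure(cfg, class = "simulation_config")
}

#' Ground-truth effect table for simulated compounds
#'
#' One row per compound: multiplicative effects on the post-induction
#' growth and shedding rates (multiplicative so percent-change semantics
#' are scale-free), per-image probabilities for the three qualitative
#' content areas, and target/pathway annotation.
#'
#' @param compound_id Character vector of compound identifiers.
#' @param growth_multiplier,shed_multiplier Non-negative multipliers on the
#'   weekly baseline rates (1 = no effect).
#' @param phagosome_prob,misloc_prob,cmz_prob Per-image flag probabilities.
#' @param target,pathway Annotation strings.
#' @return A `data.frame` of compound effects.
#' @export
compound_effects <- function(compound_id,
                             growth_multiplier = 1,
                             shed_multiplier = 1,
                             phagosome_prob = 0.02,
                             misloc_prob = 0.02,
                             cmz_prob = 0.02,
                             target = "none",
                             pathway = "unannotated") {
  eff <- data.frame(compound_id = as.character(compound_id),
                    growth_multiplier = growth_multiplier,
                    shed_multiplier = shed_multiplier,
                    phagosome_prob = phagosome_prob,
                    misloc_prob = misloc_prob,
                    cmz_prob = cmz_prob,
                    target = target, pathway = pathway,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(eff$compound_id)) stop("duplicate compound_id in effects")
  if (any(eff$growth_multiplier < 0) || any(eff$shed_multiplier < 0))
    stop("multipliers must be >= 0")
  probs <- c(eff$phagosome_prob, eff$misloc_prob, eff$cmz_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  eff
}

#' @rdname compound_effects
#' @param n Number of null compounds to generate.
#' @param prefix Identifier prefix.
#' @export
null_effects <- function(n, prefix = "C") {
  compound_effects(sprintf("%s%04d", prefix, seq_len(n)))
}

# Deterministic child seed for a week, kept inside 32-bit integer range.
week_seed <- function(seed, week_index) {
  as.integer((as.double(seed) * 7919 + as.double(week_index) * 104729) %%
               2147483629)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate one screening week
#'
#' Draws a weekly baseline for the growth and shedding rates (normal around
#' the configured control rates with SD `week_sd` divided by the treatment
#' window, i.e. `week_sd` on the distance scale), applies each surviving
#' compound's multiplicative effect, then simulates fish with normal random
#' intercepts and rods with normal residual noise, flooring distances at
#' zero. Shedding distances are missing for a random subset of rods so that
#' missingness is independent of treatment. Lethal compounds contribute no
#' measurement or image rows but appear in the truth table.
#'
#' @param config A [simulation_config()].
#' @param week_index 1-based week number; the week's RNG stream is derived
#'   from `config$seed` and this index.
#' @param effects Effect table from [compound_effects()] for this week's
#'   compounds.
#' @return List with `measurements`, `qualitative` and `truth` data frames.
#' @export
simulate_week <- function(config, week_index, effects) {
  stopifnot(inherits(config, "simulation_config"), nrow(effects) >= 1)
  with_local_seed(week_seed(config$seed, week_index), {
    wk <- sprintf("W%03d", week_index)
    td <- treatment_days(config$timeline)
    g_week <- max(0, stats::rnorm(1, config$base_growth_rate,
                                  config$week_sd / td))
    s_week <- max(0, stats::rnorm(1, config$base_shed_rate,
                                  config$week_sd / td))
    lethal <- stats::rbinom(nrow(effects), 1, config$lethality_prob) == 1

    groups <- data.frame(
      compound_id = c(config$control_label, effects$compound_id),
      treatment_role = c("control", rep("compound", nrow(effects))),
      gmult = c(1, effects$growth_multiplier),
      smult = c(1, effects$shed_multiplier),
      alive = c(TRUE, !lethal),
      stringsAsFactors = FALSE)

    meas <- vector("list", nrow(groups))
    for (i in seq_len(nrow(groups))) {
      if (!groups$alive[i]) next
      mu <- expected_distances(
        renewal_rates(g_week * groups$gmult[i], s_week * groups$smult[i]),
        config$timeline)
      nf <- config$fish_per_compound
      n_dg <- sample_range(nf, config$rods_per_fish_dg)
      n_ds <- pmin(n_dg, sample_range(nf, config$rods_per_fish_ds))
      rows <- vector("list", nf)
      for (f in seq_len(nf)) {
        ig <- stats::rnorm(1, 0, config$fish_sd)
        is_ <- stats::rnorm(1, 0, config$fish_sd)
        dg <- pmax(0, stats::rnorm(n_dg[f], mu$dg + ig, config$rod_sd))
        ds <- rep(NA_real_, n_dg[f])
        keep <- sample(n_dg[f], n_ds[f])
        ds[keep] <- pmax(0, stats::rnorm(n_ds[f], mu$ds + is_, config$rod_sd))
        rows[[f]] <- data.frame(
          week_id = wk, compound_id = groups$compound_id[i],
          treatment_role = groups$treatment_role[i],
          fish_id = sprintf("%s_f%d", groups$compound_id[i], f),
          rod_id = sprintf("r%03d", seq_len(n_dg[f])),
          d_growth_um = round(dg, 4), d_shed_um = round(ds, 4),
          stringsAsFactors = FALSE)
      }
      meas[[i]] <- do.call(rbind, rows)
    }
    measurements <- do.call(rbind, meas[!vapply(meas, is.null, logical(1))])
    rownames(measurements) <- NULL

    # qualitative flags: 3 photoreceptor-layer images for phagosome and
    # mislocalization content areas, a single CMZ image
    qual <- vector("list", nrow(groups))
    for (i in seq_len(nrow(groups))) {
      if (!groups$alive[i]) next
      if (groups$treatment_role[i] == "control") {
        p <- rep(config$control_flag_prob, 3)
      } else {
        j <- match(groups$compound_id[i], effects$compound_id)
        p <- c(effects$phagosome_prob[j], effects$misloc_prob[j],
               effects$cmz_prob[j])
      }
      area <- c(rep("phagosome", 3), rep("mislocalization", 3), "cmz")
      img <- c(1:3, 1:3, 1L)
      pr <- c(rep(p[1], 3), rep(p[2], 3), p[3])
      qual[[i]] <- data.frame(
        week_id = wk, compound_id = groups$compound_id[i],
        content_area = area, image_index = img,
        flag = stats::rbinom(length(pr), 1, pr) == 1,
        stringsAsFactors = FALSE)
    }
    qualitative <- do.call(rbind, qual[!vapply(qual, is.null, logical(1))])
    rownames(qualitative) <- NULL

    truth <- data.frame(
      week_id = wk, compound_id = effects$compound_id,
      growth_multiplier = effects$growth_multiplier,
      shed_multiplier = effects$shed_multiplier,
      lethal = lethal,
      week_growth_rate = g_week, week_shed_rate = s_week,
      stringsAsFactors = FALSE)

    list(measurements = measurements, qualitative = qualitative,
         truth = truth)
  })
}

#' Simulate a multi-week screen
#'
#' Draws the number of compounds for each week, assigns effects to weeks in
#' order (disjointly), and concatenates [simulate_week()] over all weeks.
#' Week streams are derived deterministically from the configured seed, so
#' the same configuration always yields byte-identical tables.
#'
#' @param config A [simulation_config()].
#' @param effects Optional effect table; if `NULL`, null compounds (all
#'   multipliers 1) are generated to fill the screen. If supplied it must
#'   contain at least as many compounds as the drawn weekly counts require.
#' @return An object of class `ros_screen`: list with `measurements`,
#'   `qualitative`, `annotations`, `truth` data frames and the `config`.
#' @export
simulate_screen <- function(config, effects = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  counts <- with_local_seed(config$seed,
                            sample_range(config$n_weeks,
                                         config$compounds_per_week))
  total <- sum(counts)
  if (is.null(effects)) effects <- null_effects(total)
  if (nrow(effects) < total)
    stop(sprintf("need %d compounds for the drawn weekly counts, got %d",
                 total, nrow(effects)))
  offset <- 0L
  weeks <- vector("list", config$n_weeks)
  for (w in seq_len(config$n_weeks)) {
    eff_w <- effects[seq_len(counts[w]) + offset, , drop = FALSE]
    offset <- offset + counts[w]
    weeks[[w]] <- simulate_week(config, w, eff_w)
  }
  used <- effects[seq_len(offset), , drop = FALSE]
  annotations <- data.frame(compound_id = used$compound_id,
                            name = used$compound_id,
                            target = used$target, pathway = used$pathway,
                            stringsAsFactors = FALSE)
  out <- list(
    measurements = do.call(rbind, lapply(weeks, `[[`, "measurements")),
    qualitative = do.call(rbind, lapply(weeks, `[[`, "qualitative")),
    annotations = annotations,
    truth = do.call(rbind, lapply(weeks, `[[`, "truth")),
    config = config)
  rownames(out$measurements) <- rownames(out$qualitative) <-
    rownames(out$truth) <- NULL
  class(out) <- "ros_screen"
  out
}

#' @export
print.ros_screen <- function(x, ...) {
  cat(sprintf(
    "Synthetic renewal screen: %d week(s), %d compound(s) (%d lethal), %d measurement rows\n",
    length(unique(x$truth$week_id)), nrow(x$truth), sum(x$truth$lethal),
    nrow(x$measurements)))
  invisible(x)
}
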