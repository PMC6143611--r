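# Hit calling: the dual biological/statistical thresholds, qualitative
# at-least-one-image rules, per-pathway tallies, and the full screen report.

#' Hit-calling thresholds
#'
#' The biological threshold is a percent change relative to the
#' week-matched control (non-strict, "at least"); the statistical tiers are
#' strict upper bounds on the Dunnett-adjusted p-value. A primary hit must
#' clear both the percent and the primary p threshold.
#'
#' @param pct_threshold Biological threshold in percent (default 20).
#' @param p_primary,p_secondary,p_tertiary Significance tiers (defaults
#'   0.001, 0.01, 0.05; must be increasing).
#' @return An object of class `hit_thresholds`.
#' @export
hit_thresholds <- function(pct_threshold = 20, p_primary = 0.001,
                           p_secondary = 0.01, p_tertiary = 0.05) {
  if (!(p_primary < p_secondary && p_secondary < p_tertiary))
    stop("require p_primary < p_secondary < p_tertiary")
  if (pct_threshold <= 0) stop("pct_threshold must be > 0")
  structure(list(pct_threshold = pct_threshold, p_primary = p_primary,
                 p_secondary = p_secondary, p_tertiary = p_tertiary),
            class = "hit_thresholds")
}

#' Classify one compound-vs-control comparison
#'
#' Returns `"primary-increase"`/`"primary-decrease"` when the absolute
#' percent change meets the biological threshold (non-strict) and the
#' adjusted p-value is below the primary tier (strict);
#' `"same-target-followup"` when the comparison misses primary but is
#' significant at any tier and a primary hit in the same direction already
#' exists for the same target; `"tiered-increase"`/`"tiered-decrease"` when
#' significant at the secondary or tertiary tier without such a companion;
#' `"none"` otherwise. Classification uses the full-precision percent
#' change; integer rounding is reporting-only.
#'
#' @param result A single comparison: list or one-row data frame with
#'   `percent_change` and `p_adj`.
#' @param thresholds A [hit_thresholds()].
#' @param same_target_primary_exists Whether a primary hit with the same
#'   target and the same direction of effect exists for this metric.
#' @return Call label (character scalar).
#' @export
call_distance_hit <- function(result, thresholds = hit_thresholds(),
                              same_target_primary_exists = FALSE) {
  stopifnot(inherits(thresholds, "hit_thresholds"))
  pct <- result$percent_change
  p <- result$p_adj
  stopifnot(length(pct) == 1, length(p) == 1)
  if (is.na(pct) || is.na(p)) return("none")
  dir <- if (pct >= 0) "increase" else "decrease"
  if (abs(pct) >= thresholds$pct_threshold && p < thresholds$p_primary)
    return(paste0("primary-", dir))
  if (p < thresholds$p_tertiary) {
    if (isTRUE(same_target_primary_exists)) return("same-target-followup")
    return(paste0("tiered-", dir))
  }
  "none"
}

#' Qualitative content-area hit from per-image flags
#'
#' A compound is a qualitative hit if at least one of its images shows the
#' phenotype. Phagosome accumulation and Rhodopsin mislocalization are
#' scored on up to three photoreceptor-layer images; the ciliary marginal
#' zone on a single representative image.
#'
#' @param image_flags Logical vector of per-image flags (length 1-3).
#' @return `TRUE` if any image is flagged.
#' @export
qualitative_hit <- function(image_flags) {
  if (length(image_flags) == 0) stop("no image flags supplied")
  if (!is.logical(image_flags) || anyNA(image_flags))
    stop("image flags must be TRUE/FALSE")
  any(image_flags)
}

#' Tally hit compounds by annotated pathway
#'
#' Counts the compounds whose call matches a content area, grouped by
#' pathway annotation. Distance content areas count primary calls of the
#' matching direction; qualitative areas count flagged compounds. Missing
#' annotations are counted under `"unannotated"`. Ordering is
#' deterministic: count descending, then pathway label.
#'
#' @param hits Hit-record data frame from [build_report()] (`$hits`).
#' @param content_area One of `"growth-increase"`, `"growth-decrease"`,
#'   `"shed-increase"`, `"shed-decrease"`, `"phagosome"`,
#'   `"mislocalization"`, `"cmz"`.
#' @return Data frame with columns `pathway`, `count`.
#' @export
tally_by_pathway <- function(hits, content_area = c(
    "growth-increase", "growth-decrease", "shed-increase", "shed-decrease",
    "phagosome", "mislocalization", "cmz")) {
  content_area <- match.arg(content_area)
  sel <- switch(content_area,
    "growth-increase" = hits$dg_call %in% "primary-increase",
    "growth-decrease" = hits$dg_call %in% "primary-decrease",
    "shed-increase"   = hits$ds_call %in% "primary-increase",
    "shed-decrease"   = hits$ds_call %in% "primary-decrease",
    "phagosome"       = hits$phagosome_hit %in% TRUE,
    "mislocalization" = hits$misloc_hit %in% TRUE,
    "cmz"             = hits$cmz_hit %in% TRUE)
  sel <- sel & !hits$lethal
  if (!any(sel)) {
    return(data.frame(pathway = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  pw <- hits$pathway[sel]
  pw[is.na(pw) | pw == ""] <- "unannotated"
  tab <- table(pw)
  out <- data.frame(pathway = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$pathway), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

# Run fit -> contrasts -> Dunnett for one week and metric; returns a
# ros_comparisons table (possibly empty) with week/metric columns added.
week_comparisons <- function(meas_week, metric, dunnett_points = 2e5,
                             dunnett_seed = 1L) {
  fit <- fit_random_intercept(meas_week, metric)
  ctr <- contrast_control(fit)
  if (nrow(ctr$table) == 0) {
    cmp <- empty_comparisons()
    cmp$control_mean <- cmp$treated_mean <- cmp$percent_change <- numeric(0)
  } else {
    df_all <- satterthwaite_df(fit, ctr)
    cmp <- dunnett_adjust(ctr, df = min(df_all), n_points = dunnett_points,
                          seed = dunnett_seed)
  }
  cmp$week_id <- rep(fit$week_id, nrow(cmp))
  cmp$metric <- rep(metric, nrow(cmp))
  cmp
}

#' Build the full screen report
#'
#' Runs the whole pipeline: per week and metric, a random-intercept REML
#' fit, control contrasts with a common (minimum) Satterthwaite df, and
#' Dunnett-adjusted p-values; then distance hit calls with same-target
#' follow-up resolution, qualitative hit calls, pooled control benchmarks,
#' and per-pathway tallies for all seven content-area views. Compounds
#' present in the annotation table but absent from the measurements (no
#' surviving fish) are marked lethal and receive no distance calls.
#'
#' @param measurements Measurement table (schema of [read_measurements()]).
#' @param annotations Optional annotation table (`compound_id`, `name`,
#'   `target`, `pathway`); defaults to unannotated compounds observed in
#'   the measurements.
#' @param qualitative Optional per-image flag table (`week_id`,
#'   `compound_id`, `content_area`, `image_index`, `flag`).
#' @param thresholds A [hit_thresholds()].
#' @param timeline A [study_timeline()] (carried into the report for
#'   rate conversions).
#' @param dunnett_points,dunnett_seed Quasi-Monte-Carlo settings passed to
#'   [dunnett_adjust()].
#' @return An object of class `ros_screen_report`: list with `comparisons`
#'   (per compound x metric), `hits` (one row per compound), `benchmarks`
#'   (pooled controls for both metrics), `tallies` (named list of pathway
#'   tables), `thresholds`, `timeline`.
#' @export
build_report <- function(measurements, annotations = NULL,
                         qualitative = NULL,
                         thresholds = hit_thresholds(),
                         timeline = study_timeline(),
                         dunnett_points = 2e5, dunnett_seed = 1L) {
  check_measurement_frame(measurements)
  weeks <- unique(measurements$week_id)
  no_control <- weeks[!vapply(weeks, function(w) {
    any(measurements$treatment_role[measurements$week_id == w] == "control")
  }, logical(1))]
  if (length(no_control) > 0)
    stop("week(s) without a control group: ",
         paste(no_control, collapse = ", "))

  comparisons <- list()
  for (w in weeks) {
    mw <- measurements[measurements$week_id == w, , drop = FALSE]
    for (metric in c("growth", "shed")) {
      col <- paste0("d_", metric, "_um")
      if (all(is.na(mw[[col]]))) next
      comparisons[[paste(w, metric)]] <-
        week_comparisons(mw, metric, dunnett_points, dunnett_seed)
    }
  }
  comparisons <- do.call(rbind, comparisons)
  rownames(comparisons) <- NULL

  screened <- unique(measurements$compound_id[
    measurements$treatment_role == "compound"])
  if (is.null(annotations)) {
    annotations <- data.frame(compound_id = screened, name = screened,
                              target = NA_character_,
                              pathway = NA_character_,
                              stringsAsFactors = FALSE)
  }
  compounds <- annotations$compound_id
  lethal <- !(compounds %in% screened)

  hits <- data.frame(
    compound_id = compounds,
    name = annotations$name,
    target = annotations$target,
    pathway = annotations$pathway,
    lethal = lethal,
    stringsAsFactors = FALSE)
  hits$week_id <- comparisons$week_id[match(compounds,
                                            comparisons$compound_id)]

  for (metric in c("growth", "shed")) {
    pre <- if (metric == "growth") "dg" else "ds"
    cm <- comparisons[comparisons$metric == metric, , drop = FALSE]
    idx <- match(compounds, cm$compound_id)
    hits[[paste0(pre, "_percent_change")]] <- cm$percent_change[idx]
    hits[[paste0(pre, "_p_adj")]] <- cm$p_adj[idx]
    hits[[paste0(pre, "_tier")]] <- cm$tier[idx]

    # first pass without same-target context, then resolve follow-ups
    call1 <- rep("none", length(compounds))
    for (i in seq_along(compounds)) {
      if (lethal[i] || is.na(idx[i])) next
      call1[i] <- call_distance_hit(cm[idx[i], ], thresholds, FALSE)
    }
    primaries <- grepl("^primary-", call1)
    for (i in seq_along(compounds)) {
      if (lethal[i] || is.na(idx[i]) || primaries[i]) next
      tg <- hits$target[i]
      if (is.na(tg) || tg == "" || tg == "none") next
      dir_i <- sign(cm$percent_change[idx[i]])
      companion <- any(primaries & hits$target == tg &
                         sign(hits[[paste0(pre, "_percent_change")]]) == dir_i,
                       na.rm = TRUE)
      call1[i] <- call_distance_hit(cm[idx[i], ], thresholds, companion)
    }
    hits[[paste0(pre, "_call")]] <- call1
  }

  for (area in c("phagosome", "mislocalization", "cmz")) {
    colname <- switch(area, phagosome = "phagosome_hit",
                      mislocalization = "misloc_hit", cmz = "cmz_hit")
    hits[[colname]] <- NA
    if (!is.null(qualitative)) {
      for (i in seq_along(compounds)) {
        if (lethal[i]) next
        fl <- qualitative$flag[qualitative$compound_id == compounds[i] &
                                 qualitative$content_area == area]
        if (length(fl) > 0) hits[[colname]][i] <- qualitative_hit(fl)
      }
    }
  }

  controls <- measurements[measurements$treatment_role == "control", ,
                           drop = FALSE]
  benchmarks <- list(
    growth = if (any(!is.na(controls$d_growth_um)))
      pool_controls(controls, "growth") else NULL,
    shed = if (any(!is.na(controls$d_shed_um)))
      pool_controls(controls, "shed") else NULL)

  areas <- c("growth-increase", "growth-decrease", "shed-increase",
             "shed-decrease", "phagosome", "mislocalization", "cmz")
  tallies <- stats::setNames(
    lapply(areas, function(a) tally_by_pathway(hits, a)), areas)

  structure(list(comparisons = comparisons, hits = hits,
                 benchmarks = benchmarks, tallies = tallies,
                 thresholds = thresholds, timeline = timeline),
            class = "ros_screen_report")
}

#' @export
print.ros_screen_report <- function(x, ...) {
  h <- x$hits
  cat(sprintf("Renewal screen report: %d compound(s), %d lethal\n",
              nrow(h), sum(h$lethal)))
  for (m in c("dg", "ds")) {
    calls <- h[[paste0(m, "_call")]]
    lab <- if (m == "dg") "D^G (growth)" else "D^S (shedding)"
    cat(sprintf("  %s: %d primary, %d tiered, %d same-target follow-up\n",
                lab, sum(grepl("^primary", calls)),
                sum(grepl("^tiered", calls)),
                sum(calls == "same-target-followup")))
  }
  cat(sprintf("  qualitative hits: phagosome %d, mislocalization %d, CMZ %d\n",
              sum(h$phagosome_hit %in% TRUE), sum(h$misloc_hit %in% TRUE),
              sum(h$cmz_hit %in% TRUE)))
  if (!is.null(x$benchmarks$growth)) print(x$benchmarks$growth)
  if (!is.null(x$benchmarks$shed)) print(x$benchmarks$shed)
  invisible(x)
}
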