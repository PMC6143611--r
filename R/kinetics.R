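# Pulse-chase renewal kinetics: mapping stripe-position observables to
# growth/shedding rates and the control-benchmark arithmetic.

#' Pulse-chase study timeline
#'
#' Describes the clock of a stripe-based renewal assay: when rods are born,
#' when the membrane-tethered fluorescent stripe is induced by heat shock,
#' and when fish are fixed. Outer segment growth before induction is assumed
#' linear at `pre_rate`.
#'
#' The defaults (3, 6, 10 dpf, 1.6 um/day) encode the standard larval screen
#' design: rod births from 3 dpf, heat shock at 6 dpf, fixation at 10 dpf,
#' giving 3 days of pre-label growth (4.8 um at 1.6 um/day) and a 4-day
#' treatment window.
#'
#' @param birth_dpf Day post fertilization when rod outer segment growth
#'   starts (integer-valued, days).
#' @param heatshock_dpf Day of heat-shock induction of the stripe label.
#' @param fix_dpf Day of fixation.
#' @param pre_rate Outer segment growth rate before heat shock (um/day).
#' @return An object of class `study_timeline`.
#' @examples
#' tl <- study_timeline()
#' treatment_days(tl)  # 4
#' pre_growth(tl)      # 4.8
#' @export
study_timeline <- function(birth_dpf = 3, heatshock_dpf = 6, fix_dpf = 10,
                           pre_rate = 1.6) {
  stopifnot(is.numeric(birth_dpf), is.numeric(heatshock_dpf),
            is.numeric(fix_dpf), is.numeric(pre_rate),
            length(birth_dpf) == 1, length(heatshock_dpf) == 1,
            length(fix_dpf) == 1, length(pre_rate) == 1)
  if (!(birth_dpf < heatshock_dpf && heatshock_dpf < fix_dpf))
    stop("invalid timeline: require birth_dpf < heatshock_dpf < fix_dpf")
  if (pre_rate < 0)
    stop("invalid timeline: pre_rate must be >= 0")
  structure(list(birth_dpf = birth_dpf, heatshock_dpf = heatshock_dpf,
                 fix_dpf = fix_dpf, pre_rate = pre_rate),
            class = "study_timeline")
}

#' @rdname study_timeline
#' @param timeline A `study_timeline`.
#' @export
treatment_days <- function(timeline) {
  stopifnot(inherits(timeline, "study_timeline"))
  timeline$fix_dpf - timeline$heatshock_dpf
}

#' @rdname study_timeline
#' @export
pre_growth <- function(timeline) {
  stopifnot(inherits(timeline, "study_timeline"))
  timeline$pre_rate * (timeline$heatshock_dpf - timeline$birth_dpf)
}

#' @export
print.study_timeline <- function(x, ...) {
  cat(sprintf(
    "Pulse-chase timeline: birth %g dpf, heat shock %g dpf, fixation %g dpf\n",
    x$birth_dpf, x$heatshock_dpf, x$fix_dpf))
  cat(sprintf("  pre-label growth %g um/day over %g days (%g um)\n",
              x$pre_rate, x$heatshock_dpf - x$birth_dpf, pre_growth(x)))
  invisible(x)
}

#' Post-induction renewal rates
#'
#' Growth rate at the outer segment base and shedding rate at the tip,
#' both per day, after heat-shock induction of the stripe.
#'
#' A negative `shed_rate` can arise from inference on noisy means (the
#' observed shedding distance exceeds the assumed pre-label growth); it is
#' kept as-is and flagged via the `negative_shed` field rather than clamped,
#' so simulation-vs-inference round trips stay honest. For simulation a
#' non-negative shed rate is required.
#'
#' @param growth_rate Growth at the base (um/day), must be >= 0.
#' @param shed_rate Shedding at the tip (um/day).
#' @return An object of class `renewal_rates` with fields `growth_rate`,
#'   `shed_rate`, `negative_shed`.
#' @export
renewal_rates <- function(growth_rate, shed_rate) {
  stopifnot(is.numeric(growth_rate), is.numeric(shed_rate),
            length(growth_rate) == 1, length(shed_rate) == 1)
  if (growth_rate < 0) stop("growth_rate must be >= 0")
  structure(list(growth_rate = growth_rate, shed_rate = shed_rate,
                 negative_shed = shed_rate < 0),
            class = "renewal_rates")
}

#' @export
print.renewal_rates <- function(x, ...) {
  cat(sprintf("Renewal rates: growth %.4f um/day, shed %.4f um/day%s\n",
              x$growth_rate, x$shed_rate,
              if (x$negative_shed) " (negative shed rate, flagged)" else ""))
  invisible(x)
}

#' Expected stripe distances under given renewal rates
#'
#' Maps renewal rates to the two observables of the assay: the growth
#' distance D^G (base of the outer segment to the stripe; growth after heat
#' shock) and the shedding distance D^S (stripe to the tip; pre-label growth
#' minus post-label shedding). D^S is floored at zero — the stripe cannot
#' move past the tip — and the flooring is reported in `ds_truncated`.
#'
#' @param rates A `renewal_rates` object with `shed_rate >= 0`.
#' @param timeline A `study_timeline`.
#' @return List with `dg`, `ds` (um) and logical `ds_truncated`.
#' @examples
#' expected_distances(renewal_rates(1.25, 0.35), study_timeline())
#' @export
expected_distances <- function(rates, timeline = study_timeline()) {
  stopifnot(inherits(rates, "renewal_rates"),
            inherits(timeline, "study_timeline"))
  if (rates$shed_rate < 0)
    stop("expected_distances requires shed_rate >= 0")
  td <- treatment_days(timeline)
  dg <- rates$growth_rate * td
  ds_raw <- pre_growth(timeline) - rates$shed_rate * td
  list(dg = dg, ds = max(0, ds_raw), ds_truncated = ds_raw < 0)
}

#' Infer renewal rates from mean stripe distances
#'
#' Inverts the pulse-chase model: growth rate is the mean growth distance
#' divided by the treatment window; shedding rate is the pre-label growth
#' minus the mean shedding distance, divided by the treatment window. If the
#' observed D^S exceeds the assumed pre-label growth the inferred shed rate
#' is negative; it is returned as-is with `negative_shed = TRUE`.
#'
#' @param dg_mean Mean growth distance (um), >= 0.
#' @param ds_mean Mean shedding distance (um), >= 0.
#' @param timeline A `study_timeline`.
#' @return A `renewal_rates` object.
#' @examples
#' infer_rates(5.01, 3.40)  # growth 1.25 um/day (2 d.p.), shed 0.35 um/day
#' @export
infer_rates <- function(dg_mean, ds_mean, timeline = study_timeline()) {
  stopifnot(is.numeric(dg_mean), is.numeric(ds_mean),
            length(dg_mean) == 1, length(ds_mean) == 1,
            inherits(timeline, "study_timeline"))
  if (dg_mean < 0 || ds_mean < 0)
    stop("distance means must be >= 0")
  td <- treatment_days(timeline)
  if (td <= 0) stop("division error: fixation must be after heat shock")
  renewal_rates(dg_mean / td, (pre_growth(timeline) - ds_mean) / td)
}

#' Shedding-distance threshold and its suppression equivalent
#'
#' Converts a percent increase in the shedding-distance benchmark into the
#' equivalent amount of material shed: a larger D^S means less was shed from
#' the tip. Returns the thresholded D^S, the total shed over the treatment
#' window at that threshold, and the per-day shed rate.
#'
#' @param benchmark_ds Benchmark mean shedding distance (um), > 0.
#' @param pct_increase Percent increase applied to the benchmark, >= 0.
#' @param timeline A `study_timeline`.
#' @return List with `ds_threshold`, `shed_total` (um over the window) and
#'   `shed_per_day` (um/day).
#' @examples
#' # +20% on a 3.40 um benchmark: D^S 4.08 um, 0.72 um shed, 0.18 um/day
#' suppression_equivalent(3.40, 20)
#' @export
suppression_equivalent <- function(benchmark_ds, pct_increase,
                                   timeline = study_timeline()) {
  stopifnot(is.numeric(benchmark_ds), is.numeric(pct_increase),
            length(benchmark_ds) == 1, length(pct_increase) == 1,
            inherits(timeline, "study_timeline"))
  if (benchmark_ds <= 0) stop("benchmark_ds must be > 0")
  if (pct_increase < 0) stop("pct_increase must be >= 0")
  ds_threshold <- benchmark_ds * (1 + pct_increase / 100)
  shed_total <- pre_growth(timeline) - ds_threshold
  list(ds_threshold = ds_threshold, shed_total = shed_total,
       shed_per_day = shed_total / treatment_days(timeline))
}

#' Percent change of a treated mean relative to its control
#'
#' Returns the signed percent change at full precision; use
#' [round_percent()] for the integer form used in reporting (rounded half
#' away from zero).
#'
#' @param treated_mean Treated group mean (um).
#' @param control_mean Control group mean (um), must be > 0.
#' @return Signed percent change (full precision).
#' @examples
#' round_percent(percent_change(5.88, 4.40))  # +34
#' @export
percent_change <- function(treated_mean, control_mean) {
  stopifnot(is.numeric(treated_mean), is.numeric(control_mean))
  if (any(control_mean <= 0))
    stop("invalid control: control_mean must be > 0")
  100 * (treated_mean - control_mean) / control_mean
}

#' @rdname percent_change
#' @param pct Percent value(s) to round.
#' @export
round_percent <- function(pct) {
  # round half away from zero (base round() rounds half to even)
  sign(pct) * floor(abs(pct) + 0.5)
}

#' Pool vehicle-control measurements into a study-wide benchmark
#'
#' Pools control fish across all weeks of a screen. The unit of replication
#' is the fish, so the benchmark mean is the grand mean of fish-level means
#' and the benchmark SD is the standard deviation across fish-level means;
#' rod-level mean and SD are also reported. With a single fish the SD is
#' defined as 0 and flagged.
#'
#' @param measurements Measurement table (see [read_measurements()] for the
#'   schema); every row must be a control record with a non-missing value
#'   for the requested metric.
#' @param metric `"growth"` (D^G) or `"shed"` (D^S).
#' @return An object of class `ros_benchmark` with fields `metric`, `mean`,
#'   `sd`, `n_rods`, `n_fish`, `rod_mean`, `rod_sd`, `single_fish`.
#' @export
pool_controls <- function(measurements, metric = c("growth", "shed")) {
  metric <- match.arg(metric)
  col <- paste0("d_", metric, "_um")
  check_measurement_frame(measurements)
  if (!all(measurements$treatment_role == "control"))
    stop("pool_controls expects control records only")
  x <- measurements[!is.na(measurements[[col]]), , drop = FALSE]
  if (nrow(x) == 0) stop("empty benchmark: no control measurements for ", metric)
  fish <- interaction(x$week_id, x$compound_id, x$fish_id, drop = TRUE)
  fish_means <- tapply(x[[col]], fish, mean)
  n_fish <- length(fish_means)
  structure(list(
    metric = metric,
    mean = mean(fish_means),
    sd = if (n_fish > 1) stats::sd(fish_means) else 0,
    n_rods = nrow(x),
    n_fish = n_fish,
    rod_mean = mean(x[[col]]),
    rod_sd = if (nrow(x) > 1) stats::sd(x[[col]]) else 0,
    single_fish = n_fish == 1
  ), class = "ros_benchmark")
}

#' @export
print.ros_benchmark <- function(x, ...) {
  cat(sprintf(
    "Control benchmark [%s]: mean %.3f um (fish-level SD %.3f um), %d rods from %d fish\n",
    x$metric, x$mean, x$sd, x$n_rods, x$n_fish))
  cat(sprintf("  rod-level: mean %.3f um, SD %.3f um\n", x$rod_mean, x$rod_sd))
  invisible(x)
}
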