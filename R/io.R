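# Comma-separated table formats, configuration files, and validation.
# Distances are stored in micrometres with up to 4 decimals.

measurement_cols <- c("week_id", "compound_id", "treatment_role",
                      "fish_id", "rod_id", "d_growth_um", "d_shed_um")

check_measurement_frame <- function(x) {
  if (!is.data.frame(x) || !all(measurement_cols %in% names(x)))
    stop("measurement table must have columns: ",
         paste(measurement_cols, collapse = ", "))
  invisible(x)
}

#' Read a per-rod measurement table
#'
#' Reads comma-separated text with header
#' `week_id,compound_id,treatment_role,fish_id,rod_id,d_growth_um,d_shed_um`.
#' Empty distance cells become missing values; distances are in
#' micrometres. Every row must carry at least one of the two distances,
#' both non-negative, and `treatment_role` must be `control` or `compound`.
#' Validation errors name the offending file line (header is line 1).
#'
#' @param path Path to the CSV file.
#' @return Data frame of typed measurement rows.
#' @export
read_measurements <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(week_id = "character",
                                      compound_id = "character",
                                      treatment_role = "character",
                                      fish_id = "character",
                                      rod_id = "character",
                                      d_growth_um = "numeric",
                                      d_shed_um = "numeric"))
  if (!identical(names(x), measurement_cols))
    stop("unexpected header in ", path, "; expected: ",
         paste(measurement_cols, collapse = ","))
  line <- seq_len(nrow(x)) + 1L
  bad_role <- !(x$treatment_role %in% c("control", "compound"))
  if (any(bad_role))
    stop("unknown treatment_role ",
         paste(unique(x$treatment_role[bad_role]), collapse = ", "),
         " at line(s) ", paste(line[bad_role], collapse = ", "))
  neg <- (x$d_growth_um < 0 & !is.na(x$d_growth_um)) |
    (x$d_shed_um < 0 & !is.na(x$d_shed_um))
  if (any(neg))
    stop("negative distance at line(s) ", paste(line[neg], collapse = ", "))
  none <- is.na(x$d_growth_um) & is.na(x$d_shed_um)
  if (any(none))
    stop("row(s) with neither distance at line(s) ",
         paste(line[none], collapse = ", "))
  x
}

#' @rdname read_measurements
#' @param measurements Measurement data frame to write.
#' @export
write_measurements <- function(measurements, path) {
  check_measurement_frame(measurements)
  out <- measurements[, measurement_cols]
  out$d_growth_um <- round(out$d_growth_um, 4)
  out$d_shed_um <- round(out$d_shed_um, 4)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read compound annotation and qualitative-flag tables
#'
#' Annotations: `compound_id,name,target,pathway`. Qualitative flags:
#' `week_id,compound_id,content_area,image_index,flag` with `flag` given as
#' `TRUE`/`FALSE` and `content_area` one of `phagosome`,
#' `mislocalization`, `cmz`.
#'
#' @param path Path to the CSV file.
#' @return Data frame.
#' @export
read_annotations <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("compound_id", "name", "target", "pathway")
  if (!all(need %in% names(x)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  x[, need]
}

#' @rdname read_annotations
#' @export
read_qualitative <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("week_id", "compound_id", "content_area", "image_index", "flag")
  if (!all(need %in% names(x)))
    stop("qualitative table must have columns: ",
         paste(need, collapse = ", "))
  bad <- !(x$content_area %in% c("phagosome", "mislocalization", "cmz"))
  if (any(bad))
    stop("unknown content_area at line(s) ",
         paste(which(bad) + 1L, collapse = ", "))
  x$flag <- as.logical(x$flag)
  if (anyNA(x$flag)) stop("flag column must be TRUE/FALSE")
  x[, need]
}

#' Write all tables of a simulated screen
#'
#' Writes `measurements.csv`, `qualitative.csv`, `annotations.csv` and
#' `truth.csv` into a directory.
#'
#' @param screen A `ros_screen` from [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_screen <- function(screen, dir) {
  stopifnot(inherits(screen, "ros_screen"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_measurements(screen$measurements, file.path(dir, "measurements.csv"))
  utils::write.csv(screen$qualitative, file.path(dir, "qualitative.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(screen$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(screen$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write the hit report table
#'
#' One row per compound and metric with the comparison statistics, tier,
#' call, qualitative hits and lethality. Lethal compounds appear with empty
#' statistics.
#'
#' @param report A `ros_screen_report` from [build_report()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_hit_report <- function(report, path) {
  stopifnot(inherits(report, "ros_screen_report"))
  h <- report$hits
  rows <- list()
  for (metric in c("growth", "shed")) {
    pre <- if (metric == "growth") "dg" else "ds"
    cm <- report$comparisons
    cm <- cm[cm$metric == metric, , drop = FALSE]
    idx <- match(h$compound_id, cm$compound_id)
    rows[[metric]] <- data.frame(
      compound_id = h$compound_id, name = h$name, target = h$target,
      pathway = h$pathway, metric = metric,
      control_mean_um = round(cm$control_mean[idx], 4),
      treated_mean_um = round(cm$treated_mean[idx], 4),
      percent_change = round_percent(cm$percent_change[idx]),
      se_um = round(cm$se[idx], 4),
      df = round(cm$df[idx], 2),
      p_raw = signif(cm$p_raw[idx], 6),
      p_adj = signif(cm$p_adj[idx], 6),
      tier = cm$tier[idx],
      call = h[[paste0(pre, "_call")]],
      phagosome_hit = h$phagosome_hit,
      misloc_hit = h$misloc_hit,
      cmz_hit = h$cmz_hit,
      lethal = h$lethal,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$compound_id, out$metric), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

config_blocks <- list(
  timeline = c("birth_dpf", "heatshock_dpf", "fix_dpf",
               "pre_rate_um_per_day"),
  thresholds = c("pct_threshold", "p_primary", "p_secondary", "p_tertiary"),
  simulation = c("n_weeks", "compounds_per_week", "fish_per_compound",
                 "rods_per_fish_dg", "rods_per_fish_ds", "week_sd",
                 "fish_sd", "rod_sd", "lethality_prob", "control_label",
                 "base_growth_rate", "base_shed_rate", "control_flag_prob",
                 "seed"),
  top = c("output_dir", "log_level"))

#' Read a screen configuration file
#'
#' YAML with up to three blocks (`timeline`, `thresholds`, `simulation`)
#' plus optional top-level `output_dir` and `log_level`. Unknown keys are
#' rejected with a message naming them. Each block is validated by the
#' corresponding constructor.
#'
#' @param path Path to the YAML configuration.
#' @return List with `timeline` ([study_timeline()]), `thresholds`
#'   ([hit_thresholds()]), `simulation` ([simulation_config()]),
#'   `output_dir`, `log_level`.
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown_top <- setdiff(names(raw),
                         c("timeline", "thresholds", "simulation",
                           config_blocks$top))
  if (length(unknown_top) > 0)
    stop("unknown configuration key(s): ",
         paste(unknown_top, collapse = ", "))
  for (blk in c("timeline", "thresholds", "simulation")) {
    extra <- setdiff(names(raw[[blk]]), config_blocks[[blk]])
    if (length(extra) > 0)
      stop("unknown key(s) in block '", blk, "': ",
           paste(extra, collapse = ", "))
  }
  tl_args <- raw$timeline
  if (!is.null(tl_args$pre_rate_um_per_day)) {
    tl_args$pre_rate <- tl_args$pre_rate_um_per_day
    tl_args$pre_rate_um_per_day <- NULL
  }
  timeline <- do.call(study_timeline, tl_args %||% list())
  thresholds <- do.call(hit_thresholds, raw$thresholds %||% list())
  sim_args <- raw$simulation %||% list()
  sim_args$timeline <- timeline
  simulation <- do.call(simulation_config, sim_args)
  list(timeline = timeline, thresholds = thresholds,
       simulation = simulation,
       output_dir = raw$output_dir %||% ".",
       log_level = raw$log_level %||% "info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable hash of a configuration
#'
#' MD5 of a canonical serialization in which list keys are recursively
#' sorted, so the hash is invariant to key order in the source file.
#'
#' @param config Any R list (e.g. from [read_screen_config()] or the raw
#'   YAML).
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      nm <- names(x)
      if (!is.null(nm)) x <- x[order(nm)]
      lapply(x, canon)
    } else x
  }
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(canon(unclass_all(config))), tmp)
  unname(tools::md5sum(tmp))
}

unclass_all <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_all) else x
}
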