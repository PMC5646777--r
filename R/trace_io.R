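# Reading, validating and writing body-temperature traces and cohort tables.
# Internally a trace keeps time as seconds since experiment onset; timestamps
# are serialized as ISO-8601 UTC so duration arithmetic never crosses a
# timezone.

# iButton DS1922L operating range
.TB_LOGGER_RANGE <- c(-40, 85)

#' Construct a body-temperature trace
#'
#' A `tb_trace` holds one individual's regularly sampled body-temperature
#' (Tb) series together with the experiment window it is analysed over.
#' Sampling-interval violations (missing samples) are recorded as gap
#' annotations; they are never silently repaired. How gaps are treated during
#' segmentation is decided by the `gap_policy` of [detect_bouts()].
#'
#' @param individual_id Character scalar identifying the animal.
#' @param time Sample timestamps: `POSIXct`, or numeric seconds since
#'   `t0`. Must be strictly increasing.
#' @param tb_celsius Numeric body temperatures, one per timestamp, within the
#'   logger range \eqn{[-40, 85]} degC.
#' @param t0,t1 Experiment onset / end. Defaults: first and last sample time.
#'   `t0` must not be after the first sample. Analysis is restricted to
#'   `[t0, t1]`.
#' @param sampling_interval_min Nominal sampling interval in minutes
#'   (default 90, the logger programming used throughout). Consecutive gaps
#'   differing from it by more than 1 second are annotated as gaps.
#'
#' @return An object of class `tb_trace`: a list with elements
#'   `individual_id`, `t0` (POSIXct, UTC), `t1`, `sampling_interval_min`,
#'   `time_s` (seconds since `t0`), `tb`, and `gaps` (data frame with one row
#'   per annotated gap: `after_index`, `from_s`, `to_s`, `gap_s`).
#' @export
tb_trace <- function(individual_id, time, tb_celsius,
                     t0 = NULL, t1 = NULL, sampling_interval_min = 90) {
  stopifnot(is.character(individual_id), length(individual_id) == 1L)
  if (length(time) != length(tb_celsius))
    stop("`time` and `tb_celsius` must have the same length", call. = FALSE)
  if (length(time) < 1L)
    stop("a trace needs at least one sample", call. = FALSE)

  if (inherits(time, "POSIXct")) {
    if (is.null(t0)) t0 <- time[1L]
    t0 <- as.POSIXct(t0, tz = "UTC")
    time_s <- as.numeric(difftime(time, t0, units = "secs"))
  } else {
    time_s <- as.numeric(time)
    t0 <- if (is.null(t0)) as.POSIXct(0, origin = "1970-01-01", tz = "UTC")
          else as.POSIXct(t0, tz = "UTC")
  }
  if (any(diff(time_s) <= 0))
    stop(sprintf("timestamps of individual '%s' are not strictly increasing",
                 individual_id), call. = FALSE)
  if (time_s[1L] < -1e-9)
    stop(sprintf("individual '%s': first sample precedes t0_experiment",
                 individual_id), call. = FALSE)

  tb <- as.numeric(tb_celsius)
  if (anyNA(tb))
    stop(sprintf("individual '%s': missing tb_celsius values", individual_id),
         call. = FALSE)
  if (any(tb < .TB_LOGGER_RANGE[1L] | tb > .TB_LOGGER_RANGE[2L]))
    stop(sprintf("individual '%s': tb_celsius outside logger range [%g, %g]",
                 individual_id, .TB_LOGGER_RANGE[1L], .TB_LOGGER_RANGE[2L]),
         call. = FALSE)

  t1 <- if (is.null(t1)) t0 + time_s[length(time_s)]
        else as.POSIXct(t1, tz = "UTC")
  if (as.numeric(difftime(t1, t0, units = "secs")) <= 0)
    stop("t1_experiment must be after t0_experiment", call. = FALSE)

  interval_s <- sampling_interval_min * 60
  d <- diff(time_s)
  gap_idx <- which(abs(d - interval_s) > 1)  # 1-second tolerance
  gaps <- data.frame(
    after_index = gap_idx,
    from_s = time_s[gap_idx],
    to_s = time_s[gap_idx + 1L],
    gap_s = d[gap_idx]
  )

  structure(
    list(individual_id = individual_id,
         t0 = t0, t1 = t1,
         sampling_interval_min = sampling_interval_min,
         time_s = time_s, tb = tb, gaps = gaps),
    class = "tb_trace")
}

#' @export
print.tb_trace <- function(x, ...) {
  span_d <- as.numeric(difftime(x$t1, x$t0, units = "days"))
  cat(sprintf("<tb_trace> individual %s: %d samples @ %g min, %.1f d window",
              x$individual_id, length(x$tb), x$sampling_interval_min, span_d))
  cat(sprintf(", Tb %.1f-%.1f degC", min(x$tb), max(x$tb)))
  if (nrow(x$gaps)) cat(sprintf(", %d gap(s)", nrow(x$gaps)))
  cat("\n")
  invisible(x)
}

#' Number of samples in a trace
#' @param x A `tb_trace`.
#' @export
length.tb_trace <- function(x) length(x$tb)

#' Read body-temperature traces from CSV
#'
#' Expects a UTF-8 comma-separated file with header columns `individual_id`,
#' `timestamp` (ISO-8601; parsed as UTC) and `tb_celsius`. One `tb_trace` is
#' built per individual; within an individual timestamps must be strictly
#' increasing and sampling-interval violations are annotated as gaps on the
#' trace, not repaired.
#'
#' @param path Path to the traces CSV.
#' @param t0,t1 Optional experiment window applied to all traces (ISO-8601
#'   strings or POSIXct). Defaults to each individual's first/last sample.
#' @param sampling_interval_min Nominal sampling interval in minutes
#'   (default 90).
#' @return A named list of [tb_trace] objects, one per individual, in first
#'   order of appearance.
#' @export
read_traces <- function(path, t0 = NULL, t1 = NULL,
                        sampling_interval_min = 90) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("individual_id", "timestamp", "tb_celsius")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("traces file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) {
    warning("traces file is empty; returning no traces")
    return(list())
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%d"))
  if (anyNA(ts)) stop("unparseable timestamp(s) in traces file", call. = FALSE)
  ids <- unique(df$individual_id)
  traces <- lapply(ids, function(id) {
    sel <- df$individual_id == id
    ti <- ts[sel]
    if (any(diff(as.numeric(ti)) == 0))
      stop(sprintf("individual '%s': duplicated timestamp", id), call. = FALSE)
    tb_trace(as.character(id), ti, df$tb_celsius[sel], t0 = t0, t1 = t1,
             sampling_interval_min = sampling_interval_min)
  })
  names(traces) <- ids
  traces
}

#' Write traces to CSV
#'
#' Inverse of [read_traces()]: timestamps are serialized as ISO-8601 UTC.
#' `write_traces` followed by `read_traces` reproduces ids and timestamps
#' exactly and temperatures to full double precision (the CSV keeps 15
#' significant digits).
#'
#' @param traces A list of [tb_trace] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "tb_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(
      individual_id = tr$individual_id,
      timestamp = format(tr$t0 + tr$time_s, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      tb_celsius = formatC(tr$tb, digits = 15, format = "g"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a cohort covariate table
#'
#' The cohort CSV holds one row per individual: experimental group, body
#' masses before/after the experiment, food provided and remaining masses
#' per item, and white-adipose-tissue PUFA proportions before/after (percent
#' of total fatty acids; may be missing, e.g. when an animal could not be
#' sampled).
#'
#' @param path Path to the cohort CSV with columns `individual_id`, `group`
#'   (`control` or `HF`), `mass_pre_g`, `mass_post_g`, `pellets_provided_g`,
#'   `seeds_provided_g`, `pellets_remaining_g`, `seeds_remaining_g`,
#'   `pufa_pre_pct`, `pufa_post_pct`.
#' @param study_replica If `TRUE` (default), enforce that control animals
#'   were provided no seeds; the simulator may relax this.
#' @return A data frame of validated rows with `group` as a factor with
#'   levels `control`, `HF`. Missing PUFA measurements are kept as `NA` and
#'   reported in a message.
#' @export
read_cohort <- function(path, study_replica = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("individual_id", "group", "mass_pre_g", "mass_post_g",
                "pellets_provided_g", "seeds_provided_g",
                "pellets_remaining_g", "seeds_remaining_g",
                "pufa_pre_pct", "pufa_post_pct")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) {
    warning("cohort file is empty; returning zero rows")
    df$group <- factor(character(), levels = c("control", "HF"))
    return(df)
  }
  validate_cohort(df, study_replica = study_replica)
}

#' Validate a cohort table already in memory
#'
#' @param df A data frame with the columns documented in [read_cohort()].
#' @inheritParams read_cohort
#' @return The validated data frame (group coerced to factor).
#' @export
validate_cohort <- function(df, study_replica = TRUE) {
  if (anyDuplicated(df$individual_id))
    stop("duplicated individual_id in cohort", call. = FALSE)
  if (!all(df$group %in% c("control", "HF")))
    stop("group must be 'control' or 'HF'", call. = FALSE)
  df$group <- factor(df$group, levels = c("control", "HF"))

  for (col in c("mass_pre_g", "mass_post_g", "pellets_provided_g",
                "seeds_provided_g", "pellets_remaining_g",
                "seeds_remaining_g")) {
    v <- df[[col]]
    if (anyNA(v) || any(v < 0))
      stop("cohort column ", col, " must be non-negative and complete",
           call. = FALSE)
  }
  for (item in c("pellets", "seeds")) {
    prov <- df[[paste0(item, "_provided_g")]]
    rem <- df[[paste0(item, "_remaining_g")]]
    bad <- rem > prov
    if (any(bad))
      stop(sprintf("%s remaining exceeds provided for individual(s): %s",
                   item, paste(df$individual_id[bad], collapse = ", ")),
           call. = FALSE)
  }
  for (col in c("pufa_pre_pct", "pufa_post_pct")) {
    v <- df[[col]]
    ok <- is.na(v) | (v >= 0 & v <= 100)
    if (!all(ok))
      stop("cohort column ", col, " must lie in [0, 100] when present",
           call. = FALSE)
  }
  if (study_replica) {
    bad <- df$group == "control" & df$seeds_provided_g != 0
    if (any(bad))
      stop("control individuals must have seeds_provided_g = 0 in ",
           "study-replica mode: ",
           paste(df$individual_id[bad], collapse = ", "), call. = FALSE)
  }
  n_miss <- sum(is.na(df$pufa_pre_pct))
  if (n_miss)
    message(n_miss, " individual(s) lack a pre-experiment PUFA measurement")
  df
}
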