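# Torpor bout detection and classification.
#
# A bout is a maximal run of consecutive samples with Tb below the euthermia
# threshold. It begins at the first sub-threshold sample and ends at the
# first subsequent sample at/above the threshold (the recovery sample);
# duration is clock time between those two timestamps. Thresholds are read
# strictly: Tb exactly at 30 degC is euthermic, a bout minimum exactly at
# 20 degC is short-shallow, and a duration of exactly 24 h is short.

#' Segmentation parameters
#'
#' @param euthermia_threshold Tb (degC) below which an animal is considered
#'   torpid. Default 30.
#' @param deep_tb_threshold Tb (degC): a bout whose minimum is strictly below
#'   this is deep or short, otherwise short-shallow. Default 20.
#' @param deep_duration_h Duration (hours): among bouts with minimum below
#'   `deep_tb_threshold`, strictly longer than this is deep, otherwise
#'   short. Default 24.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(euthermia_threshold = 30,
                                deep_tb_threshold = 20,
                                deep_duration_h = 24) {
  stopifnot(is.finite(euthermia_threshold), is.finite(deep_tb_threshold),
            is.finite(deep_duration_h), deep_duration_h > 0)
  if (!(deep_tb_threshold < euthermia_threshold))
    stop("deep_tb_threshold must be below euthermia_threshold", call. = FALSE)
  structure(list(euthermia_threshold = euthermia_threshold,
                 deep_tb_threshold = deep_tb_threshold,
                 deep_duration_h = deep_duration_h),
            class = "segmentation_params")
}

#' Classify a torpor bout from its minimum Tb and duration
#'
#' The classification is a total function of `(min_tb, duration_h)`,
#' exhaustive and mutually exclusive:
#' * `DEEP` — minimum Tb strictly below `deep_tb_threshold` *and* duration
#'   strictly longer than `deep_duration_h`;
#' * `SHORT` — minimum Tb strictly below `deep_tb_threshold`, duration at
#'   most `deep_duration_h`;
#' * `SHORT_SHALLOW` — minimum Tb at or above `deep_tb_threshold`.
#'
#' @param min_tb Numeric vector of per-bout minimum Tb (degC).
#' @param duration_h Numeric vector of bout durations (hours), positive.
#' @param params A [segmentation_params()] object.
#' @return Character vector in `c("DEEP", "SHORT", "SHORT_SHALLOW")`.
#' @export
classify_bout <- function(min_tb, duration_h, params = segmentation_params()) {
  stopifnot(length(min_tb) == length(duration_h))
  if (any(!is.finite(duration_h)) || any(duration_h <= 0))
    stop("duration_h must be positive and finite", call. = FALSE)
  ifelse(min_tb >= params$deep_tb_threshold, "SHORT_SHALLOW",
         ifelse(duration_h > params$deep_duration_h, "DEEP", "SHORT"))
}

#' Detect torpor bouts in a body-temperature trace
#'
#' Scans the samples inside the experiment window `[t0, t1]` for maximal
#' runs below the euthermia threshold. Each run yields exactly one bout:
#' `start` is the timestamp of the run's first sample; `end` is the
#' timestamp of the first subsequent sample at/above the threshold. If the
#' record ends while still below threshold, the bout is flagged `truncated`
#' and `end` is set to the last sample time plus one sampling interval.
#'
#' `min_tb` is the minimum over in-bout samples. `mean_tb` is by default the
#' mean over samples from the bout start through the recovery sample
#' inclusive (the convention used for reported bout means); set
#' `include_recovery_in_mean = FALSE` for the in-bout-only alternative.
#'
#' Annotated sampling gaps are handled by `gap_policy`:
#' * `"bridge"` (default) — the series is treated as continuous across the
#'   gap; a gap inside a bout contributes its wall-clock time to the
#'   duration but no samples to `min_tb`/`mean_tb`.
#' * `"split"` — a gap terminates any open bout (as a truncated bout ending
#'   one sampling interval after the last pre-gap sample) and detection
#'   restarts after the gap.
#' * `"error"` — any gap inside the analysis window raises an error.
#'
#' @param trace A [tb_trace()] with at least 2 samples in the window.
#' @param params A [segmentation_params()] object.
#' @param gap_policy One of `"bridge"`, `"split"`, `"error"`.
#' @param include_recovery_in_mean Logical; include the recovery sample in
#'   `mean_tb` (default `TRUE`).
#' @return A data frame with one row per bout, ordered by start:
#'   `individual_id`, `start`, `end` (POSIXct UTC), `start_s`, `end_s`
#'   (seconds since `t0`), `duration_h`, `min_tb`, `mean_tb`, `bout_type`,
#'   `truncated`, `n_samples`.
#' @export
detect_bouts <- function(trace, params = segmentation_params(),
                         gap_policy = c("bridge", "split", "error"),
                         include_recovery_in_mean = TRUE) {
  stopifnot(inherits(trace, "tb_trace"))
  gap_policy <- match.arg(gap_policy)

  span_s <- as.numeric(difftime(trace$t1, trace$t0, units = "secs"))
  sel <- trace$time_s >= -1e-9 & trace$time_s <= span_s + 1e-9
  time_s <- trace$time_s[sel]
  tb <- trace$tb[sel]
  n <- length(tb)
  if (n < 2L)
    stop("trace must contain at least 2 samples within the experiment window",
         call. = FALSE)
  interval_s <- trace$sampling_interval_min * 60

  # indices (into the windowed series) after which an annotated gap opens
  gap_after <- integer(0)
  if (nrow(trace$gaps)) {
    orig_idx <- which(sel)
    gap_after <- match(trace$gaps$after_index, orig_idx)
    gap_after <- gap_after[!is.na(gap_after) & gap_after < n]
  }
  if (gap_policy == "error" && length(gap_after))
    stop(sprintf("individual '%s': %d sampling gap(s) in analysis window",
                 trace$individual_id, length(gap_after)), call. = FALSE)

  seg_breaks <- if (gap_policy == "split") gap_after else integer(0)
  seg_start <- c(1L, seg_breaks + 1L)
  seg_end <- c(seg_breaks, n)

  out <- list()
  for (s in seq_along(seg_start)) {
    idx <- seg_start[s]:seg_end[s]
    below <- tb[idx] < params$euthermia_threshold
    if (!any(below)) next
    r <- rle(below)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- idx[run_start[k]]
      i1 <- idx[run_end[k]]
      has_recovery <- run_end[k] < length(idx)
      if (has_recovery) {
        i_rec <- idx[run_end[k] + 1L]
        end_s <- time_s[i_rec]
        truncated <- FALSE
      } else {
        end_s <- time_s[i1] + interval_s
        truncated <- TRUE
      }
      mean_idx <- if (has_recovery && include_recovery_in_mean)
        i0:i_rec else i0:i1
      out[[length(out) + 1L]] <- data.frame(
        individual_id = trace$individual_id,
        start_s = time_s[i0], end_s = end_s,
        duration_h = (end_s - time_s[i0]) / 3600,
        min_tb = min(tb[i0:i1]),
        mean_tb = mean(tb[mean_idx]),
        truncated = truncated,
        n_samples = i1 - i0 + 1L,
        stringsAsFactors = FALSE)
    }
  }

  if (!length(out)) return(empty_bout_table())
  bouts <- do.call(rbind, out)
  bouts <- bouts[order(bouts$start_s), , drop = FALSE]
  rownames(bouts) <- NULL
  bouts$bout_type <- classify_bout(bouts$min_tb, bouts$duration_h, params)
  bouts$start <- trace$t0 + bouts$start_s
  bouts$end <- trace$t0 + bouts$end_s
  bouts[, c("individual_id", "start", "end", "start_s", "end_s",
            "duration_h", "min_tb", "mean_tb", "bout_type", "truncated",
            "n_samples")]
}

empty_bout_table <- function() {
  data.frame(individual_id = character(),
             start = as.POSIXct(character(), tz = "UTC"),
             end = as.POSIXct(character(), tz = "UTC"),
             start_s = numeric(), end_s = numeric(),
             duration_h = numeric(), min_tb = numeric(),
             mean_tb = numeric(), bout_type = character(),
             truncated = logical(), n_samples = integer(),
             stringsAsFactors = FALSE)
}

#' Pool short and short-shallow bouts into a combined shallow category
#'
#' Short bouts occur rarely and their expression does not warrant a separate
#' statistical category, so short (`SHORT`) and short-shallow
#' (`SHORT_SHALLOW`) bouts are relabelled `SHALLOW` for downstream
#' statistics. Deep bouts are untouched; the mapping is idempotent and
#' preserves counts.
#'
#' @param bouts A bout table as returned by [detect_bouts()].
#' @return The bout table with `bout_type` in `c("DEEP", "SHALLOW")`.
#' @export
merge_shallow <- function(bouts) {
  if (nrow(bouts) == 0L) return(bouts)
  bouts$bout_type[bouts$bout_type %in% c("SHORT", "SHORT_SHALLOW")] <-
    "SHALLOW"
  bouts
}

#' Write a bout table to CSV
#'
#' Columns: `individual_id`, `start`, `end` (ISO-8601 UTC), `duration_h`,
#' `min_tb`, `mean_tb`, `bout_type`, `truncated`.
#'
#' @param bouts A bout table from [detect_bouts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bouts <- function(bouts, path) {
  out <- data.frame(
    individual_id = bouts$individual_id,
    start = format(bouts$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    end = format(bouts$end, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    duration_h = bouts$duration_h,
    min_tb = bouts$min_tb,
    mean_tb = bouts$mean_tb,
    bout_type = bouts$bout_type,
    truncated = bouts$truncated,
    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
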