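#' @title Global/local fixation classification and switching
#' @description Short fixations indicate global (ambient) exploration, long
#'   fixations local (focal) inspection. A fixation is labelled local when its
#'   duration strictly exceeds the threshold (default 187 ms, a cohort mean
#'   fixation duration); exactly-threshold durations are global. Derived
#'   per-participant measures: the global/local count ratio and the rate of
#'   switching between the two modes per second of inspection time.
#' @name global_local
NULL

#' Label fixations as global or local by duration threshold
#'
#' @param x a `scanpath`, or a numeric vector of fixation durations (ms).
#' @param threshold_ms duration threshold in ms (default 187); a fixation is
#'   `"local"` iff duration > threshold.
#' @return character vector of `"global"`/`"local"`, in fixation order.
#' @export
#' @examples
#' label_fixations(c(100, 300))            # "global" "local"
#' label_fixations(c(187, 188))            # threshold itself is global
label_fixations <- function(x, threshold_ms = 187) {
  stopifnot(is.numeric(threshold_ms), threshold_ms > 0)
  durations <- if (inherits(x, "scanpath")) x$fixations$duration_ms else
    as.numeric(x)
  if (length(durations) == 0) return(character(0))
  ifelse(durations > threshold_ms, "local", "global")
}

#' Global/local ratio of a label sequence
#'
#' Count of global fixations divided by count of local fixations. With no
#' local fixation the ratio is undefined: `NA` is returned with a warning, and
#' such participants are excluded from group means.
#'
#' @param labels character vector of `"global"`/`"local"`.
#' @return ratio (dimensionless), or `NA` if undefined.
#' @export
global_local_ratio <- function(labels) {
  n_local <- sum(labels == "local")
  n_global <- sum(labels == "global")
  if (n_local == 0) {
    warning("global/local ratio undefined: no local fixations", call. = FALSE)
    return(NA_real_)
  }
  n_global / n_local
}

#' Switching rate between global and local viewing
#'
#' Number of transitions between differing consecutive labels, divided by the
#' inspection time in seconds.
#'
#' @param labels character vector of `"global"`/`"local"`.
#' @param inspection_time_ms inspection time in ms, > 0.
#' @return switches per second (Hz).
#' @export
#' @examples
#' switch_rate(c("global", "global", "local", "global"), 10000) # 0.2 Hz
switch_rate <- function(labels, inspection_time_ms) {
  stopifnot(inspection_time_ms > 0)
  n <- length(labels)
  switches <- if (n < 2) 0L else sum(labels[-1] != labels[-n])
  switches / (inspection_time_ms / 1000)
}

#' Mean fixation duration across a cohort
#'
#' Used for the `threshold_ms = "cohort_mean"` mode: the classification
#' threshold is then the mean fixation duration over all fixations in the
#' table, the same construction that produced the 187 ms default.
#'
#' @param ft a `fixation_table`.
#' @return mean duration, ms.
#' @export
cohort_mean_duration <- function(ft) {
  stopifnot(inherits(ft, "fixation_table"))
  mean(ft$duration_ms)
}

#' Per-participant global/local metrics
#'
#' @param ft a `fixation_table`.
#' @param threshold_ms numeric threshold in ms, or `"cohort_mean"` to use
#'   [cohort_mean_duration()] of `ft`.
#' @param inspection `"span"` or `"sum"`, see [inspection_time()].
#' @return data frame, one row per (participant, sculpture): `n_fixations`,
#'   `n_global`, `n_local`, `gl_ratio` (`NA` when undefined), `gl_defined`,
#'   `switch_rate_hz`, `inspection_time_ms`. The threshold used is stored in
#'   attribute `"threshold_ms"`.
#' @export
global_local_metrics <- function(ft, threshold_ms = 187,
                                 inspection = c("span", "sum")) {
  inspection <- match.arg(inspection)
  if (identical(threshold_ms, "cohort_mean")) {
    threshold_ms <- cohort_mean_duration(ft)
  }
  sps <- scanpaths(ft)
  rows <- lapply(sps, function(sp) {
    labels <- label_fixations(sp, threshold_ms)
    n_local <- sum(labels == "local")
    n_global <- sum(labels == "global")
    it <- inspection_time(sp, inspection)
    data.frame(
      participant_id = sp$participant_id,
      sculpture_id = sp$sculpture_id,
      n_fixations = length(labels),
      n_global = n_global,
      n_local = n_local,
      gl_ratio = if (n_local > 0) n_global / n_local else NA_real_,
      gl_defined = n_local > 0,
      switch_rate_hz = switch_rate(labels, it),
      inspection_time_ms = it,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_undef <- sum(!out$gl_defined)
  if (n_undef > 0) {
    warning(sprintf("%d participant/sculpture combination(s) have no local fixations; gl_ratio undefined", n_undef),
            call. = FALSE)
  }
  attr(out, "threshold_ms") <- threshold_ms
  out
}

#' Per-level mean and SD of a participant metric
#'
#' Aggregates a per-participant metric by expertise level, adding a `Total`
#' row over all included participants. With equal group sizes the Total mean
#' equals the unweighted mean of the level means. SD is the sample standard
#' deviation (n - 1 denominator); levels with a single participant get SD 0
#' and `degenerate = TRUE`. `NA` metric values (e.g. undefined ratios) are
#' excluded with a warning; empty levels are omitted with a warning.
#'
#' @param metrics data frame with `participant_id` and the metric column.
#' @param profiles output of [expertise_profiles()].
#' @param value_col name of the metric column in `metrics`.
#' @return data frame: `level` (`"Total"` last), `n`, `mean`, `sd`,
#'   `degenerate`.
#' @export
group_summary <- function(metrics, profiles, value_col) {
  stopifnot(value_col %in% names(metrics))
  df <- merge(metrics, profiles[, c("participant_id", "level")],
              by = "participant_id")
  v <- df[[value_col]]
  if (anyNA(v)) {
    warning(sprintf("%d undefined value(s) of '%s' excluded from group summary",
                    sum(is.na(v)), value_col), call. = FALSE)
    df <- df[!is.na(v), ]
  }
  summarise_one <- function(vals) {
    n <- length(vals)
    data.frame(n = n, mean = mean(vals),
               sd = if (n > 1) stats::sd(vals) else 0,
               degenerate = n == 1)
  }
  rows <- list()
  for (lev in EXPERTISE_LEVELS) {
    vals <- df[[value_col]][df$level == lev]
    if (length(vals) == 0) {
      warning(sprintf("level '%s' has no included participants; omitted", lev),
              call. = FALSE)
      next
    }
    rows[[lev]] <- cbind(data.frame(level = lev), summarise_one(vals))
  }
  rows[["Total"]] <- cbind(data.frame(level = "Total"),
                           summarise_one(df[[value_col]]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
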