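#' Spot-timing model for synthetic delivery logs
#'
#' The delivery log records, for every spot, the beam-on interval in integer
#' microseconds. The generator models the nominal spot duration as
#' MU / beam-current, applies multiplicative Gaussian jitter (default SD 0.9%,
#' the dry-run run-to-run variation the generator is designed to emulate), and
#' separates consecutive spots by a dead time. Interlocks and field
#' resumptions are not modelled: every synthetic log represents a single
#' uninterrupted delivery. Scanning transit dose between spots is ignored;
#' dose rate uses beam-on duration only.
#'
#' By default the beam current is chosen per field as
#' `mean(mu) / t_typical_ms`, so typical durations sit in the several-ms range
#' regardless of the absolute MU scale; a per-field `current_factor` greater
#' than 1 shortens all durations of that field (a "hot", high-dose-rate
#' field), leaving the delivered dose untouched.
#'
#' @param t_typical_ms target mean spot duration in ms when the current is
#'   auto-derived (default 8 ms).
#' @param jitter_sd relative SD of the multiplicative duration jitter
#'   (default 0.009, i.e. 0.9%).
#' @param dead_time_ms dead time between consecutive spots, ms (default 2).
#' @param current_mu_s fixed beam current in MU/s; `NULL` (default) derives it
#'   per field from the mean MU and `t_typical_ms`.
#' @return An object of class `timing_model`.
#' @export
timing_model <- function(t_typical_ms = 8, jitter_sd = 0.009,
                         dead_time_ms = 2, current_mu_s = NULL) {
  stop_if_not_scalar_pos(t_typical_ms, "t_typical_ms")
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0")
  if (dead_time_ms < 0) stop("`dead_time_ms` must be >= 0")
  if (!is.null(current_mu_s) && current_mu_s <= 0)
    stop("`current_mu_s` must be positive")
  structure(list(t_typical_ms = t_typical_ms, jitter_sd = jitter_sd,
                 dead_time_ms = dead_time_ms, current_mu_s = current_mu_s),
            class = "timing_model")
}

#' Synthesize a delivery log for a spot table
#'
#' @param spots data.frame with `field_id`, `spot_id`, `mu` (delivery order is
#'   row order within each field).
#' @param tm a [timing_model()].
#' @param seed integer seed for the duration jitter.
#' @param current_factors optional named numeric vector (by `field_id`) of
#'   beam-current multipliers; factor > 1 shortens that field's durations.
#' @return data.frame with `field_id, spot_id, t_start_us, t_end_us,
#'   duration_us` (times in integer microseconds).
#' @export
synthesize_log <- function(spots, tm = timing_model(), seed = 1,
                           current_factors = NULL) {
  with_seed(seed, {
    out <- vector("list", 0)
    dead_us <- tm$dead_time_ms * 1000
    for (f in unique(as.character(spots$field_id))) {
      sf <- spots[as.character(spots$field_id) == f, , drop = FALSE]
      current <- tm$current_mu_s %||% (mean(sf$mu) / (tm$t_typical_ms / 1000))
      fac <- if (!is.null(current_factors) && f %in% names(current_factors))
        current_factors[[f]] else 1
      current <- current * fac
      if (current <= 0) stop(sprintf("field '%s': non-positive beam current", f))
      nominal_us <- sf$mu / current * 1e6
      jitter <- if (tm$jitter_sd > 0)
        1 + stats::rnorm(nrow(sf), 0, tm$jitter_sd) else rep(1, nrow(sf))
      dur <- pmax(1, round(nominal_us * pmax(jitter, 0.01)))
      t_end <- cumsum(dur + dead_us)
      t_start <- t_end - dur
      out[[length(out) + 1L]] <- data.frame(
        field_id = sf$field_id, spot_id = sf$spot_id,
        t_start_us = as.integer(round(t_start)),
        t_end_us = as.integer(round(t_start + dur)),
        stringsAsFactors = FALSE)
    }
    log <- do.call(rbind, out)
    log$duration_us <- log$t_end_us - log$t_start_us
    rownames(log) <- NULL
    log
  })
}

#' Write / parse a delivery log CSV
#'
#' The log dialect is fixed: a CSV with header
#' `field_id,spot_id,t_start_us,t_end_us`, times in integer microseconds.
#' `parse_log` validates that each (field, spot) appears exactly once, that
#' every interval is strictly increasing, and — when a reference spot table is
#' given — that all and only the plan's spots are present. Durations outside
#' 0.1-100 ms trigger a sanity warning (typical PBS spot durations are a few
#' ms).
#'
#' @param log data.frame as returned by [synthesize_log()].
#' @param path file path.
#' @export
write_log <- function(log, path) {
  utils::write.csv(log[, c("field_id", "spot_id", "t_start_us", "t_end_us")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_log
#' @param expected optional data.frame of plan spots (`field_id`, `spot_id`)
#'   that must be covered exactly once each.
#' @return `parse_log`: data.frame with integer `t_start_us`, `t_end_us` and
#'   derived `duration_us`.
#' @export
parse_log <- function(path, expected = NULL) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("field_id", "spot_id", "t_start_us", "t_end_us")
  if (!all(need %in% names(log)))
    stop("log is missing required columns: ",
         paste(setdiff(need, names(log)), collapse = ", "))
  key <- paste(log$field_id, log$spot_id, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate log entry for spot ", key[duplicated(key)][1])
  bad <- log$t_end_us <= log$t_start_us
  if (any(bad))
    stop("non-monotone beam-on interval for spot ", key[bad][1])
  if (!is.null(expected)) {
    ekey <- paste(expected$field_id, expected$spot_id, sep = "/")
    miss <- setdiff(ekey, key)
    if (length(miss)) stop("log is missing spot ", miss[1])
    extra <- setdiff(key, ekey)
    if (length(extra)) stop("log contains unknown spot ", extra[1])
  }
  log$t_start_us <- as.integer(log$t_start_us)
  log$t_end_us <- as.integer(log$t_end_us)
  log$duration_us <- log$t_end_us - log$t_start_us
  if (any(log$duration_us < 100 | log$duration_us > 1e5))
    warning("some spot durations fall outside the typical 0.1-100 ms range")
  log
}

#' Spot-duration reproducibility across repeated deliveries
#'
#' Given two or more logs of the same field(s), computes per-spot relative
#' deviations from the per-spot mean duration and summarizes them as the mean
#' absolute deviation and the pooled (unbiased, per-spot degrees of freedom)
#' standard deviation, both in percent. Identical logs give (0, 0); the
#' statistic is scale-free.
#'
#' @param logs list of >= 2 log data.frames covering identical spot sets.
#' @return named numeric vector `c(mean_abs_pct = , sd_pct = )`.
#' @export
duration_reproducibility <- function(logs) {
  if (!is.list(logs) || length(logs) < 2L)
    stop("need at least two logs")
  keys <- lapply(logs, function(l) paste(l$field_id, l$spot_id, sep = "/"))
  ref <- sort(keys[[1]])
  for (k in keys[-1])
    if (!identical(sort(k), ref)) stop("logs cover mismatched spot sets")
  dur <- sapply(seq_along(logs), function(i) {
    l <- logs[[i]]
    l$duration_us[order(keys[[i]])]
  })
  m <- rowMeans(dur)
  rel <- (dur - m) / m
  n <- ncol(dur)
  pooled_var <- mean(rowSums(rel^2) / (n - 1))
  c(mean_abs_pct = mean(abs(rel)) * 100, sd_pct = sqrt(pooled_var) * 100)
}
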