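# Lick microstructure: debouncing, burst segmentation, and the per-session
# panel of licking metrics used to index palatability.
#
# Conventions (all stated in the methods vignette):
#  * bursts are maximal runs of >= 2 licks whose consecutive inter-lick
#    intervals are strictly under the threshold (default 1 s) -- an ILI of
#    exactly 1.0 s splits;
#  * burst duration = last lick onset - first lick onset (onset-only data);
#  * post-delivery windows are half-open [delivery_i, delivery_{i+1});
#  * deliveries with no qualifying lick/burst are excluded from means, not
#    imputed.

#' Debounce raw lickometer contacts
#'
#' Greedy left-to-right merge: a contact closer than `window` to the last
#' retained lick is discarded (lickometer minimum bin, default 10 ms).
#'
#' @param raw_contact_times Sorted numeric vector of contact times (s).
#' @param window Debounce window in seconds.
#' @return Numeric vector of retained lick onsets; strictly increasing with
#'   consecutive differences `>= window`.
#' @export
debounce_licks <- function(raw_contact_times, window = 0.010) {
  stopifnot(is.numeric(raw_contact_times), window > 0)
  if (is.unsorted(raw_contact_times)) {
    stop("contact times must be sorted", call. = FALSE)
  }
  n <- length(raw_contact_times)
  if (n == 0) return(numeric(0))
  if (n == 1 || all(diff(raw_contact_times) >= window)) {
    return(raw_contact_times)
  }
  keep <- logical(n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (raw_contact_times[i] - last >= window) {
      keep[i] <- TRUE
      last <- raw_contact_times[i]
    }
  }
  raw_contact_times[keep]
}

#' Segment a lick train into bursts
#'
#' Partitions licks into maximal runs whose internal inter-lick intervals
#' are strictly below `ili_threshold`; runs with at least `min_licks` licks
#' become bursts, shorter runs are isolated licks. Bursts are disjoint and
#' ordered.
#'
#' @param times Sorted numeric vector of debounced lick onsets (s).
#' @param ili_threshold Burst criterion in seconds (default 1 s; strictly
#'   "under", so an ILI equal to the threshold splits).
#' @param min_licks Minimum licks per burst (default 2).
#' @return `data.frame` of class `lick_bursts` with columns `start`, `end`,
#'   `duration`, `n_licks`, one row per burst, and attribute `within_ilis`:
#'   the pooled inter-lick intervals inside bursts.
#' @export
segment_bursts <- function(times, ili_threshold = 1.0, min_licks = 2) {
  if (!is.numeric(ili_threshold) || ili_threshold <= 0) {
    stop("ili_threshold must be positive", call. = FALSE)
  }
  stopifnot(min_licks >= 2)
  if (is.unsorted(times, strictly = FALSE)) {
    stop("lick times must be sorted", call. = FALSE)
  }
  n <- length(times)
  empty <- structure(
    data.frame(start = numeric(0), end = numeric(0), duration = numeric(0),
               n_licks = integer(0)),
    within_ilis = numeric(0), class = c("lick_bursts", "data.frame"))
  if (n == 0) return(empty)
  gaps <- diff(times)
  run_id <- cumsum(c(TRUE, gaps >= ili_threshold))
  run_len <- tabulate(run_id)
  burst_runs <- which(run_len >= min_licks)
  if (!length(burst_runs)) return(empty)
  first_idx <- match(burst_runs, run_id)
  last_idx <- length(run_id) + 1L - match(burst_runs, rev(run_id))
  out <- data.frame(start = times[first_idx], end = times[last_idx],
                    duration = times[last_idx] - times[first_idx],
                    n_licks = run_len[burst_runs])
  in_burst_gap <- gaps < ili_threshold & run_len[run_id[-1]] >= min_licks
  structure(out, within_ilis = gaps[in_burst_gap],
            class = c("lick_bursts", "data.frame"))
}

#' Burst ratio
#'
#' Fraction of all licks that occur within bursts; 0 when there are licks
#' but no bursts. A train with zero licks is an error (the ratio is
#' undefined, which is distinct from 0).
#'
#' @param times Lick onsets the bursts were segmented from.
#' @param bursts Output of [segment_bursts()] on `times`.
#' @return Fraction in `[0, 1]`.
#' @export
burst_ratio <- function(times, bursts) {
  if (length(times) == 0) {
    stop("burst ratio is undefined for an empty lick train", call. = FALSE)
  }
  sum(bursts$n_licks) / length(times)
}

#' Lick counts per time bin
#'
#' Half-open bins `[a, b)` of width `bin_width`; the final partial bin is
#' included, and a lick at exactly the session end is counted in the last
#' bin so that the counts always partition the total.
#'
#' @param times Lick onsets (s).
#' @param session_duration Session length in seconds (> 0).
#' @param bin_width Bin width in seconds (default 600 = 10 min).
#' @return Integer vector of counts, one per bin; `sum()` equals
#'   `length(times)`.
#' @export
lick_rate_bins <- function(times, session_duration, bin_width = 600) {
  stopifnot(session_duration > 0, bin_width > 0)
  if (length(times) && any(times > session_duration)) {
    stop("lick beyond session duration", call. = FALSE)
  }
  n_bins <- max(1L, ceiling(session_duration / bin_width))
  if (!length(times)) return(integer(n_bins))
  idx <- pmin(floor(times / bin_width) + 1L, n_bins)
  tabulate(idx, nbins = n_bins)
}

# First index k with x[k] >= t ("at or after"), or length(x) + 1.
first_at_or_after <- function(t, x) findInterval(t, x, left.open = TRUE) + 1L

#' Mean latency to begin licking after a delivery
#'
#' For each delivery, the latency is the time from the delivery to the first
#' lick at or after it and before the next delivery (windows are half-open;
#' the final window runs to the session end). Deliveries with no qualifying
#' lick are excluded from the mean, not imputed.
#'
#' @param times Sorted lick onsets (s).
#' @param deliveries Sorted delivery times (s).
#' @return Mean latency in seconds, with attribute `latencies` (the included
#'   per-delivery values); `NA` when no delivery has a qualifying lick.
#' @export
latency_after_delivery <- function(times, deliveries) {
  if (is.unsorted(times) || is.unsorted(deliveries)) {
    stop("inputs must be sorted", call. = FALSE)
  }
  n_d <- length(deliveries)
  lat <- rep(NA_real_, n_d)
  for (i in seq_len(n_d)) {
    k <- first_at_or_after(deliveries[i], times)
    if (k > length(times)) next
    if (i < n_d && times[k] >= deliveries[i + 1]) next
    lat[i] <- times[k] - deliveries[i]
  }
  lat <- lat[!is.na(lat)]
  structure(if (length(lat)) mean(lat) else NA_real_, latencies = lat)
}

#' First lick burst following each delivery
#'
#' For each delivery, selects the first burst whose *start* is at or after
#' the delivery and before the next delivery. A burst already ongoing at the
#' delivery (started earlier) is not selected. Deliveries without a
#' qualifying burst are omitted.
#'
#' @param bursts Output of [segment_bursts()].
#' @param deliveries Sorted delivery times (s).
#' @return `data.frame` with columns `delivery`, `start`, `duration`,
#'   `n_licks`, one row per delivery that has a qualifying burst.
#' @export
first_burst_after_delivery <- function(bursts, deliveries) {
  if (is.unsorted(deliveries)) stop("deliveries must be sorted",
                                    call. = FALSE)
  n_d <- length(deliveries)
  rows <- vector("list", n_d)
  for (i in seq_len(n_d)) {
    k <- first_at_or_after(deliveries[i], bursts$start)
    if (k > nrow(bursts)) next
    if (i < n_d && bursts$start[k] >= deliveries[i + 1]) next
    rows[[i]] <- data.frame(delivery = deliveries[i],
                            start = bursts$start[k],
                            duration = bursts$duration[k],
                            n_licks = bursts$n_licks[k])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(delivery = numeric(0), start = numeric(0),
                      duration = numeric(0), n_licks = integer(0)))
  }
  do.call(rbind, rows)
}

#' Summarize lick microstructure for a session
#'
#' Assembles the full per-session panel: total licks, licks per time bin,
#' mean latency to lick after a delivery, burst ratio, mean burst duration,
#' mean licks per burst, mean within-burst inter-lick interval, duration and
#' lick count of the first burst after each delivery (averaged over
#' deliveries), and the latency to the very first lick of the session.
#' Burst-based fields are `NA` when the session has no licks or no bursts.
#'
#' @param session A [session()] containing `lick_contact` (and usually
#'   `sucrose_delivery`) events.
#' @param ili_threshold Burst criterion in seconds, see [segment_bursts()].
#' @param debounce Debounce window in seconds, see [debounce_licks()].
#' @param bin_width Rate-bin width in seconds, see [lick_rate_bins()].
#' @return Object of class `microstructure_summary` (a named list); use
#'   [as.data.frame.microstructure_summary()] for a tidy one-row table.
#' @export
lick_microstructure <- function(session, ili_threshold = 1.0,
                                debounce = 0.010, bin_width = 600) {
  stopifnot(inherits(session, "lick_session"))
  licks <- debounce_licks(event_times(session, "lick_contact"), debounce)
  deliveries <- event_times(session, "sucrose_delivery")
  bursts <- segment_bursts(licks, ili_threshold)
  ilis <- attr(bursts, "within_ilis")
  post <- first_burst_after_delivery(bursts, deliveries)
  lat <- if (length(licks) && length(deliveries)) {
    latency_after_delivery(licks, deliveries)
  } else NA_real_
  structure(list(
    subject_id = session$subject_id,
    total_licks = length(licks),
    rate_bins = lick_rate_bins(licks, session$duration, bin_width),
    latency_after_delivery = as.numeric(lat),
    burst_ratio = if (length(licks)) burst_ratio(licks, bursts) else NA_real_,
    n_bursts = nrow(bursts),
    mean_burst_duration = if (nrow(bursts)) mean(bursts$duration) else NA_real_,
    mean_licks_per_burst = if (nrow(bursts)) mean(bursts$n_licks) else NA_real_,
    mean_within_burst_ili = if (length(ilis)) mean(ilis) else NA_real_,
    post_delivery_burst_duration = if (nrow(post)) mean(post$duration)
                                   else NA_real_,
    post_delivery_burst_licks = if (nrow(post)) mean(post$n_licks)
                                else NA_real_,
    latency_first_lick_session = if (length(licks)) licks[1] else NA_real_),
    class = "microstructure_summary")
}

#' @export
print.microstructure_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<microstructure_summary> subject %s\n",
    "  total licks %d | burst ratio %.3f | bursts %d\n",
    "  licks/burst %.2f | burst duration %.3f s | within-burst ILI %.1f ms\n",
    "  latency after delivery %.2f s | post-delivery burst: %.3f s, %.2f licks\n"),
    x$subject_id, x$total_licks, x$burst_ratio, x$n_bursts,
    x$mean_licks_per_burst, x$mean_burst_duration,
    1000 * x$mean_within_burst_ili, x$latency_after_delivery,
    x$post_delivery_burst_duration, x$post_delivery_burst_licks))
  invisible(x)
}

#' Flatten a microstructure summary to a one-row data frame
#'
#' Rate bins become columns `licks_bin_1 ... licks_bin_k`.
#'
#' @param x A `microstructure_summary`.
#' @param ... Unused.
#' @return One-row `data.frame`.
#' @export
as.data.frame.microstructure_summary <- function(x, ...) {
  bins <- as.list(x$rate_bins)
  names(bins) <- sprintf("licks_bin_%d", seq_along(bins))
  scalars <- x[setdiff(names(x), "rate_bins")]
  as.data.frame(c(scalars, bins), stringsAsFactors = FALSE)
}
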