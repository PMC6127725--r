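#' Track inclusion filter configuration
#'
#' Reconstruction of very small filopodia is noisy, so downstream
#' quantification keeps only tracks that reached a maximum length of at
#' least 3 µm and existed for at least two time frames (15-s frame
#' interval); counts are reported over a 15-minute window.
#'
#' @param min_max_length_um minimum maximum length (µm), closed bound.
#' @param min_lifetime_frames minimum number of frames present, closed
#'   bound.
#' @param frame_interval_s seconds per frame.
#' @param window_min reporting window (minutes).
#' @param strict_consecutive when \code{TRUE}, the lifetime condition
#'   additionally requires at least one pair of consecutive frames
#'   (tracks may otherwise satisfy it across a linking gap).
#' @return A list of class \code{filo_filter_config}.
#' @export
filter_config <- function(min_max_length_um = 3, min_lifetime_frames = 2L,
                          frame_interval_s = 15, window_min = 15,
                          strict_consecutive = FALSE) {
  stopifnot(min_max_length_um > 0, min_lifetime_frames >= 1,
            frame_interval_s > 0, window_min > 0)
  structure(list(min_max_length_um = min_max_length_um,
                 min_lifetime_frames = as.integer(min_lifetime_frames),
                 frame_interval_s = frame_interval_s,
                 window_min = window_min,
                 strict_consecutive = strict_consecutive),
            class = "filo_filter_config")
}

#' Filter tracks to quantifiable filopodia
#'
#' Keeps a track iff its maximum length is at least
#' \code{min_max_length_um} and it was present in at least
#' \code{min_lifetime_frames} frames (both bounds closed). Idempotent;
#' raising either threshold never adds survivors.
#'
#' @param tracks a track table with \code{max_length_um} and
#'   \code{lifetime_frames} columns.
#' @param config a \code{\link{filter_config}}.
#' @return The surviving rows, attributes preserved.
#' @export
filter_tracks <- function(tracks, config = filter_config()) {
  keep <- tracks$max_length_um >= config$min_max_length_um &
    tracks$lifetime_frames >= config$min_lifetime_frames
  if (config$strict_consecutive && "data" %in% names(tracks)) {
    consec <- vapply(tracks$data,
                     function(d) any(diff(sort(d$frame)) == 1L), logical(1))
    consec[tracks$lifetime_frames < 2L] <- FALSE
    keep <- keep & consec
  }
  out <- tracks[keep, ]
  attr(out, "calibration") <- attr(tracks, "calibration")
  out
}

#' Per-frame filopodia counts over a time window
#'
#' Counts, for every frame of the window, the tracks with an instance in
#' that frame. The attached summary reports the mean per-frame count and
#' the number of distinct tracks seen in the window (both conventions of
#' "number of filopodia" are of interest, and the distinct count is
#' always at least the per-frame maximum).
#'
#' @param tracks a (typically filtered) track table with nested
#'   \code{data}.
#' @param window integer frame range \code{c(first, last)}; defaults to
#'   the span implied by the filter configuration's 15-minute window
#'   starting at the first frame observed, clamped (with a warning) to the
#'   observed span.
#' @param config a \code{\link{filter_config}} (supplies the frame
#'   interval and window length).
#' @return Tibble \code{(frame, n_filopodia)} of class
#'   \code{filo_counts}; \code{summary()} or the \code{"summary"}
#'   attribute gives mean count and distinct-track count.
#' @export
count_filopodia <- function(tracks, window = NULL,
                            config = filter_config()) {
  if (nrow(tracks) == 0) {
    out <- tibble::tibble(frame = integer(), n_filopodia = integer())
    attr(out, "summary") <- tibble::tibble(mean_count = NA_real_,
                                           distinct_tracks = 0L)
    class(out) <- c("filo_counts", class(out))
    return(out)
  }
  present <- tidyr::unnest(tracks[c("track_id", "data")], "data")
  span <- range(present$frame)
  if (is.null(window)) {
    # frames after the last observed instance simply count zero
    window_frames <- floor(config$window_min * 60 / config$frame_interval_s)
    window <- c(span[1], span[1] + window_frames - 1L)
  } else if (window[2] > span[2]) {
    warn(sprintf("window end %d exceeds last observed frame %d; clamping",
                 window[2], span[2]))
    window[2] <- span[2]
  }
  frames <- seq(window[1], window[2])
  inwin <- present[present$frame >= window[1] & present$frame <= window[2], ]
  counts <- vapply(frames, function(f) sum(inwin$frame == f), integer(1))
  out <- tibble::tibble(frame = as.integer(frames), n_filopodia = counts)
  attr(out, "summary") <- tibble::tibble(
    mean_count = mean(counts),
    distinct_tracks = length(unique(inwin$track_id)))
  class(out) <- c("filo_counts", class(out))
  out
}

#' @export
summary.filo_counts <- function(object, ...) attr(object, "summary")

#' ECDF of maximum filopodium lengths
#'
#' Empirical cumulative distribution of the per-track maximum lengths:
#' each point gives the proportion of filopodia with a given maximum
#' length or less (right-continuous, reaching 1 at the sample maximum).
#' Apply \code{\link{filter_tracks}} first to impose the 3-µm cut-off on
#' the shortest structures.
#'
#' @param tracks a track table with \code{max_length_um}, or a numeric
#'   vector of maximum lengths.
#' @return Tibble \code{(max_length_um, proportion)} of class
#'   \code{filo_ecdf}, one row per observation in ascending order.
#' @export
ecdf_max_length <- function(tracks) {
  x <- if (is.numeric(tracks)) tracks else tracks$max_length_um
  if (length(x) == 0) abort("no tracks: cannot build an ECDF")
  x <- sort(x)
  out <- tibble::tibble(max_length_um = x,
                        proportion = seq_along(x) / length(x))
  class(out) <- c("filo_ecdf", class(out))
  out
}

#' Exponential diagnostic of the maximum-length distribution
#'
#' Maximum filopodium lengths above the reconstruction cut-off follow an
#' approximately exponential distribution (many short filopodia,
#' gradually fewer long ones), consistent with stochastic actin
#' incorporation rather than a preferred length. This fits a shifted
#' exponential by maximum likelihood (rate = 1 / mean excess over the
#' offset) and reports the Kolmogorov–Smirnov distance between the
#' excess lengths and the fitted distribution.
#'
#' @param tracks a track table or numeric vector of maximum lengths (µm).
#' @param offset shift of the exponential (µm); defaults to the 3-µm
#'   inclusion threshold.
#' @param min_n minimum sample size above the offset.
#' @return An object of class \code{filo_expfit}; see
#'   \code{\link[generics]{tidy}} and \code{\link[generics]{glance}}.
#' @export
exponential_diagnostic <- function(tracks, offset = 3, min_n = 10L) {
  x <- if (is.numeric(tracks)) tracks else tracks$max_length_um
  x <- x[x >= offset]
  if (length(x) < min_n) {
    abort(sprintf("need at least %d maximum lengths above the offset, got %d",
                  min_n, length(x)))
  }
  excess <- x - offset
  m <- mean(excess)
  if (m <= 0) abort("degenerate sample: all values equal the offset")
  rate <- 1 / m
  ks <- suppressWarnings(ks.test(excess, "pexp", rate = rate))
  structure(list(rate = rate, mean_excess = m, offset = offset,
                 n = length(x), ks_statistic = unname(ks$statistic),
                 ks_p_value = ks$p.value,
                 log_lik = sum(stats::dexp(excess, rate, log = TRUE)),
                 sample = x),
            class = "filo_expfit")
}

#' @export
print.filo_expfit <- function(x, ...) {
  cat(sprintf(
    "<shifted exponential fit> rate = %.4g / um (mean = %.3g + %.3g um), n = %d\n",
    x$rate, x$offset, x$mean_excess, x$n))
  cat(sprintf("  KS distance %.4f (p = %.3g)\n", x$ks_statistic, x$ks_p_value))
  invisible(x)
}

#' @rdname exponential_diagnostic
#' @param x a \code{filo_expfit} object.
#' @param ... unused.
#' @export
tidy.filo_expfit <- function(x, ...) {
  tibble::tibble(term = "rate", estimate = x$rate,
                 std.error = x$rate / sqrt(x$n))
}

#' @rdname exponential_diagnostic
#' @export
glance.filo_expfit <- function(x, ...) {
  tibble::tibble(rate = x$rate, offset = x$offset, nobs = x$n,
                 ks_statistic = x$ks_statistic, ks_p_value = x$ks_p_value,
                 logLik = x$log_lik)
}

#' Rank-based comparison of two groups
#'
#' Two-sided Mann–Whitney (Wilcoxon rank-sum) test on per-movie counts or
#' per-track maximum lengths: exact for small untied samples (both
#' n <= 20), normal approximation with tie correction otherwise.
#'
#' @param sample_a,sample_b numeric samples.
#' @return One-row tibble: \code{statistic} (the U statistic for the
#'   first sample), \code{p_value}, sample sizes and \code{method}.
#' @export
compare_groups <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    abort("both samples must be non-empty")
  }
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- !ties && length(sample_a) <= 20 && length(sample_b) <= 20
  ht <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = "two.sided",
                       exact = exact, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_a = length(sample_a), n_b = length(sample_b),
                 method = if (exact) "exact" else "normal approximation")
}

#' Per-movie summary
#'
#' Gathers the headline readouts of one recording: total and passing
#' track counts, mean per-frame filopodia count and the maximum-length
#' sample.
#'
#' @param tracks an unfiltered track table.
#' @param group optional group label (genotype / stage).
#' @param movie_id optional identifier.
#' @param config a \code{\link{filter_config}}.
#' @return One-row tibble with list-columns \code{counts} (per-frame) and
#'   \code{max_lengths}.
#' @export
movie_summary <- function(tracks, group = NA_character_,
                          movie_id = NA_character_,
                          config = filter_config()) {
  passing <- filter_tracks(tracks, config)
  counts <- count_filopodia(passing, config = config)
  s <- attr(counts, "summary")
  tibble::tibble(
    movie_id = movie_id, group = group,
    tracks_total = nrow(tracks), tracks_passing = nrow(passing),
    mean_count = s$mean_count, distinct_tracks = s$distinct_tracks,
    counts = list(counts), max_lengths = list(passing$max_length_um))
}
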