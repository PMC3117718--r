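#' Configuration for the basic read filters
#'
#' Thresholds for the per-read cleaning predicates. None of these are
#' dictated by the method itself; the defaults are conservative values
#' for 454-era long reads and every one is meant to be tuned per run.
#'
#' @param length_min,length_max inclusive read-length window in bases
#'   (defaults 50 and 1000).
#' @param length_std_k multiplier k for the standard-deviation length
#'   filter: keep reads within mean +/- k * sd of the pristine input
#'   length distribution (default 2).
#' @param complexity_threshold compression-complexity percentage a read
#'   (or one window of it) must strictly exceed to be kept (default 25:
#'   uniform-random DNA scores roughly 35-40 under the zlib codec while
#'   homopolymer runs score under 2, so 25 separates the two with margin).
#' @param complexity_window,complexity_step sliding-window size and step
#'   in bases for the windowed complexity filter (defaults 100 and 50).
#' @param quality_threshold Phred score; a read is kept only if at least
#'   one base is strictly above it (default 20).
#' @param n_rate_max maximum tolerated fraction of undetermined (N)
#'   bases (default 0.02).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(length_min = 50L, length_max = 1000L,
                          length_std_k = 2.0, complexity_threshold = 25,
                          complexity_window = 100L, complexity_step = 50L,
                          quality_threshold = 20L, n_rate_max = 0.02) {
  stopifnot(length_min > 0, length_max >= length_min, length_std_k > 0,
            complexity_threshold >= 0, complexity_window > 0,
            complexity_step > 0, quality_threshold >= 0, n_rate_max >= 0)
  structure(list(length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 length_std_k = length_std_k,
                 complexity_threshold = complexity_threshold,
                 complexity_window = as.integer(complexity_window),
                 complexity_step = as.integer(complexity_step),
                 quality_threshold = as.integer(quality_threshold),
                 n_rate_max = n_rate_max),
            class = "filter_config")
}

#' Length-window filter
#'
#' @param r a single-read `ReadSet` or character sequence.
#' @param cfg a [filter_config()].
#' @return `TRUE` to keep the read (length within the inclusive window).
#' @export
filter_length_window <- function(r, cfg = filter_config()) {
  len <- nchar(if (inherits(r, "ReadSet")) r$seq[1] else r)
  len >= cfg$length_min && len <= cfg$length_max
}

#' Standard-deviation length filter
#'
#' The mean and population standard deviation (divisor N) of read length
#' are computed once over all input reads, before any removal; reads
#' outside `mean +/- k * sd` are discarded. With fewer than two reads
#' the filter is a no-op (a warning is raised).
#'
#' @param rs a `ReadSet`.
#' @param cfg a [filter_config()].
#' @return A list with `kept` (a `ReadSet`), `removed_ids`, and the
#'   `mean` and `sd` actually used.
#' @export
filter_length_std <- function(rs, cfg = filter_config()) {
  if (length(rs) < 2) {
    warning("fewer than 2 reads; standard-deviation length filter skipped")
    return(list(kept = rs, removed_ids = character(0),
                mean = NA_real_, sd = NA_real_))
  }
  lens <- read_lengths(rs)
  mu <- mean(lens)
  sigma <- sqrt(mean((lens - mu)^2))   # population sd
  lo <- mu - cfg$length_std_k * sigma
  hi <- mu + cfg$length_std_k * sigma
  keep <- lens >= lo & lens <= hi
  list(kept = rs[which(keep)], removed_ids = rs$id[!keep],
       mean = mu, sd = sigma)
}

#' Compression-based sequence complexity
#'
#' Complexity is the DEFLATE-compressed byte length of the sequence
#' (zlib, R's fixed default level), minus the compressed length of the
#' empty string (codec overhead, so short reads are not penalised),
#' expressed as a percentage of the sequence length. Low-information
#' sequence (homopolymers, simple repeats) compresses well and scores
#' low; uniform-random DNA scores roughly 35-40.
#'
#' @param s a DNA string (non-empty).
#' @return Complexity percentage (numeric scalar).
#' @export
complexity_score <- function(s) {
  if (!is.character(s) || length(s) != 1 || nchar(s) == 0)
    stop("complexity_score() needs one non-empty sequence")
  baseline <- length(memCompress(raw(0), "gzip"))
  100 * (length(memCompress(charToRaw(s), "gzip")) - baseline) / nchar(s)
}

#' Whole-read complexity filter
#'
#' @param r a single-read `ReadSet` or character sequence.
#' @param cfg a [filter_config()].
#' @return `TRUE` to keep (complexity strictly above the threshold).
#' @export
filter_complexity_full <- function(r, cfg = filter_config()) {
  s <- if (inherits(r, "ReadSet")) r$seq[1] else r
  complexity_score(s) > cfg$complexity_threshold
}

#' Windowed complexity filter
#'
#' The read is cut into windows of `complexity_window` bases every
#' `complexity_step`; a trailing short window is scored too when it is
#' at least half a window long. The read is kept if at least one window
#' is complex (score strictly above the threshold). A read shorter than
#' one window is scored as a single whole-read window.
#'
#' @param r a single-read `ReadSet` or character sequence.
#' @param cfg a [filter_config()].
#' @return `TRUE` to keep.
#' @export
filter_complexity_window <- function(r, cfg = filter_config()) {
  s <- if (inherits(r, "ReadSet")) r$seq[1] else r
  len <- nchar(s)
  w <- cfg$complexity_window
  if (len <= w)
    return(complexity_score(s) > cfg$complexity_threshold)
  starts <- seq(1L, len - w + 1L, by = cfg$complexity_step)
  windows <- substring(s, starts, starts + w - 1L)
  tail_start <- max(starts) + cfg$complexity_step
  if (tail_start <= len && (len - tail_start + 1L) >= w / 2)
    windows <- c(windows, substring(s, tail_start, len))
  any(vapply(windows, complexity_score, numeric(1)) > cfg$complexity_threshold)
}

#' Quality filter
#'
#' A read is kept if at least one of its bases has a quality strictly
#' above the threshold; a read whose every base is at or below it is
#' discarded. (Deliberately permissive: a single good base saves the
#' read.) Reads without qualities are kept with a warning.
#'
#' @param r a single-read `ReadSet`.
#' @param cfg a [filter_config()].
#' @return `TRUE` to keep.
#' @export
filter_quality <- function(r, cfg = filter_config()) {
  if (!inherits(r, "ReadSet") || is.null(r$qual)) {
    warning("read has no qualities; quality filter keeps it")
    return(TRUE)
  }
  max(r$qual[[1]]) > cfg$quality_threshold
}

#' Undetermined-base (N) rate filter
#'
#' @param r a single-read `ReadSet` or character sequence.
#' @param cfg a [filter_config()].
#' @return `TRUE` to keep (N fraction at most `n_rate_max`).
#' @export
filter_n_rate <- function(r, cfg = filter_config()) {
  s <- if (inherits(r, "ReadSet")) r$seq[1] else r
  n_count <- nchar(s) - nchar(gsub("N", "", s, fixed = TRUE))
  n_count / nchar(s) <= cfg$n_rate_max
}
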