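# From speech interval annotations to per-frame dialogue conditions and
# valid training-sample index sets. Intervals are half-open [start, end) in
# seconds; frame t (1-based) covers [(t-1)/fs, t/fs) and counts as speech
# when its midpoint lies inside an inter-pausal unit.

#' Detect inter-pausal units
#'
#' An inter-pausal unit (IPU) is a maximal speech segment from one speaker
#' surrounded by pauses longer than `min_pause_s`. Consecutive raw bursts
#' separated by gaps of at most `min_pause_s` are merged; strictly greater
#' gaps separate IPUs. Unsorted or overlapping input intervals are
#' normalized first; negative times are an error.
#'
#' @param raw_intervals two-column matrix or data frame of
#'   `[start_s, end_s)` speech bursts.
#' @param min_pause_s minimal pause separating IPUs, in seconds
#'   (default 0.1).
#' @return object of class `ipu_list`: list with `intervals` (sorted,
#'   non-overlapping matrix) and `min_pause_s`.
#' @export
detect_ipus <- function(raw_intervals, min_pause_s = 0.1) {
  iv <- as.matrix(raw_intervals)
  if (nrow(iv) == 0L)
    return(structure(list(intervals = iv, min_pause_s = min_pause_s),
                     class = "ipu_list"))
  stopifnot(ncol(iv) == 2)
  if (any(iv < 0)) stop("negative interval times")
  if (any(iv[, 2] < iv[, 1])) stop("interval end before start")
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    gap <- iv[i, 1] - out[nrow(out), 2]
    if (gap <= min_pause_s + 1e-9)  # tolerance for float time arithmetic
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    else out <- rbind(out, iv[i, ])
  }
  colnames(out) <- c("start_s", "end_s")
  structure(list(intervals = out, min_pause_s = min_pause_s),
            class = "ipu_list")
}

#' @export
print.ipu_list <- function(x, ...) {
  cat(sprintf("<ipu_list> %d IPUs, %.1f s of speech\n", nrow(x$intervals),
              sum(x$intervals[, 2] - x$intervals[, 1])))
  invisible(x)
}

.point_in_intervals <- function(t, iv) {
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv)))
    inside <- inside | (t >= iv[i, 1] & t < iv[i, 2])
  inside
}

#' Per-frame dialogue condition from one participant's perspective
#'
#' Labels every frame `S` (only self speaks), `E` (only the other speaks),
#' `B` (both speak) or `Silence` (neither). `B` frames are analyzed from
#' both perspectives downstream: the `E|B` model uses the other's features,
#' the `S|B` model one's own.
#'
#' @param self_ipus,other_ipus [detect_ipus()] results (or bare interval
#'   matrices) for self and the interlocutor.
#' @param n_frames number of frames covering the session.
#' @param fs frame rate in Hz.
#' @return object of class `condition_mask`: list with `labels` (character
#'   vector of length `n_frames`) and `fs`.
#' @export
label_conditions <- function(self_ipus, other_ipus, n_frames, fs) {
  get_iv <- function(x) if (inherits(x, "ipu_list")) x$intervals else as.matrix(x)
  mid <- (seq_len(n_frames) - 0.5) / fs
  s <- .point_in_intervals(mid, get_iv(self_ipus))
  o <- .point_in_intervals(mid, get_iv(other_ipus))
  labels <- rep("Silence", n_frames)
  labels[s & !o] <- "S"
  labels[!s & o] <- "E"
  labels[s & o] <- "B"
  structure(list(labels = labels, fs = fs), class = "condition_mask")
}

#' @export
print.condition_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("E", "S", "B", "Silence")))
  cat(sprintf("<condition_mask> %d frames @ %g Hz | %s\n",
              length(x$labels), x$fs,
              paste(names(tab), tab, sep = ":", collapse = " ")))
  invisible(x)
}

#' Valid training-sample indices for a condition
#'
#' A frame index `t` is a valid sample for a condition when all frames
#' `[t - window_frames + 1, t]` carry that condition — i.e. the participant
#' has been uninterruptedly in the condition for the full lag window
#' (600 ms = 77 frames at 128 Hz by default), with overlapping windows at a
#' one-frame step.
#'
#' @param mask a [label_conditions()] result.
#' @param condition one of `"E"`, `"S"`, `"B"`, `"Silence"`.
#' @param window_frames window length in frames (default 77).
#' @return integer vector of valid frame indices (possibly empty).
#' @export
extract_training_samples <- function(mask, condition, window_frames = 77) {
  stopifnot(inherits(mask, "condition_mask"), window_frames >= 1)
  ok <- mask$labels == condition
  if (!any(ok)) return(integer(0))
  r <- rle(ok)
  streak <- sequence(r$lengths) * rep(as.integer(r$values), r$lengths)
  which(streak >= window_frames)
}

#' Read a speaker interval table
#'
#' Reads a `speaker,start_s,end_s` CSV and returns the per-speaker
#' [detect_ipus()] results.
#'
#' @param path CSV file path.
#' @param min_pause_s IPU merge threshold in seconds.
#' @return named list of `ipu_list`, one per speaker label.
#' @export
read_intervals_csv <- function(path, min_pause_s = 0.1) {
  df <- utils::read.csv(path)
  stopifnot(all(c("speaker", "start_s", "end_s") %in% names(df)))
  out <- lapply(split(df, df$speaker), function(d)
    detect_ipus(as.matrix(d[, c("start_s", "end_s")]), min_pause_s))
  out
}

#' Read interval tiers from a Praat TextGrid
#'
#' Parses a long-format TextGrid and returns, per interval tier, the
#' non-empty labeled intervals as a `[start_s, end_s)` matrix.
#'
#' @param path TextGrid file path.
#' @return named list of two-column matrices, one per interval tier.
#' @export
read_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  num <- function(s) as.numeric(sub(".*= *", "", s))
  str <- function(s) gsub("\"", "", sub(".*= *", "", s))
  tiers <- list()
  tier_name <- NULL
  xmin <- NA
  starts <- ends <- labels <- NULL
  flush <- function() {
    if (!is.null(tier_name)) {
      keep <- !is.na(labels) & labels != ""
      m <- cbind(start_s = starts[keep], end_s = ends[keep])
      tiers[[tier_name]] <<- m
    }
  }
  for (ln in lines) {
    s <- trimws(ln)
    if (grepl("^class *= *\"IntervalTier\"", s)) next
    if (grepl("^name *= *", s)) {
      flush()
      tier_name <- str(s)
      starts <- ends <- numeric(0); labels <- character(0)
    } else if (grepl("^xmin *= *", s)) {
      xmin <- num(s)
    } else if (grepl("^xmax *= *", s)) {
      if (!is.null(tier_name)) {
        starts <- c(starts, xmin); ends <- c(ends, num(s))
        labels <- c(labels, NA)
      }
    } else if (grepl("^text *= *", s)) {
      if (length(labels)) labels[length(labels)] <- str(s)
    }
  }
  flush()
  tiers
}

#' Write a condition mask as CSV
#'
#' @param mask a [label_conditions()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_condition_mask <- function(mask, path) {
  utils::write.csv(
    data.frame(frame = seq_along(mask$labels),
               time_s = (seq_along(mask$labels) - 0.5) / mask$fs,
               condition = mask$labels),
    path, row.names = FALSE)
  invisible(path)
}
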