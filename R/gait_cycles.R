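## Gait-cycle segmentation ---------------------------------------------------

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  half <- (w - 1L) %/% 2L
  ## edge-replicated centered moving average (keeps length, no NAs)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], w - 1L - half))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 1))[w:(w - 1L + length(x))]
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Segment a sequence into gait cycles
#'
#' The detection signal is the horizontal ankle separation
#' `|u(l_ankle) - u(r_ankle)|` per frame (X separation for a 3D sequence),
#' mean-subtracted and smoothed with a centered moving average of window
#' `ceiling(fps / 10)` frames. The separation peaks twice per stride (once
#' per step), so cycle boundaries are placed at every second local maximum —
#' same-foot strike to same-foot strike. If fewer than two maxima are found
#' a single cycle spanning the whole sequence is returned with a warning, so
#' segmentation never rejects a sequence.
#'
#' @param x A `projected_sequence` or a normalized `GSI17`
#'   [skeleton_sequence].
#' @param fps Frame rate; defaults to the one stored in `x`.
#' @return A `cycle_segmentation`: `boundaries` (strictly increasing frame
#'   indices; consecutive boundaries delimit one cycle, each at least 4
#'   frames), `signal` (the smoothed detection signal) and `n_frames`.
#' @export
segment_cycles <- function(x, fps = NULL) {
  if (is.null(fps)) fps <- x$fps
  kp <- gsi17_keypoints()
  li <- match("l_ankle", kp); ri <- match("r_ankle", kp)
  if (inherits(x, "projected_sequence")) {
    sep <- abs(x$frames[li, 1, ] - x$frames[ri, 1, ])
  } else if (inherits(x, "skeleton_sequence") && x$layout == "GSI17") {
    sep <- abs(x$frames[li, 1, ] - x$frames[ri, 1, ])
  } else {
    stop("segment_cycles needs a projected or GSI17 sequence", call. = FALSE)
  }
  nf <- length(sep)
  w <- max(1L, as.integer(ceiling(fps / 10)))
  sig <- moving_average(sep - mean(sep), w)
  peaks <- local_maxima(sig)
  if (length(peaks) < 2L) {
    warning("fewer than 2 ankle-separation maxima; returning one cycle ",
            "spanning the whole sequence")
    boundaries <- c(1L, nf)
  } else {
    boundaries <- peaks[seq(1L, length(peaks), by = 2L)]
    if (length(boundaries) < 2L) boundaries <- c(boundaries, nf)
  }
  ## enforce a minimum cycle length of 4 frames
  keep <- boundaries[1]
  for (b in boundaries[-1]) if (b - keep[length(keep)] >= 4L) keep <- c(keep, b)
  if (length(keep) < 2L) keep <- c(1L, nf)
  structure(list(boundaries = as.integer(keep), signal = sig,
                 n_frames = nf),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation> %d cycle(s), boundaries: %s\n",
              length(x$boundaries) - 1L,
              paste(x$boundaries, collapse = ", ")))
  invisible(x)
}

#' Frame index ranges of the detected cycles
#' @param cs A `cycle_segmentation`.
#' @return List of integer vectors, one per cycle.
#' @export
cycle_frames <- function(cs) {
  b <- cs$boundaries
  lapply(seq_len(length(b) - 1L), function(k) seq(b[k], b[k + 1L]))
}
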