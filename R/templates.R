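## gait_template -------------------------------------------------------------

#' Construct a gait template
#'
#' A fixed-size grayscale motion template with values in `[0,1]`: the
#' time-accumulated rasterization of a skeleton sequence (line- or
#' joint-based variant) or the mean of aligned silhouettes (GEI).
#'
#' @param pixels Numeric `canvas_h x canvas_w` matrix in `[0,1]` (row 1 is
#'   the top of the image).
#' @param variant `"lines"`, `"joints"`, `"gei"` or `"unknown"`.
#' @param params List of rendering parameters (e.g. `thickness`, `radius`).
#' @param n_frames Number of frames aggregated (>= 1).
#' @param meta Metadata list (subject/trial/view/covariate).
#' @return An object of class `gait_template`.
#' @export
gait_template <- function(pixels, variant, params = list(), n_frames = 1L,
                          meta = list()) {
  stopifnot(is.matrix(pixels), n_frames >= 1L)
  if (any(!is.finite(pixels)) || any(pixels < 0 | pixels > 1))
    stop("template values must lie in [0,1]", call. = FALSE)
  structure(list(pixels = pixels, variant = variant, params = params,
                 n_frames = as.integer(n_frames), meta = meta),
            class = "gait_template")
}

#' @export
print.gait_template <- function(x, ...) {
  cat(sprintf(
    "<gait_template> %s, %dx%d px, %d frame(s), support %.1f%%\n",
    x$variant, ncol(x$pixels), nrow(x$pixels), x$n_frames,
    100 * mean(x$pixels > 0)))
  invisible(x)
}

## Rasterization -------------------------------------------------------------

## distance-based stamp onto mask: pixels whose center lies within `rad`
## of the segment p1-p2 (capsule; a disc when p1 == p2). mask is h x w,
## pixel (row r, col c) has center (c - 0.5, r - 0.5).
stamp_capsule <- function(mask, p1, p2, rad) {
  h <- nrow(mask); w <- ncol(mask)
  c0 <- max(1L, floor(min(p1[1], p2[1]) - rad) + 1L)
  c1 <- min(w, ceiling(max(p1[1], p2[1]) + rad) + 1L)
  r0 <- max(1L, floor(min(p1[2], p2[2]) - rad) + 1L)
  r1 <- min(h, ceiling(max(p1[2], p2[2]) + rad) + 1L)
  if (c0 > c1 || r0 > r1) return(mask)
  uc <- (c0:c1) - 0.5
  vc <- (r0:r1) - 0.5
  U <- matrix(uc, nrow = length(vc), ncol = length(uc), byrow = TRUE)
  V <- matrix(vc, nrow = length(vc), ncol = length(uc))
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 == 0) {
    d2 <- (U - p1[1])^2 + (V - p1[2])^2
  } else {
    tt <- pmin(1, pmax(0, ((U - p1[1]) * d[1] + (V - p1[2]) * d[2]) / len2))
    d2 <- (U - (p1[1] + tt * d[1]))^2 + (V - (p1[2] + tt * d[2]))^2
  }
  sub <- mask[r0:r1, c0:c1, drop = FALSE]
  sub[d2 <= rad^2] <- 1
  mask[r0:r1, c0:c1] <- sub
  mask
}

#' Rasterize one projected frame
#'
#' `rasterize_lines()` draws each of the 16 bone edges whose two endpoints
#' are valid (confidence > 0) as a hard capsule of width `thickness`: a
#' pixel is set iff its center lies within `thickness/2` of the bone
#' segment. `rasterize_joints()` sets every pixel whose center lies within
#' `radius` of a valid keypoint. Both are binary, with no anti-aliasing, and
#' clip at the canvas borders.
#'
#' @param points `17 x 2` matrix of `(u, v)` canvas coordinates (pixel
#'   centers at integer + 0.5), or a `projected_sequence` frame slice.
#' @param thickness,radius Stroke width / marker radius in pixels (>= 1).
#' @param canvas_w,canvas_h Canvas size.
#' @param conf Optional length-17 confidences; joints with 0 are skipped
#'   (edges with an invalid endpoint are skipped, not extrapolated).
#' @return Binary `canvas_h x canvas_w` matrix.
#' @export
rasterize_lines <- function(points, thickness = 8, canvas_w = 80L,
                            canvas_h = 120L, conf = NULL) {
  stopifnot(thickness >= 1)
  if (is.null(conf)) conf <- rep(1, nrow(points))
  mask <- matrix(0, canvas_h, canvas_w)
  edge_idx <- gsi17_edge_index()
  for (e in seq_len(nrow(edge_idx))) {
    i <- edge_idx[e, 1]; j <- edge_idx[e, 2]
    if (conf[i] <= 0 || conf[j] <= 0) next
    mask <- stamp_capsule(mask, points[i, ], points[j, ], thickness / 2)
  }
  mask
}

#' @rdname rasterize_lines
#' @export
rasterize_joints <- function(points, radius = 8, canvas_w = 80L,
                             canvas_h = 120L, conf = NULL) {
  stopifnot(radius >= 1)
  if (is.null(conf)) conf <- rep(1, nrow(points))
  mask <- matrix(0, canvas_h, canvas_w)
  for (i in seq_len(nrow(points))) {
    if (conf[i] <= 0) next
    mask <- stamp_capsule(mask, points[i, ], points[i, ], radius)
  }
  mask
}

## Accumulation --------------------------------------------------------------

#' Accumulate per-frame rasterizations into a template
#'
#' Pixel-wise arithmetic mean (energy-image style) of the binary frames;
#' `method = "max"` takes the pixel-wise maximum instead.
#'
#' @param frames Nonempty list of equal-size binary matrices.
#' @param method `"mean"` (default) or `"max"`.
#' @param variant,params,meta Passed through to [gait_template()].
#' @return A [gait_template] with `n_frames = length(frames)`.
#' @export
accumulate <- function(frames, method = c("mean", "max"),
                       variant = "lines", params = list(), meta = list()) {
  method <- match.arg(method)
  if (length(frames) == 0L) stop("no frames to accumulate", call. = FALSE)
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("frames must share dimensions", call. = FALSE)
  px <- if (method == "mean") {
    Reduce(`+`, frames) / length(frames)
  } else {
    Reduce(pmax, frames)
  }
  gait_template(px, variant = variant, params = params,
                n_frames = length(frames), meta = meta)
}

## Full pipeline -------------------------------------------------------------

#' Compute a Gait Skeleton Image template
#'
#' Runs the full deterministic pipeline: layout conversion (if needed), view
#' normalization, trajectory removal, orthographic projection onto the
#' canvas, gait-cycle segmentation, per-frame rasterization and temporal
#' accumulation. Identical input and configuration give a bit-identical
#' template. By default one template covers all frames spanned by the
#' detected cycles; with `cfg$per_cycle` a list with one template per cycle
#' is returned.
#'
#' @param seq A [skeleton_sequence] in any supported layout.
#' @param cfg A [gsi_config()] with `variant` `"lines"` or `"joints"`.
#' @return A [gait_template] (or a list of them when `cfg$per_cycle`).
#' @export
compute_gsi <- function(seq, cfg = gsi_config()) {
  stopifnot(inherits(cfg, "gsi_config"), cfg$variant %in% c("lines", "joints"))
  norm <- normalize_sequence(seq)
  proj <- project_and_fit(norm, canvas_w = cfg$canvas_w,
                          canvas_h = cfg$canvas_h, margin = cfg$margin)
  cs <- segment_cycles(proj)
  raster1 <- function(k) {
    pts <- proj$frames[, , k]
    if (cfg$variant == "lines")
      rasterize_lines(pts, thickness = cfg$param, canvas_w = cfg$canvas_w,
                      canvas_h = cfg$canvas_h, conf = proj$conf[, k])
    else
      rasterize_joints(pts, radius = cfg$param, canvas_w = cfg$canvas_w,
                       canvas_h = cfg$canvas_h, conf = proj$conf[, k])
  }
  params <- if (cfg$variant == "lines") list(thickness = cfg$param)
            else list(radius = cfg$param)
  if (cfg$per_cycle) {
    lapply(cycle_frames(cs), function(idx)
      accumulate(lapply(idx, raster1), method = cfg$accumulate,
                 variant = cfg$variant, params = params, meta = seq$meta))
  } else {
    idx <- seq(cs$boundaries[1], cs$boundaries[length(cs$boundaries)])
    accumulate(lapply(idx, raster1), method = cfg$accumulate,
               variant = cfg$variant, params = params, meta = seq$meta)
  }
}

## GEI baseline --------------------------------------------------------------

align_silhouette <- function(f, canvas_w, canvas_h, margin) {
  fg <- which(f > 0, arr.ind = TRUE)
  out <- matrix(0, canvas_h, canvas_w)
  if (nrow(fg) == 0L) return(out)
  r0 <- min(fg[, 1]); r1 <- max(fg[, 1])
  hgt <- r1 - r0 + 1L
  s <- (margin * canvas_h) / hgt           # output px per input px
  com_c <- mean(fg[, 2])                   # horizontal center of mass
  mid_r <- (r0 + r1) / 2
  ## nearest-neighbor inverse mapping
  rr <- seq_len(canvas_h); cc <- seq_len(canvas_w)
  src_r <- round(mid_r + (rr - 0.5 - canvas_h / 2) / s + 0.5)
  src_c <- round(com_c + (cc - 0.5 - canvas_w / 2) / s + 0.5)
  ok_r <- which(src_r >= 1 & src_r <= nrow(f))
  ok_c <- which(src_c >= 1 & src_c <= ncol(f))
  out[ok_r, ok_c] <- f[src_r[ok_r], src_c[ok_c]]
  out
}

#' Compute the Gait Energy Image baseline
#'
#' Size-normalizes every binary silhouette (height scaled to `margin` of the
#' canvas height, horizontally centered on the foreground center of mass,
#' vertically centered on the body box) and averages the aligned frames
#' pixel-wise.
#'
#' @param sil A [silhouette_stack].
#' @param canvas_w,canvas_h,margin Canvas geometry (defaults as in
#'   [gsi_config()]).
#' @return A [gait_template] with `variant = "gei"`.
#' @export
compute_gei <- function(sil, canvas_w = 80L, canvas_h = 120L, margin = 0.9) {
  stopifnot(inherits(sil, "silhouette_stack"))
  if (length(sil$frames) == 0L) stop("empty silhouette stack", call. = FALSE)
  aligned <- lapply(sil$frames, align_silhouette, canvas_w = canvas_w,
                    canvas_h = canvas_h, margin = margin)
  accumulate(aligned, method = "mean", variant = "gei", params = list(),
             meta = sil$meta)
}

## Parameter sweep -----------------------------------------------------------

#' Render templates across rendering-parameter values
#'
#' Computes one template per (sequence, value) pair, by default over the
#' evaluated thickness/radius grid `{2, 4, 6, 8, 10, 12}` px. The
#' recommended downstream default is 8 px.
#'
#' @param seqs List of [skeleton_sequence] objects (a single sequence is
#'   accepted).
#' @param values Nonempty integer vector of thickness/radius values.
#' @param cfg Base [gsi_config()]; its `param` is overridden by each value.
#' @return Named list: one entry per value, each a list of templates
#'   parallel to `seqs`.
#' @export
sweep_params <- function(seqs, values = c(2L, 4L, 6L, 8L, 10L, 12L),
                         cfg = gsi_config()) {
  if (length(values) == 0L) stop("empty value list", call. = FALSE)
  if (inherits(seqs, "skeleton_sequence")) seqs <- list(seqs)
  out <- lapply(values, function(v) {
    cfg$param <- as.integer(v)
    lapply(seqs, compute_gsi, cfg = cfg)
  })
  names(out) <- as.character(values)
  out
}
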