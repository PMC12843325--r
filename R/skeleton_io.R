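## Joint layouts ------------------------------------------------------------

#' Joint names of the supported skeleton layouts
#'
#' `gsi17_keypoints()` returns the fixed keypoint order of the unified
#' 17-keypoint body model; `kinect25_joints()` and `mediapipe33_landmarks()`
#' return the source layouts in their native joint order.
#'
#' @return Character vector of joint names.
#' @export
gsi17_keypoints <- function() {
  c("head", "neck", "shoulder_center", "spine_center", "hip_center",
    "l_shoulder", "r_shoulder", "l_elbow", "r_elbow", "l_wrist", "r_wrist",
    "l_hip", "r_hip", "l_knee", "r_knee", "l_ankle", "r_ankle")
}

#' @rdname gsi17_keypoints
#' @export
kinect25_joints <- function() {
  c("SpineBase", "SpineMid", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight",
    "SpineShoulder", "HandTipLeft", "ThumbLeft", "HandTipRight", "ThumbRight")
}

#' @rdname gsi17_keypoints
#' @export
mediapipe33_landmarks <- function() {
  c("nose", "left_eye_inner", "left_eye", "left_eye_outer",
    "right_eye_inner", "right_eye", "right_eye_outer",
    "left_ear", "right_ear", "mouth_left", "mouth_right",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_pinky", "right_pinky",
    "left_index", "right_index", "left_thumb", "right_thumb",
    "left_hip", "right_hip", "left_knee", "right_knee",
    "left_ankle", "right_ankle", "left_heel", "right_heel",
    "left_foot_index", "right_foot_index")
}

layout_joints <- function(layout) {
  switch(layout,
    GSI17       = gsi17_keypoints(),
    KINECT25    = kinect25_joints(),
    MEDIAPIPE33 = mediapipe33_landmarks(),
    stop("unknown layout: ", layout, call. = FALSE)
  )
}

layout_size <- function(layout) length(layout_joints(layout))

## skeleton_sequence ---------------------------------------------------------

#' Construct a skeleton sequence
#'
#' A `skeleton_sequence` holds ordered per-frame 3D joint coordinates in
#' meters, camera convention x right, y up, z toward the camera. Joints may
#' be flagged missing only through a confidence of 0 (their coordinates are
#' then conventionally `(0,0,0)`).
#'
#' @param frames Numeric array `joints x 3 x n_frames`, or a list of
#'   `joints x 3` matrices.
#' @param layout One of `"KINECT25"`, `"MEDIAPIPE33"`, `"GSI17"`.
#' @param fps Frame rate in frames/second, `> 0`.
#' @param meta Named list; recognised entries: `subject`, `trial`,
#'   `view_deg`, `covariate` (one of `"NM"`, `"BG"`, `"CL"`).
#' @param conf Optional per-joint confidence in `[0,1]`: matrix
#'   `joints x n_frames`. Defaults to all 1.
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(frames, layout = "GSI17", fps = 30,
                              meta = list(), conf = NULL) {
  if (is.list(frames)) {
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(nrow(frames[[1]]), 3L, length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L, dim(frames)[2] == 3L)
  nj <- dim(frames)[1]
  nf <- dim(frames)[3]
  if (is.null(conf)) conf <- matrix(1, nj, nf)
  x <- structure(
    list(frames = frames, layout = layout, fps = fps, meta = meta,
         conf = conf),
    class = "skeleton_sequence")
  validate_skeleton_sequence(x)
}

validate_skeleton_sequence <- function(x) {
  nj <- layout_size(x$layout)
  if (dim(x$frames)[1] != nj)
    stop(sprintf("layout %s expects %d joints per frame, got %d",
                 x$layout, nj, dim(x$frames)[1]), call. = FALSE)
  if (dim(x$frames)[3] < 2L)
    stop("a skeleton sequence needs at least 2 frames", call. = FALSE)
  if (!is.numeric(x$fps) || length(x$fps) != 1L || x$fps <= 0)
    stop("fps must be a single value > 0", call. = FALSE)
  if (any(!is.finite(x$frames)))
    stop("joint coordinates must be finite (no NaN/Inf)", call. = FALSE)
  if (any(x$conf < 0 | x$conf > 1))
    stop("confidences must lie in [0,1]", call. = FALSE)
  if (!all(dim(x$conf) == dim(x$frames)[c(1L, 3L)]))
    stop("conf must be a joints x n_frames matrix", call. = FALSE)
  x
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence> %s, %d frames @ %g fps\n",
              x$layout, n_frames(x), x$fps))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a sequence
#' @param x A `skeleton_sequence` or `projected_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  if (inherits(x, "silhouette_stack")) return(length(x$frames))
  dim(x$frames)[3]
}

## joint accessor: J x F matrix of one coordinate, or 3 x F for one joint
joint_track <- function(seq, joint) {
  i <- match(joint, layout_joints(seq$layout))
  if (is.na(i)) stop("no joint '", joint, "' in layout ", seq$layout,
                     call. = FALSE)
  seq$frames[i, , , drop = TRUE]  # 3 x F
}

## silhouette_stack ----------------------------------------------------------

#' Construct a silhouette stack
#'
#' Binary (0/1) silhouette images of identical size, the input to the Gait
#' Energy Image baseline.
#'
#' @param frames List of 0/1 integer/numeric matrices of identical dimensions.
#' @param fps Frame rate, `> 0`.
#' @param meta Named metadata list (as in [skeleton_sequence()]).
#' @return An object of class `silhouette_stack`.
#' @export
silhouette_stack <- function(frames, fps = 30, meta = list()) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), d))
      stop("all silhouette frames must share the same dimensions",
           call. = FALSE)
    if (!all(f %in% c(0, 1)))
      stop("silhouette pixels must be 0 or 1", call. = FALSE)
  }
  structure(list(frames = frames, fps = fps, meta = meta),
            class = "silhouette_stack")
}

## JSON-lines sequence format ------------------------------------------------

#' Read / write skeleton sequences as JSON-lines
#'
#' One frame per line with fields `t`, `joints` (list of `[x,y,z]`), `conf`;
#' the first line is a header carrying `layout`, `fps` and metadata. The
#' format round-trips sequences exactly (coordinates are serialized at full
#' double precision).
#'
#' @param path File path.
#' @param layout Expected layout; the header's layout must agree.
#' @return `read_sequence()` returns a [skeleton_sequence];
#'   `write_sequence()` returns `path` invisibly.
#' @export
read_sequence <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("sequence file has no frames: ", path,
                               call. = FALSE)
  hdr <- tryCatch(jsonlite::fromJSON(lines[[1]], simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed header at line 1: ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(hdr$layout)) stop("header (line 1) lacks a layout field",
                                call. = FALSE)
  if (!is.null(layout) && !identical(hdr$layout, layout))
    stop(sprintf("declared layout %s does not match file layout %s",
                 layout, hdr$layout), call. = FALSE)
  layout <- hdr$layout
  nj <- layout_size(layout)
  nf <- length(lines) - 1L
  frames <- array(NA_real_, c(nj, 3L, nf))
  conf <- matrix(1, nj, nf)
  for (k in seq_len(nf)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[k + 1L]], simplifyVector = TRUE),
                    error = function(e)
                      stop(sprintf("malformed record at line %d: %s", k + 1L,
                                   conditionMessage(e)), call. = FALSE))
    j <- rec$joints
    if (is.list(j)) j <- do.call(rbind, j)
    if (!is.matrix(j) || ncol(j) != 3L)
      stop(sprintf("malformed joints at line %d", k + 1L), call. = FALSE)
    if (nrow(j) != nj)
      stop(sprintf("layout error at frame %d: expected %d joints, got %d",
                   k, nj, nrow(j)), call. = FALSE)
    frames[, , k] <- j
    if (!is.null(rec$conf)) conf[, k] <- rec$conf
  }
  meta <- hdr$meta
  if (is.null(meta)) meta <- list()
  skeleton_sequence(frames, layout = layout, fps = hdr$fps, meta = meta,
                    conf = conf)
}

#' @rdname read_sequence
#' @param seq A [skeleton_sequence].
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  hdr <- jsonlite::toJSON(list(layout = seq$layout, fps = seq$fps,
                               meta = seq$meta),
                          auto_unbox = TRUE, digits = I(17))
  nf <- n_frames(seq)
  recs <- character(nf)
  for (k in seq_len(nf)) {
    recs[k] <- jsonlite::toJSON(
      list(t = (k - 1) / seq$fps,
           joints = unname(split(seq$frames[, , k],
                                 seq_len(dim(seq$frames)[1]))),
           conf = seq$conf[, k]),
      auto_unbox = TRUE, digits = I(17))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

## Template PNG I/O ----------------------------------------------------------

#' Read / write gait templates as 8-bit grayscale PNG
#'
#' Template values in `[0,1]` are stored as `round(v * 255)`; reading
#' restores them within `1/255`.
#'
#' @param t A [gait_template].
#' @param path File path.
#' @return `read_template()` returns a [gait_template] (metadata is not
#'   stored in the PNG); `write_template()` returns `path` invisibly.
#' @export
write_template <- function(t, path) {
  stopifnot(inherits(t, "gait_template"))
  px <- t$pixels
  if (any(px < 0 | px > 1) || any(!is.finite(px)))
    stop("template values must lie in [0,1]", call. = FALSE)
  png::writePNG(round(px * 255) / 255, target = path)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  gait_template(px, variant = "unknown", params = list(), n_frames = 1L)
}

## Run configuration ---------------------------------------------------------

#' Pipeline run configuration
#'
#' Holds the template variant, rendering parameter and canvas geometry used
#' throughout the pipeline. The canvas defaults to 80x120 pixels and the
#' fitted skeleton height to 90% of the canvas height; the rendering
#' parameter defaults to 8 px, the value at which both template variants
#' perform best.
#'
#' @param variant `"lines"`, `"joints"` or `"gei"`.
#' @param param Line thickness (lines) or marker radius (joints) in pixels,
#'   integer in 1..64.
#' @param canvas_w,canvas_h Canvas size in pixels (each >= 16).
#' @param margin Fitted-height fraction of the canvas height.
#' @param accumulate `"mean"` (default, energy-image style) or `"max"`.
#' @param per_cycle If `TRUE`, one template per detected gait cycle.
#' @param seed Integer seed recorded with the configuration.
#' @param protocol `"loto"` or `"gallery_probe"` (used by run drivers).
#' @return A `gsi_config` list.
#' @export
gsi_config <- function(variant = c("joints", "lines", "gei"), param = 8L,
                       canvas_w = 80L, canvas_h = 120L, margin = 0.9,
                       accumulate = c("mean", "max"), per_cycle = FALSE,
                       seed = 1L, protocol = c("loto", "gallery_probe")) {
  variant <- match.arg(variant)
  accumulate <- match.arg(accumulate)
  protocol <- match.arg(protocol)
  param <- as.integer(param)
  if (param < 1L || param > 64L)
    stop("rendering parameter must be an integer in 1..64", call. = FALSE)
  if (canvas_w < 16L || canvas_h < 16L)
    stop("canvas dimensions must be >= 16", call. = FALSE)
  structure(list(variant = variant, param = param,
                 canvas_w = as.integer(canvas_w),
                 canvas_h = as.integer(canvas_h), margin = margin,
                 accumulate = accumulate, per_cycle = per_cycle,
                 seed = as.integer(seed), protocol = protocol),
            class = "gsi_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match the arguments of [gsi_config()].
#' @return A `gsi_config`.
#' @export
read_config <- function(path) {
  do.call(gsi_config, yaml::read_yaml(path))
}
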