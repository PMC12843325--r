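## 17-keypoint body model ----------------------------------------------------

#' Bone edges of the 17-keypoint body model
#'
#' The kinematic tree: an axial chain head-neck-shoulder_center-spine_center-
#' hip_center, shoulder and hip attachments, and the four limb chains.
#' 16 undirected edges over 17 keypoints; connected, acyclic, and with no
#' direct left-to-right limb link (limbs join only through the axial chain).
#'
#' @return A 16 x 2 character matrix of keypoint-name pairs.
#' @export
gsi17_edges <- function() {
  e <- rbind(
    c("head", "neck"),
    c("neck", "shoulder_center"),
    c("shoulder_center", "spine_center"),
    c("spine_center", "hip_center"),
    c("shoulder_center", "l_shoulder"),
    c("shoulder_center", "r_shoulder"),
    c("l_shoulder", "l_elbow"),
    c("l_elbow", "l_wrist"),
    c("r_shoulder", "r_elbow"),
    c("r_elbow", "r_wrist"),
    c("hip_center", "l_hip"),
    c("hip_center", "r_hip"),
    c("l_hip", "l_knee"),
    c("l_knee", "l_ankle"),
    c("r_hip", "r_knee"),
    c("r_knee", "r_ankle"))
  colnames(e) <- c("from", "to")
  e
}

## edge index matrix (16 x 2, integer into gsi17_keypoints order)
gsi17_edge_index <- function() {
  kp <- gsi17_keypoints()
  e <- gsi17_edges()
  cbind(match(e[, 1], kp), match(e[, 2], kp))
}

## Source-layout mapping tables ----------------------------------------------

#' Load a source-layout mapping table
#'
#' Mapping rules are shipped as YAML so the exact conversion is inspectable:
#' `direct` (source joint copied), `midpoints` (mean of two already-produced
#' keypoints), `discarded` (source joints dropped), and `axis_flip_z`
#' (whether the source z axis must be negated to match the internal camera
#' convention).
#'
#' @param layout `"KINECT25"` or `"MEDIAPIPE33"`.
#' @return A list with elements `direct`, `midpoints`, `discarded`,
#'   `axis_flip_z`.
#' @export
source_mapping <- function(layout = c("KINECT25", "MEDIAPIPE33")) {
  layout <- match.arg(layout)
  f <- switch(layout,
              KINECT25 = "kinect25_to_gsi17.yaml",
              MEDIAPIPE33 = "mediapipe33_to_gsi17.yaml")
  path <- system.file("extdata", f, package = "gsigait", mustWork = TRUE)
  m <- yaml::read_yaml(path)
  validate_mapping(m, layout)
  m
}

validate_mapping <- function(m, layout) {
  kp <- gsi17_keypoints()
  produced <- c(names(m$direct), names(m$midpoints))
  if (!setequal(produced, kp) || anyDuplicated(produced))
    stop("mapping must produce every keypoint exactly once", call. = FALSE)
  src <- layout_joints(layout)
  used <- c(unlist(m$direct, use.names = FALSE), m$discarded)
  if (!setequal(used, src) || anyDuplicated(used))
    stop("every source joint must be used or discarded exactly once",
         call. = FALSE)
  invisible(m)
}

## Converters ----------------------------------------------------------------

#' Convert a source-layout sequence to the 17-keypoint layout
#'
#' `map_to_gsi17()` dispatches on the sequence layout; the layout-specific
#' functions insist on their layout. Conversion is frame-local: direct rules
#' copy a source joint (with its confidence), midpoint rules average two
#' already-produced keypoints (confidence = min of the two), and discarded
#' source joints are dropped. Kinect input has its z axis negated first
#' (Kinect z points away from the camera).
#'
#' @param seq A [skeleton_sequence] in `KINECT25` or `MEDIAPIPE33` layout
#'   (`GSI17` input is returned unchanged by `map_to_gsi17()`).
#' @return A [skeleton_sequence] in `GSI17` layout with the same frame count,
#'   fps and metadata.
#' @export
map_to_gsi17 <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  switch(seq$layout,
         GSI17 = seq,
         KINECT25 = map_kinect25_to_gsi17(seq),
         MEDIAPIPE33 = map_mediapipe33_to_gsi17(seq))
}

#' @rdname map_to_gsi17
#' @export
map_kinect25_to_gsi17 <- function(seq) {
  if (!identical(seq$layout, "KINECT25"))
    stop("expected a KINECT25 sequence, got ", seq$layout, call. = FALSE)
  apply_mapping(seq, source_mapping("KINECT25"))
}

#' @rdname map_to_gsi17
#' @export
map_mediapipe33_to_gsi17 <- function(seq) {
  if (!identical(seq$layout, "MEDIAPIPE33"))
    stop("expected a MEDIAPIPE33 sequence, got ", seq$layout, call. = FALSE)
  apply_mapping(seq, source_mapping("MEDIAPIPE33"))
}

apply_mapping <- function(seq, m) {
  src_names <- layout_joints(seq$layout)
  kp <- gsi17_keypoints()
  nf <- n_frames(seq)
  src <- seq$frames
  if (isTRUE(m$axis_flip_z)) src[, 3, ] <- -src[, 3, ]
  out <- array(NA_real_, c(17L, 3L, nf))
  conf <- matrix(NA_real_, 17L, nf)
  for (g in names(m$direct)) {
    gi <- match(g, kp)
    si <- match(m$direct[[g]], src_names)
    out[gi, , ] <- src[si, , ]
    conf[gi, ] <- seq$conf[si, ]
  }
  for (g in names(m$midpoints)) {
    gi <- match(g, kp)
    ab <- match(m$midpoints[[g]], kp)
    out[gi, , ] <- (out[ab[1], , ] + out[ab[2], , ]) / 2
    conf[gi, ] <- pmin(conf[ab[1], ], conf[ab[2], ])
  }
  ## joints flagged missing keep the conventional (0,0,0)
  miss <- conf == 0
  if (any(miss)) for (d in 1:3) out[, d, ][miss] <- 0
  skeleton_sequence(out, layout = "GSI17", fps = seq$fps, meta = seq$meta,
                    conf = conf)
}
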