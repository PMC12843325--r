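## Homogeneous-coordinate helpers -------------------------------------------

translation_matrix <- function(t) {
  M <- diag(4)
  M[1:3, 4] <- t
  M
}

rotation_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  M <- diag(4)
  M[1, 1] <- c; M[1, 3] <- s
  M[3, 1] <- -s; M[3, 3] <- c
  M
}

rotation_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  M <- diag(4)
  M[1, 1] <- c; M[1, 2] <- -s
  M[2, 1] <- s; M[2, 2] <- c
  M
}

reflection_x <- function(on = TRUE) {
  M <- diag(4)
  if (on) M[1, 1] <- -1
  M
}

valid_hip_frames <- function(seq) {
  hi <- match("hip_center", gsi17_keypoints())
  which(seq$conf[hi, ] > 0)
}

## Walking direction ---------------------------------------------------------

#' Estimate the horizontal walking direction
#'
#' Fits a total-least-squares line to the hip-center trajectory in the
#' horizontal (XZ) plane and returns its unit direction, oriented from the
#' first toward the last frame. Vertical motion (Y) is ignored, so gait
#' bounce does not bias the estimate.
#'
#' @param seq A `GSI17` [skeleton_sequence] with at least 2 frames of valid
#'   hip center.
#' @return Length-3 unit vector `(dx, 0, dz)`.
#' @export
estimate_walking_direction <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"), seq$layout == "GSI17")
  hip <- joint_track(seq, "hip_center")   # 3 x F
  ok <- valid_hip_frames(seq)
  if (length(ok) < 2L)
    stop("degenerate trajectory: fewer than 2 frames with a valid hip center",
         call. = FALSE)
  P <- t(hip[c(1, 3), ok, drop = FALSE])  # F x 2 (x, z)
  disp <- P[nrow(P), ] - P[1, ]
  if (sqrt(sum(disp^2)) < 0.01)
    stop("degenerate trajectory: total hip displacement below 1 cm ",
         "(stationary subject)", call. = FALSE)
  Pc <- sweep(P, 2, colMeans(P))
  ev <- eigen(crossprod(Pc), symmetric = TRUE)
  d <- ev$vectors[, 1]
  if (sum(d * disp) < 0) d <- -d
  c(d[1], 0, d[2]) / sqrt(sum(d^2))
}

## View transform ------------------------------------------------------------

#' Build the rigid view-normalization transform
#'
#' Composes `M_view = Rz(theta_z) S Ry(theta_y) T`:
#' `T` translates the sequence-mean hip center to the origin; `Ry(theta_y)`
#' rotates the estimated walking direction onto the X axis (the rotation is
#' kept within +/-90 degrees); the reflection `S = diag(-1,1,1,1)` is applied
#' iff the walk then points along -X, enforcing a consistent facing
#' direction; and `Rz(theta_z)` removes residual in-plane tilt so the mean
#' torso axis (hip center to shoulder center) is vertical.
#'
#' @param seq A `GSI17` [skeleton_sequence].
#' @return A `view_transform`: list with `T`, `theta_y`, `S`, `theta_z`,
#'   `M_view` (all 4x4 except the angles) and `reflected`.
#' @export
build_view_transform <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"), seq$layout == "GSI17")
  hip <- joint_track(seq, "hip_center")
  ok <- valid_hip_frames(seq)
  t0 <- rowMeans(hip[, ok, drop = FALSE])
  Tm <- translation_matrix(-t0)

  d <- estimate_walking_direction(seq)
  alpha <- atan2(d[3], d[1])
  if (abs(alpha) <= pi / 2) {
    theta_y <- alpha
    reflected <- FALSE
  } else {
    theta_y <- alpha - sign(alpha) * pi
    reflected <- TRUE
  }
  Ry <- rotation_y(theta_y)
  S <- reflection_x(reflected)

  ## mean torso axis after S Ry (translation does not affect directions)
  R1 <- (S %*% Ry)[1:3, 1:3]
  torso <- joint_track(seq, "shoulder_center") - hip   # 3 x F
  si <- match("shoulder_center", gsi17_keypoints())
  ok2 <- which(seq$conf[si, ] > 0 & seq$conf[match("hip_center",
                gsi17_keypoints()), ] > 0)
  v <- R1 %*% rowMeans(torso[, ok2, drop = FALSE])
  theta_z <- atan2(v[1], v[2])
  Rz <- rotation_z(theta_z)

  M <- Rz %*% S %*% Ry %*% Tm
  structure(list(T = Tm, theta_y = theta_y, S = S, theta_z = theta_z,
                 M_view = M, reflected = reflected),
            class = "view_transform")
}

#' @export
print.view_transform <- function(x, ...) {
  cat(sprintf(
    "<view_transform> theta_y = %.2f deg, theta_z = %.2f deg, reflected = %s\n",
    x$theta_y * 180 / pi, x$theta_z * 180 / pi, x$reflected))
  invisible(x)
}

#' Apply a view transform to a sequence
#'
#' Maps every joint `p` (homogeneous) to `M_view p`. The transform is rigid
#' (up to reflection), so all intra-frame pairwise distances are preserved.
#'
#' @param seq A `GSI17` [skeleton_sequence].
#' @param vt A `view_transform` from [build_view_transform()], or any 4x4
#'   homogeneous matrix.
#' @return The transformed [skeleton_sequence].
#' @export
apply_view_transform <- function(seq, vt) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  M <- if (inherits(vt, "view_transform")) vt$M_view else vt
  stopifnot(is.matrix(M), all(dim(M) == c(4, 4)))
  d <- dim(seq$frames)
  P <- matrix(aperm(seq$frames, c(2, 1, 3)), nrow = 3)  # 3 x (J*F)
  P2 <- M[1:3, 1:3] %*% P + M[1:3, 4]
  seq$frames <- aperm(array(P2, c(3, d[1], d[3])), c(2, 1, 3))
  seq
}

#' Remove the horizontal walking trajectory
#'
#' Subtracts each frame's hip-center X and Z from all joints of that frame,
#' anchoring every frame to the vertical axis through the hip. Y is left
#' untouched so the vertical gait oscillation survives.
#'
#' @param seq A view-normalized `GSI17` [skeleton_sequence] (walking along
#'   +X).
#' @return The stabilized [skeleton_sequence]; every frame's hip center lies
#'   on the Y axis.
#' @export
normalize_translation <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"), seq$layout == "GSI17")
  hi <- match("hip_center", gsi17_keypoints())
  hx <- seq$frames[hi, 1, ]
  hz <- seq$frames[hi, 3, ]
  seq$frames[, 1, ] <- sweep(seq$frames[, 1, ], 2, hx)
  seq$frames[, 3, ] <- sweep(seq$frames[, 3, ], 2, hz)
  seq
}

## Orthographic projection ---------------------------------------------------

#' Project onto the fixed canvas
#'
#' Drops the depth (Z) component, computes the sequence-global XY bounding
#' box over valid joints, and maps world coordinates to pixel coordinates
#' with one uniform scale chosen so the box height equals `margin` of the
#' canvas height; the box is centered on the canvas and Y is flipped (image
#' v grows downward). The same scale and offset apply to every frame, so
#' frame-to-frame excursion is preserved.
#'
#' @param seq A normalized `GSI17` [skeleton_sequence].
#' @param canvas_w,canvas_h Canvas size in pixels.
#' @param margin Fraction of the canvas height occupied by the skeleton box.
#' @return A `projected_sequence`: per-frame `(u, v)` keypoints (array
#'   `17 x 2 x F`), the pixel-per-meter `scale`, offsets, canvas size,
#'   confidences, fps, metadata.
#' @export
project_and_fit <- function(seq, canvas_w = 80L, canvas_h = 120L,
                            margin = 0.9) {
  stopifnot(inherits(seq, "skeleton_sequence"), seq$layout == "GSI17")
  valid <- seq$conf > 0                       # J x F
  X <- seq$frames[, 1, ]; Y <- seq$frames[, 2, ]
  if (!any(valid)) stop("no valid joints to project", call. = FALSE)
  xr <- range(X[valid]); yr <- range(Y[valid])
  height <- diff(yr)
  if (height <= 0)
    stop("degenerate geometry: zero-height bounding box", call. = FALSE)
  s <- margin * canvas_h / height
  cx <- mean(xr); cy <- mean(yr)
  U <- canvas_w / 2 + (X - cx) * s
  V <- canvas_h / 2 - (Y - cy) * s
  d <- dim(seq$frames)
  frames <- array(0, c(d[1], 2L, d[3]))
  frames[, 1, ] <- U
  frames[, 2, ] <- V
  structure(list(frames = frames, conf = seq$conf,
                 scale = s, center = c(cx, cy),
                 canvas_w = as.integer(canvas_w),
                 canvas_h = as.integer(canvas_h),
                 fps = seq$fps, meta = seq$meta),
            class = "projected_sequence")
}

#' @export
print.projected_sequence <- function(x, ...) {
  cat(sprintf("<projected_sequence> %d frames on %dx%d canvas, %.1f px/m\n",
              n_frames(x), x$canvas_w, x$canvas_h, x$scale))
  invisible(x)
}

#' Normalize a sequence end to end
#'
#' Convenience composition: layout conversion (if needed), view transform,
#' trajectory removal.
#'
#' @param seq A [skeleton_sequence] in any supported layout.
#' @return A normalized `GSI17` [skeleton_sequence].
#' @export
normalize_sequence <- function(seq) {
  seq <- map_to_gsi17(seq)
  vt <- build_view_transform(seq)
  normalize_translation(apply_view_transform(seq, vt))
}
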