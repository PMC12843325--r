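## Deterministic seed splitting ----------------------------------------------

## small string hash (31-polynomial mod a prime below 2^31) so per-subject
## randomness is independent of call order
hash_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147480009
  as.integer(h)
}

split_seed <- function(seed, ...) {
  h <- as.integer(seed) %% 2147480009
  for (k in list(...)) {
    kk <- if (is.character(k)) hash_string(k) else as.integer(k) %% 2147480009
    h <- (h * 48271 + kk) %% 2147480009
  }
  as.integer(h)
}

## Gait parameters -----------------------------------------------------------

#' Per-subject kinematic gait parameters
#'
#' Limb lengths in meters, cadence in strides per second, stride amplitude
#' (peak hip swing angle) and knee/arm swing amplitudes in radians, vertical
#' bounce in meters. `draw_gait_params()` draws a subject's parameters
#' deterministically from `(seed, subject_id)` over realistic adult ranges,
#' so the same subject always walks the same way.
#'
#' @param thigh,shank,upper_arm,forearm,torso,neck_head Segment lengths (m).
#' @param shoulder_width,hip_width Lateral spacing (m).
#' @param cadence Stride frequency (Hz), in `[0.6, 1.4]`.
#' @param hip_amp Peak hip swing angle (rad).
#' @param knee_amp Peak knee flexion (rad).
#' @param arm_amp Peak shoulder swing angle (rad).
#' @param bounce Vertical hip oscillation amplitude (m).
#' @return A `gait_params` list.
#' @export
gait_params <- function(thigh = 0.44, shank = 0.42, upper_arm = 0.30,
                        forearm = 0.26, torso = 0.50, neck_head = 0.25,
                        shoulder_width = 0.38, hip_width = 0.30,
                        cadence = 1.0, hip_amp = 0.45, knee_amp = 0.5,
                        arm_amp = 0.35, bounce = 0.025) {
  p <- list(thigh = thigh, shank = shank, upper_arm = upper_arm,
            forearm = forearm, torso = torso, neck_head = neck_head,
            shoulder_width = shoulder_width, hip_width = hip_width,
            cadence = cadence, hip_amp = hip_amp, knee_amp = knee_amp,
            arm_amp = arm_amp, bounce = bounce)
  lengths <- unlist(p[c("thigh", "shank", "upper_arm", "forearm", "torso",
                        "neck_head")])
  if (any(lengths < 0.1 | lengths > 0.8))
    stop("segment lengths must lie in [0.1, 0.8] m", call. = FALSE)
  if (cadence < 0.6 || cadence > 1.4)
    stop("cadence must lie in [0.6, 1.4] Hz", call. = FALSE)
  if (any(unlist(p[c("hip_amp", "knee_amp", "arm_amp", "bounce")]) < 0))
    stop("amplitudes must be >= 0", call. = FALSE)
  structure(p, class = "gait_params")
}

#' @rdname gait_params
#' @param seed Integer master seed.
#' @param subject_id Subject identifier string.
#' @export
draw_gait_params <- function(seed, subject_id) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(split_seed(seed, "params", subject_id))
  r <- function(lo, hi) runif(1, lo, hi)
  gait_params(
    thigh = r(0.38, 0.48), shank = r(0.36, 0.46),
    upper_arm = r(0.26, 0.34), forearm = r(0.22, 0.30),
    torso = r(0.42, 0.55), neck_head = r(0.20, 0.28),
    shoulder_width = r(0.32, 0.42), hip_width = r(0.24, 0.34),
    cadence = r(0.8, 1.2), hip_amp = r(0.32, 0.55),
    knee_amp = r(0.35, 0.70), arm_amp = r(0.20, 0.50),
    bounce = r(0.015, 0.035))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Covariate specification for simulated walks
#'
#' Emulates acquisition covariates: `NM` normal walking; `BG` carrying a bag
#' (arm swing on the carrying side suppressed to a fraction of its normal
#' amplitude); `CL` wearing a coat (torso/hip keypoints biased outward and
#' extra joint noise, mimicking keypoint perturbation by loose clothing).
#' `view_deg` is the camera yaw, applied as a rigid Y rotation of the whole
#' sequence.
#'
#' @param condition `"NM"`, `"BG"` or `"CL"`.
#' @param view_deg Viewing angle in degrees, in `[0, 360)`.
#' @param bag_arm_factor BG only: remaining fraction of arm swing on the
#'   carrying side, in `[0, 0.3]`.
#' @param coat_offset CL only: outward bias of torso/hip keypoints (m, up to
#'   0.03).
#' @param coat_noise CL only: extra joint noise standard deviation (m).
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(condition = c("NM", "BG", "CL"), view_deg = 90,
                           bag_arm_factor = 0.2, coat_offset = 0.02,
                           coat_noise = 0.008) {
  condition <- match.arg(condition)
  if (view_deg < 0 || view_deg >= 360)
    stop("view_deg must lie in [0, 360)", call. = FALSE)
  if (bag_arm_factor < 0 || bag_arm_factor > 0.3)
    stop("bag_arm_factor must lie in [0, 0.3]", call. = FALSE)
  if (coat_offset < 0 || coat_offset > 0.03)
    stop("coat_offset must lie in [0, 0.03] m", call. = FALSE)
  structure(list(condition = condition, view_deg = view_deg,
                 bag_arm_factor = bag_arm_factor, coat_offset = coat_offset,
                 coat_noise = coat_noise),
            class = "covariate_spec")
}

## Simulator -----------------------------------------------------------------

#' Simulate a 3D walking sequence
#'
#' Generates joint trajectories from a planar-dominant kinematic chain: the
#' hip center advances along +X at `stride length x cadence` with vertical
#' bounce at twice the stride frequency; legs swing as antiphase hip/knee
#' sinusoids, arms antiphase to their ipsilateral legs; i.i.d. Gaussian
#' noise of standard deviation `noise_sigma` is added to every coordinate;
#' the covariate perturbation and the viewing rotation are applied last.
#' Bone lengths are constant over time in the noise-free limit.
#'
#' @param params A [gait_params()].
#' @param cov A [covariate_spec()].
#' @param duration Sequence length in seconds (`duration * fps >= 2`).
#' @param fps Frame rate.
#' @param noise_sigma Joint noise standard deviation (m).
#' @param seed Integer seed fixing all randomness.
#' @param layout `"GSI17"` (native) or `"KINECT25"` (extremity joints
#'   extrapolated from wrists/ankles, to exercise the layout converters).
#' @return A [skeleton_sequence] with subject metadata taken from
#'   `params`/`cov` attributes when present.
#' @param meta Metadata list stored on the sequence.
#' @export
simulate_sequence <- function(params, cov = covariate_spec("NM", 90),
                              duration = 4, fps = 30, noise_sigma = 0.005,
                              seed = 1L, layout = c("GSI17", "KINECT25"),
                              meta = list()) {
  stopifnot(inherits(params, "gait_params"), inherits(cov, "covariate_spec"))
  layout <- match.arg(layout)
  nf <- as.integer(round(duration * fps))
  if (nf < 2L) stop("duration * fps must be at least 2", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(split_seed(seed, "sim", cov$condition, round(cov$view_deg * 1000)))

  p <- params
  tt <- (seq_len(nf) - 1L) / fps
  phi <- 2 * pi * p$cadence * tt
  leg <- p$thigh + p$shank
  step_len <- 2 * leg * sin(p$hip_amp)
  speed <- 2 * step_len * p$cadence        # two steps per stride

  arm_amp_l <- p$arm_amp
  arm_amp_r <- p$arm_amp
  if (cov$condition == "BG") arm_amp_r <- p$arm_amp * cov$bag_arm_factor

  hip_y <- leg * 0.96 + p$bounce * cos(2 * phi)
  hip_c <- rbind(speed * tt, hip_y, 0)

  kp <- gsi17_keypoints()
  J <- array(0, c(17L, 3L, nf))
  put <- function(name, m) J[match(name, kp), , ] <<- m

  put("hip_center", hip_c)
  sh_c <- hip_c + c(0, p$torso, 0)
  put("shoulder_center", sh_c)
  put("spine_center", (hip_c + sh_c) / 2)
  put("neck", sh_c + c(0, 0.4 * p$neck_head, 0))
  put("head", sh_c + c(0, p$neck_head, 0))

  ## legs: hip angle about Z at the hip joint, knee flexion backward
  leg_side <- function(zoff, phase) {
    th_hip <- p$hip_amp * sin(phi + phase)
    th_knee <- p$knee_amp * (1 - cos(phi + phase)) / 2
    hip <- hip_c + c(0, 0, zoff)
    knee <- hip + rbind(p$thigh * sin(th_hip), -p$thigh * cos(th_hip), 0)
    ankle <- knee + rbind(p$shank * sin(th_hip - th_knee),
                          -p$shank * cos(th_hip - th_knee), 0)
    list(hip = hip, knee = knee, ankle = ankle)
  }
  L <- leg_side(+p$hip_width / 2, 0)
  R <- leg_side(-p$hip_width / 2, pi)
  put("l_hip", L$hip); put("l_knee", L$knee); put("l_ankle", L$ankle)
  put("r_hip", R$hip); put("r_knee", R$knee); put("r_ankle", R$ankle)

  ## arms: antiphase to the ipsilateral leg, slight constant elbow flexion
  arm_side <- function(zoff, phase, amp) {
    th_arm <- amp * sin(phi + phase + pi)
    sh <- sh_c + c(0, 0, zoff)
    elb <- sh + rbind(p$upper_arm * sin(th_arm), -p$upper_arm * cos(th_arm), 0)
    wr <- elb + rbind(p$forearm * sin(th_arm + 0.35),
                      -p$forearm * cos(th_arm + 0.35), 0)
    list(sh = sh, elb = elb, wr = wr)
  }
  AL <- arm_side(+p$shoulder_width / 2, 0, arm_amp_l)
  AR <- arm_side(-p$shoulder_width / 2, pi, arm_amp_r)
  put("l_shoulder", AL$sh); put("l_elbow", AL$elb); put("l_wrist", AL$wr)
  put("r_shoulder", AR$sh); put("r_elbow", AR$elb); put("r_wrist", AR$wr)

  ## measurement noise on every coordinate
  if (noise_sigma > 0)
    J <- J + array(rnorm(length(J), 0, noise_sigma), dim(J))

  ## covariate perturbations (after noise, before the viewing rotation)
  if (cov$condition == "CL") {
    torso_kp <- match(c("shoulder_center", "spine_center", "hip_center",
                        "l_hip", "r_hip", "l_shoulder", "r_shoulder"), kp)
    ## outward bias along z (toward/away from camera), fixed per joint
    bias <- runif(length(torso_kp), 0, cov$coat_offset) *
      sample(c(-1, 1), length(torso_kp), replace = TRUE)
    J[torso_kp, 3, ] <- J[torso_kp, 3, ] + bias
    J <- J + array(rnorm(length(J), 0, cov$coat_noise), dim(J))
  }

  ## viewing rotation (camera yaw) as a rigid Y rotation
  th <- cov$view_deg * pi / 180
  Ry <- rotation_y(th)[1:3, 1:3]
  d <- dim(J)
  J <- aperm(array(Ry %*% matrix(aperm(J, c(2, 1, 3)), nrow = 3),
                   c(3, d[1], d[3])), c(2, 1, 3))

  meta <- utils::modifyList(list(view_deg = cov$view_deg,
                                 covariate = cov$condition), meta)
  out <- skeleton_sequence(J, layout = "GSI17", fps = fps, meta = meta)
  if (layout == "KINECT25") out <- gsi17_to_kinect25(out)
  out
}

## inverse layout embedding used only by the simulator: extremities are
## extrapolated so the KINECT25 -> GSI17 converter can be exercised
gsi17_to_kinect25 <- function(seq) {
  stopifnot(seq$layout == "GSI17")
  kp <- gsi17_keypoints()
  kj <- kinect25_joints()
  m <- source_mapping("KINECT25")
  nf <- n_frames(seq)
  out <- array(0, c(25L, 3L, nf))
  for (g in names(m$direct))
    out[match(m$direct[[g]], kj), , ] <- seq$frames[match(g, kp), , ]
  ext <- function(base, prev, f) {
    seq$frames[match(base, kp), , ] +
      f * (seq$frames[match(base, kp), , ] - seq$frames[match(prev, kp), , ])
  }
  out[match("HandLeft", kj), , ]     <- ext("l_wrist", "l_elbow", 0.25)
  out[match("HandTipLeft", kj), , ]  <- ext("l_wrist", "l_elbow", 0.40)
  out[match("ThumbLeft", kj), , ]    <- ext("l_wrist", "l_elbow", 0.20)
  out[match("HandRight", kj), , ]    <- ext("r_wrist", "r_elbow", 0.25)
  out[match("HandTipRight", kj), , ] <- ext("r_wrist", "r_elbow", 0.40)
  out[match("ThumbRight", kj), , ]   <- ext("r_wrist", "r_elbow", 0.20)
  out[match("FootLeft", kj), , ]     <- ext("l_ankle", "l_knee", 0.15)
  out[match("FootRight", kj), , ]    <- ext("r_ankle", "r_knee", 0.15)
  ## the io convention has z toward the camera; Kinect z points away
  out[, 3, ] <- -out[, 3, ]
  skeleton_sequence(out, layout = "KINECT25", fps = seq$fps, meta = seq$meta)
}

#' Render silhouettes for a simulated sequence
#'
#' Orthographic binary body silhouettes: the union of thick capsules along
#' the bone edges, rendered on the canvas at a fixed sequence-global scale.
#' With `body_width = 0` this reduces to the 1-px line rasterization of the
#' projected skeleton.
#'
#' @param seq A `GSI17` [skeleton_sequence] (typically noise-free simulator
#'   output).
#' @param body_width Capsule diameter in meters added around each bone.
#' @param canvas_w,canvas_h,margin Canvas geometry.
#' @return A [silhouette_stack] with one frame per input frame.
#' @export
simulate_silhouettes <- function(seq, body_width = 0.10, canvas_w = 80L,
                                 canvas_h = 120L, margin = 0.9) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  norm <- normalize_sequence(seq)
  proj <- project_and_fit(norm, canvas_w = canvas_w, canvas_h = canvas_h,
                          margin = margin)
  tpx <- max(1, body_width * proj$scale)   # body width in pixels
  frames <- lapply(seq_len(n_frames(proj)), function(k)
    rasterize_lines(proj$frames[, , k], thickness = tpx,
                    canvas_w = canvas_w, canvas_h = canvas_h,
                    conf = proj$conf[, k]))
  silhouette_stack(frames, fps = seq$fps, meta = seq$meta)
}

## Cohorts -------------------------------------------------------------------

#' Generate a labelled synthetic cohort
#'
#' Draws per-subject gait parameters deterministically from the master seed
#' and simulates every (subject, trial, view, covariate) combination. Trial
#' randomness (noise realization, small cadence jitter) differs between
#' trials of one subject; kinematic identity does not.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param trials_per_subject Trials per subject/view/covariate cell.
#' @param views Numeric vector of viewing angles (degrees).
#' @param covariates Character subset of `c("NM", "BG", "CL")`.
#' @param seed Master seed; all randomness derives from it.
#' @param duration,fps,noise_sigma Passed to [simulate_sequence()].
#' @param dir Optional directory; when given, sequences are written there in
#'   the JSON-lines format and the manifest gains a `file` column.
#' @return A tibble manifest with columns `subject`, `trial`, `view_deg`,
#'   `covariate`, `sequence` (list column) and optionally `file`.
#' @export
make_cohort <- function(n_subjects, trials_per_subject, views = 90,
                        covariates = "NM", seed = 1L, duration = 4,
                        fps = 30, noise_sigma = 0.005, dir = NULL) {
  if (n_subjects < 2L) stop("a cohort needs at least 2 subjects",
                            call. = FALSE)
  stopifnot(all(covariates %in% c("NM", "BG", "CL")))
  grid <- expand.grid(trial = seq_len(trials_per_subject),
                      subject = sprintf("S%03d", seq_len(n_subjects)),
                      view_deg = views, covariate = covariates,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject, grid$covariate, grid$view_deg,
                     grid$trial), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    p <- draw_gait_params(seed, g$subject)
    cv <- covariate_spec(g$covariate, view_deg = g$view_deg)
    s <- simulate_sequence(
      p, cv, duration = duration, fps = fps, noise_sigma = noise_sigma,
      seed = split_seed(seed, g$subject, g$trial),
      meta = list(subject = g$subject, trial = g$trial,
                  view_deg = g$view_deg, covariate = g$covariate))
    tibble::tibble(subject = g$subject, trial = g$trial,
                   view_deg = g$view_deg, covariate = g$covariate,
                   sequence = list(s))
  })
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- sprintf("%s_t%02d_v%03d_%s.jsonl", manifest$subject,
                     manifest$trial, round(manifest$view_deg),
                     manifest$covariate)
    paths <- file.path(dir, files)
    for (i in seq_len(nrow(manifest)))
      write_sequence(manifest$sequence[[i]], paths[i])
    manifest$file <- paths
    utils::write.csv(
      manifest[, c("subject", "trial", "view_deg", "covariate", "file")],
      file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  manifest
}
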