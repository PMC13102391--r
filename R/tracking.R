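#' Synthetic open-field frame stack
#'
#' Renders a dark circular blob moving over a white background along a
#' supplied pixel path, optionally corrupted by salt-and-pepper noise —
#' a minimal stand-in for an overhead open-field video with known ground
#' truth.
#'
#' @param path Numeric matrix or data frame with columns `x`, `y`: blob
#'   centre per frame, in pixels (x = column, y = row). Centres must lie
#'   within the frame.
#' @param width,height Frame size in pixels.
#' @param radius Blob radius in pixels.
#' @param noise Fraction of pixels per frame flipped to pure black or
#'   white (salt-and-pepper density; 0 disables).
#' @param fps Frames per second of the notional recording.
#' @param scale_cm_per_px Pixel-to-cm conversion factor.
#' @param seed RNG seed for the noise.
#' @return Object of class `frame_stack`: list with `frames` (array
#'   `height x width x n`, grayscale in `[0, 1]`), `fps`,
#'   `scale_cm_per_px`.
#' @export
synth_frames <- function(path, width = 200, height = 200, radius = 8,
                         noise = 0, fps = 25, scale_cm_per_px = 0.1,
                         seed = 1L) {
  path <- as_xy(path)
  stopifnot(fps > 0, scale_cm_per_px > 0, radius > 0, noise >= 0,
            noise < 1)
  if (any(path$x < 1 | path$x > width | path$y < 1 | path$y > height)) {
    stop("path leaves the frame bounds", call. = FALSE)
  }
  n <- nrow(path)
  frames <- array(1, dim = c(height, width, n))
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  rows <- matrix(seq_len(height), height, width)
  for (i in seq_len(n)) {
    disk <- (cols - path$x[i])^2 + (rows - path$y[i])^2 <= radius^2
    f <- frames[, , i]
    f[disk] <- 0
    frames[, , i] <- f
  }
  if (noise > 0) {
    frames <- with_seed(seed, {
      npix <- round(noise * width * height)
      for (i in seq_len(n)) {
        idx <- sample.int(width * height, npix)
        f <- frames[, , i]
        f[idx] <- ifelse(stats::runif(npix) > 0.5, 1, 0)
        frames[, , i] <- f
      }
      frames
    })
  }
  structure(list(frames = frames, fps = fps,
                 scale_cm_per_px = scale_cm_per_px),
            class = "frame_stack")
}

#' Detect the animal centroid in one grayscale frame
#'
#' Foreground extraction for a dark animal on a light background:
#' edge-preserving median denoising, Gaussian blur, intensity threshold
#' (Otsu's histogram method by default), connected-component labelling,
#' and the area centroid of the largest component. Frames with no
#' component above the minimum area — or with essentially no contrast —
#' yield a no-detection flag rather than an error.
#'
#' @param frame Numeric matrix in `[0, 1]` (rows = y, columns = x).
#' @param threshold Binarisation threshold; `NULL` (default) uses Otsu's
#'   method on the blurred frame.
#' @param blur_sigma Gaussian blur SD in pixels (0 disables).
#' @param median_size Half-width of the median denoising filter in
#'   pixels (0 disables).
#' @param min_area Minimum component area in pixels.
#' @return List `x`, `y` (centroid in pixels, `NA` if undetected),
#'   `detected` (logical), `area` (component area in pixels).
#' @export
detect_centroid <- function(frame, threshold = NULL, blur_sigma = 1,
                            median_size = 1, min_area = 20) {
  no_detection <- list(x = NA_real_, y = NA_real_, detected = FALSE,
                       area = 0L)
  if (diff(range(frame)) < 0.02) return(no_detection)
  img <- EBImage::Image(frame)
  if (median_size > 0) img <- EBImage::medianFilter(img, median_size)
  if (blur_sigma > 0) img <- EBImage::gblur(img, sigma = blur_sigma)
  th <- if (is.null(threshold)) EBImage::otsu(img) else threshold
  mask <- img < th
  lab <- EBImage::bwlabel(mask)
  labels <- as.integer(as.vector(lab))
  sizes <- tabulate(labels[labels > 0L])
  if (!length(sizes) || max(sizes) < min_area) return(no_detection)
  k <- which.max(sizes)
  idx <- which(matrix(labels, nrow = nrow(frame)) == k, arr.ind = TRUE)
  list(x = mean(idx[, 2]), y = mean(idx[, 1]), detected = TRUE,
       area = sizes[k])
}

# Choose the most-smoothed cubic smoothing spline whose residual sum of
# squares does not exceed `target` (the smoothing-condition
# parameterisation), and predict at `t_out`.
spline_with_rss <- function(t, y, target, t_out) {
  lin_pred <- function() {
    f <- stats::lm(y ~ t)
    unname(stats::predict(f, data.frame(t = t_out)))
  }
  if (length(unique(t)) < 4 || stats::sd(y) == 0) {
    if (length(unique(t)) < 2 || stats::sd(y) == 0) {
      return(rep(mean(y), length(t_out)))
    }
    return(lin_pred())
  }
  rss_at <- function(spar) {
    fit <- stats::smooth.spline(t, y, spar = spar)
    sum((stats::predict(fit, t)$y - y)^2)
  }
  fit_at <- function(spar) {
    fit <- stats::smooth.spline(t, y, spar = spar)
    stats::predict(fit, t_out)$y
  }
  out <- tryCatch({
    lo <- -1.5
    hi <- 1.5
    if (rss_at(hi) <= target) {
      fit_at(hi)
    } else if (rss_at(lo) >= target) {
      fit_at(lo)
    } else {
      spar <- stats::uniroot(function(s) rss_at(s) - target,
                             c(lo, hi))$root
      fit_at(spar)
    }
  }, error = function(e) lin_pred())
  out
}

#' Track and smooth an animal trajectory across a frame stack
#'
#' Runs [detect_centroid()] on every frame, then smooths each coordinate
#' with a cubic smoothing spline whose smoothing condition is
#' `smooth_factor` times the number of valid detections (i.e. the
#' fitted residual sum of squares is capped at `0.2 * N` pixels^2 by
#' default). Detection gaps shorter than `max_gap_s` seconds are filled
#' by the spline; longer gaps split the trajectory and remain invalid.
#'
#' @param stack A [synth_frames()]-style `frame_stack` (or list with
#'   `frames`, `fps`).
#' @param smooth_factor Smoothing condition per valid frame
#'   (default 0.2).
#' @param max_gap_s Longest detection gap, in seconds, interpolated by
#'   the spline.
#' @inheritParams detect_centroid
#' @return Tibble `frame, x_px, y_px, valid, x_s, y_s` where `x_s`,
#'   `y_s` are the smoothed coordinates (`NA` on long gaps).
#' @export
track_and_smooth <- function(stack, threshold = NULL, blur_sigma = 1,
                             median_size = 1, min_area = 20,
                             smooth_factor = 0.2, max_gap_s = 0.5) {
  frames <- stack$frames
  n <- dim(frames)[3]
  det <- lapply(seq_len(n), function(i)
    detect_centroid(frames[, , i], threshold = threshold,
                    blur_sigma = blur_sigma, median_size = median_size,
                    min_area = min_area))
  traj <- tibble::tibble(
    frame = seq_len(n),
    x_px = vapply(det, `[[`, numeric(1), "x"),
    y_px = vapply(det, `[[`, numeric(1), "y"),
    valid = vapply(det, `[[`, logical(1), "detected")
  )
  if (sum(traj$valid) < 2) {
    stop("fewer than 2 valid detections; cannot smooth", call. = FALSE)
  }
  max_gap <- max(1L, floor(max_gap_s * stack$fps))

  # split at invalid runs of length >= max_gap
  runs <- rle(traj$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segment <- integer(n)
  seg_id <- 1L
  for (j in seq_along(runs$lengths)) {
    if (!runs$values[j] && runs$lengths[j] >= max_gap) {
      segment[starts[j]:ends[j]] <- NA_integer_
      seg_id <- seg_id + 1L
    } else {
      segment[starts[j]:ends[j]] <- seg_id
    }
  }

  traj$x_s <- traj$y_s <- NA_real_
  for (s in unique(stats::na.omit(segment))) {
    in_seg <- which(segment == s)
    v <- in_seg[traj$valid[in_seg]]
    if (length(v) < 2) next
    span <- min(v):max(v)  # do not extrapolate beyond outer detections
    target <- smooth_factor * length(v)
    traj$x_s[span] <- spline_with_rss(traj$frame[v], traj$x_px[v],
                                      target, traj$frame[span])
    traj$y_s[span] <- spline_with_rss(traj$frame[v], traj$y_px[v],
                                      target, traj$frame[span])
  }
  traj
}

#' Distance travelled and windowed speed from a smoothed trajectory
#'
#' Sums the frame-to-frame displacements of the smoothed trajectory for
#' the total distance, converts per-frame steps to instantaneous speeds
#' (`step * fps * scale`), and averages the speeds over centred sliding
#' windows of 1 s.
#'
#' @param traj Output of [track_and_smooth()].
#' @param fps Frames per second (> 0).
#' @param scale_cm_per_px Pixel-to-cm scale factor (> 0).
#' @return List with `total_distance_cm`, `mean_speed_cm_s`, and `speed`
#'   (tibble `frame, speed_cm_s` of 1-s-window averages; `NA` where the
#'   trajectory is undefined).
#' @export
kinematics <- function(traj, fps, scale_cm_per_px) {
  if (fps <= 0 || scale_cm_per_px <= 0) {
    stop("fps and scale_cm_per_px must be positive", call. = FALSE)
  }
  n <- nrow(traj)
  dx <- diff(traj$x_s)
  dy <- diff(traj$y_s)
  step_px <- sqrt(dx^2 + dy^2)                # NA across undefined frames
  total <- sum(step_px, na.rm = TRUE) * scale_cm_per_px
  inst <- c(NA_real_, step_px * fps * scale_cm_per_px)

  half <- max(0L, floor(round(fps) / 2))
  win_speed <- vapply(seq_len(n), function(i) {
    w <- inst[max(1L, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))

  list(
    total_distance_cm = total,
    mean_speed_cm_s = mean(inst, na.rm = TRUE),
    speed = tibble::tibble(frame = traj$frame, speed_cm_s = win_speed)
  )
}
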