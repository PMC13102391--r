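# Rotate footprint coordinates into a travel-aligned frame: x along the
# direction of travel, y lateral. The travel direction defaults to the
# first principal axis of the right prints, oriented so their given row
# order progresses forwards.
travel_frame <- function(prints, travel = NULL) {
  xy <- cbind(prints$x, prints$y)
  is_r <- prints$side == "R"
  if (is.null(travel)) {
    ref <- if (sum(is_r) >= 2) xy[is_r, , drop = FALSE] else xy
    u <- stats::prcomp(ref, center = TRUE)$rotation[, 1]
    if (sum(diff(ref %*% u)) < 0) u <- -u
  } else {
    u <- travel / sqrt(sum(travel^2))
  }
  nvec <- c(-u[2], u[1])
  data.frame(side = prints$side,
             px = as.vector(xy %*% u),
             py = as.vector(xy %*% nvec))
}

point_line_distance <- function(p, a, b) {
  ab <- b - a
  abs(ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])) / sqrt(sum(ab^2))
}

#' Footprint gait metrics
#'
#' Computes the footprint-pattern metrics from ordered hindpaw centroid
#' coordinates (left/right side, x, y in cm):
#'
#' * `stride_length`: mean distance between consecutive same-side
#'   prints (right-right and left-left pooled);
#' * `hindbase_width`: mean distance between paired right and left
#'   prints (each left print paired with the right print preceding it
#'   along travel);
#' * `linearity`: a perpendicular reference line is erected at the first
#'   right print; the angle from it to each subsequent right print is
#'   measured, and the mean absolute change between consecutive angles
#'   (degrees) is reported — 0 for right prints collinear along travel,
#'   high for meandering paths;
#' * `sigma`: SD of the pooled right-right and left-left step distances
#'   (step-length regularity);
#' * `gait_width`: mean perpendicular distance of each print to the line
#'   joining its opposite-side preceding and succeeding prints;
#' * `alternation_coefficient`: mean of `|0.5 - d(R_i, L_i) /
#'   d(R_i, R_{i+1})|` over left prints enclosed by consecutive right
#'   prints — 0 for perfectly alternating steps.
#'
#' Metrics whose own preconditions fail (e.g. fewer than 3 right prints
#' for linearity) are reported as `NA`; fewer than 2 prints in total is
#' an error. All metrics are invariant under rigid motions of the whole
#' print set; the length-valued ones scale with the coordinates and
#' linearity is scale-free.
#'
#' @param prints Data frame with columns `side` (`"L"`/`"R"`), `x`, `y`
#'   in cm, same-side prints ordered along travel.
#' @param travel Optional length-2 direction of travel; when `NULL`,
#'   estimated as the first principal axis of the right prints.
#' @return One-row tibble of the six metrics.
#' @examples
#' prints <- data.frame(
#'   side = c("R", "R", "R", "R", "L", "L", "L"),
#'   x = c(0, 10, 20, 30, 5, 15, 25),
#'   y = c(0, 0, 0, 0, 3, 3, 3))
#' compute_gait(prints)
#' @export
compute_gait <- function(prints, travel = NULL) {
  if (!all(c("side", "x", "y") %in% names(prints))) {
    stop("prints must have columns side, x, y", call. = FALSE)
  }
  if (!all(prints$side %in% c("L", "R"))) {
    stop("side must be 'L' or 'R'", call. = FALSE)
  }
  if (nrow(prints) < 2) stop("need at least 2 prints", call. = FALSE)

  pf <- travel_frame(prints, travel)
  r <- pf[pf$side == "R", ]
  l <- pf[pf$side == "L", ]
  r <- r[order(r$px), ]
  l <- l[order(l$px), ]

  step_dist <- function(s) {
    if (nrow(s) < 2) return(numeric(0))
    sqrt(diff(s$px)^2 + diff(s$py)^2)
  }
  steps <- c(step_dist(r), step_dist(l))
  stride_length <- if (length(steps)) mean(steps) else NA_real_
  sigma <- if (length(steps) >= 2) stats::sd(steps) else NA_real_

  linearity <- NA_real_
  if (nrow(r) >= 3) {
    v <- cbind(r$px[-1] - r$px[1], r$py[-1] - r$py[1])
    ang <- atan2(v[, 1], v[, 2]) * 180 / pi  # angle from the perpendicular
    linearity <- mean(abs(diff(ang)))
  }

  # gait width: each print vs the line through its opposite-side
  # flanking prints
  widths <- numeric(0)
  for (side_pair in list(list(p = r, o = l), list(p = l, o = r))) {
    p <- side_pair$p
    o <- side_pair$o
    if (nrow(o) < 2) next
    for (i in seq_len(nrow(p))) {
      prev <- which(o$px < p$px[i])
      nxt <- which(o$px > p$px[i])
      if (length(prev) && length(nxt)) {
        a <- as.numeric(o[max(prev), c("px", "py")])
        b <- as.numeric(o[min(nxt), c("px", "py")])
        widths <- c(widths,
                    point_line_distance(as.numeric(p[i, c("px", "py")]),
                                        a, b))
      }
    }
  }
  gait_width <- if (length(widths)) mean(widths) else NA_real_

  # alternation and hindbase: left print enclosed by consecutive rights
  alt <- hind <- numeric(0)
  if (nrow(r) >= 2 && nrow(l) >= 1) {
    for (i in seq_len(nrow(r) - 1)) {
      inside <- which(l$px >= r$px[i] & l$px < r$px[i + 1])
      if (!length(inside)) next
      li <- inside[1]
      d_rl <- sqrt((l$px[li] - r$px[i])^2 + (l$py[li] - r$py[i])^2)
      d_rr <- sqrt((r$px[i + 1] - r$px[i])^2 + (r$py[i + 1] - r$py[i])^2)
      alt <- c(alt, abs(0.5 - d_rl / d_rr))
      hind <- c(hind, d_rl)
    }
  }
  tibble::tibble(
    stride_length = stride_length,
    hindbase_width = if (length(hind)) mean(hind) else NA_real_,
    linearity = linearity,
    sigma = sigma,
    gait_width = gait_width,
    alternation_coefficient = if (length(alt)) mean(alt) else NA_real_
  )
}
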