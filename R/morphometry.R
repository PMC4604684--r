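#' Parameters of a synthetic vessel-ring image
#'
#' Describes an annular vessel cross section: a wall of elevated intensity
#' between the inner (lumen) and outer (external lamina) boundary, with
#' optional concentric elastic-lamina ridges, angular branch gaps, and
#' additive Gaussian noise. `axis_ratio < 1` turns the ring into a radially
#' scaled ellipse (semi-minor / semi-major), so the radial wall extent along
#' an angle has a closed geometric form that serves as the measurement
#' oracle.
#'
#' @param size image side length (pixels, >= 64).
#' @param center ring centre, `c(row, col)` in 1-based pixel coordinates;
#'   default the image centre.
#' @param inner_radius,outer_radius semi-major lumen / external radii (px).
#' @param axis_ratio semi-minor over semi-major axis (1 = circle).
#' @param n_laminae number of concentric bright ridges inside the wall.
#' @param wall_intensity,background,laminae_contrast,laminae_sigma intensity
#'   levels (arbitrary units) and ridge width (px).
#' @param branch_angles optional matrix/list of `c(angle_deg, half_width_deg)`
#'   rows: the wall is removed within `half_width` of each angle (a branch
#'   point / incomplete ring).
#' @param edge_width width of the linear intensity ramp at each wall boundary
#'   (px); the half-maximum crossing sits exactly on the boundary.
#' @param noise_sd additive Gaussian noise (intensity units).
#' @param scale microns per pixel, or `NULL`.
#' @return object of class `ring_image_params`.
#' @export
ring_image_params <- function(size = 192, center = NULL, inner_radius = 40,
                              outer_radius = 60, axis_ratio = 1,
                              n_laminae = 4, wall_intensity = 0.5,
                              background = 0.1, laminae_contrast = 0.3,
                              laminae_sigma = 0.7, branch_angles = NULL,
                              edge_width = 1, noise_sd = 0, scale = NULL) {
  if (size < 64) stop_param("image size must be at least 64 px")
  if (!(inner_radius > 0 && inner_radius < outer_radius))
    stop_param("need 0 < inner_radius < outer_radius")
  if (outer_radius >= size / 2)
    stop_param("outer_radius must fit inside the image")
  if (axis_ratio <= 0 || axis_ratio > 1)
    stop_param("axis_ratio must lie in (0, 1]")
  if (n_laminae < 0) stop_param("n_laminae must be >= 0")
  if (!is.null(branch_angles)) {
    branch_angles <- rbind(branch_angles)
    if (ncol(branch_angles) != 2)
      stop_param("branch_angles needs columns angle, half_width (degrees)")
  }
  center <- center %||% c((size + 1) / 2, (size + 1) / 2)
  structure(list(size = size, center = center, inner_radius = inner_radius,
                 outer_radius = outer_radius, axis_ratio = axis_ratio,
                 n_laminae = n_laminae, wall_intensity = wall_intensity,
                 background = background, laminae_contrast = laminae_contrast,
                 laminae_sigma = laminae_sigma, branch_angles = branch_angles,
                 edge_width = edge_width, noise_sd = noise_sd, scale = scale),
            class = "ring_image_params")
}

# radial extent of a radially scaled ellipse along angle theta (radians)
ellipse_radius <- function(theta, a, b) {
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

#' Generate a synthetic vessel-ring image
#'
#' Renders the annulus described by a [ring_image_params()] with analytic
#' per-angle ground truth for the 16 standard sampling angles.
#'
#' @param params a [ring_image_params()].
#' @param seed integer seed for the noise; `NULL` leaves the RNG alone.
#' @param truth_angles angles (degrees) at which ground truth is tabulated.
#' @return list with `image` (matrix, rows = y, 1-based) and `truth`
#'   (data frame: `angle`, `inner`, `outer`, `thickness`, `in_gap`).
#' @export
generate_ring_image <- function(params, seed = NULL,
                                truth_angles = seq(0, 337.5, by = 22.5)) {
  stopifnot(inherits(params, "ring_image_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  n <- p$size
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  x <- col - p$center[2]
  y <- -(row - p$center[1]) # angles counter-clockwise from +x axis
  rho <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  a_out <- p$outer_radius
  b_out <- p$outer_radius * p$axis_ratio
  a_in <- p$inner_radius
  b_in <- p$inner_radius * p$axis_ratio
  r_out <- ellipse_radius(theta, a_out, b_out)
  r_in <- ellipse_radius(theta, a_in, b_in)
  e <- p$edge_width
  ramp <- function(z) pmin(1, pmax(0, z + 0.5))
  wall <- ramp((rho - r_in) / e) * (1 - ramp((rho - r_out) / e))
  gap <- matrix(1, n, n)
  ang_deg <- (theta * 180 / pi) %% 360
  if (!is.null(p$branch_angles)) {
    for (i in seq_len(nrow(p$branch_angles))) {
      d <- abs(((ang_deg - p$branch_angles[i, 1]) + 180) %% 360 - 180)
      gap[d <= p$branch_angles[i, 2]] <- 0
    }
  }
  img <- p$background + p$wall_intensity * wall * gap
  if (p$n_laminae > 0) {
    for (k in seq_len(p$n_laminae)) {
      fr <- (k - 0.5) / p$n_laminae
      r_k <- r_in + fr * (r_out - r_in)
      img <- img + p$laminae_contrast *
        exp(-(rho - r_k)^2 / (2 * p$laminae_sigma^2)) * wall * gap
    }
  }
  if (p$noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, p$noise_sd), n, n)
  th <- truth_angles * pi / 180
  in_gap <- rep(FALSE, length(th))
  if (!is.null(p$branch_angles)) {
    for (i in seq_len(nrow(p$branch_angles))) {
      d <- abs(((truth_angles - p$branch_angles[i, 1]) + 180) %% 360 - 180)
      in_gap <- in_gap | d <= p$branch_angles[i, 2]
    }
  }
  truth <- data.frame(
    angle = truth_angles,
    inner = ellipse_radius(th, a_in, b_in),
    outer = ellipse_radius(th, a_out, b_out),
    in_gap = in_gap
  )
  truth$thickness <- truth$outer - truth$inner
  list(image = img, truth = truth, params = p)
}

#' Locate the ring centre
#'
#' Intensity-weighted centroid of the pixels above the half-range threshold.
#'
#' @param image numeric matrix.
#' @param min_frac minimum fraction of pixels the ring must occupy.
#' @return `c(row, col)`, 1-based fractional pixel coordinates.
#' @export
find_center <- function(image, min_frac = 0.01) {
  rng <- range(image)
  if (diff(rng) < 1e-9) stop_param("image is blank: no ring found")
  thr <- rng[1] + 0.5 * diff(rng)
  mask <- image > thr
  if (mean(mask) < min_frac)
    stop_param("thresholded ring occupies under %.0f%% of the image",
               100 * min_frac)
  w <- (image - rng[1]) * mask
  rows <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  cols <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)
  c(row = sum(rows * w) / sum(w), col = sum(cols * w) / sum(w))
}

#' Cast radial sampling rays through the ring
#'
#' `n_lines` lines through the centre at `180 / n_lines` degree increments
#' yield `2 * n_lines` rays (the standard 8 lines at 22.5 degrees give 16
#' intersection points). Each ray is sampled from the centre to the image
#' edge at sub-pixel steps by bilinear interpolation. Angles are measured
#' counter-clockwise from the +x (column) axis.
#'
#' @param image numeric matrix.
#' @param center `c(row, col)` centre (1-based).
#' @param n_lines number of lines (rays = 2 * n_lines).
#' @param step radial sampling step (px).
#' @return list of per-ray lists with `angle` (degrees), `r` (radii, px) and
#'   `intensity`.
#' @export
cast_rays <- function(image, center, n_lines = 8, step = 0.25) {
  nr <- nrow(image)
  nc <- ncol(image)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc)
    stop_param("center lies outside the image")
  angles <- (seq_len(2 * n_lines) - 1) * 180 / n_lines
  lapply(angles, function(a) {
    th <- a * pi / 180
    dc <- cos(th)
    dr <- -sin(th)
    tmax <- Inf
    if (dr > 1e-12) tmax <- min(tmax, (nr - center[1]) / dr)
    if (dr < -1e-12) tmax <- min(tmax, (1 - center[1]) / dr)
    if (dc > 1e-12) tmax <- min(tmax, (nc - center[2]) / dc)
    if (dc < -1e-12) tmax <- min(tmax, (1 - center[2]) / dc)
    r <- seq(0, tmax, by = step)
    list(angle = a, r = r,
         intensity = bilinear(image, center[1] + r * dr, center[2] + r * dc))
  })
}

#' Wall thickness along one radial profile
#'
#' The inner boundary is the first crossing of the profile above the
#' half-maximum level (relative to the profile's own minimum and maximum)
#' moving outward from the lumen; the outer boundary is the last such
#' crossing (the external lamina). Crossing positions are interpolated
#' between samples. Rays without a wall are excluded with a reason.
#'
#' @param ray one element of [cast_rays()] output.
#' @param scale microns per pixel, or `NULL`.
#' @param min_contrast minimum profile range below which no wall is declared.
#' @return one-row data frame: `angle`, `inner`, `outer`, `thickness_px`,
#'   `thickness_um`, `laminae`, `excluded`, `reason`.
#' @export
measure_thickness <- function(ray, scale = NULL, min_contrast = 0.05) {
  v <- ray$intensity
  r <- ray$r
  out <- data.frame(angle = ray$angle, inner = NA_real_, outer = NA_real_,
                    thickness_px = NA_real_, thickness_um = NA_real_,
                    laminae = NA_integer_, excluded = TRUE,
                    reason = "no wall", stringsAsFactors = FALSE)
  if (diff(range(v)) < min_contrast) return(out)
  # half-max relative to the wall plateau, not the profile maximum: bright
  # laminae ridges would otherwise pull the level up and bias both crossings
  # into the wall
  level0 <- min(v) + 0.5 * diff(range(v))
  plateau <- stats::median(v[v >= level0])
  level <- min(v) + 0.5 * (plateau - min(v))
  above <- v >= level
  if (!any(above)) return(out)
  i1 <- which(above)[1]
  i2 <- which(above)[length(which(above))]
  interp_cross <- function(i_lo, i_hi) {
    # linear interpolation of the crossing between samples i_lo < i_hi
    r[i_lo] + (level - v[i_lo]) / (v[i_hi] - v[i_lo]) * (r[i_hi] - r[i_lo])
  }
  inner <- if (i1 == 1) r[1] else interp_cross(i1 - 1, i1)
  outer <- if (i2 == length(v)) r[i2] else interp_cross(i2 + 1, i2)
  out$inner <- inner
  out$outer <- outer
  out$thickness_px <- outer - inner
  if (!is.null(scale)) out$thickness_um <- out$thickness_px * scale
  out$excluded <- FALSE
  out$reason <- ""
  out
}

#' Count elastic laminae along one radial profile
#'
#' Number of local maxima of the profile within the wall bounds whose
#' elevation above the wall plateau (the lower decile of wall intensity,
#' which is insensitive to how much of the wall the ridges cover) exceeds
#' `prominence_frac` of the wall contrast (wall maximum above the lumen
#' baseline). Measuring ridge prominence against the plateau makes a
#' uniform wall count zero: its only "peak" is the plateau itself.
#'
#' @param ray one element of [cast_rays()] output.
#' @param inner,outer wall bounds (px) from [measure_thickness()].
#' @param prominence_frac prominence threshold as a fraction of wall
#'   contrast.
#' @param bound_margin margin (px) trimmed inside each wall boundary so the
#'   boundary intensity ramps themselves are not counted as ridges.
#' @return integer count.
#' @export
count_laminae <- function(ray, inner, outer, prominence_frac = 0.2,
                          bound_margin = 1) {
  if (is.na(inner) || is.na(outer)) return(NA_integer_)
  keep <- ray$r >= inner + bound_margin & ray$r <= outer - bound_margin
  v <- ray$intensity[keep]
  if (length(v) < 3) return(0L)
  contrast <- max(v) - min(ray$intensity)
  if (contrast <= 0) return(0L)
  plateau <- stats::quantile(v, 0.10, names = FALSE)
  pk <- local_maxima(v)
  if (!length(pk)) return(0L)
  sum(v[pk] - plateau >= prominence_frac * contrast)
}

#' Measure one vessel ring
#'
#' Full radial morphometry of one cross-section image: centre finding, ray
#' casting, per-ray wall thickness and laminae count, and automatic
#' exclusion of rays whose wall extent deviates from the ring median by more
#' than `extent_tol` (branch points / incomplete portions), plus optional
#' user-supplied excluded angle ranges.
#'
#' @param image numeric matrix.
#' @param n_lines number of sampling lines (rays = 2 * n_lines).
#' @param step radial sampling step (px).
#' @param scale microns per pixel, or `NULL`.
#' @param center optional `c(row, col)`; default [find_center()].
#' @param exclude_angles optional matrix/list of `c(from_deg, to_deg)` rows;
#'   rays with angles inside any range are excluded as user-masked.
#' @param extent_tol relative deviation of a ray's thickness from the ring
#'   median beyond which the ray is excluded.
#' @param prominence_frac passed to [count_laminae()].
#' @return data frame with one row per ray (see [measure_thickness()]).
#' @export
measure_ring <- function(image, n_lines = 8, step = 0.25, scale = NULL,
                         center = NULL, exclude_angles = NULL,
                         extent_tol = 0.5, prominence_frac = 0.2) {
  center <- center %||% find_center(image)
  rays <- cast_rays(image, center, n_lines = n_lines, step = step)
  rows <- lapply(rays, measure_thickness, scale = scale)
  df <- do.call(rbind, rows)
  for (i in seq_along(rays)) {
    if (!df$excluded[i])
      df$laminae[i] <- count_laminae(rays[[i]], df$inner[i], df$outer[i],
                                     prominence_frac = prominence_frac)
  }
  med <- stats::median(df$thickness_px[!df$excluded])
  if (is.finite(med) && med > 0) {
    dev <- abs(df$thickness_px - med) / med
    bad <- !df$excluded & dev > extent_tol
    df$excluded[bad] <- TRUE
    df$reason[bad] <- "wall extent deviates from ring median"
  }
  if (!is.null(exclude_angles)) {
    exclude_angles <- rbind(exclude_angles)
    for (i in seq_len(nrow(exclude_angles))) {
      inr <- df$angle >= exclude_angles[i, 1] &
        df$angle <= exclude_angles[i, 2]
      df$excluded[inr] <- TRUE
      df$reason[inr] <- "user-masked angle"
    }
  }
  attr(df, "center") <- center
  df
}

#' Aggregate ring measurements across sections
#'
#' Mean thickness over the included points of each ring, averaged across
#' sections (the standard three 5-um sections per animal); the same
#' aggregation for laminae counts.
#'
#' @param sections list of per-ring data frames from [measure_ring()].
#' @return list of class `morphometry_summary`: `mean_thickness_px`,
#'   `mean_thickness_um`, `mean_laminae`, `n_included`, `per_section`.
#' @export
summarize_rings <- function(sections) {
  if (!length(sections)) stop_param("no sections supplied")
  per <- lapply(sections, function(df) {
    inc <- df[!df$excluded, ]
    if (!nrow(inc))
      return(data.frame(thickness_px = NA_real_, thickness_um = NA_real_,
                        laminae = NA_real_, n_included = 0L))
    data.frame(thickness_px = mean(inc$thickness_px),
               thickness_um = mean(inc$thickness_um),
               laminae = mean(inc$laminae, na.rm = TRUE),
               n_included = nrow(inc))
  })
  per <- do.call(rbind, per)
  if (all(per$n_included == 0))
    stop_param("all rays excluded in every section")
  ok <- per$n_included > 0
  structure(list(mean_thickness_px = mean(per$thickness_px[ok]),
                 mean_thickness_um = mean(per$thickness_um[ok]),
                 mean_laminae = mean(per$laminae[ok]),
                 n_included = per$n_included,
                 per_section = per),
            class = "morphometry_summary")
}
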