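# Trajectory safety metrics: intracerebral length from the inner skull
# crossing, drilling angle against the outer skull normal, proximity-based
# risk along the intracerebral segment, clearance from the brainstem,
# contact with the amygdalohippocampal core, and ventricular transgression.

#' Construct a trajectory
#'
#' @param entry,target World-space points (mm, RAS+). Must differ.
#' @param label Free-text label (e.g. `"manual"`, `"cap"`).
#' @return Object of class `trajectory` with fields `entry`, `target`,
#'   `direction` (unit vector entry -> target) and `label`.
#' @export
trajectory <- function(entry, target, label = "") {
  entry <- as.numeric(entry); target <- as.numeric(target)
  stopifnot(length(entry) == 3, length(target) == 3)
  if (sqrt(sum((target - entry)^2)) < 1e-9)
    stop("trajectory entry and target coincide")
  structure(list(entry = entry, target = target,
                 direction = unit3(target - entry), label = label),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory%s: entry (%s) -> target (%s), %.1f mm\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              paste(sprintf("%.1f", x$entry), collapse = ", "),
              paste(sprintf("%.1f", x$target), collapse = ", "),
              sqrt(sum((x$target - x$entry)^2))))
  invisible(x)
}

#' Risk-model parameters
#'
#' The proximity risk ramp assigns risk 1 to points closer than `d_lo` mm
#' to a critical structure and risk 0 beyond `d_hi` mm, falling linearly in
#' between. Overall trajectory risk is the path integral of pointwise risk
#' over the intracerebral segment divided by `norm_length`. `safety_margin`
#' is the feasibility clearance from critical structures.
#'
#' @param d_lo,d_hi Risk ramp endpoints, mm (defaults 3 and 10).
#' @param sample_step Sampling interval along the trajectory, mm.
#' @param norm_length Normalizing length for the risk integral, mm.
#' @param safety_margin Minimum allowed clearance, mm (default 3).
#' @return Object of class `risk_params`.
#' @export
risk_params <- function(d_lo = 3, d_hi = 10, sample_step = 1.0,
                        norm_length = 10.0, safety_margin = 3) {
  stopifnot(d_lo > 0, d_hi > d_lo, sample_step > 0, norm_length > 0,
            safety_margin >= 0)
  structure(list(d_lo = d_lo, d_hi = d_hi, sample_step = sample_step,
                 norm_length = norm_length, safety_margin = safety_margin),
            class = "risk_params")
}

#' Pointwise risk of proximity to critical structures
#'
#' Risk is 1 at distances at or below `d_lo`, 0 at or beyond `d_hi`, and
#' falls linearly in between: continuous and non-increasing in distance.
#'
#' @param d Distance(s) from the nearest critical structure, mm (>= 0).
#' @param params A [risk_params].
#' @return Risk value(s) in `[0, 1]`.
#' @export
pointwise_risk <- function(d, params = risk_params()) {
  stopifnot(all(d >= 0))
  pmin(1, pmax(0, (params$d_hi - d) / (params$d_hi - params$d_lo)))
}

# First zero crossing of an interpolated signed field along the ray
# p(t) = origin + t * dir, bracketing by coarse marching then bisection.
ray_surface_crossing <- function(signed, affine, origin, dir,
                                 t_range, coarse = 1.0, tol = 0.01) {
  ts <- seq(t_range[1], t_range[2], by = coarse)
  if (ts[length(ts)] < t_range[2]) ts <- c(ts, t_range[2])
  pts <- outer(ts, dir) + matrix(origin, length(ts), 3, byrow = TRUE)
  v <- interp_trilinear(signed, affine, pts)
  pos <- which(v > 0); neg <- which(v <= 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  i <- which(v[-length(v)] > 0 & v[-1] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  a <- ts[i]; b <- ts[i + 1]
  while (b - a > tol) {
    m <- (a + b) / 2
    vm <- interp_trilinear(signed, affine,
                           matrix(origin + m * dir, 1, 3))
    if (vm > 0) a <- m else b <- m
  }
  (a + b) / 2
}

# Entry-side crossing of a skull surface for a trajectory. The entry point
# of a planned trajectory lies on (inside) the brain surface, so the search
# starts from a point pushed outward beyond the skull along the backward
# extension of the trajectory line.
skull_crossing_point <- function(traj, skull, surface = c("inner", "outer"),
                                 back = 60) {
  surface <- match.arg(surface)
  signed <- if (surface == "inner") skull$inner_signed else
    skull$outer_signed
  dir <- traj$direction
  t_len <- sqrt(sum((traj$target - traj$entry)^2))
  t0 <- -back
  # push the start outward until the signed field is positive there
  repeat {
    v0 <- interp_trilinear(signed, skull$affine,
                           matrix(traj$entry + t0 * dir, 1, 3))
    if (v0 > 0 || t0 < -400) break
    t0 <- t0 - 30
  }
  if (v0 <= 0) stop("no ", surface, "-skull crossing found along trajectory")
  tc <- ray_surface_crossing(signed, skull$affine, traj$entry, dir,
                             c(t0, t_len))
  if (is.na(tc)) stop("no ", surface, "-skull crossing found along trajectory")
  list(t = tc, point = traj$entry + tc * dir)
}

#' Intracerebral trajectory length
#'
#' Euclidean distance from the first inner-skull (intracranial boundary)
#' crossing of the trajectory line to the target, the crossing located by
#' bisection on the interpolated signed distance field to 0.01 mm.
#'
#' @param traj A [trajectory]; its target must lie inside the inner skull.
#' @param skull A [skull_model].
#' @return Length in mm.
#' @export
intracerebral_length <- function(traj, skull) {
  vt <- interp_trilinear(skull$inner_signed, skull$affine,
                         matrix(traj$target, 1, 3))
  if (vt > 0) stop("trajectory target lies outside the inner skull")
  cr <- skull_crossing_point(traj, skull, "inner")
  sqrt(sum((traj$target - cr$point)^2))
}

#' Drilling angle at the outer skull surface
#'
#' Angle between the trajectory direction and the outward surface normal at
#' the first outer-skull crossing, folded into `[0, 90]` degrees; 0 degrees
#' is orthogonal drilling.
#'
#' @inheritParams intracerebral_length
#' @return Angle in degrees.
#' @export
drilling_angle <- function(traj, skull) {
  cr <- skull_crossing_point(traj, skull, "outer")
  n <- skull_outer_normal(skull, matrix(cr$point, 1, 3))[1, ]
  cosv <- abs(sum(traj$direction * n))
  acos(min(1, cosv)) * 180 / pi
}

# Midpoint-rule samples of the intracerebral segment: returns sample
# points, the step actually used and the segment length.
intracerebral_samples <- function(traj, skull, step) {
  cr <- skull_crossing_point(traj, skull, "inner")
  p0 <- cr$point; p1 <- traj$target
  L <- sqrt(sum((p1 - p0)^2))
  n <- max(1L, ceiling(L / step))
  tmid <- (seq_len(n) - 0.5) / n
  pts <- outer(tmid, p1 - p0) + matrix(p0, n, 3, byrow = TRUE)
  list(points = pts, ds = L / n, length = L, p0 = p0, p1 = p1)
}

#' Overall trajectory risk
#'
#' Path integral of the pointwise proximity risk over the intracerebral
#' segment (midpoint rule at `sample_step` mm, trilinear interpolation of
#' the critical-structure distance field), divided by the normalizing
#' length. Values above 1 indicate sustained travel close to critical
#' structures.
#'
#' @param traj A [trajectory].
#' @param critical A [distance_field] to the critical structures.
#' @param skull A [skull_model].
#' @param params A [risk_params].
#' @return Dimensionless risk >= 0.
#' @export
overall_risk <- function(traj, critical, skull, params = risk_params()) {
  s <- intracerebral_samples(traj, skull, params$sample_step)
  d <- interp_trilinear(critical$field, critical$affine, s$points)
  sum(pointwise_risk(d, params)) * s$ds / params$norm_length
}

# Golden-section refinement of the minimum of an interpolated field along
# the segment p0 -> p1, seeded at the minimal coarse sample.
refine_line_min <- function(field, affine, p0, p1, t_samples, values,
                            tol = 0.01) {
  L <- sqrt(sum((p1 - p0)^2))
  i <- which.min(values)
  a <- t_samples[max(1, i - 1)]; b <- t_samples[min(length(t_samples), i + 1)]
  gr <- (sqrt(5) - 1) / 2
  f <- function(t) interp_trilinear(field, affine,
                                    matrix(p0 + t * (p1 - p0), 1, 3))
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while ((b - a) * L > tol) {
    if (f1 <= f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2) }
  }
  min(min(values), f1, f2)
}

# Minimum of a distance field over the intracerebral segment, golden-
# section refined to sub-voxel precision.
segment_min_distance <- function(traj, dfield, skull, step = 1.0) {
  s <- intracerebral_samples(traj, skull, step)
  n <- nrow(s$points)
  tmid <- (seq_len(n) - 0.5) / n
  ts <- c(0, tmid, 1)
  pts <- rbind(s$p0, s$points, s$p1)
  vals <- interp_trilinear(dfield$field, dfield$affine, pts)
  refine_line_min(dfield$field, dfield$affine, s$p0, s$p1, ts, vals)
}

#' Minimum distance from critical structures
#'
#' @inheritParams overall_risk
#' @return Minimum interpolated distance (mm) over the intracerebral
#'   segment.
#' @export
min_critical_distance <- function(traj, critical, skull,
                                  params = risk_params()) {
  segment_min_distance(traj, critical, skull, params$sample_step)
}

#' Minimum distance from the brainstem
#'
#' @param traj A [trajectory].
#' @param brainstem Brainstem [roi_mask] (non-empty).
#' @param volume The parent [label_volume].
#' @param skull A [skull_model].
#' @param params A [risk_params].
#' @param at Either `"minimum"` over the intracerebral segment (default) or
#'   `"midpoint"`, the distance at the segment's center.
#' @return Distance in mm.
#' @export
brainstem_distance <- function(traj, brainstem, volume, skull,
                               params = risk_params(),
                               at = c("minimum", "midpoint")) {
  at <- match.arg(at)
  if (!any(brainstem$mask)) stop("brainstem mask is empty")
  df <- distance_field(brainstem, volume)
  if (at == "midpoint") {
    s <- intracerebral_samples(traj, skull, params$sample_step)
    mid <- (s$p0 + s$p1) / 2
    return(interp_trilinear(df$field, df$affine, matrix(mid, 1, 3)))
  }
  segment_min_distance(traj, df, skull, params$sample_step)
}

#' Proportion of the trajectory within the AHC core
#'
#' Operationalizes "contact with the center of the amygdalohippocampal
#' complex": the arc length of the trajectory inside the AHC core (voxels
#' at least `core_margin` mm interior to the AHC boundary) divided by the
#' extent of the AHC along its first principal axis, clipped to `[0, 1]`.
#'
#' @param traj A [trajectory].
#' @param ahc AHC [roi_mask] (amygdala plus tectal-truncated hippocampus).
#' @param volume The parent [label_volume].
#' @param core_margin Erosion depth defining the core, mm (default 1.5).
#' @param step Arc-length sampling interval, mm.
#' @return Fraction in `[0, 1]`.
#' @export
ahc_center_proportion <- function(traj, ahc, volume, core_margin = 1.5,
                                  step = 0.25, cache = NULL) {
  if (!any(ahc$mask)) stop("AHC mask is empty")
  if (is.null(cache)) cache <- ahc_geometry(ahc, volume)
  depth <- cache$depth
  if (max(depth[ahc$mask]) < core_margin) {
    warning("AHC core is empty at margin ", core_margin,
            " mm; using the full AHC mask")
    core_margin <- 0
  }
  L <- sqrt(sum((traj$target - traj$entry)^2))
  n <- max(1L, ceiling(L / step))
  tmid <- (seq_len(n) - 0.5) / n
  pts <- outer(tmid, traj$target - traj$entry) +
    matrix(traj$entry, n, 3, byrow = TRUE)
  dv <- interp_trilinear(depth, volume$affine, pts)
  inside_len <- sum(if (core_margin > 0) dv >= core_margin else dv > 0) *
    (L / n)
  min(1, max(0, inside_len / cache$extent))
}

# Interior depth field of the AHC and its principal-axis extent; computed
# once per bundle and reused across candidate trajectories.
ahc_geometry <- function(ahc, volume) {
  depth <- sqrt(.edt_squared(!ahc$mask, dim(ahc$mask), volume$spacing))
  coords <- mask_world_coords(ahc$mask, volume$affine)
  ctr <- colMeans(coords)
  pc1 <- eigen(stats::cov(coords), symmetric = TRUE)$vectors[, 1]
  proj <- as.vector(sweep(coords, 2, ctr) %*% pc1)
  list(depth = depth, extent = max(proj) - min(proj))
}

#' Assemble the anatomical model bundle for planning and metrics
#'
#' Extracts the role masks, truncates the hippocampus at the tectal plate,
#' forms the AHC, and precomputes the skull model and distance fields that
#' the metric, planner and ablation modules consume.
#'
#' @param volume A [label_volume] with the required roles.
#' @param tectal_plane_y Coronal world y of the tectal plate, mm.
#' @return A list of class `anatomy_bundle` with masks (`amygdala`,
#'   `hippocampus`, `hippocampus_full`, `ahc`, `ventricles`, `brainstem`,
#'   `critical`), `skull`, distance fields `critical_field` and
#'   `brainstem_field`, `tectal_plane_y`, `side` (hemisphere of the
#'   amygdala centroid) and the `volume`.
#' @export
anatomy_bundle <- function(volume, tectal_plane_y) {
  amy <- extract_roi(volume, "amygdala")
  hip_full <- extract_roi(volume, "hippocampus")
  hip <- truncate_hippocampus(hip_full, volume, tectal_plane_y)
  ahc <- roi_mask("ahc", amy$mask | hip$mask, volume)
  vent <- extract_roi(volume, "ventricles")
  stem <- extract_roi(volume, "brainstem")
  crit <- extract_roi(volume, "critical")
  side <- if (mean(mask_world_coords(amy$mask, volume$affine)[, 1]) < 0)
    "left" else "right"
  structure(list(
    volume = volume, amygdala = amy, hippocampus = hip,
    hippocampus_full = hip_full, ahc = ahc, ventricles = vent,
    brainstem = stem, critical = crit,
    skull = skull_model(volume),
    critical_field = distance_field(crit, volume),
    brainstem_field = distance_field(stem, volume),
    ahc_cache = ahc_geometry(ahc, volume),
    tectal_plane_y = tectal_plane_y, side = side),
    class = "anatomy_bundle")
}

#' Compute the full safety-metric bundle for one trajectory
#'
#' Aggregates intracerebral length, drilling angle, minimum critical
#' distance, overall risk, AHC-core contact proportion, brainstem distance
#' and ventricular transgression. Metric failures are collected per metric
#' (value `NA`) rather than aborting the bundle.
#'
#' @param traj A [trajectory].
#' @param bundle An [anatomy_bundle].
#' @param params A [risk_params].
#' @return Object of class `trajectory_metrics`; fields
#'   `intracerebral_length`, `drilling_angle`, `min_critical_distance`,
#'   `overall_risk`, `ahc_center_proportion`, `brainstem_distance`,
#'   `ventricle_hit`, plus `errors` (named character vector of failures).
#' @export
compute_metrics <- function(traj, bundle, params = risk_params()) {
  errors <- character(0)
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }
  len <- grab("intracerebral_length",
              intracerebral_length(traj, bundle$skull))
  ang <- grab("drilling_angle", drilling_angle(traj, bundle$skull))
  mind <- grab("min_critical_distance",
               min_critical_distance(traj, bundle$critical_field,
                                     bundle$skull, params))
  risk <- grab("overall_risk",
               overall_risk(traj, bundle$critical_field, bundle$skull,
                            params))
  ahc <- grab("ahc_center_proportion",
              ahc_center_proportion(traj, bundle$ahc, bundle$volume,
                                    cache = bundle$ahc_cache))
  stem <- grab("brainstem_distance",
               segment_min_distance(traj, bundle$brainstem_field,
                                    bundle$skull, params$sample_step))
  vhit <- grab("ventricle_hit", {
    s <- intracerebral_samples(traj, bundle$skull, 0.25)
    any(mask_lookup(bundle$ventricles$mask, bundle$volume$affine,
                    s$points))
  })
  structure(list(intracerebral_length = len, drilling_angle = ang,
                 min_critical_distance = mind, overall_risk = risk,
                 ahc_center_proportion = ahc, brainstem_distance = stem,
                 ventricle_hit = isTRUE(vhit), errors = errors),
            class = "trajectory_metrics")
}

#' @export
print.trajectory_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "trajectory metrics:\n",
    "  intracerebral length : %.1f mm\n",
    "  drilling angle       : %.1f deg\n",
    "  min critical distance: %.2f mm\n",
    "  overall risk         : %.3f\n",
    "  AHC core proportion  : %.3f\n",
    "  brainstem distance   : %.1f mm\n",
    "  ventricle hit        : %s\n"),
    x$intracerebral_length, x$drilling_angle, x$min_critical_distance,
    x$overall_risk, x$ahc_center_proportion, x$brainstem_distance,
    x$ventricle_hit))
  if (length(x$errors))
    cat("  metric errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
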