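# Parametric head phantom: a spherical head with ellipsoid amygdala, tube
# hippocampus, ventricular horn, sulcal sheets (critical-structure proxies),
# brainstem cylinder and three entry-gyrus surface patches, all with analytic
# ground truth. Stands in for a parcellated patient scan so the planner,
# metrics and ablation modules are testable end to end.

PHANTOM_LABELS <- c(
  brain = 1L, skull = 2L, amygdala = 3L, hippocampus = 4L,
  entorhinal = 5L, parahippocampal = 6L, ventricles = 7L, critical = 8L,
  brainstem = 9L, entry_inferior_occipital = 10L,
  entry_middle_occipital = 11L, entry_posterior_middle_temporal = 12L)

#' Parameters of the synthetic head phantom
#'
#' All geometry is expressed in RAS+ world millimetres for a left-sided
#' phantom and mirrored across the midsagittal plane when `side = "right"`.
#' Structures: spherical skull shell; ellipsoid amygdala; hippocampus and
#' parahippocampal gyrus / entorhinal cortex as tubes along polylines; the
#' temporal/occipital horn of the lateral ventricle as a tube with
#' per-vertex radii; sulci as thin planar sheets anchored at the basal
#' surface and rising along an in-plane direction to a configurable depth
#' (the collateral sulcus carries the `depth` knob used by the
#' deep-collateral-sulcus variant); a brainstem cylinder; and three
#' entry-gyrus patches (angular sectors of the brain surface shell).
#'
#' @param grid_shape Integer 3-vector, voxels per axis.
#' @param voxel_spacing Numeric 3-vector, mm per axis (all > 0).
#' @param side `"left"` or `"right"` hemisphere of pathology.
#' @param skull_outer_radius,skull_inner_radius Skull shell radii in mm.
#' @param amygdala_center,amygdala_radii Ellipsoid center and semi-axes, mm.
#' @param hippocampus_curve Matrix of world points (rows) for the tube
#'   centerline.
#' @param hippocampus_radius Tube radius, mm.
#' @param ventricle_curve,ventricle_radius Horn centerline and radius
#'   (scalar or per-vertex).
#' @param sulci_planes Named list of sheet specs; each a list with fields
#'   `c` (anchor point on the bottom edge), `n` (unit sheet normal),
#'   `depth` (mm risen along the in-plane up-direction), `thickness` (mm)
#'   and `y_range` (anterior-posterior extent).
#' @param brainstem_axis 2 x 3 matrix (axis endpoints).
#' @param brainstem_radius Cylinder radius, mm.
#' @param entry_patch_specs Named list (one per entry role) of lists with
#'   `dir` (unit direction of the patch center from the head center) and
#'   `angle_deg` (angular patch radius).
#' @param patch_thickness Radial thickness of the entry-patch shell, mm.
#' @param encx_curve,encx_radius,phg_curve,phg_radius Entorhinal cortex and
#'   parahippocampal gyrus tubes.
#' @param tectal_plane_y Coronal world y of the tectal plate, mm.
#' @param jitter_sd Standard deviation (mm) of seeded random perturbation
#'   applied to tube centerline vertices; 0 disables jitter.
#' @param seed Integer seed for the jitter.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(192L, 192L, 192L),
                           voxel_spacing = c(1, 1, 1),
                           side = c("left", "right"),
                           skull_outer_radius = 85,
                           skull_inner_radius = 78,
                           amygdala_center = c(-26, 4, -16),
                           amygdala_radii = c(8, 7, 7),
                           hippocampus_curve = rbind(
                             c(-24.0,   2, -19.0),
                             c(-24.3,  -8, -20.5),
                             c(-24.8, -18, -21.7),
                             c(-25.5, -28, -22.7)),
                           hippocampus_radius = 5,
                           ventricle_curve = rbind(
                             c(-30,  -2, -9),
                             c(-31, -14, -8),
                             c(-32, -28, -7),
                             c(-33, -44, -5),
                             c(-32, -56, -3)),
                           ventricle_radius = 3.5,
                           sulci_planes = list(
                             collateral = list(
                               c = c(-35.5, -32, -43.7),
                               n = c(0.89, 0, -0.45),
                               depth = 13, thickness = 1,
                               y_range = c(-56, -10)),
                             occipitotemporal = list(
                               c = c(-44, -30, -44),
                               n = c(0.80, 0, -0.60),
                               depth = 14, thickness = 1,
                               y_range = c(-54, -8))),
                           brainstem_axis = rbind(c(-4, -24, -42),
                                                  c(-4, -20, 10)),
                           brainstem_radius = 9,
                           entry_patch_specs = list(
                             entry_inferior_occipital = list(
                               dir = c(-27, -70, -27), angle_deg = 5),
                             entry_middle_occipital = list(
                               dir = c(-56, -50.7, -7.8), angle_deg = 6),
                             entry_posterior_middle_temporal = list(
                               dir = c(-68, -32, -10), angle_deg = 6)),
                           patch_thickness = 3,
                           encx_curve = rbind(c(-20, 4, -24),
                                              c(-22, -8, -25)),
                           encx_radius = 4,
                           phg_curve = rbind(
                             c(-24,   0, -27),
                             c(-25, -10, -28),
                             c(-26, -22, -28.5),
                             c(-27, -30, -29)),
                           phg_radius = 4.5,
                           tectal_plane_y = -26,
                           jitter_sd = 0,
                           seed = 1L) {
  side <- match.arg(side)
  p <- list(grid_shape = as.integer(grid_shape),
            voxel_spacing = as.numeric(voxel_spacing), side = side,
            skull_outer_radius = skull_outer_radius,
            skull_inner_radius = skull_inner_radius,
            amygdala_center = amygdala_center,
            amygdala_radii = amygdala_radii,
            hippocampus_curve = hippocampus_curve,
            hippocampus_radius = hippocampus_radius,
            ventricle_curve = ventricle_curve,
            ventricle_radius = ventricle_radius,
            sulci_planes = sulci_planes,
            brainstem_axis = brainstem_axis,
            brainstem_radius = brainstem_radius,
            entry_patch_specs = entry_patch_specs,
            patch_thickness = patch_thickness,
            encx_curve = encx_curve, encx_radius = encx_radius,
            phg_curve = phg_curve, phg_radius = phg_radius,
            tectal_plane_y = tectal_plane_y,
            jitter_sd = jitter_sd, seed = as.integer(seed))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (any(p$voxel_spacing <= 0))
    stop("voxel_spacing must be positive on all axes")
  if (p$skull_inner_radius >= p$skull_outer_radius)
    stop("skull_inner_radius must be smaller than skull_outer_radius")
  rin <- p$skull_inner_radius
  reach <- function(pts, r) max(sqrt(rowSums(matrix(pts, ncol = 3)^2))) + r
  checks <- c(
    amygdala = sqrt(sum(p$amygdala_center^2)) + max(p$amygdala_radii),
    hippocampus = reach(p$hippocampus_curve, p$hippocampus_radius),
    ventricles = reach(p$ventricle_curve, max(p$ventricle_radius)),
    entorhinal = reach(p$encx_curve, p$encx_radius),
    parahippocampal = reach(p$phg_curve, p$phg_radius),
    brainstem = reach(p$brainstem_axis, p$brainstem_radius))
  bad <- names(checks)[checks >= rin]
  if (length(bad) > 0)
    stop("structure extends outside the inner skull: ",
         paste(bad, collapse = ", "))
  for (nm in names(p$sulci_planes)) {
    s <- p$sulci_planes[[nm]]
    if (s$depth < 0) stop("negative sulcus depth: ", nm)
    u <- sheet_up(s$n)
    edge <- rbind(s$c, s$c + s$depth * u)
    if (max(sqrt(rowSums(edge^2))) + s$thickness >= rin)
      stop("structure extends outside the inner skull: sulcus ", nm)
  }
  specs <- p$entry_patch_specs
  for (nm in names(specs)) {
    if (specs[[nm]]$angle_deg <= 0)
      stop("entry patch has non-positive angular radius: ", nm)
  }
  if (length(specs) > 1) {
    nms <- names(specs)
    for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
      a <- unit3(specs[[nms[i]]]$dir); b <- unit3(specs[[nms[j]]]$dir)
      sep <- acos(min(1, max(-1, sum(a * b)))) * 180 / pi
      if (sep <= specs[[nms[i]]]$angle_deg + specs[[nms[j]]]$angle_deg)
        stop("entry patches overlap: ", nms[i], " / ", nms[j])
    }
  }
  invisible(p)
}

# In-plane "up" direction of a sulcal sheet: perpendicular to the normal,
# within the x-z plane, rising (+z) and medially (+x for the left template).
sheet_up <- function(n) {
  n <- unit3(n)
  u <- c(-n[3], 0, n[1])
  if (u[3] < 0) u <- -u
  u
}

mirror_x_params <- function(p) {
  flip <- function(m) { m <- matrix(m, ncol = 3); m[, 1] <- -m[, 1]; m }
  p$amygdala_center[1] <- -p$amygdala_center[1]
  p$hippocampus_curve <- flip(p$hippocampus_curve)
  p$ventricle_curve <- flip(p$ventricle_curve)
  p$encx_curve <- flip(p$encx_curve)
  p$phg_curve <- flip(p$phg_curve)
  p$brainstem_axis <- flip(p$brainstem_axis)
  for (nm in names(p$sulci_planes)) {
    p$sulci_planes[[nm]]$c[1] <- -p$sulci_planes[[nm]]$c[1]
    p$sulci_planes[[nm]]$n[1] <- -p$sulci_planes[[nm]]$n[1]
  }
  for (nm in names(p$entry_patch_specs))
    p$entry_patch_specs[[nm]]$dir[1] <- -p$entry_patch_specs[[nm]]$dir[1]
  p
}

#' Generate a synthetic parcellated head phantom
#'
#' Deterministic for fixed parameters and seed. Returns the label volume
#' together with analytic ground truth (structure centroids and volumes,
#' tectal plane, the parameters used).
#'
#' @param params A [phantom_params] object.
#' @return A list of class `phantom` with elements `volume`
#'   ([label_volume]) and `ground_truth` (list with `centroids`,
#'   `volumes_mm3`, `tectal_plane_y`, `side`, `params`).
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  validate_phantom_params(params)
  p <- params
  if (p$side == "right") p <- mirror_x_params(p)
  if (p$jitter_sd > 0) p <- jitter_curves(p)

  dm <- p$grid_shape; sp <- p$voxel_spacing
  off <- (dm - 1) / 2 * sp
  affine <- rbind(cbind(diag(sp), -off), c(0, 0, 0, 1))
  xs <- (0:(dm[1] - 1)) * sp[1] - off[1]
  ys <- (0:(dm[2] - 1)) * sp[2] - off[2]
  zs <- (0:(dm[3] - 1)) * sp[3] - off[3]

  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  lab <- array(0L, dm)
  lab[r2 < p$skull_inner_radius^2] <- PHANTOM_LABELS[["brain"]]

  # entry patches: 3 mm shell sectors on the brain surface
  rr <- sqrt(r2)
  shell <- rr < p$skull_inner_radius &
    rr >= p$skull_inner_radius - p$patch_thickness
  ux <- outer(outer(xs, ys * 0, "+"), zs * 0, "+")
  uy <- outer(outer(xs * 0, ys, "+"), zs * 0, "+")
  uz <- outer(outer(xs * 0, ys * 0, "+"), zs, "+")
  for (nm in names(p$entry_patch_specs)) {
    spec <- p$entry_patch_specs[[nm]]
    d <- unit3(spec$dir)
    cosang <- (ux * d[1] + uy * d[2] + uz * d[3]) / pmax(rr, 1e-9)
    sel <- shell & cosang >= cos(spec$angle_deg * pi / 180)
    if (!any(sel)) stop("entry patch is empty: ", nm)
    lab[sel] <- PHANTOM_LABELS[[nm]]
  }
  rm(ux, uy, uz, rr)

  paint <- function(lab, sel, label) { lab[sel] <- label; lab }
  inside <- r2 < p$skull_inner_radius^2

  lab <- paint(lab, inside & tube_mask(xs, ys, zs, p$encx_curve,
                                       p$encx_radius),
               PHANTOM_LABELS[["entorhinal"]])
  lab <- paint(lab, inside & tube_mask(xs, ys, zs, p$phg_curve,
                                       p$phg_radius),
               PHANTOM_LABELS[["parahippocampal"]])
  lab <- paint(lab, inside & tube_mask(xs, ys, zs, p$ventricle_curve,
                                       p$ventricle_radius),
               PHANTOM_LABELS[["ventricles"]])
  lab <- paint(lab, inside & tube_mask(xs, ys, zs, p$brainstem_axis,
                                       p$brainstem_radius),
               PHANTOM_LABELS[["brainstem"]])
  for (nm in names(p$sulci_planes)) {
    s <- p$sulci_planes[[nm]]
    if (s$depth <= 0) next
    lab <- paint(lab, inside & sheet_mask(xs, ys, zs, s),
                 PHANTOM_LABELS[["critical"]])
  }
  lab <- paint(lab, inside & tube_mask(xs, ys, zs, p$hippocampus_curve,
                                       p$hippocampus_radius),
               PHANTOM_LABELS[["hippocampus"]])
  lab <- paint(lab, inside & ellipsoid_mask(xs, ys, zs, p$amygdala_center,
                                            p$amygdala_radii),
               PHANTOM_LABELS[["amygdala"]])
  lab <- paint(lab, r2 >= p$skull_inner_radius^2 &
                 r2 <= p$skull_outer_radius^2,
               PHANTOM_LABELS[["skull"]])
  rm(r2, inside)

  role_map <- lapply(PHANTOM_LABELS, function(x) x)
  vol <- label_volume(lab, affine, role_map)
  present <- PHANTOM_LABELS %in% unique(as.vector(lab))
  if (!all(present))
    stop("phantom structure produced no voxels: ",
         paste(names(PHANTOM_LABELS)[!present], collapse = ", "))

  gt <- list(
    centroids = list(
      amygdala = p$amygdala_center,
      hippocampus = polyline_centroid(p$hippocampus_curve),
      ventricles = polyline_centroid(p$ventricle_curve),
      brainstem = polyline_centroid(p$brainstem_axis)),
    volumes_mm3 = list(
      amygdala = 4 / 3 * pi * prod(p$amygdala_radii),
      hippocampus = capsule_volume(p$hippocampus_curve,
                                   p$hippocampus_radius),
      ventricles = capsule_volume(p$ventricle_curve, p$ventricle_radius),
      entorhinal = capsule_volume(p$encx_curve, p$encx_radius),
      parahippocampal = capsule_volume(p$phg_curve, p$phg_radius)),
    tectal_plane_y = p$tectal_plane_y,
    side = params$side,
    params = params)
  structure(list(volume = vol, ground_truth = gt), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("synthetic head phantom (", x$ground_truth$side, " side)\n", sep = "")
  print(x$volume)
  invisible(x)
}

#' Generate an anatomical-variant phantom
#'
#' Variants reshape the posteroinferior corridor so that no straight path
#' from the inferior-occipital entry patch to the planning target remains
#' feasible, forcing the planner's entry-gyrus fallback:
#' `deep_collateral_sulcus` extends the posterior collateral-sulcus sheet
#' upward into the corridor; `enlarged_occipital_horn` balloons the
#' occipital horn of the lateral ventricle inferiorly into it.
#'
#' @param params Base [phantom_params].
#' @param variant `"deep_collateral_sulcus"` or `"enlarged_occipital_horn"`.
#' @param magnitude Size of the deformation: extra sulcal depth in mm
#'   (default 21) or ventricular bulge scale (default 1). A magnitude of 0
#'   reproduces the base phantom exactly.
#' @return A `phantom`, as [generate_phantom].
#' @export
generate_variant <- function(params = phantom_params(),
                             variant = c("deep_collateral_sulcus",
                                         "enlarged_occipital_horn"),
                             magnitude = NULL) {
  variant <- match.arg(variant)
  p <- params
  if (variant == "deep_collateral_sulcus") {
    if (is.null(magnitude)) magnitude <- 21
    if (magnitude > 0) {
      s <- p$sulci_planes[["collateral"]]
      s$depth <- s$depth + magnitude
      # a deep collateral sulcus is modeled as a fuller sulcal fold:
      # thicker sheet, and posterior only (its anterior limit retreats so
      # the deepened segment stays clear of the hippocampal tail)
      s$thickness <- max(s$thickness, 3)
      s$y_range[2] <- min(s$y_range[2], -33)
      p$sulci_planes[["collateral"]] <- s
    }
  } else {
    if (is.null(magnitude)) magnitude <- 1
    if (magnitude > 0) {
      bulge <- rbind(c(-27, -32, -16), c(-27, -40, -17), c(-28, -47, -16))
      radii <- c(9, 11, 9) * magnitude
      nv <- nrow(p$ventricle_curve)
      vr <- rep(p$ventricle_radius, length.out = nv)
      # branch the horn: connect from the nearest main-horn vertex
      p$ventricle_curve <- rbind(p$ventricle_curve[seq_len(nv), ],
                                 p$ventricle_curve[nv - 1, ], bulge)
      p$ventricle_radius <- c(vr, vr[nv - 1], radii)
    }
  }
  generate_phantom(p)
}

# Seeded jitter of tube centerlines; leaves the global RNG state untouched.
jitter_curves <- function(p) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(p$seed)
  jit <- function(m) m + matrix(stats::rnorm(length(m), 0, p$jitter_sd),
                                ncol = 3)
  p$hippocampus_curve <- jit(p$hippocampus_curve)
  p$ventricle_curve <- jit(p$ventricle_curve)
  p$phg_curve <- jit(p$phg_curve)
  p
}

# ---- analytic geometry primitives over separable coordinate vectors ----

crop_range <- function(coords, lo, hi) {
  which(coords >= lo & coords <= hi)
}

# Ellipsoid membership mask on the full grid (evaluated in a bounding box).
ellipsoid_mask <- function(xs, ys, zs, center, radii) {
  out <- array(FALSE, c(length(xs), length(ys), length(zs)))
  ii <- crop_range(xs, center[1] - radii[1], center[1] + radii[1])
  jj <- crop_range(ys, center[2] - radii[2], center[2] + radii[2])
  kk <- crop_range(zs, center[3] - radii[3], center[3] + radii[3])
  if (!length(ii) || !length(jj) || !length(kk)) return(out)
  q <- outer(outer(((xs[ii] - center[1]) / radii[1])^2,
                   ((ys[jj] - center[2]) / radii[2])^2, "+"),
             ((zs[kk] - center[3]) / radii[3])^2, "+")
  out[ii, jj, kk] <- q <= 1
  out
}

# Capsule around a polyline with (possibly per-vertex) radii: a voxel is
# inside when its distance to some segment is within the linearly
# interpolated radius at the closest point of that segment.
tube_mask <- function(xs, ys, zs, pts, radius) {
  pts <- matrix(pts, ncol = 3)
  nseg <- nrow(pts) - 1
  radii <- rep(radius, length.out = nrow(pts))
  rmax <- max(radii)
  lo <- apply(pts, 2, min) - rmax; hi <- apply(pts, 2, max) + rmax
  ii <- crop_range(xs, lo[1], hi[1]); jj <- crop_range(ys, lo[2], hi[2])
  kk <- crop_range(zs, lo[3], hi[3])
  out <- array(FALSE, c(length(xs), length(ys), length(zs)))
  if (!length(ii) || !length(jj) || !length(kk)) return(out)
  gx <- rep(xs[ii], times = length(jj) * length(kk))
  gy <- rep(rep(ys[jj], each = length(ii)), times = length(kk))
  gz <- rep(zs[kk], each = length(ii) * length(jj))
  inside <- logical(length(gx))
  for (s in seq_len(nseg)) {
    a <- pts[s, ]; b <- pts[s + 1, ]
    ab <- b - a; len2 <- sum(ab^2)
    if (len2 == 0) {
      t <- rep(0, length(gx))
    } else {
      t <- ((gx - a[1]) * ab[1] + (gy - a[2]) * ab[2] +
              (gz - a[3]) * ab[3]) / len2
      t <- pmin(pmax(t, 0), 1)
    }
    dx <- gx - (a[1] + t * ab[1]); dy <- gy - (a[2] + t * ab[2])
    dz <- gz - (a[3] + t * ab[3])
    r <- radii[s] + t * (radii[s + 1] - radii[s])
    inside <- inside | (dx * dx + dy * dy + dz * dz <= r * r)
  }
  out[ii, jj, kk] <- inside
  out
}

# Thin planar sheet anchored at its bottom edge `c`, rising `depth` mm along
# the in-plane up direction, clipped to a y-range.
sheet_mask <- function(xs, ys, zs, s) {
  n <- unit3(s$n); u <- sheet_up(s$n)
  corners <- rbind(s$c, s$c + s$depth * u)
  lo <- apply(corners, 2, min) - s$thickness
  hi <- apply(corners, 2, max) + s$thickness
  lo[2] <- min(s$y_range); hi[2] <- max(s$y_range)
  ii <- crop_range(xs, lo[1], hi[1]); jj <- crop_range(ys, lo[2], hi[2])
  kk <- crop_range(zs, lo[3], hi[3])
  out <- array(FALSE, c(length(xs), length(ys), length(zs)))
  if (!length(ii) || !length(jj) || !length(kk)) return(out)
  dxn <- outer(outer((xs[ii] - s$c[1]) * n[1],
                     (ys[jj] - s$c[2]) * n[2], "+"),
               (zs[kk] - s$c[3]) * n[3], "+")
  dxu <- outer(outer((xs[ii] - s$c[1]) * u[1],
                     (ys[jj] - s$c[2]) * u[2], "+"),
               (zs[kk] - s$c[3]) * u[3], "+")
  out[ii, jj, kk] <- abs(dxn) <= s$thickness / 2 &
    dxu >= 0 & dxu <= s$depth
  out
}

polyline_centroid <- function(pts) {
  pts <- matrix(pts, ncol = 3)
  if (nrow(pts) == 1) return(pts[1, ])
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  mid <- (pts[-1, , drop = FALSE] + pts[-nrow(pts), , drop = FALSE]) / 2
  colSums(mid * len) / sum(len)
}

# Closed-form capsule volume: cylinder segments plus hemispherical end
# caps; joint overlaps of a gently curved polyline are neglected.
capsule_volume <- function(pts, radius) {
  pts <- matrix(pts, ncol = 3)
  radii <- rep(radius, length.out = nrow(pts))
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  rmid <- (radii[-1] + radii[-length(radii)]) / 2
  sum(pi * rmid^2 * len) + 2 / 3 * pi * radii[1]^3 +
    2 / 3 * pi * radii[length(radii)]^3
}

#' Write a phantom to disk
#'
#' Writes `volume.nii.gz` (labels), `labelmap.json`
#' (`{label: role}`) and `ground_truth.json` into a directory.
#'
#' @param phantom A `phantom` from [generate_phantom].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vol <- phantom$volume
  img_path <- file.path(dir, "volume.nii.gz")
  write_label_nifti(vol, img_path)
  lm <- stats::setNames(
    as.list(names(vol$role_map)),
    vapply(vol$role_map, function(x) as.character(x[1]), ""))
  lm_path <- file.path(dir, "labelmap.json")
  jsonlite::write_json(lm, lm_path, auto_unbox = TRUE, pretty = TRUE)
  gt <- phantom$ground_truth
  gt$params <- NULL # parameters are not JSON-stable; keep geometry facts
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(volume = img_path, labelmap = lm_path,
              ground_truth = gt_path))
}

#' Write a label or mask array as NIfTI-1
#'
#' @param volume A [label_volume], or a list with `data`/logical array and
#'   `affine`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_label_nifti <- function(volume, path) {
  data <- volume$data
  storage.mode(data) <- "integer"
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- affine_spacing(volume$affine)
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
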