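# Cylindrical ablation-zone model: a flat-capped cylinder dilated around
# the trajectory, per-ROI overlap volumetrics and residual mesial
# hippocampal head depth.

ABLATION_ROLES <- c("amygdala", "hippocampus", "entorhinal",
                    "parahippocampal")

#' Model the expected ablation zone
#'
#' A finite cylinder of the given diameter around the trajectory line with
#' flat caps: the distal cap at the target, the proximal cap at the tectal
#' coronal plane (default) or at a fixed distance from the target.
#'
#' @param traj A [trajectory].
#' @param volume The [label_volume] grid to voxelize on.
#' @param diameter Ablation diameter in mm, within `[5, 20]` (default 15,
#'   the conservative device maximum applied to the model).
#' @param extent Either `"tectal"` (proximal cap where the trajectory
#'   crosses the tectal plane) or a single number: the cylinder length in
#'   mm back from the target.
#' @param tectal_plane_y Required when `extent = "tectal"`.
#' @param supersample Integer s: estimate the zone volume with s^3
#'   subsamples per voxel in addition to the center-rule mask (1 = off).
#' @return Object of class `ablation_zone`: `axis` (the trajectory),
#'   `diameter`, `proximal_limit`, `distal_limit`, `mask` (center-rule
#'   voxelization), `volume_mm3` and, when supersampled,
#'   `volume_supersampled_mm3`.
#' @export
ablation_zone <- function(traj, volume, diameter = 15, extent = "tectal",
                          tectal_plane_y = NULL, supersample = 1L) {
  if (diameter < 5 || diameter > 20)
    stop("ablation diameter must be within [5, 20] mm, got ", diameter)
  dir <- traj$direction
  distal <- traj$target
  if (identical(extent, "tectal")) {
    if (is.null(tectal_plane_y))
      stop("extent = \"tectal\" requires tectal_plane_y")
    if (abs(dir[2]) < 1e-9)
      stop("trajectory parallel to the tectal plane; ",
           "use a fixed-length extent")
    t_cross <- (tectal_plane_y - traj$entry[2]) / dir[2]
    t_target <- (traj$target[2] - traj$entry[2]) / dir[2]
    if (t_cross <= 0 || t_cross >= t_target)
      stop("trajectory does not cross the tectal plane between entry ",
           "and target; use a fixed-length extent")
    proximal <- traj$entry + t_cross * dir
  } else {
    L <- as.numeric(extent)
    if (!is.finite(L) || L <= 0) stop("invalid fixed-length extent")
    proximal <- distal - L * dir
  }
  r <- diameter / 2
  len <- sqrt(sum((distal - proximal)^2))
  axis_u <- unit3(distal - proximal)

  vox_in_cyl <- function(xyz) {
    rel <- sweep(xyz, 2, proximal)
    a <- rel %*% axis_u
    perp2 <- rowSums(rel^2) - a^2
    a >= 0 & a <= len & perp2 <= r^2
  }

  dm <- dim(volume$data)
  # bounding box in voxel space
  corners <- rbind(proximal, distal)
  lo_w <- pmin(corners[1, ], corners[2, ]) - r - max(volume$spacing)
  hi_w <- pmax(corners[1, ], corners[2, ]) + r + max(volume$spacing)
  vlo <- floor(voxel_from_world(volume$affine, rbind(lo_w, hi_w)))
  vhi <- ceiling(voxel_from_world(volume$affine, rbind(lo_w, hi_w)))
  lo <- pmax(apply(rbind(vlo, vhi), 2, min), 0)
  hi <- pmin(apply(rbind(vlo, vhi), 2, max), dm - 1)
  if (any(hi < lo)) stop("ablation zone lies outside the volume grid")
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  grid_ijk <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  xyz <- world_from_voxel(volume$affine, grid_ijk)
  inside <- vox_in_cyl(xyz)
  mask <- array(FALSE, dm)
  mask[grid_ijk + 1] <- inside
  voxvol <- prod(volume$spacing)
  out <- list(axis = traj, diameter = diameter, proximal_limit = proximal,
              distal_limit = distal, mask = mask,
              volume_mm3 = sum(mask) * voxvol)
  if (supersample > 1L) {
    s <- as.integer(supersample)
    offs <- (seq_len(s) - (s + 1) / 2) / s # sub-voxel offsets in [-0.5,0.5)
    sub <- as.matrix(expand.grid(dx = offs, dy = offs, dz = offs))
    frac <- numeric(nrow(grid_ijk))
    for (q in seq_len(nrow(sub))) {
      xyz_q <- world_from_voxel(volume$affine,
                                sweep(grid_ijk, 2, sub[q, ], "+"))
      frac <- frac + vox_in_cyl(xyz_q)
    }
    out$volume_supersampled_mm3 <- sum(frac / nrow(sub)) * voxvol
  }
  structure(out, class = "ablation_zone")
}

#' @export
print.ablation_zone <- function(x, ...) {
  cat(sprintf("ablation zone: %.0f mm diameter, %.1f mm long, %.0f mm^3\n",
              x$diameter,
              sqrt(sum((x$distal_limit - x$proximal_limit)^2)),
              x$volume_mm3))
  invisible(x)
}

# Shared volumetrics: overlap of an arbitrary cavity mask with each ROI.
cavity_volumetrics <- function(cavity_mask, rois, volume) {
  dm <- dim(volume$data)
  voxvol <- prod(volume$spacing)
  rows <- lapply(rois, function(roi) {
    if (!all(dim(roi$mask) == dm))
      stop("ROI grid does not match the cavity grid: ", roi$role)
    abl <- sum(cavity_mask & roi$mask) * voxvol
    data.frame(role = roi$role, anatomical_volume_mm3 = roi$volume_mm3,
               ablated_volume_mm3 = abl,
               percent_ablated = if (roi$volume_mm3 > 0)
                 100 * abl / roi$volume_mm3 else 0,
               stringsAsFactors = FALSE)
  })
  per_roi <- do.call(rbind, rows)
  roles <- per_roi$role
  tot_sel <- roles %in% ABLATION_ROLES
  total <- data.frame(
    role = "total",
    anatomical_volume_mm3 = sum(per_roi$anatomical_volume_mm3[tot_sel]),
    ablated_volume_mm3 = sum(per_roi$ablated_volume_mm3[tot_sel]),
    percent_ablated = NA_real_, stringsAsFactors = FALSE)
  total$percent_ablated <- if (total$anatomical_volume_mm3 > 0)
    100 * total$ablated_volume_mm3 / total$anatomical_volume_mm3 else 0
  ahc_sel <- roles %in% c("amygdala", "hippocampus")
  ahc <- data.frame(
    role = "ahc",
    anatomical_volume_mm3 = sum(per_roi$anatomical_volume_mm3[ahc_sel]),
    ablated_volume_mm3 = sum(per_roi$ablated_volume_mm3[ahc_sel]),
    percent_ablated = NA_real_, stringsAsFactors = FALSE)
  ahc$percent_ablated <- if (ahc$anatomical_volume_mm3 > 0)
    100 * ahc$ablated_volume_mm3 / ahc$anatomical_volume_mm3 else 0
  cavity_vol <- sum(cavity_mask) * voxvol
  gray <- if (cavity_vol > 0)
    sum(per_roi$ablated_volume_mm3[tot_sel]) / cavity_vol else 0
  structure(list(per_roi = rbind(per_roi, ahc, total),
                 ablation_zone_volume_mm3 = cavity_vol,
                 gray_fraction = gray,
                 residual_mhh_depth_mm = NA_real_),
            class = "ablation_report")
}

#' Per-ROI expected ablation volumetrics
#'
#' Overlap of the modeled ablation cylinder with each region of interest:
#' absolute ablated volume, percentage of the anatomical volume, the AHC
#' row (amygdala + tectal-truncated hippocampus) and a total over the
#' mesial temporal ROIs. Pass the tectal-truncated hippocampus mask for
#' hippocampal rows.
#'
#' @param zone An [ablation_zone].
#' @param rois List of [roi_mask] objects on the same grid.
#' @param volume The parent [label_volume].
#' @return Object of class `ablation_report` with `per_roi` (data frame),
#'   `ablation_zone_volume_mm3`, `gray_fraction` and
#'   `residual_mhh_depth_mm` (NA here; see [residual_mhh_depth]).
#' @export
roi_overlap_volumes <- function(zone, rois, volume) {
  cavity_volumetrics(zone$mask, rois, volume)
}

#' Volumetrics of an achieved (segmented) ablation cavity
#'
#' Same volumetrics as [roi_overlap_volumes] with an arbitrary cavity mask
#' (e.g. a manually segmented postablation cavity) in place of the
#' cylinder; additionally reports the fraction of the cavity occupied by
#' the mesial temporal ROIs (`gray_fraction`).
#'
#' @param cavity A [roi_mask] (or logical array) of the achieved cavity.
#' @param rois List of [roi_mask] objects on the same grid.
#' @param volume The parent [label_volume].
#' @return An `ablation_report`.
#' @export
achieved_cavity_report <- function(cavity, rois, volume) {
  m <- if (inherits(cavity, "roi_mask")) cavity$mask else cavity
  if (!any(m)) warning("achieved cavity mask is empty")
  cavity_volumetrics(m, rois, volume)
}

#' Residual depth of the mesial hippocampal head
#'
#' For each coronal slice intersecting the head region: start at the
#' medial-most head voxel (toward the midline given the side) and walk
#' laterally along x until the first ablated head voxel; the slice residual
#' is the walked distance (0 when the medial-most voxel is ablated, the
#' full medial-lateral head extent of the slice when no head voxel in the
#' slice is ablated). Returns the maximum slice residual.
#'
#' @param head Hippocampal-head [roi_mask] (see [hippocampal_head]),
#'   non-empty.
#' @param zone An [ablation_zone] (or logical cavity mask).
#' @param volume The parent [label_volume].
#' @param side `"left"` or `"right"`.
#' @return Residual depth in mm.
#' @export
residual_mhh_depth <- function(head, zone, volume,
                               side = c("left", "right")) {
  side <- match.arg(side)
  if (!any(head$mask)) stop("hippocampal head mask is empty")
  zmask <- if (inherits(zone, "ablation_zone")) zone$mask else zone
  idx <- which(head$mask, arr.ind = TRUE)
  abl <- head$mask & zmask
  dx <- volume$spacing[1]
  # medial-most along x: for RAS with the left hemisphere at negative x,
  # medial means larger x on the left and smaller x on the right
  a11 <- volume$affine[1, 1]
  medial_hi <- (side == "left") == (a11 > 0)
  residuals <- tapply(seq_len(nrow(idx)), idx[, 2], function(rows) {
    xi <- idx[rows, 1]
    x_med <- if (medial_hi) max(xi) else min(xi)
    abl_rows <- rows[abl[idx[rows, , drop = FALSE]]]
    if (length(abl_rows) == 0) return((max(xi) - min(xi)) * dx)
    xa <- idx[abl_rows, 1]
    x_abl <- if (medial_hi) max(xa) else min(xa)
    abs(x_med - x_abl) * dx
  })
  max(unlist(residuals))
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("ablation report (zone ",
      sprintf("%.0f", x$ablation_zone_volume_mm3), " mm^3, gray fraction ",
      sprintf("%.2f", x$gray_fraction), ")\n", sep = "")
  df <- x$per_roi
  df$anatomical_volume_mm3 <- round(df$anatomical_volume_mm3, 1)
  df$ablated_volume_mm3 <- round(df$ablated_volume_mm3, 1)
  df$percent_ablated <- round(df$percent_ablated, 2)
  print(df, row.names = FALSE)
  if (!is.na(x$residual_mhh_depth_mm))
    cat(sprintf("residual MHH depth: %.1f mm\n", x$residual_mhh_depth_mm))
  invisible(x)
}
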