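# Label-volume anatomy: role masks, distance fields, skull geometry and the
# tectal-plate truncation used for all amygdalohippocampal volumetrics.

REQUIRED_ROLES <- c("amygdala", "hippocampus", "ventricles", "critical",
                    "skull", "brain")

#' Construct a label volume
#'
#' A `label_volume` bundles a 3D integer array of anatomical labels, the
#' voxel-index-to-world affine (RAS+ mm, 0-based indices) and a role map
#' assigning anatomical roles (amygdala, hippocampus, ventricles, critical
#' structures, skull, brain, entry gyri, ...) to sets of label IDs.
#'
#' @param data 3D array of integer label IDs (0 = background).
#' @param affine 4x4 invertible voxel-to-world matrix.
#' @param role_map Named list: role string -> integer vector of label IDs.
#'   Label sets of distinct roles must be disjoint.
#' @return An object of class `label_volume` with fields `data`, `affine`,
#'   `role_map` and `spacing` (mm per axis).
#' @export
label_volume <- function(data, affine, role_map) {
  if (length(dim(data)) != 3L) stop("label data must be a 3D array")
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12)
    stop("affine is not invertible")
  if (any(abs(data - round(data)) > 0)) {
    stop("label volume contains non-integer voxel values")
  }
  all_ids <- unlist(role_map, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("role_map label-ID sets are not disjoint")
  spacing <- affine_spacing(affine)
  if (any(spacing <= 0)) stop("voxel spacing must be positive on all axes")
  structure(list(data = data, affine = affine,
                 role_map = lapply(role_map, as.integer),
                 spacing = spacing),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$data), collapse = " x "),
      "voxels,", paste(signif(x$spacing, 3), collapse = " x "), "mm\n")
  cat("roles:", paste(names(x$role_map), collapse = ", "), "\n")
  invisible(x)
}

#' Load a label volume from NIfTI plus a JSON label map
#'
#' The JSON label map is an object `{ "label_int": "role_string", ... }`.
#' Required roles (amygdala, hippocampus, ventricles, critical, skull,
#' brain) must be present; roles mapped to zero voxels are reported.
#'
#' @param image_path Path to a NIfTI-1 image with integer-valued data.
#' @param labelmap_path Path to the JSON label map.
#' @return A [label_volume].
#' @export
load_label_volume <- function(image_path, labelmap_path) {
  img <- RNifti::readNifti(image_path)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  data <- as.array(img)
  if (any(abs(data - round(data)) > 1e-9))
    stop("label image contains non-integer voxel values: ", image_path)
  data <- array(as.integer(round(data)), dim(data))
  lm <- jsonlite::read_json(labelmap_path, simplifyVector = TRUE)
  labels <- as.integer(names(lm))
  roles <- as.character(unlist(lm))
  role_map <- split(labels, roles)
  missing <- setdiff(REQUIRED_ROLES, names(role_map))
  if (length(missing) > 0)
    stop("label map is missing required role(s): ",
         paste(missing, collapse = ", "))
  vol <- label_volume(data, affine, role_map)
  present <- unique(as.vector(data))
  for (role in names(role_map)) {
    if (!any(role_map[[role]] %in% present))
      message("role mapped to zero voxels: ", role)
  }
  vol
}

#' Extract a region-of-interest mask for one anatomical role
#'
#' @param volume A [label_volume].
#' @param role Role string present in the volume's role map.
#' @return An object of class `roi_mask`: fields `role`, `mask` (3D logical
#'   array on the volume grid) and `volume_mm3`.
#' @export
extract_roi <- function(volume, role) {
  if (!role %in% names(volume$role_map))
    stop("unknown role: ", role)
  ids <- volume$role_map[[role]]
  mask <- array(volume$data %in% ids, dim(volume$data))
  roi_mask(role, mask, volume)
}

# roi_mask constructor (internal; volume_mm3 = voxel count x voxel volume)
roi_mask <- function(role, mask, volume) {
  structure(list(role = role, mask = mask,
                 volume_mm3 = sum(mask) * prod(volume$spacing)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask '%s': %d voxels, %.1f mm^3\n",
              x$role, sum(x$mask), x$volume_mm3))
  invisible(x)
}

#' Euclidean distance field to a structure
#'
#' Exact anisotropy-aware Euclidean distance transform: every voxel holds the
#' world-mm distance from its center to the nearest source voxel center.
#'
#' @param mask A [roi_mask] (non-empty) or a 3D logical array.
#' @param volume The [label_volume] supplying grid geometry.
#' @return An object of class `distance_field` with fields `source_role`,
#'   `field` (3D numeric array, mm) and `affine`.
#' @export
distance_field <- function(mask, volume) {
  role <- if (inherits(mask, "roi_mask")) mask$role else "custom"
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!any(m)) stop("distance field undefined for empty mask: ", role)
  sq <- .edt_squared(as.logical(m), dim(m), volume$spacing)
  structure(list(source_role = role, field = sqrt(sq),
                 affine = volume$affine),
            class = "distance_field")
}

# Signed distance to the boundary of a mask: positive outside, negative
# inside (mm). Used for surface-crossing searches along trajectories.
signed_distance <- function(mask, volume) {
  if (!any(mask)) stop("signed distance undefined for empty mask")
  if (all(mask)) stop("signed distance undefined for full-grid mask")
  d_out <- sqrt(.edt_squared(as.logical(mask), dim(mask), volume$spacing))
  d_in <- sqrt(.edt_squared(!mask, dim(mask), volume$spacing))
  d_out - d_in
}

#' Union mask of all intracranial (non-skull) structures
#'
#' The per-role masks of a label volume are disjoint; the full intracranial
#' mask used for surface detection and skull geometry is the union of every
#' labeled voxel that is not skull.
#'
#' @param volume A [label_volume].
#' @return A 3D logical array.
#' @export
intracranial_mask <- function(volume) {
  skull_ids <- volume$role_map[["skull"]]
  volume$data != 0L & !(volume$data %in% skull_ids)
}

#' Build the skull surface model
#'
#' The outer surface (skull + contents, filled head) carries the drilling
#' angle; the inner surface (intracranial boundary) defines intracerebral
#' length. Outward normals are the normalized gradient of the signed
#' distance to the head, sampled by trilinear interpolation.
#'
#' @param volume A [label_volume] with `skull` role labels.
#' @return An object of class `skull_model` with logical `outer_mask` and
#'   `inner_mask`, signed distance fields `outer_signed` and `inner_signed`
#'   (mm), and the grid affine.
#' @export
skull_model <- function(volume) {
  inner <- intracranial_mask(volume)
  skull <- array(volume$data %in% volume$role_map[["skull"]],
                 dim(volume$data))
  outer <- inner | skull
  if (!any(skull)) stop("volume has no skull voxels")
  structure(list(outer_mask = outer, inner_mask = inner,
                 outer_signed = signed_distance(outer, volume),
                 inner_signed = signed_distance(inner, volume),
                 affine = volume$affine),
            class = "skull_model")
}

# Outward unit normal of the outer skull surface at world points. The
# finite-difference half-step spans a full voxel so that the quantization
# of the voxelized signed distance field averages out.
skull_outer_normal <- function(skull, xyz) {
  h <- max(affine_spacing(skull$affine))
  g <- field_gradient(skull$outer_signed, skull$affine, xyz, h = h)
  n <- sqrt(rowSums(g^2))
  if (any(n < 1e-9)) stop("degenerate skull surface normal")
  g / n
}

#' Truncate the hippocampus at the tectal plate
#'
#' Only hippocampus anterior to the coronal plane through the tectal plate
#' enters amygdalohippocampal volumetrics and planning. Keeps voxels whose
#' world y-coordinate is strictly greater (more anterior, RAS) than the
#' plane.
#'
#' @param hipp Hippocampus [roi_mask].
#' @param volume The parent [label_volume].
#' @param tectal_plane_y Coronal plane world y-coordinate (mm).
#' @return A [roi_mask] with role `"hippocampus"`. Empty results warn.
#' @export
truncate_hippocampus <- function(hipp, volume, tectal_plane_y) {
  keep <- voxel_y_at_least(hipp$mask, volume,
                           tectal_plane_y, strict = TRUE)
  if (!any(keep))
    warning("tectal-plane truncation removed the entire hippocampus")
  roi_mask(hipp$role, keep, volume)
}

#' Mesial hippocampal head region
#'
#' Defined as hippocampal voxels anterior to (or at) the coronal plane
#' through the posterior border of the amygdala.
#'
#' @param hipp Hippocampus [roi_mask] (tectal-truncated or not).
#' @param amygdala Amygdala [roi_mask], non-empty.
#' @param volume The parent [label_volume].
#' @return A [roi_mask] with role `"hippocampal_head"`; warns when empty.
#' @export
hippocampal_head <- function(hipp, amygdala, volume) {
  if (!any(hipp$mask) || !any(amygdala$mask))
    stop("hippocampal_head requires non-empty hippocampus and amygdala")
  amy_y <- mask_world_coords(amygdala$mask, volume$affine)[, 2]
  keep <- voxel_y_at_least(hipp$mask, volume, min(amy_y), strict = FALSE)
  if (!any(keep)) warning("hippocampal head region is empty")
  roi_mask("hippocampal_head", keep, volume)
}

# Internal: subset mask to voxels with world y > (or >=) a coronal plane.
voxel_y_at_least <- function(mask, volume, y0, strict = TRUE) {
  dm <- dim(mask)
  # world y of every voxel as a separable function of indices
  i <- 0:(dm[1] - 1); j <- 0:(dm[2] - 1); k <- 0:(dm[3] - 1)
  a <- volume$affine
  yv <- outer(outer(a[2, 1] * i, a[2, 2] * j, "+"),
              a[2, 3] * k, "+") + a[2, 4]
  keep <- if (strict) yv > y0 else yv >= y0
  mask & keep
}
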