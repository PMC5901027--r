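# Shared fixtures: coarse phantoms (2 mm grid, same world geometry as the
# default) cached across test files, analytic sphere skulls, and brute-force
# oracles kept independent of the implementation paths they check.

.fixture_cache <- new.env(parent = emptyenv())

coarse_params <- function(seed = 1L, jitter = 0, ...) {
  phantom_params(grid_shape = c(96L, 96L, 96L), voxel_spacing = c(2, 2, 2),
                 seed = seed, jitter_sd = jitter, ...)
}

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

coarse_phantom <- function(variant = NULL) {
  key <- paste0("phantom_", variant %||% "base")
  cached(key, {
    p <- coarse_params()
    if (is.null(variant)) generate_phantom(p) else generate_variant(p, variant)
  })
}

coarse_bundle <- function(variant = NULL) {
  key <- paste0("bundle_", variant %||% "base")
  cached(key, {
    ph <- coarse_phantom(variant)
    anatomy_bundle(ph$volume, ph$ground_truth$tectal_plane_y)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Analytic spherical skull model: signed fields sampled from the exact
# closed form r - R, bypassing mask voxelization for sub-voxel oracles.
analytic_sphere_skull <- function(dim = 96L, spacing = 2, r_in = 70,
                                  r_out = 76) {
  dm <- rep(dim, 3)
  off <- (dm - 1) / 2 * spacing
  affine <- rbind(cbind(diag(rep(spacing, 3)), -off), c(0, 0, 0, 1))
  xs <- (0:(dm[1] - 1)) * spacing - off[1]
  rr <- sqrt(outer(outer(xs^2, xs^2, "+"), xs^2, "+"))
  structure(list(outer_mask = rr <= r_out, inner_mask = rr < r_in,
                 outer_signed = rr - r_out, inner_signed = rr - r_in,
                 affine = affine),
            class = "skull_model")
}

# O(N * M) brute-force Euclidean distance transform oracle.
edt_brute_force <- function(mask, spacing) {
  src <- which(mask, arr.ind = TRUE)
  out <- array(NA_real_, dim(mask))
  all_idx <- which(array(TRUE, dim(mask)), arr.ind = TRUE)
  sx <- src[, 1] * spacing[1]; sy <- src[, 2] * spacing[2]
  sz <- src[, 3] * spacing[3]
  for (v in seq_len(nrow(all_idx))) {
    dx <- sx - all_idx[v, 1] * spacing[1]
    dy <- sy - all_idx[v, 2] * spacing[2]
    dz <- sz - all_idx[v, 3] * spacing[3]
    out[v] <- sqrt(min(dx * dx + dy * dy + dz * dz))
  }
  out
}

# Independent planner oracle: exhaustive loop over the same candidate set,
# with the constraint checks and the score formula written out explicitly.
brute_force_plan <- function(bundle, config = plan_config()) {
  target <- make_target(bundle$amygdala, bundle$volume, bundle$side,
                        config$target_offset)
  brain <- intracranial_mask(bundle$volume)
  for (role in config$entry_roles) {
    patch <- extract_roi(bundle$volume, role)
    cands <- suppressWarnings(
      candidate_entries(patch, brain, bundle$volume, config$entry_spacing))
    if (nrow(cands) == 0) next
    best <- NULL
    for (i in seq_len(nrow(cands))) {
      tr <- trajectory(cands[i, ], target)
      m <- compute_metrics(tr, bundle, config$risk_params)
      if (length(m$errors) > 0 || any(is.na(unlist(
        m[c("min_critical_distance", "drilling_angle")])))) next
      if (m$ventricle_hit) next
      if (config$enforce_safety_margin &&
          m$min_critical_distance < config$risk_params$safety_margin) next
      if (m$drilling_angle > config$max_drilling_angle) next
      w <- config$weights
      sc <- w[[1]] * m$overall_risk - w[[2]] * m$ahc_center_proportion +
        w[[3]] * m$intracerebral_length / 150 +
        w[[4]] * m$drilling_angle / 90
      key <- c(sc, m$overall_risk, m$intracerebral_length, i)
      if (is.null(best) || lexi_less(key, best$key))
        best <- list(key = key, entry = cands[i, ], score = sc,
                     role = role, metrics = m)
    }
    if (!is.null(best)) return(best)
  }
  NULL
}

lexi_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# Head phantom whose only critical structure is a single parasagittal
# plane of voxels at world x = 20 (z in [-30, 30], full y extent), used
# for safety-margin threshold and risk-integral tests.
plane_critical_params <- function() {
  phantom_params(
    grid_shape = c(89L, 89L, 89L), voxel_spacing = c(2, 2, 2),
    sulci_planes = list(
      test_plane = list(c = c(20, 0, -30), n = c(1, 0, 0), depth = 60,
                        thickness = 1.9, y_range = c(-80, 80))))
}

plane_critical_bundle <- function() {
  cached("bundle_plane", {
    ph <- generate_phantom(plane_critical_params())
    anatomy_bundle(ph$volume, ph$ground_truth$tectal_plane_y)
  })
}

# Test trajectory running anteriorly at z = -10 (inside the sheet's z
# span), at constant closest-approach distance d from the critical plane.
plane_offset_trajectory <- function(d) {
  trajectory(entry = c(20 + d, -70, -10), target = c(20 + d, 0, -10))
}
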