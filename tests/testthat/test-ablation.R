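# Ablation-zone model: cylinder voxelization against closed forms,
# per-ROI volumetrics, residual mesial-hippocampal-head depth and
# achieved-cavity reports.

# open box-world label volume: all brain, 1 mm spacing, centered so that
# voxel centers fall on integer world coordinates
box_volume <- function(n = 71L) {
  dm <- rep(n, 3)
  lab <- array(1L, dm)
  lab[1, , ] <- 2L # token skull wall
  aff <- rbind(cbind(diag(c(1, 1, 1)), -(n - 1) / 2), c(0, 0, 0, 1))
  label_volume(lab, aff, list(brain = 1L, skull = 2L))
}

test_that("cylinder voxelization matches pi r^2 h and supersampling", {
  vol <- box_volume()
  # cap planes off the voxel lattice so the center rule is unbiased
  tr <- trajectory(c(0, 35.3, 0), c(0, -24.7, 0))
  z15 <- ablation_zone(tr, vol, diameter = 15, extent = 50,
                       supersample = 5L)
  expect_equal(z15$volume_mm3, pi * 7.5^2 * 50, tolerance = 0.02)
  expect_equal(z15$volume_supersampled_mm3, z15$volume_mm3,
               tolerance = 0.03)
  # caps: proximal at 50 mm from the target, distal at the target
  expect_equal(z15$distal_limit, tr$target)
  expect_equal(sqrt(sum((z15$distal_limit - z15$proximal_limit)^2)), 50)
  # nesting across diameters
  z5 <- ablation_zone(tr, vol, diameter = 5, extent = 50)
  expect_true(all(z15$mask[z5$mask]))
  expect_lt(sum(z5$mask), sum(z15$mask))
  # oblique axis agrees with the closed form too
  tro <- trajectory(c(20, 28, 24), c(-10, -17, -12))
  zo <- ablation_zone(tro, vol, diameter = 12, extent = 40)
  expect_equal(zo$volume_mm3, pi * 6^2 * 40, tolerance = 0.02)
  # diameter domain
  expect_error(ablation_zone(tr, vol, diameter = 4, extent = 50), "5")
  expect_error(ablation_zone(tr, vol, diameter = 21, extent = 50),
               "\\[5, 20\\]")
})

test_that("tectal-plane extent places the proximal cap on the plane", {
  b <- coarse_bundle()
  res <- plan_trajectory(b)
  z <- ablation_zone(res$trajectory, b$volume, diameter = 15,
                     extent = "tectal",
                     tectal_plane_y = b$tectal_plane_y)
  expect_equal(z$proximal_limit[2], b$tectal_plane_y, tolerance = 1e-9)
  expect_equal(z$distal_limit, res$trajectory$target)
  # both limits on the trajectory line
  d <- res$trajectory$direction
  rel <- z$proximal_limit - res$trajectory$entry
  expect_lt(sqrt(sum((rel - sum(rel * d) * d)^2)), 1e-6)
  # a trajectory that never crosses the plane errors
  tr_ant <- trajectory(c(-23, 30, -19), c(-23, 5, -19))
  expect_error(ablation_zone(tr_ant, b$volume, extent = "tectal",
                             tectal_plane_y = -26), "fixed")
})

test_that("ROI overlap volumetrics respect containment and additivity", {
  vol <- box_volume()
  tr <- trajectory(c(0, 35.3, 0), c(0, -24.7, 0))
  zone <- ablation_zone(tr, vol, diameter = 15, extent = 50)
  # an ROI fully inside the zone
  cube_mask <- function(lo, hi) {
    idx <- which(array(TRUE, dim(vol$data)), arr.ind = TRUE)
    w <- littplan:::world_from_voxel(vol$affine, idx - 1)
    array(w[, 1] >= lo[1] & w[, 1] <= hi[1] &
          w[, 2] >= lo[2] & w[, 2] <= hi[2] &
          w[, 3] >= lo[3] & w[, 3] <= hi[3], dim(vol$data))
  }
  amy <- littplan:::roi_mask("amygdala", cube_mask(c(-3, -8, -3),
                                                   c(3, -2, 3)), vol)
  far <- littplan:::roi_mask("parahippocampal",
                             cube_mask(c(25, 25, 25), c(33, 33, 33)), vol)
  rep1 <- roi_overlap_volumes(zone, list(amy, far), vol)
  amy_row <- rep1$per_roi[rep1$per_roi$role == "amygdala", ]
  expect_equal(amy_row$ablated_volume_mm3, amy_row$anatomical_volume_mm3)
  expect_equal(amy_row$percent_ablated, 100)
  far_row <- rep1$per_roi[rep1$per_roi$role == "parahippocampal", ]
  expect_equal(far_row$ablated_volume_mm3, 0)
  expect_equal(far_row$percent_ablated, 0)
  # a 10 mm cube straddling the distal cap plane: about half ablated
  strad <- littplan:::roi_mask("hippocampus",
                               cube_mask(c(-5, -29.7, -5),
                                         c(4, -19.7, 4)), vol)
  rep2 <- roi_overlap_volumes(zone, list(strad), vol)
  h_row <- rep2$per_roi[rep2$per_roi$role == "hippocampus", ]
  expect_equal(h_row$ablated_volume_mm3, 500, tolerance = 0.05)
})

test_that("phantom plan volumetrics are diameter-monotone with exact AHC
           additivity", {
  b <- coarse_bundle()
  res <- plan_trajectory(b)
  rois <- list(b$amygdala, b$hippocampus,
               extract_roi(b$volume, "entorhinal"),
               extract_roi(b$volume, "parahippocampal"))
  prev <- NULL
  for (diam in c(5, 10, 15, 20)) {
    z <- ablation_zone(res$trajectory, b$volume, diameter = diam,
                       extent = "tectal",
                       tectal_plane_y = b$tectal_plane_y)
    rep_d <- roi_overlap_volumes(z, rois, b$volume)
    vols <- rep_d$per_roi$ablated_volume_mm3
    names(vols) <- rep_d$per_roi$role
    if (!is.null(prev)) expect_true(all(vols >= prev - 1e-9))
    prev <- vols
    expect_equal(vols[["ahc"]], vols[["amygdala"]] +
                   vols[["hippocampus"]])
    expect_true(all(rep_d$per_roi$ablated_volume_mm3 <=
                      rep_d$per_roi$anatomical_volume_mm3 + 1e-9))
  }
})

test_that("residual MHH depth follows the medial-walk definition", {
  vol <- box_volume()
  # head: a 12 mm cube on the left (x in [-12, 0] shifted medially)
  idx <- which(array(TRUE, dim(vol$data)), arr.ind = TRUE)
  w <- littplan:::world_from_voxel(vol$affine, idx - 1)
  head_mask <- array(w[, 1] >= -12 & w[, 1] <= -1 &
                     w[, 2] >= -6 & w[, 2] <= 5 &
                     w[, 3] >= -6 & w[, 3] <= 5, dim(vol$data))
  head_roi <- littplan:::roi_mask("hippocampal_head", head_mask, vol)
  # zone covering everything: residual 0
  all_zone <- array(TRUE, dim(vol$data))
  expect_equal(residual_mhh_depth(head_roi, all_zone, vol, "left"), 0)
  # zone covering only the lateral 8 mm (x <= -5): residual ~4 mm
  lat_zone <- array(w[, 1] <= -5, dim(vol$data))
  expect_equal(residual_mhh_depth(head_roi, lat_zone, vol, "left"), 4,
               tolerance = 1)
  # disjoint zone: full medial-lateral extent (11 mm of voxel centers)
  no_zone <- array(w[, 1] > 50, dim(vol$data))
  expect_equal(residual_mhh_depth(head_roi, no_zone, vol, "left"), 11,
               tolerance = 1e-9)
  # mirrored geometry for the right side
  head_r <- littplan:::roi_mask("hippocampal_head",
                                array(w[, 1] <= 12 & w[, 1] >= 1 &
                                      abs(w[, 2]) <= 5 & abs(w[, 3]) <= 5,
                                      dim(vol$data)), vol)
  lat_zone_r <- array(w[, 1] >= 5, dim(vol$data))
  expect_equal(residual_mhh_depth(head_r, lat_zone_r, vol, "right"), 4,
               tolerance = 1)
})

test_that("phantom-plan residual MHH depth shrinks with diameter", {
  b <- coarse_bundle()
  res <- plan_trajectory(b)
  head_roi <- hippocampal_head(b$hippocampus, b$amygdala, b$volume)
  z5 <- ablation_zone(res$trajectory, b$volume, diameter = 5,
                      extent = "tectal", tectal_plane_y = b$tectal_plane_y)
  z15 <- ablation_zone(res$trajectory, b$volume, diameter = 15,
                       extent = "tectal",
                       tectal_plane_y = b$tectal_plane_y)
  r5 <- residual_mhh_depth(head_roi, z5, b$volume, b$side)
  r15 <- residual_mhh_depth(head_roi, z15, b$volume, b$side)
  expect_lte(r15, r5)
  expect_gte(r5, 0)
})

test_that("achieved-cavity reports substitute exactly and track gray
           fraction", {
  b <- coarse_bundle()
  res <- plan_trajectory(b)
  rois <- list(b$amygdala, b$hippocampus,
               extract_roi(b$volume, "entorhinal"),
               extract_roi(b$volume, "parahippocampal"))
  z <- ablation_zone(res$trajectory, b$volume, diameter = 15,
                     extent = "tectal", tectal_plane_y = b$tectal_plane_y)
  exp_rep <- roi_overlap_volumes(z, rois, b$volume)
  ach_rep <- achieved_cavity_report(z$mask, rois, b$volume)
  expect_identical(exp_rep$per_roi, ach_rep$per_roi)
  expect_identical(exp_rep$gray_fraction, ach_rep$gray_fraction)
  # constructed cavity with exactly half its volume inside an ROI
  vol <- box_volume()
  idx <- which(array(TRUE, dim(vol$data)), arr.ind = TRUE)
  w <- littplan:::world_from_voxel(vol$affine, idx - 1)
  cav <- array(abs(w[, 1]) <= 4 & w[, 2] >= -4 & w[, 2] <= 5 &
                 abs(w[, 3]) <= 4, dim(vol$data))
  roi_half <- littplan:::roi_mask("amygdala",
                                  cav & array(w[, 2] >= 1,
                                              dim(vol$data)), vol)
  rep_h <- achieved_cavity_report(cav, list(roi_half), vol)
  expect_equal(rep_h$gray_fraction, 0.5, tolerance = 0.02)
  # empty cavity warns and zeroes
  expect_warning(rep0 <- achieved_cavity_report(
    array(FALSE, dim(vol$data)), list(roi_half), vol), "empty")
  expect_true(all(rep0$per_roi$ablated_volume_mm3 == 0))
  # estimation error consumes matched reports
  err <- estimation_error(exp_rep, ach_rep)
  expect_true(all(err$error_percent_of_anatomical == 0))
})
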