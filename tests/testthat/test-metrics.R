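# Safety metrics: sphere-skull closed forms, the risk ramp and its
# integral, sub-voxel minimum distances, AHC contact and aggregation.

unit_helper <- function(v) v / sqrt(sum(v^2))

test_that("intracerebral length matches radial and chord closed forms on
           an analytic sphere skull", {
  sk <- analytic_sphere_skull(dim = 96L, spacing = 2, r_in = 70,
                              r_out = 76)
  # radial: any outside entry to the center travels exactly r_in
  tr <- trajectory(c(0, 0, 75), c(0, 0, 0))
  expect_equal(intracerebral_length(tr, sk), 70, tolerance = 0.05)
  tr2 <- trajectory(c(50, 50, 30), c(0, 0, 0))
  expect_equal(intracerebral_length(tr2, sk), 70, tolerance = 0.05)
  # chord at impact parameter b: the crossing-to-center-plane distance is
  # sqrt(r_in^2 - b^2); target at the chord midpoint
  b <- 30
  entry <- c(b, 0, 80)
  target <- c(b, 0, 0)
  expect_equal(intracerebral_length(trajectory(entry, target), sk),
               sqrt(70^2 - b^2), tolerance = 0.05)
  # target 10 mm past the crossing along the ray
  u <- unit_helper(c(0, 0, -1))
  cross <- c(b, 0, sqrt(70^2 - b^2))
  tr10 <- trajectory(entry, cross + 10 * u)
  expect_equal(intracerebral_length(tr10, sk), 10, tolerance = 0.05)
  # target outside the inner skull errors
  expect_error(intracerebral_length(trajectory(c(0, 0, 80), c(0, 0, 72)),
                                    sk), "outside")
})

test_that("drilling angle matches analytic sphere normals", {
  sk <- analytic_sphere_skull(dim = 96L, spacing = 2, r_in = 70,
                              r_out = 76)
  # radial trajectory: orthogonal drilling
  expect_equal(drilling_angle(trajectory(c(0, 0, 85), c(0, 0, 10)), sk),
               0, tolerance = 1)
  # construct a 30-degree impact at outer surface point P
  for (ang in c(15, 30, 45)) {
    u <- c(0, 0, 1)
    tvec <- c(1, 0, 0)
    P <- 76 * u
    d <- -cos(ang * pi / 180) * u + sin(ang * pi / 180) * tvec
    tr <- trajectory(P - 10 * d, P + 25 * d)
    expect_equal(drilling_angle(tr, sk), ang, tolerance = 1)
  }
})

test_that("pointwise risk ramp hits its endpoints and is monotone", {
  p <- risk_params()
  expect_identical(pointwise_risk(2, p), 1)
  expect_identical(pointwise_risk(12, p), 0)
  expect_equal(pointwise_risk(6.5, p), 0.5)
  d <- seq(0, 15, by = 0.01)
  r <- pointwise_risk(d, p)
  expect_true(all(diff(r) <= 0))
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(range(r), c(0, 1))
  # continuity at the ramp ends
  expect_equal(pointwise_risk(3 + 1e-9, p), 1, tolerance = 1e-6)
  expect_equal(pointwise_risk(10 - 1e-9, p), 0, tolerance = 1e-6)
  expect_error(pointwise_risk(-1, p))
})

test_that("overall risk integrates the ramp along the segment", {
  b <- plane_critical_bundle()
  sk <- b$skull
  # far from the plane: zero risk
  tr_far <- plane_offset_trajectory(40)
  expect_equal(overall_risk(tr_far, b$critical_field, sk), 0)
  # a constant-distance segment: risk = ramp(d) * L / norm_length
  tr2 <- plane_offset_trajectory(2)
  L <- intracerebral_length(tr2, sk)
  expect_equal(overall_risk(tr2, b$critical_field, sk), L / 10,
               tolerance = 0.02)
  tr65 <- plane_offset_trajectory(6.5)
  L65 <- intracerebral_length(tr65, sk)
  expect_equal(overall_risk(tr65, b$critical_field, sk), 0.5 * L65 / 10,
               tolerance = 0.02)
  # fine-step midpoint-rule oracle on a phantom trajectory
  bb <- coarse_bundle("deep_collateral_sulcus")
  tgt <- make_target(bb$amygdala, bb$volume, bb$side)
  tr <- trajectory(c(-27, -67, -25), tgt)
  r1 <- overall_risk(tr, bb$critical_field, bb$skull, risk_params())
  fine <- risk_params(sample_step = 0.1)
  r_fine <- overall_risk(tr, bb$critical_field, bb$skull, fine)
  expect_gt(r_fine, 0)
  expect_equal(r1, r_fine, tolerance = 0.02)
})

test_that("minimum critical distance is exact for constructed geometry", {
  b <- plane_critical_bundle()
  for (d in c(1.5, 3, 5)) {
    tr <- plane_offset_trajectory(d)
    expect_equal(min_critical_distance(tr, b$critical_field, b$skull),
                 d, tolerance = 0.1)
  }
  # a line through the critical plane itself
  tr0 <- trajectory(c(60, 0, -30), c(0, 0, -30))
  expect_equal(min_critical_distance(tr0, b$critical_field, b$skull), 0,
               tolerance = 0.1)
  # point source: closest approach by the point-line formula
  dm <- c(41L, 41L, 41L)
  lab <- array(1L, dm) # all brain
  lab[21, 21, 21] <- 8L
  lab[1, , ] <- 2L # a skull wall so the model has a skull
  aff <- rbind(cbind(diag(c(1, 1, 1)), -20), c(0, 0, 0, 1))
  vol <- label_volume(lab, aff, list(brain = 1L, critical = 8L,
                                     skull = 2L))
  df <- distance_field(extract_roi(vol, "critical"), vol)
  sk <- analytic_sphere_skull(dim = 41L, spacing = 1, r_in = 19,
                              r_out = 19.5)
  tr <- trajectory(c(5, -18, 0), c(5, 18, 0)) # closest approach 5 mm
  expect_equal(littplan:::segment_min_distance(tr, df, sk), 5,
               tolerance = 0.15)
  # order statistic: min <= mean along the segment
  b2 <- coarse_bundle()
  tgt <- make_target(b2$amygdala, b2$volume, b2$side)
  tr2 <- trajectory(c(-27, -67, -25), tgt)
  s <- littplan:::intracerebral_samples(tr2, b2$skull, 1)
  vals <- littplan:::interp_trilinear(b2$critical_field$field,
                                      b2$volume$affine, s$points)
  expect_lte(min_critical_distance(tr2, b2$critical_field, b2$skull),
             mean(vals))
})

test_that("AHC center proportion reflects tube cannulation", {
  # straight tube AHC: axis-aligned cylinder 40 mm long, radius 6
  dm <- c(48L, 48L, 48L)
  aff <- rbind(cbind(diag(c(2, 2, 2)), -47), c(0, 0, 0, 1))
  xs <- (0:47) * 2 - 47
  X <- array(rep(xs, times = 48 * 48), dm)
  Y <- array(rep(rep(xs, each = 48), times = 48), dm)
  Z <- array(rep(xs, each = 48 * 48), dm)
  mask <- Y >= -20 & Y <= 20 & (X^2 + Z^2) <= 36
  lab <- array(1L, dm)
  lab[mask] <- 3L
  vol <- label_volume(lab, aff, list(brain = 1L, ahc = 3L))
  ahc <- extract_roi(vol, "ahc")
  axis_tr <- trajectory(c(0, -40, 0), c(0, 40, 0))
  expect_gte(ahc_center_proportion(axis_tr, ahc, vol), 0.9)
  # fully outside
  out_tr <- trajectory(c(40, -40, 40), c(40, 40, 40))
  expect_equal(ahc_center_proportion(out_tr, ahc, vol), 0)
  # non-increasing in the core margin
  p1 <- ahc_center_proportion(axis_tr, ahc, vol, core_margin = 1)
  p3 <- ahc_center_proportion(axis_tr, ahc, vol, core_margin = 3)
  p5 <- ahc_center_proportion(axis_tr, ahc, vol, core_margin = 5)
  expect_true(p1 >= p3 && p3 >= p5)
})

test_that("brainstem distance matches the line-cylinder closed form", {
  b <- coarse_bundle()
  # brainstem is a cylinder of radius 9 around a near-vertical axis;
  # construct a vertical line at known closest approach to the axis
  axis_top <- c(-4, -20, 8)
  tr <- trajectory(c(-4, -45.75, 55), c(-4, -45.75, -55))
  d <- brainstem_distance(tr, b$brainstem, b$volume, b$skull)
  # closest approach to the axis (endpoint at y = -24, z = -42) is
  # 21.75 mm, minus the 9 mm cylinder radius: 12.75 mm to the surface
  expect_equal(d, 12.75, tolerance = 0.3)
  # touching the mask gives ~0
  ctr <- littplan:::polyline_centroid(rbind(c(-4, -24, -42), axis_top))
  tr0 <- trajectory(c(-4, -60, ctr[3]), c(-4, ctr[2], ctr[3]))
  expect_equal(brainstem_distance(tr0, b$brainstem, b$volume, b$skull), 0,
               tolerance = 0.1)
  # midpoint variant is at least the minimum
  dm <- brainstem_distance(tr, b$brainstem, b$volume, b$skull,
                           at = "midpoint")
  expect_gte(dm + 1e-9, d)
})

test_that("compute_metrics aggregates the individual operations", {
  b <- coarse_bundle()
  tgt <- make_target(b$amygdala, b$volume, b$side)
  tr <- trajectory(c(-27, -67, -25), tgt, label = "cap")
  m1 <- compute_metrics(tr, b)
  m2 <- compute_metrics(tr, b)
  expect_identical(m1[names(m1) != "errors"], m2[names(m2) != "errors"])
  expect_equal(m1$intracerebral_length, intracerebral_length(tr, b$skull))
  expect_equal(m1$drilling_angle, drilling_angle(tr, b$skull))
  expect_equal(m1$min_critical_distance,
               min_critical_distance(tr, b$critical_field, b$skull))
  expect_equal(m1$overall_risk,
               overall_risk(tr, b$critical_field, b$skull))
  expect_equal(m1$ahc_center_proportion,
               ahc_center_proportion(tr, b$ahc, b$volume))
  expect_false(m1$ventricle_hit)
  # a trajectory through the ventricle tube is flagged
  vent_pt <- colMeans(littplan:::mask_world_coords(b$ventricles$mask,
                                                   b$volume$affine))
  tr_v <- trajectory(c(-30, -70, 20), vent_pt)
  expect_true(compute_metrics(tr_v, b)$ventricle_hit)
})

test_that("metrics are invariant under rigid translation of the scene", {
  ph <- coarse_phantom()
  vol <- ph$volume
  shift <- c(7, -11, 5)
  aff2 <- vol$affine
  aff2[1:3, 4] <- aff2[1:3, 4] + shift
  vol2 <- label_volume(vol$data, aff2, vol$role_map)
  b1 <- coarse_bundle()
  b2 <- anatomy_bundle(vol2, ph$ground_truth$tectal_plane_y + shift[2])
  tgt <- make_target(b1$amygdala, b1$volume, b1$side)
  tr1 <- trajectory(c(-27, -67, -25), tgt)
  tr2 <- trajectory(c(-27, -67, -25) + shift, tgt + shift)
  m1 <- compute_metrics(tr1, b1)
  m2 <- compute_metrics(tr2, b2)
  for (f in c("intracerebral_length", "drilling_angle",
              "min_critical_distance", "overall_risk",
              "ahc_center_proportion", "brainstem_distance")) {
    expect_equal(m1[[f]], m2[[f]], tolerance = 1e-6, label = f)
  }
})

test_that("halving the sample step is stable for every metric", {
  b <- coarse_bundle("deep_collateral_sulcus")
  tgt <- make_target(b$amygdala, b$volume, b$side)
  tr <- trajectory(c(-27, -67, -25), tgt)
  m1 <- compute_metrics(tr, b, risk_params(sample_step = 1))
  m2 <- compute_metrics(tr, b, risk_params(sample_step = 0.5))
  for (f in c("intracerebral_length", "drilling_angle",
              "min_critical_distance", "overall_risk",
              "ahc_center_proportion", "brainstem_distance")) {
    expect_equal(m1[[f]], m2[[f]], tolerance = 0.02, label = f)
  }
})
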