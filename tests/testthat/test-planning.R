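test_that("layer count matches a hand count on a 30 mm sphere target", {
  wp <- water_phantom()  # sphere CTV radius 15 mm in uniform water
  b <- small_beam()
  pl <- place_spots(wp, b, list(c(0, 1, 0)), depth_margin_mm = 4)
  nl <- length(pl$fields[[1]]$layers)
  # depth extent of the CTV in water +- margins, on the 4 mm layer ladder
  wed <- wed_volume(wp$planning_density, c(0, 1, 0))
  ext <- range(wed[wp$masks$CTV])
  expected <- length(seq(ext[1] - 4, ext[2] + 4, by = 4))
  expect_lte(abs(nl - expected), 1)   # +-1 from energy-ladder snapping
  # layers are in descending energy (distal first)
  en <- vapply(pl$fields[[1]]$layers, `[[`, numeric(1), "energy_MeV")
  expect_true(all(diff(en) < 0))
})

test_that("spot counts scale with the lateral grid pitch and spot size", {
  wp <- water_phantom()
  b <- small_beam()
  # pure grid scaling (no fixed setup margin): halved pitch ~ 4x spots
  n1 <- nrow(plan_spot_table(place_spots(wp, b, list(c(0, 1, 0)),
                                         lateral_spacing_sigma = 1,
                                         setup_margin_mm = 0)))
  n2 <- nrow(plan_spot_table(place_spots(wp, b, list(c(0, 1, 0)),
                                         lateral_spacing_sigma = 0.5,
                                         setup_margin_mm = 0)))
  # the minimum one-node dilation damps the pure 4x scaling somewhat
  expect_gt(n2 / n1, 2.5)
  expect_lt(n2 / n1, 5.5)
  # sigma-proportional pitch: the large model needs fewer spots
  nl <- nrow(plan_spot_table(place_spots(wp, large_beam(),
                                         list(c(0, 1, 0)))))
  expect_lt(nl, n1)
})

test_that("unreachable targets are rejected", {
  wp <- water_phantom(dims = c(40L, 120L, 40L))  # 360 mm of water
  co <- spotlab:::grid_coord_arrays(wp$planning_density)
  wp$masks$CTV[] <- sqrt(co$x^2 + (co$y - 160)^2 + co$z^2) <= 15
  expect_error(place_spots(wp, small_beam(), list(c(0, 1, 0))),
               "outside reachable range")
})

test_that("one-spot toy problem is solved exactly", {
  wp <- water_phantom(dims = c(21L, 40L, 21L),
                      ctv_fun = function(x, y, z)
                        abs(x) < 1 & abs(y - 28.5) < 1 & abs(z) < 1)
  b <- small_beam()
  e <- b$energies[which.min(abs(b$r0_mm - 90))]
  pl <- manual_plan(list(list(energy_MeV = e,
                              spots = data.frame(x_mm = 0, y_mm = 0,
                                                 mu = 1))))
  pl$prescription_cGy <- 7000
  st <- optimize_settings(scenarios = list(nominal_scenario()),
                          ring_weight = 0, maxit = 200L,
                          over_weight = 1)  # symmetric: exact linear solve
  res <- suppressWarnings(robust_optimize(pl, b, wp, st))
  w <- plan_spot_table(res)$mu
  # unit dose of this spot at the single CTV voxel
  pt <- spotlab:::grid_points(wp$planning_density)[which(wp$masks$CTV), ,
                                                   drop = FALSE]
  a <- influence_matrices(pl, b, wp$planning_density, pt,
                          list(nominal_scenario()))[[1]][[1]][1, 1]
  expect_equal(w, 7000 / a, tolerance = 1e-5)
})

test_that("slab target yields a flat SOBP (<= 3% ripple)", {
  wp <- water_phantom(dims = c(31L, 60L, 31L),
                      ctv_fun = function(x, y, z)
                        abs(x) <= 15 & y >= 12 & y <= 52 & abs(z) <= 15)
  # fine energy ladder and symmetric objective: the classic SOBP setting
  b <- beam_model("small", energy_step_mm = 2)
  pl <- place_spots(wp, b, list(c(0, 1, 0)), layer_spacing_mm = 2)
  st <- optimize_settings(scenarios = list(nominal_scenario()),
                          ring_weight = 0, maxit = 1500L, over_weight = 1)
  res <- suppressWarnings(robust_optimize(pl, b, wp, st))
  d <- plan_dose(res, b, wp$planning_density)
  ax <- grid_axes(d)
  ix <- which.min(abs(ax$x)); iz <- which.min(abs(ax$z))
  sel <- ax$y >= 14 & ax$y <= 50      # plateau, half a layer off each edge
  prof <- d$values[ix, sel, iz]
  expect_lt(max(prof) / min(prof), 1.03)
})

test_that("optimized plans respect the minimum-MU rule", {
  pl <- tiny_plan()
  mu <- plan_spot_table(pl)$mu
  expect_true(all(mu[mu > 0] >= 0.015 * pl$normalization$scale - 1e-12))
})

test_that("D99 normalization is linear and reports min-MU violations", {
  wp <- water_phantom()
  b <- small_beam()
  e <- b$energies[5]
  pl <- manual_plan(list(list(energy_MeV = e,
                              spots = data.frame(x_mm = c(0, 3),
                                                 y_mm = c(0, 0),
                                                 mu = c(2, 1)))))
  # synthetic dose: uniform 6600 on the CTV -> scale 6930/6600 = 1.05
  v <- array(0, dim = dim(wp$planning_density$values))
  v[wp$masks$CTV] <- 6600
  res <- normalize_d99(pl, dose_grid(v, 3), wp$masks$CTV)
  expect_equal(res$normalization$scale, 1.05, tolerance = 2e-4)
  expect_equal(plan_spot_table(res)$mu,
               c(2, 1) * res$normalization$scale)
  # identity when D99 is already on target
  v[wp$masks$CTV] <- 6930
  res2 <- normalize_d99(pl, dose_grid(v, 3), wp$masks$CTV)
  expect_equal(res2$normalization$scale, 1, tolerance = 2e-4)
  # scaling below the deliverable minimum is reported, not silently dropped
  pl_small <- manual_plan(list(list(energy_MeV = e,
                                    spots = data.frame(x_mm = 0, y_mm = 0,
                                                       mu = 0.016))))
  v[wp$masks$CTV] <- 14000
  expect_warning(res3 <- normalize_d99(pl_small, dose_grid(v, 3),
                                       wp$masks$CTV),
                 "minimum MU")
  expect_length(res3$normalization$min_mu_violations, 1L)
})

test_that("normalized D99 recomputes to 6930 +- 1 cGy(RBE) on a real plan", {
  ph <- tiny_phantom()
  b <- tiny_beam()
  pl <- tiny_plan()
  d <- plan_dose(pl, b, ph$planning_density)
  d99 <- dose_at_volume(dvh(d, ph$masks$CTV), pct = 99)
  expect_lt(abs(d99 - 6930), 1)
})

test_that("volumetric repainting splits MU and alternates layer order", {
  b <- small_beam()
  e5 <- b$energies[10:14]  # five layers, distal first
  layers <- lapply(sort(e5, decreasing = TRUE), function(e)
    list(energy_MeV = e, spots = data.frame(x_mm = 0, y_mm = 0, mu = 0.10)))
  pl <- manual_plan(layers)
  vr <- make_volumetric_repainting(pl, 5)
  expect_length(vr$paintings, 5L)
  # 0.10 MU -> five passes of 0.02, all deliverable
  mus <- vapply(vr$paintings, function(p) p$spots$mu[1], numeric(1))
  expect_equal(mus, rep(0.02, 5))
  expect_true(all(mus >= 0.015))
  # alternating traversal: odd paintings distal->proximal, even reversed
  for (k in 1:5) {
    en <- vr$paintings[[k]]$spots$energy_MeV
    if (k %% 2 == 1) expect_true(all(diff(en) < 0)) else
      expect_true(all(diff(en) > 0))
  }
  # painting MUs sum bitwise to the planned MU
  expect_identical(painting_totals(vr), plan_spot_table(pl)$mu)
  expect_error(make_volumetric_repainting(vr, 5), "already")
})

test_that("min-MU fallback reduces the painting count, conserving MU", {
  b <- small_beam()
  pl <- manual_plan(list(list(energy_MeV = b$energies[10],
                              spots = data.frame(x_mm = c(0, 4),
                                                 y_mm = c(0, 0),
                                                 mu = c(0.05, 1)))))
  vr <- make_volumetric_repainting(pl, 5)
  # 0.05 MU: floor(0.05/0.015) = 3 passes, assigned to paintings 1..3
  present <- vapply(vr$paintings, function(p) 1 %in% p$spots$spot_id,
                    logical(1))
  expect_equal(present, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  per_pass <- vapply(vr$paintings[1:3], function(p)
    p$spots$mu[p$spots$spot_id == 1], numeric(1))
  expect_true(all(per_pass >= 0.015))
  expect_identical(sum(per_pass), 0.05)
  expect_identical(painting_totals(vr), c(0.05, 1))
})

test_that("repainted static dose is bitwise identical to the unpainted plan", {
  ph <- tiny_phantom_static()
  b <- tiny_beam()
  pl <- tiny_plan_static()
  vr <- make_volumetric_repainting(pl, 5)
  d0 <- plan_dose(pl, b, ph$planning_density)
  # rebuild the plan from the painting totals and recompute
  tot <- painting_totals(vr)
  pl2 <- spotlab:::set_plan_mu(pl, tot)
  d1 <- plan_dose(pl2, b, ph$planning_density)
  expect_identical(d1$values, d0$values)
})

test_that("plan JSON round trip preserves structure and MU", {
  pl <- make_volumetric_repainting(tiny_plan_static(), 3)
  f <- tempfile(fileext = ".json")
  write_plan_json(pl, f)
  pl2 <- read_plan_json(f)
  expect_equal(pl2$beam_model, pl$beam_model)
  expect_equal(pl2$prescription_cGy, pl$prescription_cGy)
  t1 <- plan_spot_table(pl); t2 <- plan_spot_table(pl2)
  expect_equal(t2$mu, t1$mu, tolerance = 1e-12)
  expect_equal(t2$energy_MeV, t1$energy_MeV)
  expect_length(pl2$paintings, length(pl$paintings))
  expect_equal(pl2$paintings[[2]]$spots$mu, pl$paintings[[2]]$spots$mu,
               tolerance = 1e-12)
  unlink(f)
})

test_that("per-field SFUD doses are individually near-uniform on the CTV", {
  ph <- tiny_phantom()
  b <- tiny_beam()
  pl <- tiny_plan()
  for (f in seq_along(pl$fields)) {
    h <- dvh(plan_dose(pl, b, ph$planning_density, fields = f),
             ph$masks$CTV)
    ratio <- dose_at_volume(h, pct = 1) / dose_at_volume(h, pct = 99)
    expect_lt(ratio, 1.4)
  }
})
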