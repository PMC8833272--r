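test_that("beam model pair: sigma anchors, scaling, identical IDDs", {
  bs <- small_beam(); bl <- large_beam()
  expect_equal(sigma_iso(bs, 226.5), 3)
  expect_equal(sigma_iso(bl, 226.5), 8)
  # sigma decreases monotonically with energy
  expect_true(all(diff(bs$sigma_iso_mm) < 0))
  # large profile is the small profile scaled in width at every energy
  expect_equal(bl$sigma_iso_mm / bs$sigma_iso_mm,
               rep(8 / 3, length(bs$energies)))
  # IDDs and absolute output identical between the models
  expect_identical(bs$idd, bl$idd)
  expect_identical(bs$energies, bl$energies)
  expect_equal(bs$mu_min, 0.015)
})

test_that("fitted lateral 1-sigma at shallow depth matches the anchor within 2%", {
  den <- water_grid(c(41, 16, 41), spacing = 2)
  moment_sigma <- function(prof, x) {
    w <- prof / sum(prof)
    sqrt(sum(w * x^2) - sum(w * x)^2)
  }
  for (bm in list(small_beam(), large_beam())) {
    sp <- list(x_mm = 0, y_mm = 0, energy_MeV = 226.5, mu = 1,
               direction = c(0, 1, 0))
    d <- spot_dose(sp, bm, den)
    ax <- grid_axes(d)
    iz <- which.min(abs(ax$z))
    prof <- d$values[, 4, iz]   # ~7 mm depth: MCS growth still negligible
    s <- moment_sigma(prof, ax$x)
    expect_lt(abs(s - bm$sigma_iso_ref_mm) / bm$sigma_iso_ref_mm, 0.02)
  }
})

test_that("lateral integral of a spot layer equals MU x IDD (within 1%)", {
  b <- small_beam()
  den <- water_grid(c(41, 101, 41), spacing = 2)
  e <- b$energies[which.min(abs(b$r0_mm - 150))]
  mu <- 2.5
  d <- spot_dose(list(x_mm = 0, y_mm = 0, energy_MeV = e, mu = mu,
                      direction = c(0, 1, 0)), b, den)
  ax <- grid_axes(d)
  wed <- ax$y - ax$y[1] + den$spacing[2] / 2
  zt <- seq(0, by = b$idd_dz, length.out = nrow(b$idd))
  ei <- spotlab:::energy_index(b, e)
  for (iy in c(10, 30, 50, 65)) {
    lat <- sum(d$values[, iy, ]) * prod(den$spacing[c(1, 3)])
    ref <- mu * stats::approx(zt, b$idd[, ei], xout = wed[iy])$y * b$rbe
    expect_lt(abs(lat - ref) / ref, 0.01)
  }
})

test_that("dose is linear in MU and zero for MU = 0", {
  b <- tiny_beam()
  den <- water_grid(c(21, 61, 21), 2)
  mk <- function(mu) spot_dose(list(x_mm = 0, y_mm = 0, energy_MeV = 226.5,
                                    mu = mu, direction = c(0, 1, 0)), b, den)
  expect_equal(max(mk(0)$values), 0)
  expect_equal(mk(2)$values, 2 * mk(1)$values, tolerance = 1e-12)
  expect_error(mk(-1), "MU")
})

test_that("plan dose is the superposition of its spots and deterministic", {
  b <- tiny_beam()
  den <- water_grid(c(21, 61, 21), 2)
  e <- b$energies[10]
  pl <- manual_plan(list(list(energy_MeV = e,
                              spots = data.frame(x_mm = c(-4, 4),
                                                 y_mm = c(0, 2),
                                                 mu = c(1, 2)))))
  d1 <- plan_dose(pl, b, den)
  s1 <- spot_dose(list(x_mm = -4, y_mm = 0, energy_MeV = e, mu = 1,
                       direction = c(0, 1, 0)), b, den)
  s2 <- spot_dose(list(x_mm = 4, y_mm = 2, energy_MeV = e, mu = 2,
                       direction = c(0, 1, 0)), b, den)
  expect_equal(d1$values, s1$values + s2$values, tolerance = 1e-12)
  # doubling all MUs doubles every voxel
  pl2 <- spotlab:::set_plan_mu(pl, c(2, 4))
  expect_equal(plan_dose(pl2, b, den)$values, 2 * d1$values,
               tolerance = 1e-12)
  # bitwise determinism of the nominal recomputation
  expect_identical(plan_dose(pl, b, den)$values, d1$values)
})

test_that("range scaling moves the Bragg peak 3.5% deeper (one grid step)", {
  b <- small_beam()
  den <- water_grid(c(21, 181, 21), 2)
  e <- b$energies[which.min(abs(b$r0_mm - 160))]
  sp <- list(x_mm = 0, y_mm = 0, energy_MeV = e, mu = 1,
             direction = c(0, 1, 0))
  peak_depth <- function(d) {
    ax <- grid_axes(d)
    wed <- ax$y - ax$y[1] + den$spacing[2] / 2
    wed[which.max(apply(d$values, 2, sum))]
  }
  p0 <- peak_depth(spot_dose(sp, b, den))
  p1 <- peak_depth(spot_dose(sp, b, den, scenario(range_scale = 1.035)))
  expect_lt(abs(p1 - 1.035 * p0), den$spacing[2] + 1e-9)
})

test_that("isocenter shift translates the dose grid on a homogeneous phantom", {
  b <- tiny_beam()
  den <- water_grid(c(31, 81, 31), 2)
  e <- b$energies[8]
  sp <- list(x_mm = 1, y_mm = -2, energy_MeV = e, mu = 1,
             direction = c(0, 1, 0))
  d0 <- spot_dose(sp, b, den)$values
  dsh <- spot_dose(sp, b, den, scenario(shift_mm = c(4, 0, -2)))$values
  # lateral shift (4, 0, -2) mm = (2, 0, -1) voxels: dose_shift(r) = dose0(r - s)
  n <- dim(d0)
  inner <- d0[1:(n[1] - 2), , 2:n[3]]
  shifted <- dsh[3:n[1], , 1:(n[3] - 1)]
  expect_lt(max(abs(shifted - inner)) / max(d0), 1e-6)
  # a shift along the beam axis leaves the surface-referenced dose unchanged
  dlong <- spot_dose(sp, b, den, scenario(shift_mm = c(0, 6, 0)))$values
  expect_identical(dlong, d0)
})

test_that("small and large plans differ only laterally (depth integrals agree)", {
  bs <- small_beam(); bl <- large_beam()
  den <- water_grid(c(61, 101, 61), 3)
  e <- bs$energies[which.min(abs(bs$r0_mm - 120))]
  pl <- manual_plan(list(list(energy_MeV = e,
                              spots = data.frame(x_mm = 0, y_mm = 0,
                                                 mu = 3))))
  ds <- plan_dose(pl, bs, den)
  pl$beam_model <- "large"
  dl <- plan_dose(pl, bl, den)
  is_ <- apply(ds$values, 2, sum)
  il <- apply(dl$values, 2, sum)
  sel <- is_ > 0.02 * max(is_)
  expect_lt(max(abs(is_[sel] - il[sel]) / max(is_)), 0.01)
  # but lateral profiles differ in width
  iy <- 20
  expect_gt(max(ds$values[, iy, ]), 2 * max(dl$values[, iy, ]))
})

test_that("energy outside the model and zero-density paths are handled", {
  b <- tiny_beam()
  den <- water_grid(c(21, 61, 21), 2)
  expect_error(spot_dose(list(x_mm = 0, y_mm = 0, energy_MeV = 123.456,
                              mu = 1, direction = c(0, 1, 0)), b, den),
               "not in beam model")
  # air-only path: the Bragg peak is never reached inside the grid; only
  # the entrance plateau is sampled (dose escapes at maximum range). Use an
  # energy whose peak lies inside the water grid for the comparison.
  air <- dose_grid(array(0.0012, dim = c(21, 61, 21)), 2, units = "g/cc")
  e <- b$energies[which.min(abs(b$r0_mm - 100))]
  sp <- list(x_mm = 0, y_mm = 0, energy_MeV = e, mu = 1,
             direction = c(0, 1, 0))
  dair <- spot_dose(sp, b, air)$values
  dwat <- spot_dose(sp, b, den)$values
  # plane-integrated depth profiles: air samples only the entrance plateau
  pa <- apply(dair, 2, sum); pw <- apply(dwat, 2, sum)
  expect_lt(max(pa), 0.6 * max(pw))   # entrance plateau, not the peak
  expect_lt(max(pa) / pa[2], 1.05)    # flat plateau, no peak in grid
})

test_that("non-axis-aligned beam directions are rejected", {
  expect_error(spotlab:::parse_direction(c(1, 1, 0)), "axis-aligned")
})
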