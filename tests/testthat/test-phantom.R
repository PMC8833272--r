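test_that("phantom generation is deterministic for a fixed config and seed", {
  a <- generate_phantom(tiny_phantom_config(), seed = 11)
  b <- generate_phantom(tiny_phantom_config(), seed = 11)
  expect_identical(a, b)
  c <- generate_phantom(tiny_phantom_config(), seed = 12)
  expect_false(identical(a$tumor_center_mm, c$tumor_center_mm))
})

test_that("amplitude and geometry preconditions are enforced", {
  expect_error(generate_phantom(tiny_phantom_config(amplitude_mm = 15)),
               "amplitude")
  expect_error(generate_phantom(tiny_phantom_config(amplitude_mm = -1)),
               "amplitude")
  expect_error(generate_phantom(tiny_phantom_config(spacing_mm = 0)),
               "spacing")
  expect_error(
    generate_phantom(tiny_phantom_config(tumor_center_mm = c(52, 6, 0),
                                         jitter_mm = 0)),
    "external")
})

test_that("phantom satisfies its structural invariants", {
  ph <- tiny_phantom()
  expect_length(ph$phases, 10L)
  # reference-phase displacement identically zero
  expect_equal(max(abs(displacement_field(ph, ph$reference_phase_index))), 0)
  # water override inside IGTV, lung below 0.5 g/cc
  expect_true(all(ph$planning_density$values[ph$masks$IGTV] == 1.0))
  expect_true(all(ph$planning_density$values[ph$masks$total_lung] < 0.5))
  # CTV excluded from total lung; all masks inside the external contour
  expect_equal(sum(ph$masks$CTV & ph$masks$total_lung), 0L)
  for (nm in setdiff(names(ph$masks), "external"))
    expect_true(all(ph$masks$external[ph$masks[[nm]]]), label = nm)
  expect_true(all(ph$masks$IGTV[ph$masks$IGTV & ph$masks$CTV]))
})

test_that("tumor centroid excursion matches the configured amplitude", {
  for (amp in c(6, 13.2)) {
    ph <- generate_phantom(tiny_phantom_config(amplitude_mm = amp,
                                               falloff_width_mm = 30),
                           seed = 7)
    cents <- t(vapply(0:9, function(p) tumor_centroid(ph, p), numeric(3)))
    exc <- max(dist(cents))
    expect_lt(abs(exc - amp), max(ph$planning_density$spacing))
  }
})

test_that("centroid trace follows the sin^2 waveform at every phase", {
  ph <- tiny_phantom()
  ref <- tumor_centroid(ph, ph$reference_phase_index)
  for (p in 0:9) {
    shift <- tumor_centroid(ph, p) - ref
    expect_lt(max(abs(shift - ph$phase_shifts_mm[p + 1, ])),
              0.5 * max(ph$planning_density$spacing))
  }
})

test_that("zero amplitude gives identical phases and zero displacement", {
  ph <- tiny_phantom_static()
  for (p in 2:10)
    expect_identical(ph$phases[[p]]$values, ph$phases[[1]]$values)
  for (p in 0:9)
    expect_equal(max(abs(displacement_field(ph, p))), 0)
})

test_that("voxelized CTV volume matches the analytic sphere within 10%", {
  ph <- generate_phantom(tiny_phantom_config(amplitude_mm = 0,
                                             igtv_radius_mm = 15),
                         seed = 3)
  vol_cc <- sum(ph$masks$CTV) * voxel_volume_cc(ph$planning_density)
  analytic <- 4 / 3 * pi * 20^3 / 1000   # IGTV 15 mm + 5 mm margin
  expect_lt(abs(vol_cc - analytic) / analytic, 0.10)
})

test_that("point displacement is exact at the extremes and invertible", {
  ph <- tiny_phantom()
  pt <- ph$tumor_center_mm
  # reference phase: identity
  expect_equal(displace_point(ph, ph$reference_phase_index, pt), pt)
  # T0: full amplitude along the motion direction at the rigid core
  d0 <- displace_point(ph, 0, pt) - pt
  expect_equal(as.numeric(d0), ph$phase_shifts_mm[1, ], tolerance = 1e-12)
  expect_equal(sqrt(sum(d0^2)), ph$motion_amplitude_mm, tolerance = 1e-9)
  # round trip through the falloff annulus recovers the point to < 0.01 mm
  for (off in list(c(0, 0, 0), c(12, 0, 6), c(-20, 8, -15))) {
    p0 <- ph$tumor_center_mm + off
    p1 <- displace_point(ph, 0, p0)
    expect_lt(max(abs(inverse_displace_point(ph, 0, p1) - p0)), 0.01)
  }
  expect_error(displace_point(ph, 0, c(1e4, 0, 0)), "outside")
})

test_that("phantom serialization is reproducible bitwise", {
  ph <- tiny_phantom()
  d1 <- file.path(tempdir(), "ph1"); d2 <- file.path(tempdir(), "ph2")
  write_phantom(ph, d1); write_phantom(ph, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$reference_phase_index, ph$reference_phase_index)
  expect_length(man$phase_order, 10L)
  g <- read_nrrd(file.path(d1, man$phase_order[[1]]))
  expect_equal(g$values, ph$phases[[1]]$values, tolerance = 1e-8)
  unlink(c(d1, d2), recursive = TRUE)
})
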