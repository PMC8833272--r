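# Shared fixtures, memoized per test session (several are expensive).

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# A small thorax phantom (44^3 @ 3 mm) for unit tests; geometry scaled so the
# tumor stays deliverable with the reduced-minimum-energy test beam.
tiny_phantom_config <- function(...) {
  base <- list(
    dims = c(44L, 44L, 44L), spacing_mm = 3,
    amplitude_mm = 6, igtv_radius_mm = 8, jitter_mm = 1,
    core_margin_mm = 6, falloff_width_mm = 25,
    tumor_center_mm = c(27, 6, -12),
    geometry = list(external_semi_mm = c(58, 52),
                    lung_center_mm = c(27, -3, 0),
                    lung_semi_mm = c(22, 27, 54),
                    heart_center_mm = c(-8, 5, -10),
                    heart_semi_mm = c(17, 16, 22),
                    esophagus_center_xy_mm = c(1, 10),
                    esophagus_radius_mm = 3.5,
                    cord_center_xy_mm = c(0, 34),
                    cord_radius_mm = 4))
  do.call(phantom_config, utils::modifyList(base, list(...)))
}

tiny_phantom <- function() memo_fixture("tiny_phantom",
  generate_phantom(tiny_phantom_config(), seed = 11))

tiny_phantom_static <- function() memo_fixture("tiny_phantom_static",
  generate_phantom(tiny_phantom_config(amplitude_mm = 0), seed = 11))

# Test beam: small model with a lower minimum energy so the shallow tiny
# phantom stays in range.
tiny_beam <- function() memo_fixture("tiny_beam",
  beam_model("small", e_min_MeV = 50))

small_beam <- function() memo_fixture("small_beam", beam_model("small"))
large_beam <- function() memo_fixture("large_beam", beam_model("large"))

# Uniform water grid for engine tests.
water_grid <- function(dims = c(31, 121, 31), spacing = 2)
  dose_grid(array(1.0, dim = dims), spacing, units = "g/cc")

# A "bare" phantom-like object: homogeneous water with simple masks, for
# planning tests that need full analytic control of the geometry.
water_phantom <- function(dims = c(40L, 40L, 40L), spacing = 3,
                          ctv_fun = NULL) {
  den <- dose_grid(array(1.0, dim = dims), spacing, units = "g/cc")
  co <- spotlab:::grid_coord_arrays(den)
  if (is.null(ctv_fun))
    ctv_fun <- function(x, y, z) sqrt(x^2 + y^2 + z^2) <= 15
  ctv <- ctv_fun(co$x, co$y, co$z)
  list(planning_density = den,
       masks = list(CTV = ctv, external = array(TRUE, dim = dims)))
}

# Lightly optimized tiny plan (nominal scenario only), normalized; shared by
# interplay and planning tests.
tiny_plan <- function() memo_fixture("tiny_plan", {
  ph <- tiny_phantom()
  b <- tiny_beam()
  pl <- place_spots(ph, b, list(c(0, -1, 0), c(0, 1, 0)))
  st <- optimize_settings(scenarios = list(nominal_scenario()), maxit = 150L)
  pl <- suppressWarnings(robust_optimize(pl, b, ph, st))
  d <- plan_dose(pl, b, ph$planning_density)
  normalize_d99(pl, d, ph$masks$CTV)
})

tiny_plan_static <- function() memo_fixture("tiny_plan_static", {
  ph <- tiny_phantom_static()
  b <- tiny_beam()
  pl <- place_spots(ph, b, list(c(0, -1, 0), c(0, 1, 0)))
  st <- optimize_settings(scenarios = list(nominal_scenario()), maxit = 150L)
  pl <- suppressWarnings(robust_optimize(pl, b, ph, st))
  d <- plan_dose(pl, b, ph$planning_density)
  normalize_d99(pl, d, ph$masks$CTV)
})

# Hand-built one-field plan for timeline arithmetic tests.
manual_plan <- function(layers, direction = c(0, 1, 0),
                        beam_model = "small") {
  structure(list(
    fields = list(list(direction = direction, layers = layers)),
    beam_model = beam_model, prescription_cGy = 7000, fractions = 35L,
    paintings = NULL), class = "spot_plan")
}
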