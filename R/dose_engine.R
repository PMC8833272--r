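#' Setup/range perturbation scenario
#'
#' @param shift_mm length-3 isocenter shift (mm) in patient axes
#'   RL(x)/AP(y)/SI(z); the beam system is translated by this vector.
#' @param range_scale multiplicative factor on proton range (1.035 means all
#'   protons penetrate 3.5\% deeper in water-equivalent depth).
#' @param label optional scenario label.
#' @export
scenario <- function(shift_mm = c(0, 0, 0), range_scale = 1, label = NULL) {
  shift_mm <- rep_len(as.numeric(shift_mm), 3L)
  if (!is.finite(range_scale) || range_scale <= 0)
    stop("range_scale must be positive")
  if (is.null(label))
    label <- sprintf("shift(%g,%g,%g)/range%.3f", shift_mm[1], shift_mm[2],
                     shift_mm[3], range_scale)
  structure(list(shift_mm = shift_mm, range_scale = range_scale,
                 label = label), class = "scenario")
}

#' The unperturbed scenario
#' @export
nominal_scenario <- function() scenario(c(0, 0, 0), 1, "nominal")

# Parse an axis-aligned beam direction unit vector -> axis (1..3), sign.
parse_direction <- function(direction) {
  direction <- as.numeric(direction)
  stopifnot(length(direction) == 3L)
  nz <- which(abs(direction) > 1e-9)
  if (length(nz) != 1L)
    stop("beam directions must be axis-aligned (one nonzero component)")
  list(axis = nz, sign = sign(direction[nz]),
       unit = direction / abs(direction[nz]),
       lateral = setdiff(1:3, nz))
}

#' Water-equivalent depth volume along an axis-aligned beam
#'
#' Radiological path length (mm of water) from the grid boundary where the
#' beam enters to each voxel centre, by straight-ray midpoint integration of
#' the relative mass density along the beam axis.
#'
#' @param density a density `dose_grid` (g/cc, water = 1).
#' @param direction axis-aligned beam travel direction (unit vector).
#' @return array of WED values (mm), same dims as the grid.
#' @export
wed_volume <- function(density, direction) {
  pd <- parse_direction(direction)
  d <- dim(density$values)
  perm <- c(pd$axis, setdiff(1:3, pd$axis))
  m <- matrix(aperm(density$values, perm), nrow = d[pd$axis])
  if (pd$sign < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  cs <- apply(m, 2, cumsum)
  wed <- (cs - m / 2) * density$spacing[pd$axis]
  if (pd$sign < 0) wed <- wed[rev(seq_len(nrow(wed))), , drop = FALSE]
  aperm(array(wed, dim = d[perm]), order(perm))
}

# Spot matrix (u, v, mu, eidx0) for one plan field; rows follow
# plan_spot_table() order within the field.
field_spot_matrix <- function(field, beam) {
  rows <- lapply(seq_along(field$layers), function(li) {
    ly <- field$layers[[li]]
    eidx <- energy_index(beam, ly$energy_MeV)
    cbind(ly$spots$x_mm, ly$spots$y_mm, ly$spots$mu, eidx - 1L)
  })
  do.call(rbind, rows)
}

#' Dose of a single spot
#'
#' Analytic pencil-beam deposit: `MU x IDD(E, z) x Gaussian(lateral; sigma(z))`
#' with `z = WED / range_scale`, linear in MU. A scenario's isocenter shift
#' translates the beam apparatus: the lateral components displace the spot
#' pattern, while the component along the beam axis leaves the dose unchanged
#' (parallel beam, depth referenced to the patient surface along unchanged
#' rays). Output in cGy(RBE) (constant RBE folded in) or physical cGy with
#' `rbe = FALSE`.
#'
#' @param spot list with `x_mm`, `y_mm` (lateral position on the two
#'   non-beam axes, in increasing axis order), `energy_MeV`, `mu`, and
#'   `direction` (axis-aligned beam travel unit vector).
#' @param beam a [beam_model()].
#' @param density density `dose_grid` (g/cc).
#' @param scen a [scenario()].
#' @param rbe logical; fold in the constant RBE (default TRUE).
#' @param cutoff_sigmas lateral truncation radius in units of sigma.
#' @return dose `dose_grid`.
#' @export
spot_dose <- function(spot, beam, density, scen = nominal_scenario(),
                      rbe = TRUE, cutoff_sigmas = 3.5) {
  if (spot$mu < 0) stop("spot MU must be >= 0")
  energy_index(beam, spot$energy_MeV)  # errors if absent
  plan <- list(fields = list(list(
    direction = spot$direction,
    layers = list(list(energy_MeV = spot$energy_MeV,
                       spots = data.frame(x_mm = spot$x_mm, y_mm = spot$y_mm,
                                          mu = spot$mu))))),
    beam_model = beam$name)
  plan_dose(plan, beam, density, scen, rbe = rbe,
            cutoff_sigmas = cutoff_sigmas)
}

#' Dose of a full spot plan
#'
#' Superposition of [spot_dose()] over all spots of all fields (SFUD
#' additivity); per-field water-equivalent depths are ray-traced once.
#'
#' @param plan a spot plan (see [place_spots()]).
#' @param beam a [beam_model()].
#' @param density density `dose_grid`.
#' @param scen a [scenario()].
#' @param rbe logical; cGy(RBE) output when TRUE.
#' @param cutoff_sigmas lateral truncation radius (sigmas).
#' @param fields optional integer subset of fields to compute.
#' @return dose `dose_grid` in cGy(RBE) (or cGy).
#' @export
plan_dose <- function(plan, beam, density, scen = nominal_scenario(),
                      rbe = TRUE, cutoff_sigmas = 3.5, fields = NULL) {
  if (!is.null(plan$beam_model) && !identical(plan$beam_model, beam$name))
    warning("plan references beam model '", plan$beam_model,
            "' but dose is computed with '", beam$name, "'")
  d <- dim(density$values)
  dose <- numeric(prod(d))
  out_f <- if (rbe) beam$rbe else 1
  idx <- if (is.null(fields)) seq_along(plan$fields) else fields
  for (fi in idx) {
    fld <- plan$fields[[fi]]
    pd <- parse_direction(fld$direction)
    wed <- wed_volume(density, fld$direction)
    sp <- field_spot_matrix(fld, beam)
    if (is.null(sp) || nrow(sp) == 0) next
    cpp_deposit_spots(dose, d, density$spacing, density$origin,
                      as.vector(wed), pd$axis - 1L, sp,
                      beam$r0_mm, beam$sigma_iso_mm,
                      beam$idd, beam$idd_dz, beam$mcs_k, beam$mcs_p,
                      scen$shift_mm, 0, scen$range_scale, cutoff_sigmas,
                      out_f)
  }
  dose_grid(array(dose, dim = d), density$spacing, density$origin,
            if (rbe) "cGyRBE" else "cGy")
}

#' Influence matrices at sample points
#'
#' Dose per unit MU of every spot at a set of sample points, per field and
#' per scenario; the optimizer's cached dose model.
#'
#' @param plan spot plan.
#' @param beam beam model.
#' @param density density `dose_grid`.
#' @param points n x 3 matrix of sample coordinates (mm).
#' @param scenarios list of [scenario()] objects.
#' @param rbe logical, as in [plan_dose()].
#' @param cutoff_sigmas lateral truncation (sigmas).
#' @return list over fields; each element a list over scenarios of
#'   (npoints x nspots) matrices.
#' @export
influence_matrices <- function(plan, beam, density, points, scenarios,
                               rbe = TRUE, cutoff_sigmas = 3.5) {
  d <- dim(density$values)
  out_f <- if (rbe) beam$rbe else 1
  lapply(plan$fields, function(fld) {
    pd <- parse_direction(fld$direction)
    wed <- wed_volume(density, fld$direction)
    wed_pts <- cpp_trilinear(as.vector(wed), d, density$spacing,
                             density$origin, points)
    sp <- field_spot_matrix(fld, beam)
    lapply(scenarios, function(sc) {
      cpp_influence(points, wed_pts, pd$axis - 1L, sp,
                    beam$r0_mm, beam$sigma_iso_mm, beam$idd, beam$idd_dz,
                    beam$mcs_k, beam$mcs_p,
                    sc$shift_mm, 0, sc$range_scale, cutoff_sigmas, out_f)
    })
  })
}
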