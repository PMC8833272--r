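#' Configuration for the synthetic 4D thorax phantom
#'
#' The phantom is a voxelized thorax built from analytic primitives: an
#' elliptic-cylinder body, two ellipsoidal lungs, an ellipsoidal heart,
#' cylindrical esophagus and spinal cord, and a spherical gross tumor volume
#' whose breathing excursion sweeps out a capsule-shaped internal gross tumor
#' volume (IGTV). The IGTV is overridden with water density (1.0 g/cc) and
#' the CTV is the IGTV expanded by an isotropic margin. Tumor motion follows
#' a sin^2 waveform, superior-inferior dominant, with end-exhale (T50) as the
#' rest/reference position and end-inhale (T0) at full amplitude.
#'
#' @param dims integer length-3, grid size in voxels.
#' @param spacing_mm voxel spacing (mm), scalar or length-3.
#' @param amplitude_mm peak-to-peak tumor excursion in mm; must be < 15.
#' @param motion_dir direction of tumor excursion (RL, AP, SI components,
#'   normalized internally). Default is SI-dominant with small AP/RL parts.
#' @param breathing_period_s breathing period (s); 10 uniform phase bins.
#' @param reference_phase 0-based index of the reference phase (default 5,
#'   i.e. T50 / end-exhale).
#' @param igtv_radius_mm radius of the spherical tumor (mm).
#' @param ctv_margin_mm isotropic IGTV-to-CTV margin (mm).
#' @param tumor_center_mm tumor rest-position centre (mm); `NULL` picks a
#'   right-lung default, or a mediastinum-adjacent default when
#'   `mediastinal = TRUE`.
#' @param mediastinal logical; place the target against the mediastinum
#'   (near esophagus/heart), emulating mediastinum-involved cases.
#' @param jitter_mm uniform random jitter applied to tumor and heart centres
#'   (seeded; set 0 for a fully deterministic geometry).
#' @param core_margin_mm rigid-motion core radius beyond the IGTV radius (mm).
#' @param falloff_width_mm width of the cosine falloff annulus over which the
#'   displacement decays to zero (mm); must exceed
#'   `amplitude_mm * pi / 2` for the field to stay invertible.
#' @param densities named list: `air`, `soft`, `lung`, `tumor` (g/cc).
#' @param geometry named list of organ primitives (see source for fields).
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(80L, 80L, 80L),
                           spacing_mm = 3,
                           amplitude_mm = 8,
                           motion_dir = c(0.1, 0.2, -1),
                           breathing_period_s = 4,
                           reference_phase = 5L,
                           igtv_radius_mm = 12,
                           ctv_margin_mm = 5,
                           tumor_center_mm = NULL,
                           mediastinal = FALSE,
                           jitter_mm = 2,
                           core_margin_mm = 8,
                           falloff_width_mm = 30,
                           densities = list(air = 0.0012, soft = 1.0,
                                            lung = 0.26, tumor = 1.0),
                           geometry = NULL) {
  if (is.null(tumor_center_mm))
    tumor_center_mm <- if (mediastinal) c(28, 12, -20) else c(50, 10, -25)
  if (is.null(geometry))
    geometry <- list(
      external_semi_mm = c(105, 95),
      lung_center_mm = c(50, -5, 0),     # mirrored for the left lung
      lung_semi_mm = c(40, 50, 100),
      heart_center_mm = c(-12, 8, -20),
      heart_semi_mm = c(32, 30, 40),
      esophagus_center_xy_mm = c(2, 18),
      esophagus_radius_mm = 5,
      cord_center_xy_mm = c(0, 62),
      cord_radius_mm = 6)
  cfg <- list(dims = as.integer(rep_len(dims, 3L)),
              spacing_mm = rep_len(as.numeric(spacing_mm), 3L),
              amplitude_mm = amplitude_mm,
              motion_dir = motion_dir,
              breathing_period_s = breathing_period_s,
              reference_phase = as.integer(reference_phase),
              igtv_radius_mm = igtv_radius_mm,
              ctv_margin_mm = ctv_margin_mm,
              tumor_center_mm = tumor_center_mm,
              mediastinal = mediastinal,
              jitter_mm = jitter_mm,
              core_margin_mm = core_margin_mm,
              falloff_width_mm = falloff_width_mm,
              densities = densities,
              geometry = geometry)
  class(cfg) <- "phantom_config"
  cfg
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Distance from points to the motion segment [a, a + len * mhat].
dist_to_segment <- function(x, y, z, a, mhat, len) {
  if (len <= 0) {
    return(sqrt((x - a[1])^2 + (y - a[2])^2 + (z - a[3])^2))
  }
  s <- (x - a[1]) * mhat[1] + (y - a[2]) * mhat[2] + (z - a[3]) * mhat[3]
  s <- pmin(pmax(s, 0), len)
  sqrt((x - a[1] - s * mhat[1])^2 +
       (y - a[2] - s * mhat[2])^2 +
       (z - a[3] - s * mhat[3])^2)
}

# Cosine falloff: 1 inside r0, 0 beyond r1.
motion_falloff <- function(rho, r0, r1) {
  f <- numeric(length(rho))
  f[rho <= r0] <- 1
  mid <- rho > r0 & rho < r1
  f[mid] <- 0.5 * (1 + cos(pi * (rho[mid] - r0) / (r1 - r0)))
  f
}

# sin^2 breathing waveform sampled at the 10 phase bins; 0 at the reference
# phase (rest), 1 at the opposite extreme.
breathing_waveform <- function(reference_phase, n_phases = 10L) {
  p <- seq_len(n_phases) - 1L
  sin(pi * (p - reference_phase) / n_phases)^2
}

phantom_geometry_fun <- function(cfg, tumor_center, heart_center) {
  g <- cfg$geometry
  dn <- cfg$densities
  mhat <- cfg$motion_dir / sqrt(sum(cfg$motion_dir^2))
  rg <- cfg$igtv_radius_mm
  # Analytic density at arbitrary coordinates. The moving tumor is the
  # spherical GTV at its rest position plus tumor_shift; the IGTV water
  # override is a planning construct applied separately (planning grid only).
  function(x, y, z, tumor_shift = c(0, 0, 0)) {
    dens <- x * 0 + dn$air   # same shape as input (array or vector)
    ext <- (x / g$external_semi_mm[1])^2 + (y / g$external_semi_mm[2])^2 <= 1
    dens[ext] <- dn$soft
    for (side in c(1, -1)) {
      lc <- g$lung_center_mm * c(side, 1, 1)
      inl <- ((x - lc[1]) / g$lung_semi_mm[1])^2 +
             ((y - lc[2]) / g$lung_semi_mm[2])^2 +
             ((z - lc[3]) / g$lung_semi_mm[3])^2 <= 1
      dens[inl] <- dn$lung
    }
    hc <- heart_center
    inh <- ((x - hc[1]) / g$heart_semi_mm[1])^2 +
           ((y - hc[2]) / g$heart_semi_mm[2])^2 +
           ((z - hc[3]) / g$heart_semi_mm[3])^2 <= 1
    dens[inh] <- dn$soft
    ine <- (x - g$esophagus_center_xy_mm[1])^2 +
           (y - g$esophagus_center_xy_mm[2])^2 <= g$esophagus_radius_mm^2
    dens[ine & ext] <- dn$soft
    inc <- (x - g$cord_center_xy_mm[1])^2 +
           (y - g$cord_center_xy_mm[2])^2 <= g$cord_radius_mm^2
    dens[inc & ext] <- dn$soft
    a <- tumor_center + tumor_shift
    rho <- sqrt((x - a[1])^2 + (y - a[2])^2 + (z - a[3])^2)
    dens[rho <= rg] <- dn$tumor
    dens
  }
}

#' Generate a seeded synthetic 4D thorax phantom
#'
#' Builds 10 breathing-phase density grids with a known, analytic, invertible
#' displacement field between the reference phase and every other phase. Each
#' phase density is the exact pull-back of the reference geometry under that
#' field, so 4D dose mapping is testable against ground truth. Organ masks
#' (CTV, IGTV, total lung excluding CTV, heart, esophagus, spinal cord,
#' external) are defined on the reference phase.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed controlling the (small) random organ jitter.
#' @return An object of class `phantom4d` with fields `phases` (list of 10
#'   density `dose_grid`s, T0..T90), `planning_density`,
#'   `reference_phase_index` (0-based), `masks`, `motion_amplitude_mm`,
#'   `breathing_period_s`, `waveform`, `phase_shifts_mm` (10 x 3 matrix),
#'   and the displacement-field parameters.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  cfg <- config
  if (cfg$amplitude_mm < 0 || cfg$amplitude_mm >= 15)
    stop("tumor motion amplitude must be in [0, 15) mm; got ",
         cfg$amplitude_mm)
  if (any(cfg$spacing_mm <= 0)) stop("grid spacing must be > 0")
  if (cfg$amplitude_mm * pi / (2 * cfg$falloff_width_mm) >= 1)
    stop("falloff_width_mm too small for an invertible displacement field")

  jit <- with_local_seed(seed, list(
    tumor = stats::runif(3, -cfg$jitter_mm, cfg$jitter_mm),
    heart = stats::runif(3, -cfg$jitter_mm, cfg$jitter_mm)))
  tumor_center <- cfg$tumor_center_mm + jit$tumor
  heart_center <- cfg$geometry$heart_center_mm + jit$heart

  mhat <- cfg$motion_dir / sqrt(sum(cfg$motion_dir^2))
  w <- breathing_waveform(cfg$reference_phase)
  d_mat <- outer(w, mhat) * cfg$amplitude_mm   # 10 x 3 core shifts (mm)

  proto <- dose_grid(array(0, dim = cfg$dims), cfg$spacing_mm, units = "g/cc")
  co <- grid_coord_arrays(proto)
  geom <- phantom_geometry_fun(cfg, tumor_center, heart_center)

  # The motion core is rigid around the resting tumor sphere (the moving
  # GTV), with a cosine falloff annulus; the IGTV capsule is the planning
  # construct swept out by the sphere over the cycle.
  r0 <- cfg$igtv_radius_mm + cfg$core_margin_mm
  r1 <- r0 + cfg$falloff_width_mm
  disp <- list(a = tumor_center, mhat = mhat, len = cfg$amplitude_mm,
               r0 = r0, r1 = r1, d_mat = d_mat)

  dens_ref <- geom(co$x, co$y, co$z)
  rho_sph <- sqrt((co$x - tumor_center[1])^2 + (co$y - tumor_center[2])^2 +
                  (co$z - tumor_center[3])^2)
  rho_cap <- dist_to_segment(co$x, co$y, co$z, tumor_center, mhat,
                             cfg$amplitude_mm)

  phases <- vector("list", 10L)
  for (p in seq_len(10L)) {
    dp <- d_mat[p, ]
    if (max(abs(dp)) < 1e-12) {
      vals <- dens_ref
    } else {
      vals <- dens_ref
      sel <- which(rho_sph <= r1 + sqrt(sum(dp^2)))
      xs <- co$x[sel]; ys <- co$y[sel]; zs <- co$z[sel]
      # invert T_p by fixed-point iteration: y <- x - f(|y - a|) * d_p
      yx <- xs; yy <- ys; yz <- zs
      for (it in seq_len(40L)) {
        f <- motion_falloff(
          sqrt((yx - tumor_center[1])^2 + (yy - tumor_center[2])^2 +
               (yz - tumor_center[3])^2), r0, r1)
        nx <- xs - f * dp[1]; ny <- ys - f * dp[2]; nz <- zs - f * dp[3]
        delta <- max(abs(nx - yx), abs(ny - yy), abs(nz - yz))
        yx <- nx; yy <- ny; yz <- nz
        if (delta < 1e-7) break
      }
      vals[sel] <- geom(yx, yy, yz)
    }
    phases[[p]] <- dose_grid(vals, cfg$spacing_mm, proto$origin, "g/cc")
  }

  # Planning grid: reference anatomy with the IGTV overridden to water.
  plan_vals <- phases[[cfg$reference_phase + 1L]]$values
  plan_vals[rho_cap <= cfg$igtv_radius_mm] <- cfg$densities$tumor
  planning <- dose_grid(plan_vals, cfg$spacing_mm, proto$origin, "g/cc")

  # Masks on the reference phase.
  g <- cfg$geometry
  ig <- rho_cap <= cfg$igtv_radius_mm
  ctv <- rho_cap <= cfg$igtv_radius_mm + cfg$ctv_margin_mm
  ext <- (co$x / g$external_semi_mm[1])^2 +
         (co$y / g$external_semi_mm[2])^2 <= 1
  lungs <- array(FALSE, dim = cfg$dims)
  for (side in c(1, -1)) {
    lc <- g$lung_center_mm * c(side, 1, 1)
    lungs <- lungs |
      (((co$x - lc[1]) / g$lung_semi_mm[1])^2 +
       ((co$y - lc[2]) / g$lung_semi_mm[2])^2 +
       ((co$z - lc[3]) / g$lung_semi_mm[3])^2 <= 1)
  }
  heart <- ((co$x - heart_center[1]) / g$heart_semi_mm[1])^2 +
           ((co$y - heart_center[2]) / g$heart_semi_mm[2])^2 +
           ((co$z - heart_center[3]) / g$heart_semi_mm[3])^2 <= 1
  eso <- ((co$x - g$esophagus_center_xy_mm[1])^2 +
          (co$y - g$esophagus_center_xy_mm[2])^2 <=
          g$esophagus_radius_mm^2) & ext
  cord <- ((co$x - g$cord_center_xy_mm[1])^2 +
           (co$y - g$cord_center_xy_mm[2])^2 <= g$cord_radius_mm^2) & ext
  total_lung <- lungs & !heart & !eso & !cord & !ctv

  if (any(ctv & !ext))
    stop("CTV extends outside the external contour; adjust the geometry")

  masks <- list(CTV = ctv, IGTV = ig, total_lung = total_lung, heart = heart,
                esophagus = eso, spinal_cord = cord, external = ext)

  structure(list(
    phases = phases,
    planning_density = planning,
    reference_phase_index = cfg$reference_phase,
    masks = masks,
    motion_amplitude_mm = cfg$amplitude_mm,
    breathing_period_s = cfg$breathing_period_s,
    waveform = w,
    phase_shifts_mm = d_mat,
    displacement = disp,
    tumor_center_mm = tumor_center,
    heart_center_mm = heart_center,
    config = cfg,
    seed = as.integer(seed)),
    class = "phantom4d")
}

#' @export
print.phantom4d <- function(x, ...) {
  d <- dim(x$planning_density$values)
  cat(sprintf(paste0("<phantom4d> %d x %d x %d voxels @ %s mm, 10 phases, ",
                     "amplitude %.1f mm, period %.1f s, reference T%d0\n"),
              d[1], d[2], d[3],
              paste(signif(x$planning_density$spacing, 3), collapse = "x"),
              x$motion_amplitude_mm, x$breathing_period_s,
              x$reference_phase_index))
  v <- voxel_volume_cc(x$planning_density)
  cat(sprintf("  CTV %.1f cc, IGTV %.1f cc, total lung %.0f cc, seed %d\n",
              sum(x$masks$CTV) * v, sum(x$masks$IGTV) * v,
              sum(x$masks$total_lung) * v, x$seed))
  invisible(x)
}

# Displacement u_p at arbitrary coordinates (vectors), mm. Rigid inside the
# core sphere around the resting tumor, cosine falloff to zero at r1.
displacement_at <- function(phantom, phase, x, y, z) {
  dp <- phantom$phase_shifts_mm[phase + 1L, ]
  ds <- phantom$displacement
  f <- motion_falloff(sqrt((x - ds$a[1])^2 + (y - ds$a[2])^2 +
                           (z - ds$a[3])^2), ds$r0, ds$r1)
  cbind(f * dp[1], f * dp[2], f * dp[3])
}

#' Per-phase displacement field as an (nvox x 3) matrix
#'
#' Maps reference-phase voxel-centre coordinates to their position in the
#' given phase (mm). Column-major voxel order.
#'
#' @param phantom a `phantom4d`.
#' @param phase 0-based phase index (0..9).
#' @export
displacement_field <- function(phantom, phase) {
  stopifnot(phase %in% 0:9)
  co <- grid_coord_arrays(phantom$planning_density)
  displacement_at(phantom, phase, as.vector(co$x), as.vector(co$y),
                  as.vector(co$z))
}

#' Displace a reference-phase point into a breathing phase
#'
#' @param phantom a `phantom4d`.
#' @param phase 0-based phase index (0..9).
#' @param point numeric length-3 coordinate (mm) on the reference phase.
#' @return the point's coordinate (mm) in the given phase.
#' @export
displace_point <- function(phantom, phase, point) {
  stopifnot(phase %in% 0:9, length(point) == 3L)
  ax <- grid_axes(phantom$planning_density)
  lo <- c(ax$x[1], ax$y[1], ax$z[1])
  hi <- c(max(ax$x), max(ax$y), max(ax$z))
  if (any(point < lo) || any(point > hi))
    stop("point outside grid bounds")
  point + as.vector(displacement_at(phantom, phase,
                                    point[1], point[2], point[3]))
}

#' Invert the phase mapping of a point
#'
#' Numerically inverts the analytic displacement field by fixed-point
#' iteration; round-trips with [displace_point()] to < 0.01 mm.
#'
#' @inheritParams displace_point
#' @param point coordinate (mm) in the given phase.
#' @return the point's reference-phase coordinate (mm).
#' @export
inverse_displace_point <- function(phantom, phase, point) {
  stopifnot(phase %in% 0:9, length(point) == 3L)
  y <- point
  for (it in seq_len(60L)) {
    u <- as.vector(displacement_at(phantom, phase, y[1], y[2], y[3]))
    yn <- point - u
    if (max(abs(yn - y)) < 1e-9) { y <- yn; break }
    y <- yn
  }
  y
}

#' Voxelized tumor centroid in a breathing phase
#'
#' Centroid (mm) of the spherical GTV voxelized on the phase geometry; used
#' to validate that the configured motion waveform is realized on the grid.
#'
#' @inheritParams displace_point
#' @export
tumor_centroid <- function(phantom, phase) {
  stopifnot(phase %in% 0:9)
  dp <- phantom$phase_shifts_mm[phase + 1L, ]
  a <- phantom$displacement$a + dp
  co <- grid_coord_arrays(phantom$planning_density)
  rho <- sqrt((co$x - a[1])^2 + (co$y - a[2])^2 + (co$z - a[3])^2)
  m <- rho <= phantom$config$igtv_radius_mm
  c(mean(co$x[m]), mean(co$y[m]), mean(co$z[m]))
}

#' Serialize a phantom to a directory (ASCII NRRD per grid + JSON manifest)
#'
#' @param phantom a `phantom4d`.
#' @param dir output directory (created if missing).
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  phase_files <- sprintf("phase_T%02d.nrrd", (0:9) * 10)
  for (p in seq_len(10L))
    write_nrrd(phantom$phases[[p]], file.path(dir, phase_files[p]))
  mask_files <- sprintf("mask_%s.nrrd", names(phantom$masks))
  for (i in seq_along(phantom$masks)) {
    m <- phantom$masks[[i]]
    write_nrrd(dose_grid(array(as.numeric(m), dim = dim(m)),
                         phantom$planning_density$spacing,
                         phantom$planning_density$origin, "binary"),
               file.path(dir, mask_files[i]))
  }
  manifest <- list(
    phase_order = phase_files,
    masks = as.list(stats::setNames(mask_files, names(phantom$masks))),
    reference_phase_index = phantom$reference_phase_index,
    motion_amplitude_mm = phantom$motion_amplitude_mm,
    breathing_period_s = phantom$breathing_period_s,
    waveform = phantom$waveform,
    seed = phantom$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
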