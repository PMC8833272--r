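#' Place spots and energy layers to cover the CTV
#'
#' For each field, CTV voxels are projected onto the lateral plane on a grid
#' of pitch `lateral_spacing_sigma * sigma_iso(E_ref)` and energy layers are
#' chosen so their water ranges span the CTV's water-equivalent depth extent
#' plus margins. A layer gets a spot at a lateral node if some CTV voxel
#' projects near that node within the layer's depth band; the lateral spot
#' set is then dilated by `lateral_margin_sigma` sigma. Initial weights are
#' uniform (1 MU).
#'
#' @param phantom a `phantom4d` (planned on its reference-phase density with
#'   the IGTV water override).
#' @param beam a [beam_model()].
#' @param field_directions list of 2-3 axis-aligned beam travel unit vectors.
#' @param lateral_spacing_sigma lateral spot pitch in units of the model's
#'   reference sigma (default 1.0).
#' @param layer_spacing_mm energy-layer spacing in water range (mm).
#' @param lateral_margin_sigma lateral expansion of each layer's spot set, in
#'   units of sigma (penumbra coverage).
#' @param setup_margin_mm additional lateral expansion (mm) covering the
#'   setup-uncertainty envelope, so every optimization scenario has spots
#'   available where the shifted target moves (default 5, matching the 5 mm
#'   setup uncertainty).
#' @param depth_margin_mm proximal/distal extension of the layer stack (mm).
#' @param prescription_cGy total prescription, default 7000 cGy(RBE).
#' @param fractions number of fractions, default 35.
#' @return A spot plan: list with `fields` (direction + descending energy
#'   layers + spots), `beam_model`, `prescription_cGy`, `fractions`,
#'   `paintings` (NULL until [make_volumetric_repainting()]).
#' @export
place_spots <- function(phantom, beam, field_directions,
                        lateral_spacing_sigma = 1.0,
                        layer_spacing_mm = 4,
                        lateral_margin_sigma = 1.5,
                        setup_margin_mm = 5,
                        depth_margin_mm = 4,
                        prescription_cGy = 7000,
                        fractions = 35L) {
  if (length(field_directions) < 1L)
    stop("at least one field direction is required")
  density <- phantom$planning_density
  ctv_idx <- which(phantom$masks$CTV)
  pts <- grid_points(density)[ctv_idx, , drop = FALSE]
  pitch <- lateral_spacing_sigma * beam$sigma_iso_ref_mm

  fields <- lapply(field_directions, function(dirv) {
    pd <- parse_direction(dirv)
    wed <- wed_volume(density, dirv)
    wed_ctv <- as.vector(wed)[ctv_idx]
    if (max(wed_ctv) + depth_margin_mm > max(beam$r0_mm))
      stop("CTV outside reachable range for beam model '", beam$name, "'")
    u <- pts[, pd$lateral[1]]
    v <- pts[, pd$lateral[2]]

    layer_depths <- seq(max(min(wed_ctv) - depth_margin_mm,
                            min(beam$r0_mm)),
                        max(wed_ctv) + depth_margin_mm,
                        by = layer_spacing_mm)
    # snap layers to available energies; dedupe, distal (deepest) first
    eidx <- unique(vapply(layer_depths, function(dd)
      which.min(abs(beam$r0_mm - dd)), integer(1)))
    eidx <- eidx[order(beam$r0_mm[eidx], decreasing = TRUE)]

    # lateral node grid covering the CTV projection
    n0u <- floor(min(u) / pitch) - 1L; n1u <- ceiling(max(u) / pitch) + 1L
    n0v <- floor(min(v) / pitch) - 1L; n1v <- ceiling(max(v) / pitch) + 1L
    nu <- n1u - n0u + 1L; nv <- n1v - n0v + 1L
    node_u <- function(i) (n0u + i - 1L) * pitch
    node_v <- function(j) (n0v + j - 1L) * pitch
    iu <- pmin(pmax(round(u / pitch) - n0u + 1L, 1L), nu)
    iv <- pmin(pmax(round(v / pitch) - n0v + 1L, 1L), nv)
    dil <- max(1L, ceiling((lateral_margin_sigma * beam$sigma_iso_ref_mm +
                              setup_margin_mm) / pitch))
    band <- layer_spacing_mm

    layers <- lapply(eidx, function(ei) {
      depth <- beam$r0_mm[ei]
      selv <- abs(wed_ctv - depth) <= band |
        (depth > max(wed_ctv) & depth - max(wed_ctv) <= depth_margin_mm) |
        (depth < min(wed_ctv) & min(wed_ctv) - depth <= depth_margin_mm)
      occ <- matrix(FALSE, nu, nv)
      occ[cbind(iu[selv], iv[selv])] <- TRUE
      if (!any(occ)) return(NULL)
      # dilate by `dil` nodes (chebyshev)
      occd <- occ
      for (s1 in -dil:dil) for (s2 in -dil:dil) {
        if (s1 == 0 && s2 == 0) next
        src <- occ[max(1, 1 - s1):min(nu, nu - s1),
                   max(1, 1 - s2):min(nv, nv - s2), drop = FALSE]
        occd[max(1, 1 + s1):min(nu, nu + s1),
             max(1, 1 + s2):min(nv, nv + s2)] <-
          occd[max(1, 1 + s1):min(nu, nu + s1),
               max(1, 1 + s2):min(nv, nv + s2)] | src
      }
      w <- which(occd, arr.ind = TRUE)
      list(energy_MeV = beam$energies[ei],
           spots = data.frame(x_mm = node_u(w[, 1]), y_mm = node_v(w[, 2]),
                              mu = 1))
    })
    layers <- Filter(Negate(is.null), layers)
    list(direction = as.numeric(dirv), layers = layers)
  })

  structure(list(fields = fields, beam_model = beam$name,
                 prescription_cGy = prescription_cGy,
                 fractions = as.integer(fractions), paintings = NULL),
            class = "spot_plan")
}

#' @export
print.spot_plan <- function(x, ...) {
  tab <- plan_spot_table(x)
  cat(sprintf(paste0("<spot_plan:%s> %d fields, %d layers, %d spots, ",
                     "total %.1f MU, %d paintings\n"),
              x$beam_model, length(x$fields),
              sum(vapply(x$fields, function(f) length(f$layers), integer(1))),
              nrow(tab), sum(tab$mu),
              if (is.null(x$paintings)) 0L else length(x$paintings)))
  invisible(x)
}

#' Flat spot table of a plan
#'
#' @param plan a spot plan.
#' @return data.frame with `spot_id`, `field`, `layer` (delivery order,
#'   distal first), `energy_MeV`, `x_mm`, `y_mm`, `mu`.
#' @export
plan_spot_table <- function(plan) {
  rows <- list()
  for (fi in seq_along(plan$fields)) {
    fld <- plan$fields[[fi]]
    for (li in seq_along(fld$layers)) {
      ly <- fld$layers[[li]]
      rows[[length(rows) + 1L]] <-
        data.frame(field = fi, layer = li, energy_MeV = ly$energy_MeV,
                   x_mm = ly$spots$x_mm, y_mm = ly$spots$y_mm,
                   mu = ly$spots$mu)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- cbind(spot_id = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

# Replace all spot MUs from a vector in plan_spot_table order.
set_plan_mu <- function(plan, mu) {
  k <- 0L
  for (fi in seq_along(plan$fields)) {
    for (li in seq_along(plan$fields[[fi]]$layers)) {
      n <- nrow(plan$fields[[fi]]$layers[[li]]$spots)
      plan$fields[[fi]]$layers[[li]]$spots$mu <- mu[k + seq_len(n)]
      k <- k + n
    }
  }
  stopifnot(k == length(mu))
  plan
}

# Scale all MUs (planned and painting passes) by a factor.
scale_plan_mu <- function(plan, factor) {
  for (fi in seq_along(plan$fields))
    for (li in seq_along(plan$fields[[fi]]$layers))
      plan$fields[[fi]]$layers[[li]]$spots$mu <-
        plan$fields[[fi]]$layers[[li]]$spots$mu * factor
  if (!is.null(plan$paintings))
    for (k in seq_along(plan$paintings))
      plan$paintings[[k]]$spots$mu <- plan$paintings[[k]]$spots$mu * factor
  plan
}

#' Optimizer settings for [robust_optimize()]
#'
#' @param scenarios list of scenarios the worst-case objective sees; default
#'   nominal + the 12 evaluation scenarios.
#' @param n_ctv_sample,n_ring_sample sample sizes for target / normal-tissue
#'   shell points.
#' @param ring_gap_mm shell around the CTV penalized for overdose (inner and
#'   outer distance, mm).
#' @param ring_weight relative weight of the shell hinge penalty.
#' @param ring_cap_frac shell hinge threshold as a fraction of the per-field
#'   target dose.
#' @param under_weight,over_weight relative penalties on CTV underdose vs
#'   overdose (underdose weighted harder, as clinical optimizers do, so the
#'   cold tail that sets D99 is pulled up).
#' @param lse_sharpness worst-case smoothing: softmax temperature as a
#'   multiple of the initial loss scale (higher = closer to a hard max).
#' @param maxit L-BFGS-B iteration cap.
#' @param sample_seed seed for the deterministic point subsampling.
#' @export
optimize_settings <- function(scenarios = NULL,
                              n_ctv_sample = 1200L,
                              n_ring_sample = 800L,
                              ring_gap_mm = c(6, 20),
                              ring_weight = 0.1,
                              ring_cap_frac = 1.0,
                              under_weight = 1,
                              over_weight = 0.25,
                              lse_sharpness = 12,
                              maxit = 500L,
                              sample_seed = 1L) {
  if (is.null(scenarios))
    scenarios <- c(list(nominal_scenario()), make_scenarios())
  list(scenarios = scenarios, n_ctv_sample = n_ctv_sample,
       n_ring_sample = n_ring_sample, ring_gap_mm = ring_gap_mm,
       ring_weight = ring_weight, ring_cap_frac = ring_cap_frac,
       under_weight = under_weight, over_weight = over_weight,
       lse_sharpness = lse_sharpness, maxit = maxit,
       sample_seed = sample_seed)
}

#' Robust SFUD spot-weight optimization
#'
#' Each field is optimized independently (single-field uniform dose) to
#' deliver `prescription / n_fields` uniformly to the CTV: nonnegative MU
#' weights minimize a smooth worst case (log-sum-exp softmax) of the
#' per-scenario mean squared CTV deviation over the nominal plus perturbed
#' scenarios, plus a hinge penalty on overdose to a normal-tissue shell
#' around the target. Weights below the deliverable minimum MU are rounded
#' to 0 or the minimum afterwards.
#'
#' @param plan spot plan from [place_spots()].
#' @param beam beam model.
#' @param phantom `phantom4d`.
#' @param settings an [optimize_settings()] list.
#' @return the plan with optimized MUs; `plan$opt` carries per-field
#'   convergence info and a `status` of `"converged"` or
#'   `"converged-with-warning"`.
#' @export
robust_optimize <- function(plan, beam, phantom,
                            settings = optimize_settings()) {
  density <- phantom$planning_density
  ctv <- phantom$masks$CTV
  all_pts <- grid_points(density)
  ctv_idx <- which(ctv)

  # deterministic subsampling
  sub <- function(idx, n) {
    if (length(idx) <= n) return(idx)
    with_local_seed(settings$sample_seed, sample(idx, n))
  }
  ctv_s <- sub(ctv_idx, settings$n_ctv_sample)

  # normal-tissue shell: voxels whose distance to the CTV surface lies in
  # ring_gap_mm, approximated via distance to nearest CTV sample point
  out_idx <- which(!ctv & phantom$masks$external)
  ctv_pts <- all_pts[ctv_s, , drop = FALSE]
  cand <- sub(out_idx, 8L * settings$n_ring_sample)
  cp <- all_pts[cand, , drop = FALSE]
  dmin <- vapply(seq_len(nrow(cp)), function(i) {
    sqrt(min((ctv_pts[, 1] - cp[i, 1])^2 + (ctv_pts[, 2] - cp[i, 2])^2 +
             (ctv_pts[, 3] - cp[i, 3])^2))
  }, numeric(1))
  ring_idx <- cand[dmin >= settings$ring_gap_mm[1] &
                   dmin <= settings$ring_gap_mm[2]]
  ring_s <- sub(ring_idx, settings$n_ring_sample)

  pts <- all_pts[c(ctv_s, ring_s), , drop = FALSE]
  n_t <- length(ctv_s)
  n_r <- length(ring_s)
  scen <- settings$scenarios

  infl <- influence_matrices(plan, beam, density, pts, scen)
  target <- plan$prescription_cGy / length(plan$fields)
  cap <- settings$ring_cap_frac * target

  mu_all <- numeric(0)
  opt_info <- list()
  for (fi in seq_along(plan$fields)) {
    A <- infl[[fi]]
    At <- lapply(A, function(m) m[seq_len(n_t), , drop = FALSE])
    Ar <- A[[1]][n_t + seq_len(n_r), , drop = FALSE]   # nominal-scenario ring
    nsp <- ncol(At[[1]])

    # uniform-weight initialization
    a1 <- rowSums(At[[1]])
    w0 <- rep(max(sum(a1 * target) / max(sum(a1^2), 1e-12), 0), nsp)

    w_u <- settings$under_weight
    w_o <- settings$over_weight
    loss_s <- function(w) vapply(At, function(m) {
      r <- m %*% w - target
      (w_u * mean(pmin(r, 0)^2) + w_o * mean(pmax(r, 0)^2)) / target^2
    }, numeric(1))
    tau <- settings$lse_sharpness / max(mean(loss_s(w0)), 1e-9)

    fn <- function(w) {
      ls <- loss_s(w)
      mx <- max(ls)
      lse <- mx + log(sum(exp(tau * (ls - mx)))) / tau
      rr <- pmax(Ar %*% w - cap, 0)
      lse + settings$ring_weight * mean(rr * rr) / target^2
    }
    gr <- function(w) {
      ls <- loss_s(w)
      mx <- max(ls)
      sm <- exp(tau * (ls - mx)); sm <- sm / sum(sm)
      g <- numeric(length(w))
      for (s in seq_along(At)) {
        if (sm[s] < 1e-12) next
        r <- At[[s]] %*% w - target
        rw <- w_u * pmin(r, 0) + w_o * pmax(r, 0)
        g <- g + sm[s] * 2 * as.vector(crossprod(At[[s]], rw)) /
          (length(r) * target^2)
      }
      rr <- pmax(Ar %*% w - cap, 0)
      g + settings$ring_weight * 2 *
        as.vector(crossprod(Ar, rr)) / (nrow(Ar) * target^2)
    }
    res <- stats::optim(w0, fn, gr, method = "L-BFGS-B", lower = 0,
                        control = list(maxit = settings$maxit))
    w <- res$par
    # minimum-MU post-processing
    w[w > 0 & w < beam$mu_min / 2] <- 0
    w[w > 0 & w < beam$mu_min] <- beam$mu_min
    mu_all <- c(mu_all, w)
    opt_info[[fi]] <- list(value = res$value, counts = res$counts,
                           convergence = res$convergence)
  }
  plan <- set_plan_mu(plan, mu_all)

  # nominal CTV coverage check (goal: D99 >= 99% of prescription)
  dose <- plan_dose(plan, beam, density)
  d99 <- dose_at_volume(dvh(dose, ctv), pct = 99)
  status <- if (d99 >= 0.99 * plan$prescription_cGy) "converged"
            else "converged-with-warning"
  if (status == "converged-with-warning")
    warning(sprintf("nominal CTV D99 = %.0f cGy(RBE) misses the 99%% goal",
                    d99))
  plan$opt <- list(fields = opt_info, nominal_d99 = d99, status = status)
  plan
}

#' Normalize a plan so that CTV D99 equals 99\% of prescription
#'
#' All MUs (and painting MUs, if present) are scaled by
#' `0.99 * prescription / D99(current)`; dose is linear in MU so the
#' renormalized D99 matches to interpolation accuracy (+- 1 cGy).
#'
#' @param plan spot plan.
#' @param dose the plan's current nominal dose `dose_grid`.
#' @param ctv logical CTV mask array.
#' @return the scaled plan; `plan$normalization` records the scale factor and
#'   any spots pushed below the deliverable minimum MU.
#' @export
normalize_d99 <- function(plan, dose, ctv) {
  d99 <- dose_at_volume(dvh(dose, ctv), pct = 99)
  if (d99 <= 0) stop("CTV D99 must be positive to normalize")
  target <- 0.99 * plan$prescription_cGy
  f <- target / d99
  plan <- scale_plan_mu(plan, f)
  tab <- plan_spot_table(plan)
  viol <- tab$spot_id[tab$mu > 0 & tab$mu < 0.015]
  if (length(viol))
    warning(length(viol), " spot(s) fell below the minimum MU after ",
            "normalization")
  plan$normalization <- list(scale = f, target_cGy = target,
                             min_mu_violations = viol)
  plan
}

#' Build an alternating-order volumetric repainting structure
#'
#' Splits every spot's MU across `n_paintings` full passes. Odd paintings
#' traverse energy layers distal-to-proximal (the plan's stored order), even
#' paintings in the reverse direction, so consecutive paintings meet at the
#' same energy layer. When an even split would fall below the deliverable
#' minimum MU, that spot's painting count is reduced to
#' `floor(MU / mu_min)` (at least 1) and its passes are assigned to the
#' earliest paintings; MU is conserved exactly (the last pass carries the
#' floating-point remainder).
#'
#' @param plan spot plan without paintings.
#' @param n_paintings number of paintings (default 5).
#' @param mu_min deliverable minimum MU per spot per pass.
#' @return the plan with `paintings`: a list of passes, each with `direction`
#'   (`"down"` = distal to proximal) and a delivery-ordered spot table.
#' @export
make_volumetric_repainting <- function(plan, n_paintings = 5L,
                                       mu_min = 0.015) {
  if (!is.null(plan$paintings)) stop("plan already has a painting structure")
  n_paintings <- as.integer(n_paintings)
  stopifnot(n_paintings >= 1L)
  tab <- plan_spot_table(plan)
  tab <- tab[tab$mu > 0, , drop = FALSE]

  n_pass <- pmin(n_paintings, pmax(1L, floor(tab$mu / mu_min)))
  paintings <- vector("list", n_paintings)
  for (k in seq_len(n_paintings)) {
    act <- n_pass >= k
    if (!any(act)) { paintings[[k]] <- NULL; next }
    sub <- tab[act, , drop = FALSE]
    np <- n_pass[act]
    q <- sub$mu / np
    # last pass carries the exact remainder so painting MUs sum bitwise to mu
    mu_k <- ifelse(k < np, q, sub$mu - q * (np - 1))
    sub$mu <- mu_k
    down <- (k %% 2L) == 1L
    ord <- order(sub$field,
                 if (down) sub$layer else -sub$layer,
                 sub$spot_id)
    sub <- sub[ord, , drop = FALSE]
    rownames(sub) <- NULL
    paintings[[k]] <- list(index = k,
                           direction = if (down) "down" else "up",
                           spots = sub)
  }
  plan$paintings <- Filter(Negate(is.null), paintings)
  plan
}

#' Per-spot MU totals over the painting structure
#'
#' @param plan a repainted plan.
#' @return numeric vector indexed by `spot_id` of the summed painting MUs
#'   (zero-MU planned spots excluded from paintings contribute 0).
#' @export
painting_totals <- function(plan) {
  if (is.null(plan$paintings)) stop("plan has no painting structure")
  tab <- plan_spot_table(plan)
  tot <- numeric(nrow(tab))
  for (p in plan$paintings) {
    # sum in painting order; pass k < np adds q, the final pass the remainder
    tot[p$spots$spot_id] <- tot[p$spots$spot_id] + p$spots$mu
  }
  tot
}

#' Write a plan as JSON
#' @param plan spot plan.
#' @param path output file.
#' @export
write_plan_json <- function(plan, path) {
  obj <- list(
    beam_model = plan$beam_model,
    prescription_cGy = plan$prescription_cGy,
    fractions = plan$fractions,
    fields = lapply(plan$fields, function(f) list(
      direction = f$direction,
      layers = lapply(f$layers, function(l) list(
        energy_MeV = l$energy_MeV,
        spots = l$spots)))),
    paintings = if (is.null(plan$paintings)) NULL else
      lapply(plan$paintings, function(p) list(
        index = p$index, direction = p$direction, spots = p$spots)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a plan written by [write_plan_json()]
#' @param path JSON file.
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  fields <- lapply(obj$fields, function(f) {
    layers <- lapply(f$layers, function(l)
      list(energy_MeV = l$energy_MeV,
           spots = as.data.frame(l$spots)))
    list(direction = as.numeric(f$direction), layers = layers)
  })
  paintings <- NULL
  if (!is.null(obj$paintings) && length(obj$paintings))
    paintings <- lapply(obj$paintings, function(p)
      list(index = p$index, direction = p$direction,
           spots = as.data.frame(p$spots)))
  structure(list(fields = fields, beam_model = obj$beam_model,
                 prescription_cGy = obj$prescription_cGy,
                 fractions = obj$fractions, paintings = paintings),
            class = "spot_plan")
}
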