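#' Default configuration of the spot-size comparison experiment
#'
#' Bundles every stage's settings: the phantom, the small/large beam-model
#' pair, field directions, planning and optimization settings, the painting
#' count, interplay start phases, and the robustness criterion. A run is
#' reproducible from this configuration plus its seed alone.
#'
#' @param seed integer master seed.
#' @param phantom a [phantom_config()].
#' @param field_directions list of axis-aligned beam travel unit vectors
#'   (default: posterior and anterior fields, which keep the proximal CTV
#'   within the deliverable energy range without a range shifter).
#' @param beam_args list of shared arguments to [beam_model_pair()].
#' @param optimize a [optimize_settings()] list.
#' @param n_paintings volumetric repainting count (default 5).
#' @param start_phases interplay delivery start phases.
#' @param criterion_cGy robustness pass threshold for CTV D95.
#' @export
default_experiment_config <- function(seed = 1L,
                                      phantom = phantom_config(),
                                      field_directions =
                                        list(c(0, -1, 0), c(0, 1, 0)),
                                      beam_args = list(),
                                      optimize = optimize_settings(),
                                      n_paintings = 5L,
                                      start_phases = c("T0", "T50"),
                                      criterion_cGy = 6860) {
  list(seed = as.integer(seed), phantom = phantom,
       field_directions = field_directions, beam_args = beam_args,
       optimize = optimize, n_paintings = n_paintings,
       start_phases = start_phases, criterion_cGy = criterion_cGy)
}

#' Plan, normalize and repaint one beam model on a phantom
#'
#' Convenience for the per-model half of the experiment: spot placement,
#' robust optimization, D99 normalization, and the volumetric repainting
#' copy. Returns both the no-repainting (NR) and volumetric-repainting (VR)
#' plans plus the normalized nominal dose.
#'
#' @param phantom `phantom4d`.
#' @param beam beam model.
#' @param config experiment configuration ([default_experiment_config()]).
#' @export
build_model_plans <- function(phantom, beam, config) {
  plan <- place_spots(phantom, beam, config$field_directions)
  plan <- robust_optimize(plan, beam, phantom, config$optimize)
  dose0 <- plan_dose(plan, beam, phantom$planning_density)
  plan <- normalize_d99(plan, dose0, phantom$masks$CTV)
  dose <- plan_dose(plan, beam, phantom$planning_density)
  plan_vr <- make_volumetric_repainting(plan, config$n_paintings,
                                        beam$mu_min)
  list(plan_nr = plan, plan_vr = plan_vr, nominal_dose = dose)
}

#' Run the full small-vs-large spot comparison experiment
#'
#' For each beam model (small sigma = 3 mm, large sigma = 8 mm at 226.5 MeV)
#' the pipeline builds an SFUD plan, robustly optimizes, normalizes CTV D99
#' to 99\% of prescription, evaluates 12-scenario robustness, EUD/NTCP for
#' lung/heart/esophagus, and the interplay effect with and without
#' volumetric repainting for both start phases. Differences (Delta) follow
#' the convention large minus small.
#'
#' @param config a [default_experiment_config()].
#' @param out_dir optional directory; when given, stage tables are written
#'   as CSV/JSON plus a manifest.
#' @return a report bundle (list) with `phantom`, per-model results,
#'   `delta` tables, and `status` per stage.
#' @export
run_experiment <- function(config = default_experiment_config(),
                           out_dir = NULL) {
  status <- list()
  stage <- function(name, expr) {
    r <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, value = NULL,
                                           msg = conditionMessage(e)))
    status[[name]] <<- if (r$ok) "ok" else paste("failed:", r$msg)
    r$value
  }

  phantom <- stage("phantom", generate_phantom(config$phantom, config$seed))
  beams <- stage("beam_models", do.call(beam_model_pair, config$beam_args))
  models <- list()
  scen <- make_scenarios()
  labels <- vapply(scen, function(s) s$label, character(1))

  for (mn in c("small", "large")) {
    beam <- beams[[mn]]
    built <- stage(paste0("plan_", mn),
                   build_model_plans(phantom, beam, config))
    if (is.null(built)) next
    sdoses <- stage(paste0("scenario_doses_", mn), {
      c(list(nominal = built$nominal_dose),
        stats::setNames(lapply(scen, function(s)
          plan_dose(built$plan_nr, beam, phantom$planning_density, s)),
          labels))
    })
    rob <- stage(paste0("robustness_", mn),
                 evaluate_robustness(built$plan_nr, beam, phantom, scen,
                                     config$criterion_cGy, doses = sdoses))
    rb <- stage(paste0("radiobio_", mn),
                evaluate_radiobio(sdoses, phantom$masks,
                                  fractions = built$plan_nr$fractions))
    interplay <- list()
    for (sp in config$start_phases) {
      interplay[[paste0("NR_", sp)]] <- stage(
        paste0("interplay_NR_", sp, "_", mn),
        simulate_interplay(built$plan_nr, beam, phantom, sp))
      interplay[[paste0("VR_", sp)]] <- stage(
        paste0("interplay_VR_", sp, "_", mn),
        simulate_interplay(built$plan_vr, beam, phantom, sp))
    }
    nominal_dvh <- dvh(built$nominal_dose, phantom$masks$CTV, organ = "CTV")
    models[[mn]] <- list(
      plans = built, robustness = rob, radiobio = rb,
      interplay = interplay,
      nominal = c(D95 = dose_at_volume(nominal_dvh, pct = 95),
                  D99 = dose_at_volume(nominal_dvh, pct = 99),
                  HI = homogeneity_index(nominal_dvh)))
  }

  deltas <- stage("delta_tables", {
    if (!all(c("small", "large") %in% names(models))) NULL else {
      rt_s <- models$small$robustness$table
      rt_l <- models$large$robustness$table
      rob_delta <- data.frame(metric = rt_s$metric,
                              nominal_delta = delta(rt_l$nominal,
                                                    rt_s$nominal),
                              wcs_delta = delta(rt_l$wcs, rt_s$wcs))
      rb_s <- models$small$radiobio$table
      rb_l <- models$large$radiobio$table
      rb_delta <- data.frame(organ = rb_s$organ, quantity = rb_s$quantity,
                             small_wcs = rb_s$wcs, large_wcs = rb_l$wcs,
                             delta = delta(rb_l$wcs, rb_s$wcs))
      ip <- do.call(rbind, lapply(names(models$small$interplay), function(k) {
        data.frame(case = k,
                   small_D99 = models$small$interplay[[k]]$metrics["D99"],
                   large_D99 = models$large$interplay[[k]]$metrics["D99"],
                   row.names = NULL)
      }))
      ip$delta_D99 <- delta(ip$large_D99, ip$small_D99)
      list(robustness = rob_delta, radiobio = rb_delta, interplay = ip)
    }
  })

  bundle <- list(config = config, phantom = phantom, beams = beams,
                 models = models, delta = deltas, status = status)
  if (!is.null(out_dir)) write_experiment_bundle(bundle, out_dir)
  if (any(grepl("^failed", unlist(status))))
    warning("one or more stages failed; see bundle$status")
  bundle
}

#' Write an experiment bundle's tables and doses to disk
#'
#' @param bundle result of [run_experiment()].
#' @param out_dir output directory (created).
#' @export
write_experiment_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = bundle$config$seed, status = bundle$status,
                   files = list())
  add <- function(name, path) manifest$files[[name]] <<- basename(path)
  for (mn in names(bundle$models)) {
    m <- bundle$models[[mn]]
    p <- file.path(out_dir, sprintf("robustness_%s.csv", mn))
    write_robustness_report(m$robustness, p); add(paste0("robustness_", mn), p)
    p <- file.path(out_dir, sprintf("radiobio_%s.csv", mn))
    utils::write.csv(m$radiobio$table, p, row.names = FALSE)
    add(paste0("radiobio_", mn), p)
    p <- file.path(out_dir, sprintf("nominal_dose_%s.nrrd", mn))
    write_nrrd(m$plans$nominal_dose, p); add(paste0("nominal_dose_", mn), p)
    p <- file.path(out_dir, sprintf("plan_%s.json", mn))
    write_plan_json(m$plans$plan_vr, p); add(paste0("plan_", mn), p)
    ip <- do.call(rbind, lapply(names(m$interplay), function(k)
      data.frame(case = k, t(m$interplay[[k]]$metrics), row.names = NULL)))
    p <- file.path(out_dir, sprintf("interplay_%s.csv", mn))
    utils::write.csv(ip, p, row.names = FALSE); add(paste0("interplay_", mn), p)
  }
  if (!is.null(bundle$delta)) {
    for (nm in names(bundle$delta)) {
      p <- file.path(out_dir, sprintf("delta_%s.csv", nm))
      utils::write.csv(bundle$delta[[nm]], p, row.names = FALSE)
      add(paste0("delta_", nm), p)
    }
  }
  manifest$md5 <- as.list(tools::md5sum(
    file.path(out_dir, unlist(manifest$files))))
  names(manifest$md5) <- basename(names(manifest$md5))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
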