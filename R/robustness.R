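#' The 12 perturbed evaluation scenarios
#'
#' Cartesian product of one +-`shift_mm` isocenter shift along each patient
#' axis (SI, AP, RL) with the two range scalings (+-`range_pct`): exactly 12
#' scenarios; the nominal scenario is not included.
#'
#' @param shift_mm setup shift magnitude (mm), default 5.
#' @param range_pct range uncertainty in percent, default 3.5.
#' @return list of 12 [scenario()] objects, labelled `S1..S12`.
#' @export
make_scenarios <- function(shift_mm = 5, range_pct = 3.5) {
  axes <- list(SI = c(0, 0, 1), AP = c(0, 1, 0), RL = c(1, 0, 0))
  out <- list()
  k <- 0L
  for (ax in names(axes)) for (sgn in c(1, -1)) for (rs in c(1, -1)) {
    k <- k + 1L
    out[[k]] <- scenario(
      shift_mm = sgn * shift_mm * axes[[ax]],
      range_scale = 1 + rs * range_pct / 100,
      label = sprintf("S%d:%s%s/range%s", k, ax,
                      if (sgn > 0) "+" else "-",
                      if (rs > 0) "+" else "-"))
  }
  out
}

# The paper-style metric set: name, evaluator, and worst-case direction.
robustness_metric_defs <- function() {
  list(
    list(name = "ctv_D95",  organ = "CTV", wcs = "min",
         fn = function(h) dose_at_volume(h, pct = 95)),
    list(name = "ctv_D96",  organ = "CTV", wcs = "min",
         fn = function(h) dose_at_volume(h, pct = 96)),
    list(name = "ctv_D97",  organ = "CTV", wcs = "min",
         fn = function(h) dose_at_volume(h, pct = 97)),
    list(name = "ctv_D98",  organ = "CTV", wcs = "min",
         fn = function(h) dose_at_volume(h, pct = 98)),
    list(name = "ctv_D99",  organ = "CTV", wcs = "min",
         fn = function(h) dose_at_volume(h, pct = 99)),
    list(name = "ctv_D0.03cc", organ = "CTV", wcs = "max",
         fn = function(h) dose_at_volume(h, cc = 0.03)),
    list(name = "ctv_HI",   organ = "CTV", wcs = "min",
         fn = homogeneity_index),
    list(name = "lung_Dmean", organ = "total_lung", wcs = "max",
         fn = dvh_mean),
    list(name = "lung_V20", organ = "total_lung", wcs = "max",
         fn = function(h) volume_at_dose(h, 2000)),
    list(name = "lung_V5",  organ = "total_lung", wcs = "max",
         fn = function(h) volume_at_dose(h, 500)),
    list(name = "heart_Dmean", organ = "heart", wcs = "max",
         fn = dvh_mean),
    list(name = "esophagus_Dmean", organ = "esophagus", wcs = "max",
         fn = dvh_mean),
    list(name = "cord_D0.03cc", organ = "spinal_cord", wcs = "max",
         fn = function(h) dose_at_volume(h, cc = 0.03)))
}

# Evaluate the full metric list on one dose distribution.
scenario_metrics <- function(dose, masks) {
  defs <- robustness_metric_defs()
  vapply(defs, function(df) {
    m <- masks[[df$organ]]
    if (is.null(m) || !any(m)) {
      warning("mask '", df$organ, "' missing or empty; metric ", df$name,
              " skipped")
      return(NA_real_)
    }
    df$fn(dvh(dose, m, organ = df$organ))
  }, numeric(1))
}

#' Worst-case robustness evaluation over the 12 perturbed scenarios
#'
#' Recomputes the plan dose for the nominal and every perturbed scenario on
#' the planning density, evaluates the full metric list (CTV D95-D99,
#' D0.03cc, HI; total-lung Dmean/V20/V5; heart and esophagus Dmean; cord
#' D0.03cc), and aggregates worst-case values: minimum over scenarios for
#' coverage/homogeneity, maximum for hot-spot and organ-at-risk metrics.
#' Also counts scenarios passing the clinical criterion CTV D95 >=
#' `criterion_cGy`.
#'
#' @param plan normalized spot plan.
#' @param beam beam model.
#' @param phantom `phantom4d`.
#' @param scenarios list of scenarios (default [make_scenarios()]).
#' @param criterion_cGy D95 pass threshold, default 6860 cGy(RBE) (98\% of
#'   7000).
#' @param doses optional precomputed named list of dose grids
#'   (`nominal` + one per scenario label) to reuse.
#' @return object of class `robustness_report`: `table` (one row per metric:
#'   nominal, S1..S12, WCS, rule), `pass_count`, `scenario_labels`.
#' @export
evaluate_robustness <- function(plan, beam, phantom,
                                scenarios = make_scenarios(),
                                criterion_cGy = 6860,
                                doses = NULL) {
  density <- phantom$planning_density
  defs <- robustness_metric_defs()
  labels <- vapply(scenarios, function(s) s$label, character(1))

  if (is.null(doses)) {
    doses <- c(list(nominal = plan_dose(plan, beam, density)),
               stats::setNames(lapply(scenarios, function(s)
                 plan_dose(plan, beam, density, s)), labels))
  }
  vals <- vapply(doses, scenario_metrics, numeric(length(defs)),
                 masks = phantom$masks)
  rownames(vals) <- vapply(defs, `[[`, character(1), "name")

  rule <- vapply(defs, `[[`, character(1), "wcs")
  wcs <- vapply(seq_along(defs), function(i) {
    v <- vals[i, -1]
    if (all(is.na(v))) return(NA_real_)
    if (rule[i] == "min") min(v, na.rm = TRUE) else max(v, na.rm = TRUE)
  }, numeric(1))

  tab <- data.frame(metric = rownames(vals), nominal = vals[, 1],
                    vals[, -1, drop = FALSE], wcs = wcs, rule = rule,
                    row.names = NULL, check.names = FALSE)
  d95 <- vals["ctv_D95", -1]
  structure(list(table = tab,
                 pass_count = sum(d95 >= criterion_cGy, na.rm = TRUE),
                 criterion_cGy = criterion_cGy,
                 scenario_labels = labels),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<robustness_report> %d scenarios, pass count %d/%d (CTV D95 >= %.0f cGy(RBE))\n",
              length(x$scenario_labels), x$pass_count,
              length(x$scenario_labels), x$criterion_cGy))
  print(x$table[, c("metric", "nominal", "wcs", "rule")], digits = 4)
  invisible(x)
}

#' Write a robustness report as CSV (+ JSON sidecar)
#' @param report a `robustness_report`.
#' @param path CSV path; a `.json` with the pass count is written alongside.
#' @export
write_robustness_report <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  jsonlite::write_json(
    list(pass_count = report$pass_count,
         criterion_cGy = report$criterion_cGy,
         scenario_labels = report$scenario_labels),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Large-spot minus small-spot difference (Delta)
#'
#' Sign convention: positive means the large-spot plan's value is higher.
#'
#' @param metric_LS metric value from the large-spot plan.
#' @param metric_SS same metric from the small-spot plan.
#' @export
delta <- function(metric_LS, metric_SS) metric_LS - metric_SS
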