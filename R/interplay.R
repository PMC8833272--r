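#' Delivery timing parameters
#'
#' @param layer_switch_s energy-layer switching time (s), default 1.0.
#' @param spot_s_per_mu spot delivery time per MU (s/MU), default 0.004
#'   (4 ms/MU; purely MU-proportional, no fixed per-spot overhead).
#' @param scan_speed_cm_s lateral scanning speed between spots (cm/s),
#'   default 250.
#' @param field_gap_s dead time between fields (s), default 30.
#' @export
delivery_params <- function(layer_switch_s = 1.0, spot_s_per_mu = 0.004,
                            scan_speed_cm_s = 250, field_gap_s = 30) {
  list(layer_switch_s = layer_switch_s, spot_s_per_mu = spot_s_per_mu,
       scan_speed_cm_s = scan_speed_cm_s, field_gap_s = field_gap_s)
}

#' Build the time-resolved spot delivery timeline
#'
#' Spots are delivered painting by painting, traversing energy layers in each
#' painting's direction. Per spot, delivery lasts `MU x spot_s_per_mu`;
#' between consecutive spots of a layer, the scan travel time is the lateral
#' distance over `scan_speed_cm_s`; an energy change inserts one
#' `layer_switch_s` (so no switch is inserted across a painting boundary when
#' the alternating order resumes at the same layer). Fields are delivered
#' sequentially separated by `field_gap_s`. Plans without a painting
#' structure are delivered as a single painting in planned order.
#'
#' @param plan spot plan (painted or not).
#' @param params a [delivery_params()] list.
#' @return object of class `delivery_timeline`: `events` data.frame
#'   (`field`, `painting`, `layer`, `energy_MeV`, `spot_id`, `x_mm`, `y_mm`,
#'   `mu`, `t_start_s`, `duration_s`), `params`, `total_time_s`.
#' @export
build_timeline <- function(plan, params = delivery_params()) {
  paintings <- plan$paintings
  if (is.null(paintings)) {
    tab <- plan_spot_table(plan)
    tab <- tab[tab$mu > 0, , drop = FALSE]
    paintings <- list(list(index = 1L, direction = "down", spots = tab))
  }
  if (any(vapply(paintings, function(p) any(p$spots$mu < 0), logical(1))))
    stop("negative MU in painting structure")
  speed_mm_s <- params$scan_speed_cm_s * 10

  ev <- list()
  n_fields <- max(vapply(paintings, function(p) max(p$spots$field),
                         numeric(1)))
  t <- 0
  for (fi in seq_len(n_fields)) {
    cur_energy <- NA_real_
    last_x <- NA_real_; last_y <- NA_real_
    for (p in paintings) {
      sub <- p$spots[p$spots$field == fi, , drop = FALSE]
      if (!nrow(sub)) next
      for (i in seq_len(nrow(sub))) {
        if (!is.na(cur_energy) && sub$energy_MeV[i] != cur_energy) {
          t <- t + params$layer_switch_s
          last_x <- NA_real_   # travel during the switch
        } else if (!is.na(last_x)) {
          t <- t + sqrt((sub$x_mm[i] - last_x)^2 +
                        (sub$y_mm[i] - last_y)^2) / speed_mm_s
        }
        cur_energy <- sub$energy_MeV[i]
        dur <- sub$mu[i] * params$spot_s_per_mu
        ev[[length(ev) + 1L]] <- data.frame(
          field = fi, painting = p$index, layer = sub$layer[i],
          energy_MeV = cur_energy, spot_id = sub$spot_id[i],
          x_mm = sub$x_mm[i], y_mm = sub$y_mm[i], mu = sub$mu[i],
          t_start_s = t, duration_s = dur)
        t <- t + dur
        last_x <- sub$x_mm[i]; last_y <- sub$y_mm[i]
      }
    }
    if (fi < n_fields) t <- t + params$field_gap_s
  }
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  structure(list(events = events, params = params, total_time_s = t),
            class = "delivery_timeline")
}

#' @export
print.delivery_timeline <- function(x, ...) {
  cat(sprintf("<delivery_timeline> %d events, %.1f s total, %.1f MU\n",
              nrow(x$events), x$total_time_s, sum(x$events$mu)))
  invisible(x)
}

#' Write a timeline as CSV
#' @param timeline a `delivery_timeline`.
#' @param path CSV path.
#' @export
write_timeline_csv <- function(timeline, path) {
  utils::write.csv(timeline$events, path, row.names = FALSE)
  invisible(path)
}

#' Assign delivery events to breathing phases
#'
#' Phase of an event is determined by its start time on a 10-bin periodic
#' breathing cycle: `floor(((t + offset) mod T) / (T/10))`, where the offset
#' is 0 for delivery starting at end-inhale (T0) and `T/2` for end-exhale
#' (T50). Spots are assigned whole to the phase active at their start (spot
#' durations are milliseconds, phase bins hundreds of milliseconds).
#'
#' @param timeline a `delivery_timeline`.
#' @param period_s breathing period (s), > 0.
#' @param start_phase `"T0"` or `"T50"`.
#' @return integer vector of 0-based phase indices per event.
#' @export
assign_phases <- function(timeline, period_s, start_phase = c("T0", "T50")) {
  start_phase <- match.arg(start_phase)
  if (period_s <= 0) stop("breathing period must be > 0")
  offset <- if (start_phase == "T0") 0 else period_s / 2
  t <- timeline$events$t_start_s
  as.integer(floor(((t + offset) %% period_s) / (period_s / 10))) %% 10L
}

#' Accumulate the interplay dose on the reference phase
#'
#' For each breathing phase, the dose of the spots assigned to that phase is
#' computed on the phase's density grid, pulled back to the reference phase
#' through the phantom's analytic displacement field (trilinear, with a
#' global energy renormalization so the total energy dose x mass is
#' conserved by the mapping), and summed.
#'
#' @param plan spot plan the timeline was built from.
#' @param beam beam model.
#' @param phantom `phantom4d`.
#' @param timeline a `delivery_timeline`.
#' @param phase_idx per-event 0-based phase assignment ([assign_phases()]).
#' @param scen optional [scenario()] perturbation (default nominal).
#' @return object of class `interplay_result`: `dose` (reference-phase
#'   accumulated dose), `metrics` (CTV D95, D99, HI), `phase_mu` (MU per
#'   phase).
#' @export
accumulate_interplay <- function(plan, beam, phantom, timeline, phase_idx,
                                 scen = nominal_scenario()) {
  stopifnot(length(phase_idx) == nrow(timeline$events))
  ref <- phantom$reference_phase_index
  d <- dim(phantom$planning_density$values)
  acc <- numeric(prod(d))
  phase_mu <- numeric(10L)
  tab <- plan_spot_table(plan)

  for (p in 0:9) {
    sel <- phase_idx == p
    if (!any(sel)) next
    sub <- timeline$events[sel, , drop = FALSE]
    phase_mu[p + 1L] <- sum(sub$mu)
    # per-spot MU delivered in this phase
    mu_vec <- numeric(nrow(tab))
    agg <- tapply(sub$mu, sub$spot_id, sum)
    mu_vec[as.integer(names(agg))] <- as.numeric(agg)
    sub_plan <- set_plan_mu(plan, mu_vec)
    dens_p <- phantom$phases[[p + 1L]]
    dose_p <- plan_dose(sub_plan, beam, dens_p, scen)
    if (p == ref) {
      acc <- acc + as.vector(dose_p$values)
    } else {
      disp <- displacement_field(phantom, p)
      mapped <- cpp_pullback(as.vector(dose_p$values), d, dens_p$spacing,
                             dens_p$origin, disp)
      e_in <- sum(dose_p$values * dens_p$values)
      e_out <- sum(mapped *
                     phantom$phases[[ref + 1L]]$values)
      if (e_out > 0) mapped <- mapped * (e_in / e_out)
      acc <- acc + mapped
    }
  }
  dose <- dose_grid(array(acc, dim = d), phantom$planning_density$spacing,
                    phantom$planning_density$origin, "cGyRBE")
  h <- dvh(dose, phantom$masks$CTV, organ = "CTV")
  structure(list(dose = dose,
                 metrics = c(D95 = dose_at_volume(h, pct = 95),
                             D99 = dose_at_volume(h, pct = 99),
                             HI = homogeneity_index(h)),
                 phase_mu = phase_mu),
            class = "interplay_result")
}

#' @export
print.interplay_result <- function(x, ...) {
  cat(sprintf("<interplay_result> CTV D95 %.0f, D99 %.0f cGy(RBE), HI %.3f\n",
              x$metrics["D95"], x$metrics["D99"], x$metrics["HI"]))
  invisible(x)
}

#' One-call interplay simulation
#'
#' Simulates the time-resolved delivery of a single fraction: the plan's
#' monitor units are divided by its fraction count, the delivery timeline is
#' built at the per-fraction spot durations (this is what sets the real
#' interplay timescale — a 2 Gy(RBE) fraction, not the whole course, is
#' delivered in one session), breathing phases are assigned for the
#' requested start phase, the 4D fraction dose is accumulated on the
#' reference phase, and the result is scaled back to the course dose (all
#' fractions assumed identical, as in a per-plan evaluation with a fixed
#' start phase). Set `fractions = 1` to deliver the stored MU as one
#' session.
#'
#' @inheritParams accumulate_interplay
#' @param start_phase `"T0"` (end-inhale) or `"T50"` (end-exhale).
#' @param params [delivery_params()].
#' @param fractions number of fractions the stored MU spans (default: the
#'   plan's own fraction count).
#' @export
simulate_interplay <- function(plan, beam, phantom,
                               start_phase = c("T0", "T50"),
                               params = delivery_params(),
                               scen = nominal_scenario(),
                               fractions = NULL) {
  start_phase <- match.arg(start_phase)
  if (is.null(fractions))
    fractions <- if (is.null(plan$fractions)) 1L else plan$fractions
  fr_plan <- if (fractions > 1) scale_plan_mu(plan, 1 / fractions) else plan
  tl <- build_timeline(fr_plan, params)
  ph <- assign_phases(tl, phantom$breathing_period_s, start_phase)
  res <- accumulate_interplay(fr_plan, beam, phantom, tl, ph, scen)
  if (fractions > 1) {
    res$dose$values <- res$dose$values * fractions
    h <- dvh(res$dose, phantom$masks$CTV, organ = "CTV")
    res$metrics <- c(D95 = dose_at_volume(h, pct = 95),
                     D99 = dose_at_volume(h, pct = 99),
                     HI = homogeneity_index(h))
    res$phase_mu <- res$phase_mu * fractions
  }
  res$fractions <- fractions
  res$start_phase <- start_phase
  res$timeline_total_s <- tl$total_time_s
  res
}
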