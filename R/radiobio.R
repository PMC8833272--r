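#' Equivalent dose in 2-Gy fractions (EQD2)
#'
#' Linear-quadratic conversion of a total dose delivered in `n_f` fractions
#' to the biologically equivalent total dose at 2 Gy per fraction:
#' \deqn{EQD = D \frac{\alpha/\beta + D/n_f}{\alpha/\beta + 2}.}
#' At 2 Gy per fraction the conversion is the identity.
#'
#' @param dose_gy total dose (Gy), vectorized (e.g. per DVH bin).
#' @param n_f number of fractions (>= 1).
#' @param alpha_beta tissue alpha/beta ratio (Gy, > 0).
#' @return EQD2 (Gy).
#' @export
eqd <- function(dose_gy, n_f, alpha_beta) {
  if (n_f < 1) stop("n_f must be >= 1")
  if (alpha_beta <= 0) stop("alpha_beta must be > 0")
  dose_gy * (alpha_beta + dose_gy / n_f) / (alpha_beta + 2)
}

#' Niemierko equivalent uniform dose (EUD)
#'
#' Generalized power mean of the (EQD-converted) dose distribution:
#' \deqn{EUD = \left(\sum_i v_i\, D_i^{a}\right)^{1/a}} with partial volumes
#' \eqn{v_i} summing to 1. `a = 1` gives the mean dose; large `a` approaches
#' the maximum; negative `a` emphasizes cold spots (targets).
#'
#' @param x a `dvh` (its voxel doses are used, each voxel an equal partial
#'   volume) or a numeric vector of bin doses.
#' @param a volume-effect parameter (nonzero).
#' @param v optional partial volumes when `x` is a numeric vector
#'   (default equal; must sum to 1).
#' @return EUD in the units of the input doses.
#' @export
eud <- function(x, a, v = NULL) {
  if (a == 0) stop("a = 0 is undefined for the power-mean EUD")
  d <- if (inherits(x, "dvh")) x$doses_sorted else as.numeric(x)
  if (is.null(v)) v <- rep(1 / length(d), length(d))
  if (length(v) != length(d)) stop("v must match the dose vector")
  if (abs(sum(v) - 1) > 1e-6) stop("partial volumes must sum to 1")
  if (a < 0 && any(d <= 0))
    stop("negative 'a' requires strictly positive doses")
  sum(v * d^a)^(1 / a)
}

#' EUD-based logistic NTCP
#'
#' \deqn{NTCP = \frac{1}{1 + (TD_{50}/EUD)^{4\gamma_{50}}}} — 0.5 when the
#' EUD equals the whole-organ 50\% tolerance dose, with slope set by
#' \eqn{\gamma_{50}}. `eud = 0` returns 0 (the limit).
#'
#' @param eud_val EUD; same units as `td50` (both Gy or both cGy).
#' @param td50 whole-organ tolerance dose for 50\% complication rate.
#' @param gamma50 normalized dose-response slope (> 0).
#' @return complication probability as a fraction in [0, 1].
#' @export
ntcp <- function(eud_val, td50, gamma50) {
  if (td50 <= 0 || gamma50 <= 0) stop("td50 and gamma50 must be > 0")
  if (any(eud_val < 0)) stop("eud must be >= 0")
  ifelse(eud_val == 0, 0, 1 / (1 + (td50 / eud_val)^(4 * gamma50)))
}

#' Fit (TD50, gamma50) from (EUD, NTCP) pairs
#'
#' In log-odds space the logistic model is linear:
#' \eqn{\ln((1-N)/N) = 4\gamma_{50}(\ln TD_{50} - \ln EUD)}. Two pairs give
#' the exact 2x2 solution; more pairs are fit by least squares. Pairs with
#' NTCP of exactly 0 or 1 carry no information and are dropped with a
#' warning.
#'
#' @param eud_vals EUD values (any consistent unit).
#' @param ntcp_fracs complication probabilities as fractions in (0, 1).
#' @return list with `td50` (input units) and `gamma50`.
#' @export
fit_ntcp_params <- function(eud_vals, ntcp_fracs) {
  stopifnot(length(eud_vals) == length(ntcp_fracs))
  keep <- ntcp_fracs > 0 & ntcp_fracs < 1
  if (any(!keep))
    warning(sum(!keep), " pair(s) with NTCP of 0 or 1 excluded from the fit")
  e <- eud_vals[keep]; n <- ntcp_fracs[keep]
  if (length(unique(e)) < 2L)
    stop("need at least 2 pairs with distinct EUD and NTCP in (0,1)")
  y <- log((1 - n) / n)
  fit <- stats::lm(y ~ log(e))
  slope <- unname(stats::coef(fit)[2])       # = -4 * gamma50
  intercept <- unname(stats::coef(fit)[1])   # =  4 * gamma50 * ln(TD50)
  if (slope >= 0) stop("pairs imply a non-increasing dose response")
  gamma50 <- -slope / 4
  td50 <- exp(intercept / (4 * gamma50))
  list(td50 = td50, gamma50 = gamma50)
}

#' Load the organ radiobiological parameter registry
#'
#' The registry (YAML) carries, per organ: the endpoint, the volume-effect
#' parameter `a`, `alpha_beta` (Gy), `td50_gy` (EQD2 Gy), and `gamma50`.
#' These parameters are configuration with photon-literature defaults; they
#' are not outputs of this package.
#'
#' @param path YAML file; defaults to the registry shipped with the package.
#' @return named list of organ models.
#' @export
load_organ_models <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "organ_models.yaml", package = "spotlab")
  reg <- yaml::read_yaml(path)
  for (nm in names(reg)) {
    om <- reg[[nm]]
    if (om$td50_gy <= 0 || om$gamma50 <= 0 || om$a == 0)
      stop("invalid parameters for organ '", nm, "'")
  }
  reg
}

#' EUD of an organ dose distribution in EQD2 space
#'
#' Converts the organ's voxel doses (cGy(RBE), full course) to EQD2 per
#' voxel via [eqd()] with the plan's fractionation, then applies the
#' power-mean [eud()].
#'
#' @param x a `dvh` of the organ (cGy(RBE)).
#' @param organ_model one entry of [load_organ_models()].
#' @param fractions number of fractions the dose was planned in.
#' @return EUD in cGy(RBE), EQD2-based.
#' @export
organ_eud <- function(x, organ_model, fractions) {
  d_gy <- x$doses_sorted / 100
  e <- eqd(d_gy, fractions, organ_model$alpha_beta)
  eud(e, organ_model$a) * 100
}

#' EUD/NTCP evaluation over nominal and perturbed scenario doses
#'
#' @param doses named list of dose `dose_grid`s: `nominal` first, then one
#'   per perturbed scenario.
#' @param masks phantom mask list (needs `total_lung`, `heart`, `esophagus`).
#' @param organ_models registry from [load_organ_models()].
#' @param fractions fractionation of the plans.
#' @return object of class `radiobio_result`: per-organ tables of EUD
#'   (cGy(RBE), EQD2) and NTCP (%) for every scenario, plus worst-case
#'   (maximum) columns.
#' @export
evaluate_radiobio <- function(doses, masks, organ_models = load_organ_models(),
                              fractions = 35L) {
  organs <- intersect(names(organ_models), names(masks))
  rows <- lapply(organs, function(org) {
    om <- organ_models[[org]]
    euds <- vapply(doses, function(dg)
      organ_eud(dvh(dg, masks[[org]], organ = org), om, fractions),
      numeric(1))
    ntcps <- 100 * ntcp(euds / 100, om$td50_gy, om$gamma50)
    scen <- setdiff(names(euds), "nominal")
    data.frame(organ = org, endpoint = om$endpoint,
               quantity = c("EUD_cGyRBE", "NTCP_pct"),
               rbind(euds, ntcps),
               wcs = c(max(euds[scen]), max(ntcps[scen])),
               row.names = NULL, check.names = FALSE)
  })
  structure(list(table = do.call(rbind, rows), fractions = fractions),
            class = "radiobio_result")
}

#' @export
print.radiobio_result <- function(x, ...) {
  cat("<radiobio_result> EUD (cGy(RBE), EQD2-based) and NTCP (%) per organ\n")
  print(x$table[, c("organ", "endpoint", "quantity", "nominal", "wcs")],
        digits = 4)
  invisible(x)
}
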