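#' Cumulative dose-volume histogram
#'
#' Builds the cumulative DVH of the voxel doses inside a mask. The binned
#' curve starts at volume fraction 1 at zero dose and reaches 0 one bin past
#' the maximum dose; the raw sorted voxel doses are kept alongside so that
#' mean dose and small-volume hot-spot metrics (D0.03cc) can be computed
#' exactly rather than from bins.
#'
#' @param dose dose `dose_grid` (cGy(RBE)).
#' @param mask logical array of the same dims.
#' @param bin_width_cGy DVH bin width (default 1 cGy).
#' @param organ optional organ name carried in the object.
#' @return object of class `dvh` with `curve` (`dose_cGy`,
#'   `volume_fraction`), `doses_sorted` (decreasing), `volume_cc`,
#'   `voxel_cc`, `bin_width_cGy`.
#' @export
dvh <- function(dose, mask, bin_width_cGy = 1, organ = NULL) {
  stopifnot(identical(dim(dose$values), dim(mask)))
  doses <- dose$values[mask]
  if (!length(doses)) stop("empty mask: no voxels to histogram")
  if (any(!is.finite(doses)) || any(doses < -1e-9))
    stop("dose must be finite and non-negative")
  doses <- pmax(doses, 0)
  ds <- sort(doses, decreasing = TRUE)
  edges <- seq(0, (floor(max(ds) / bin_width_cGy) + 1) * bin_width_cGy,
               by = bin_width_cGy)
  # V(d) = fraction of voxels with dose >= d at each bin edge
  n <- length(ds)
  frac <- 1 - (findInterval(edges, sort(doses), left.open = TRUE) / n)
  frac[1] <- 1
  structure(list(curve = data.frame(dose_cGy = edges, volume_fraction = frac),
                 doses_sorted = ds,
                 volume_cc = n * voxel_volume_cc(dose),
                 voxel_cc = voxel_volume_cc(dose),
                 bin_width_cGy = bin_width_cGy,
                 organ = organ),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh%s> %.1f cc, mean %.0f cGy, max %.0f cGy, bin %g cGy\n",
              if (is.null(x$organ)) "" else paste0(":", x$organ),
              x$volume_cc, dvh_mean(x), max(x$doses_sorted),
              x$bin_width_cGy))
  invisible(x)
}

#' Mean dose (computed on voxels, not bins)
#' @param x a `dvh`.
#' @export
dvh_mean <- function(x) mean(x$doses_sorted)

#' Dose at volume (Dx\% / Dx cc)
#'
#' `Dx%` is the minimum dose received by the hottest x\% of the organ,
#' read off the cumulative DVH with linear interpolation between bins.
#' Absolute-volume requests (`cc`) are evaluated on the sorted voxel tail
#' (nearest voxel count) to avoid bin-resolution bias for small volumes.
#'
#' @param x a `dvh`.
#' @param pct percent volume in (0, 100].
#' @param cc absolute volume in cc (alternative to `pct`).
#' @return dose in cGy(RBE).
#' @export
dose_at_volume <- function(x, pct = NULL, cc = NULL) {
  if (is.null(pct) == is.null(cc))
    stop("give exactly one of pct or cc")
  if (!is.null(cc)) {
    if (cc <= 0 || cc > x$volume_cc)
      stop("requested volume outside (0, organ volume]")
    k <- max(1L, round(cc / x$voxel_cc))
    return(x$doses_sorted[min(k, length(x$doses_sorted))])
  }
  if (pct <= 0 || pct > 100) stop("pct must be in (0, 100]")
  p <- pct / 100
  d <- x$curve$dose_cGy
  f <- x$curve$volume_fraction
  i <- max(which(f >= p))
  if (i == length(f) || f[i] == p || f[i] == f[i + 1]) return(d[i])
  d[i] + (f[i] - p) / (f[i] - f[i + 1]) * (d[i + 1] - d[i])
}

#' Volume at dose (Vd), in percent
#'
#' Fraction of the organ receiving at least `dose_cGy`, linearly
#' interpolated between DVH bins, returned in percent.
#'
#' @param x a `dvh`.
#' @param dose_cGy dose threshold in cGy(RBE).
#' @export
volume_at_dose <- function(x, dose_cGy) {
  if (dose_cGy < 0) stop("dose must be >= 0")
  d <- x$curve$dose_cGy
  f <- x$curve$volume_fraction
  if (dose_cGy >= max(d)) return(0)
  100 * stats::approx(d, f, xout = dose_cGy)$y
}

#' Homogeneity index D99\% / D1\%
#'
#' Equals 1 for a perfectly uniform distribution and decreases as the
#' distribution spreads.
#'
#' @param x a `dvh`.
#' @export
homogeneity_index <- function(x) {
  d1 <- dose_at_volume(x, pct = 1)
  if (d1 <= 0) stop("D1% must be positive for the homogeneity index")
  dose_at_volume(x, pct = 99) / d1
}

#' Write / read a DVH curve as CSV (`dose_cGy,volume_fraction`)
#' @param x a `dvh`.
#' @param path file path.
#' @export
write_dvh_csv <- function(x, path) {
  utils::write.csv(x$curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dvh_csv
#' @param volume_cc total organ volume (the CSV stores fractions only).
#' @export
read_dvh_csv <- function(path, volume_cc = NA_real_) {
  curve <- utils::read.csv(path)
  stopifnot(all(c("dose_cGy", "volume_fraction") %in% names(curve)))
  structure(list(curve = curve, doses_sorted = NULL, volume_cc = volume_cc,
                 voxel_cc = NA_real_,
                 bin_width_cGy = diff(curve$dose_cGy[1:2]), organ = NULL),
            class = "dvh")
}
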