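#' Create a 3D scalar grid
#'
#' A `dose_grid` is the package's voxel container: a 3D numeric array with
#' isotropic or anisotropic spacing and a physical origin (mm), in patient
#' axes RL(x) / AP(y) / SI(z). The same container holds dose in cGy(RBE),
#' mass density in g/cc, and binary masks.
#'
#' @param values 3D numeric array (column-major, x fastest).
#' @param spacing numeric length-3, voxel spacing in mm (> 0).
#' @param origin numeric length-3, physical coordinate (mm) of voxel
#'   `[1,1,1]`'s centre.
#' @param units unit label, e.g. `"cGyRBE"`, `"g/cc"`, `"binary"`.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = NULL, units = "cGyRBE") {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be positive and finite")
  if (is.null(origin)) origin <- -(dim(values) - 1) / 2 * spacing
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(values = values, spacing = spacing, origin = origin,
                 units = units),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing %s mm, units %s\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              x$units))
  cat(sprintf("  range [%.4g, %.4g], origin (%s) mm\n",
              min(x$values), max(x$values),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Voxel axis coordinates of a grid
#' @param grid a `dose_grid`.
#' @return list of numeric vectors `x`, `y`, `z` (mm, voxel centres).
#' @export
grid_axes <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3])
}

#' Voxel volume in cc
#' @param grid a `dose_grid`.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

# Coordinate arrays (same dims as grid) for vectorized geometry evaluation.
grid_coord_arrays <- function(grid) {
  d <- dim(grid$values)
  ax <- grid_axes(grid)
  list(x = array(rep(ax$x, times = d[2] * d[3]), dim = d),
       y = array(rep(rep(ax$y, each = d[1]), times = d[3]), dim = d),
       z = array(rep(ax$z, each = d[1] * d[2]), dim = d))
}

# Matrix (nvox x 3) of all voxel centre coordinates, column-major voxel order.
grid_points <- function(grid) {
  co <- grid_coord_arrays(grid)
  cbind(as.vector(co$x), as.vector(co$y), as.vector(co$z))
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Write a grid as an ASCII-encoded NRRD file
#'
#' Minimal NRRD writer (detached headers and compressed encodings are not
#' supported; `encoding: ascii` keeps the artifact plain text).
#'
#' @param grid a `dose_grid`.
#' @param path output file path.
#' @export
write_nrrd <- function(grid, path) {
  d <- dim(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    sprintf("# spotlab grid, units: %s", grid$units),
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %.9g %.9g %.9g",
            grid$spacing[1], grid$spacing[2], grid$spacing[3]),
    sprintf("axis mins: %.9g %.9g %.9g",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    "encoding: ascii",
    ""), con)
  writeLines(paste(format(as.vector(grid$values), digits = 10, trim = TRUE,
                          scientific = TRUE),
                   collapse = " "), con)
  invisible(path)
}

#' Read an ASCII-encoded NRRD file written by [write_nrrd()]
#' @param path file path.
#' @return a `dose_grid` (units recovered from the comment line if present).
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "NRRD")) stop("not an NRRD file: ", path)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("malformed NRRD header (no blank line)")
  hdr <- lines[2:(blank - 1)]
  field <- function(name) {
    ln <- grep(paste0("^", name, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^", name, ":"), "", ln[1]))
  }
  if (!identical(field("encoding"), "ascii"))
    stop("only ascii-encoded NRRD is supported")
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(field("spacings"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(field("axis mins"), "\\s+")[[1]])
  units <- "unknown"
  cm <- grep("units:", hdr, value = TRUE)
  if (length(cm)) units <- trimws(sub(".*units:", "", cm[1]))
  vals <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
               quiet = TRUE)
  if (length(vals) != prod(sizes)) stop("NRRD data length mismatch")
  dose_grid(array(vals, dim = sizes), spacing, origin, units)
}
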