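#' Specify a plane for electrostatic-potential maps
#'
#' @param origin length-3 corner point of the grid (Angstrom).
#' @param axis1,axis2 in-plane direction vectors; they are normalized and
#'   must be orthogonal to 1e-10 after normalization.
#' @return list of class `plane_spec`.
#' @export
plane_spec <- function(origin, axis1, axis2) {
  e1 <- axis1 / sqrt(sum(axis1^2))
  e2 <- axis2 / sqrt(sum(axis2^2))
  if (abs(sum(e1 * e2)) > 1e-10) stop("plane axes must be orthonormal")
  structure(list(origin = as.numeric(origin), e1 = e1, e2 = e2),
            class = "plane_spec")
}

#' Electrostatic potential on a plane grid
#'
#' Evaluates the potential of a parameter set on an `nx` x `ny` grid in a
#' plane. Grid node (i, j) sits at
#' `origin + (i-1) * spacing * e1 + (j-1) * spacing * e2`. Nodes closer than
#' `min_dist` to any included site are masked (`NA` value, `TRUE` in the
#' mask matrix) rather than reported as near-singular numbers.
#'
#' @param sites an [atom_sites] object.
#' @param plane a [plane_spec].
#' @param nx,ny grid node counts (>= 2).
#' @param spacing node spacing in Angstrom.
#' @param level `"charges"` or `"multipoles"`.
#' @param exclude exclusion groups to omit.
#' @param min_dist singularity-mask radius in Angstrom (default 1e-3).
#' @return An object of class `esp_grid`: list with `plane`, `nx`, `ny`,
#'   `spacing`, `values` (nx x ny matrix, V) and `mask` (logical matrix).
#' @export
esp_grid <- function(sites, plane, nx, ny, spacing,
                     level = c("multipoles", "charges"),
                     exclude = NULL, min_dist = 1e-3) {
  level <- match.arg(level)
  stopifnot(inherits(plane, "plane_spec"), nx >= 2, ny >= 2, spacing > 0)
  ij <- expand.grid(i = seq_len(nx) - 1, j = seq_len(ny) - 1)
  pts <- matrix(plane$origin, nrow(ij), 3, byrow = TRUE) +
    outer(ij$i * spacing, plane$e1) + outer(ij$j * spacing, plane$e2)
  v <- potential_at_points(sites, pts, exclude = exclude, level = level,
                           min_dist = min_dist)
  values <- matrix(v, nx, ny)
  structure(list(plane = plane, nx = nx, ny = ny, spacing = spacing,
                 values = values, mask = is.na(values)),
            class = "esp_grid")
}

#' Node-wise difference of two ESP grids
#'
#' Used to visualize how one electrostatic description differs from
#' another (e.g. a multipolar parameter set minus a charges-only one) on
#' the same plane. Grids must share plane, shape and mask.
#'
#' @param a,b `esp_grid` objects on identical grids.
#' @return An `esp_grid` holding `a$values - b$values`.
#' @export
esp_difference <- function(a, b) {
  stopifnot(inherits(a, "esp_grid"), inherits(b, "esp_grid"))
  same_plane <- isTRUE(all.equal(a$plane$origin, b$plane$origin)) &&
    isTRUE(all.equal(a$plane$e1, b$plane$e1)) &&
    isTRUE(all.equal(a$plane$e2, b$plane$e2))
  if (!same_plane || a$nx != b$nx || a$ny != b$ny ||
      !isTRUE(all.equal(a$spacing, b$spacing))) {
    stop("ESP grids have mismatched plane specifications")
  }
  if (!identical(a$mask, b$mask)) stop("ESP grids have mismatched masks")
  out <- a
  out$values <- a$values - b$values
  out
}

#' @export
print.esp_grid <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf(
    "esp_grid: %d x %d nodes, spacing %.3g A, potential range [%.4g, %.4g] V, %d masked\n",
    x$nx, x$ny, x$spacing, rng[1], rng[2], sum(x$mask)))
  invisible(x)
}
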