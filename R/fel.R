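# Free-energy landscapes over binned collective variables:
# G = -kT ln P, shifted so the occupied-grid minimum is 0. Empty bins are
# masked, never +Inf, in outputs.

.bin_axis <- function(values, width, name) {
  lo <- floor(min(values) / width) * width
  hi <- ceiling(max(values) / width) * width
  if (hi <= lo) hi <- lo + width
  breaks <- seq(lo, hi, by = width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  idx <- pmin(findInterval(values, breaks, rightmost.closed = TRUE),
              length(breaks) - 1L)
  list(name = name, breaks = breaks, width = width,
       mid = (breaks[-1] + breaks[-length(breaks)]) / 2, index = idx)
}

#' Two-dimensional free-energy landscape
#'
#' Bins two collective-variable series on a regular grid and converts bin
#' probabilities to free energies `G = -kT ln P`, shifted so the global
#' minimum of the occupied grid is zero. G is stored in kT units; multiply
#' by `kB * temperature` for kcal/mol.
#'
#' @param x_values,y_values Equal-length numeric series.
#' @param x_width,y_width Bin widths.
#' @param x_name,y_name Axis names.
#' @param config An `analysis_config` (supplies `temperature` and `kB`).
#' @return A `fel_grid`: axes, probability matrix `P`, free energy `G`
#'   (kT, `NA` on empty bins), `occupied` mask, and per-sample bin indices.
#' @export
compute_fel_2d <- function(x_values, y_values,
                           x_width, y_width,
                           x_name = "x", y_name = "y",
                           config = analysis_config()) {
  stopifnot(length(x_values) == length(y_values), length(x_values) > 0,
            x_width > 0, y_width > 0)
  ax <- .bin_axis(x_values, x_width, x_name)
  ay <- .bin_axis(y_values, y_width, y_name)
  nx <- length(ax$mid); ny <- length(ay$mid)
  counts <- matrix(0, nx, ny)
  tab <- table(factor(ax$index, levels = seq_len(nx)),
               factor(ay$index, levels = seq_len(ny)))
  counts <- matrix(as.numeric(tab), nx, ny)
  p <- counts / length(x_values)
  occupied <- counts > 0
  g <- matrix(NA_real_, nx, ny)
  g[occupied] <- -log(p[occupied])
  g <- g - min(g, na.rm = TRUE)
  structure(list(x = ax, y = ay, P = p, G = g, occupied = occupied,
                 n = length(x_values),
                 sample_bin = cbind(ax$index, ay$index),
                 temperature = config$temperature, kB = config$kB),
            class = "fel_grid")
}

#' One-dimensional free-energy profile
#'
#' Either marginalises an existing 2D grid over the other axis, or bins a
#' raw value series directly.
#'
#' @param x A `fel_grid` or a numeric value series.
#' @param axis For a grid: `"x"` or `"y"`.
#' @param width For a raw series: bin width.
#' @param name Axis name for a raw series.
#' @param config An `analysis_config`.
#' @return Data frame `mid`, `P`, `G` (kT, `NA` where empty).
#' @export
project_fel_1d <- function(x, axis = "x", width = NULL, name = "cv",
                           config = analysis_config()) {
  if (inherits(x, "fel_grid")) {
    p <- if (axis == "x") rowSums(x$P) else colSums(x$P)
    mid <- if (axis == "x") x$x$mid else x$y$mid
  } else {
    stopifnot(!is.null(width))
    ax <- .bin_axis(x, width, name)
    counts <- tabulate(ax$index, nbins = length(ax$mid))
    p <- counts / length(x)
    mid <- ax$mid
  }
  g <- rep(NA_real_, length(p))
  g[p > 0] <- -log(p[p > 0])
  g <- g - min(g, na.rm = TRUE)
  data.frame(mid = mid, P = p, G = g)
}

.neighbors8 <- as.matrix(expand.grid(di = -1:1, dj = -1:1))
.neighbors8 <- .neighbors8[rowSums(abs(.neighbors8)) > 0, ]

#' Detect free-energy basins on a 2D grid
#'
#' Local minima over the 8-neighbourhood of the occupied grid are filtered
#' to those with `G <= min(G) + min_depth_kT` and pairwise Chebyshev
#' separation of at least `min_separation_bins` (deeper minima win).
#' Every occupied bin is then assigned to a basin by steepest descent; a
#' descent ending in a discarded minimum joins the nearest retained basin.
#' Labels `a`, `b`, ... are ordered by descending x-axis coordinate of the
#' basin minimum, then ascending G.
#'
#' @param grid A `fel_grid`.
#' @param min_depth_kT,min_separation_bins See [analysis_config()].
#' @return A `basin_set`: data frame `basins` (label, bin indices, bin
#'   centers, G, population) plus `bin_basin` (basin label per grid bin)
#'   and `sample_basin` (basin label per input sample of the grid).
#' @export
find_basins <- function(grid,
                        min_depth_kT = 1.0,
                        min_separation_bins = 2L) {
  g <- grid$G
  occ <- grid$occupied
  nx <- nrow(g); ny <- ncol(g)
  occ_idx <- which(occ, arr.ind = TRUE)
  # local minima: no occupied 8-neighbour with strictly lower G
  is_min <- logical(nrow(occ_idx))
  lower_neighbor <- matrix(0L, nx, ny)  # linear index of steepest neighbour
  for (r in seq_len(nrow(occ_idx))) {
    i <- occ_idx[r, 1]; j <- occ_idx[r, 2]
    best <- g[i, j]; best_lin <- 0L
    for (k in seq_len(nrow(.neighbors8))) {
      ii <- i + .neighbors8[k, 1]; jj <- j + .neighbors8[k, 2]
      if (ii < 1 || jj < 1 || ii > nx || jj > ny || !occ[ii, jj]) next
      if (g[ii, jj] < best - 1e-12) {
        best <- g[ii, jj]; best_lin <- ii + nx * (jj - 1L)
      }
    }
    is_min[r] <- best_lin == 0L
    lower_neighbor[i, j] <- best_lin
  }
  minima <- occ_idx[is_min, , drop = FALSE]
  g_min <- g[minima]
  ord <- order(g_min)
  minima <- minima[ord, , drop = FALSE]
  g_min <- g_min[ord]
  keep <- g_min <= min(g_min) + min_depth_kT
  # separation filter, deepest first
  kept <- integer(0)
  for (r in which(keep)) {
    if (!length(kept)) { kept <- r; next }
    cheb <- pmax(abs(minima[kept, 1] - minima[r, 1]),
                 abs(minima[kept, 2] - minima[r, 2]))
    if (all(cheb >= min_separation_bins)) kept <- c(kept, r)
  }
  kept_min <- minima[kept, , drop = FALSE]
  # steepest-descent basin of every occupied bin (path compression via memo)
  basin_of_lin <- integer(nx * ny)
  endpoint <- function(i, j) {
    path <- integer(0)
    repeat {
      lin <- i + nx * (j - 1L)
      if (basin_of_lin[lin] > 0L) break
      nxt <- lower_neighbor[i, j]
      if (nxt == 0L) { basin_of_lin[lin] <<- lin; break }
      path <- c(path, lin)
      j <- (nxt - 1L) %/% nx + 1L
      i <- nxt - nx * (j - 1L)
    }
    lin <- i + nx * (j - 1L)
    root <- basin_of_lin[lin]
    if (length(path)) basin_of_lin[path] <<- root
    root
  }
  for (r in seq_len(nrow(occ_idx))) endpoint(occ_idx[r, 1], occ_idx[r, 2])
  # map descent endpoints onto kept minima (nearest kept, ties by lower G)
  kept_lin <- kept_min[, 1] + nx * (kept_min[, 2] - 1L)
  remap <- function(lin) {
    hit <- match(lin, kept_lin)
    if (!is.na(hit)) return(hit)
    i <- (lin - 1L) %% nx + 1L; j <- (lin - 1L) %/% nx + 1L
    cheb <- pmax(abs(kept_min[, 1] - i), abs(kept_min[, 2] - j))
    which.min(cheb * 1e6 + g[kept_lin])  # distance first, then depth
  }
  roots <- unique(basin_of_lin[basin_of_lin > 0L])
  root_to_basin <- vapply(roots, remap, integer(1))
  # order kept basins: descending x coordinate, then ascending G
  bx <- grid$x$mid[kept_min[, 1]]
  bg <- g[kept_min]
  lab_ord <- order(-bx, bg)
  label <- character(nrow(kept_min))
  label[lab_ord] <- letters[seq_len(nrow(kept_min))]
  bin_basin <- matrix(NA_character_, nx, ny)
  for (r in seq_len(nrow(occ_idx))) {
    lin <- occ_idx[r, 1] + nx * (occ_idx[r, 2] - 1L)
    bin_basin[lin] <- label[root_to_basin[match(basin_of_lin[lin], roots)]]
  }
  sample_basin <- bin_basin[cbind(grid$sample_bin[, 1], grid$sample_bin[, 2])]
  pop <- table(factor(sample_basin, levels = label[lab_ord]))
  basins <- data.frame(
    label = label[lab_ord],
    i = kept_min[lab_ord, 1], j = kept_min[lab_ord, 2],
    x = grid$x$mid[kept_min[lab_ord, 1]],
    y = grid$y$mid[kept_min[lab_ord, 2]],
    G = bg[lab_ord],
    population = as.integer(pop), stringsAsFactors = FALSE)
  structure(list(basins = basins, bin_basin = bin_basin,
                 sample_basin = sample_basin),
            class = "basin_set")
}

#' Relative basin free energies from populations
#'
#' `dG_i = -kT ln(P_i / P_max)`; the most populated basin sits at 0. A
#' zero-population basin is reported as `NA` (masked), never `Inf`.
#'
#' @param populations Non-negative counts or probabilities.
#' @param config An `analysis_config`.
#' @param unit `"kT"` or `"kcal"`.
#' @return Numeric vector of relative free energies.
#' @export
basin_relative_free_energy <- function(populations,
                                       config = analysis_config(),
                                       unit = c("kT", "kcal")) {
  unit <- match.arg(unit)
  if (any(populations < 0) || all(populations == 0)) {
    stop("populations must be non-negative and not all zero")
  }
  dg <- rep(NA_real_, length(populations))
  pos <- populations > 0
  dg[pos] <- -log(populations[pos] / max(populations))
  if (unit == "kcal") dg <- dg * config$kB * config$temperature
  dg
}

#' Write a 2D free-energy grid as a TSV table
#'
#' One row per occupied-or-not bin with centers, probability and G (kT);
#' masked bins carry `NA`.
#'
#' @param grid A `fel_grid`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fel <- function(grid, path) {
  df <- expand.grid(xi = seq_along(grid$x$mid), yi = seq_along(grid$y$mid))
  out <- data.frame(
    x = grid$x$mid[df$xi], y = grid$y$mid[df$yi],
    P = grid$P[cbind(df$xi, df$yi)],
    G_kT = grid$G[cbind(df$xi, df$yi)])
  names(out)[1:2] <- c(grid$x$name, grid$y$name)
  write_table(out, path)
}
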