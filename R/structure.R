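#' Rasterize a causal-plane point cloud
#'
#' Bins `(H, C)` or `(H, F)` points onto a regular `npix x npix` grid over
#' `[0, 1] x [0, 1]` (pixels are half-open, `[i/npix, (i+1)/npix)`, with the
#' top edge closed) and normalizes the counts to sum to one, so rasters from
#' runs with different numbers of grid cells are comparable. The normalized
#' count vector is the "fingerprint" of a model run used by the structure
#' diagnostic; in the entropy-complexity plane the pixels above the upper
#' limit curve are empty by construction.
#'
#' @param points Two-column matrix or data.frame of coordinates in
#'   `[0, 1]^2`: first column `H`, second `C` or `F`. Rows with `NA` are
#'   dropped.
#' @param plane `"HC"` or `"HF"` (metadata; recorded for compatibility
#'   checks).
#' @param npix Pixels per axis (default 25).
#' @param label Optional run identifier.
#' @return An object of class `plane_raster`: `counts` (npix x npix matrix,
#'   x pixel = row), `plane`, `npix`, `n_points`, `label`, `normalized`.
#' @export
rasterize_plane <- function(points, plane = c("HC", "HF"), npix = 25L,
                            label = NULL) {
  plane <- match.arg(plane)
  npix <- as.integer(npix)
  stopifnot(npix >= 1L)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) == 0L) stop("no valid points to rasterize")
  if (any(pts < 0 | pts > 1)) stop("coordinates must lie in [0, 1]")
  ix <- pmin(floor(pts[, 1] * npix), npix - 1L) + 1L  # top edge closed
  iy <- pmin(floor(pts[, 2] * npix), npix - 1L) + 1L
  counts <- matrix(0, npix, npix)
  for (k in seq_len(nrow(pts))) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  counts <- counts / sum(counts)
  structure(list(counts = counts, plane = plane, npix = npix,
                 n_points = nrow(pts), label = label, normalized = TRUE),
            class = "plane_raster")
}

#' @export
print.plane_raster <- function(x, ...) {
  cat(sprintf("<plane_raster> %s, %d x %d, %d points%s\n", x$plane, x$npix,
              x$npix, x$n_points,
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' Assemble raster fingerprints into a run-by-pixel matrix
#'
#' Flattens a list of normalized plane rasters into rows of one matrix and
#' drops pixel columns that are zero across every run (they carry no
#' information and only inflate dimensionality). Because removed columns are
#' all-zero, row sums remain 1.
#'
#' @param rasters List of [rasterize_plane()] results sharing `plane` and
#'   `npix`.
#' @return A numeric matrix (runs x kept pixels) with rownames from raster
#'   labels and attribute `kept_pixels`: the retained column indices of the
#'   flattened `npix^2` vector (column-major over `counts`).
#' @export
assemble_count_matrix <- function(rasters) {
  stopifnot(length(rasters) >= 1L)
  if (!all(vapply(rasters, inherits, logical(1), "plane_raster")))
    stop("all elements must be plane_raster objects")
  planes <- vapply(rasters, function(r) r$plane, character(1))
  npix <- vapply(rasters, function(r) r$npix, integer(1))
  if (length(unique(planes)) != 1L) stop("mixed plane types")
  if (length(unique(npix)) != 1L) stop("mixed raster resolutions")
  m <- t(vapply(rasters, function(r) as.numeric(r$counts),
                numeric(npix[1]^2)))
  labs <- vapply(seq_along(rasters), function(i) {
    if (is.null(rasters[[i]]$label)) sprintf("run%d", i) else
      as.character(rasters[[i]]$label)
  }, character(1))
  rownames(m) <- labs
  keep <- which(colSums(m) > 0)
  m <- m[, keep, drop = FALSE]
  attr(m, "kept_pixels") <- keep
  m
}

#' Principal component scores of run fingerprints
#'
#' Mean-centers the pixel columns (no variance scaling: all entries share
#' the normalized-count scale) and computes a singular value decomposition,
#' returning the scores of the leading components and the fraction of
#' variance each explains. Runs of models with different internal structure
#' separate along the leading components, while variants of one model under
#' different forcing scenarios stay close together.
#'
#' @param m Matrix from [assemble_count_matrix()] (runs x pixels).
#' @param n_components Number of components to keep.
#' @return An object of class `structure_scores`: `labels`, `scores`
#'   (runs x components), `explained_variance`, `kept_pixels`.
#' @export
pca_scores <- function(m, n_components = 2L) {
  n_components <- as.integer(n_components)
  if (nrow(m) < 2L) stop("need at least 2 runs")
  if (n_components > min(nrow(m) - 1L, ncol(m)))
    stop("n_components exceeds min(runs - 1, pixels)")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    labels = rownames(m),
    scores = pc$x[, seq_len(n_components), drop = FALSE],
    explained_variance = ev[seq_len(n_components)],
    kept_pixels = attr(m, "kept_pixels")
  ), class = "structure_scores")
}

#' @export
print.structure_scores <- function(x, ...) {
  cat(sprintf("<structure_scores> %d runs, %d components (%.1f%% variance in PC1)\n",
              length(x$labels), ncol(x$scores), 100 * x$explained_variance[1]))
  invisible(x)
}

#' Per-window plane rasters of a gridded run
#'
#' Slices the time axis of a gridded field into windows of `window_length`
#' steps advanced by `stride`, computes cell-wise quantifier points inside
#' each window, and rasterizes each window's point cloud. This turns one
#' long simulation into a sequence of fingerprints (e.g. 30-year windows
#' every 10 years of a monthly run), the unit of the structure PCA.
#'
#' @param grid A [gridded_field].
#' @param window_length Window length in time steps.
#' @param stride Step between window starts, in time steps.
#' @param config An [ordinal_config].
#' @param plane `"HC"` or `"HF"`.
#' @param npix Raster resolution.
#' @param label Run identifier prefixed to each window label.
#' @param min_valid_fraction Passed to [itq_map()].
#' @return List of [plane_raster]s, labelled `"<label>@<start>"`.
#' @export
windowed_runs <- function(grid, window_length, stride,
                          config = ordinal_config(), plane = c("HC", "HF"),
                          npix = 25L, label = "run",
                          min_valid_fraction = 0.9) {
  stopifnot(inherits(grid, "gridded_field"))
  plane <- match.arg(plane)
  nt <- dim(grid$values)[1]
  window_length <- as.integer(window_length); stride <- as.integer(stride)
  if (window_length < 1L || window_length > nt)
    stop("window_length must lie in 1..time length")
  if (stride < 1L) stop("stride must be >= 1")
  starts <- seq(1L, nt - window_length + 1L, by = stride)
  lapply(starts, function(s) {
    sub <- gridded_field(grid$values[s:(s + window_length - 1L), , , drop = FALSE],
                         time = grid$time[s:(s + window_length - 1L)],
                         lat = grid$lat, lon = grid$lon)
    maps <- itq_map(sub, config, min_valid_fraction)
    y <- if (plane == "HC") maps$C else maps$F
    pts <- cbind(as.numeric(maps$H), as.numeric(y))
    rasterize_plane(pts, plane = plane, npix = npix,
                    label = sprintf("%s@%d", label, s))
  })
}
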