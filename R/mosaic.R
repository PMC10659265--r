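#' Merge oversplit units
#'
#' When spike sorting splits one physical cell into several units, the
#' cell's dendritic amplitude profile is recovered as the elementwise
#' maximum of the dendritic amplitudes over the oversplit units.
#'
#' @param fits list of `ei_decomposition` fits (or numeric amplitude
#'   vectors) for the oversplit units of one cell
#' @return length-N merged dendritic amplitude vector
#' @export
merge_oversplits <- function(fits) {
  amps <- lapply(fits, function(f) {
    if (inherits(f, "ei_decomposition")) f$amplitudes[2, ] else as.numeric(f)
  })
  do.call(pmax, amps)
}

#' Rasterize and blur a dendritic amplitude profile
#'
#' Deposits per-electrode dendritic amplitudes onto the nearest points of a
#' regular grid over the array bounding box (padded by two blur SDs),
#' convolves with a 2D Gaussian of standard deviation `sigma_um` (default
#' 54 um), and normalizes the surface by its maximum so amplitudes are
#' equalized between cells.
#'
#' @param amplitudes length-N dendritic amplitude vector
#' @param array the [electrode_array()]
#' @param grid_spacing raster pixel size in um (default 6)
#' @param sigma_um Gaussian blur SD in um (default 54)
#' @param cell_id optional identifier stored with the raster
#' @return a `dendritic_field_raster`: list with `grid` (nx x ny matrix in
#'   `[0, 1]`), `xs`, `ys` (pixel-center coordinates in um),
#'   `grid_spacing`, `cell_id`
#' @export
rasterize_and_blur <- function(amplitudes, array, grid_spacing = 6,
                               sigma_um = 54, cell_id = NULL) {
  if (all(amplitudes == 0)) stop("all-zero dendritic amplitudes")
  pos <- array$positions
  pad <- 2 * sigma_um
  xs <- seq(min(pos[, 1]) - pad, max(pos[, 1]) + pad, by = grid_spacing)
  ys <- seq(min(pos[, 2]) - pad, max(pos[, 2]) + pad, by = grid_spacing)
  G <- redeposit_and_blur(pos, amplitudes, xs, ys, grid_spacing, sigma_um)
  structure(list(grid = G, xs = xs, ys = ys,
                 grid_spacing = grid_spacing, cell_id = cell_id,
                 positions = pos, amplitudes = as.numeric(amplitudes),
                 sigma_um = sigma_um),
            class = "dendritic_field_raster")
}

# separable Gaussian convolution with a truncated (4 sigma) kernel;
# mass-preserving for interior sources (kernel normalized to sum 1).
# The banded convolution matrices are cached (the rotation null re-blurs
# thousands of rasters on the same grid).
.conv_cache <- new.env(parent = emptyenv())

conv_mat_cached <- function(n, sigma_px) {
  key <- sprintf("%d_%.8g", n, sigma_px)
  M <- .conv_cache[[key]]
  if (!is.null(M)) return(M)
  half <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-half):half)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (o in (-half):half) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    M[cbind(i[ok], j[ok])] <- M[cbind(i[ok], j[ok])] + k[o + half + 1]
  }
  .conv_cache[[key]] <- M
  M
}

gaussian_blur <- function(G, sigma_px) {
  conv_mat_cached(nrow(G), sigma_px) %*% G %*%
    t(conv_mat_cached(ncol(G), sigma_px))
}

#' Uniformity index
#'
#' Fraction of the valid recording area contained within exactly one of
#' the supplied binary contour masks.
#'
#' @param masks list of logical matrices on a common grid
#' @param valid_mask logical matrix marking the recording area (default:
#'   everything)
#' @return scalar in `[0, 1]`
#' @export
uniformity_index <- function(masks, valid_mask = NULL) {
  counts <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (is.null(valid_mask)) valid_mask <- array(TRUE, dim(counts))
  sum(counts == 1L & valid_mask) / sum(valid_mask)
}

#' Valid-area mask for a raster grid
#'
#' Marks raster pixels inside the convex hull of the electrode positions
#' (the MEA recording area).
#'
#' @param raster a [rasterize_and_blur()] raster (supplies the grid)
#' @param array the [electrode_array()]
#' @return logical matrix
#' @export
mea_valid_mask <- function(raster, array) {
  hull <- array$positions[grDevices::chull(array$positions), , drop = FALSE]
  nx <- length(raster$xs); ny <- length(raster$ys)
  px <- rep(raster$xs, times = ny)
  py <- rep(raster$ys, each = nx)
  inside <- rep(TRUE, length(px))
  nh <- nrow(hull)
  # hull from chull() is clockwise; points must lie on the same side of
  # every edge
  for (i in seq_len(nh)) {
    a <- hull[i, ]; b <- hull[if (i == nh) 1L else i + 1L, ]
    cross <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & cross <= 1e-9
  }
  matrix(inside, nx, ny)
}

#' Maximum-tiling contours
#'
#' Selects the single shared threshold level (over all cells of a type)
#' that maximizes the uniformity index of the thresholded, max-normalized
#' dendritic-field surfaces; ties are broken toward the lower threshold.
#' Contour masks are `grid >= threshold`.
#'
#' @param rasters list of [rasterize_and_blur()] rasters on a common grid
#' @param threshold_grid candidate levels in (0, 1) (default 99 uniform
#'   levels)
#' @param valid_mask optional logical matrix (e.g. [mea_valid_mask()])
#' @return a `mosaic_result`: list with `threshold`, `masks`,
#'   `uniformity_index`, `ui_by_threshold`, `valid_mask`
#' @export
max_tiling_contours <- function(rasters, threshold_grid = seq(0.01, 0.99, by = 0.01),
                                valid_mask = NULL) {
  if (length(rasters) < 1L) stop("need at least one raster")
  grids <- lapply(rasters, function(r) if (is.matrix(r)) r else r$grid)
  dm <- dim(grids[[1]])
  if (!all(vapply(grids, function(g) identical(dim(g), dm), logical(1)))) {
    stop("rasters must share a common grid")
  }
  if (is.null(valid_mask)) valid_mask <- array(TRUE, dm)
  nvalid <- sum(valid_mask)
  vals <- vapply(grids, function(g) g[valid_mask], numeric(nvalid))
  # a pixel is covered by exactly one contour at level t iff its largest
  # cell value is >= t and its second largest is < t
  if (ncol(vals) == 1L) {
    m1 <- vals[, 1]; m2 <- rep(-Inf, nvalid)
  } else {
    m1 <- do.call(pmax, asplit(vals, 2))
    vals2 <- vals
    vals2[cbind(seq_len(nvalid), max.col(vals, ties.method = "first"))] <- -Inf
    m2 <- do.call(pmax, asplit(vals2, 2))
  }
  ui <- vapply(threshold_grid, function(th) sum(m1 >= th & m2 < th) / nvalid,
               numeric(1))
  best <- which.max(ui)  # which.max returns the first (lowest) maximizer
  th <- threshold_grid[best]
  masks <- lapply(grids, function(g) g >= th)
  structure(list(threshold = th, masks = masks,
                 uniformity_index = ui[best], ui_by_threshold = ui,
                 valid_mask = valid_mask),
            class = "mosaic_result")
}

#' @export
print.mosaic_result <- function(x, ...) {
  cat(sprintf("<mosaic_result> %d cells, threshold %.2f, uniformity index %.4f\n",
              length(x$masks), x$threshold, x$uniformity_index))
  invisible(x)
}

# rotate a raster grid about a pivot (grid units) by angle, bilinear
# interpolation, zeros outside
rotate_raster <- function(G, angle, pivot) {
  nx <- nrow(G); ny <- ncol(G)
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  ca <- cos(-angle); sa <- sin(-angle)
  dx <- ix - pivot[1]; dy <- iy - pivot[2]
  sx <- pivot[1] + ca * dx - sa * dy
  sy <- pivot[2] + sa * dx + ca * dy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- function(xi, yi) {
    ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
    v <- numeric(length(xi))
    v[ok] <- G[cbind(xi[ok], yi[ok])]
    v
  }
  out <- (1 - fx) * (1 - fy) * val(x0, y0) +
    fx * (1 - fy) * val(x0 + 1, y0) +
    (1 - fx) * fy * val(x0, y0 + 1) +
    fx * fy * val(x0 + 1, y0 + 1)
  matrix(out, nx, ny)
}

raster_centroid <- function(G) {
  w <- sum(G)
  c(sum(row(G) * G), sum(col(G) * G)) / w
}

#' Rotation null test for mosaic coordination
#'
#' Tests whether the observed tiling of dendritic-field contours exceeds
#' chance by comparing the observed uniformity index against a null
#' distribution built by independently rotating each cell's field about
#' its amplitude centroid by a uniform random angle and recontouring
#' (default N = 250 null draws). The p-value is the fraction of null
#' uniformity indices strictly greater than the observed one; with N null
#' draws the smallest resolvable nonzero p is 1/N, so a reported 0 means
#' p < 1/N.
#'
#' When the rasters carry their source deposits ([rasterize_and_blur()]
#' output), rotation is performed exactly by rotating the electrode
#' amplitude deposits about their centroid and re-blurring — the Gaussian
#' blur is isotropic, so it commutes with rotation and the null draws pass
#' through exactly the same deposit-snap-blur pipeline as the observed
#' field. (Rotating the blurred surface by interpolation instead smooths
#' the null draws slightly but not the observed surface, which measurably
#' biases the null; plain grids without source information fall back to
#' bilinear rotation.)
#'
#' @param rasters list of rasters on a common grid
#' @param n_null number of null draws (default 250)
#' @param threshold_grid forwarded to [max_tiling_contours()]
#' @param valid_mask forwarded to [max_tiling_contours()]
#' @param seed integer seed (deterministic null distribution)
#' @return list with `observed_ui`, `null_uis`, `p_value`, `p_upper_bound`
#'   (`(#exceed + 1) / (n_null + 1)`), `threshold`
#' @export
rotation_null_test <- function(rasters, n_null = 250L,
                               threshold_grid = seq(0.01, 0.99, by = 0.01),
                               valid_mask = NULL, seed = 0L) {
  obs <- max_tiling_contours(rasters, threshold_grid, valid_mask)
  exact <- all(vapply(rasters, function(r) !is.matrix(r) &&
                        !is.null(r$positions), logical(1)))
  if (exact) {
    cents <- lapply(rasters, function(r) {
      colSums(r$positions * r$amplitudes) / sum(r$amplitudes)
    })
  } else {
    grids <- lapply(rasters, function(r) if (is.matrix(r)) r else r$grid)
    cents <- lapply(grids, raster_centroid)
  }
  rot_one <- function(i, angle) {
    if (exact) {
      r <- rasters[[i]]
      ca <- cos(angle); sa <- sin(angle)
      Rm <- matrix(c(ca, sa, -sa, ca), 2, 2)
      pos <- t(Rm %*% (t(r$positions) - cents[[i]]) + cents[[i]])
      redeposit_and_blur(pos, r$amplitudes, r$xs, r$ys, r$grid_spacing,
                         r$sigma_um)
    } else {
      g <- rotate_raster(grids[[i]], angle, cents[[i]])
      m <- max(g)
      if (m > 0) g / m else g
    }
  }
  null_uis <- withr_seed(seed, {
    vapply(seq_len(n_null), function(b) {
      rot <- lapply(seq_along(rasters), function(i)
        rot_one(i, runif(1, 0, 2 * pi)))
      max_tiling_contours(rot, threshold_grid, valid_mask)$uniformity_index
    }, numeric(1))
  })
  p <- mean(null_uis > obs$uniformity_index)
  list(observed_ui = obs$uniformity_index, null_uis = null_uis,
       p_value = p, p_upper_bound = (sum(null_uis > obs$uniformity_index) + 1) /
         (n_null + 1),
       threshold = obs$threshold)
}

# deposit amplitudes at the nearest grid points of an existing raster grid,
# blur and max-normalize (shared by rasterize_and_blur and the exact
# rotation null); deposits falling outside the grid are discarded
redeposit_and_blur <- function(pos, amplitudes, xs, ys, grid_spacing,
                               sigma_um) {
  G <- matrix(0, length(xs), length(ys))
  ix <- round((pos[, 1] - xs[1]) / grid_spacing) + 1
  iy <- round((pos[, 2] - ys[1]) / grid_spacing) + 1
  ok <- ix >= 1 & ix <= length(xs) & iy >= 1 & iy <= length(ys)
  for (e in which(ok)) {
    G[ix[e], iy[e]] <- G[ix[e], iy[e]] + amplitudes[e]
  }
  G <- gaussian_blur(G, sigma_um / grid_spacing)
  G / max(G)
}

#' Export mosaic contours as GeoJSON
#'
#' Writes each cell's contour mask boundary as a GeoJSON MultiPolygon of
#' pixel squares in electrode coordinates (um). Simple pixel-outline
#' polygons; adequate for interchange and plotting.
#'
#' @param mosaic a [max_tiling_contours()] result
#' @param rasters the rasters the mosaic was computed from (for coordinates)
#' @param path output file
#' @export
write_mosaic_geojson <- function(mosaic, rasters, path) {
  feats <- lapply(seq_along(mosaic$masks), function(i) {
    r <- rasters[[i]]
    m <- mosaic$masks[[i]]
    idx <- which(m, arr.ind = TRUE)
    h <- r$grid_spacing / 2
    polys <- lapply(seq_len(nrow(idx)), function(j) {
      cx <- r$xs[idx[j, 1]]; cy <- r$ys[idx[j, 2]]
      list(list(c(cx - h, cy - h), c(cx + h, cy - h), c(cx + h, cy + h),
                c(cx - h, cy + h), c(cx - h, cy - h)))
    })
    list(type = "Feature",
         properties = list(cell_id = r$cell_id %||% i),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
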