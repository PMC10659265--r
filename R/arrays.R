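#' Electrode array geometry
#'
#' Constructs an electrode-array object holding electrode positions (in
#' micrometers) and the lattice pitch. Positions are re-centered so the
#' origin is at the array centroid, which keeps downstream coordinate
#' transforms well-conditioned; no community standard fixes an origin.
#'
#' @param positions N x 2 numeric matrix of (x, y) electrode coordinates, um
#' @param pitch lattice pitch in um
#' @param layout_tag one of `"hex519_30um"`, `"rect512_60um"`, `"custom"`
#' @param recenter re-center coordinates at the centroid (default TRUE)
#' @return an object of class `electrode_array` with fields `positions`,
#'   `pitch`, `layout_tag`, `n`
#' @export
electrode_array <- function(positions, pitch,
                            layout_tag = c("custom", "hex519_30um", "rect512_60um"),
                            recenter = TRUE) {
  layout_tag <- match.arg(layout_tag)
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop("positions must be an N x 2 matrix")
  if (nrow(positions) < 7L) stop("an electrode array needs at least 7 electrodes")
  if (anyDuplicated(round(positions, 9)) > 0L) stop("electrode positions must be unique")
  stopifnot_finite(positions, "electrode positions")
  if (recenter) positions <- sweep(positions, 2, colMeans(positions))
  structure(
    list(positions = unname(positions), pitch = pitch,
         layout_tag = layout_tag, n = nrow(positions)),
    class = "electrode_array"
  )
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array> %d electrodes, pitch %g um, layout %s\n",
              x$n, x$pitch, x$layout_tag))
  invisible(x)
}

#' Hexagonal electrode array
#'
#' Builds a hexagonal lattice of electrodes: `n_rings` full rings around a
#' center electrode (so 1 + 3 r (r+1) electrodes). `n_rings = 13` with pitch
#' 30 um gives the 519-electrode / 30 um layout used for dense retinal
#' recordings; small ring counts are convenient for simulation and testing.
#'
#' @param n_rings number of complete rings around the center electrode
#' @param pitch electrode spacing in um (default 30)
#' @return an `electrode_array`
#' @export
hex_array <- function(n_rings = 4, pitch = 30) {
  # axial hex coordinates -> cartesian
  pts <- list(c(0, 0))
  for (q in -n_rings:n_rings) {
    for (r in max(-n_rings, -q - n_rings):min(n_rings, -q + n_rings)) {
      if (q == 0 && r == 0) next
      pts[[length(pts) + 1L]] <- c(q, r)
    }
  }
  ax <- do.call(rbind, pts)
  xy <- cbind(pitch * (ax[, 1] + ax[, 2] / 2), pitch * ax[, 2] * sqrt(3) / 2)
  n <- nrow(xy)
  tag <- if (n == 519L && pitch == 30) "hex519_30um" else "custom"
  electrode_array(xy, pitch, tag)
}

#' Rectangular electrode array
#'
#' Builds a rectangular lattice. `nx = 32, ny = 16, pitch = 60` gives the
#' 512-electrode / 60 um layout covering roughly a 1 x 2 mm area.
#'
#' @param nx,ny electrodes per row / column
#' @param pitch electrode spacing in um (default 60)
#' @return an `electrode_array`
#' @export
rect_array <- function(nx = 8, ny = 8, pitch = 60) {
  xy <- as.matrix(expand.grid(x = (0:(nx - 1)) * pitch, y = (0:(ny - 1)) * pitch))
  tag <- if (nx * ny == 512L && pitch == 60) "rect512_60um" else "custom"
  electrode_array(xy, pitch, tag)
}

#' Nearest-neighbor electrodes
#'
#' Indices of the `k` electrodes nearest to electrode `e` by Euclidean
#' distance, excluding `e` itself. Ties are broken by index order. On an
#' interior electrode of a hexagonal lattice with `k = 6` this returns the
#' six lattice neighbors at distance = pitch; at edges and corners the
#' nearest available electrodes are returned even if farther than the pitch.
#'
#' @param array an `electrode_array`
#' @param e electrode index (1-based)
#' @param k number of neighbors to return (`k < N`)
#' @return integer vector of `k` electrode indices
#' @export
neighbor_indices <- function(array, e, k = 6L) {
  if (k >= array$n) stop("k must be smaller than the number of electrodes")
  d <- sqrt(colSums((t(array$positions) - array$positions[e, ])^2))
  d[e] <- Inf
  ord <- order(d, seq_along(d))
  ord[seq_len(k)]
}

#' Read an electrode map from CSV
#'
#' Reads the plain-text electrode-map dialect with columns
#' `electrode_id,x_um,y_um` (ordered by `electrode_id`).
#'
#' @param path CSV file path
#' @param pitch lattice pitch in um; if `NULL`, estimated as the minimum
#'   inter-electrode distance
#' @return an `electrode_array`
#' @export
read_electrode_map <- function(path, pitch = NULL) {
  df <- read.csv(path)
  need <- c("electrode_id", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("electrode map must have columns electrode_id,x_um,y_um")
  }
  df <- df[order(df$electrode_id), ]
  xy <- cbind(df$x_um, df$y_um)
  if (is.null(pitch)) pitch <- min(stats::dist(xy))
  electrode_array(xy, pitch, "custom")
}

#' Write an electrode map to CSV
#'
#' @param array an `electrode_array`
#' @param path output CSV path
#' @export
write_electrode_map <- function(array, path) {
  df <- data.frame(electrode_id = seq_len(array$n),
                   x_um = array$positions[, 1], y_um = array$positions[, 2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
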