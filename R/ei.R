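#' Electrical image container
#'
#' An electrical image (EI) is the mean spatiotemporal voltage footprint of a
#' cell's spikes across all electrodes of a dense array: a T x N matrix of
#' mean spike-triggered voltages (uV), where T spans a window around the
#' spike time and N is the number of electrodes. The default window follows
#' the standard convention for dense retinal MEA recordings: 3 ms (60
#' samples) before to 6 ms (120 samples) after the spike at 20 kHz, so
#' T = 180 with the spike aligned at sample `pre_samples`.
#'
#' @param data T x N numeric matrix of voltages (uV)
#' @param array an [electrode_array()] with N electrodes
#' @param sampling_rate sampling rate in Hz (default 20000)
#' @param pre_samples samples before the spike time (default 60)
#' @param n_spikes number of spikes averaged to form the EI
#' @return an object of class `electrical_image`
#' @export
electrical_image <- function(data, array, sampling_rate = 20000,
                             pre_samples = 60L, n_spikes = NA_integer_) {
  data <- as.matrix(data)
  if (!inherits(array, "electrode_array")) stop("array must be an electrode_array")
  if (ncol(data) != array$n) {
    stop(sprintf("EI has %d columns but the array has %d electrodes",
                 ncol(data), array$n))
  }
  stopifnot_finite(data, "EI data")
  if (pre_samples >= nrow(data)) stop("pre_samples must be smaller than T")
  structure(
    list(data = unname(data), array = array, sampling_rate = sampling_rate,
         pre_samples = as.integer(pre_samples), n_spikes = n_spikes),
    class = "electrical_image"
  )
}

#' @export
print.electrical_image <- function(x, ...) {
  cat(sprintf(
    "<electrical_image> T=%d samples x N=%d electrodes @ %g kHz (pre=%d, n_spikes=%s)\n",
    nrow(x$data), ncol(x$data), x$sampling_rate / 1000, x$pre_samples,
    ifelse(is.na(x$n_spikes), "?", x$n_spikes)))
  cat(sprintf("  peak |V| = %.2f uV\n", max(abs(x$data))))
  invisible(x)
}

#' Spike train container
#'
#' Holds sorted spike times (sample indices into a raw recording) for one
#' unit, with identifiers for the unit and the preparation it came from.
#'
#' @param spike_times strictly increasing nonnegative sample indices
#' @param unit_id,preparation_id identifiers
#' @return an object of class `spike_train`
#' @export
spike_train <- function(spike_times, unit_id = "unit", preparation_id = "prep") {
  spike_times <- as.numeric(spike_times)
  if (any(spike_times < 0)) stop("spike times must be nonnegative")
  if (is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike times must be strictly increasing")
  }
  structure(list(spike_times = spike_times, unit_id = unit_id,
                 preparation_id = preparation_id),
            class = "spike_train")
}

#' Compute an electrical image from raw traces and spike times
#'
#' Crops a window of `pre` samples before to `post` samples after each spike
#' time from the raw voltage traces and averages the windows. Spikes whose
#' windows overrun the recording boundaries are dropped rather than
#' zero-padded, since padding would bias the mean.
#'
#' @param raw T_rec x N matrix of raw voltages (uV)
#' @param spikes a [spike_train()]
#' @param array an [electrode_array()]
#' @param pre,post window extent in samples (defaults 60 / 120)
#' @param sampling_rate sampling rate in Hz
#' @return an [electrical_image()] with `n_spikes` = number of retained spikes
#' @export
compute_ei <- function(raw, spikes, array, pre = 60L, post = 120L,
                       sampling_rate = 20000) {
  raw <- as.matrix(raw)
  t_rec <- nrow(raw)
  st <- spikes$spike_times
  keep <- st - pre >= 0 & st + post <= t_rec
  st <- st[keep]
  if (length(st) == 0L) stop("empty EI: no spike windows fit inside the recording")
  T <- pre + post
  acc <- matrix(0, T, ncol(raw))
  for (t0 in st) {
    acc <- acc + raw[(t0 - pre + 1L):(t0 + post), , drop = FALSE]
  }
  electrical_image(acc / length(st), array, sampling_rate, pre,
                   n_spikes = length(st))
}

#' Subsample a spike train
#'
#' Uniform random subset of `k` spikes without replacement, re-sorted.
#' Deterministic given `seed`. Used to emulate shorter recordings when
#' probing the sensitivity of downstream analyses to EI signal-to-noise
#' ratio (EIs from 100 / 1000 / 10000 spikes).
#'
#' @param spikes a [spike_train()]
#' @param k number of spikes to keep (`k <=` available)
#' @param seed integer RNG seed
#' @return a [spike_train()]
#' @export
subsample_spikes <- function(spikes, k, seed = 0L) {
  n <- length(spikes$spike_times)
  if (k > n) stop("cannot subsample more spikes than available")
  keep <- withr_seed(seed, sample.int(n, k))
  spike_train(sort(spikes$spike_times[keep]), spikes$unit_id,
              spikes$preparation_id)
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read electrical images
#'
#' Plain-text (JSON) container for EIs, preserving voltages, electrode
#' geometry, sampling rate and counts bit-exactly on round trip. Layout
#' mirrors the field structure: `ei/data`, `ei/sampling_rate`,
#' `ei/pre_samples`, `ei/n_spikes`, `array/positions`, `array/pitch`,
#' `array/layout_tag`; multiple cells may be stored in one file under
#' named entries.
#'
#' @param ei an [electrical_image()] (or named list of them for multi-cell files)
#' @param path file path
#' @return `read_ei` returns an `electrical_image` (or named list);
#'   `write_ei` returns `path` invisibly
#' @export
write_ei <- function(ei, path) {
  ser1 <- function(e) {
    ei_fields <- list(data = e$data, sampling_rate = e$sampling_rate,
                      pre_samples = e$pre_samples)
    if (!is.na(e$n_spikes)) ei_fields$n_spikes <- e$n_spikes
    list(ei = ei_fields,
         array = list(positions = e$array$positions, pitch = e$array$pitch,
                      layout_tag = e$array$layout_tag))
  }
  obj <- if (inherits(ei, "electrical_image")) {
    list(format = "ei-json", version = 1L, cells = list(cell = ser1(ei)))
  } else {
    list(format = "ei-json", version = 1L, cells = lapply(ei, ser1))
  }
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ei
#' @export
read_ei <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$cells)) stop("not an EI container: missing 'cells'")
  de1 <- function(cell) {
    if (is.null(cell$array) || is.null(cell$array$positions)) {
      stop("EI container lacks electrode geometry")
    }
    if (is.null(cell$ei) || is.null(cell$ei$data)) stop("EI container lacks data")
    data <- as.matrix(cell$ei$data)
    pos <- as.matrix(cell$array$positions)
    if (ncol(data) != nrow(pos)) {
      stop("shape mismatch: EI columns do not match electrode positions")
    }
    arr <- electrode_array(pos, as.numeric(cell$array$pitch),
                           cell$array$layout_tag %||% "custom", recenter = FALSE)
    electrical_image(data, arr, as.numeric(cell$ei$sampling_rate),
                     as.integer(cell$ei$pre_samples),
                     as.integer(cell$ei$n_spikes %||% NA_integer_))
  }
  cells <- lapply(obj$cells, de1)
  if (length(cells) == 1L) cells[[1L]] else cells
}
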