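#' Stereotyped compartment basis waveforms
#'
#' Difference-of-Gaussians parameterizations of the three stereotyped
#' extracellular compartment waveforms: somatic (biphasic, strong fast
#' negative peak followed by a slower positive peak), dendritic (biphasic,
#' strong fast positive peak followed by a slower negative peak) and axonal
#' (triphasic: small positive, strong negative, positive lobe, the
#' signature of a traveling wave). Each template is normalized to unit peak
#' absolute amplitude, so fitted amplitudes carry the uV scale.
#'
#' @param sampling_rate sampling rate in Hz (default 20000)
#' @param T window length in samples (default 180)
#' @param pre samples before the spike time (default 60); lobes are
#'   centered near this index
#' @param time_scale dimensionless stretch applied to all lobe widths and
#'   latencies (per-preparation waveform time-scale variation)
#' @param morph optional list with `width` and `ratio` length-3 multipliers
#'   (per compartment) modifying lobe widths and secondary-lobe amplitudes;
#'   used to emulate cell-type-dependent waveform shape differences
#' @return C = 3 x T matrix (rows: soma, dendrite, axon)
#' @export
stereotyped_templates <- function(sampling_rate = 20000, T = 180L, pre = 60L,
                                  time_scale = 1, morph = NULL) {
  w <- morph$width %||% c(1, 1, 1)
  r <- morph$ratio %||% c(1, 1, 1)
  tt <- ((seq_len(T) - 1) - pre) / sampling_rate * 1000  # ms rel. spike
  g <- function(mu, sig) exp(-(tt - mu * time_scale)^2 / (2 * (sig * time_scale)^2))
  # dendritic return currents are slower and broader than the fast somatic
  # sodium spike, and the axonal spike is narrow with pronounced flanking
  # lobes; the lobe widths below keep the three shapes well separated
  soma <- -1.00 * g(0.00, 0.12 * w[1]) + 0.45 * r[1] * g(0.50, 0.35 * w[1])
  dend <- +0.85 * g(0.25, 0.32 * w[2]) - 0.35 * r[2] * g(1.30, 0.75 * w[2])
  axon <- +0.45 * r[3] * g(-0.35, 0.14 * w[3]) - 1.00 * g(0.00, 0.08 * w[3]) +
    0.60 * r[3] * g(0.30, 0.18 * w[3])
  B <- rbind(soma, dend, axon)
  unname(B / apply(abs(B), 1, max))
}

#' Synthesize a ground-truth cell
#'
#' Builds a cell with known compartment geometry and per-electrode
#' amplitudes/shifts on a given array. The spatial amplitude kernels are
#' phenomenological rather than biophysical: a Gaussian around the soma
#' for the somatic compartment, an (optionally anisotropic) Gaussian disk
#' around the dendritic-field center for the dendritic compartment, and
#' exponential lateral decay from the axon polyline for the axonal
#' compartment. Axonal shifts grow with arc length along the axon at the
#' conduction velocity; somatic and dendritic shifts default to 0 with
#' optional +/- 1 sample jitter.
#'
#' @param array an [electrode_array()]
#' @param cell_type one of `"ON_parasol"`, `"OFF_parasol"`, `"ON_midget"`,
#'   `"OFF_midget"`, `"OFF_SM"`, `"broad_thorny"`
#' @param soma_xy soma position (um); random near the array center if NULL
#' @param dend_center dendritic-field center (um); defaults to the soma
#'   plus `dend_offset`
#' @param dend_offset offset applied to the soma to place the dendritic
#'   center when `dend_center` is NULL
#' @param dendritic_radius dendritic-field Gaussian radius (um)
#' @param elongation anisotropy of the dendritic field (1 = isotropic;
#'   radii scaled by `elongation` / `1/elongation` along the orientation)
#' @param orientation dendritic-field orientation (radians)
#' @param axon_angle axon direction (radians)
#' @param conduction_velocity axonal conduction velocity (m/s, default 1)
#' @param amp_soma,amp_dend,amp_axon peak compartment amplitudes (uV)
#' @param templates basis waveforms (default [stereotyped_templates()])
#' @param sampling_rate,T,pre EI window parameters
#' @param shift_jitter if TRUE, somatic/dendritic shifts get +/- 1 sample jitter
#' @param rf_center_xy,rf_sigma receptive-field center and radius in
#'   stimulus-pixel units (defaults derived from the dendritic field)
#' @param seed integer seed for the randomized defaults
#' @return an object of class `gt_cell` holding geometry, `templates`,
#'   `true_amplitudes` (3 x N), `true_shifts` (3 x N) and receptive-field
#'   ground truth
#' @export
synthesize_cell <- function(array, cell_type = "ON_parasol", soma_xy = NULL,
                            dend_center = NULL, dend_offset = NULL,
                            dendritic_radius = 60, elongation = 1,
                            orientation = 0, axon_angle = NULL,
                            conduction_velocity = 1, amp_soma = 200,
                            amp_dend = 80, amp_axon = 80,
                            templates = NULL, sampling_rate = 20000,
                            T = 180L, pre = 60L, shift_jitter = FALSE,
                            rf_center_xy = NULL, rf_sigma = NULL, seed = 0L) {
  withr_seed(seed, {
    pos <- array$positions
    span <- apply(pos, 2, function(v) diff(range(v)))
    if (is.null(soma_xy)) {
      soma_xy <- colMeans(pos) + runif(2, -0.15, 0.15) * span
    }
    if (is.null(dend_offset)) dend_offset <- runif(2, -15, 15)
    if (is.null(dend_center)) dend_center <- soma_xy + dend_offset
    if (is.null(axon_angle)) axon_angle <- runif(1, 0, 2 * pi)
    if (is.null(templates)) {
      templates <- stereotyped_templates(sampling_rate, T, pre)
    }
    path_len <- 1.5 * sqrt(sum(span^2)) + 100
    s_grid <- seq(0, path_len, by = 5)
    axon_path <- cbind(soma_xy[1] + s_grid * cos(axon_angle),
                       soma_xy[2] + s_grid * sin(axon_angle))

    # somatic kernel
    d_soma <- sqrt(colSums((t(pos) - soma_xy)^2))
    a_soma <- amp_soma * exp(-d_soma^2 / (2 * 35^2))

    # dendritic kernel (anisotropic Gaussian disk)
    R <- matrix(c(cos(orientation), sin(orientation),
                  -sin(orientation), cos(orientation)), 2, 2)
    q <- t(R %*% (t(pos) - dend_center))
    rad <- c(dendritic_radius * elongation, dendritic_radius / elongation)
    a_dend <- amp_dend * exp(-0.5 * ((q[, 1] / rad[1])^2 + (q[, 2] / rad[2])^2))

    # axonal kernel: project electrodes onto the axon ray
    rel <- t(pos) - soma_xy
    u <- c(cos(axon_angle), sin(axon_angle))
    s_proj <- pmax(0, pmin(path_len, colSums(rel * u)))
    lat <- sqrt(colSums((rel - outer(u, s_proj))^2))
    # the proximal axon (initial segment) contributes little extracellular
    # signal; the propagating axonal signal develops past ~120 um, which
    # also keeps the axonal and somatic contributions temporally distinct
    a_axon <- amp_axon * exp(-lat / 45) * as.numeric(s_proj > 120)

    # amplitudes far below the compartment peak carry no resolvable signal;
    # a hard support floor keeps the ground truth well-posed
    zap <- function(a) { a[a < 0.05 * max(a, 1e-12)] <- 0; a }
    A <- unname(rbind(zap(a_soma), zap(a_dend), zap(a_axon)))

    tau_axon <- as.integer(round(s_proj * 1e-6 / conduction_velocity * sampling_rate))
    tau_sd <- if (shift_jitter) {
      matrix(sample(-1:1, 2 * array$n, TRUE), 2, array$n)
    } else matrix(0L, 2, array$n)
    tau <- unname(rbind(tau_sd, tau_axon)) %% T
    tau[A == 0] <- 0L
    storage.mode(tau) <- "integer"

    if (is.null(rf_sigma)) rf_sigma <- dendritic_radius / 60
    if (is.null(rf_center_xy)) rf_center_xy <- dend_center / 60

    structure(
      list(cell_type = cell_type, soma_xy = soma_xy,
           dendritic_center_xy = dend_center,
           dendritic_radius = dendritic_radius, elongation = elongation,
           orientation = orientation, axon_path = axon_path,
           conduction_velocity = conduction_velocity,
           true_amplitudes = A, true_shifts = tau, templates = templates,
           sampling_rate = sampling_rate, T = as.integer(T),
           pre = as.integer(pre),
           rf_center_xy = rf_center_xy, rf_sigma = rf_sigma),
      class = "gt_cell"
    )
  })
}

#' Synthesize the EI of a ground-truth cell
#'
#' Forward model: the EI equals the shifted nonnegative superposition of
#' the cell's templates with its true amplitudes and shifts, plus i.i.d.
#' Gaussian noise per sample per electrode. With `noise_sd = 0` the EI is
#' exactly reconstructable from the ground truth. To emulate EIs averaged
#' over `n` spikes, scale a base noise SD by `1 / sqrt(n)`.
#'
#' @param cell a [synthesize_cell()] object
#' @param array the [electrode_array()] the cell was placed on
#' @param noise_sd additive noise SD in uV
#' @param seed integer seed (same seed, same EI)
#' @return an [electrical_image()]
#' @export
synthesize_cell_ei <- function(cell, array, noise_sd = 0, seed = 0L) {
  clean <- reconstruct_matrix(cell$templates, cell$true_amplitudes,
                              cell$true_shifts)
  noise <- if (noise_sd > 0) {
    withr_seed(seed, matrix(rnorm(length(clean), 0, noise_sd), nrow(clean)))
  } else 0
  electrical_image(clean + noise, array, cell$sampling_rate, cell$pre)
}

#' Parameter-recovery benchmark EI
#'
#' Synthesizes an EI from fully known ground truth with every compartment
#' substantially observable on every electrode: amplitudes drawn uniformly
#' from `amp_range` (uV), shifts uniform over the window, plus Gaussian
#' noise with SD `noise_frac` times the peak somatic amplitude. This is the
#' well-posed benchmark for testing the inverse solver itself (shift and
#' amplitude recovery); spatially realistic cells, where many electrodes
#' carry signal near or below the noise floor and recovery is inherently
#' ambiguous, come from [synthesize_cell()].
#'
#' @param array an [electrode_array()] (geometry is carried along but plays
#'   no role in the amplitudes)
#' @param T,pre,sampling_rate EI window parameters
#' @param amp_range amplitude range (uV)
#' @param noise_frac noise SD as a fraction of the peak somatic amplitude
#' @param templates basis waveforms (default [stereotyped_templates()])
#' @param seed integer seed
#' @return list with `ei` ([electrical_image()]), `amplitudes` (3 x N),
#'   `shifts` (3 x N), `templates`, `noise_sd`
#' @export
synthesize_recovery_ei <- function(array, T = 180L, pre = 60L,
                                   sampling_rate = 20000,
                                   amp_range = c(50, 200), noise_frac = 0.05,
                                   templates = NULL, seed = 0L) {
  if (is.null(templates)) templates <- stereotyped_templates(sampling_rate, T, pre)
  N <- array$n
  withr_seed(seed, {
    A <- matrix(runif(3 * N, amp_range[1], amp_range[2]), 3, N)
    tau <- matrix(sample(0:(T - 1), 3 * N, replace = TRUE), 3, N)
    noise_sd <- noise_frac * max(A[1, ])
    X <- reconstruct_matrix(templates, A, tau) +
      matrix(rnorm(T * N, 0, noise_sd), T, N)
    list(ei = electrical_image(X, array, sampling_rate, pre),
         amplitudes = A, shifts = tau, templates = templates,
         noise_sd = noise_sd)
  })
}

#' Synthesize a mosaic of cells of one type
#'
#' Places dendritic-field centers on a jittered hexagonal lattice covering
#' the array, optionally with anisotropic (elongated) dendritic profiles.
#' With `interdigitate = TRUE`, co-oriented elongated fields are packed on
#' a brick lattice (x-spacing stretched by the elongation, row spacing
#' compressed by it, alternate rows offset by half a period) so the fields
#' tile tightly — a positive control for coordination tests, since random
#' rotation destroys the packing. Otherwise orientations are independent
#' and uniform, the exchangeable case for the rotation null.
#'
#' @param array an [electrode_array()]
#' @param cell_type type label for all cells
#' @param spacing lattice spacing in um
#' @param jitter SD of isotropic Gaussian center jitter (um)
#' @param elongation dendritic-field anisotropy (1 = isotropic)
#' @param interdigitate alternate orientations by row (see above)
#' @param dendritic_radius field radius (um); defaults to `0.55 * spacing`
#' @param margin keep lattice centers within the electrode bounding box
#'   shrunk by this amount (um)
#' @param seed integer seed
#' @param ... forwarded to [synthesize_cell()]
#' @return list of `gt_cell` objects
#' @export
synthesize_mosaic <- function(array, cell_type = "OFF_SM", spacing = 120,
                              jitter = 0, elongation = 1,
                              interdigitate = FALSE, dendritic_radius = NULL,
                              margin = 0, seed = 0L, ...) {
  if (is.null(dendritic_radius)) dendritic_radius <- 0.55 * spacing
  pos <- array$positions
  xr <- range(pos[, 1]) + c(margin, -margin)
  yr <- range(pos[, 2]) + c(margin, -margin)
  sx <- if (interdigitate) spacing * elongation else spacing
  dy <- if (interdigitate) spacing / elongation else spacing * sqrt(3) / 2
  rows <- seq(yr[1], yr[2], by = dy)
  cells <- list()
  withr_seed(seed, {
    k <- 0L
    for (i in seq_along(rows)) {
      off <- if (i %% 2 == 0) sx / 2 else 0
      xs <- seq(xr[1] + off, xr[2], by = sx)
      for (x in xs) {
        k <- k + 1L
        ctr <- c(x, rows[i]) + if (jitter > 0) rnorm(2, 0, jitter) else c(0, 0)
        ori <- if (interdigitate) 0 else runif(1, 0, 2 * pi)
        cells[[k]] <- synthesize_cell(
          array, cell_type, soma_xy = ctr - c(10, 0), dend_center = ctr,
          dendritic_radius = dendritic_radius, elongation = elongation,
          orientation = ori, seed = seed * 10007L + k, ...)
      }
    }
  })
  cells
}

major_types <- c("ON_parasol", "OFF_parasol", "ON_midget", "OFF_midget")

#' Effect-size configuration for synthetic preparations
#'
#' Defaults emulate the separability structure reported for real
#' recordings: parasol cells have roughly twice the somatic and dendritic
#' amplitude norms of midget cells, ON cells have ~1.3x the norms of their
#' OFF counterparts, and cell types differ moderately in waveform shape
#' (lobe widths and secondary-lobe ratios), with per-preparation global
#' time-scale and gain variation on top. `morph_strength` and
#' `amp_strength` scale the type effects (0 = null model in which labels
#' carry no information).
#'
#' @param morph_strength scales waveform-shape type differences
#' @param amp_strength scales amplitude-norm type differences
#' @param prep_time_scale_sd lognormal SD of the per-preparation time scale
#' @param prep_gain_sd lognormal SD of the per-preparation gain
#' @param cell_waveform_noise per-sample waveform noise SD (units of peak)
#' @param cell_norm_sd lognormal SD of per-cell compartment norms
#' @param dend_offset_sd named vector: SD (um) of dendritic-center offsets
#'   from the soma, per type (midgets substantially more offset)
#' @return a list of effect parameters
#' @export
effect_config <- function(morph_strength = 1, amp_strength = 1,
                          prep_time_scale_sd = 0.06, prep_gain_sd = 0.2,
                          cell_waveform_noise = 0.08, cell_norm_sd = 0.3,
                          dend_offset_sd = c(ON_parasol = 15, OFF_parasol = 15,
                                             ON_midget = 45, OFF_midget = 45)) {
  list(
    morph_strength = morph_strength, amp_strength = amp_strength,
    prep_time_scale_sd = prep_time_scale_sd, prep_gain_sd = prep_gain_sd,
    cell_waveform_noise = cell_waveform_noise, cell_norm_sd = cell_norm_sd,
    dend_offset_sd = dend_offset_sd,
    type_amp = list(ON_parasol = c(2.6, 2.6, 1.25),
                    OFF_parasol = c(2.0, 2.0, 1.20),
                    ON_midget = c(1.3, 1.3, 1.05),
                    OFF_midget = c(1.0, 1.0, 1.00)),
    type_morph = list(ON_parasol = list(width = c(1.00, 1.00, 1.00),
                                        ratio = c(1.00, 1.00, 1.00)),
                      OFF_parasol = list(width = c(1.12, 1.10, 1.05),
                                         ratio = c(0.80, 0.85, 0.95)),
                      ON_midget = list(width = c(0.90, 0.92, 0.95),
                                       ratio = c(1.15, 1.10, 1.05)),
                      OFF_midget = list(width = c(1.00, 1.05, 1.00),
                                        ratio = c(0.70, 0.75, 0.90)))
  )
}

scale_effect <- function(mult, strength) exp(strength * log(mult))

type_templates <- function(type, time_scale, effect, sampling_rate = 20000,
                           T = 180L, pre = 60L) {
  m <- effect$type_morph[[type]]
  morph <- list(width = scale_effect(m$width, effect$morph_strength),
                ratio = scale_effect(m$ratio, effect$morph_strength))
  stereotyped_templates(sampling_rate, T, pre, time_scale, morph)
}

#' Synthesize a cohort of preparations
#'
#' Generates `n_preps` synthetic preparations, each containing cells of the
#' four major retinal ganglion cell types on a small array, with
#' type-dependent waveform morphs and amplitude scales, per-preparation
#' time-scale and gain variation, and type-dependent dendritic offsets.
#' The default cohort size of 29 preparations matches the scale at which
#' the downstream leave-one-out analyses are defined.
#'
#' @param n_preps number of preparations (default 29)
#' @param types cell types to include (default the four major types)
#' @param cells_per_type cells of each type per preparation (default 6)
#' @param effect an [effect_config()]
#' @param array electrode array shared by all preparations (default a small
#'   hexagonal array); per-cell EIs are only instantiated on demand
#' @param T,pre,sampling_rate EI window parameters
#' @param seed integer seed (the whole cohort is reproducible from it)
#' @return list of `synthetic_preparation` objects, each with `cells`,
#'   `array`, `time_scale`, `gain`, `prep_id`
#' @export
synthesize_preparation_set <- function(n_preps = 29L, types = major_types,
                                       cells_per_type = 6L,
                                       effect = effect_config(),
                                       array = NULL, T = 180L, pre = 60L,
                                       sampling_rate = 20000, seed = 0L) {
  if (is.null(array)) array <- hex_array(4, 60)
  preps <- vector("list", n_preps)
  for (p in seq_len(n_preps)) {
    pseed <- seed * 1000003L + p
    prep <- withr_seed(pseed, {
      time_scale <- exp(rnorm(1, 0, effect$prep_time_scale_sd))
      gain <- exp(rnorm(1, 0, effect$prep_gain_sd))
      axon_dir <- runif(1, 0, 2 * pi)
      cells <- list()
      k <- 0L
      for (ty in types) {
        amp <- scale_effect(effect$type_amp[[ty]], effect$amp_strength) * gain
        tmpl <- type_templates(ty, time_scale, effect, sampling_rate, T, pre)
        for (j in seq_len(cells_per_type)) {
          k <- k + 1L
          off_sd <- effect$dend_offset_sd[[ty]] %||% 20
          ang <- runif(1, 0, 2 * pi)
          off <- abs(rnorm(1, off_sd, off_sd / 4)) * c(cos(ang), sin(ang))
          # parasol dendritic trees span larger areas than midget trees;
          # the radius ratio scales with the amplitude effect strength so
          # a null configuration removes it too
          radius <- 40 * scale_effect(if (grepl("parasol", ty)) 75 / 40 else 1,
                                      effect$amp_strength)
          cells[[k]] <- synthesize_cell(
            array, ty, dend_offset = off,
            dendritic_radius = radius,
            axon_angle = axon_dir + rnorm(1, 0, 0.1),
            amp_soma = 200 * amp[1], amp_dend = 80 * amp[2],
            amp_axon = 60 * amp[3], templates = tmpl,
            sampling_rate = sampling_rate, T = T, pre = pre,
            seed = pseed * 131L + k)
        }
      }
      list(cells = cells, time_scale = time_scale, gain = gain)
    })
    preps[[p]] <- structure(
      list(cells = prep$cells, array = array, time_scale = prep$time_scale,
           gain = prep$gain, prep_id = sprintf("prep%02d", p), seed = pseed),
      class = "synthetic_preparation")
  }
  preps
}

#' Ground-truth typed records for a preparation cohort
#'
#' Emulates the per-cell output of the decomposition for every cell of a
#' cohort: the cell's (type-morphed, time-scaled) basis waveforms plus
#' additive measurement noise, and its compartment amplitude L2 norms with
#' lognormal per-cell variability. Used to exercise the featurization and
#' classification pipeline at cohort scale without refitting every cell;
#' the full EI -> decomposition -> features path is exercised separately by
#' [decompose_preparation()].
#'
#' @param preps a [synthesize_preparation_set()] cohort
#' @param effect the [effect_config()] used to build the cohort
#' @param seed integer seed for the measurement noise
#' @return a `typed_records` object: list with `waveforms` (list of 3 x T
#'   matrices), `norms` (n x 3), `label` (factor), `prep` (factor)
#' @export
typed_records <- function(preps, effect = effect_config(), seed = 0L) {
  wl <- list(); norms <- NULL; label <- character(0); prep <- character(0)
  k <- 0L
  for (p in seq_along(preps)) {
    for (cell in preps[[p]]$cells) {
      k <- k + 1L
      noise <- withr_seed(seed * 7919L + k, {
        matrix(rnorm(length(cell$templates), 0, effect$cell_waveform_noise),
               nrow(cell$templates))
      })
      wl[[k]] <- cell$templates + noise
      nrm <- sqrt(rowSums(cell$true_amplitudes^2))
      jit <- withr_seed(seed * 104729L + k, exp(rnorm(3, 0, effect$cell_norm_sd)))
      norms <- rbind(norms, nrm * jit)
      label <- c(label, cell$cell_type)
      prep <- c(prep, preps[[p]]$prep_id)
    }
  }
  structure(list(waveforms = wl, norms = unname(norms),
                 label = factor(label), prep = factor(prep)),
            class = "typed_records")
}

#' Decompose every cell of a preparation
#'
#' Runs the full pipeline for one preparation: synthesizes each cell's EI
#' at the given noise level, fits the decomposition, and assembles typed
#' records (fitted waveforms and fitted compartment amplitude norms). The
#' EI noise SD is `base_noise_sd / sqrt(n_spikes)`, emulating EIs averaged
#' over a given number of spikes.
#'
#' The waveform-shape prior uses the generic stereotyped templates shared
#' across all cells and preparations (estimating prior means from one
#' reference preparation would play the same role); using each cell's own
#' type-specific templates would leak type information into the fits.
#'
#' @param prep a `synthetic_preparation`
#' @param n_spikes effective spike count (scales down the noise)
#' @param base_noise_sd per-sample single-trace noise SD (uV)
#' @param search,max_iters,lambda_frac decomposition settings; the default
#'   search narrows the somatic/dendritic shift windows to small
#'   perisomatic lags and the axonal window to forward propagation delays
#' @param seed integer seed
#' @return a `typed_records` object for the preparation's cells
#' @export
decompose_preparation <- function(prep, n_spikes = 1000,
                                  base_noise_sd = 120,
                                  search = NULL, max_iters = 4L,
                                  lambda_frac = 0.05, seed = 0L) {
  noise_sd <- base_noise_sd / sqrt(n_spikes)
  wl <- list(); norms <- NULL; label <- character(0)
  c0 <- prep$cells[[1]]
  tmpl <- stereotyped_templates(c0$sampling_rate, c0$T, c0$pre)
  if (is.null(search)) {
    search <- shift_search(ranges = list(c(-4L, 4L), c(-4L, 4L), c(0L, 40L)))
  }
  for (k in seq_along(prep$cells)) {
    cell <- prep$cells[[k]]
    ei <- synthesize_cell_ei(cell, prep$array, noise_sd,
                             seed = seed * 271L + k)
    prior <- build_shape_prior(tmpl, cell$sampling_rate,
                               lambda_l = default_lambda_l(ei, lambda_frac),
                               lambda_p = 1)
    fit <- canonicalize_decomposition(
      fit_decomposition(ei, prior, search = search, max_iters = max_iters))
    wl[[k]] <- fit$waveforms
    norms <- rbind(norms, sqrt(rowSums(fit$amplitudes^2)))
    label <- c(label, cell$cell_type)
  }
  structure(list(waveforms = wl, norms = unname(norms),
                 label = factor(label),
                 prep = factor(rep(prep$prep_id, length(wl)))),
            class = "typed_records")
}

#' Concatenate typed records
#' @param ... `typed_records` objects
#' @return a single `typed_records`
#' @export
bind_records <- function(...) {
  rs <- list(...)
  if (length(rs) == 1L && is.list(rs[[1]]) && !inherits(rs[[1]], "typed_records"))
    rs <- rs[[1]]
  structure(list(
    waveforms = do.call(c, lapply(rs, `[[`, "waveforms")),
    norms = do.call(rbind, lapply(rs, `[[`, "norms")),
    label = factor(unlist(lapply(rs, function(r) as.character(r$label)))),
    prep = factor(unlist(lapply(rs, function(r) as.character(r$prep))))),
    class = "typed_records")
}

#' Synthesize a spike-triggered average
#'
#' Separable space-time STA: a 2D Gaussian intensity profile at the cell's
#' receptive-field center (stimulus-pixel units, pixel centers at integer
#' + 0.5) multiplied by a biphasic time course, plus i.i.d. Gaussian noise.
#' OFF-type cells get a sign-flipped profile.
#'
#' @param cell a `gt_cell` (uses `rf_center_xy` and `rf_sigma`)
#' @param nx,ny stimulus grid dimensions (pixels)
#' @param n_frames STA depth in frames
#' @param noise_sd additive noise SD (units of peak intensity)
#' @param seed integer seed
#' @return `nx x ny x n_frames` array
#' @export
synthesize_sta <- function(cell, nx = 40L, ny = 40L, n_frames = 25L,
                           noise_sd = 0, seed = 0L) {
  ctr <- cell$rf_center_xy
  px <- (seq_len(nx) - 0.5)
  py <- (seq_len(ny) - 0.5)
  spatial <- outer(exp(-(px - ctr[1])^2 / (2 * cell$rf_sigma^2)),
                   exp(-(py - ctr[2])^2 / (2 * cell$rf_sigma^2)))
  sign <- if (grepl("^OFF", cell$cell_type)) -1 else 1
  fr <- seq_len(n_frames)
  tc <- exp(-(fr - n_frames * 0.7)^2 / (2 * 2^2)) -
    0.45 * exp(-(fr - n_frames * 0.45)^2 / (2 * 3^2))
  sta <- outer(sign * spatial, tc)
  if (noise_sd > 0) {
    sta <- sta + withr_seed(seed, array(rnorm(length(sta), 0, noise_sd), dim(sta)))
  }
  sta
}
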