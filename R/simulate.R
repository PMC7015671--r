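#' Simple phase-contrast transfer function parameters
#'
#' A deliberately minimal CTF: defocus plus amplitude contrast, no
#' astigmatism or envelope, applied as a radial multiplier in Fourier space.
#' Synthetic data carries a known CTF, so estimation from micrographs is not
#' modelled.
#'
#' @param defocus_um Defocus in micrometres (positive = underfocus).
#' @param voltage_kV Acceleration voltage, kV.
#' @param amplitude_contrast Amplitude contrast fraction in `[0, 1]`.
#' @return A list of class `ctf_params`.
#' @export
ctf_params <- function(defocus_um = 1.8, voltage_kV = 300,
                       amplitude_contrast = 0.07) {
  structure(list(defocus_um = defocus_um, voltage_kV = voltage_kV,
                 amplitude_contrast = amplitude_contrast),
            class = "ctf_params")
}

# electron wavelength in Angstroms (relativistic)
electron_lambda_A <- function(voltage_kV) {
  v <- voltage_kV * 1e3
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

# radial CTF evaluated on the FFT frequency grid of an n x n image
ctf_image <- function(n, voxel_size_A, ctf) {
  f <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) / (n * voxel_size_A)
  s2 <- outer(f^2, f^2, "+")
  lambda <- electron_lambda_A(ctf$voltage_kV)
  chi <- pi * lambda * (ctf$defocus_um * 1e4) * s2
  a <- ctf$amplitude_contrast
  -(sqrt(1 - a^2) * sin(chi) + a * cos(chi))
}

apply_ctf <- function(img, voxel_size_A, ctf) {
  n <- nrow(img)
  Re(fft(fft(img) * ctf_image(n, voxel_size_A, ctf), inverse = TRUE)) / (n * n)
}

# footprint of the projected filament: pixels carrying appreciable signal
mt_footprint <- function(clean, frac = 0.02) {
  abs(clean) > frac * max(abs(clean))
}

#' Simulate a stack of microtubule segment images
#'
#' Generates overlapping segment projections of a decorated-microtubule
#' volume the way filaments are windowed from micrographs: per filament,
#' `floor((len - box) / spacing) + 1` segments spaced `spacing_A` apart
#' (default 80 Angstroms, about one dimer repeat). The in-plane view angle
#' (`rot`) advances with axial position according to the lattice one-start
#' twist/rise, filaments lie in the ice plane (`tilt` 90 degrees plus
#' optional jitter), an optional CTF is applied, and Gaussian white noise is
#' added to reach the requested signal-to-noise ratio measured inside the
#' projected filament footprint. All ground truth lands in the metadata.
#'
#' @param lattice A [lattice_spec()].
#' @param dens A [density_spec()].
#' @param n_filaments Number of filaments.
#' @param filament_len_A Filament length, Angstroms; must be at least the box
#'   extent.
#' @param spacing_A Segment spacing along the filament, Angstroms.
#' @param snr Signal-to-noise ratio (signal variance over noise variance in
#'   the filament footprint); `Inf` for noiseless.
#' @param ctf Optional [ctf_params()]; `NULL` to skip the CTF.
#' @param tilt_jitter_deg SD of tilt jitter about 90 degrees.
#' @param shift_jitter_A Half-range of the uniform true in-plane shifts.
#' @param seed Integer seed.
#' @param volume Optional prebuilt volume (a `density_map` from
#'   [build_volume()]); built from `lattice`/`dens` when missing.
#' @return A list of class `segment_stack`: `images` (n x n x n_seg array),
#'   `meta` (tibble, one row per segment), `voxel_size_A`, and the clean
#'   generating `volume`.
#' @export
simulate_segment_stack <- function(lattice, dens, n_filaments = 4,
                                   filament_len_A = 2000, spacing_A = 80,
                                   snr = Inf, ctf = NULL,
                                   tilt_jitter_deg = 0, shift_jitter_A = 0,
                                   seed = 1, volume = NULL) {
  if (!is.infinite(snr) && snr <= 0) abort("snr must be > 0 (or Inf)")
  if (is.null(volume)) volume <- build_volume(lattice, dens, seed = seed)
  n <- box_px(volume)
  box_extent <- n * volume$voxel_size_A
  if (filament_len_A < box_extent)
    abort("filament_len_A must be at least the box extent")
  hp <- helical_params(lattice)
  n_seg <- floor((filament_len_A - box_extent) / spacing_A) + 1

  set.seed(seed)
  meta <- purrr::map_dfr(seq_len(n_filaments), function(f) {
    rot0 <- runif(1, 0, 360)
    tibble(
      filament_id = f,
      segment_index = seq_len(n_seg),
      axial_position_A = (seq_len(n_seg) - 1) * spacing_A,
      rot = wrap360(rot0 + (seq_len(n_seg) - 1) * spacing_A / hp$rise_A *
                      hp$twist_deg),
      tilt = 90 + rnorm(n_seg, 0, tilt_jitter_deg),
      psi = 0,
      shift_x = runif(n_seg, -shift_jitter_A, shift_jitter_A),
      shift_y = runif(n_seg, -shift_jitter_A, shift_jitter_A)
    )
  })
  meta$segment_id <- seq_len(nrow(meta))
  meta$pf_number_true <- lattice$n_pf
  meta$defocus_um <- if (is.null(ctf)) NA_real_ else ctf$defocus_um
  meta$snr <- snr
  meta$seed <- seed

  images <- array(0, c(n, n, nrow(meta)))
  for (i in seq_len(nrow(meta))) {
    clean <- project_map(volume, c(meta$rot[i], meta$tilt[i], meta$psi[i]),
                         c(meta$shift_x[i], meta$shift_y[i]))
    if (!is.null(ctf)) clean <- apply_ctf(clean, volume$voxel_size_A, ctf)
    if (is.infinite(snr)) {
      images[, , i] <- clean
    } else {
      fp <- mt_footprint(clean)
      noise_sd <- sqrt(var(clean[fp]) / snr)
      images[, , i] <- clean + rnorm(length(clean), 0, noise_sd)
    }
  }
  structure(list(images = images, meta = dplyr::relocate(
    meta, segment_id, filament_id, segment_index),
    voxel_size_A = volume$voxel_size_A, volume = volume),
    class = "segment_stack")
}

#' @export
print.segment_stack <- function(x, ...) {
  cat(sprintf("<segment_stack> %d segments of %d filament(s), %d px, %.2f A/px\n",
              dim(x$images)[3], length(unique(x$meta$filament_id)),
              dim(x$images)[1], x$voxel_size_A))
  invisible(x)
}

#' Empirical SNR of a segment stack
#'
#' Signal variance over noise variance inside the filament footprint,
#' estimated against supplied clean images.
#'
#' @param images Noisy image array (n x n x k).
#' @param clean Matching clean image array.
#' @return Mean empirical SNR across segments.
#' @export
empirical_snr <- function(images, clean) {
  k <- dim(images)[3]
  mean(vapply(seq_len(k), function(i) {
    fp <- mt_footprint(clean[, , i])
    var(clean[, , i][fp]) / var((images[, , i] - clean[, , i])[fp])
  }, numeric(1)))
}
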