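#' Generate a synthetic Michaelis-Menten ATPase dataset
#'
#' Steady-state MT-stimulated ATP hydrolysis rates
#' `v = kcat * S / (Km + S)` with multiplicative Gaussian noise
#' `(1 + eps)`, `eps ~ N(0, noise_cv)` — the error structure of a
#' rate measurement whose uncertainty scales with the rate.
#'
#' @param kcat_per_s Maximal turnover rate, 1/s.
#' @param km_nM Half-saturation MT concentration, nM.
#' @param concs_nM Vector of MT concentrations, nM (> 0).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return A tibble with columns `mt_conc_nM`, `rate_per_s`.
#' @export
#' @examples
#' gen_mm_dataset(7.1, 680, c(68, 680, 6800), noise_cv = 0)
gen_mm_dataset <- function(kcat_per_s, km_nM, concs_nM, noise_cv = 0.03,
                           seed = 1) {
  if (!length(concs_nM)) abort("concs_nM must be non-empty")
  if (any(concs_nM <= 0)) abort("concentrations must be > 0")
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  set.seed(seed)
  v <- kcat_per_s * concs_nM / (km_nM + concs_nM)
  tibble(mt_conc_nM = concs_nM,
         rate_per_s = v * (1 + rnorm(length(v), 0, noise_cv)))
}

#' Generate a synthetic single-motor motility sample
#'
#' Velocities (and, proportionally, fluorescence intensities) are drawn from
#' a 1- or 2-component Gaussian mixture; run lengths are exponential with
#' the given mean and right-censored at the observation window limit, with a
#' per-record censoring flag.
#'
#' @param components A data frame or list of rows with `mean`, `sd`, `weight`
#'   (weights must sum to 1).
#' @param n Number of motility events.
#' @param runlen_mean_um Mean of the exponential run-length distribution, um.
#' @param censor_limit_um Observation-window censoring limit, um.
#' @param intensity_scale Multiplier mapping velocity components to intensity
#'   components (arbitrary units); intensities share the mixture labels.
#' @param seed Integer seed.
#' @return A tibble with `velocity_nm_s`, `intensity_au`, `component`
#'   (ground-truth label), `run_length_um`, `censored`, plus the censor limit
#'   as an attribute `censor_limit_um`.
#' @export
gen_motility_dataset <- function(components, n, runlen_mean_um = 10,
                                 censor_limit_um = 25, intensity_scale = 50,
                                 seed = 1) {
  comp <- as_tibble(components)
  if (!all(c("mean", "sd", "weight") %in% names(comp)))
    abort("components must have mean, sd and weight")
  if (abs(sum(comp$weight) - 1) > 1e-9) abort("weights must sum to 1")
  if (any(comp$sd <= 0)) abort("component sds must be > 0")
  set.seed(seed)
  lab <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
  vel <- rnorm(n, comp$mean[lab], comp$sd[lab])
  inten <- rnorm(n, comp$mean[lab] * intensity_scale,
                 comp$sd[lab] * intensity_scale)
  rl_true <- rexp(n, 1 / runlen_mean_um)
  censored <- rl_true > censor_limit_um
  out <- tibble(velocity_nm_s = vel, intensity_au = inten, component = lab,
                run_length_um = pmin(rl_true, censor_limit_um),
                censored = censored)
  attr(out, "censor_limit_um") <- censor_limit_um
  out
}

#' Generate a synthetic plateau-force versus overlap-length dataset
#'
#' Plateau pushing forces scale linearly with the antiparallel overlap
#' length: `F = slope * L + N(0, noise_sd)`, overlaps uniform over the given
#' range.
#'
#' @param slope_pN_per_um Generating slope, pN per um of overlap.
#' @param n Number of sliding events (>= 2).
#' @param overlap_range_um Length-2 range of overlap lengths, um.
#' @param noise_sd_pN SD of additive force noise, pN.
#' @param seed Integer seed.
#' @return A tibble with `overlap_um`, `plateau_pN`.
#' @export
gen_force_dataset <- function(slope_pN_per_um, n, overlap_range_um = c(1, 8),
                              noise_sd_pN = 1, seed = 1) {
  if (n < 2) abort("n must be >= 2")
  if (diff(range(overlap_range_um)) <= 0) abort("degenerate overlap range")
  set.seed(seed)
  ov <- runif(n, overlap_range_um[1], overlap_range_um[2])
  tibble(overlap_um = ov,
         plateau_pN = slope_pN_per_um * ov + rnorm(n, 0, noise_sd_pN))
}

#' Generate a synthetic two-compartment cell image
#'
#' A pixel image of a cell with a spindle compartment inside it and
#' background regions outside: each pixel is its region mean plus Gaussian
#' noise. Masks are returned with the image so the background-subtracted
#' spindle-to-cytoplasm ratio can be measured exactly as in fixed-cell
#' quantification.
#'
#' @param spindle_mean,cyto_mean,bg_mean Region mean intensities (a.u.).
#' @param noise_sd Pixel noise SD.
#' @param nx,ny Image size in pixels.
#' @param seed Integer seed.
#' @return A list of class `roi_image`: `pixels` matrix, logical
#'   `spindle_mask`, `cell_mask`, and `background_rois` (list of two logical
#'   masks outside the cell).
#' @export
gen_roi_image <- function(spindle_mean, cyto_mean, bg_mean = 100,
                          noise_sd = 0, nx = 120, ny = 90, seed = 1) {
  set.seed(seed)
  xs <- matrix(rep(seq_len(nx), ny), nx, ny)
  ys <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  cx <- nx / 2
  cy <- ny / 2
  # elliptical cell, elongated spindle ellipse inside it
  cell <- ((xs - cx) / (0.38 * nx))^2 + ((ys - cy) / (0.38 * ny))^2 <= 1
  spindle <- ((xs - cx) / (0.22 * nx))^2 + ((ys - cy) / (0.12 * ny))^2 <= 1
  if (!all(spindle[spindle] & cell[spindle]))
    abort("spindle mask must lie inside the cell mask")
  bg1 <- xs <= 0.12 * nx & ys <= 0.3 * ny
  bg2 <- xs >= 0.88 * nx & ys >= 0.7 * ny
  if (any(bg1 & cell) || any(bg2 & cell))
    abort("background ROIs overlap the cell mask")
  px <- matrix(bg_mean, nx, ny)
  px[cell] <- cyto_mean
  px[spindle] <- spindle_mean
  px <- px + matrix(rnorm(nx * ny, 0, noise_sd), nx, ny)
  structure(list(pixels = px, spindle_mask = spindle, cell_mask = cell,
                 background_rois = list(bg1, bg2)),
            class = "roi_image")
}
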