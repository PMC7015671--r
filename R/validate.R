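#' Fourier shell correlation between two maps
#'
#' Normalised complex correlation of the Fourier coefficients of two maps,
#' binned into spherical shells of spatial frequency. Resolution claims read
#' this curve at a threshold (0.143 between independent half-maps).
#'
#' Half-map provenance matters: overlapping segments from the same filament
#' are not independent, so half-sets must be split by filament. Maps whose
#' `meta$split_by` records a segment-level split are refused unless
#' `allow_segment_split = TRUE`.
#'
#' @param mapA,mapB `density_map`s on identical grids.
#' @param shell_width_px Shell width in Fourier voxels (default 1).
#' @param mask `"cylinder"` (default) applies a soft cylindrical mask (45%
#'   of the box, 10% cosine edge) to both maps before the transform —
#'   helical specimens live inside a cylinder and the empty corners carry
#'   only reconstruction streaks; `"none"` compares the raw grids; or a 3D
#'   0-1 array.
#' @param allow_segment_split Override the half-set provenance check.
#' @return An `fsc_curve`: a tibble with `freq` (1/Angstrom, shell centres),
#'   `fsc`, `n_voxels`; attributes `voxel_size_A`, `nyquist`, `mask`.
#' @export
fsc <- function(mapA, mapB, shell_width_px = 1, mask = "cylinder",
                allow_segment_split = FALSE) {
  stopifnot(inherits(mapA, "density_map"), inherits(mapB, "density_map"))
  if (!identical(dim(mapA$values), dim(mapB$values)) ||
      mapA$voxel_size_A != mapB$voxel_size_A)
    abort("grid mismatch between maps")
  splits <- c(mapA$meta$split_by, mapB$meta$split_by)
  if (!allow_segment_split && any(splits == "segment"))
    abort(paste("half-maps were split by segment; overlapping segments are",
                "not independent. Split by filament, or set",
                "allow_segment_split = TRUE."))
  n <- box_px(mapA)
  vox <- mapA$voxel_size_A
  mdesc <- "none"
  va <- mapA$values
  vb <- mapB$values
  if (is.character(mask) && mask == "cylinder") {
    mk <- cylinder_mask(n, vox, 0.45 * n * vox, soft_A = 0.1 * n * vox)
    va <- va * mk
    vb <- vb * mk
    mdesc <- "cylinder"
  } else if (is.array(mask)) {
    va <- va * mask
    vb <- vb * mask
    mdesc <- "custom"
  }
  fa <- fft(va)
  fb <- fft(vb)
  f1 <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) / (n * vox)
  s2 <- outer(outer(f1^2, f1^2, "+"), f1^2, "+")
  s <- sqrt(s2)
  df <- shell_width_px / (n * vox)
  shell <- pmin(as.integer(floor(s / df)), as.integer(floor(n / 2 / shell_width_px)))
  nshell <- floor(n / 2 / shell_width_px)
  num <- Re(tapply(fa * Conj(fb), shell, sum))
  da <- tapply(abs(fa)^2, shell, sum)
  db <- tapply(abs(fb)^2, shell, sum)
  cnt <- tapply(rep(1, length(shell)), shell, sum)
  keep <- as.integer(names(num)) >= 1 & as.integer(names(num)) <= nshell
  corr <- num[keep] / sqrt(da[keep] * db[keep])
  corr[!is.finite(corr)] <- 0
  out <- tibble(freq = (as.integer(names(num))[keep] + 0.5) * df,
                fsc = as.numeric(corr),
                n_voxels = as.integer(cnt[keep]))
  out <- out[order(out$freq), ]
  attr(out, "voxel_size_A") <- vox
  attr(out, "nyquist") <- 1 / (2 * vox)
  attr(out, "mask") <- mdesc
  class(out) <- c("fsc_curve", class(out))
  out
}

#' Resolution at an FSC threshold
#'
#' Finds the first downward crossing of the threshold, linearly interpolated
#' between shells, and reports it as a resolution in Angstroms. A curve that
#' never drops below the threshold saturates at Nyquist (flag `"saturated"`);
#' a curve never above it is undefined (flag `"undefined"`, value `NA`).
#'
#' @param curve An `fsc_curve` from [fsc()].
#' @param threshold FSC cutoff (0.143 for independent half-maps by default).
#' @return Resolution in Angstroms with attribute `flag` in
#'   `c("ok", "saturated", "undefined")`.
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  f <- curve$freq
  v <- curve$fsc
  if (all(v < threshold)) {
    out <- NA_real_
    attr(out, "flag") <- "undefined"
    return(out)
  }
  below <- which(v < threshold)
  above_start <- v[1] >= threshold
  cross <- if (above_start && length(below)) below[1] else NA_integer_
  if (is.na(cross)) {
    nyq <- attr(curve, "nyquist") %||% max(f)
    out <- 1 / nyq
    attr(out, "flag") <- "saturated"
    return(out)
  }
  i1 <- cross - 1
  fc <- f[i1] + (f[cross] - f[i1]) * (v[i1] - threshold) / (v[i1] - v[cross])
  out <- 1 / fc
  attr(out, "flag") <- "ok"
  out
}

#' Apply a B factor to a map
#'
#' Scales Fourier amplitudes by `exp(-B * s^2 / 4)` (s in 1/Angstrom).
#' Positive B blurs, negative B sharpens; phases are untouched, and
#' `apply_bfactor(B)` then `apply_bfactor(-B)` recovers the input to
#' floating point tolerance. Sharpening a final map for display is the
#' negative-B use.
#'
#' @param map A `density_map`.
#' @param B_A2 B factor in square Angstroms.
#' @return The filtered `density_map`.
#' @export
apply_bfactor <- function(map, B_A2) {
  stopifnot(inherits(map, "density_map"))
  if (B_A2 == 0) return(map)
  n <- box_px(map)
  vox <- map$voxel_size_A
  f1 <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) / (n * vox)
  s2 <- outer(outer(f1^2, f1^2, "+"), f1^2, "+")
  vals <- Re(fft(fft(map$values) * exp(-B_A2 * s2 / 4), inverse = TRUE)) / n^3
  density_map(vals, vox, meta = map$meta)
}

# soft (Hann) window cube for local FSC
hann_cube <- function(w) {
  h <- 0.5 * (1 - cos(2 * pi * (seq_len(w) - 1) / (w - 1)))
  outer(outer(h, h), h)
}

#' Windowed local resolution map
#'
#' Slides a soft-edged cubic window over both half-maps, computes the FSC in
#' each window, reads the resolution at the (small-window) threshold, writes
#' it at the window centre and linearly interpolates between the step
#' positions. This is the block-wise local resolution estimate used to
#' report, e.g., better-ordered tubulin versus disordered tail density.
#'
#' @param half1,half2 Half-map `density_map`s.
#' @param window_A Window edge, Angstroms (>= several voxels).
#' @param step_px Window grid spacing in voxels.
#' @param threshold FSC threshold inside windows (default 0.5; small-window
#'   FSC statistics run higher than the global 0.143 criterion).
#' @param allow_segment_split Passed to [fsc()].
#' @return A `density_map` of local resolutions (Angstroms; `NA` where
#'   undefined).
#' @export
local_resolution <- function(half1, half2, window_A, step_px = NULL,
                             threshold = 0.5, allow_segment_split = FALSE) {
  stopifnot(inherits(half1, "density_map"), inherits(half2, "density_map"))
  if (!identical(dim(half1$values), dim(half2$values)))
    abort("grid mismatch")
  n <- box_px(half1)
  vox <- half1$voxel_size_A
  w <- round(window_A / vox)
  w <- max(6L, w + w %% 2L)  # even, at least 6 voxels
  if (w > n) abort("window larger than box")
  step_px <- step_px %||% max(2L, w %/% 2L)
  splits <- c(half1$meta$split_by, half2$meta$split_by)
  if (!allow_segment_split && any(splits == "segment"))
    abort("half-maps were split by segment; see ?fsc")

  centers <- seq(w %/% 2 + 1, n - w %/% 2, by = step_px)
  win <- hann_cube(w)
  res <- array(NA_real_, rep(length(centers), 3))
  for (ci in seq_along(centers)) for (cj in seq_along(centers))
    for (ck in seq_along(centers)) {
      ix <- centers[ci] + seq_len(w) - w %/% 2 - 1
      iy <- centers[cj] + seq_len(w) - w %/% 2 - 1
      iz <- centers[ck] + seq_len(w) - w %/% 2 - 1
      a <- density_map(half1$values[ix, iy, iz] * win, vox)
      b <- density_map(half2$values[ix, iy, iz] * win, vox)
      r <- resolution_at(fsc(a, b, mask = "none"), threshold)
      res[ci, cj, ck] <- if (is.na(r)) NA_real_ else as.numeric(r)
    }
  # separable linear interpolation of the coarse grid onto the full grid
  full <- interp_coarse3(res, centers, n)
  density_map(full, vox, meta = list(window_A = w * vox, step_px = step_px,
                                     threshold = threshold))
}

# trilinear interpolation of a coarse grid (values at `centers` voxel
# positions along each axis) onto an n^3 grid; clamped at the edges
interp_coarse3 <- function(vals, centers, n) {
  pos <- seq_len(n)
  idx <- findInterval(pos, centers, all.inside = TRUE)
  lo <- centers[idx]
  hi <- centers[idx + 1]
  f <- pmin(pmax((pos - lo) / (hi - lo), 0), 1)
  out <- array(NA_real_, c(n, n, n))
  vals_na <- vals
  vals_na[is.na(vals_na)] <- Inf  # undefined windows propagate as Inf -> NA
  g <- function(i, j, k) vals_na[cbind(i, j, k)]
  I <- idx; Fx <- f
  for (k in seq_len(n)) {
    kz <- idx[k]; fz <- f[k]
    # build n x n slice by blending the 8 surrounding coarse nodes
    blend2 <- function(kk) {
      m00 <- outer(1 - Fx, 1 - Fx) * vals_na[I, I, kk][seq_len(n), seq_len(n)]
      m10 <- outer(Fx, 1 - Fx) * vals_na[I + 1, I, kk][seq_len(n), seq_len(n)]
      m01 <- outer(1 - Fx, Fx) * vals_na[I, I + 1, kk][seq_len(n), seq_len(n)]
      m11 <- outer(Fx, Fx) * vals_na[I + 1, I + 1, kk][seq_len(n), seq_len(n)]
      m00 + m10 + m01 + m11
    }
    sl <- (1 - fz) * blend2(kz) + fz * blend2(kz + 1)
    out[, , k] <- sl
  }
  out[!is.finite(out)] <- NA_real_
  out
}

#' Reconstruct two half-maps split by filament
#'
#' Splits the segment stack into two halves at the filament level (odd/even
#' filament ids), back-projects each half with the supplied alignments and
#' symmetrizes. Segment-level splits are deliberately not offered: spaced,
#' overlapping segments of one filament are correlated and would inflate the
#' FSC.
#'
#' @param stack A `segment_stack`.
#' @param alignments Alignment table.
#' @param params [helical_params()] for symmetrization; `NULL` to skip.
#' @param n_pf Protofilament count for symmetrization.
#' @return List of two `density_map`s with `meta$split_by = "filament"`.
#' @export
halfset_reconstruct <- function(stack, alignments, params = NULL,
                                n_pf = NULL) {
  fids <- sort(unique(stack$meta$filament_id))
  if (length(fids) < 2) abort("need at least two filaments to split")
  h1 <- fids[seq_along(fids) %% 2 == 1]
  sub <- function(keep) {
    idx <- which(stack$meta$filament_id %in% keep)
    s <- list(images = stack$images[, , idx, drop = FALSE],
              meta = stack$meta[idx, ], voxel_size_A = stack$voxel_size_A)
    class(s) <- "segment_stack"
    m <- backproject(s, alignments[alignments$segment_id %in%
                                     s$meta$segment_id, ])
    if (!is.null(params)) m <- symmetrize(m, params, n_pf)
    m$meta$split_by <- "filament"
    m
  }
  list(sub(h1), sub(setdiff(fids, h1)))
}
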