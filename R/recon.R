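#' Build a projection gallery for matching
#'
#' Projects a reference map over an in-plane view-angle grid (`rot` from 0 to
#' 360 in `angular_step_deg` steps) at fixed tilt/psi. Filaments lie in the
#' ice plane, so the gallery is restricted to tilt ~ 90 degrees; this
#' restriction is what makes exhaustive matching affordable.
#'
#' @param reference A `density_map`.
#' @param angular_step_deg Rot sampling step, degrees (> 0).
#' @param tilt,psi Fixed tilt and psi for the gallery, degrees.
#' @return A list with `images` (n x n x G array, each slice zero-mean,
#'   unit-norm), and `angles` tibble (`rot`, `tilt`, `psi`).
#' @export
make_gallery <- function(reference, angular_step_deg, tilt = 90, psi = 0) {
  if (angular_step_deg <= 0) abort("angular_step_deg must be > 0")
  rots <- seq(0, 360 - angular_step_deg / 2, by = angular_step_deg)
  n <- box_px(reference)
  imgs <- array(0, c(n, n, length(rots)))
  for (g in seq_along(rots)) {
    p <- project_map(reference, c(rots[g], tilt, psi))
    p <- p - mean(p)
    nrm <- sqrt(sum(p^2))
    imgs[, , g] <- if (nrm > 0) p / nrm else p
  }
  list(images = imgs, angles = tibble(rot = rots, tilt = tilt, psi = psi))
}

# quadratic sub-pixel peak refinement from three samples, clamped to half a step
parabolic_peak <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (!is.finite(den) || den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
}

#' Exhaustive projection matching of a segment stack
#'
#' For every segment image, finds the gallery orientation and integer-pixel
#' shift maximising normalised cross-correlation, with parabolic sub-pixel
#' shift refinement; ties are broken toward the lowest gallery index. This is
#' the matching step of iterative helical real-space refinement.
#'
#' @param stack A `segment_stack` (or list with `images`, `meta`,
#'   `voxel_size_A`).
#' @param reference A `density_map` with the same box as the stack.
#' @param angular_step_deg Gallery rot step, degrees.
#' @param shift_range_A Maximum in-plane shift searched, Angstroms.
#' @param gallery Optional precomputed [make_gallery()] result.
#' @return An alignment table (tibble): `segment_id`, `filament_id`,
#'   `segment_index`, `rot`, `tilt`, `psi`, `shift_x`, `shift_y` (Angstroms),
#'   `cc_score`, `pf_assignment`.
#' @export
projection_match <- function(stack, reference, angular_step_deg = 4,
                             shift_range_A = 10, gallery = NULL) {
  if (dim(stack$images)[3] == 0) abort("empty stack")
  if (box_px(reference) != dim(stack$images)[1])
    abort("reference box does not match segment box")
  if (is.null(gallery))
    gallery <- make_gallery(reference, angular_step_deg)
  vox <- stack$voxel_size_A
  max_shift <- max(0L, as.integer(floor(shift_range_A / vox)))
  m <- cpp_match_stack(stack$images, gallery$images, max_shift)
  ns <- 2 * max_shift + 1
  n_img <- dim(stack$images)[3]
  sub <- t(vapply(seq_len(n_img), function(i) {
    dx <- m$dx[i] + max_shift + 1
    dy <- m$dy[i] + max_shift + 1
    cc <- m$cc_shift[, , i]
    fx <- if (dx > 1 && dx < ns)
      parabolic_peak(cc[dx - 1, dy], cc[dx, dy], cc[dx + 1, dy]) else 0
    fy <- if (dy > 1 && dy < ns)
      parabolic_peak(cc[dx, dy - 1], cc[dx, dy], cc[dx, dy + 1]) else 0
    c(fx, fy)
  }, numeric(2)))
  ang <- gallery$angles[m$gallery_index, ]
  tibble(
    segment_id = stack$meta$segment_id,
    filament_id = stack$meta$filament_id,
    segment_index = stack$meta$segment_index,
    rot = ang$rot, tilt = ang$tilt, psi = ang$psi,
    shift_x = (m$dx + sub[, 1]) * vox,
    shift_y = (m$dy + sub[, 2]) * vox,
    cc_score = m$cc,
    pf_assignment = NA_integer_
  )
}

# 1D ramp (|frequency|) filter along the image y axis: the transverse
# direction for in-plane filaments (tilt ~ 90, psi ~ 0). Plain smearing
# back-projection weights Fourier space by 1/|s|; the ramp undoes that, as
# in filtered back-projection.
ramp_filter_y <- function(img) {
  n <- ncol(img)
  w <- abs(c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1))) / n
  t(Re(mvfft(mvfft(t(img)) * w, inverse = TRUE)) / n)
}

#' Asymmetric real-space back-projection
#'
#' Smears every aligned segment image back through the volume along its
#' viewing direction, normalising each voxel by its hit count. By default
#' images are ramp-filtered along the transverse axis first (filtered
#' back-projection); `filter = "none"` gives the plain smear. Voxels with
#' zero coverage are flagged in `meta$n_zero_coverage` and left at zero.
#'
#' @param stack A `segment_stack`.
#' @param alignments An alignment table with one row per stack image.
#' @param filter `"ramp"` (default) or `"none"`.
#' @return A `density_map`.
#' @export
backproject <- function(stack, alignments, filter = c("ramp", "none")) {
  filter <- match.arg(filter)
  n_img <- dim(stack$images)[3]
  if (nrow(alignments) != n_img)
    abort("alignments must have one row per stack image")
  al <- alignments[match(stack$meta$segment_id, alignments$segment_id), ]
  if (any(is.na(al$rot))) abort("missing alignment rows for some segments")
  Rs <- matrix(0, 3, 3 * n_img)
  for (i in seq_len(n_img))
    Rs[, (3 * i - 2):(3 * i)] <- euler_matrix(al$rot[i], al$tilt[i], al$psi[i])
  shifts <- cbind(al$shift_x, al$shift_y) / stack$voxel_size_A
  imgs <- stack$images
  if (filter == "ramp")
    for (i in seq_len(n_img)) imgs[, , i] <- ramp_filter_y(imgs[, , i])
  bp <- cpp_backproject(imgs, Rs, shifts)
  vals <- bp$sum
  cover <- bp$weight > 0
  vals[cover] <- vals[cover] / bp$weight[cover]
  density_map(vals, stack$voxel_size_A,
              meta = list(n_zero_coverage = sum(!cover), n_images = n_img))
}

#' Estimate helical parameters from a map
#'
#' Grid search maximising the real-space correlation between the map and its
#' copy transformed by (twist, rise) inside a cylindrical mask (restricted to
#' the central half of the axial extent to avoid edge artefacts), followed by
#' parabolic refinement about the grid optimum. Flags are set when the
#' optimum sits on a range boundary or when the correlation surface is flat.
#'
#' @param map A `density_map`.
#' @param guess A [helical_params()] bracketed by the ranges.
#' @param twist_range,rise_range Length-2 search ranges (deg, Angstroms).
#' @param grid_step Length-2 step `(twist_deg, rise_A)`.
#' @param mask_radius_A Cylindrical mask radius; default 45% of the box.
#' @return A `helical_params` with attributes `correlation`, `boundary_flag`,
#'   `flat_flag`.
#' @export
estimate_helical_params <- function(map, guess, twist_range, rise_range,
                                    grid_step = c(0.25, 0.1),
                                    mask_radius_A = NULL) {
  stopifnot(inherits(map, "density_map"), inherits(guess, "helical_params"))
  if (diff(range(twist_range)) < 0 || diff(range(rise_range)) < 0)
    abort("empty search range")
  if (guess$twist_deg < twist_range[1] || guess$twist_deg > twist_range[2] ||
      guess$rise_A < rise_range[1] || guess$rise_A > rise_range[2])
    abort("ranges must bracket the guess")
  n <- box_px(map)
  vox <- map$voxel_size_A
  mask_radius_A <- mask_radius_A %||% (0.45 * n * vox)
  mask <- cylinder_mask(n, vox, mask_radius_A) > 0.5
  zc <- abs(axis_coords(n, vox))
  zkeep <- array(rep(zc <= n * vox / 4, each = n * n), c(n, n, n))
  mask <- mask & zkeep

  twists <- seq(twist_range[1], twist_range[2], by = grid_step[1])
  rises <- seq(rise_range[1], rise_range[2], by = grid_step[2])
  score <- matrix(NA_real_, length(twists), length(rises))
  for (i in seq_along(twists)) {
    for (j in seq_along(rises)) {
      tf <- structure(list(
        R = euler_matrix(twists[i], 0, 0), t = c(0, 0, rises[j])),
        class = "rigid_transform")
      tv <- cpp_transform_volume(map$values, tf$R, tf$t / vox)
      score[i, j] <- ncc(map$values, tv, mask)
    }
  }
  # a map with no helical signature shows no twist dependence (a pure
  # rotation leaves it unchanged); rise dependence alone cannot pin both
  twist_var <- max(apply(score, 2, function(col) diff(range(col))))
  flat <- (max(score) - min(score)) < 1e-6 || twist_var < 1e-5
  if (flat) {
    out <- new_helical_params(guess$twist_deg, guess$rise_A)
    attr(out, "correlation") <- max(score)
    attr(out, "flat_flag") <- TRUE
    attr(out, "boundary_flag") <- FALSE
    return(out)
  }
  idx <- which(score == max(score), arr.ind = TRUE)[1, ]
  i0 <- idx[1]; j0 <- idx[2]
  boundary <- i0 == 1 || i0 == length(twists) || j0 == 1 || j0 == length(rises)
  dt <- if (i0 > 1 && i0 < length(twists))
    parabolic_peak(score[i0 - 1, j0], score[i0, j0], score[i0 + 1, j0]) else 0
  dr <- if (j0 > 1 && j0 < length(rises))
    parabolic_peak(score[i0, j0 - 1], score[i0, j0], score[i0, j0 + 1]) else 0
  out <- new_helical_params(twists[i0] + dt * grid_step[1],
                            rises[j0] + dr * grid_step[2])
  attr(out, "correlation") <- score[i0, j0]
  attr(out, "flat_flag") <- FALSE
  attr(out, "boundary_flag") <- boundary
  out
}

#' N-fold helical symmetrization of a map
#'
#' Arithmetic mean of the `k = 0 .. n_pf - 1` copies of the map transformed
#' by the protofilament symmetry operators. A symmetric window of `k` values
#' centred on zero is used so axial edge loss is balanced.
#'
#' @param map A `density_map`.
#' @param params [helical_params()] of the monomer lattice.
#' @param n_pf Number of symmetry-related copies to average.
#' @return A symmetrized `density_map`.
#' @export
symmetrize <- function(map, params, n_pf) {
  stopifnot(inherits(map, "density_map"), inherits(params, "helical_params"))
  ks <- seq_len(n_pf) - 1L - (n_pf %/% 2L)
  acc <- array(0, dim(map$values))
  for (k in ks) {
    if (k == 0) {
      acc <- acc + map$values
    } else {
      tf <- pf_symmetry_transform(params, k)
      acc <- acc + cpp_transform_volume(map$values, tf$R,
                                        tf$t / map$voxel_size_A)
    }
  }
  density_map(acc / n_pf, map$voxel_size_A,
              meta = c(map$meta, list(symmetrized_n = n_pf)))
}

#' Iterative helical real-space refinement
#'
#' Alternates projection matching, asymmetric back-projection, helical
#' parameter estimation and N-fold symmetrized averaging — each symmetrized
#' model seeding the next round of matching — until the helical parameters
#' stop moving or `n_iter` rounds have run.
#'
#' @param stack A `segment_stack`.
#' @param initial_map Starting reference `density_map`.
#' @param params0 Starting [helical_params()].
#' @param n_pf Protofilament count for symmetrization.
#' @param n_iter Maximum iterations (`0` returns the initial map unchanged).
#' @param angular_step_deg,shift_range_A Matching search parameters.
#' @param twist_window_deg,rise_window_A Half-widths of the per-iteration
#'   symmetry search around the current parameters.
#' @param grid_step Length-2 symmetry-search step `(deg, Angstroms)`.
#' @param tol Length-2 convergence tolerances on `(|d twist|, |d rise|)`.
#' @return A list of class `ihrsr_result`: `map`, `alignments`, `params`,
#'   and a per-iteration `log` tibble (twist, rise, mean cc).
#' @export
ihrsr_refine <- function(stack, initial_map, params0, n_pf,
                         n_iter = 3, angular_step_deg = 4, shift_range_A = 10,
                         twist_window_deg = 1.5, rise_window_A = 0.8,
                         grid_step = c(0.25, 0.1), tol = c(0.05, 0.05)) {
  if (n_iter < 0) abort("n_iter must be >= 0")
  map <- initial_map
  params <- params0
  alignments <- NULL
  log <- tibble(iteration = integer(), twist_deg = numeric(),
                rise_A = numeric(), mean_cc = numeric())
  if (n_iter == 0)
    return(structure(list(map = map, alignments = alignments, params = params,
                          log = log), class = "ihrsr_result"))
  for (it in seq_len(n_iter)) {
    alignments <- projection_match(stack, map, angular_step_deg, shift_range_A)
    bp <- backproject(stack, alignments)
    new_params <- estimate_helical_params(
      bp, params,
      twist_range = params$twist_deg + c(-1, 1) * twist_window_deg,
      rise_range = params$rise_A + c(-1, 1) * rise_window_A,
      grid_step = grid_step)
    map <- symmetrize(bp, new_params, n_pf)
    log <- dplyr::bind_rows(log, tibble(
      iteration = it, twist_deg = new_params$twist_deg,
      rise_A = new_params$rise_A, mean_cc = mean(alignments$cc_score)))
    dtw <- abs(new_params$twist_deg - params$twist_deg)
    dri <- abs(new_params$rise_A - params$rise_A)
    params <- new_params
    if (it > 1 && dtw < tol[1] && dri < tol[2]) break
  }
  structure(list(map = map, alignments = alignments, params = params,
                 log = log), class = "ihrsr_result")
}

#' Sort filaments by protofilament number
#'
#' Matches every segment against reference galleries for each candidate
#' protofilament count and assigns each filament by majority vote over its
#' segments' best-correlating references; vote ties are left unassigned.
#'
#' @param stack A `segment_stack`.
#' @param references Named list of `density_map` references; names are the
#'   protofilament counts (e.g. `"13"`, `"14"`, `"15"`).
#' @param angular_step_deg,shift_range_A Matching search parameters.
#' @return A list with `segments` (per-segment cc per reference and winner)
#'   and `filaments` (tibble: `filament_id`, `pf_assignment` — `NA` for
#'   ties — `n_segments`, `n_votes`).
#' @export
sort_pf_number <- function(stack, references, angular_step_deg = 4,
                           shift_range_A = 10) {
  if (length(references) < 2) abort("need at least 2 references")
  if (is.null(names(references)) || any(!nzchar(names(references))))
    abort("references must be a named list (names = pf counts)")
  counts <- table(stack$meta$filament_id)
  if (any(counts == 0)) abort("filament with zero segments")
  ccs <- purrr::map(references, function(ref) {
    projection_match(stack, ref, angular_step_deg, shift_range_A)$cc_score
  })
  ccm <- do.call(cbind, ccs)
  win <- names(references)[max.col(ccm, ties.method = "first")]
  segments <- tibble(segment_id = stack$meta$segment_id,
                     filament_id = stack$meta$filament_id)
  segments <- dplyr::bind_cols(segments,
                               as_tibble(as.data.frame(ccm)))
  segments$winner <- win
  filaments <- segments |>
    dplyr::group_by(filament_id) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      pf_assignment = {
        tb <- table(winner)
        top <- tb[tb == max(tb)]
        if (length(top) > 1) NA_integer_ else as.integer(names(top))
      },
      n_votes = max(table(winner)),
      .groups = "drop")
  list(segments = segments, filaments = filaments)
}

# unwrap a wrapped angle series so successive differences lie in (-180, 180]
unwrap_deg <- function(a) {
  if (length(a) < 2) return(a)
  d <- diff(a)
  d <- d - 360 * round(d / 360)
  c(a[1], a[1] + cumsum(d))
}

#' Smooth per-filament alignment parameters
#'
#' Filament geometry varies smoothly along its length, so the view angle and
#' shifts of consecutive segments should follow low-order polynomials of
#' axial position. Per filament, fits a polynomial (degree <= `max_degree`)
#' to the unwrapped `rot` and to each shift component, flags residuals beyond
#' `outlier_sigma` robust SDs (MAD), refits without them, and replaces the
#' outliers with the refitted values. Filaments with fewer than
#' `max_degree + 2` segments pass through unchanged.
#'
#' @param table An alignment table (see [projection_match()]), ordered by
#'   segment within filaments; an `axial_position_A` column is used as the
#'   predictor when present, else `segment_index`.
#' @param max_degree Maximum polynomial degree.
#' @param outlier_sigma Outlier threshold in MAD-scaled SDs.
#' @return The smoothed alignment table, plus a logical `smoothed` column
#'   marking replaced entries.
#' @export
smooth_alignments <- function(table, max_degree = 2, outlier_sigma = 3) {
  smooth_col <- function(y, t) {
    deg <- min(max_degree, length(y) - 2)
    fit <- lm(y ~ poly(t, deg, raw = TRUE))
    res <- y - fitted(fit)
    s <- mad(res)
    out <- s > 0 & abs(res) > outlier_sigma * s
    if (!any(out)) return(list(y = y, out = out))
    refit <- lm(y ~ poly(t, deg, raw = TRUE), subset = !out)
    y[out] <- predict(refit, newdata = data.frame(t = t))[out]
    list(y = y, out = out)
  }
  table |>
    dplyr::group_by(filament_id) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$segment_index), ]
      if (nrow(df) < max_degree + 2) {
        df$smoothed <- FALSE
        return(df)
      }
      t <- if ("axial_position_A" %in% names(df)) df$axial_position_A
           else df$segment_index
      r <- smooth_col(unwrap_deg(df$rot), t)
      sx <- smooth_col(df$shift_x, t)
      sy <- smooth_col(df$shift_y, t)
      df$rot <- wrap360(r$y)
      df$shift_x <- sx$y
      df$shift_y <- sy$y
      df$smoothed <- r$out | sx$out | sy$out
      df
    }) |>
    dplyr::ungroup()
}
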