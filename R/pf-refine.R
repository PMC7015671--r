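#' Wedge mask specification
#'
#' Describes a soft angular wedge in cylindrical coordinates that isolates
#' one protofilament column of a microtubule map. The wedge of column `j`
#' is centred on that column's azimuth and spans `360 / n_pf` degrees with a
#' cosine crossfade of width `soft_edge_deg` at each boundary, so the
#' `n_pf` single-column masks form a partition of unity inside the radial
#' annulus.
#'
#' @param n_pf Protofilament count.
#' @param pf_index Column to keep (0-based).
#' @param angular_width_deg Wedge width; default `360 / n_pf`.
#' @param soft_edge_deg Total width of the cosine falloff across each wedge
#'   boundary (0 = hard edge). Hard edges ring under interpolation, so the
#'   default is 5 degrees.
#' @param radial_inner_A,radial_outer_A Annulus radii, Angstroms.
#'   `radial_outer_A = NULL` defaults to 49% of the box extent at mask time.
#' @param handedness Sign convention of the lattice azimuths (matches
#'   [lattice_spec()]).
#' @param center_deg Explicit wedge centre azimuth; default
#'   `handedness * 360 * pf_index / n_pf`.
#' @return A list of class `wedge_mask_spec`.
#' @export
wedge_mask_spec <- function(n_pf, pf_index, angular_width_deg = 360 / n_pf,
                            soft_edge_deg = 5, radial_inner_A = 60,
                            radial_outer_A = NULL, handedness = -1,
                            center_deg = NULL) {
  if (pf_index < 0 || pf_index >= n_pf)
    abort("pf_index must satisfy 0 <= pf_index < n_pf")
  if (soft_edge_deg < 0) abort("soft_edge_deg must be >= 0")
  if (!is.null(radial_outer_A) && radial_inner_A >= radial_outer_A)
    abort("radial_inner_A must be < radial_outer_A")
  structure(list(
    n_pf = as.integer(n_pf), pf_index = as.integer(pf_index),
    angular_width_deg = angular_width_deg, soft_edge_deg = soft_edge_deg,
    radial_inner_A = radial_inner_A, radial_outer_A = radial_outer_A,
    center_deg = center_deg %||% (handedness * 360 * pf_index / n_pf)),
    class = "wedge_mask_spec")
}

#' Build a single-protofilament wedge mask
#'
#' @param grid_like A `density_map` supplying the grid geometry.
#' @param spec A [wedge_mask_spec()].
#' @return A `density_map` with values in `[0, 1]`.
#' @export
make_wedge_mask <- function(grid_like, spec) {
  stopifnot(inherits(grid_like, "density_map"),
            inherits(spec, "wedge_mask_spec"))
  n <- box_px(grid_like)
  vox <- grid_like$voxel_size_A
  r_out <- spec$radial_outer_A %||% (0.49 * n * vox)
  if (r_out > 0.5 * n * vox + 1e-9)
    abort("annulus outside box: radial_outer_A exceeds half the box extent")
  ax <- axis_coords(n, vox)
  xg <- matrix(rep(ax, n), n, n)
  yg <- matrix(rep(ax, each = n), n, n)
  r <- sqrt(xg^2 + yg^2)
  theta <- atan2(yg, xg) * 180 / pi
  d <- ang_diff(theta, spec$center_deg) - spec$angular_width_deg / 2
  s <- spec$soft_edge_deg
  angular <- if (s > 0) {
    ifelse(d <= -s / 2, 1, ifelse(d >= s / 2, 0, 0.5 * (1 - sin(pi * d / s))))
  } else {
    # half-open interval (with a float-safe tolerance) so pixels exactly on
    # a boundary belong to exactly one wedge
    eps <- 1e-9
    dd <- ((theta - spec$center_deg + 180) %% 360) - 180
    as.numeric(dd > -spec$angular_width_deg / 2 + eps &
                 dd <= spec$angular_width_deg / 2 + eps)
  }
  m2 <- angular * (r >= spec$radial_inner_A) * (r <= r_out)
  density_map(array(rep(m2, n), c(n, n, n)), vox,
              meta = list(wedge = spec))
}

# mask the map down to one protofilament column
single_pf_map <- function(map, lattice, pf_index, soft_edge_deg = 5,
                          radial_inner_A = 60, radial_outer_A = NULL) {
  spec <- wedge_mask_spec(lattice$n_pf, pf_index,
                          soft_edge_deg = soft_edge_deg,
                          radial_inner_A = radial_inner_A,
                          radial_outer_A = radial_outer_A,
                          handedness = lattice$handedness)
  m <- make_wedge_mask(map, spec)
  density_map(map$values * m$values, map$voxel_size_A, meta = map$meta)
}

#' Subtract all other protofilaments from a segment image
#'
#' Removes the projected density of every protofilament except `pf_index`
#' from an experimental segment image: the map is multiplied by the
#' complement of the single-column wedge mask, projected at the segment's
#' alignment, and subtracted. Under a linear projection this equals, for
#' noiseless data, the direct projection of the single-column masked map —
#' the oracle identity the tests exercise.
#'
#' @param image Segment image matrix.
#' @param map The symmetrized microtubule `density_map`.
#' @param alignment A one-row alignment (list/tibble with `rot`, `tilt`,
#'   `psi`, `shift_x`, `shift_y`).
#' @param pf_index Column to keep (0-based).
#' @param lattice The [lattice_spec()] describing the map.
#' @param ... Passed to [wedge_mask_spec()] (`soft_edge_deg`, radii).
#' @return The residual image matrix.
#' @export
subtract_other_pfs <- function(image, map, alignment, pf_index, lattice, ...) {
  if (pf_index < 0 || pf_index >= lattice$n_pf)
    abort("pf_index out of range")
  spec <- wedge_mask_spec(lattice$n_pf, pf_index,
                          handedness = lattice$handedness, ...)
  m <- make_wedge_mask(map, spec)
  compl <- density_map(map$values * (1 - m$values), map$voxel_size_A)
  proj <- project_map(compl, c(alignment$rot, alignment$tilt, alignment$psi),
                      c(alignment$shift_x, alignment$shift_y))
  image - proj
}

# beta-tubulin anchor site of column j nearest the box equator, model frame
pf_anchor_site <- function(lattice, pf_index, n_dimer_repeats = 6) {
  sites <- lattice_positions(lattice, n_dimer_repeats)
  b <- sites[sites$kind == "beta" & sites$pf_index == pf_index, ]
  b[which.min(abs(b$z)), ]
}

# bilinear crop of `img` in a box_out window centred on (cx, cy) (1-based px)
crop_shift <- function(img, cx, cy, box_out) {
  n <- nrow(img)
  off <- (seq_len(box_out) - 1) - floor(box_out / 2)
  xs <- cx + off
  ys <- cy + off
  x0 <- floor(xs); fx <- xs - x0
  y0 <- floor(ys); fy <- ys - y0
  cl <- function(i) pmin(pmax(i, 1L), n)
  a00 <- img[cl(x0), cl(y0), drop = FALSE]
  a10 <- img[cl(x0 + 1), cl(y0), drop = FALSE]
  a01 <- img[cl(x0), cl(y0 + 1), drop = FALSE]
  a11 <- img[cl(x0 + 1), cl(y0 + 1), drop = FALSE]
  out <- a00 * outer(1 - fx, 1 - fy) + a10 * outer(fx, 1 - fy) +
    a01 * outer(1 - fx, fy) + a11 * outer(fx, fy)
  inside <- outer(xs >= 1 & xs <= n, ys >= 1 & ys <= n)
  out * inside
}

#' Extract one particle per protofilament per segment
#'
#' For each segment and each column `j`, subtracts the other protofilaments
#' ([subtract_other_pfs()]), recentres the residual so the target column's
#' tubulin dimer nearest the box equator sits at the particle centre, and
#' records the particle's initial alignment as the microtubule alignment
#' composed with the j-th protofilament symmetry step. Segment spacing of
#' one dimer repeat makes this one particle per imaged tubulin dimer, so
#' `n_segments * n_pf` particles come out of `n_segments` segments.
#'
#' @param stack A `segment_stack`.
#' @param alignments Alignment table covering every segment.
#' @param lattice The [lattice_spec()].
#' @param map Symmetrized reference `density_map` used for subtraction.
#' @param box_out Particle box in pixels; default half the segment box.
#' @param ... Wedge-mask options passed through.
#' @return A `pf_particle_set`: `images` (box_out^2 x P array), `meta`
#'   tibble with provenance (`segment_id`, `pf_index`), initial alignments,
#'   and ground-truth occupancy columns when the stack's generating volume
#'   carries them.
#' @export
extract_pf_particles <- function(stack, alignments, lattice, map,
                                 box_out = NULL, ...) {
  n <- dim(stack$images)[1]
  box_out <- box_out %||% (n %/% 2L)
  vox <- stack$voxel_size_A
  al <- alignments[match(stack$meta$segment_id, alignments$segment_id), ]
  if (any(is.na(al$rot))) abort("missing alignment rows for some segments")
  hp <- helical_params(lattice)
  n_pf <- lattice$n_pf
  n_seg <- nrow(al)
  cpx <- floor(n / 2) + 1

  anchors <- purrr::map_dfr(seq_len(n_pf) - 1L,
                            function(j) pf_anchor_site(lattice, j))
  occ <- stack$volume$meta$occupancy
  # complement volumes (map minus column j) computed once per column
  compl <- lapply(seq_len(n_pf) - 1L, function(j) {
    spec <- wedge_mask_spec(n_pf, j, handedness = lattice$handedness, ...)
    m <- make_wedge_mask(map, spec)
    density_map(map$values * (1 - m$values), map$voxel_size_A)
  })
  images <- array(0, c(box_out, box_out, n_seg * n_pf))
  meta <- vector("list", n_seg * n_pf)
  p <- 0L
  for (i in seq_len(n_seg)) {
    a <- al[i, ]
    R <- euler_matrix(a$rot, a$tilt, a$psi)
    for (j in seq_len(n_pf) - 1L) {
      resid <- stack$images[, , i] -
        project_map(compl[[j + 1]], c(a$rot, a$tilt, a$psi),
                    c(a$shift_x, a$shift_y))
      q <- unlist(anchors[j + 1, c("x", "y", "z")])
      pim <- R %*% q
      cx <- cpx + (pim[1] + a$shift_x) / vox
      cy <- cpx + (pim[2] + a$shift_y) / vox
      p <- p + 1L
      images[, , p] <- crop_shift(resid, cx, cy, box_out)
      truth <- if (!is.null(occ)) {
        o <- occ[occ$pf_index == j, ]
        o <- o[which.min(abs(o$z - anchors$z[j + 1])), ]
        list(motor_true = o$motor_occupied, tail_true = o$tail_occupied)
      } else list(motor_true = NA, tail_true = NA)
      meta[[p]] <- tibble(
        particle_id = p, segment_id = a$segment_id,
        filament_id = a$filament_id, pf_index = j,
        dimer_id = (a$filament_id - 1L) * n_pf + j + 1L,
        rot = wrap360(a$rot + j * hp$twist_deg), tilt = a$tilt, psi = a$psi,
        shift_x = 0, shift_y = 0, cc = NA_real_, class = NA_integer_,
        motor_true = truth$motor_true, tail_true = truth$tail_true)
    }
  }
  structure(list(images = images, meta = dplyr::bind_rows(meta),
                 voxel_size_A = vox, box_out = box_out, lattice = lattice),
            class = "pf_particle_set")
}

#' @export
print.pf_particle_set <- function(x, ...) {
  cat(sprintf("<pf_particle_set> %d particles (%d px box, %.2f A/px)\n",
              dim(x$images)[3], x$box_out, x$voxel_size_A))
  invisible(x)
}

#' Canonical single-protofilament reference volume
#'
#' Masks the reference map down to one column, then translates that column's
#' anchor dimer to the origin so the volume lives in the particle frame used
#' by [extract_pf_particles()]. Projecting it at a particle's recorded Euler
#' angles predicts that particle's image.
#'
#' @param map Symmetrized `density_map`.
#' @param lattice The [lattice_spec()].
#' @param box_out Output box, pixels.
#' @param pf_index Which column to standardise on (default the wedge at
#'   azimuth 0).
#' @param ... Wedge-mask options.
#' @return A `density_map` of edge `box_out`.
#' @export
canonical_pf_volume <- function(map, lattice, box_out, pf_index = 0, ...) {
  sp <- single_pf_map(map, lattice, pf_index, ...)
  q <- unlist(pf_anchor_site(lattice, pf_index)[, c("x", "y", "z")])
  ang <- -lattice$handedness * 360 * pf_index / lattice$n_pf
  # move anchor to origin, then rotate the column to azimuth 0
  moved <- cpp_transform_volume(sp$values, euler_matrix(ang, 0, 0),
                                -(euler_matrix(ang, 0, 0) %*% q) /
                                  map$voxel_size_A)
  n <- box_px(map)
  c0 <- floor(n / 2) + 1
  idx <- c0 + ((seq_len(box_out) - 1) - floor(box_out / 2))
  density_map(moved[idx, idx, idx], map$voxel_size_A)
}

#' Local refinement of protofilament particle alignments
#'
#' Constrained grid search about each particle's initial alignment: the
#' in-plane view angle is scanned over `± ang_range_deg` in `step_deg`
#' increments (tilt and psi held), shifts over an integer-pixel grid within
#' `± shift_range_A`, scoring normalised cross-correlation against
#' projections of the single-protofilament reference. Refined values never
#' leave the stated ranges.
#'
#' @param particles A `pf_particle_set`.
#' @param single_pf_reference Canonical reference from
#'   [canonical_pf_volume()], box matching the particle box.
#' @param ang_range_deg,step_deg Rot search half-range and step, degrees.
#' @param shift_range_A Shift search half-range, Angstroms.
#' @return The particle set with `meta` gaining `rot_refined`,
#'   `shift_x_refined`, `shift_y_refined`, `cc`.
#' @export
local_refine_pf <- function(particles, single_pf_reference,
                            ang_range_deg = 2, step_deg = 1,
                            shift_range_A = 5) {
  if (box_px(single_pf_reference) != particles$box_out)
    abort("reference box does not match particle box")
  if (ang_range_deg <= 0 || shift_range_A < 0 || step_deg <= 0)
    abort("search ranges must be positive")
  vox <- particles$voxel_size_A
  max_shift <- as.integer(floor(shift_range_A / vox))
  deltas <- seq(-ang_range_deg, ang_range_deg, by = step_deg)
  deltas <- deltas[order(abs(deltas))]  # prefer the initial value on ties
  cache <- new.env(parent = emptyenv())
  proj_at <- function(rot, tilt, psi) {
    key <- sprintf("%.6f_%.4f_%.4f", wrap360(rot), tilt, psi)
    got <- cache[[key]]
    if (is.null(got)) {
      p <- project_map(single_pf_reference, c(wrap360(rot), tilt, psi))
      p <- p - mean(p)
      nrm <- sqrt(sum(p^2))
      got <- if (nrm > 0) p / nrm else p
      cache[[key]] <- got
    }
    got
  }
  meta <- particles$meta
  b <- particles$box_out
  res <- purrr::map_dfr(seq_len(nrow(meta)), function(i) {
    gal <- array(0, c(b, b, length(deltas)))
    for (g in seq_along(deltas))
      gal[, , g] <- proj_at(meta$rot[i] + deltas[g], meta$tilt[i], meta$psi[i])
    m <- cpp_match_stack(particles$images[, , i, drop = FALSE], gal, max_shift)
    tibble(rot_refined = wrap360(meta$rot[i] + deltas[m$gallery_index[1]]),
           shift_x_refined = m$dx[1] * vox,
           shift_y_refined = m$dy[1] * vox,
           cc = m$cc[1])
  })
  particles$meta <- dplyr::bind_cols(
    dplyr::select(meta, -dplyr::any_of(c("rot_refined", "shift_x_refined",
                                         "shift_y_refined"))),
    dplyr::select(res, -dplyr::any_of("cc")))
  particles$meta$cc <- res$cc
  particles
}

# back-project particles in the particle frame using chosen alignments
#' Reconstruct a volume from protofilament particles
#'
#' @param particles A `pf_particle_set`.
#' @param use `"initial"` or `"refined"` alignments.
#' @param filter `"ramp"` (filtered back-projection, default) or `"none"`.
#' @return A `density_map` of edge `box_out`.
#' @export
backproject_particles <- function(particles, use = c("initial", "refined"),
                                  filter = c("ramp", "none")) {
  use <- match.arg(use)
  filter <- match.arg(filter)
  meta <- particles$meta
  rots <- if (use == "refined") meta$rot_refined else meta$rot
  sx <- if (use == "refined") meta$shift_x_refined else meta$shift_x
  sy <- if (use == "refined") meta$shift_y_refined else meta$shift_y
  n_img <- nrow(meta)
  Rs <- matrix(0, 3, 3 * n_img)
  for (i in seq_len(n_img))
    Rs[, (3 * i - 2):(3 * i)] <- euler_matrix(rots[i], meta$tilt[i],
                                              meta$psi[i])
  imgs <- particles$images
  if (filter == "ramp")
    for (i in seq_len(n_img)) imgs[, , i] <- ramp_filter_y(imgs[, , i])
  bp <- cpp_backproject(imgs, Rs, cbind(sx, sy) / particles$voxel_size_A)
  vals <- bp$sum
  cover <- bp$weight > 0
  vals[cover] <- vals[cover] / bp$weight[cover]
  density_map(vals, particles$voxel_size_A,
              meta = list(n_zero_coverage = sum(!cover)))
}

#' Focused classification of protofilament particles
#'
#' Alternating hard classification with alignments held fixed: particles are
#' back-projected class-wise into class-average volumes in the particle
#' frame, and each particle is re-assigned to the class whose volume,
#' projected at the particle's own view angles, correlates best with it
#' inside the focus mask. Because particles sit at heterogeneous view
#' angles, class averages are 3D volumes rather than 2D means. Deterministic
#' given the seed (random initial split).
#'
#' @param particles A `pf_particle_set` (refined alignments used when
#'   present).
#' @param k_classes Number of classes (>= 1).
#' @param n_iter Maximum alternation rounds.
#' @param seed Integer seed for the initial split.
#' @param focus_mask Either a 2D 0/1 matrix (particle box) applied to every
#'   particle, or a 3D `density_map` focus region in the particle frame that
#'   is projected at each particle's view angles — the right choice when the
#'   focus sits off-axis (a tail site), because its image position moves with
#'   the view. Default: a centred disc of radius 45% of the particle box.
#' @param group Optional name of a `meta` column identifying particles that
#'   image the same physical unit (e.g. `"dimer_id"` when several segments
#'   view the same dimer). Class scores are pooled within a group and the
#'   group is assigned one label: a single 2D view of an off-axis site is
#'   often partly occluded by the rest of the lattice, and pooling the views
#'   of one unit restores the contrast. `NULL` assigns per particle.
#' @param init `"focus"` (default) splits on the mean density inside the
#'   focus region — the quantity the classification is focused on — before
#'   alternation; `"random"` uses a seeded random split.
#' @return A list of class `focused_classes`: `labels` (integer per
#'   particle), `class_volumes` (list of `density_map`), `fractions`,
#'   `n_iter_run`, `empty_class_flag` (a class emptied), `degenerate_flag`
#'   (the alternation cycled without finding a stable split), and
#'   `changed_last`.
#' @export
focused_classify <- function(particles, k_classes = 2, n_iter = 8, seed = 1,
                             focus_mask = NULL, group = NULL,
                             init = c("focus", "random")) {
  init <- match.arg(init)
  P <- dim(particles$images)[3]
  if (k_classes < 1) abort("k_classes must be >= 1")
  if (k_classes > P) abort("k_classes exceeds the number of particles")
  b <- particles$box_out
  vox <- particles$voxel_size_A
  meta <- particles$meta
  refined <- "rot_refined" %in% names(meta) && !anyNA(meta$rot_refined)
  rots <- if (refined) meta$rot_refined else meta$rot
  sx <- if (refined) meta$shift_x_refined else meta$shift_x
  sy <- if (refined) meta$shift_y_refined else meta$shift_y
  if (is.null(focus_mask)) {
    ax <- axis_coords(b, vox)
    focus_mask <- (sqrt(outer(ax^2, ax^2, "+")) <= 0.45 * b * vox) * 1
  }
  mask3d <- NULL
  if (inherits(focus_mask, "density_map")) {
    if (box_px(focus_mask) != b) abort("3D focus mask box mismatch")
    mask3d <- focus_mask$values
  }
  mask_for <- function(R) {
    if (is.null(mask3d)) return(focus_mask > 0.5)
    pm <- cpp_project(mask3d, R, 0, 0)
    pm > 0.05 * max(pm)
  }

  grp <- if (is.null(group)) seq_len(P) else {
    if (!group %in% names(meta)) abort(sprintf("no meta column '%s'", group))
    as.integer(factor(meta[[group]]))
  }
  set.seed(seed)
  if (init == "random") {
    glab <- sample(rep_len(seq_len(k_classes), max(grp)))
    labels <- glab[grp]
  } else {
    # initial split on the mean density inside the (projected) focus region
    feat <- vapply(seq_len(P), function(i) {
      R <- euler_matrix(rots[i], meta$tilt[i], meta$psi[i])
      keep <- mask_for(R)
      mean(particles$images[, , i][keep])
    }, numeric(1))
    gfeat <- as.numeric(tapply(feat, grp, mean))
    qs <- quantile(gfeat, probs = seq_len(k_classes - 1) / k_classes)
    glab <- as.integer(cut(gfeat, c(-Inf, qs, Inf), labels = FALSE))
    labels <- glab[grp]
  }
  if (k_classes == 1) labels <- rep(1L, P)

  filtered <- particles$images
  for (i in seq_len(P)) filtered[, , i] <- ramp_filter_y(filtered[, , i])
  sub_bp <- function(idx) {
    ni <- length(idx)
    Rs <- matrix(0, 3, 3 * ni)
    for (m in seq_len(ni)) {
      i <- idx[m]
      Rs[, (3 * m - 2):(3 * m)] <- euler_matrix(rots[i], meta$tilt[i],
                                                meta$psi[i])
    }
    bp <- cpp_backproject(filtered[, , idx, drop = FALSE], Rs,
                          cbind(sx[idx], sy[idx]) / vox)
    v <- bp$sum
    cov <- bp$weight > 0
    v[cov] <- v[cov] / bp$weight[cov]
    v
  }

  empty_flag <- FALSE
  degenerate_flag <- FALSE
  seen <- character()
  changed <- NA_integer_
  it_run <- 0L
  vols <- NULL
  for (it in seq_len(max(1L, n_iter))) {
    it_run <- it
    vols <- lapply(seq_len(k_classes), function(k) sub_bp(which(labels == k)))
    if (k_classes == 1) break
    cache <- new.env(parent = emptyenv())
    score <- matrix(0, P, k_classes)
    for (i in seq_len(P)) {
      key <- sprintf("%.6f_%.4f_%.4f", wrap360(rots[i]), meta$tilt[i],
                     meta$psi[i])
      R <- euler_matrix(rots[i], meta$tilt[i], meta$psi[i])
      pr <- cache[[key]]
      if (is.null(pr)) {
        pr <- c(lapply(vols, function(v) cpp_project(v, R, 0, 0)),
                list(keep = mask_for(R)))
        cache[[key]] <- pr
      }
      keep <- pr$keep
      img <- crop_shift(particles$images[, , i], floor(b / 2) + 1 + sx[i] / vox,
                        floor(b / 2) + 1 + sy[i] / vox, b)
      iv <- img[keep]
      iv <- iv - mean(iv)
      nv <- sqrt(sum(iv^2))
      if (nv > 0) iv <- iv / nv
      n_in_class <- tabulate(labels, k_classes)
      for (k in seq_len(k_classes)) {
        tv <- pr[[k]][keep]
        # leave-one-out: a particle's own (noisy) contribution to its class
        # average re-projects to roughly itself; the resulting
        # self-correlation freezes the alternation at low SNR
        if (k == labels[i] && n_in_class[k] > 1)
          tv <- (tv * n_in_class[k] - img[keep]) / (n_in_class[k] - 1)
        tv <- tv - mean(tv)
        ntv <- sqrt(sum(tv^2))
        score[i, k] <- if (ntv > 0) sum(iv * tv / ntv) else 0
      }
    }
    gscore <- rowsum(score, grp)
    new_labels <- max.col(gscore, ties.method = "first")[grp]
    if (length(unique(new_labels)) < k_classes) {
      empty_flag <- TRUE
      changed <- sum(new_labels != labels)
      break
    }
    changed <- sum(new_labels != labels)
    labels <- new_labels
    if (changed == 0) break
    key <- paste(labels, collapse = "")
    if (key %in% seen) {
      # alternation cycles without progress: no stable split exists
      degenerate_flag <- TRUE
      break
    }
    seen <- c(seen, key)
  }
  structure(list(
    labels = labels,
    class_volumes = lapply(vols, density_map, voxel_size_A = vox),
    fractions = as.numeric(table(factor(labels, seq_len(k_classes)))) / P,
    n_iter_run = it_run, empty_class_flag = empty_flag,
    degenerate_flag = degenerate_flag,
    changed_last = changed), class = "focused_classes")
}

#' @export
print.focused_classes <- function(x, ...) {
  cat(sprintf("<focused_classes> %d classes, fractions %s%s\n",
              length(x$class_volumes),
              paste(sprintf("%.2f", x$fractions), collapse = "/"),
              if (x$empty_class_flag) " [empty-class flag]" else ""))
  invisible(x)
}
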