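#' Cubic density map
#'
#' A light container for a cubic 3D density grid: a numeric array plus the
#' voxel size in Angstroms. The geometric origin sits at voxel
#' `floor(N/2) + 1` (1-based) on each axis, and in the model frame the
#' microtubule axis runs along z.
#'
#' @param values Cubic numeric 3D array.
#' @param voxel_size_A Voxel edge length in Angstroms.
#' @param meta Optional named list of provenance metadata.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, voxel_size_A, meta = list()) {
  d <- dim(values)
  if (length(d) != 3 || length(unique(d)) != 1)
    abort("values must be a cubic 3D array")
  if (any(is.nan(values)) || any(is.infinite(values)))
    abort("values must be finite (NA allowed for undefined voxels)")
  if (voxel_size_A <= 0) abort("voxel_size_A must be > 0")
  structure(list(values = values, voxel_size_A = voxel_size_A, meta = meta),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  n <- dim(x$values)[1]
  cat(sprintf("<density_map> %d^3 voxels, %.3f A/voxel (%.1f A box)\n",
              n, x$voxel_size_A, n * x$voxel_size_A))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

box_px <- function(map) dim(map$values)[1]
box_A <- function(map) dim(map$values)[1] * map$voxel_size_A

#' Density model specification for synthetic decorated microtubules
#'
#' Per-species Gaussian blob parameters used by [build_volume()]. Tubulin
#' monomers sit on the lattice cylinder; motor blobs sit radially outward of
#' their beta-tubulin site and tail blobs outward of the motor.
#'
#' @param voxel_size_A Voxel size, Angstroms.
#' @param box_px Cubic box edge in voxels.
#' @param amp Named amplitudes (arbitrary density units) for `alpha`, `beta`,
#'   `motor`, `tail`.
#' @param sigma_A Named isotropic Gaussian sigmas (Angstroms), same names.
#' @param motor_occupancy,tail_occupancy Bernoulli occupancy probabilities per
#'   dimer site, in `[0, 1]`. Tail occupancy is conditional on a motor being
#'   present.
#' @param motor_radius_offset_A,tail_radius_offset_A Radial offsets of the
#'   blob centres from the tubulin cylinder, Angstroms.
#' @return A list of class `density_spec`.
#' @export
density_spec <- function(voxel_size_A = 5.5, box_px = 72,
                         amp = c(alpha = 1, beta = 1, motor = 1, tail = 1),
                         sigma_A = c(alpha = 9, beta = 9, motor = 10, tail = 10),
                         motor_occupancy = 1, tail_occupancy = 0,
                         motor_radius_offset_A = 35,
                         tail_radius_offset_A = 55) {
  if (voxel_size_A <= 0) abort("voxel_size_A must be > 0")
  if (motor_occupancy < 0 || motor_occupancy > 1 ||
      tail_occupancy < 0 || tail_occupancy > 1)
    abort("occupancies must lie in [0, 1]")
  need <- c("alpha", "beta", "motor", "tail")
  if (!all(need %in% names(amp)) || !all(need %in% names(sigma_A)))
    abort("amp and sigma_A must name alpha, beta, motor and tail")
  structure(list(voxel_size_A = voxel_size_A, box_px = as.integer(box_px),
                 amp = amp, sigma_A = sigma_A,
                 motor_occupancy = motor_occupancy,
                 tail_occupancy = tail_occupancy,
                 motor_radius_offset_A = motor_radius_offset_A,
                 tail_radius_offset_A = tail_radius_offset_A),
            class = "density_spec")
}

# voxel-centre coordinate vector (Angstroms) for one axis
axis_coords <- function(n, voxel) (seq_len(n) - 1 - floor(n / 2)) * voxel

#' Build a decorated microtubule density volume
#'
#' Sums isotropic Gaussian blobs at every tubulin monomer site of the lattice
#' and, with the given occupancy probabilities, at motor and tail sites
#' attached to each dimer. Occupancy draws are recorded per site so the
#' ground truth is available to downstream classification tests.
#'
#' Blobs whose radial (x/y) support of 3 sigma would leave the box raise an
#' error naming the offending site; axial (z) clipping at the box face is
#' allowed, since a filament volume intentionally fills the box along its
#' axis.
#'
#' @param lattice A [lattice_spec()].
#' @param dens A [density_spec()].
#' @param seed Integer seed for the occupancy draws.
#' @param n_dimer_repeats Dimer repeats along z; default fills the box.
#' @return A `density_map` whose `meta$sites` tibble carries per-site
#'   positions, species and occupancy flags, and `meta$lattice`/`meta$dens`
#'   echo the generating parameters.
#' @export
build_volume <- function(lattice, dens, seed = 1, n_dimer_repeats = NULL) {
  validate_lattice_spec(lattice)
  n <- dens$box_px
  vox <- dens$voxel_size_A
  if (is.null(n_dimer_repeats))
    n_dimer_repeats <- ceiling(n * vox / (2 * lattice$monomer_rise_A)) + 1L
  sites <- lattice_positions(lattice, n_dimer_repeats)
  sites$species <- sites$kind
  sites$amp <- unname(dens$amp[sites$kind])
  sites$sigma <- unname(dens$sigma_A[sites$kind])

  # decoration: one motor (and optionally tail) site per dimer, anchored at
  # the beta monomer, offset radially outward
  withr_seed <- seed
  set.seed(withr_seed)
  beta <- sites[sites$kind == "beta", ]
  rr <- sqrt(beta$x^2 + beta$y^2)
  ux <- beta$x / rr
  uy <- beta$y / rr
  motor_on <- rbinom(nrow(beta), 1, dens$motor_occupancy) == 1
  tail_on <- motor_on & (rbinom(nrow(beta), 1, dens$tail_occupancy) == 1)
  deco <- function(offset, species, on) {
    k <- tibble(
      pf_index = beta$pf_index, axial_index = beta$axial_index,
      kind = species, x = beta$x + ux * offset, y = beta$y + uy * offset,
      z = beta$z, theta_deg = beta$theta_deg, species = species,
      amp = unname(dens$amp[species]), sigma = unname(dens$sigma_A[species])
    )
    k[on, , drop = FALSE]
  }
  motors <- deco(dens$motor_radius_offset_A, "motor", motor_on)
  tails <- deco(dens$tail_radius_offset_A, "tail", tail_on)
  all_sites <- dplyr::bind_rows(sites[, names(motors)], motors, tails)

  half <- n * vox / 2
  bad <- abs(all_sites$x) + 3 * all_sites$sigma > half |
    abs(all_sites$y) + 3 * all_sites$sigma > half
  if (any(bad)) {
    b <- all_sites[which(bad)[1], ]
    abort(sprintf(
      "blob exceeds box radially: %s site at pf %d, axial %d (x=%.1f, y=%.1f, sigma=%.1f A, half-box %.1f A)",
      b$species, b$pf_index, b$axial_index, b$x, b$y, b$sigma, half))
  }

  ax <- axis_coords(n, vox)
  vol <- array(0, c(n, n, n))
  # accumulate each blob over its local support only
  for (i in seq_len(nrow(all_sites))) {
    s <- all_sites[i, ]
    r3 <- 3.5 * s$sigma
    ix <- which(abs(ax - s$x) <= r3)
    iy <- which(abs(ax - s$y) <= r3)
    iz <- which(abs(ax - s$z) <= r3)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(ax[ix] - s$x)^2 / (2 * s$sigma^2))
    gy <- exp(-(ax[iy] - s$y)^2 / (2 * s$sigma^2))
    gz <- exp(-(ax[iz] - s$z)^2 / (2 * s$sigma^2))
    blob <- s$amp * outer(outer(gx, gy), gz)
    vol[ix, iy, iz] <- array(vol[ix, iy, iz], dim(blob)) + blob
  }

  occupancy <- tibble(pf_index = beta$pf_index,
                      axial_index = beta$axial_index,
                      z = beta$z,
                      motor_occupied = motor_on, tail_occupied = tail_on)
  density_map(vol, vox, meta = list(sites = all_sites, occupancy = occupancy,
                                    lattice = lattice, dens = dens,
                                    seed = seed))
}

#' Project a density map
#'
#' Line integral of the map along the viewing axis after rotating by the ZYZ
#' Euler angles and shifting in-plane. The projection is exactly linear in
#' the map for a fixed orientation, which downstream signal subtraction
#' relies on.
#'
#' @param map A `density_map`.
#' @param euler Length-3 numeric `(rot, tilt, psi)` in degrees.
#' @param shift_A Length-2 in-plane shift `(x, y)` in Angstroms applied to
#'   the image content.
#' @return A numeric matrix (`n x n` image, in density * voxel units).
#' @export
project_map <- function(map, euler = c(0, 0, 0), shift_A = c(0, 0)) {
  stopifnot(inherits(map, "density_map"))
  R <- euler_matrix(euler[1], euler[2], euler[3])
  cpp_project(map$values, R, shift_A[1] / map$voxel_size_A,
              shift_A[2] / map$voxel_size_A)
}

#' Apply a rigid transform to a density map
#'
#' Resamples the map under `y = R x + t` by trilinear interpolation.
#'
#' @param map A `density_map`.
#' @param tf A `rigid_transform` with translation in Angstroms.
#' @return A transformed `density_map`.
#' @export
transform_map <- function(map, tf) {
  stopifnot(inherits(map, "density_map"), inherits(tf, "rigid_transform"))
  vals <- cpp_transform_volume(map$values, tf$R, tf$t / map$voxel_size_A)
  density_map(vals, map$voxel_size_A, meta = map$meta)
}

#' Normalised cross-correlation between two arrays
#'
#' Pearson correlation of the (optionally masked) voxel/pixel values.
#'
#' @param a,b Numeric arrays of identical dimension.
#' @param mask Optional logical/0-1 array selecting the region to compare.
#' @return NCC in `[-1, 1]`.
#' @export
ncc <- function(a, b, mask = NULL) {
  if (inherits(a, "density_map")) a <- a$values
  if (inherits(b, "density_map")) b <- b$values
  if (!is.null(mask)) {
    keep <- as.logical(mask)
    a <- a[keep]
    b <- b[keep]
  }
  av <- a - mean(a)
  bv <- b - mean(b)
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den == 0) return(0)
  sum(av * bv) / den
}

#' Spherical focus mask
#'
#' A 0/1 ball in a cubic grid, for use as a 3D focus region (e.g. around a
#' tail-binding site) in [focused_classify()].
#'
#' @param box_px Cubic box edge, voxels.
#' @param voxel_size_A Voxel size, Angstroms.
#' @param center_A Ball centre `(x, y, z)` in Angstroms, model/particle frame.
#' @param radius_A Ball radius, Angstroms.
#' @return A `density_map` with 0/1 values.
#' @export
ball_mask <- function(box_px, voxel_size_A, center_A, radius_A) {
  ax <- axis_coords(box_px, voxel_size_A)
  dx2 <- (ax - center_A[1])^2
  dy2 <- (ax - center_A[2])^2
  dz2 <- (ax - center_A[3])^2
  v <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius_A^2
  density_map(array(as.numeric(v), rep(box_px, 3)), voxel_size_A)
}

# soft or hard cylindrical mask (axis along z), radii in Angstroms
cylinder_mask <- function(n, voxel, r_outer, r_inner = 0, soft_A = 0) {
  ax <- axis_coords(n, voxel)
  r <- sqrt(outer(ax^2, ax^2, "+"))   # n x n radius in xy
  m2 <- matrix(1, n, n)
  ramp <- function(d, s) ifelse(d <= 0, 1, ifelse(d >= s, 0, 0.5 * (1 + cos(pi * d / s))))
  if (soft_A > 0) {
    m2 <- ramp(r - r_outer, soft_A)
    if (r_inner > 0) m2 <- m2 * ramp(r_inner - r, soft_A)
  } else {
    m2 <- (r <= r_outer) * (r >= r_inner)
  }
  array(rep(m2, n), c(n, n, n))
}
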