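#' Microtubule lattice specification
#'
#' Describes the pseudo-helical monomer lattice of a microtubule: `n_pf`
#' protofilament columns of alternating alpha/beta tubulin on a cylinder,
#' related laterally by a `start_number`-start helix. The defaults give the
#' canonical in-vitro lattice with an ~82 Angstrom dimer repeat.
#'
#' @param n_pf Protofilament count (11-16).
#' @param start_number Lateral helix start number (monomers climbed per full
#'   turn). Default 3.
#' @param monomer_rise_A Axial monomer spacing along one protofilament in
#'   Angstroms. Default 40.95 (dimer repeat 81.9 A).
#' @param radius_A Cylinder radius to monomer centres, Angstroms.
#' @param pf_skew_deg Protofilament skew per monomer, degrees (0 = ideal
#'   unskewed lattice).
#' @param seam_index Column index (0-based) at which the alpha/beta lateral
#'   register break sits.
#' @param handedness Sign of the lateral twist, +1 or -1. The lateral monomer
#'   helix is left-handed by default.
#' @return An object of class `lattice_spec`.
#' @export
#' @examples
#' lattice_spec(n_pf = 14)
lattice_spec <- function(n_pf = 14, start_number = 3, monomer_rise_A = 40.95,
                         radius_A = 110, pf_skew_deg = 0, seam_index = 0,
                         handedness = -1) {
  spec <- structure(
    list(n_pf = as.integer(n_pf), start_number = as.integer(start_number),
         monomer_rise_A = monomer_rise_A, radius_A = radius_A,
         pf_skew_deg = pf_skew_deg, seam_index = as.integer(seam_index),
         handedness = as.integer(handedness)),
    class = "lattice_spec"
  )
  validate_lattice_spec(spec)
  spec
}

validate_lattice_spec <- function(spec) {
  if (!inherits(spec, "lattice_spec")) abort("not a lattice_spec")
  if (spec$n_pf < 11 || spec$n_pf > 16)
    abort(sprintf("n_pf must be in [11, 16], got %d", spec$n_pf))
  if (spec$monomer_rise_A <= 0) abort("monomer_rise_A must be > 0")
  if (spec$radius_A <= 0) abort("radius_A must be > 0")
  if (spec$seam_index < 0 || spec$seam_index >= spec$n_pf)
    abort("seam_index must satisfy 0 <= seam_index < n_pf")
  if (!spec$handedness %in% c(-1L, 1L)) abort("handedness must be +1 or -1")
  invisible(spec)
}

#' @export
print.lattice_spec <- function(x, ...) {
  hp <- helical_params(x)
  cat(sprintf(
    "<lattice_spec> %d pf, %d-start, monomer rise %.2f A, radius %.1f A\n",
    x$n_pf, x$start_number, x$monomer_rise_A, x$radius_A))
  cat(sprintf("  one-start helix: twist %.4f deg, rise %.4f A; seam at pf %d\n",
              hp$twist_deg, hp$rise_A, x$seam_index))
  invisible(x)
}

#' Helical parameters of the monomer lattice
#'
#' The one-start helical parameters relating laterally adjacent monomers:
#' `twist = handedness * 360 / n_pf` degrees and
#' `rise = start_number * monomer_rise / n_pf` Angstroms. These are the
#' parameters used to generate and average the N symmetry-related copies of
#' an asymmetric microtubule reconstruction.
#'
#' @param spec A [lattice_spec()].
#' @return An object of class `helical_params` with fields `twist_deg` and
#'   `rise_A`.
#' @export
#' @examples
#' helical_params(lattice_spec(n_pf = 13))  # 27.69 deg, 9.45 A
helical_params <- function(spec) {
  validate_lattice_spec(spec)
  new_helical_params(spec$handedness * 360 / spec$n_pf,
                     spec$start_number * spec$monomer_rise_A / spec$n_pf)
}

new_helical_params <- function(twist_deg, rise_A) {
  if (rise_A <= 0) abort("rise_A must be > 0")
  if (abs(twist_deg) > 360 / 11 + 1e-9)
    abort("|twist_deg| must not exceed 360/11 (lattices have >= 11 pf)")
  structure(list(twist_deg = twist_deg, rise_A = rise_A),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("<helical_params> twist %.4f deg, rise %.4f A per subunit\n",
              x$twist_deg, x$rise_A))
  invisible(x)
}

#' Monomer site positions of a microtubule lattice
#'
#' Lays out `n_pf * 2 * n_dimer_repeats` monomer sites. Column `j` sits at
#' azimuth `j * handedness * 360 / n_pf` and climbs by the lateral rise
#' `start_number * monomer_rise / n_pf`; within a column monomers alternate
#' alpha/beta every `monomer_rise_A`. The 3-monomer climb per turn forces a
#' single register break (the seam), which is placed at the boundary entering
#' column `seam_index`.
#'
#' @param spec A [lattice_spec()].
#' @param n_dimer_repeats Number of dimer repeats along each protofilament.
#' @param centered Centre the axial extent on z = 0 (default TRUE).
#' @return A tibble with columns `pf_index`, `axial_index`, `kind`
#'   (alpha/beta), `x`, `y`, `z` (Angstroms), `theta_deg`.
#' @export
#' @examples
#' nrow(lattice_positions(lattice_spec(n_pf = 13), 1))  # 26 sites
lattice_positions <- function(spec, n_dimer_repeats, centered = TRUE) {
  validate_lattice_spec(spec)
  if (n_dimer_repeats < 1) abort("n_dimer_repeats must be >= 1")
  n_ax <- 2L * as.integer(n_dimer_repeats)
  rise_lat <- spec$start_number * spec$monomer_rise_A / spec$n_pf
  grid <- tidyr::expand_grid(pf_index = seq_len(spec$n_pf) - 1L,
                             axial_index = seq_len(n_ax) - 1L)
  # shifted column index so the start-helix wrap (the seam) lands at the
  # boundary entering seam_index
  jshift <- (grid$pf_index - spec$seam_index) %% spec$n_pf
  theta <- spec$handedness * 360 * grid$pf_index / spec$n_pf +
    spec$pf_skew_deg * grid$axial_index
  z <- grid$axial_index * spec$monomer_rise_A + jshift * rise_lat
  if (centered) z <- z - mean(range(z))
  tibble(
    pf_index = grid$pf_index,
    axial_index = grid$axial_index,
    kind = ifelse(grid$axial_index %% 2L == 0L, "alpha", "beta"),
    x = spec$radius_A * cos(theta * pi / 180),
    y = spec$radius_A * sin(theta * pi / 180),
    z = z,
    theta_deg = wrap360(theta)
  )
}

#' Protofilament symmetry transform
#'
#' The rigid transform relating subunit `k` of the one-start lattice helix to
#' subunit 0: rotation by `k * twist` about z composed with translation
#' `k * rise` along z. `pf_symmetry_transform(params, 0)` is the identity and
#' the transforms compose additively in `k`.
#'
#' @param params A [helical_params()] object.
#' @param k Integer subunit step (may be negative).
#' @return A list with `R` (3x3 rotation) and `t` (length-3 translation,
#'   Angstroms), class `rigid_transform`.
#' @export
pf_symmetry_transform <- function(params, k) {
  stopifnot(inherits(params, "helical_params"))
  a <- k * params$twist_deg * pi / 180
  structure(list(
    R = matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3),
    t = c(0, 0, k * params$rise_A)
  ), class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param tf A `rigid_transform` (see [pf_symmetry_transform()]).
#' @param xyz A numeric matrix with 3 columns, or length-3 vector.
#' @return Transformed coordinates, same shape.
#' @export
apply_transform <- function(tf, xyz) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  sweep(xyz %*% t(tf$R), 2, -tf$t)
}

# compose two rigid transforms: a after b
compose_transform <- function(a, b) {
  structure(list(R = a$R %*% b$R, t = as.vector(a$R %*% b$t) + a$t),
            class = "rigid_transform")
}
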