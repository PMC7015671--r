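test_that("projection matching recovers gallery members exactly", {
  sym <- fx_sym14()
  gal <- make_gallery(sym, angular_step_deg = 24)
  n <- dim(gal$images)[1]
  pick <- c(2, 7, 12)
  stack <- structure(list(
    images = gal$images[, , pick],
    meta = tibble::tibble(segment_id = seq_along(pick),
                          filament_id = 1, segment_index = seq_along(pick)),
    voxel_size_A = sym$voxel_size_A), class = "segment_stack")
  al <- projection_match(stack, sym, angular_step_deg = 24, shift_range_A = 6)
  expect_equal(al$rot, gal$angles$rot[pick])
  expect_true(all(al$cc_score > 1 - 1e-6))
  expect_equal(al$shift_x, rep(0, 3), tolerance = 1e-9)
})

test_that("off-grid orientations are recovered within half a step and one shift step", {
  sym <- fx_sym14()
  st <- fx_stack_sym()
  al <- projection_match(st, sym, angular_step_deg = 4, shift_range_A = 8)
  err <- ang_dist(al$rot, st$meta$rot)
  expect_gte(mean(err <= 2 + 1e-9), 0.9)   # within step/2 almost always
  expect_true(all(err <= 4 + 1e-9))        # never more than one step off
  expect_true(all(abs(al$shift_x - st$meta$shift_x) <= st$voxel_size_A))
  expect_true(all(abs(al$shift_y - st$meta$shift_y) <= st$voxel_size_A))
})

test_that("pure-noise images correlate weakly with the gallery", {
  sym <- fx_sym14()
  set.seed(3)
  n <- dim(sym$values)[1]
  stack <- structure(list(
    images = array(rnorm(n * n * 6), c(n, n, 6)),
    meta = tibble::tibble(segment_id = 1:6, filament_id = 1,
                          segment_index = 1:6),
    voxel_size_A = sym$voxel_size_A), class = "segment_stack")
  al <- projection_match(stack, sym, angular_step_deg = 8, shift_range_A = 0)
  expect_lt(mean(al$cc_score), 0.2)
  expect_error(projection_match(stack, sym, angular_step_deg = 0), "angular")
})

test_that("back-projection localises a point source and flags coverage", {
  n <- 48
  ps <- array(0, c(n, n, n))
  ps[30, 22, 28] <- 1
  psm <- density_map(ps, 2)
  angles <- c(0, 45, 90, 135, 200, 260, 310)
  imgs <- array(0, c(n, n, length(angles)))
  for (i in seq_along(angles))
    imgs[, , i] <- project_map(psm, c(angles[i], 90, 0))
  stack <- structure(list(
    images = imgs,
    meta = tibble::tibble(segment_id = seq_along(angles), filament_id = 1,
                          segment_index = seq_along(angles)),
    voxel_size_A = 2), class = "segment_stack")
  al <- tibble::tibble(segment_id = seq_along(angles), filament_id = 1,
                       segment_index = seq_along(angles), rot = angles,
                       tilt = 90, psi = 0, shift_x = 0, shift_y = 0,
                       cc_score = 1, pf_assignment = NA_integer_)
  bp <- backproject(stack, al)
  mx <- which(bp$values == max(bp$values), arr.ind = TRUE)
  expect_equal(as.integer(mx[1, ]), c(30, 22, 28))

  # a single image back-projects to density constant along the beam
  one <- structure(list(images = imgs[, , 1, drop = FALSE],
                        meta = stack$meta[1, ], voxel_size_A = 2),
                   class = "segment_stack")
  bp1 <- backproject(one, al[1, ], filter = "none")
  # beam at rot 0, tilt 90 runs along model x: profiles along x are constant
  inner <- 10:38
  profs <- bp1$values[inner, 22, 28]
  expect_lt(diff(range(profs)), 1e-6 * max(abs(bp1$values)))
})

test_that("match + backproject + symmetrize reproduces a noiseless map", {
  lat <- fx_lat14()
  hp <- fx_hp14()
  st <- fx_stack_sym4()
  al <- projection_match(st, fx_sym14(), angular_step_deg = 4,
                         shift_range_A = 8)
  rec <- symmetrize(backproject(st, al), hp, 14)
  m <- central_mask(rec, r_outer = 170)
  expect_gt(ncc(rec$values[m], fx_sym14()$values[m]), 0.95)
})

test_that("helical parameter estimation recovers the generating twist and rise", {
  hp <- fx_hp14()
  est <- estimate_helical_params(
    fx_sym14(), hp,
    twist_range = hp$twist_deg + c(-1, 1),
    rise_range = hp$rise_A + c(-0.5, 0.5),
    grid_step = c(0.25, 0.1))
  expect_lt(abs(est$twist_deg - hp$twist_deg), 0.25)
  expect_lt(abs(est$rise_A - hp$rise_A), 0.1)
  expect_false(attr(est, "boundary_flag"))
  expect_false(attr(est, "flat_flag"))
})

test_that("parameter search flags flat surfaces and range boundaries", {
  hp <- fx_hp14()
  n <- 32
  ax <- (seq_len(n) - 1 - floor(n / 2)) * 5
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  ball <- density_map(exp(-r2 / (2 * 40^2)), 5)
  g <- kinhelix:::new_helical_params(-20, 8)
  est <- estimate_helical_params(ball, g, c(-22, -18), c(7, 9),
                                 grid_step = c(1, 0.5))
  expect_true(attr(est, "flat_flag"))
  expect_equal(est$twist_deg, g$twist_deg)

  est2 <- estimate_helical_params(
    fx_sym14(), kinhelix:::new_helical_params(hp$twist_deg + 1.8,
                                              hp$rise_A),
    twist_range = hp$twist_deg + c(1.0, 2.0),
    rise_range = hp$rise_A + c(-0.2, 0.2),
    grid_step = c(0.25, 0.1))
  expect_true(attr(est2, "boundary_flag"))
  expect_error(estimate_helical_params(fx_sym14(), hp,
                                       hp$twist_deg + c(1, 2),
                                       hp$rise_A + c(-1, 1)),
               "bracket")
})

test_that("estimation error shrinks as the grid is refined", {
  hp <- fx_hp14()
  errs <- vapply(c(0.8, 0.4, 0.2), function(step) {
    est <- estimate_helical_params(
      fx_sym14(), hp, hp$twist_deg + c(-1.6, 1.6),
      hp$rise_A + c(-0.6, 0.6), grid_step = c(step, step / 4))
    abs(est$twist_deg - hp$twist_deg)
  }, numeric(1))
  expect_lte(errs[3], errs[1] + 1e-3)      # refinement never makes it worse
  expect_true(all(errs < c(0.4, 0.2, 0.1) + 1e-9))  # always below step/2
})

test_that("symmetrization is idempotent and averages noise by 1/N", {
  hp <- fx_hp14()
  sym <- fx_sym14()
  sym2 <- symmetrize(sym, hp, 14)
  m <- central_mask(sym, r_outer = 170)
  expect_gt(ncc(sym2$values[m], sym$values[m]), 0.99)

  set.seed(8)
  n <- dim(sym$values)[1]
  noise <- density_map(array(rnorm(n^3), c(n, n, n)), sym$voxel_size_A)
  snoise <- symmetrize(noise, hp, 14)
  core <- central_mask(sym, r_outer = 120, z_margin_A = 75)
  ratio <- var(snoise$values[core]) / var(noise$values[core])
  # interpolation smooths each transformed copy, so the reduction can
  # overshoot 1/N somewhat; it must sit near 1/14, far from 1
  expect_lt(ratio, 1.6 / 14)
  expect_gt(ratio, 0.2 / 14)
})

test_that("symmetrizing a map with one removed site dilutes it by (N-1)/N", {
  lat <- fx_lat14()
  hp <- fx_hp14()
  full <- fx_vol14()
  # remove one beta-tubulin blob analytically: alpha and beta amplitudes are
  # equal, so every symmetry copy carries an identical blob at this radius
  # regardless of the seam's alpha/beta register swap, and the averaging
  # arithmetic is exactly (N-1)/N. (A motor blob would not do: copies whose
  # one-start path wraps past the seam land on alpha sites, the documented
  # alpha/beta ambiguity of monomer-lattice averaging.)
  sites <- full$meta$sites
  mo <- sites[sites$species == "beta", ]
  pick <- mo[which.min(abs(mo$z) + abs(mo$theta_deg)), ]
  n <- dim(full$values)[1]
  ax <- (seq_len(n) - 1 - floor(n / 2)) * full$voxel_size_A
  gx <- exp(-(ax - pick$x)^2 / (2 * pick$sigma^2))
  gy <- exp(-(ax - pick$y)^2 / (2 * pick$sigma^2))
  gz <- exp(-(ax - pick$z)^2 / (2 * pick$sigma^2))
  blob <- pick$amp * outer(outer(gx, gy), gz)
  missing <- density_map(full$values - blob, full$voxel_size_A)
  sym_missing <- symmetrize(missing, hp, 14)
  sym_full <- symmetrize(full, hp, 14)
  # compare summed density in a ball around the site: integrals survive the
  # interpolation of the symmetry copies better than single voxels
  ball <- ball_mask(n, full$voxel_size_A,
                    c(pick$x, pick$y, pick$z), 18)$values > 0.5
  v_missing <- sum(sym_missing$values[ball])
  v_full <- sum(sym_full$values[ball])
  expect_equal(v_missing / v_full, 13 / 14, tolerance = 0.03)
})

test_that("ihrsr returns the input at n_iter 0 and converges on noiseless data", {
  lat <- fx_lat14()
  hp <- fx_hp14()
  st <- fx_stack_sym4()
  r0 <- ihrsr_refine(st, fx_sym14(), hp, 14, n_iter = 0)
  expect_identical(r0$map$values, fx_sym14()$values)
  expect_equal(nrow(r0$log), 0)

  init <- apply_bfactor(fx_sym14(), 800)
  pert <- kinhelix:::new_helical_params(hp$twist_deg + 0.5, hp$rise_A - 0.3)
  res <- ihrsr_refine(st, init, pert, 14, n_iter = 4,
                      angular_step_deg = 4, shift_range_A = 8)
  lg <- res$log
  expect_gte(nrow(lg), 2)
  last2 <- utils::tail(lg$twist_deg, 2)
  expect_lt(abs(diff(last2)), 0.05)
  expect_lt(abs(res$params$rise_A - hp$rise_A), 0.1)
  # map agreement with the generating truth does not degrade over rounds
  expect_true(all(diff(lg$mean_cc) > -0.02))
})

test_that("filaments sort to their protofilament number, improving with SNR", {
  dens <- fx_dens()
  lats <- lapply(c(13, 14, 15), function(n) lattice_spec(n_pf = n))
  refs <- lapply(lats, function(l)
    symmetrize(build_volume(l, dens, seed = 1), helical_params(l), l$n_pf))
  names(refs) <- c("13", "14", "15")
  acc_at <- function(snr, seeds = 21:23) {
    stacks <- purrr::map2(lats, seeds, function(l, s)
      simulate_segment_stack(l, dens, n_filaments = 2,
                             filament_len_A = 1300, snr = snr, seed = s))
    st <- merge_stacks(stacks)
    srt <- sort_pf_number(st, refs, angular_step_deg = 6, shift_range_A = 6)
    truth <- rep(c(13, 14, 15), each = 2)
    mean(srt$filaments$pf_assignment == truth, na.rm = FALSE)
  }
  a_clean <- acc_at(Inf)
  a_low <- acc_at(0.1)
  a_tiny <- acc_at(0.02)
  expect_equal(a_clean, 1)
  expect_gte(a_low, 0.9)
  expect_true(a_tiny <= a_low + 1e-9 && a_low <= a_clean + 1e-9)
})

test_that("single-segment filaments inherit their segment's winner", {
  dens <- fx_dens()
  lat14 <- fx_lat14()
  lat13 <- lattice_spec(n_pf = 13)
  refs <- list(`13` = symmetrize(build_volume(lat13, dens, seed = 1),
                                 helical_params(lat13), 13),
               `14` = fx_sym14())
  st <- simulate_segment_stack(lat14, dens, n_filaments = 1,
                               filament_len_A = 480, snr = Inf, seed = 4)
  expect_equal(dim(st$images)[3], 2)
  st$images <- st$images[, , 1, drop = FALSE]
  st$meta <- st$meta[1, ]
  srt <- sort_pf_number(st, refs, angular_step_deg = 8, shift_range_A = 6)
  expect_equal(srt$filaments$pf_assignment, 14L)
  expect_equal(srt$segments$winner, "14")
})

test_that("alignment smoothing restores corrupted segments and passes degenerate cases", {
  al <- tibble::tibble(segment_id = 1:10, filament_id = 1,
                       segment_index = 1:10,
                       rot = wrap360(10 + 23 * (1:10)), tilt = 90, psi = 0,
                       shift_x = seq(0, 2, length.out = 10), shift_y = 0.5,
                       cc_score = 1, pf_assignment = 14L)
  sm <- smooth_alignments(al)
  expect_equal(sm$rot, al$rot)
  expect_equal(sm$shift_x, al$shift_x)
  expect_false(any(sm$smoothed))

  al2 <- al
  al2$shift_x[5] <- 8
  sm2 <- smooth_alignments(al2)
  expect_true(sm2$smoothed[5])
  expect_lt(abs(sm2$shift_x[5] - al$shift_x[5]), 0.5)

  al3 <- al[1:3, ]
  sm3 <- smooth_alignments(al3, max_degree = 2)
  expect_equal(sm3$rot, al3$rot)
  expect_false(any(sm3$smoothed))
})
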