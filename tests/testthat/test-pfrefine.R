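test_that("single-column wedge masks partition the annulus", {
  sym <- fx_sym14()
  n <- dim(sym$values)[1]
  vox <- sym$voxel_size_A
  wsum <- 0
  for (j in 0:13)
    wsum <- wsum + make_wedge_mask(sym, wedge_mask_spec(14, j))$values[, , 1]
  ax <- (seq_len(n) - 1 - floor(n / 2)) * vox
  r <- sqrt(outer(ax^2, ax^2, "+"))
  ann <- r >= 60 & r <= 0.49 * n * vox
  expect_lt(max(abs(wsum[ann] - 1)), 1e-6)
  expect_true(all(wsum >= 0 & wsum <= 1 + 1e-9))
})

test_that("adjacent wedge masks are related by a 360/N rotation", {
  sym <- fx_sym14()
  m0 <- make_wedge_mask(sym, wedge_mask_spec(14, 0))
  m1 <- make_wedge_mask(sym, wedge_mask_spec(14, 1))
  tf <- structure(list(R = euler_matrix(-360 / 14, 0, 0), t = c(0, 0, 0)),
                  class = "rigid_transform")
  rot <- transform_map(m0, tf)
  n <- dim(sym$values)[1]
  inner <- 2:(n - 1)
  expect_gt(ncc(rot$values[inner, inner, inner],
                m1$values[inner, inner, inner]), 0.99)
})

test_that("a hard-edged wedge occupies 1/N of the annulus", {
  # fine grid so pixelation error at the wedge boundary is small
  n <- 160
  vox <- 2
  grid <- density_map(array(0, rep(n, 3)), vox)
  ax <- (seq_len(n) - 1 - floor(n / 2)) * vox
  r <- sqrt(outer(ax^2, ax^2, "+"))
  ann <- r >= 60 & r <= 150
  fracs <- vapply(0:13, function(j) {
    m <- make_wedge_mask(grid, wedge_mask_spec(14, j, soft_edge_deg = 0,
                                               radial_inner_A = 60,
                                               radial_outer_A = 150))
    sum(m$values[, , 1][ann]) / sum(ann)
  }, numeric(1))
  # every wedge near 1/14 (boundary pixel columns shift a few percent
  # between the two wedges sharing an axis-aligned boundary), and the hard
  # wedges exactly tile the annulus
  expect_equal(fracs[2], 1 / 14, tolerance = 0.02)
  expect_true(all(abs(fracs * 14 - 1) < 0.03))
  expect_equal(sum(fracs), 1, tolerance = 1e-9)
  sym <- fx_sym14()
  expect_error(make_wedge_mask(sym, wedge_mask_spec(14, 0,
                                                    radial_outer_A = 1000)),
               "annulus")
  expect_error(wedge_mask_spec(14, 14), "pf_index")
})

test_that("signal subtraction equals direct projection of the kept column", {
  lat <- fx_lat14()
  sym <- fx_sym14()
  st <- fx_stack_sym()
  al <- fx_true_alignments(st)
  for (i in c(1, 4)) {
    a <- al[i, ]
    res <- subtract_other_pfs(st$images[, , i], sym, a, 3, lat)
    direct <- project_map(kinhelix:::single_pf_map(sym, lat, 3),
                          c(a$rot, a$tilt, a$psi),
                          c(a$shift_x, a$shift_y))
    expect_gt(ncc(res, direct), 0.99)
  }
  expect_error(subtract_other_pfs(st$images[, , 1], sym, al[1, ], 14, lat),
               "out of range")
})

test_that("subtracting everything leaves approximately nothing", {
  lat <- fx_lat14()
  sym <- fx_sym14()
  st <- fx_stack_sym()
  a <- fx_true_alignments(st)[1, ]
  # complement of an empty wedge is the full map: the residual is the image
  # minus the full-microtubule projection, i.e. interpolation crumbs only
  full_proj <- project_map(sym, c(a$rot, a$tilt, a$psi),
                           c(a$shift_x, a$shift_y))
  resid <- st$images[, , 1] - full_proj
  expect_lt(sd(resid) / sd(st$images[, , 1]), 0.05)
})

test_that("subtraction preserves the noise power budget", {
  lat <- fx_lat14()
  sym <- fx_sym14()
  snr <- 1
  noisy <- simulate_segment_stack(lat, fx_dens(), n_filaments = 1,
                                  filament_len_A = 900, snr = snr, seed = 13,
                                  volume = sym)
  clean <- simulate_segment_stack(lat, fx_dens(), n_filaments = 1,
                                  filament_len_A = 900, snr = Inf, seed = 13,
                                  volume = sym)
  a <- fx_true_alignments(noisy)[1, ]
  res_noisy <- subtract_other_pfs(noisy$images[, , 1], sym, a, 3, lat)
  res_clean <- subtract_other_pfs(clean$images[, , 1], sym, a, 3, lat)
  noise <- noisy$images[, , 1] - clean$images[, , 1]
  # residual power = single-column signal power + noise power
  expect_equal(mean(res_noisy^2), mean(res_clean^2) + mean(noise^2),
               tolerance = 0.1 * mean(res_noisy^2))
})

test_that("extraction yields one particle per column per segment with unique provenance", {
  lat <- fx_lat14()
  sym <- fx_sym14()
  st <- fx_stack_sym()
  al <- fx_true_alignments(st)
  pp <- extract_pf_particles(st, al, lat, sym)
  n_seg <- dim(st$images)[3]
  expect_equal(dim(pp$images)[3], n_seg * 14)
  expect_equal(nrow(pp$meta), n_seg * 14)
  expect_false(any(duplicated(pp$meta[, c("segment_id", "pf_index")])))
  expect_true(all(!is.na(pp$meta$segment_id)))

  one <- st
  one$images <- one$images[, , 1, drop = FALSE]
  one$meta <- one$meta[1, ]
  lat13 <- lattice_spec(n_pf = 13)
  sym13 <- symmetrize(build_volume(lat13, fx_dens(), seed = 1),
                      helical_params(lat13), 13)
  st13 <- simulate_segment_stack(lat13, fx_dens(), n_filaments = 1,
                                 filament_len_A = 500, snr = Inf, seed = 1,
                                 volume = sym13)
  st13$images <- st13$images[, , 1, drop = FALSE]
  st13$meta <- st13$meta[1, ]
  pp13 <- extract_pf_particles(st13, fx_true_alignments(st13), lat13, sym13)
  expect_equal(dim(pp13$images)[3], 13)
  expect_error(extract_pf_particles(st, al[-1, ], lat, sym), "missing")
})

test_that("metadata expansion reproduces the full-scale particle bookkeeping", {
  big <- tibble::tibble(segment_id = seq_len(19128), filament_id = 1L,
                        segment_index = seq_len(19128),
                        rot = 0, tilt = 90, psi = 0, shift_x = 0,
                        shift_y = 0, cc_score = 1, pf_assignment = 14L)
  ex <- expand_pf_metadata(big, 14)
  expect_identical(nrow(ex), 267792L)
  expect_false(any(duplicated(ex[, c("segment_id", "pf_index")])))
})

test_that("local refinement stays home when initialised at the truth", {
  lat <- fx_lat14()
  sym <- fx_sym14()
  st <- fx_stack_sym()
  pp <- extract_pf_particles(st, fx_true_alignments(st), lat, sym)
  canon <- canonical_pf_volume(sym, lat, pp$box_out)
  ref <- local_refine_pf(pp, canon, ang_range_deg = 4, step_deg = 2,
                         shift_range_A = 6)
  # a single column's projection is nearly insensitive to small rotations
  # about the filament axis at some views, so a minority of particles may
  # wander a step along the flat direction; shifts must stay put exactly
  moved <- ang_dist(ref$meta$rot_refined, ref$meta$rot)
  expect_gte(mean(moved <= 2 + 1e-9), 0.75)
  expect_true(all(moved <= 4 + 1e-9))
  expect_equal(max(abs(ref$meta$shift_x_refined)), 0)
  expect_equal(max(abs(ref$meta$shift_y_refined)), 0)
  expect_gt(mean(ref$meta$cc), 0.9)
})

test_that("local refinement recovers perturbed initial angles", {
  lat <- fx_lat14()
  sym <- fx_sym14()
  st <- fx_stack_sym()
  pp <- extract_pf_particles(st, fx_true_alignments(st), lat, sym)
  canon <- canonical_pf_volume(sym, lat, pp$box_out)
  truth <- pp$meta$rot
  set.seed(17)
  pp$meta$rot <- wrap360(truth + sample(c(-2, 2), nrow(pp$meta),
                                        replace = TRUE))
  ref <- local_refine_pf(pp, canon, ang_range_deg = 4, step_deg = 2,
                         shift_range_A = 6)
  # recovered to the gallery point nearest the truth for most particles;
  # flat-view particles may sit one step off
  err <- ang_dist(ref$meta$rot_refined, truth)
  expect_lt(median(err), 2 + 1e-9)
  expect_true(mean(err <= 2 + 1e-9) > 0.9)
  expect_error(local_refine_pf(pp, fx_sym14()), "box")
})

test_that("refined alignments reconstruct better than perturbed ones", {
  lat <- fx_lat14()
  sym <- fx_sym14()
  st <- fx_stack_sym()
  pp <- extract_pf_particles(st, fx_true_alignments(st), lat, sym)
  canon <- canonical_pf_volume(sym, lat, pp$box_out)
  truth <- pp$meta$rot
  set.seed(19)
  pp$meta$rot <- wrap360(truth + runif(nrow(pp$meta), -3, 3))
  pp$meta$shift_x <- runif(nrow(pp$meta), -4, 4)
  rec_pert <- backproject_particles(pp, use = "initial")
  ref <- local_refine_pf(pp, canon, ang_range_deg = 4, step_deg = 1,
                         shift_range_A = 6)
  rec_ref <- backproject_particles(ref, use = "refined")
  m <- array(canon$values > 0.05 * max(canon$values), dim(canon$values))
  expect_gt(ncc(rec_ref$values[m], canon$values[m]),
            ncc(rec_pert$values[m], canon$values[m]))
})

test_that("focused classification separates tail-occupied dimers", {
  lat <- fx_lat14()
  hp <- fx_hp14()
  vol <- fx_vol_tail()
  sym <- fx_sym_tail()
  st <- simulate_segment_stack(lat, fx_dens_tail(), n_filaments = 4,
                               filament_len_A = 1300, snr = 0.5, seed = 7,
                               volume = vol)
  pp <- extract_pf_particles(st, fx_true_alignments(st), lat, sym)
  fm <- ball_mask(pp$box_out, pp$voxel_size_A, c(55, 0, 0), 28)
  fc <- focused_classify(pp, k_classes = 2, n_iter = 10, seed = 11,
                         focus_mask = fm, group = "dimer_id")
  truth <- pp$meta$tail_true
  acc <- max(mean((fc$labels == 1) == truth),
             mean((fc$labels == 2) == truth))
  expect_gte(acc, 0.95)

  # class-average volumes show the tail contrast: occupied class carries
  # > 2x the density at the tail site
  tail_region <- fm$values > 0.5
  d1 <- mean(fc$class_volumes[[1]]$values[tail_region])
  d2 <- mean(fc$class_volumes[[2]]$values[tail_region])
  occupied_first <- mean(truth[fc$labels == 1]) > mean(truth[fc$labels == 2])
  ratio <- if (occupied_first) d1 / d2 else d2 / d1
  expect_gt(ratio, 2)
})

test_that("degenerate classification inputs are handled", {
  lat <- fx_lat14()
  sym <- fx_sym14()
  st <- fx_stack_sym()
  pp <- extract_pf_particles(st, fx_true_alignments(st), lat, sym)
  fc1 <- focused_classify(pp, k_classes = 1, n_iter = 2, seed = 1)
  expect_true(all(fc1$labels == 1))
  direct <- backproject_particles(pp, use = "initial")
  expect_equal(fc1$class_volumes[[1]]$values, direct$values,
               tolerance = 1e-12)

  # identical particles cannot sustain two classes
  ident <- pp
  for (i in seq_len(dim(ident$images)[3])) ident$images[, , i] <- pp$images[, , 1]
  ident$meta$rot <- rep(pp$meta$rot[1], nrow(ident$meta))
  fc2 <- focused_classify(ident, k_classes = 2, n_iter = 6, seed = 2,
                          init = "random")
  expect_true(fc2$empty_class_flag || fc2$degenerate_flag ||
                fc2$changed_last == 0)
  expect_error(focused_classify(pp, k_classes = 1e6), "exceeds")
})
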