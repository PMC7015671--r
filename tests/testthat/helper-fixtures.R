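# Shared fixtures, memoised so expensive volumes/stacks build once per run.
# Everything is generated in code at fixed seeds; nothing is read from disk.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(key, builder) {
  got <- .fx_cache[[key]]
  if (is.null(got)) {
    got <- builder()
    .fx_cache[[key]] <- got
  }
  got
}

fx_lat14 <- function() fx("lat14", function() lattice_spec(n_pf = 14))
fx_hp14 <- function() fx("hp14", function() helical_params(fx_lat14()))
fx_dens <- function() fx("dens", function() density_spec())

# motor-decorated, no tails, occupancy 1 (homogeneous)
fx_vol14 <- function() fx("vol14", function()
  build_volume(fx_lat14(), fx_dens(), seed = 1))
fx_sym14 <- function() fx("sym14", function()
  symmetrize(fx_vol14(), fx_hp14(), 14))

# noiseless stack simulated from the symmetrized map (subtraction oracle
# identities are exact against the map actually subtracted)
fx_stack_sym <- function() fx("stack_sym", function()
  simulate_segment_stack(fx_lat14(), fx_dens(), n_filaments = 2,
                         filament_len_A = 1000, snr = Inf, seed = 5,
                         volume = fx_sym14()))

# richer stack for reconstruction-quality checks
fx_stack_sym4 <- function() fx("stack_sym4", function()
  simulate_segment_stack(fx_lat14(), fx_dens(), n_filaments = 4,
                         filament_len_A = 1300, snr = Inf, seed = 3,
                         volume = fx_sym14()))

fx_true_alignments <- function(stack) {
  dplyr::mutate(stack$meta, cc_score = 1, pf_assignment = 14L)
}

# heterogeneous tails at 50% occupancy
fx_dens_tail <- function() fx("dens_tail", function()
  density_spec(tail_occupancy = 0.5))
fx_vol_tail <- function() fx("vol_tail", function()
  build_volume(fx_lat14(), fx_dens_tail(), seed = 2))
fx_sym_tail <- function() fx("sym_tail", function()
  symmetrize(fx_vol_tail(), fx_hp14(), 14))

# central region mask (away from symmetrization edge loss), model frame
central_mask <- function(map, r_outer = 170, r_inner = 0, z_margin_A = 70) {
  n <- dim(map$values)[1]
  vox <- map$voxel_size_A
  ax <- (seq_len(n) - 1 - floor(n / 2)) * vox
  r <- sqrt(outer(ax^2, ax^2, "+"))
  rin <- r >= r_inner & r <= r_outer
  zk <- abs(ax) < n * vox / 2 - z_margin_A
  outer(rin, zk, "&")
}

# angular distance helper for tests
ang_dist <- function(a, b) {
  d <- abs(((a - b) %% 360 + 360) %% 360)
  pmin(d, 360 - d)
}

merge_stacks <- function(stacks) {
  ns <- vapply(stacks, function(s) dim(s$images)[3], integer(1))
  n <- dim(stacks[[1]]$images)[1]
  imgs <- array(0, c(n, n, sum(ns)))
  metas <- vector("list", length(stacks))
  off <- 0L
  fid_off <- 0L
  for (i in seq_along(stacks)) {
    imgs[, , off + seq_len(ns[i])] <- stacks[[i]]$images
    m <- stacks[[i]]$meta
    m$filament_id <- m$filament_id + fid_off
    metas[[i]] <- m
    fid_off <- max(m$filament_id)
    off <- off + ns[i]
  }
  meta <- dplyr::bind_rows(metas)
  meta$segment_id <- seq_len(nrow(meta))
  structure(list(images = imgs, meta = meta,
                 voxel_size_A = stacks[[1]]$voxel_size_A),
            class = "segment_stack")
}
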