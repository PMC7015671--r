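test_that("Michaelis-Menten fitting recovers noiseless parameters exactly", {
  concs <- 680 * 10^seq(-1, log10(20), length.out = 8)
  d <- gen_mm_dataset(7.1, 680, concs, noise_cv = 0, seed = 1)
  fit <- fit_michaelis_menten(d)
  expect_equal(fit$kcat_per_s, 7.1, tolerance = 1e-4)
  expect_equal(fit$km_nM, 680, tolerance = 1e-4 * 680)
  expect_true(fit$converged)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "kcat_per_s"], fit$kcat_per_s)
})

test_that("two exact points admit the algebraic two-point solution", {
  # closed form: from v1 at S = Km and v2 at S >> Km, kcat = v2 and
  # Km = S1 (v2 / v1 - 1)
  kcat <- 5
  km <- 300
  s <- c(300, 3e6, 1000)
  v <- kcat * s / (km + s)
  fit <- fit_michaelis_menten(conc_nM = s, rate_per_s = v)
  kcat_alg <- v[2]
  km_alg <- s[1] * (kcat_alg / v[1] - 1)
  expect_equal(fit$kcat_per_s, kcat_alg, tolerance = 1e-3)
  expect_equal(fit$km_nM, km_alg, tolerance = 1e-2 * km_alg)
})

test_that("degenerate ATPase inputs are flagged or rejected", {
  expect_error(fit_michaelis_menten(conc_nM = c(1, 2), rate_per_s = c(1, 2)),
               "3")
  expect_error(fit_michaelis_menten(conc_nM = c(1, 2, 3),
                                    rate_per_s = c(0, 0, 0)), "zero")
  sat <- fit_michaelis_menten(conc_nM = c(1e5, 2e5, 4e5),
                              rate_per_s = c(6, 6, 6))
  expect_true("km_unidentifiable" %in% sat$flags)
  expect_true(is.na(sat$km_nM))
  expect_equal(sat$kcat_per_s, 6)
})

test_that("mixture fits recover one- and two-component parameters", {
  one <- gen_motility_dataset(data.frame(mean = 7, sd = 3, weight = 1),
                              n = 149, seed = 2)
  f1 <- fit_gaussian_mixture(one$velocity_nm_s, k = 1)
  expect_lt(abs(f1$components$mean - 7), 3 * 3 / sqrt(149))

  mix <- gen_motility_dataset(
    data.frame(mean = c(24, 41), sd = c(5, 4), weight = c(0.6, 0.4)),
    n = 149, seed = 3)
  f2 <- fit_gaussian_mixture(mix$velocity_nm_s, k = 2, seed = 1)
  expect_equal(nrow(f2$components), 2)
  expect_lt(abs(f2$components$weight[2] - 0.4), 0.08)
  expect_lt(abs(f2$components$mean[1] - 24), 2.5)
  expect_lt(abs(f2$components$mean[2] - 41), 2.5)
})

test_that("the EM likelihood never decreases and fits are order/seed stable", {
  mix <- gen_motility_dataset(
    data.frame(mean = c(24, 41), sd = c(5, 4), weight = c(0.6, 0.4)),
    n = 149, seed = 3)
  f <- fit_gaussian_mixture(mix$velocity_nm_s, k = 2, seed = 1)
  expect_true(all(diff(f$ll_trace) > -1e-8))

  shuf <- sample(mix$velocity_nm_s)
  f_shuf <- fit_gaussian_mixture(shuf, k = 2, seed = 99)
  expect_equal(f$components$mean, f_shuf$components$mean, tolerance = 1e-6)
  expect_equal(f$components$weight, f_shuf$components$weight,
               tolerance = 1e-6)
})

test_that("BIC prefers one component for single-Gaussian samples", {
  sel <- vapply(1:100, function(s) {
    set.seed(s)
    fit_gaussian_mixture(rnorm(400, 30, 5), seed = s)$selected_k
  }, integer(1))
  expect_gte(mean(sel == 1L), 0.95)

  # coincident components collapse to one
  set.seed(1)
  x <- rnorm(300, 10, 2)
  f <- fit_gaussian_mixture(x, seed = 1)
  expect_equal(f$selected_k, 1L)
})

test_that("binned histogram mode approximates the raw-sample fit", {
  mix <- gen_motility_dataset(
    data.frame(mean = c(24, 41), sd = c(5, 4), weight = c(0.6, 0.4)),
    n = 400, seed = 5)
  fb <- fit_gaussian_mixture(mix$velocity_nm_s, k = 2, seed = 1,
                             binned = TRUE)
  expect_lt(abs(fb$components$mean[1] - 24), 4)
  expect_lt(abs(fb$components$mean[2] - 41), 4)
})

test_that("censored run-length MLE equals the closed form and beats the naive mean", {
  x <- c(2, 4, 8)
  f <- fit_runlength(x, censored = c(FALSE, FALSE, FALSE))
  expect_equal(f$mean_um, mean(x))
  expect_equal(f$half_length_um, mean(x) * log(2))

  bias_mle <- numeric(100)
  bias_naive <- numeric(100)
  for (s in 1:100) {
    d <- gen_motility_dataset(data.frame(mean = 1, sd = 0.1, weight = 1),
                              n = 150, runlen_mean_um = 8,
                              censor_limit_um = 9.7, seed = s)
    f <- fit_runlength(d)
    bias_mle[s] <- f$mean_um - 8
    bias_naive[s] <- mean(d$run_length_um) - 8
  }
  expect_gt(mean(sapply(1:100, function(s) {
    abs(bias_naive[s]) > abs(bias_mle[s])
  })), 0.9)
  expect_lt(abs(mean(bias_mle)), 0.5)

  expect_error(fit_runlength(c(5, 5), censored = c(TRUE, TRUE)), "censored")
  expect_error(fit_runlength(c(-1, 2), censored = c(FALSE, FALSE)), "> 0")
})

test_that("censored MLE matches the survival-regression oracle", {
  skip_if_not_installed("survival")
  d <- gen_motility_dataset(data.frame(mean = 1, sd = 0.1, weight = 1),
                            n = 200, runlen_mean_um = 8,
                            censor_limit_um = 25, seed = 7)
  f <- fit_runlength(d)
  sr <- survival::survreg(
    survival::Surv(d$run_length_um, !d$censored) ~ 1,
    dist = "exponential")
  expect_equal(f$mean_um, exp(unname(coef(sr))), tolerance = 1e-6)
})

test_that("mixture EM agrees with the mclust oracle on clean data", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")   # Mclust resolves helpers by attachment
  mix <- gen_motility_dataset(
    data.frame(mean = c(24, 41), sd = c(5, 4), weight = c(0.6, 0.4)),
    n = 400, seed = 11)
  f <- fit_gaussian_mixture(mix$velocity_nm_s, k = 2, seed = 1)
  mc <- mclust::Mclust(mix$velocity_nm_s, G = 2, modelNames = "V",
                       verbose = FALSE)
  expect_equal(sort(f$components$mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05 * 41)
  expect_equal(f$loglik, mc$loglik, tolerance = 0.01 * abs(mc$loglik))
})

test_that("force-per-overlap slope is exact on a line and bootstrap covers zero", {
  d <- gen_force_dataset(4, 20, c(1, 8), noise_sd_pN = 0, seed = 3)
  f <- fit_force_per_overlap(d, seed = 1)
  expect_equal(f$slope_pN_per_um, 4, tolerance = 1e-10)
  expect_equal(f$intercept_pN, 0, tolerance = 1e-9)
  fo <- fit_force_per_overlap(d, through_origin = TRUE, seed = 1)
  expect_equal(fo$slope_pN_per_um, 4, tolerance = 1e-10)
  expect_identical(fo$intercept_pN, 0)

  cover <- vapply(1:50, function(s) {
    d0 <- gen_force_dataset(0, 25, c(1, 8), noise_sd_pN = 2, seed = s)
    ci <- fit_force_per_overlap(d0, n_boot = 400, seed = s)$ci
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.85)

  expect_error(fit_force_per_overlap(overlap_um = c(2, 2, 2),
                                     force_pN = c(1, 2, 3)), "variance")
})

test_that("roi ratio handles degenerate masks and undefined contrasts", {
  im <- gen_roi_image(250, 120, 20, noise_sd = 0, seed = 1)
  im$spindle_mask[] <- FALSE
  expect_error(roi_intensity_ratio(im), "empty spindle")

  im2 <- gen_roi_image(30, 10, 50, noise_sd = 0, seed = 1)  # cyto < bg
  r <- roi_intensity_ratio(im2)
  expect_true(is.na(r$ratio))
  expect_equal(r$flag, "undefined")
})

test_that("tidiers and glances return well-formed tibbles", {
  d <- gen_mm_dataset(7.1, 680, 680 * 10^seq(-1, 1, length.out = 6),
                      noise_cv = 0.02, seed = 1)
  fit <- fit_michaelis_menten(d)
  expect_named(tidy(fit), c("term", "estimate", "std.error"))
  expect_equal(nrow(glance(fit)), 1)

  fd <- gen_force_dataset(4, 20, c(1, 8), 1, seed = 2)
  sf <- fit_force_per_overlap(fd, n_boot = 200, seed = 1)
  expect_true(all(c("conf.low", "conf.high") %in% names(tidy(sf))))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(sf), "ggplot")
})
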