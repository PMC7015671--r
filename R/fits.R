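#' Fit Michaelis-Menten kinetics to an ATPase dataset
#'
#' Nonlinear least-squares fit of `v = kcat * S / (Km + S)` to steady-state
#' MT-stimulated ATP hydrolysis rates, initialised from the Hanes-Woolf
#' linearisation `S/v = S/kcat + Km/kcat`. Standard errors come from the
#' local curvature of the fit.
#'
#' @param data A data frame with columns `mt_conc_nM` and `rate_per_s`, or
#'   the two vectors via `conc_nM`/`rate_per_s`.
#' @param conc_nM,rate_per_s Optional explicit vectors (ignored when `data`
#'   is given).
#' @return An `mm_fit`: `kcat_per_s`, `km_nM`, their standard errors,
#'   `converged`, `flags` (e.g. `km_unidentifiable`), residual summary and
#'   the data.
#' @export
#' @examples
#' d <- gen_mm_dataset(7.1, 680, 680 * 10^seq(-1, 1.3, length.out = 8), 0)
#' fit_michaelis_menten(d)
fit_michaelis_menten <- function(data = NULL, conc_nM = NULL,
                                 rate_per_s = NULL) {
  if (!is.null(data)) {
    conc_nM <- data$mt_conc_nM
    rate_per_s <- data$rate_per_s
  }
  if (length(conc_nM) < 3) abort("need at least 3 concentration points")
  if (length(conc_nM) != length(rate_per_s)) abort("length mismatch")
  if (all(rate_per_s == 0)) abort("all rates are zero")
  flags <- character()
  if (sd(rate_per_s) < 1e-12 * abs(mean(rate_per_s))) {
    # saturated-only data: kcat is the plateau, Km has no leverage
    return(new_mm_fit(mean(rate_per_s), NA_real_, NA_real_, NA_real_,
                      converged = FALSE, flags = "km_unidentifiable",
                      conc_nM, rate_per_s, fitted = rate_per_s))
  }
  pos <- rate_per_s > 0
  hw <- lm(I(conc_nM[pos] / rate_per_s[pos]) ~ conc_nM[pos])
  kcat0 <- unname(1 / coef(hw)[2])
  km0 <- unname(coef(hw)[1] * kcat0)
  if (!is.finite(kcat0) || kcat0 <= 0) kcat0 <- max(rate_per_s)
  if (!is.finite(km0) || km0 <= 0) km0 <- median(conc_nM)
  fit <- tryCatch(
    minpack.lm::nlsLM(rate_per_s ~ kcat * conc_nM / (km + conc_nM),
                      start = list(kcat = kcat0, km = km0),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    abort("Michaelis-Menten fit failed to converge")
  sm <- summary(fit)
  est <- coef(fit)
  converged <- isTRUE(fit$convInfo$isConv) || is.null(fit$convInfo)
  if (!converged) flags <- c(flags, "not_converged")
  new_mm_fit(est[["kcat"]], est[["km"]],
             sm$coefficients["kcat", "Std. Error"],
             sm$coefficients["km", "Std. Error"],
             converged, flags, conc_nM, rate_per_s, fitted = fitted(fit))
}

new_mm_fit <- function(kcat, km, se_kcat, se_km, converged, flags,
                       conc, rate, fitted) {
  structure(list(
    kcat_per_s = unname(kcat), km_nM = unname(km),
    se_kcat = unname(se_kcat), se_km = unname(se_km),
    converged = converged, flags = flags,
    data = tibble(mt_conc_nM = conc, rate_per_s = rate,
                  fitted = as.numeric(fitted)),
    rss = sum((rate - fitted)^2), n = length(conc)),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> kcat %.4g +/- %.2g 1/s, Km %.4g +/- %.2g nM (n = %d)%s\n",
              x$kcat_per_s, x$se_kcat, x$km_nM, x$se_km, x$n,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

# log-likelihood of a 1D Gaussian mixture
gmm_loglik <- function(x, mu, sigma, w) {
  dens <- vapply(seq_along(mu),
                 function(k) w[k] * dnorm(x, mu[k], sigma[k]), numeric(length(x)))
  sum(log(rowSums(matrix(dens, ncol = length(mu)))))
}

# EM for a k-component 1D Gaussian mixture on raw samples
gmm_em <- function(x, k, max_iter = 500, tol = 1e-8, sd_floor_frac = 1e-3) {
  n <- length(x)
  floor_sd <- sd_floor_frac * sd(x)
  # deterministic quantile initialisation
  mu <- as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k))
  sigma <- rep(sd(x) / k, k)
  w <- rep(1 / k, k)
  ll <- -Inf
  ll_trace <- numeric()
  floored <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(x, mu[j], sigma[j]), numeric(n))
    dens <- matrix(dens, ncol = k)
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    r <- dens / tot
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sigma <- sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk)
    if (any(sigma < floor_sd)) {
      sigma <- pmax(sigma, floor_sd)
      floored <- TRUE
    }
    ll_new <- gmm_loglik(x, mu, sigma, w)
    ll_trace <- c(ll_trace, ll_new)
    if (is.finite(ll) && ll_new - ll < tol) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  ord <- order(mu)
  list(mu = mu[ord], sigma = sigma[ord], w = w[ord], loglik = ll,
       ll_trace = ll_trace, floored = floored)
}

#' Fit a 1- or 2-component Gaussian mixture
#'
#' Maximum-likelihood mixture fit by expectation-maximisation on the raw
#' samples (not histogram bins). When `k` is `NULL`, both one and two
#' components are fitted and the Bayesian information criterion selects
#' between them; components are reported sorted by mean. A floor on the
#' component SDs guards against degenerate collapse (flagged when hit).
#'
#' A histogram-based least-squares mode (`binned = TRUE`) is kept for
#' fidelity with bin-and-fit workflows; the raw-sample MLE is the default
#' because it needs no bin-width choice.
#'
#' @param samples Numeric sample vector (velocities, intensities, ...).
#' @param k `1`, `2`, or `NULL` to select by BIC.
#' @param seed Integer seed (the EM initialisation is deterministic; the
#'   seed covers optional restarts).
#' @param binned Fit Gaussians to histogram counts instead of raw MLE.
#' @param bins Histogram bin count for `binned = TRUE`.
#' @return A `mixture_fit`: `components` tibble (`mean`, `sd`, `weight`),
#'   `loglik`, `bic` per candidate k, `selected_k`, `flags`.
#' @export
fit_gaussian_mixture <- function(samples, k = NULL, seed = 1, binned = FALSE,
                                 bins = 20) {
  ks <- if (is.null(k)) c(1L, 2L) else as.integer(k)
  if (length(samples) < 10 * max(ks))
    abort("need at least 10 samples per component")
  set.seed(seed)
  if (binned) return(fit_gaussian_mixture_binned(samples, ks, bins))
  fits <- lapply(ks, function(kk) gmm_em(samples, kk))
  n <- length(samples)
  bic <- vapply(seq_along(ks), function(i)
    -2 * fits[[i]]$loglik + (3 * ks[i] - 1) * log(n), numeric(1))
  best <- which.min(bic)
  f <- fits[[best]]
  flags <- character()
  if (f$floored) flags <- c(flags, "sd_floor")
  # two coincident components degenerate to one
  sel_k <- ks[best]
  if (sel_k == 2 && abs(diff(f$mu)) < 1e-6 * sd(samples) && length(ks) > 1) {
    best <- which(ks == 1L)
    f <- fits[[best]]
    sel_k <- 1L
  }
  structure(list(
    components = tibble(mean = f$mu, sd = f$sigma, weight = f$w),
    loglik = f$loglik,
    bic = setNames(bic, paste0("k", ks)),
    selected_k = sel_k,
    ll_trace = f$ll_trace,
    flags = flags, n = n), class = "mixture_fit")
}

fit_gaussian_mixture_binned <- function(samples, ks, bins) {
  h <- graphics::hist(samples, breaks = bins, plot = FALSE)
  xc <- h$mids
  y <- h$counts
  bw <- diff(h$breaks[1:2])
  n <- length(samples)
  fit_k <- function(kk) {
    mu0 <- as.numeric(quantile(samples, (seq_len(kk) - 0.5) / kk))
    s0 <- rep(sd(samples) / kk, kk)
    w0 <- rep(1 / kk, kk)
    par0 <- c(mu0, log(s0), if (kk == 2) 0)
    obj <- function(p) {
      mu <- p[seq_len(kk)]
      sg <- exp(p[kk + seq_len(kk)])
      w <- if (kk == 2) {
        e <- 1 / (1 + exp(-p[2 * kk + 1]))
        c(e, 1 - e)
      } else 1
      pred <- n * bw * rowSums(vapply(seq_len(kk), function(j)
        w[j] * dnorm(xc, mu[j], sg[j]), numeric(length(xc))))
      sum((y - pred)^2)
    }
    op <- stats::optim(par0, obj, method = "BFGS",
                       control = list(maxit = 500))
    mu <- op$par[seq_len(kk)]
    sg <- exp(op$par[kk + seq_len(kk)])
    w <- if (kk == 2) {
      e <- 1 / (1 + exp(-op$par[2 * kk + 1]))
      c(e, 1 - e)
    } else 1
    ord <- order(mu)
    list(mu = mu[ord], sigma = sg[ord], w = w[ord], rss = op$value)
  }
  fits <- lapply(ks, fit_k)
  # pseudo-BIC on the binned least squares
  m <- length(xc)
  bic <- vapply(seq_along(ks), function(i)
    m * log(fits[[i]]$rss / m) + (3 * ks[i] - 1) * log(m), numeric(1))
  best <- which.min(bic)
  f <- fits[[best]]
  structure(list(
    components = tibble(mean = f$mu, sd = f$sigma, weight = f$w),
    loglik = NA_real_, bic = setNames(bic, paste0("k", ks)),
    selected_k = ks[best], ll_trace = numeric(), flags = "binned",
    n = length(samples)), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d (n = %d)\n", x$selected_k, x$n))
  print(x$components)
  invisible(x)
}

#' Fit an exponential run-length distribution with right censoring
#'
#' Run lengths end either in true detachment or at the observation limit
#' (censored). The censored-exponential maximum likelihood estimate of the
#' mean is the total observed length divided by the number of uncensored
#' (detachment) events; the naive mean of all records is biased low. The
#' half-length is `mean * ln 2`.
#'
#' @param lengths_um Observed run lengths (um), censored records truncated
#'   at the limit.
#' @param censored Logical vector; `TRUE` where the run outlived the
#'   observation window.
#' @param censor_limit_um Observation limit (um), recorded in the result.
#' @return A `runlength_fit`: `mean_um`, `half_length_um`, `se_mean_um`
#'   (`mean / sqrt(n_observed)`), `n_observed`, `n_censored`.
#' @export
fit_runlength <- function(lengths_um, censored = NULL,
                          censor_limit_um = NA_real_) {
  if (is.data.frame(lengths_um)) {
    censored <- lengths_um$censored
    censor_limit_um <- attr(lengths_um, "censor_limit_um") %||% censor_limit_um
    lengths_um <- lengths_um$run_length_um
  }
  censored <- censored %||% rep(FALSE, length(lengths_um))
  if (any(lengths_um <= 0)) abort("run lengths must be > 0")
  n_obs <- sum(!censored)
  if (n_obs == 0)
    abort("all records censored: the mean run length is unbounded")
  m <- sum(lengths_um) / n_obs
  structure(list(mean_um = m, half_length_um = m * log(2),
                 se_mean_um = m / sqrt(n_obs),
                 n_observed = n_obs, n_censored = sum(censored),
                 censor_limit_um = censor_limit_um),
            class = "runlength_fit")
}

#' @export
print.runlength_fit <- function(x, ...) {
  cat(sprintf(
    "<runlength_fit> mean %.3g um (half-length %.3g um), %d observed / %d censored\n",
    x$mean_um, x$half_length_um, x$n_observed, x$n_censored))
  invisible(x)
}

#' Fit the plateau-force versus overlap-length slope
#'
#' Least-squares line through force-overlap pairs; the slope is the plateau
#' pushing force generated per micrometre of antiparallel overlap. The
#' default keeps a free intercept; `through_origin = TRUE` constrains it to
#' zero. The confidence interval is a seeded nonparametric bootstrap over
#' event pairs.
#'
#' @param data Data frame with `overlap_um`, `plateau_pN` (or pass the two
#'   vectors).
#' @param overlap_um,force_pN Optional explicit vectors.
#' @param through_origin Constrain the intercept to zero.
#' @param n_boot Bootstrap replicates (>= 1000 recommended).
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return A `slope_fit`: `slope_pN_per_um`, `intercept_pN`, `se_slope`,
#'   `ci` (percentile bootstrap), `n`.
#' @export
fit_force_per_overlap <- function(data = NULL, overlap_um = NULL,
                                  force_pN = NULL, through_origin = FALSE,
                                  n_boot = 1000, conf = 0.95, seed = 1) {
  if (!is.null(data)) {
    overlap_um <- data$overlap_um
    force_pN <- data$plateau_pN %||% data$force_pN
  }
  if (length(unique(overlap_um)) < 2)
    abort("zero variance in overlaps: need at least 2 distinct overlap lengths")
  fit1 <- function(x, y) {
    if (through_origin) coef(lm(y ~ 0 + x)) else coef(lm(y ~ x))
  }
  cf <- fit1(overlap_um, force_pN)
  slope <- if (through_origin) cf[[1]] else cf[[2]]
  intercept <- if (through_origin) 0 else cf[[1]]
  full <- if (through_origin) lm(force_pN ~ 0 + overlap_um)
          else lm(force_pN ~ overlap_um)
  se_slope <- summary(full)$coefficients[if (through_origin) 1 else 2, 2]
  set.seed(seed)
  n <- length(overlap_um)
  reps <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (length(unique(overlap_um[i])) < 2) return(NA_real_)
    cfb <- fit1(overlap_um[i], force_pN[i])
    if (through_origin) cfb[[1]] else cfb[[2]]
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- unname(quantile(reps, c(a, 1 - a), na.rm = TRUE))
  structure(list(slope_pN_per_um = unname(slope),
                 intercept_pN = unname(intercept),
                 se_slope = unname(se_slope), ci = ci, conf = conf,
                 n = n, n_boot = n_boot,
                 data = tibble(overlap_um = overlap_um,
                               plateau_pN = force_pN)),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "<slope_fit> %.3g pN/um (%.0f%% CI %.3g-%.3g), intercept %.3g pN, n = %d\n",
    x$slope_pN_per_um, 100 * x$conf, x$ci[1], x$ci[2], x$intercept_pN, x$n))
  invisible(x)
}

#' Background-subtracted spindle-to-cytoplasm intensity ratio
#'
#' The cytoplasm region is the cell mask minus the spindle mask; the
#' background is the average over the background ROIs outside the cell. The
#' ratio is `(mean_spindle - mean_bg) / (mean_cyto - mean_bg)`, the standard
#' localisation metric for spindle-enriched fluorescence.
#'
#' @param image An `roi_image` (from [gen_roi_image()]) or a pixel matrix.
#' @param spindle_mask,cell_mask Logical masks (when `image` is a matrix).
#' @param background_rois List of logical masks outside the cell.
#' @return An `roi_ratio`: `ratio` (NA with flag `"undefined"` when the
#'   cytoplasm does not exceed background), region means and a
#'   noise-propagated standard error.
#' @export
roi_intensity_ratio <- function(image, spindle_mask = NULL, cell_mask = NULL,
                                background_rois = NULL) {
  if (inherits(image, "roi_image")) {
    spindle_mask <- image$spindle_mask
    cell_mask <- image$cell_mask
    background_rois <- image$background_rois
    image <- image$pixels
  }
  if (!sum(spindle_mask)) abort("empty spindle mask")
  if (!sum(cell_mask)) abort("empty cell mask")
  if (any(spindle_mask & !cell_mask))
    abort("spindle mask must lie inside the cell mask")
  bg_all <- Reduce(`|`, background_rois)
  if (any(bg_all & cell_mask))
    abort("background ROIs must be disjoint from the cell")
  cyto <- cell_mask & !spindle_mask
  if (!sum(cyto)) abort("empty cytoplasm region")
  ms <- mean(image[spindle_mask])
  mc <- mean(image[cyto])
  mb <- mean(image[bg_all])
  vs <- var(image[spindle_mask]) / sum(spindle_mask)
  vc <- var(image[cyto]) / sum(cyto)
  vb <- var(image[bg_all]) / sum(bg_all)
  flag <- "ok"
  ratio <- NA_real_
  se <- NA_real_
  if (mc - mb <= 0) {
    flag <- "undefined"
  } else {
    ratio <- (ms - mb) / (mc - mb)
    # first-order error propagation
    d <- mc - mb
    se <- sqrt(vs / d^2 + vc * (ms - mb)^2 / d^4 +
                 vb * (mc - ms)^2 / d^4)
  }
  structure(list(ratio = ratio, se = se, spindle_mean = ms, cyto_mean = mc,
                 bg_mean = mb, flag = flag,
                 n_spindle = sum(spindle_mask), n_cyto = sum(cyto)),
            class = "roi_ratio")
}

#' @export
print.roi_ratio <- function(x, ...) {
  cat(sprintf("<roi_ratio> %.4g +/- %.2g (spindle %.4g, cyto %.4g, bg %.4g)%s\n",
              x$ratio, x$se, x$spindle_mean, x$cyto_mean, x$bg_mean,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}
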