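#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("kcat_per_s", "km_nM"),
         estimate = c(x$kcat_per_s, x$km_nM),
         std.error = c(x$se_kcat, x$se_km))
}

#' @export
glance.mm_fit <- function(x, ...) {
  tibble(kcat_per_s = x$kcat_per_s, km_nM = x$km_nM, rss = x$rss,
         n = x$n, converged = x$converged,
         flags = paste(x$flags, collapse = ";"))
}

#' @export
tidy.mixture_fit <- function(x, ...) {
  dplyr::mutate(x$components, component = dplyr::row_number(),
                .before = 1)
}

#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(selected_k = x$selected_k, loglik = x$loglik,
         bic = min(x$bic), n = x$n,
         flags = paste(x$flags, collapse = ";"))
}

#' @export
tidy.runlength_fit <- function(x, ...) {
  tibble(term = c("mean_um", "half_length_um"),
         estimate = c(x$mean_um, x$half_length_um),
         std.error = c(x$se_mean_um, x$se_mean_um * log(2)))
}

#' @export
glance.runlength_fit <- function(x, ...) {
  tibble(mean_um = x$mean_um, half_length_um = x$half_length_um,
         n_observed = x$n_observed, n_censored = x$n_censored,
         censor_limit_um = x$censor_limit_um)
}

#' @export
tidy.slope_fit <- function(x, ...) {
  tibble(term = c("slope_pN_per_um", "intercept_pN"),
         estimate = c(x$slope_pN_per_um, x$intercept_pN),
         std.error = c(x$se_slope, NA_real_),
         conf.low = c(x$ci[1], NA_real_),
         conf.high = c(x$ci[2], NA_real_))
}

#' @export
glance.slope_fit <- function(x, ...) {
  tibble(slope_pN_per_um = x$slope_pN_per_um,
         intercept_pN = x$intercept_pN,
         ci_low = x$ci[1], ci_high = x$ci[2], n = x$n, n_boot = x$n_boot)
}

#' @export
glance.roi_ratio <- function(x, ...) {
  tibble(ratio = x$ratio, se = x$se, spindle_mean = x$spindle_mean,
         cyto_mean = x$cyto_mean, bg_mean = x$bg_mean, flag = x$flag)
}

#' @export
glance.ihrsr_result <- function(x, ...) {
  tibble(n_iter = nrow(x$log),
         twist_deg = x$params$twist_deg, rise_A = x$params$rise_A,
         mean_cc = if (nrow(x$log)) x$log$mean_cc[nrow(x$log)] else NA_real_)
}
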