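#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_histogram geom_abline labs theme_minimal after_stat
#' @export
ggplot2::autoplot

#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble(mt_conc_nM = exp(seq(log(min(object$data$mt_conc_nM)),
                                      log(max(object$data$mt_conc_nM)),
                                      length.out = 200)))
  grid$rate <- object$kcat_per_s * grid$mt_conc_nM /
    (object$km_nM + grid$mt_conc_nM)
  ggplot(object$data, aes(mt_conc_nM, rate_per_s)) +
    geom_point() +
    geom_line(data = grid, aes(y = rate), colour = "steelblue") +
    labs(x = "[MT] (nM)", y = "ATPase rate (1/s)",
         title = sprintf("Michaelis-Menten fit: kcat %.2f 1/s, Km %.0f nM",
                         object$kcat_per_s, object$km_nM)) +
    theme_minimal()
}

#' @export
autoplot.mixture_fit <- function(object, samples = NULL, ...) {
  p <- ggplot()
  if (!is.null(samples)) {
    p <- p + geom_histogram(
      data = tibble(x = samples),
      aes(x, after_stat(density)), bins = 25,
      fill = "grey85", colour = "grey60")
    xs <- seq(min(samples), max(samples), length.out = 400)
  } else {
    co <- object$components
    xs <- seq(min(co$mean - 4 * co$sd), max(co$mean + 4 * co$sd),
              length.out = 400)
  }
  dens <- purrr::pmap(object$components, function(mean, sd, weight)
    tibble(x = xs, y = weight * dnorm(xs, mean, sd)))
  total <- tibble(x = xs, y = Reduce(`+`, lapply(dens, `[[`, "y")))
  for (d in dens) p <- p + geom_line(data = d, aes(x, y), linetype = 2)
  p + geom_line(data = total, aes(x, y), colour = "steelblue") +
    labs(x = "value", y = "density",
         title = sprintf("Gaussian mixture (k = %d)", object$selected_k)) +
    theme_minimal()
}

#' @export
autoplot.fsc_curve <- function(object, threshold = 0.143, ...) {
  ggplot(object, aes(freq, fsc)) +
    geom_line() +
    geom_hline(yintercept = threshold, linetype = 2, colour = "grey40") +
    labs(x = "spatial frequency (1/Å)", y = "FSC") +
    theme_minimal()
}

#' @export
autoplot.slope_fit <- function(object, ...) {
  ggplot(object$data, aes(overlap_um, plateau_pN)) +
    geom_point() +
    geom_abline(slope = object$slope_pN_per_um,
                intercept = object$intercept_pN, colour = "steelblue") +
    labs(x = "overlap length (µm)", y = "plateau force (pN)",
         title = sprintf("%.2f pN per µm of overlap",
                         object$slope_pN_per_um)) +
    theme_minimal()
}

#' Plot the per-iteration refinement log
#'
#' @param result An `ihrsr_result`.
#' @return A ggplot object (twist/rise/mean cc vs iteration).
#' @export
plot_refinement_log <- function(result) {
  long <- tidyr::pivot_longer(result$log, -iteration,
                              names_to = "quantity", values_to = "value")
  ggplot(long, aes(iteration, value)) +
    geom_line() + geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    theme_minimal()
}
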