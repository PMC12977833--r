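# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation grid
#'
#' @param x A `vqtl_grid` from [run_grid()].
#' @param ... Unused.
#' @return A plain tibble (one row per cell x model).
#' @export
tidy.vqtl_grid <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "vqtl_grid")
  attr(out, "alpha") <- NULL
  attr(out, "n_pairs") <- NULL
  tibble::as_tibble(out)
}

#' Summarise an evaluation grid
#'
#' @inheritParams tidy.vqtl_grid
#' @return One-row tibble: numbers of cells, models, replicates, the
#'   nominal level, and the maximum null-cell rate.
#' @export
glance.vqtl_grid <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(dplyr::distinct(x, .data$a_G, .data$a_GxE, .data$noise_law, .data$scale)),
    n_models = dplyr::n_distinct(x$model),
    n_reps = max(x$n_reps),
    alpha = attr(x, "alpha") %||% 0.05,
    max_null_rate = suppressWarnings(max(x$discovery_rate[x$a_GxE == 0]))
  )
}

#' Heatmap of discovery / false-positive rates over the coefficient grid
#'
#' @param object A `vqtl_grid` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot object: `a_G` x `a_GxE` tiles filled by rate, faceted
#'   by model and noise law.
#' @export
autoplot.vqtl_grid <- function(object, ...) {
  ggplot2::ggplot(
    tidy.vqtl_grid(object),
    ggplot2::aes(
      x = factor(.data$a_GxE), y = factor(.data$a_G),
      fill = .data$discovery_rate
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data$discovery_rate)),
      size = 2.6, colour = "white"
    ) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$noise_law, .data$scale),
      cols = ggplot2::vars(.data$model)
    ) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "rate") +
    ggplot2::labs(
      x = "interaction weight a_GxE", y = "additive weight a_G",
      title = "Twin vQTL model discovery / false-positive rates"
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a cis scan result
#'
#' @param x A `cis_scan` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.cis_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cis_scan")
  for (a in c("pt_beta", "window_bp", "n_perm")) attr(out, a) <- NULL
  tibble::as_tibble(out)
}

#' Summarise a cis scan
#'
#' @inheritParams tidy.cis_scan
#' @return One-row tibble: CpGs tested/untested, significant calls, the
#'   global `p_beta` cutoff and permutation count.
#' @export
glance.cis_scan <- function(x, ...) {
  tibble::tibble(
    n_cpgs = nrow(x),
    n_tested = sum(!is.na(x$p_beta)),
    n_untested = sum(is.na(x$p_beta)),
    n_significant = sum(x$significant, na.rm = TRUE),
    pt_beta = attr(x, "pt_beta") %||% NA_real_,
    n_perm = attr(x, "n_perm") %||% NA_real_
  )
}

#' Empirical p-value diagnostic plot for a cis scan
#'
#' Plots sorted beta-approximated empirical p-values against uniform
#' quantiles (a QQ plot on the -log10 scale), colouring significant CpGs.
#'
#' @param object A `cis_scan` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cis_scan <- function(object, ...) {
  d <- dplyr::filter(tidy.cis_scan(object), !is.na(.data$p_beta))
  d <- dplyr::arrange(d, .data$p_beta)
  d$expected <- (seq_len(nrow(d)) - 0.5) / nrow(d)
  ggplot2::ggplot(d, ggplot2::aes(
    x = -log10(.data$expected), y = -log10(pmax(.data$p_beta, 1e-300)),
    colour = .data$significant
  )) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "-log10 expected uniform quantile",
      y = "-log10 empirical p (beta approximation)",
      title = "Cis scan calibration"
    ) +
    ggplot2::theme_minimal()
}
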