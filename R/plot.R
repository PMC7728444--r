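# Quick-look ggplot2 figures for fit objects and landscape grids.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_ribbon labs scale_x_log10 facet_wrap theme_minimal
NULL

zf_curve_plot <- function(object, xlab, ylab, logx = FALSE, n_grid = 200) {
  d <- object$data
  xr <- range(d$x)
  grid <- if (logx) {
    pos <- d$x[d$x > 0]
    tibble(x = 10^seq(log10(min(pos)), log10(max(pos)),
                      length.out = n_grid))
  } else {
    tibble(x = seq(xr[1], xr[2], length.out = n_grid))
  }
  for (cc in setdiff(names(d), c("x", "y", "w"))) grid[[cc]] <- d[[cc]][1]
  grid$fit <- object$fn(object$par, grid)
  p <- ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_line(data = grid, aes(y = .data$fit), colour = "steelblue") +
    geom_point() +
    labs(x = xlab, y = ylab) +
    theme_minimal()
  if (logx) p <- p + scale_x_log10()
  p
}

#' @rdname autoplot-zincfold
#' @export
autoplot.lem_fit <- function(object, ...) {
  zf_curve_plot(object, "denaturant (M)", "signal")
}

#' @rdname autoplot-zincfold
#' @export
autoplot.linkage_fit <- function(object, ...) {
  zf_curve_plot(object, "free zinc (M)", "dG_fold (kcal/mol)", logx = TRUE)
}

#' @rdname autoplot-zincfold
#' @export
autoplot.stability_fit <- function(object, ...) {
  zf_curve_plot(object, "temperature (K)", "dG_apo (kcal/mol)")
}

#' @rdname autoplot-zincfold
#' @export
autoplot.binding_fit <- function(object, ...) {
  zf_curve_plot(object, "free zinc (M)", "signal", logx = TRUE)
}

#' @rdname autoplot-zincfold
#' @export
autoplot.hill_fit <- function(object, ...) {
  zf_curve_plot(object, "ligand (M)", "signal", logx = TRUE)
}

#' @rdname autoplot-zincfold
#' @export
autoplot.ic50_fit <- function(object, ...) {
  zf_curve_plot(object, "log10 competitor (M)", "indicator signal")
}

#' Quick-look plots for zincfold objects
#'
#' `autoplot()` methods drawing each fitted curve over its data, the
#' temperature/zinc energy landscape as a filled raster, and the
#' classification scatter (stability loss vs log10 K_Zn fold-change).
#'
#' @param object A zincfold fit, `landscape_grid`, or
#'   `classification_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-zincfold
NULL

#' @rdname autoplot-zincfold
#' @export
autoplot.landscape_grid <- function(object, ...) {
  ggplot(object, aes(x = .data$log10_zn_free_M, y = .data$temperature_K,
                     fill = .data$f_holo)) +
    geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "F_holo") +
    labs(x = "log10 free zinc (M)", y = "temperature (K)",
         title = attr(object, "variant")) +
    theme_minimal()
}

#' @rdname autoplot-zincfold
#' @export
autoplot.classification_report <- function(object, ...) {
  ggplot(object$scatter,
         aes(x = .data$log10_kzn_fold, y = .data$ddg_apo,
             colour = .data$class_label)) +
    geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    labs(x = "log10 K_Zn fold-change vs WT",
         y = "stability loss ddG_apo (kcal/mol)", colour = "class") +
    theme_minimal()
}

#' Anisotropy panel overview plot
#'
#' Facets the fitted anisotropy curves by oligo, one colour per mutant.
#'
#' @param object An `anisotropy_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.anisotropy_fit <- function(object, ...) {
  pts <- purrr::imap(object$fits, function(f, og) {
    dplyr::mutate(f$data, oligo = og, fit = f$fitted)
  }) |> dplyr::bind_rows()
  ggplot(pts, aes(x = .data$x, y = .data$y,
                  colour = factor(.data$mutant_idx))) +
    geom_point() +
    geom_line(aes(y = .data$fit)) +
    scale_x_log10() +
    facet_wrap(~oligo) +
    labs(x = "protein (M)", y = "anisotropy", colour = "mutant") +
    theme_minimal()
}
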