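#' Tidy a REML fit
#'
#' @param x A `reml_fit` from [reml_kernel()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error` (only for
#'   the heritability).
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma2_a", "sigma2_e", "h2"),
    estimate = c(x$sigma2_a, x$sigma2_e, x$h2),
    std.error = c(NA_real_, NA_real_, x$se_h2)
  )
}

#' One-row summary of a REML fit
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the variance components, heritability and
#'   restricted log-likelihood.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_a = x$sigma2_a, sigma2_e = x$sigma2_e,
    h2 = x$h2, se_h2 = x$se_h2, logLik = x$loglik,
    converged = x$converged, boundary = x$boundary, nobs = x$n
  )
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> h2 = ", sprintf("%.3f", x$h2),
      if (is.finite(x$se_h2)) sprintf(" (SE %.3f)", x$se_h2),
      ", sigma2_a = ", sprintf("%.4g", x$sigma2_a),
      ", sigma2_e = ", sprintf("%.4g", x$sigma2_e),
      if (x$boundary) " [boundary]", "\n", sep = "")
  invisible(x)
}

#' Per-replicate cross-validation results
#'
#' @param x A `cv_result` from [run_cv()].
#' @param ... Unused.
#' @return Tibble with one row per replicate: `model`, `class_tag`,
#'   `replicate`, `accuracy`, `bias`.
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::mutate(x$replicates, model = x$model, class_tag = x$class_tag,
                .before = 1)
}

#' One-row cross-validation summary
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The summary tibble (mean/SD accuracy and bias, bias-vs-1 test).
#' @export
glance.cv_result <- function(x, ...) x$summary

#' Combine cross-validation results into a report table
#'
#' @param ... `cv_result` objects (or a single list of them).
#' @return Stacked [glance.cv_result()] rows, one per model.
#' @export
cv_report <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "cv_result")) xs <- xs[[1]]
  purrr::map_dfr(xs, glance)
}

#' Plot per-replicate accuracy and bias of cross-validation runs
#'
#' @param object A `cv_result`, or pass several via `...`.
#' @param ... Additional `cv_result` objects to compare.
#' @return A ggplot: per-replicate accuracy and bias distributions by model.
#' @export
autoplot.cv_result <- function(object, ...) {
  xs <- c(list(object), purrr::keep(list(...), ~inherits(.x, "cv_result")))
  df <- purrr::map_dfr(xs, tidy) |>
    dplyr::mutate(label = ifelse(.data$class_tag == "all", .data$model,
                                 paste0(.data$model, "|", .data$class_tag))) |>
    tidyr::pivot_longer(c("accuracy", "bias"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a relatedness kernel
#'
#' @param object A `gp_kernel`.
#' @param ... Unused.
#' @return A ggplot tile map of the relationship matrix.
#' @export
autoplot.gp_kernel <- function(object, ...) {
  df <- as.data.frame(as.table(object$K))
  names(df) <- c("row", "col", "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste("Kernel", object$model), x = NULL, y = NULL,
                  fill = "K") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
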