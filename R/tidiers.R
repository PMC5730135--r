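#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ICC result
#'
#' @param x a `dq_icc`.
#' @param ... unused.
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`, `n`, `model`.
#' @export
tidy.dq_icc <- function(x, ...) {
  tibble::tibble(estimate = x$icc, conf.low = x$ci95[1],
                 conf.high = x$ci95[2], n = x$n, model = x$model_tag)
}

#' @rdname tidy.dq_icc
#' @export
glance.dq_icc <- function(x, ...) tidy.dq_icc(x)

#' Tidy a Spearman result
#'
#' @param x a `dq_spearman`.
#' @param ... unused.
#' @return One-row tibble: `estimate`, `p.value`, `n`, `method`.
#' @export
tidy.dq_spearman <- function(x, ...) {
  tibble::tibble(estimate = x$rho, p.value = x$p_value, n = x$n,
                 method = x$method)
}

#' Tidy a correlation matrix into long pair form
#'
#' @param x a `dq_cormat`.
#' @param ... unused.
#' @return Tibble with one row per unordered area pair: `area1`, `area2`,
#'   `estimate`, `p.value`, `significant`.
#' @export
tidy.dq_cormat <- function(x, ...) {
  k <- length(x$areas)
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble::tibble(area1 = x$areas[idx[, 2]], area2 = x$areas[idx[, 1]],
                 estimate = x$r[idx], p.value = x$p[idx],
                 significant = x$significant[idx])
}

#' Heatmap of a correlation matrix
#'
#' Lower-triangle Spearman r as fill, significant pairs starred — a plot
#' version of the study's correlation table layout.
#'
#' @param object a `dq_cormat`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dq_cormat <- function(object, ...) {
  d <- tidy.dq_cormat(object)
  d$label <- sprintf("%.2f%s", d$estimate,
                     ifelse(d$significant, "*", ""))
  d$area1 <- factor(d$area1, levels = object$areas)
  d$area2 <- factor(d$area2, levels = rev(object$areas))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$area1, y = .data$area2,
                                  fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Spearman r") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of per-vertex signed displacement
#'
#' Shows the signed closest-point displacement distribution of a region (or
#' of the whole surface), the quantity whose colour-coded map guides area
#' selection; sign mixing is immediately visible as mass on both sides of
#' zero.
#'
#' @param source_mesh,target_mesh same-label meshes at the two time points.
#' @param region optional `dq_region` restricting the vertices.
#' @param binwidth histogram bin width, mm.
#' @return A ggplot object.
#' @export
plot_displacement_histogram <- function(source_mesh, target_mesh,
                                        region = NULL, binwidth = 0.25) {
  ids <- if (is.null(region)) seq_len(nrow(source_mesh$vertices))
         else region$vertex_ids
  d <- signed_displacement(source_mesh, target_mesh, ids)
  df <- tibble::tibble(signed_mm = d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signed_mm)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "signed displacement (mm)", y = "vertices") +
    ggplot2::theme_minimal()
}

#' Cohort displacement overview
#'
#' Mean and SD of each area's displacement across the cohort (the
#' descriptive-table content as a plot).
#'
#' @param object a `dq_cohort_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dq_cohort_report <- function(object, ...) {
  d <- object$descriptives
  d$area <- factor(d$area, levels = d$area)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$area, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = "mean displacement (mm)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
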