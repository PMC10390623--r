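#' Pairwise-complete Pearson correlation matrix
#'
#' Computes the Pearson correlation between every pair of study variables
#' using, for each pair, only the rows where both variables are observed,
#' and records the per-pair sample size.  A constant column yields an
#' undefined correlation (`NA`), flagged with a warning and excluded from
#' any derived edge list.
#'
#' @param data A cohort tibble.
#' @param variables Columns to correlate; default is `age`, the five
#'   covariates, and all canonical outcomes present in `data`.
#' @return An object of class `pairwise_cor`: list with `r` (correlation
#'   matrix), `n_used` (pairwise complete counts) and `variables`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 60, seed = 1))
#' cm <- cor_matrix(cohort)
#' cm$r["age", "numeracy"]
#' @export
cor_matrix <- function(data, variables = NULL) {
  variables <- variables %||%
    intersect(c("age", covariate_labels(), outcome_labels()), names(data))
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols)) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
          class = "agespec_data_error")
  }
  x <- as.matrix(data[variables])
  storage.mode(x) <- "double"
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  n_used <- crossprod(!is.na(x))
  if (any(is.na(r))) {
    warn("some correlations are undefined (constant column or empty overlap); they are excluded from edge lists")
  }
  if (min(n_used[upper.tri(n_used)]) < 3L) {
    warn("some variable pairs have fewer than 3 complete observations")
  }
  structure(list(r = r, n_used = n_used, variables = variables),
            class = "pairwise_cor")
}

#' @export
print.pairwise_cor <- function(x, ...) {
  cat(sprintf("Pairwise-complete Pearson correlations: %d variables, n range %d-%d\n",
              length(x$variables), min(x$n_used), max(x$n_used)))
  invisible(x)
}

#' @rdname cor_matrix
#' @param x A `pairwise_cor` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per unordered variable pair: `var_a`,
#'   `var_b`, `r`, `n_used`.
#' @export
tidy.pairwise_cor <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var_a = x$variables[idx[, 1]],
    var_b = x$variables[idx[, 2]],
    r = x$r[idx],
    n_used = as.integer(x$n_used[idx])
  )
}

#' Thresholded correlation-network edges
#'
#' Keeps the unordered variable pairs whose absolute Pearson correlation
#' meets the threshold (inclusive, so `r = 0.15` survives the default),
#' recording the sign for solid/dashed rendering downstream.  Undefined
#' correlations are dropped.
#'
#' @param x A `pairwise_cor` object from [cor_matrix()].
#' @param min_abs Inclusive absolute-correlation threshold (default 0.15).
#' @return A tibble of edges: `var_a`, `var_b`, `r`, `n_used`, `sign`
#'   (`"positive"`/`"negative"`).
#' @export
network_edges <- function(x, min_abs = 0.15) {
  stopifnot(inherits(x, "pairwise_cor"), min_abs >= 0)
  edges <- tidy(x)
  edges <- edges[!is.na(edges$r) & abs(edges$r) >= min_abs, ]
  edges$sign <- dplyr::if_else(edges$r >= 0, "positive", "negative")
  edges
}

#' Force-layout rendering of a correlation network
#'
#' A generic force-directed drawing of a thresholded edge list (requires
#' the igraph package for the layout).  Cosmetics only: node placement is
#' a generic Fruchterman-Reingold layout, not a calibrated reproduction of
#' any particular figure.
#'
#' @param edges An edge tibble from [network_edges()].
#' @param seed Layout seed.
#' @return A ggplot.
#' @export
plot_network <- function(edges, seed = 1L) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("plot_network() needs the igraph package")
  }
  if (nrow(edges) == 0L) abort("no edges to plot", class = "agespec_no_data")
  g <- igraph::graph_from_data_frame(edges[c("var_a", "var_b")],
                                     directed = FALSE)
  xy <- with_seed_or_rng(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(name = igraph::V(g)$name,
                          x = xy[, 1], y = xy[, 2])
  seg <- dplyr::left_join(edges, nodes, by = c(var_a = "name")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes, by = c(var_b = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, linetype = .data$sign,
                   linewidth = abs(.data$r)),
      colour = "grey50"
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 3, colour = "#2166ac") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -1, size = 2.8) +
    ggplot2::scale_linetype_manual(values = c(positive = "solid",
                                              negative = "dashed")) +
    ggplot2::scale_linewidth(range = c(0.2, 1.4), guide = "none") +
    ggplot2::theme_void()
}
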