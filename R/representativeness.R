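# Is the tested species sample representative of regional order richness?
# If q% of a region's species belong to an order, about q% of the tested
# species should too: the (regional %, tested %) points should scatter about
# the identity line y = x.

#' Compare tested-species proportions with regional order richness
#'
#' Aligns per-order species counts for a region with per-order counts of
#' tested species (case-insensitive exact name matching; orders present in
#' only one table get count zero), converts both to percentages, and reports
#' the Pearson correlation (p-value from the t transform on n - 2 degrees of
#' freedom), the least-squares line through the percentage pairs, and each
#' order's residual from the identity line. Slope and intercept are also
#' given on the raw count scale (the correlation is identical on either
#' scale).
#'
#' @param regional_counts Data frame with columns `order` and `count`
#'   (regional species richness per order), or a named numeric vector.
#' @param tested_counts Same layout for the species actually tested.
#' @param exclude Optional character vector of orders to drop before
#'   percentages are (re)normalised.
#' @return An `ssd_repr` object; `tidy()` gives the per-order table,
#'   `glance()` the correlation and line, `autoplot()` the scatter against
#'   the identity line.
#' @export
representativeness_fit <- function(regional_counts, tested_counts, exclude = NULL) {
  as_tbl <- function(x, what) {
    if (is.data.frame(x)) {
      stopifnot(all(c("order", "count") %in% names(x)))
      tibble::tibble(order = as.character(x$order), count = as.numeric(x$count))
    } else if (!is.null(names(x))) {
      tibble::tibble(order = names(x), count = as.numeric(x))
    } else {
      stop(what, " must be a data frame (order, count) or a named vector", call. = FALSE)
    }
  }
  reg <- as_tbl(regional_counts, "regional_counts")
  tst <- as_tbl(tested_counts, "tested_counts")
  if (any(reg$count < 0) || any(tst$count < 0)) stop("counts must be non-negative", call. = FALSE)
  reg$key <- tolower(trimws(reg$order))
  tst$key <- tolower(trimws(tst$order))
  tab <- dplyr::full_join(
    dplyr::select(reg, "key", "order", regional_count = "count"),
    dplyr::select(tst, "key", tested_count = "count"),
    by = "key"
  ) |>
    dplyr::mutate(
      order = dplyr::coalesce(.data$order, .data$key),
      regional_count = dplyr::coalesce(.data$regional_count, 0),
      tested_count = dplyr::coalesce(.data$tested_count, 0)
    )
  if (!is.null(exclude)) {
    tab <- tab[!(tab$key %in% tolower(trimws(exclude))), ]
  }
  tab$key <- NULL
  if (nrow(tab) < 3L) stop("need at least three orders after exclusions", call. = FALSE)
  tab$regional_pct <- 100 * tab$regional_count / sum(tab$regional_count)
  tab$tested_pct <- 100 * tab$tested_count / sum(tab$tested_count)
  tab$residual_from_identity <- tab$tested_pct - tab$regional_pct

  if (stats::sd(tab$regional_pct) == 0 || stats::sd(tab$tested_pct) == 0) {
    r <- NA_real_
    p <- NA_real_
    note <- "zero variance on one axis: correlation undefined"
  } else {
    ct <- stats::cor.test(tab$regional_pct, tab$tested_pct, method = "pearson")
    r <- unname(ct$estimate)
    p <- ct$p.value
    note <- NA_character_
  }
  fit_pct <- stats::lm(tested_pct ~ regional_pct, data = tab)
  fit_cnt <- stats::lm(tested_count ~ regional_count, data = tab)
  structure(
    list(
      table = tibble::as_tibble(tab),
      r = r, p_value = p, n_orders = nrow(tab),
      slope = unname(stats::coef(fit_pct)[2]),
      intercept = unname(stats::coef(fit_pct)[1]),
      slope_counts = unname(stats::coef(fit_cnt)[2]),
      intercept_counts = unname(stats::coef(fit_cnt)[1]),
      note = note
    ),
    class = "ssd_repr"
  )
}

#' @export
print.ssd_repr <- function(x, ...) {
  cat(sprintf(
    "Representativeness over %d orders: r = %.3f (P = %.4g), tested%% = %.3f + %.3f x regional%%\n",
    x$n_orders, x$r, x$p_value, x$intercept, x$slope
  ))
  invisible(x)
}

#' @rdname tidy-ssd
#' @method tidy ssd_repr
#' @export
tidy.ssd_repr <- function(x, ...) x$table

#' @rdname tidy-ssd
#' @method glance ssd_repr
#' @export
glance.ssd_repr <- function(x, ...) {
  tibble::tibble(
    r = x$r, p_value = x$p_value, n_orders = x$n_orders,
    slope = x$slope, intercept = x$intercept,
    slope_counts = x$slope_counts, intercept_counts = x$intercept_counts
  )
}

#' @method autoplot ssd_repr
#' @export
autoplot.ssd_repr <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$regional_pct, y = .data$tested_pct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red", linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "black") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "% of regional species in order",
      y = "% of tested species in order",
      title = "Tested sample vs regional order richness (dashed: y = x)"
    ) +
    ggplot2::theme_minimal()
}
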