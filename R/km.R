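# Kaplan-Meier machinery for censored SSDs.
#
# The SSD is read as a CDF: the fraction of species whose 72-h LC50 falls at
# or below a conductivity. With right-censored records ("> x") present the
# empirical CDF is biased, so the product-limit estimator is used on the
# survivor scale (fraction of species tolerating more). Interval records are
# mid-point imputed before estimation -- the mid-point rule; only the Bayesian
# module treats intervals with a genuine censored likelihood.

# mid-point rule: (time, status) pairs for product-limit estimation
.km_times <- function(records) {
  records <- as_toxicity_records(records)
  tibble::tibble(
    time = ifelse(records$censor_kind == "interval",
      (records$lo + records$hi) / 2, records$lo
    ),
    status = as.integer(records$censor_kind != "right")
  )
}

#' Fit a Kaplan-Meier species sensitivity distribution
#'
#' Estimates the SSD of 72-h LC50 values as a product-limit distribution
#' function. Interval-censored records are imputed to their interval mid-point
#' (the mid-point rule); right-censored records enter as censored at their
#' bound. At tied values, events precede censorings (the standard
#' product-limit convention).
#'
#' @param records A toxicity-record tibble (see [read_toxicity_csv()]).
#' @param conf_level Confidence level for downstream intervals.
#' @return An object of class `ssd_km`: the fitted curve is available via
#'   [tidy()][tidy.ssd_km], summary statistics via [glance()][glance.ssd_km],
#'   [km_mean_ci()] and [km_quantile()].
#' @export
#' @examples
#' recs <- as_toxicity_records(tibble::tibble(
#'   taxon = paste0("sp", 1:3), region = "toy",
#'   order_or_class = "Ephemeroptera", group = "Ephemeroptera",
#'   censor_kind = "point", lo = c(10, 20, 30), hi = c(10, 20, 30),
#'   abundance = "unknown"
#' ))
#' tidy(km_fit(recs))
km_fit <- function(records, conf_level = 0.95) {
  records <- as_toxicity_records(records)
  if (nrow(records) == 0L) {
    stop("km_fit needs at least one record", call. = FALSE)
  }
  ts <- .km_times(records)
  all_censored <- all(ts$status == 0L)
  if (all_censored) {
    warning("all records are right-censored; the SSD is identically zero over the observed range", call. = FALSE)
  }
  fit <- survival::survfit(
    survival::Surv(ts$time, ts$status) ~ 1,
    conf.int = conf_level
  )
  event <- fit$n.event > 0
  # Greenwood variance of the survivor estimate: Var(S) = S^2 * sum d/(n(n-d));
  # survfit's std.err is on the log-survivor (cumulative hazard) scale.
  greenwood <- (fit$surv * fit$std.err)^2
  curve <- tibble::tibble(
    value = fit$time[event],
    n_risk = fit$n.risk[event],
    n_event = fit$n.event[event],
    n_censored = fit$n.censor[event],
    survivor = fit$surv[event],
    cdf = 1 - fit$surv[event],
    greenwood_var = greenwood[event]
  )
  largest_obs <- max(ts$time)
  largest_is_censored <- !any(ts$status == 1L & ts$time == largest_obs)
  structure(
    list(
      fit = fit,
      curve = curve,
      n = nrow(records),
      n_point = sum(records$censor_kind == "point"),
      n_interval = sum(records$censor_kind == "interval"),
      n_right = sum(records$censor_kind == "right"),
      range_lo = if (all_censored) min(ts$time) else min(ts$time[ts$status == 1L]),
      range_hi = largest_obs,
      largest_obs = largest_obs,
      largest_is_censored = largest_is_censored,
      all_censored = all_censored,
      conf_level = conf_level
    ),
    class = "ssd_km"
  )
}

#' @export
print.ssd_km <- function(x, ...) {
  cat("Kaplan-Meier SSD:", x$n, "species (",
    x$n_point, "point,", x$n_interval, "interval,", x$n_right, "right-censored )\n"
  )
  m <- km_mean_ci(x)
  cat(sprintf(
    "  restricted mean %.3g mS/cm (%d%% CI %.3g-%.3g)%s\n",
    m$mean, round(100 * x$conf_level), m$ci_lo, m$ci_hi,
    if (m$lower_bound_only) " [lower bound: all records censored]" else ""
  ))
  invisible(x)
}

#' Restricted mean of a Kaplan-Meier SSD
#'
#' The mean LC50 implied by the curve: the area under the survivor function
#' from zero up to the largest observed or censoring value (the restricted
#' mean). The confidence interval is a normal approximation using the
#' Greenwood-based variance of the restricted mean. For an uncensored sample
#' this is exactly the arithmetic mean.
#'
#' @param x An `ssd_km` object.
#' @param level Confidence level (default taken from the fit).
#' @return A one-row tibble: `mean`, `ci_lo`, `ci_hi`, `se`,
#'   `lower_bound_only` (`TRUE` when every record was censored, in which case
#'   the mean is only a lower bound).
#' @export
km_mean_ci <- function(x, level = x$conf_level) {
  stopifnot(inherits(x, "ssd_km"))
  tab <- summary(x$fit, rmean = x$largest_obs)$table
  m <- unname(tab["rmean"])
  se <- unname(tab["se(rmean)"])
  if (x$all_censored || !is.finite(se)) se <- NA_real_
  z <- stats::qnorm((1 + level) / 2)
  tibble::tibble(
    mean = m,
    se = se,
    ci_lo = if (is.na(se)) NA_real_ else m - z * se,
    ci_hi = if (is.na(se)) NA_real_ else m + z * se,
    lower_bound_only = x$all_censored
  )
}

#' Hazardous-concentration percentiles of a Kaplan-Meier SSD
#'
#' HCp is the concentration at which p% of species have their LC50 exceeded:
#' the p-th percentile of the SSD. On a step function the percentile may not
#' be attained exactly, so three forms are reported:
#' \describe{
#'   \item{exact}{the smallest support value whose CDF equals p/100;}
#'   \item{below_min}{p/100 falls below the first step: the HCp is only known
#'     to lie below the smallest observed value (`"<x"`);}
#'   \item{interval}{p/100 falls strictly inside a jump of the CDF: the HCp is
#'     bracketed between consecutive support values (`"a–b"`);}
#'   \item{above_max}{the CDF never reaches p/100 (heavy right-censoring):
#'     only the bound `">largest"` can be given.}
#' }
#' Confidence limits invert the pointwise survivor confidence band
#' (the method behind `quantile.survfit`).
#'
#' @param x An `ssd_km` object.
#' @param p Percentages in (0, 100); may be a vector.
#' @param level Confidence level for the percentile interval.
#' @return A tibble with one row per `p`: `p`, `estimate` (the attained
#'   support value, `NA` for `above_max`), `bound_kind`, `bound_lo`,
#'   `bound_hi`, `label` (Table-style string), `ci_lo`, `ci_hi`.
#' @export
km_quantile <- function(x, p, level = x$conf_level) {
  stopifnot(inherits(x, "ssd_km"))
  if (any(p <= 0 | p >= 100)) {
    stop("p must be strictly between 0 and 100", call. = FALSE)
  }
  sup <- x$curve$value
  cdf <- x$curve$cdf
  eps <- 1e-9
  qs <- tryCatch(
    stats::quantile(x$fit, probs = p / 100, conf.int = TRUE),
    error = function(e) NULL
  )
  one <- function(pi, idx) {
    target <- pi / 100
    j <- which(cdf >= target - eps)[1]
    ci <- c(NA_real_, NA_real_)
    if (!is.null(qs)) ci <- c(qs$lower[idx], qs$upper[idx])
    if (is.na(j)) {
      return(tibble::tibble(
        p = pi, estimate = NA_real_, bound_kind = "above_max",
        bound_lo = x$largest_obs, bound_hi = Inf,
        label = paste0(">", format(x$largest_obs, digits = 15)),
        ci_lo = ci[1], ci_hi = ci[2]
      ))
    }
    if (abs(cdf[j] - target) <= eps) {
      kind <- "exact"; blo <- sup[j]; bhi <- sup[j]
      lab <- format(sup[j], digits = 15)
    } else if (j == 1L) {
      kind <- "below_min"; blo <- NA_real_; bhi <- sup[1]
      lab <- paste0("<", format(sup[1], digits = 15))
    } else {
      kind <- "interval"; blo <- sup[j - 1L]; bhi <- sup[j]
      lab <- paste0(format(blo, digits = 15), "–", format(bhi, digits = 15))
    }
    tibble::tibble(
      p = pi, estimate = sup[j], bound_kind = kind,
      bound_lo = blo, bound_hi = bhi, label = lab,
      ci_lo = ci[1], ci_hi = ci[2]
    )
  }
  purrr::list_rbind(purrr::imap(as.list(p), one))
}

#' @rdname tidy-ssd
#' @method tidy ssd_km
#' @export
tidy.ssd_km <- function(x, ...) x$curve

#' Tidy and one-line summaries of fitted SSD objects
#'
#' `tidy()` returns the estimated curve (or posterior summaries); `glance()`
#' a one-row overview.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @name tidy-ssd
NULL

#' @rdname tidy-ssd
#' @method glance ssd_km
#' @export
glance.ssd_km <- function(x, ...) {
  m <- km_mean_ci(x)
  med <- km_quantile(x, 50)
  tibble::tibble(
    n = x$n, n_point = x$n_point, n_interval = x$n_interval, n_right = x$n_right,
    range_lo = x$range_lo, range_hi = x$range_hi,
    range_hi_censored = x$largest_is_censored,
    mean = m$mean, mean_lo = m$ci_lo, mean_hi = m$ci_hi,
    median = med$estimate, median_lo = med$ci_lo, median_hi = med$ci_hi
  )
}

#' @method autoplot ssd_km
#' @export
autoplot.ssd_km <- function(object, ...) {
  dat <- dplyr::bind_rows(
    tibble::tibble(value = min(object$range_lo, object$curve$value) * 0.999, cdf = 0),
    object$curve[, c("value", "cdf")],
    tibble::tibble(value = object$largest_obs, cdf = max(object$curve$cdf))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value, y = .data$cdf)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "72-h LC50 (mS/cm)",
      y = "Fraction of species affected",
      title = "Kaplan-Meier species sensitivity distribution"
    ) +
    ggplot2::theme_minimal()
}

#' Region/taxon summary table of Kaplan-Meier SSDs
#'
#' One row per level of a grouping column: value range, restricted mean and
#' median with confidence intervals, HCp percentiles, censoring counts, and
#' letter codes marking means whose confidence intervals overlap (levels
#' sharing a letter are not distinguishable at the chosen level).
#'
#' @param records A toxicity-record tibble.
#' @param by Name of the column to stratify on (e.g. `"region"`, `"group"`);
#'   `NULL` fits one overall curve.
#' @param hc Percentages for the HC columns.
#' @param conf_level Confidence level.
#' @return A tibble, one row per stratum.
#' @export
km_summary <- function(records, by = NULL, hc = c(1, 5, 10, 20), conf_level = 0.95) {
  records <- as_toxicity_records(records)
  strata <- if (is.null(by)) {
    list(Overall = records)
  } else {
    if (!by %in% names(records)) stop("no column '", by, "' in records", call. = FALSE)
    keep <- !is.na(records[[by]])
    split(records[keep, ], records[[by]][keep])
  }
  row_for <- function(recs, label) {
    f <- km_fit(recs, conf_level = conf_level)
    g <- glance(f)
    hcs <- km_quantile(f, hc)
    hc_cols <- stats::setNames(as.list(hcs$label), paste0("hc", hc))
    dplyr::bind_cols(
      tibble::tibble(stratum = label),
      g[, c("range_lo", "range_hi", "range_hi_censored", "mean", "mean_lo", "mean_hi",
            "median", "median_lo", "median_hi")],
      tibble::as_tibble(hc_cols),
      g[, c("n_point", "n_interval", "n_right", "n")]
    )
  }
  out <- purrr::list_rbind(purrr::imap(strata, row_for))
  ok <- is.finite(out$mean_lo) & is.finite(out$mean_hi)
  if (sum(ok) >= 1L) {
    letters_tbl <- ci_letter_groups(
      tibble::tibble(
        label = out$stratum[ok], mean = out$mean[ok],
        ci_lo = out$mean_lo[ok], ci_hi = out$mean_hi[ok]
      )
    )
    out <- dplyr::left_join(out, dplyr::rename(letters_tbl, stratum = "label"), by = "stratum")
  } else {
    out$letters <- NA_character_
  }
  out
}
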