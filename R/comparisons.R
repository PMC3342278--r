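# Between-sample comparisons of censored SSDs: the weighted log-rank family
# (implemented in-package because the at-risk-count weight schemes are not the
# G-rho family), square-root-transformed ANOVA on non-censored values, and
# letter codes for confidence-interval overlap.

#' Weighted k-sample log-rank test between SSDs
#'
#' Compares the Kaplan-Meier SSDs of two or more samples of censored LC50
#' records. Interval records are mid-point imputed; right-censored records
#' enter as censored. The test statistic is the classic weighted log-rank
#' quadratic form: at each distinct event value the observed minus expected
#' event counts per sample are accumulated with a weight, and the statistic is
#' referenced to a chi-square with (number of samples - 1) degrees of freedom.
#'
#' Weight schemes: `"mantel-cox"` (weight 1, the ordinary log-rank),
#' `"breslow"` (weight = number at risk; the generalised Wilcoxon, sensitive
#' to early differences), `"tarone-ware"` (weight = square root of the number
#' at risk).
#'
#' @param records A toxicity-record tibble.
#' @param by Name of the column defining the samples (e.g. `"region"`).
#' @param weight_scheme One of `"mantel-cox"`, `"breslow"`, `"tarone-ware"`.
#' @return An object of class `ssd_logrank` (also a tibble) with `chi2`, `df`,
#'   `p_value`, `weight_scheme` and the per-sample observed/expected table in
#'   attribute `"by_sample"`.
#' @export
logrank_test <- function(records, by = "region",
                         weight_scheme = c("mantel-cox", "breslow", "tarone-ware")) {
  weight_scheme <- match.arg(weight_scheme)
  records <- as_toxicity_records(records)
  if (!by %in% names(records)) stop("no column '", by, "' in records", call. = FALSE)
  grp <- records[[by]]
  if (any(is.na(grp))) {
    records <- records[!is.na(grp), ]
    grp <- records[[by]]
  }
  labels <- sort(unique(grp))
  k <- length(labels)
  if (k < 2L) stop("logrank_test needs at least two non-empty samples", call. = FALSE)
  ts <- .km_times(records)
  gi <- match(grp, labels)

  event_times <- sort(unique(ts$time[ts$status == 1L]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in event_times) {
    at_risk <- ts$time >= t
    n_j <- sum(at_risk)
    n_ij <- tabulate(gi[at_risk], nbins = k)
    ev <- ts$status == 1L & ts$time == t
    d_j <- sum(ev)
    d_ij <- tabulate(gi[ev], nbins = k)
    w <- switch(weight_scheme,
      "mantel-cox" = 1,
      "breslow" = n_j,
      "tarone-ware" = sqrt(n_j)
    )
    O <- O + w * d_ij
    E <- E + w * d_j * n_ij / n_j
    if (n_j > 1L) {
      p_i <- n_ij / n_j
      vcontrib <- (diag(p_i, nrow = k) - outer(p_i, p_i)) *
        (d_j * (n_j - d_j) / (n_j - 1))
      V <- V + w^2 * vcontrib
    }
  }
  z <- O - E
  chi2 <- if (sum(abs(z)) < 1e-12) 0 else as.numeric(t(z) %*% MASS::ginv(V) %*% z)
  chi2 <- max(chi2, 0)
  df <- k - 1L
  out <- tibble::tibble(
    chi2 = chi2, df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
    weight_scheme = weight_scheme
  )
  attr(out, "by_sample") <- tibble::tibble(
    sample = labels, n = tabulate(gi, nbins = k), observed = O, expected = E
  )
  class(out) <- c("ssd_logrank", class(out))
  out
}

#' Pairwise log-rank tests
#'
#' Runs [logrank_test()] for every pair of levels of `by`.
#'
#' @inheritParams logrank_test
#' @return A tibble with one row per pair: `sample_a`, `sample_b`, `chi2`,
#'   `df`, `p_value`, `weight_scheme`. No multiplicity adjustment is applied.
#' @export
logrank_pairwise <- function(records, by = "region",
                             weight_scheme = c("mantel-cox", "breslow", "tarone-ware")) {
  weight_scheme <- match.arg(weight_scheme)
  records <- as_toxicity_records(records)
  labels <- sort(unique(records[[by]][!is.na(records[[by]])]))
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  purrr::list_rbind(purrr::map(pairs, function(pr) {
    sub <- records[records[[by]] %in% pr, ]
    res <- logrank_test(sub, by = by, weight_scheme = weight_scheme)
    dplyr::bind_cols(tibble::tibble(sample_a = pr[1], sample_b = pr[2]), tibble::as_tibble(res))
  }))
}

#' Square-root-transformed ANOVA on non-censored LC50 values
#'
#' Fixed-effects ANOVA of sqrt(LC50) by one or two factors (typically
#' quasi-taxonomic group and region). Right-censored records carry no usable
#' value and are excluded; interval records contribute their mid-point. The
#' square-root transform stabilises variance and improves normality of the
#' concentration data. Factor levels with fewer than two usable values are
#' dropped with a warning (mirroring the exclusion of sparse taxa from a
#' two-way layout). For unbalanced data, Type II sums of squares are used.
#'
#' @param records A toxicity-record tibble.
#' @param factors Character vector of one or two column names.
#' @return A tibble with one row per term (and residuals): `term`, `sumsq`,
#'   `df`, `statistic`, `p_value`; attribute `"ss_type"` records the
#'   sums-of-squares type and `"n_used"` the number of records analysed.
#' @export
anova_sqrt <- function(records, factors = c("group", "region")) {
  records <- as_toxicity_records(records)
  if (!length(factors) %in% 1:2) stop("supply one or two factor columns", call. = FALSE)
  miss <- setdiff(factors, names(records))
  if (length(miss)) stop("no column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  usable <- records$censor_kind != "right" &
    !Reduce(`|`, lapply(factors, function(f) is.na(records[[f]])))
  dat <- records[usable, ]
  dat$.y <- sqrt(ifelse(dat$censor_kind == "interval", (dat$lo + dat$hi) / 2, dat$lo))

  for (f in factors) {
    counts <- table(dat[[f]])
    drop <- names(counts)[counts < 2]
    if (length(drop)) {
      warning(
        "dropping ", f, " level(s) with fewer than two non-censored values: ",
        paste(drop, collapse = ", "),
        call. = FALSE
      )
      dat <- dat[!(dat[[f]] %in% drop), ]
    }
    dat[[f]] <- factor(dat[[f]])
    if (nlevels(droplevels(dat[[f]])) < 2) {
      stop("factor '", f, "' has fewer than two usable levels", call. = FALSE)
    }
  }

  if (length(factors) == 1L) {
    form <- stats::reformulate(factors[1], response = ".y")
    fit <- stats::lm(form, data = dat)
    a <- stats::anova(fit)
    out <- tibble::tibble(
      term = rownames(a), sumsq = a$`Sum Sq`, df = a$Df,
      statistic = a$`F value`, p_value = a$`Pr(>F)`
    )
    attr(out, "ss_type") <- "I (single factor)"
  } else {
    form <- stats::as.formula(paste(".y ~", factors[1], "*", factors[2]))
    fit <- stats::lm(form, data = dat)
    a <- car::Anova(fit, type = 2)
    out <- tibble::tibble(
      term = rownames(a), sumsq = a$`Sum Sq`, df = a$Df,
      statistic = a$`F value`, p_value = a$`Pr(>F)`
    )
    attr(out, "ss_type") <- "II"
  }
  attr(out, "n_used") <- nrow(dat)
  out
}

#' Letter codes for confidence-interval overlap
#'
#' Two means are treated as statistically different when their confidence
#' intervals do not overlap; means sharing at least one letter are not
#' distinguishable under this rule. Letters are assigned by a greedy sweep
#' over means sorted in ascending order: each maximal run of mutually
#' overlapping intervals receives one letter.
#'
#' @param estimates A data frame with columns `label`, `mean`, `ci_lo`,
#'   `ci_hi` (finite intervals).
#' @return A tibble `label`, `letters` (e.g. `"a"`, `"ab"`), in the input
#'   order.
#' @export
#' @examples
#' ci_letter_groups(tibble::tibble(
#'   label = c("A", "B", "C"), mean = c(1.5, 3, 3.5),
#'   ci_lo = c(1, 2.5, 3.2), ci_hi = c(2, 3.4, 4)
#' ))
ci_letter_groups <- function(estimates) {
  estimates <- tibble::as_tibble(estimates)
  if (nrow(estimates) == 0L) {
    return(tibble::tibble(label = character(), letters = character()))
  }
  stopifnot(all(c("label", "mean", "ci_lo", "ci_hi") %in% names(estimates)))
  if (any(!is.finite(estimates$ci_lo) | !is.finite(estimates$ci_hi))) {
    stop("ci_letter_groups needs finite confidence limits", call. = FALSE)
  }
  ord <- order(estimates$mean)
  lo <- estimates$ci_lo[ord]
  hi <- estimates$ci_hi[ord]
  n <- length(ord)
  # every maximal set of mutually overlapping intervals is the set of
  # intervals covering some left endpoint (interval-graph maximal cliques)
  cliques <- unique(lapply(seq_len(n), function(k) which(lo <= lo[k] & hi >= lo[k])))
  keep <- vapply(seq_along(cliques), function(a) {
    !any(vapply(seq_along(cliques), function(b) {
      b != a && length(cliques[[b]]) > length(cliques[[a]]) &&
        all(cliques[[a]] %in% cliques[[b]])
    }, logical(1)))
  }, logical(1))
  cliques <- cliques[keep]
  cliques <- cliques[order(vapply(cliques, min, numeric(1)))]
  codes <- rep("", n)
  for (r in seq_along(cliques)) {
    lt <- letters[(r - 1L) %% 26L + 1L]
    codes[cliques[[r]]] <- paste0(codes[cliques[[r]]], lt)
  }
  out <- tibble::tibble(label = estimates$label[ord], letters = codes)
  out[match(estimates$label, out$label), ]
}

#' Mean/SD/count summaries within a taxonomic rank
#'
#' Plain summaries of non-censored LC50 values (interval records contribute
#' their mid-point) grouped by a user-supplied rank column, optionally
#' crossed with another column such as region. Intended for family- and
#' genus-level tables where sample sizes are too small for formal tests.
#'
#' @param records A toxicity-record tibble with an extra rank column.
#' @param rank_col Name of the column holding the family/genus label.
#' @param by Optional further grouping column (e.g. `"region"`).
#' @return A tibble with `mean`, `sd`, `n` per group.
#' @export
taxa_summary <- function(records, rank_col, by = NULL) {
  records <- as_toxicity_records(records)
  if (!rank_col %in% names(records)) stop("no column '", rank_col, "' in records", call. = FALSE)
  dat <- records[records$censor_kind != "right", ]
  dat$.val <- ifelse(dat$censor_kind == "interval", (dat$lo + dat$hi) / 2, dat$lo)
  keys <- c(rank_col, by)
  dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean = mean(.data$.val),
      sd = stats::sd(.data$.val),
      n = dplyr::n(),
      .groups = "drop"
    )
}
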