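test_that("identical samples give a zero log-rank statistic", {
  recs <- rbind(
    point_records(c(1, 2, 3, 4, 9), region = "A"),
    point_records(c(1, 2, 3, 4, 9), region = "B")
  )
  for (w in c("mantel-cox", "breslow", "tarone-ware")) {
    res <- logrank_test(recs, by = "region", weight_scheme = w)
    expect_equal(res$chi2, 0)
    expect_equal(res$p_value, 1)
    expect_equal(res$df, 1L)
  }
})

test_that("the Mantel-Cox statistic matches survdiff on censored data", {
  set.seed(111)
  for (i in 1:12) {
    k <- sample(2:4, 1)
    regions <- LETTERS[1:k]
    recs <- purrr::list_rbind(purrr::map(regions, function(r) {
      n <- sample(8:30, 1)
      v <- round(stats::rlnorm(n, 2.4 + 0.3 * (r == "A"), 0.5), 1)
      kinds <- ifelse(stats::rbinom(n, 1, 0.75) == 1, "point", "right")
      if (all(kinds == "right")) kinds[1] <- "point"
      make_records(kinds, lo = v, region = r)
    }))
    res <- logrank_test(recs, by = "region")
    ts <- records_to_surv(recs)
    sd_fit <- survival::survdiff(survival::Surv(ts$time, ts$status) ~ recs$region)
    expect_equal(res$chi2, unname(sd_fit$chisq), tolerance = 1e-8)
    expect_equal(res$df, k - 1L)
  }
})

test_that("all weight schemes agree with a direct per-time-table oracle", {
  set.seed(222)
  schemes <- c("mantel-cox" = "unit", "breslow" = "nrisk", "tarone-ware" = "sqrt_nrisk")
  for (i in 1:8) {
    recs <- rbind(
      make_records(sample(c("point", "right"), 15, TRUE, c(.8, .2)),
        lo = round(stats::rlnorm(15, 2.2, 0.5), 1), region = "A"
      ),
      make_records(sample(c("point", "right"), 12, TRUE, c(.8, .2)),
        lo = round(stats::rlnorm(12, 2.6, 0.5), 1), region = "B"
      )
    )
    ts <- records_to_surv(recs)
    for (s in names(schemes)) {
      res <- logrank_test(recs, by = "region", weight_scheme = s)
      orc <- logrank_oracle(ts$time, ts$status, recs$region, weight = schemes[[s]])
      expect_equal(res$chi2, orc$chi2, tolerance = 1e-8)
    }
  }
})

test_that("the log-rank test is invariant to sample order and monotone transforms", {
  set.seed(333)
  recs <- rbind(
    make_records(c(rep("point", 9), "right"), lo = round(stats::rlnorm(10, 2.3, 0.4), 2), region = "A"),
    make_records(rep("point", 12), lo = round(stats::rlnorm(12, 2.7, 0.4), 2), region = "B")
  )
  base <- logrank_test(recs, by = "region")
  shuffled <- recs[sample(nrow(recs)), ]
  expect_equal(logrank_test(shuffled, by = "region")$chi2, base$chi2, tolerance = 1e-12)
  transformed <- recs
  transformed$lo <- recs$lo^1.7 # strictly increasing: ranks unchanged
  transformed$hi <- ifelse(is.finite(recs$hi), recs$hi^1.7, Inf)
  expect_equal(
    logrank_test(as_toxicity_records(transformed), by = "region")$chi2,
    base$chi2,
    tolerance = 1e-10
  )
})

test_that("the chi-square p approximates the exhaustive permutation null on a small sample", {
  # 8 uncensored values, 4 per sample: enumerate all 70 label assignments
  v <- c(3.1, 5.2, 8.4, 9.9, 12.0, 15.5, 19.3, 24.8)
  labels0 <- c("A", "A", "A", "A", "B", "B", "B", "B")
  obs <- logrank_test(point_records(v, region = "X") |>
    dplyr::mutate(region = labels0), by = "region")
  combs <- utils::combn(8, 4)
  chi2s <- apply(combs, 2, function(idx) {
    lab <- rep("B", 8)
    lab[idx] <- "A"
    logrank_test(point_records(v, region = "X") |>
      dplyr::mutate(region = lab), by = "region")$chi2
  })
  perm_p <- mean(chi2s >= obs$chi2 - 1e-12)
  # the asymptotic tail probability should approximate the exact discrete one
  expect_lt(abs(perm_p - obs$p_value), 0.15)
  # and the observed labelling is among the enumerated ones
  expect_true(any(abs(chi2s - obs$chi2) < 1e-12))
})

test_that("samples with no records are rejected", {
  recs <- point_records(c(1, 2, 3), region = "A")
  expect_error(logrank_test(recs, by = "region"), "two non-empty samples")
})

test_that("two-way sqrt ANOVA reproduces the closed-form balanced decomposition", {
  # balanced 2x2 layout, 3 replicates per cell
  set.seed(444)
  vals <- round(stats::rlnorm(12, 2.5, 0.4), 2)
  recs <- purrr::list_rbind(purrr::imap(
    list(
      c("Ephemeroptera", "A"), c("Ephemeroptera", "B"),
      c("Crustaceans", "A"), c("Crustaceans", "B")
    ),
    function(cell, i) {
      point_records(vals[(3 * i - 2):(3 * i)],
        region = cell[2], group = cell[1]
      )
    }
  ))
  out <- anova_sqrt(recs, factors = c("group", "region"))
  y <- sqrt(vals)
  g <- factor(rep(c("E", "E", "C", "C"), each = 3))
  r <- factor(rep(c("A", "B", "A", "B"), each = 3))
  # direct sums-of-squares decomposition (balanced: Type I = II = III)
  ssa <- sum(tapply(y, g, function(x) length(x) * (mean(x) - mean(y))^2))
  ssb <- sum(tapply(y, r, function(x) length(x) * (mean(x) - mean(y))^2))
  cellm <- tapply(y, interaction(g, r), mean)
  ssab <- 3 * sum((cellm - rep(tapply(y, g, mean), 2) -
    tapply(y, r, mean)[rep(1:2, each = 2)] + mean(y))^2)
  sse <- sum((y - ave(y, interaction(g, r)))^2)
  expect_equal(out$sumsq[out$term == "group"], ssa, tolerance = 1e-8)
  expect_equal(out$sumsq[out$term == "region"], ssb, tolerance = 1e-8)
  expect_equal(out$sumsq[out$term == "group:region"], ssab, tolerance = 1e-8)
  expect_equal(
    out$statistic[out$term == "group"],
    (ssa / 1) / (sse / 8),
    tolerance = 1e-8
  )
})

test_that("ANOVA excludes right-censored records and drops sparse levels", {
  recs <- rbind(
    point_records(c(10, 12, 14, 9, 11, 13), region = "A", group = "Ephemeroptera"),
    point_records(c(20, 22, 24, 19, 21, 23), region = "B", group = "Crustaceans"),
    make_records("right", 60, region = "A", group = "Ephemeroptera"),
    point_records(33, region = "A", group = "Hydracarina") # single usable value
  )
  expect_warning(
    out <- anova_sqrt(recs, factors = "group"),
    "Hydracarina"
  )
  expect_equal(attr(out, "n_used"), 12L) # censored + dropped rows excluded
  # identical value multisets across two regions: region F ~ 0
  recs2 <- rbind(
    point_records(c(5, 10, 15, 20), region = "A"),
    point_records(c(5, 10, 15, 20), region = "B")
  )
  out2 <- anova_sqrt(recs2, factors = "region")
  expect_lt(out2$statistic[out2$term == "region"], 1e-20)
})

test_that("CI letter groups share letters exactly when intervals overlap", {
  d1 <- tibble::tibble(
    label = c("x", "y"), mean = c(1.5, 3.5),
    ci_lo = c(1, 3), ci_hi = c(2, 4)
  )
  expect_equal(ci_letter_groups(d1)$letters, c("a", "b"))
  d2 <- tibble::tibble(
    label = c("x", "y"), mean = c(2, 3),
    ci_lo = c(1, 2), ci_hi = c(3, 4)
  )
  expect_equal(ci_letter_groups(d2)$letters, c("a", "a"))
  # three regions with published-style intervals: the two sensitive regions
  # share a letter, the tolerant one stands apart
  d3 <- tibble::tibble(
    label = c("FRA", "EAUS", "ISR"),
    mean = c(22.3, 33.3, 24.9),
    ci_lo = c(19.5, 30.1, 19.5),
    ci_hi = c(25.0, 36.6, 26.6)
  )
  out <- ci_letter_groups(d3)
  expect_equal(out$letters[out$label == "FRA"], out$letters[out$label == "ISR"])
  expect_false(out$letters[out$label == "EAUS"] %in% out$letters[out$label != "EAUS"])
  # chain overlap: middle interval overlaps both ends, ends do not overlap
  d4 <- tibble::tibble(
    label = c("l", "m", "h"), mean = c(1, 2, 3),
    ci_lo = c(0.5, 1.4, 2.4), ci_hi = c(1.5, 2.6, 3.5)
  )
  out4 <- ci_letter_groups(d4)
  expect_equal(out4$letters, c("a", "ab", "b"))
  expect_equal(nrow(ci_letter_groups(d1[0, ])), 0L)
})

test_that("taxa summaries report mean, SD and count of non-censored values", {
  recs <- rbind(
    point_records(c(10, 20), region = "FRA"),
    make_records("interval", 10, 14, region = "FRA"),
    make_records("right", 30, region = "FRA")
  )
  recs$family <- "Baetidae"
  out <- taxa_summary(recs, rank_col = "family", by = "region")
  expect_equal(out$n, 3L) # right-censored row excluded, interval as mid-point
  expect_equal(out$mean, mean(c(10, 20, 12)))
  expect_equal(out$sd, stats::sd(c(10, 20, 12)))
})
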