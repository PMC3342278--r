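test_that("with fixed variances the group-mean posterior matches the conjugate closed form", {
  set.seed(11)
  vals <- round(10^stats::rnorm(15, 1.2, 0.2), 3)
  recs <- point_records(vals)
  sigma <- 0.2
  tau <- 0.5
  sp <- hier_spec(
    seed = 99, n_chains = 2, n_iter = 5000, n_burnin = 1000,
    sigma_fixed = sigma, tau_fixed = tau
  )
  fit <- fit_hierarchical(recs, sp)
  draws <- fit$draws[, "mu[Ephemeroptera]"]
  y <- log10(vals)
  n <- length(y)
  # integrating out the hyper-mean, mu_g has prior N(0, prior_var + tau^2),
  # so the posterior is the normal-normal closed form
  prior_var <- 1e6 + tau^2
  post_prec <- n / sigma^2 + 1 / prior_var
  post_mean <- (sum(y) / sigma^2) / post_prec
  post_sd <- sqrt(1 / post_prec)
  mc_se <- post_sd / sqrt(200) # conservative effective sample size
  expect_lt(abs(mean(draws) - post_mean), 4 * mc_se)
  expect_lt(abs(stats::sd(draws) - post_sd) / post_sd, 0.1)
})

test_that("a group without data gets its mean from the hyper-population predictive", {
  set.seed(12)
  recs <- rbind(
    point_records(round(10^stats::rnorm(12, 1.0, 0.15), 3), group = "Ephemeroptera"),
    point_records(round(10^stats::rnorm(12, 1.5, 0.15), 3), group = "Crustaceans"),
    point_records(round(10^stats::rnorm(12, 1.2, 0.15), 3), group = "Hydracarina")
  )
  sp <- hier_spec(seed = 7, n_chains = 2, n_iter = 6000, n_burnin = 2000)
  fit <- fit_hierarchical(recs, sp, groups = c(unique(recs$group), "Non-arthropods"))
  d <- fit$draws
  mu_empty <- d[, "mu[Non-arthropods]"]
  # distributionally mu_empty | draw ~ N(mu_hyper, tau2): matching first two
  # moments of the mixture over draws
  expect_lt(abs(mean(mu_empty) - mean(d[, "mu_hyper"])), 0.1)
  expected_var <- mean(d[, "tau2_hyper"]) + stats::var(d[, "mu_hyper"])
  expect_lt(abs(stats::var(mu_empty) / expected_var - 1), 0.25)
})

test_that("tightly bracketing a point value as an interval barely moves the posterior", {
  set.seed(13)
  vals <- round(10^stats::rnorm(20, 1.25, 0.2), 3)
  point_recs <- point_records(vals)
  brack <- point_recs
  brack$censor_kind <- "interval"
  brack$lo <- vals * 0.99
  brack$hi <- vals * 1.01
  sp <- hier_spec(seed = 21, n_chains = 2, n_iter = 6000, n_burnin = 2000)
  f1 <- fit_hierarchical(point_recs, sp)
  f2 <- fit_hierarchical(as_toxicity_records(brack), sp)
  m1 <- mean(f1$draws[, "mu[Ephemeroptera]"])
  m2 <- mean(f2$draws[, "mu[Ephemeroptera]"])
  expect_lt(abs(m1 - m2), 0.02)
})

test_that("the censored likelihood pulls right-censored groups above their bound", {
  set.seed(14)
  recs <- rbind(
    point_records(round(10^stats::rnorm(10, 1.1, 0.1), 2), group = "Ephemeroptera"),
    make_records("right", rep(30, 6), group = "Crustaceans")
  )
  sp <- hier_spec(seed = 31, n_chains = 2, n_iter = 8000, n_burnin = 3000)
  fit <- fit_hierarchical(recs, sp)
  # every crustacean record says LC50 > 30 mS/cm (log10 = 1.477)
  expect_gt(mean(fit$draws[, "mu[Crustaceans]"]), log10(30) - 0.15)
  expect_gt(mean(fit$draws[, "mu[Crustaceans]"]), mean(fit$draws[, "mu[Ephemeroptera]"]))
})

test_that("weighted HC percentiles have the analytic values for symmetric mixtures", {
  groups <- c("Ephemeroptera", "Crustaceans")
  mu <- matrix(c(1.0, 1.0, 1.4, 1.8), nrow = 2) # two draws
  post <- fake_posterior(mu, sigma2_draws = c(0.04, 0.04), groups = groups)
  # single-group weight: HC50 of each draw is 10^mu
  hc1 <- weighted_hc(post, c("Ephemeroptera" = 1), p = 50, keep_draws = TRUE)
  expect_equal(attr(hc1, "draws")[, 1], 10^mu[, 1], tolerance = 1e-7)
  # equal weights, common sigma: HC50 = 10^((mu1+mu2)/2) by symmetry
  hc2 <- weighted_hc(post, c("Ephemeroptera" = 0.5, "Crustaceans" = 0.5),
    p = 50, keep_draws = TRUE
  )
  expect_equal(attr(hc2, "draws")[, 1], 10^rowMeans(mu), tolerance = 1e-7)
  expect_error(weighted_hc(post, c("Ephemeroptera" = 1), p = 0), "strictly between")
})

test_that("bisection agrees with a dense-grid inversion of the mixture CDF", {
  set.seed(15)
  groups <- c("Ephemeroptera", "Crustaceans", "Non-arthropods")
  mu <- matrix(stats::rnorm(15, 1.2, 0.3), ncol = 3)
  sig2 <- stats::runif(5, 0.02, 0.08)
  w <- c(0.2, 0.5, 0.3)
  names(w) <- groups
  post <- fake_posterior(mu, sig2, groups)
  for (p in c(5, 50, 90)) {
    hc <- weighted_hc(post, w, p = p, keep_draws = TRUE)
    dr <- attr(hc, "draws")[, 1]
    grid <- seq(-1, 4, by = 1e-5) # log10 axis
    for (d in 1:5) {
      paf <- rowSums(sapply(1:3, function(g) w[g] * stats::pnorm((grid - mu[d, g]) / sqrt(sig2[d]))))
      root <- grid[which(paf >= p / 100)[1]]
      expect_equal(log10(dr[d]), root, tolerance = 1e-4)
    }
  }
})

test_that("per-draw HCp is strictly increasing in p", {
  set.seed(16)
  groups <- c("Ephemeroptera", "Crustaceans")
  mu <- matrix(stats::rnorm(40, 1.3, 0.25), ncol = 2)
  post <- fake_posterior(mu, stats::runif(20, 0.02, 0.08), groups)
  ps <- c(1, 5, 10, 20, 50, 80)
  hc <- weighted_hc(post, c("Ephemeroptera" = 0.4, "Crustaceans" = 0.6),
    p = ps, keep_draws = TRUE
  )
  dr <- attr(hc, "draws")
  expect_true(all(apply(dr, 1, function(x) all(diff(x) > 0))))
  expect_true(all(diff(hc$median) > 0))
})

test_that("the HC5 is stable under the alternative hyper-variance prior", {
  cfg <- assemblage_config(seed = 17, n_species = 80)
  sim <- generate_assemblage(cfg)
  base <- hier_spec(seed = 23, n_chains = 2, n_iter = 6000, n_burnin = 2000)
  alt <- hier_spec(
    seed = 23, n_chains = 2, n_iter = 6000, n_burnin = 2000,
    tau_prior = "invgamma"
  )
  f1 <- fit_hierarchical(sim$records, base, groups = quasi_groups())
  f2 <- fit_hierarchical(sim$records, alt, groups = quasi_groups())
  w <- default_france_weights()
  h1 <- weighted_hc(f1, w, p = 5, keep_draws = TRUE, force = TRUE)
  h2 <- weighted_hc(f2, w, p = 5, keep_draws = TRUE, force = TRUE)
  iqr <- stats::IQR(attr(h1, "draws")[, 1])
  expect_lt(abs(h1$median - h2$median), iqr)
})

test_that("convergence gating, seed reproducibility and input checks behave", {
  set.seed(18)
  recs <- point_records(round(10^stats::rnorm(10, 1.2, 0.2), 3))
  sp <- hier_spec(seed = 5, n_chains = 2, n_iter = 2000, n_burnin = 500)
  f1 <- fit_hierarchical(recs, sp)
  f2 <- fit_hierarchical(recs, sp)
  expect_identical(f1$draws, f2$draws) # seed fixes everything
  expect_equal(nrow(f1$draws), 2 * 1500)
  # force flag bypasses the (artificially failed) convergence gate
  f1$converged <- FALSE
  expect_error(tidy(f1), "split-Rhat")
  expect_s3_class(tidy(f1, force = TRUE), "tbl_df")
  expect_error(fit_hierarchical(recs[0, ], sp), "record")
  expect_error(hier_spec(seed = 1, n_iter = 100, n_burnin = 100))
  # unmapped orders are dropped with a message
  lep <- tibble::tibble(
    taxon = "moth", region = "X", order_or_class = "Lepidoptera",
    group = NA_character_, censor_kind = "point", lo = 20, hi = 20,
    abundance = "unknown"
  )
  expect_message(
    fit_hierarchical(rbind(recs, as_toxicity_records(lep)), sp),
    "unmapped"
  )
})
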