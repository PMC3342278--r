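# build toxicity-record tibbles tersely for tests
make_records <- function(kind, lo, hi = lo, region = "X",
                         group = "Ephemeroptera", order = group,
                         taxon = NULL, abundance = "unknown") {
  n <- length(lo)
  kind <- rep_len(kind, n)
  hi <- ifelse(kind == "right", Inf, hi)
  as_toxicity_records(tibble::tibble(
    taxon = if (is.null(taxon)) paste0("sp", seq_len(n), "_", region) else taxon,
    region = region,
    order_or_class = rep_len(order, n),
    group = rep_len(group, n),
    censor_kind = kind,
    lo = lo,
    hi = hi,
    abundance = rep_len(abundance, n)
  ))
}

point_records <- function(values, ...) {
  make_records("point", values, values, ...)
}

# independent product-limit oracle: direct loop over event values.
# Returns support, survivor, and the restricted mean as the step-area sum.
km_oracle <- function(time, status) {
  ord <- order(time, -status) # events before censorings at ties
  time <- time[ord]
  status <- status[ord]
  ev <- sort(unique(time[status == 1]))
  s <- 1
  surv <- numeric(length(ev))
  for (i in seq_along(ev)) {
    n_risk <- sum(time >= ev[i])
    d <- sum(time == ev[i] & status == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  tmax <- max(time)
  grid <- c(0, ev, tmax)
  sfun <- stats::stepfun(ev, c(1, surv), right = FALSE)
  # area under the survivor step function on [0, tmax]
  knots <- unique(sort(c(0, ev[ev <= tmax], tmax)))
  area <- sum(sfun(knots[-length(knots)]) * diff(knots))
  list(support = ev, survivor = surv, rmean = area)
}

# independent weighted log-rank oracle: explicit per-event-time 2xk tables
logrank_oracle <- function(time, status, group, weight = c("unit", "nrisk", "sqrt_nrisk")) {
  weight <- match.arg(weight)
  labels <- sort(unique(group))
  k <- length(labels)
  gi <- match(group, labels)
  ev <- sort(unique(time[status == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev) {
    risk <- time >= t
    nj <- sum(risk)
    nij <- sapply(seq_len(k), function(g) sum(risk & gi == g))
    dj <- sum(time == t & status == 1)
    dij <- sapply(seq_len(k), function(g) sum(time == t & status == 1 & gi == g))
    w <- switch(weight, unit = 1, nrisk = nj, sqrt_nrisk = sqrt(nj))
    O <- O + w * dij
    E <- E + w * dj * nij / nj
    if (nj > 1) {
      pi_ <- nij / nj
      V <- V + w^2 * dj * (nj - dj) / (nj - 1) * (diag(pi_, nrow = k) - outer(pi_, pi_))
    }
  }
  z <- (O - E)[-k]
  Vr <- V[-k, -k, drop = FALSE]
  chi2 <- tryCatch(as.numeric(t(z) %*% solve(Vr) %*% z), error = function(e) 0)
  list(chi2 = chi2, df = k - 1)
}

records_to_surv <- function(records) {
  list(
    time = ifelse(records$censor_kind == "interval",
      (records$lo + records$hi) / 2, records$lo
    ),
    status = as.integer(records$censor_kind != "right")
  )
}

# minimal hand-built posterior object for testing the weighted-SSD quantile
# machinery in isolation from the sampler
fake_posterior <- function(mu_draws, sigma2_draws, groups) {
  colnames(mu_draws) <- paste0("mu[", groups, "]")
  draws <- cbind(
    mu_draws,
    sigma2 = sigma2_draws,
    mu_hyper = rowMeans(mu_draws),
    tau2_hyper = rep(0.1, nrow(mu_draws))
  )
  structure(
    list(
      draws = draws, chains = list(draws), groups = groups,
      data_groups = groups, n_records = 0L, n_censored = 0L,
      spec = hier_spec(seed = 1, n_chains = 1, n_iter = 2, n_burnin = 1),
      diagnostics = tibble::tibble(
        parameter = colnames(draws), rhat = 1, ess = nrow(draws)
      ),
      converged = TRUE
    ),
    class = "ssd_hier"
  )
}
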