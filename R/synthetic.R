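# Synthetic assemblages with the generative structure the hierarchical model
# assumes: group mean log10 tolerances drawn from a normal hyper-population,
# species drawn within groups with one shared SD, group membership multinomial
# in the richness weights, and censoring induced by a finite ladder of tested
# concentrations (as in a rapid toxicity-test design, where an LC50 is only
# ever bracketed between consecutive tested concentrations or exceeds the
# highest one).

#' Configuration of a synthetic assemblage
#'
#' Defaults describe the study conditions of a wet-temperate (France-like)
#' assemblage: hyper-mean 1.26 log10 mS/cm (about 18 mS/cm), between-group SD
#' `sqrt(0.0868)`, within-group SD `sqrt(0.0517)`, 92 tested species, and the
#' fixed test-concentration ladder 2.5-55 mS/cm spanning the observed range
#' of macroinvertebrate 72-h LC50s.
#'
#' @param seed Integer seed; required.
#' @param weights A [regional_weights()] table (default
#'   [default_france_weights()]).
#' @param mu_hyper Hyper-population mean, log10 mS/cm.
#' @param tau Between-group SD, log10 scale (>= 0).
#' @param sigma Within-group SD, log10 scale (>= 0).
#' @param n_species Number of species tested.
#' @param ladder Strictly ascending positive tested concentrations (mS/cm).
#'   Latent LC50s above the top rung become right-censored; below the bottom
#'   rung they are bracketed down to 0.1 mS/cm (dilute freshwater
#'   background).
#' @return An `assemblage_config` list.
#' @export
assemblage_config <- function(seed,
                              weights = default_france_weights(),
                              mu_hyper = 1.26,
                              tau = sqrt(0.0868),
                              sigma = sqrt(0.0517),
                              n_species = 92L,
                              ladder = c(2.5, 5, 10, 15, 20, 27.5, 35, 45, 55)) {
  if (missing(seed)) stop("assemblage_config requires an explicit seed", call. = FALSE)
  if (!is.data.frame(weights)) weights <- regional_weights(weights)
  stopifnot(
    n_species >= 1L, sigma >= 0, tau >= 0,
    all(ladder > 0), all(diff(ladder) > 0), length(ladder) >= 2L
  )
  structure(
    list(
      seed = as.integer(seed), weights = weights, mu_hyper = mu_hyper,
      tau = tau, sigma = sigma, n_species = as.integer(n_species),
      ladder = ladder
    ),
    class = "assemblage_config"
  )
}

#' Generate a synthetic censored assemblage
#'
#' Draws group means from the hyper-population, assigns species to groups
#' multinomially by richness weight, draws latent log10 LC50s within groups,
#' and reports each species as the ladder interval containing its latent
#' value (interval-censored record) or as right-censored at the ladder
#' maximum. The generating parameters are returned so recovery experiments
#' can score the fitted posterior against truth. Fully reproducible from the
#' seed.
#'
#' @param config An [assemblage_config()].
#' @return A list: `records` (toxicity-record tibble, region `"SYN"`) and
#'   `truth` (`mu_g` named by group, `sigma`, `mu_hyper`, `tau`, and the
#'   latent values `latent_log10`).
#' @export
generate_assemblage <- function(config) {
  stopifnot(inherits(config, "assemblage_config"))
  set.seed(config$seed)
  groups <- config$weights$group
  w <- config$weights$weight
  G <- length(groups)
  mu_g <- stats::rnorm(G, config$mu_hyper, config$tau)
  names(mu_g) <- groups
  gi <- sample.int(G, config$n_species, replace = TRUE, prob = w)
  latent <- stats::rnorm(config$n_species, mu_g[gi], config$sigma)
  value <- 10^latent
  ladder <- config$ladder
  floor_c <- 0.1 # dilute freshwater background conductivity, mS/cm
  idx <- findInterval(value, ladder)
  top <- max(ladder)
  kind <- ifelse(value >= top, "right", "interval")
  lo <- ifelse(kind == "right", top, ifelse(idx == 0, floor_c, ladder[pmax(idx, 1)]))
  hi <- ifelse(kind == "right", Inf, ladder[pmin(idx + 1L, length(ladder))])
  records <- tibble::tibble(
    taxon = sprintf("synthetic_sp_%04d", seq_len(config$n_species)),
    region = "SYN",
    order_or_class = groups[gi],
    group = groups[gi],
    censor_kind = kind,
    lo = lo,
    hi = hi,
    abundance = "unknown"
  )
  list(
    records = as_toxicity_records(records),
    truth = list(
      mu_g = mu_g, sigma = config$sigma, mu_hyper = config$mu_hyper,
      tau = config$tau, latent_log10 = latent, group_index = gi
    )
  )
}

#' Parameter-recovery experiment for the hierarchical model
#'
#' Repeatedly generates assemblages from known parameters, fits the
#' hierarchical censored model, and scores the posterior: mean bias of the
#' posterior mean and empirical coverage of the central 95% credible
#' interval, per parameter (group means are pooled over groups and
#' replicates). Replicates whose chains fail the split-Rhat check are
#' excluded and counted.
#'
#' @param config An [assemblage_config()]; replicate r regenerates with seed
#'   `config$seed + r`.
#' @param spec A [hier_spec()]; replicate r refits with seed
#'   `spec$seed + 1000 * r`.
#' @param n_replicates Number of replicates (keep modest; each replicate is a
#'   full MCMC fit).
#' @param level Credible level scored (default 0.95).
#' @return A tibble with one row per parameter (`mu_group`, `mu_hyper`,
#'   `sigma2`, `tau2_hyper`): `mean_bias`, `coverage`, binomial 95% bounds
#'   `coverage_lo`/`coverage_hi`, `n_scored`; attribute `"n_divergent"`
#'   counts excluded replicates.
#' @export
recovery_experiment <- function(config, spec, n_replicates = 50L, level = 0.95) {
  stopifnot(inherits(config, "assemblage_config"), inherits(spec, "hier_spec"))
  a <- (1 - level) / 2
  rows <- list()
  n_divergent <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- generate_assemblage(cfg)
    sp <- spec
    sp$seed <- spec$seed + 1000L * r
    fit <- fit_hierarchical(sim$records, sp, groups = config$weights$group)
    if (!fit$converged) {
      n_divergent <- n_divergent + 1L
      next
    }
    d <- fit$draws
    truth <- c(
      stats::setNames(
        sim$truth$mu_g[fit$groups],
        paste0("mu[", fit$groups, "]")
      ),
      sigma2 = sim$truth$sigma^2,
      mu_hyper = sim$truth$mu_hyper,
      tau2_hyper = sim$truth$tau^2
    )
    # only score group means for groups with data (others are predictive)
    present <- paste0("mu[", sort(unique(sim$records$group)), "]")
    score <- c(present, "sigma2", "mu_hyper", "tau2_hyper")
    for (pn in score) {
      dr <- d[, pn]
      ci <- stats::quantile(dr, c(a, 1 - a))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        replicate = r,
        parameter = if (startsWith(pn, "mu[")) "mu_group" else pn,
        bias = mean(dr) - truth[[pn]],
        covered = truth[[pn]] >= ci[1] && truth[[pn]] <= ci[2]
      )
    }
  }
  raw <- purrr::list_rbind(rows)
  out <- raw |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      mean_bias = mean(.data$bias),
      coverage = mean(.data$covered),
      coverage_lo = stats::binom.test(sum(.data$covered), dplyr::n())$conf.int[1],
      coverage_hi = stats::binom.test(sum(.data$covered), dplyr::n())$conf.int[2],
      n_scored = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "n_divergent") <- n_divergent
  attr(out, "replicates") <- raw
  out
}
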