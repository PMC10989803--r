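# Gaussian niche-model community simulator. Samples sit on a 1-D latent
# environmental gradient drawn from a two-region mixture (emulating a
# survey spanning two climatically distinct zones); six observed
# environmental variables are noisy linear loadings of that gradient, so
# they are correlated with each other as field variables are. Each OTU has
# a Gaussian niche (optimum mu, breadth sigma, peak intensity A) on the
# gradient; a sample's counts are one multinomial draw of fixed depth from
# the normalized niche intensities, matching a post-rarefaction table.
# Because truth (mu, sigma, ecotype) is returned alongside the data, the
# whole estimation pipeline can be validated by parameter recovery.

#' Define a simulation scenario
#'
#' Defaults emulate a two-region field survey: 472 samples, a 2000-OTU pool
#' mixing broad-niche (generalist) and narrow-niche (specialist) taxa, and
#' a rarefied depth of 9736 reads per sample, with six correlated
#' environmental variables.
#'
#' @param n_samples Number of samples.
#' @param n_otus Size of the OTU pool.
#' @param generalist_fraction Fraction of the pool drawn from the
#'   broad-niche (generalist) breadth range.
#' @param depth Reads per sample (fixed; every generated column sums to it).
#' @param region_means Latent-gradient means of the two regions.
#' @param region_sd Within-region gradient spread.
#' @param region_prop Fraction of samples in the first region.
#' @param env_loadings Named length-6 vector mapping the latent gradient to
#'   the observed variables.
#' @param env_noise_sd Gaussian noise sd added to each observed variable.
#' @param mu_range Range of niche optima.
#' @param sigma_specialist,sigma_generalist Uniform ranges of niche breadth
#'   for the two ecotype pools.
#' @param sigma_cut Breadth at or above which the truth table flags an OTU
#'   generalist.
#' @param peak_sdlog Log-sd of the lognormal peak intensities.
#' @param specialist_mu_skew If `TRUE`, specialist optima are drawn with
#'   density increasing toward the upper end of `mu_range`, so the
#'   specialist pool available to a sample grows along the gradient and a
#'   richness gradient emerges (see [scenario_richness_gradient()]).
#' @param seed Integer master seed.
#' @return Object of class `scenario`.
#' @export
scenario <- function(n_samples = 472L, n_otus = 2000L,
                     generalist_fraction = 0.25, depth = 9736L,
                     region_means = c(-1.5, 1.5), region_sd = 0.8,
                     region_prop = 0.5,
                     env_loadings = c(pH = -0.8, moisture = 0.5, TOC = 0.6,
                                      TN = 0.7, AMT = 0.9, AP = 0.85),
                     env_noise_sd = 0.6,
                     mu_range = c(-3, 3),
                     sigma_specialist = c(0.3, 1.2),
                     sigma_generalist = c(1.5, 5),
                     sigma_cut = 1.35,
                     peak_sdlog = 0.5,
                     specialist_mu_skew = FALSE,
                     seed = 42L) {
  stopifnot(n_samples >= 2, n_otus >= 1, depth >= 1,
            generalist_fraction >= 0, generalist_fraction <= 1,
            length(region_means) == 2L, region_sd > 0,
            region_prop > 0, region_prop < 1,
            length(env_loadings) >= 1L, env_noise_sd >= 0,
            diff(mu_range) > 0, all(sigma_specialist > 0),
            all(sigma_generalist > 0), sigma_cut > 0, peak_sdlog >= 0)
  if (is.null(names(env_loadings)))
    names(env_loadings) <- paste0("var", seq_along(env_loadings))
  structure(list(n_samples = as.integer(n_samples),
                 n_otus = as.integer(n_otus),
                 generalist_fraction = generalist_fraction,
                 depth = as.integer(depth),
                 region_means = region_means, region_sd = region_sd,
                 region_prop = region_prop, env_loadings = env_loadings,
                 env_noise_sd = env_noise_sd, mu_range = mu_range,
                 sigma_specialist = sigma_specialist,
                 sigma_generalist = sigma_generalist,
                 sigma_cut = sigma_cut, peak_sdlog = peak_sdlog,
                 specialist_mu_skew = specialist_mu_skew,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' Benchmark scenario for parameter-recovery checks
#'
#' A deliberately moderate-sized scenario (400 samples, 600 OTUs, depth
#' 5000) used throughout the test suite: large enough for stable recovery
#' statistics, small enough to run the full pipeline in seconds.
#'
#' @param seed Integer master seed.
#' @return A [scenario()].
#' @export
scenario_recovery <- function(seed = 42L) {
  scenario(n_samples = 400L, n_otus = 600L, depth = 5000L, seed = seed)
}

#' Richness-gradient scenario preset
#'
#' Specialist niche optima are drawn with density increasing along the
#' latent gradient, so samples further along it can recruit from a larger
#' specialist pool: richness rises by specialist addition, the
#' generalist/specialist abundance balance tilts toward specialists, and
#' community mean tolerance breadth falls — a negative richness-CMTB
#' association by construction.
#'
#' @param seed Integer master seed.
#' @return A [scenario()].
#' @export
scenario_richness_gradient <- function(seed = 42L) {
  scenario(n_samples = 200L, n_otus = 600L, depth = 5000L,
           specialist_mu_skew = TRUE, seed = seed)
}

#' Generate the environment table and latent gradient of a scenario
#'
#' Draws each sample's latent gradient position from the two-region
#' mixture, then each observed variable as `loading * gradient + noise`.
#'
#' @param sc A [scenario()].
#' @return List: `env` (samples x variables matrix), `gradient` (latent
#'   positions), `region` (factor `"R1"`/`"R2"`).
#' @export
generate_environment <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  set.seed(sc$seed)
  n1 <- round(sc$region_prop * sc$n_samples)
  n2 <- sc$n_samples - n1
  g <- c(stats::rnorm(n1, sc$region_means[1L], sc$region_sd),
         stats::rnorm(n2, sc$region_means[2L], sc$region_sd))
  region <- factor(rep(c("R1", "R2"), c(n1, n2)))
  p <- length(sc$env_loadings)
  env <- outer(g, sc$env_loadings) +
    matrix(stats::rnorm(sc$n_samples * p, 0, sc$env_noise_sd),
           nrow = sc$n_samples)
  dimnames(env) <- list(sprintf("S%03d", seq_len(sc$n_samples)),
                        names(sc$env_loadings))
  list(env = env, gradient = g, region = region)
}

#' Generate the niche truth table of a scenario
#'
#' Draws each OTU's niche optimum, breadth and peak intensity. Breadths
#' come from the generalist range with probability `generalist_fraction`
#' and the specialist range otherwise; the `ecotype` flag records the truth
#' (`sigma >= sigma_cut`).
#'
#' @param sc A [scenario()].
#' @return Data frame with columns `otu_id`, `mu`, `sigma`, `peak`,
#'   `ecotype`.
#' @export
generate_niches <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  set.seed(sc$seed + 1L)
  n <- sc$n_otus
  is_gen <- stats::runif(n) < sc$generalist_fraction
  sigma <- numeric(n)
  sigma[is_gen] <- stats::runif(sum(is_gen), sc$sigma_generalist[1L],
                                sc$sigma_generalist[2L])
  sigma[!is_gen] <- stats::runif(sum(!is_gen), sc$sigma_specialist[1L],
                                 sc$sigma_specialist[2L])
  mu <- stats::runif(n, sc$mu_range[1L], sc$mu_range[2L])
  if (sc$specialist_mu_skew) {
    # density increasing linearly toward mu_range[2] for specialists
    u <- stats::runif(sum(!is_gen))
    mu[!is_gen] <- sc$mu_range[1L] + diff(sc$mu_range) * sqrt(u)
  }
  peak <- stats::rlnorm(n, meanlog = 0, sdlog = sc$peak_sdlog)
  data.frame(otu_id = sprintf("OTU%04d", seq_len(n)),
             mu = mu, sigma = sigma, peak = peak,
             ecotype = ifelse(sigma >= sc$sigma_cut, "generalist",
                              "specialist"),
             stringsAsFactors = FALSE)
}

#' Generate a count table from niches and a gradient
#'
#' Expected intensity of OTU m in sample j is
#' `A_m * exp(-(g_j - mu_m)^2 / (2 sigma_m^2))`; each sample's counts are
#' one multinomial draw of `depth` reads from the normalized intensities.
#' Zeros arise naturally for OTUs whose niche is far from a sample.
#'
#' @param sc A [scenario()].
#' @param niches Truth table from [generate_niches()].
#' @param gradient Latent gradient from [generate_environment()].
#' @return Count matrix (OTUs x samples); every column sums to `sc$depth`.
#' @export
generate_counts <- function(sc, niches, gradient) {
  stopifnot(inherits(sc, "scenario"), length(gradient) == sc$n_samples)
  set.seed(sc$seed + 2L)
  lambda <- niches$peak *
    exp(-outer(niches$mu, gradient, "-")^2 / (2 * niches$sigma^2))
  totals <- colSums(lambda)
  if (any(totals == 0))
    stop("all-zero niche intensity in sample(s): ",
         paste(which(totals == 0), collapse = ", "))
  counts <- vapply(seq_along(gradient), function(j) {
    as.numeric(stats::rmultinom(1L, sc$depth, lambda[, j] / totals[j]))
  }, numeric(nrow(niches)))
  counts <- matrix(counts, nrow = nrow(niches))
  dimnames(counts) <- list(niches$otu_id,
                           sprintf("S%03d", seq_along(gradient)))
  counts
}

#' Simulate a complete community data set
#'
#' Runs [generate_environment()], [generate_niches()] and
#' [generate_counts()] for one scenario.
#'
#' @param sc A [scenario()].
#' @return List: `counts` (OTUs x samples), `env` (samples x variables),
#'   `truth` (niche table), `gradient`, `region`, and the `scenario`.
#' @export
simulate_community <- function(sc) {
  environment_part <- generate_environment(sc)
  niches <- generate_niches(sc)
  counts <- generate_counts(sc, niches, environment_part$gradient)
  list(counts = counts, env = environment_part$env, truth = niches,
       gradient = environment_part$gradient,
       region = environment_part$region, scenario = sc)
}
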