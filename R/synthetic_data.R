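## synthetic_data: phylogenies, lambda-scaled Brownian traits, band
## environments and communities assembled under neutral, filtering or
## limiting-similarity rules — the study structure the analysis
## assumes, generated so every stage is testable without field data.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale emulation of a multi-transect
#' elevational survey: one transect of contiguous 100-m bands, 400-m2
#' plots with ~100 stems each, a pure-birth dated phylogeny, and traits
#' evolving under lambda-scaled Brownian motion.
#'
#' @param scenario Assembly rule: `"neutral"`, `"filtering"` or
#'   `"competition"`.
#' @param n_species Size of the regional species pool.
#' @param n_bands Number of contiguous elevational bands.
#' @param band_width Band width (m).
#' @param plots_per_band Plots per band.
#' @param individuals_per_plot Stems drawn per plot.
#' @param birth,death Birth-death rates of the tree simulation
#'   (`birth > death >= 0`).
#' @param lambda_sim Pagel-lambda scaling of the trait covariance in
#'   `[0, 1]`.
#' @param sigma2 Brownian rate of the latent traits.
#' @param filter_sd Width of the Gaussian environmental filter
#'   (latent-trait units; filtering scenario).
#' @param optimum_slope Drift of the filter optimum with elevation
#'   (latent-trait units per m).
#' @param competition_delta Limiting-similarity threshold
#'   (latent-trait distance; competition scenario).
#' @param elev_min Elevation of the lowest band edge (m).
#' @param transect Transect label used in plot ids.
#' @param seed Integer master seed.
#' @return A `scenario_config` list; all parameters are serialized into
#'   the outputs for provenance.
#' @export
scenario_config <- function(scenario = c("neutral", "filtering",
                                         "competition"),
                            n_species = 80, n_bands = 10,
                            band_width = 100, plots_per_band = 10,
                            individuals_per_plot = 100,
                            birth = 1, death = 0,
                            lambda_sim = 0.8, sigma2 = 1,
                            filter_sd = 1, optimum_slope = 0.004,
                            competition_delta = 0.5,
                            elev_min = 200, transect = "T1", seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(n_species >= 2, n_bands >= 3, band_width > 0,
            plots_per_band >= 1, individuals_per_plot >= 1,
            birth > 0, death >= 0, birth > death,
            lambda_sim >= 0, lambda_sim <= 1, sigma2 >= 0)
  if (scenario == "filtering" && filter_sd <= 0) {
    stop("filter_sd must be > 0 for the filtering scenario")
  }
  if (scenario == "competition" && competition_delta < 0) {
    stop("competition_delta must be >= 0")
  }
  structure(list(scenario = scenario, n_species = n_species,
                 n_bands = n_bands, band_width = band_width,
                 plots_per_band = plots_per_band,
                 individuals_per_plot = individuals_per_plot,
                 birth = birth, death = death, lambda_sim = lambda_sim,
                 sigma2 = sigma2, filter_sd = filter_sd,
                 optimum_slope = optimum_slope,
                 competition_delta = competition_delta,
                 elev_min = elev_min, transect = transect, seed = seed),
            class = "scenario_config")
}

#' Simulate a birth-death phylogeny with a fixed number of extant tips
#'
#' Forward simulation conditioned on first passage to `n_species`
#' extant lineages; the present is placed at the moment the next event
#' would occur, so pendant edges have positive length. Under pure birth
#' the expected tree depth is `(1/birth) * sum_{k=2}^{n} 1/k`. Extinct
#' lineages are pruned, so the returned tree is ultrametric over
#' exactly `n_species` tips.
#'
#' @param n_species Number of extant tips (>= 2).
#' @param birth,death Per-lineage rates (`birth > death >= 0`).
#' @param seed Integer seed.
#' @return An ultrametric [ape::phylo] with tips `s001`, `s002`, ...
#' @export
simulate_tree <- function(n_species, birth = 1, death = 0, seed = 1) {
  if (birth <= 0) stop("birth rate must be positive")
  if (death < 0 || death >= birth) stop("need birth > death >= 0")
  if (n_species < 2) stop("n_species must be >= 2")
  with_seed(seed, {
    for (try in seq_len(1000)) {
      tr <- sim_bd_once(n_species, birth, death)
      if (!is.null(tr)) return(tr)
    }
    stop("birth-death simulation failed to reach ", n_species,
         " extant tips")
  })
}

sim_bd_once <- function(n, b, d) {
  parent <- c(NA_integer_, 1L, 1L)
  start <- c(0, 0, 0)
  end <- c(0, NA_real_, NA_real_)
  alive <- c(2L, 3L)
  extinct <- integer(0)
  t <- 0
  repeat {
    k <- length(alive)
    if (k == 0) return(NULL)
    t <- t + stats::rexp(1, k * (b + d))
    if (k == n) break   # present: the next event never happens
    who <- alive[sample.int(k, 1)]
    if (d == 0 || stats::runif(1) < b / (b + d)) {
      end[who] <- t
      ids <- length(parent) + c(1L, 2L)
      parent <- c(parent, who, who)
      start <- c(start, t, t)
      end <- c(end, NA_real_, NA_real_)
      alive <- c(setdiff(alive, who), ids)
    } else {
      end[who] <- t
      extinct <- c(extinct, who)
      alive <- setdiff(alive, who)
    }
  }
  end[alive] <- t
  is_tip <- !seq_along(parent) %in% parent
  lab <- character(length(parent))
  lab[alive] <- sprintf("s%03d", seq_along(alive))
  lab[extinct] <- sprintf("x%03d", seq_along(extinct))
  fmt <- function(x) sprintf("%.10g", x)
  build <- function(id) {
    kids <- which(parent == id)
    len <- if (id == 1) 0 else end[id] - start[id]
    if (length(kids) == 0) return(paste0(lab[id], ":", fmt(len)))
    paste0("(", build(kids[1]), ",", build(kids[2]), "):", fmt(len))
  }
  tree <- ape::read.tree(text = paste0(build(1L), ";"))
  if (length(extinct) > 0) {
    tree <- ape::drop.tip(tree, lab[extinct])
    if (is.null(tree) || length(tree$tip.label) < n) return(NULL)
  }
  tree
}

#' Simulate correlated traits under lambda-scaled Brownian motion
#'
#' Two latent traits are drawn from a multivariate normal with
#' covariance `sigma2 * C(lambda_sim)` (the lambda transform of the
#' tree's BM covariance); the five observable traits are noisy
#' log-scale affine images of the latents, so the trait PCA has a known
#' low-rank structure and all values are strictly positive. The first
#' latent trait doubles as the assembly trait of
#' [assemble_communities()], coupling functional and phylogenetic
#' dispersion without making them identical.
#'
#' @param tree An ultrametric [ape::phylo].
#' @param sigma2 Brownian rate (0 gives constant traits).
#' @param lambda_sim Lambda scaling in `[0, 1]`.
#' @param seed Integer seed.
#' @param obs_noise_sd Log-scale observation noise SD; defaults to
#'   `0.2 * sqrt(sigma2)` so it vanishes with the signal.
#' @return List: `traits` (tibble with `species`, `height_m`,
#'   `leaf_length_cm`, `leaf_width_cm`, `flowering_month`,
#'   `seed_mass_mg`), `latent` and `latent2` (named vectors).
#' @export
simulate_traits <- function(tree, sigma2 = 1, lambda_sim = 1, seed = 1,
                            obs_noise_sd = 0.2 * sqrt(sigma2)) {
  if (lambda_sim < 0 || lambda_sim > 1) stop("lambda_sim must be in [0, 1]")
  sp <- tree$tip.label
  n <- length(sp)
  C <- bm_covariance(tree)
  Cl <- lambda_transform(C, lambda_sim)
  with_seed(seed, {
    draw_latent <- function() {
      if (sigma2 == 0) return(stats::setNames(rep(0, n), sp))
      R <- chol(sigma2 * Cl + diag(1e-10, n))
      stats::setNames(as.vector(t(R) %*% stats::rnorm(n)), sp)
    }
    L1 <- draw_latent()
    L2 <- draw_latent()
    eps <- function() stats::rnorm(n, 0, obs_noise_sd)
    traits <- tibble::tibble(
      species = sp,
      height_m = exp(0.8 + 0.45 * L1 + eps()),
      leaf_length_cm = exp(1.6 + 0.40 * L1 + 0.25 * L2 + eps()),
      leaf_width_cm = exp(0.9 + 0.30 * L1 + 0.30 * L2 + eps()),
      flowering_month = exp(1.6 + 0.15 * L2 + eps()),
      seed_mass_mg = exp(2.3 + 0.55 * L1 - 0.20 * L2 + eps())
    )
    list(traits = traits, latent = L1, latent2 = L2)
  })
}

#' Simulate a band-level environment table
#'
#' Climate variables are monotone linear functions of elevation plus
#' noise (temperature-like decreasing, precipitation-like increasing on
#' the log scale); log regional area decreases with elevation;
#' topographic-heterogeneity SDs follow a hump-shaped (or flat)
#' profile. With `noise_sd = 0` the climate PC1 is exactly collinear
#' with elevation.
#'
#' @param n_bands Number of bands (>= 3).
#' @param band_width Band width (m).
#' @param elev_min Lowest band edge (m).
#' @param noise_sd Relative noise level (fraction of each variable's
#'   elevational range; default 0.1).
#' @param hetero_profile `"hump"` or `"flat"` heterogeneity profile.
#' @param seed Integer seed.
#' @return Tibble with `band` (= lower band edge, m), `elevation`
#'   (band midpoint, m), `rarea` (log km2), six climate columns and
#'   three topographic-SD columns; attributes `climate_cols` and
#'   `topo_cols` name them.
#' @export
simulate_environment <- function(n_bands, band_width = 100,
                                 elev_min = 200, noise_sd = 0.1,
                                 hetero_profile = c("hump", "flat"),
                                 seed = 1) {
  if (n_bands < 3) stop("n_bands must be >= 3")
  hetero_profile <- match.arg(hetero_profile)
  band <- elev_min + (seq_len(n_bands) - 1) * band_width
  elevation <- band + band_width / 2
  u <- (elevation - min(elevation)) / diff(range(elevation))
  with_seed(seed, {
    nz <- function(range) stats::rnorm(n_bands, 0, noise_sd * abs(range))
    h <- if (hetero_profile == "hump") {
      exp(-(u - 0.5)^2 / (2 * 0.2^2))
    } else {
      rep(0.5, n_bands)
    }
    env <- tibble::tibble(
      band = band, elevation = elevation,
      rarea = 6 - 2.5 * u + nz(2.5),
      temp_mean = 14 - 8 * u + nz(8),
      temp_min = 2 - 10 * u + nz(10),
      temp_range = 28 - 4 * u + nz(4),
      precip_log = log(900) + 0.5 * u + nz(0.5),
      precip_summer_log = log(500) + 0.6 * u + nz(0.6),
      radiation = 5.5 - 1.2 * u + nz(1.2),
      slope_sd = 5 + 6 * h + nz(6),
      aspect_sd = 60 + 40 * h + nz(40),
      relief_sd = 30 + 35 * h + nz(35)
    )
    attr(env, "climate_cols") <- c("temp_mean", "temp_min", "temp_range",
                                   "precip_log", "precip_summer_log",
                                   "radiation")
    attr(env, "topo_cols") <- c("slope_sd", "aspect_sd", "relief_sd")
    env
  })
}

#' Assemble plot communities under a neutral, filtering or
#' limiting-similarity rule
#'
#' Every plot receives `individuals_per_plot` individuals drawn from
#' the regional pool. Neutral: sampling weights proportional to fixed
#' lognormal regional abundances. Filtering: weights additionally
#' multiplied by a Gaussian kernel
#' `exp(-(t_s - mu(e))^2 / (2 filter_sd^2))` around an optimum `mu(e)`
#' linear in the plot's elevation. Competition: neutral weights, but a
#' candidate whose latent-trait distance to any already-resident
#' *other* species is below `competition_delta` is rejected and
#' redrawn (up to 100 retries, then accepted and counted as a
#' violation; conspecific redraws are always accepted).
#'
#' @param tree Phylogeny over the pool (tip set = species).
#' @param traits Output of [simulate_traits()] (the `latent` vector is
#'   the assembly trait).
#' @param env Output of [simulate_environment()] (defines the bands).
#' @param config A [scenario_config()].
#' @return A `community_matrix`; attribute `violations` counts
#'   accepted limiting-similarity violations.
#' @export
assemble_communities <- function(tree, traits, env, config) {
  stopifnot(inherits(config, "scenario_config"))
  sp <- tree$tip.label
  latent <- traits$latent[sp]
  regional <- with_seed(derive_seed(config$seed, 900001),
                        stats::setNames(stats::rlnorm(length(sp), 0, 1), sp))
  mu_of <- function(e) {
    mean(latent) + config$optimum_slope * (e - mean(env$elevation))
  }
  rows <- list()
  meta <- list()
  violations <- 0L
  total_draws <- 0L
  plot_i <- 0L
  for (bi in seq_len(nrow(env))) {
    band <- env$band[bi]
    for (pi in seq_len(config$plots_per_band)) {
      plot_i <- plot_i + 1L
      pid <- sprintf("%s_b%02d_p%02d", config$transect, bi, pi)
      res <- with_seed(derive_seed(config$seed, 300000 + plot_i), {
        e <- stats::runif(1, band, band + config$band_width)
        w <- switch(config$scenario,
          neutral = regional,
          filtering = regional *
            exp(-(latent - mu_of(e))^2 / (2 * config$filter_sd^2)),
          competition = regional)
        if (sum(w) <= 0) w <- regional
        counts <- if (config$scenario == "competition" &&
                      config$competition_delta > 0) {
          draw_limiting(sp, w, latent, config$individuals_per_plot,
                        config$competition_delta)
        } else {
          tab <- table(sample(sp, config$individuals_per_plot,
                              replace = TRUE, prob = w))
          list(counts = stats::setNames(as.integer(tab), names(tab)),
               violations = 0L)
        }
        list(elev = e, counts = counts$counts,
             violations = counts$violations)
      })
      violations <- violations + res$violations
      total_draws <- total_draws + config$individuals_per_plot
      rows[[pid]] <- tibble::tibble(plot = pid,
                                    species = names(res$counts),
                                    abundance = as.numeric(res$counts))
      meta[[pid]] <- tibble::tibble(plot = pid,
                                    transect = config$transect,
                                    elevation = res$elev)
    }
  }
  if (violations > 0.1 * total_draws) {
    warning("limiting-similarity retry cap exhausted in ",
            violations, "/", total_draws, " draws; consider a smaller ",
            "competition_delta")
  }
  comm <- community_matrix(dplyr::bind_rows(rows), dplyr::bind_rows(meta),
                           band_width = config$band_width, band_origin = 0)
  attr(comm, "violations") <- violations
  comm
}

## Sequential draws under limiting similarity: candidates closer than
## `delta` (in latent-trait distance) to any resident *other* species
## are rejected, up to 100 retries per individual.
draw_limiting <- function(sp, w, latent, n_ind, delta) {
  counts <- stats::setNames(integer(length(sp)), sp)
  residents <- character(0)
  violations <- 0L
  for (i in seq_len(n_ind)) {
    accepted <- FALSE
    for (try in seq_len(100)) {
      cand <- sample(sp, 1, prob = w)
      others <- setdiff(residents, cand)
      if (length(others) == 0 ||
          min(abs(latent[others] - latent[cand])) >= delta) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) violations <- violations + 1L
    counts[cand] <- counts[cand] + 1L
    residents <- union(residents, cand)
  }
  list(counts = counts[counts > 0], violations = violations)
}

#' Generate a complete synthetic scenario
#'
#' Tree, traits, environment and communities from one
#' [scenario_config()]; fully deterministic given the config
#' (including its seed).
#'
#' @param config A `scenario_config`.
#' @return List with `tree`, `traits` (the [simulate_traits()] output),
#'   `env`, `community` and `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  tree <- simulate_tree(config$n_species, config$birth, config$death,
                        seed = derive_seed(config$seed, 1))
  traits <- simulate_traits(tree, config$sigma2, config$lambda_sim,
                            seed = derive_seed(config$seed, 2))
  env <- simulate_environment(config$n_bands, config$band_width,
                              config$elev_min,
                              seed = derive_seed(config$seed, 3))
  community <- assemble_communities(tree, traits, env, config)
  list(tree = tree, traits = traits, env = env, community = community,
       config = config)
}

#' Write a synthetic scenario in the package's input formats
#'
#' Newick for the tree; CSV for traits, environment, long-form
#' abundances and plot metadata; a `provenance.txt` echoing the full
#' configuration.
#'
#' @param scenario Output of [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(scenario$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(scenario$traits$traits,
                   file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(scenario$env, file.path(dir, "environment.csv"),
                   row.names = FALSE)
  long <- tibble::as_tibble(as.data.frame.table(
    scenario$community$abund, responseName = "abundance"))
  names(long)[1:2] <- c("plot", "species")
  long <- long[long$abundance > 0, ]
  utils::write.csv(long, file.path(dir, "community_long.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$community$meta,
                   file.path(dir, "plot_meta.csv"), row.names = FALSE)
  cfg <- scenario$config
  writeLines(paste0(names(cfg), "=", unlist(cfg)),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}
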