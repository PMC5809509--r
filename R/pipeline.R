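## pipeline: orchestrate the full analysis — trait dendrogram,
## phylogenetic + functional dispersion over bands, signal statistics,
## and the gradient layer — on either a synthetic scenario or
## user-supplied inputs, producing the study's report tables.

#' Run the full dispersion analysis end-to-end
#'
#' Given a scenario configuration (or a pre-built input bundle with
#' `tree`, `traits`, `env`, `community`), computes: (1) the
#' phylogenetic-signal report; (2) alpha/beta-within/gamma band
#' components for the phylogenetic and functional facets, with linear
#' and quadratic elevation fits chosen by AIC; (3) band-pair
#' S.E.S. D_pw and Mantel tests against the elevational, regional-area,
#' climatic and habitat distances; (4) the simple-OLS screen; (5)
#' forward stepwise models; (6) MRM and three-set variation
#' partitioning. Deterministic given the inputs and `seed`.
#'
#' @param config A [scenario_config()] (ignored when `data` is given).
#' @param data Optional list with `tree`, `traits` (a
#'   [simulate_traits()]-style list or a raw trait data frame), `env`
#'   and `community`.
#' @param n_null Null replicates for the dispersion metrics (study
#'   default 1000).
#' @param n_perm Permutations for Mantel/MRM (study default 10000).
#' @param seed Integer master seed for the analysis layer.
#' @param inner_weighted Inner-mean weighting of D_pw (see [dpw()]).
#' @param k_pca Components kept for the trait PCA (`NULL`: smallest k
#'   reaching 94.8% variance).
#' @param output_dir If non-`NULL`, the report tables are also written
#'   there as CSV via [write_report_bundle()].
#' @return Object of class `elevdisp_run`: a named list of tibbles and
#'   fitted objects (see the vignette for the full layout).
#' @export
run_full <- function(config = scenario_config(), data = NULL,
                     n_null = 1000, n_perm = 10000, seed = 1,
                     inner_weighted = TRUE, k_pca = NULL,
                     output_dir = NULL) {
  stage <- "inputs"
  out <- list()
  tryCatch({
    if (is.null(data)) {
      data <- generate_scenario(config)
      out$config <- config
    }
    tree <- data$tree
    traits_tbl <- if (is.data.frame(data$traits)) data$traits else
      data$traits$traits
    env <- data$env
    community <- data$community

    stage <- "trait_space"
    td <- trait_dendrogram(traits_tbl, k = k_pca)
    out$pca <- td$pca
    out$dendrogram <- td$dendrogram

    stage <- "distances"
    D_phy <- cophenetic_distance(tree)
    D_fun <- cophenetic_distance(td$dendrogram)
    community <- align_community_tree(community, tree)

    stage <- "phylo_signal"
    out$signal <- signal_table(tree, traits_tbl, n_perm = 999,
                               seed = derive_seed(seed, 11))

    stage <- "dispersion"
    facets <- list(phylogenetic = D_phy, functional = D_fun)
    out$band_components <- purrr::imap_dfr(facets, function(D, nm) {
      dplyr::mutate(
        dispersion_by_band(community, D, n_null = n_null,
                           seed = derive_seed(seed, 21),
                           inner_weighted = inner_weighted),
        facet = nm, .before = 1)
    })
    out$band_beta <- purrr::imap_dfr(facets, function(D, nm) {
      dplyr::mutate(
        band_beta_matrix(community, D, n_null = n_null,
                         seed = derive_seed(seed, 22),
                         inner_weighted = inner_weighted),
        facet = nm, .before = 1)
    })

    stage <- "gradient_stats"
    env2 <- env_pca(env, attr(env, "climate_cols"),
                    attr(env, "topo_cols"))
    band_tbl <- dplyr::left_join(out$band_components, env2, by = "band")
    out$band_table <- band_tbl
    preds <- c("rarea", "pc1_clim", "pc1_hetero", "pc2_hetero")
    components <- c("alpha", "beta_within", "gamma")

    ## a component whose precondition fails (too few bands for the
    ## predictor count, a degenerate design, ...) yields a `note` row
    ## instead of aborting the whole bundle
    per_component <- function(f) {
      purrr::map_dfr(unique(band_tbl$facet), function(fc) {
        sub <- dplyr::filter(band_tbl, .data$facet == fc)
        purrr::map_dfr(components, function(comp) {
          if (all(is.na(sub[[comp]]))) return(tibble::tibble())
          res <- tryCatch(f(sub, comp), error = function(e) {
            tibble::tibble(note = conditionMessage(e))
          })
          dplyr::mutate(res, facet = fc, component = comp, .before = 1)
        })
      })
    }
    out$elevation_fits <- per_component(function(sub, comp) {
      fits <- fit_elevation_models(sub, comp, "elevation")
      dplyr::bind_rows(glance(fits$linear), glance(fits$quadratic)) |>
        dplyr::mutate(best = .data$form == fits$best)
    })
    out$ols_screen <- per_component(function(sub, comp) {
      simple_ols_screen(sub, comp, preds)
    })
    out$stepwise <- per_component(function(sub, comp) {
      glance(stepwise_forward(sub, comp, preds))
    })
    out$varpart <- per_component(function(sub, comp) {
      vp <- variation_partition(sub, comp,
                                list(rarea = "rarea",
                                     climate = "pc1_clim",
                                     hetero = c("pc1_hetero",
                                                "pc2_hetero")))
      tidy(vp)
    })

    stage <- "distance_decay"
    dists <- build_distances(env2)
    out$mantel <- purrr::map_dfr(unique(out$band_beta$facet),
                                 function(fc) {
      B <- pair_table_to_matrix(
        dplyr::filter(out$band_beta, .data$facet == fc), "ses")
      purrr::imap_dfr(dists, function(Dx, nm) {
        m <- mantel(B, Dx, n_perm = n_perm,
                    seed = derive_seed(seed, 31))
        dplyr::mutate(tidy(m), facet = fc, distance = nm, .before = 1)
      })
    })
    out$mrm <- purrr::map_dfr(unique(out$band_beta$facet),
                              function(fc) {
      B <- pair_table_to_matrix(
        dplyr::filter(out$band_beta, .data$facet == fc), "ses")
      fit <- mrm(B, dists, n_perm = min(n_perm, 999),
                 seed = derive_seed(seed, 32))
      dplyr::mutate(tidy(fit), facet = fc,
                    r_squared = fit$r_squared, .before = 1)
    })
    class(out) <- "elevdisp_run"
    if (!is.null(output_dir)) write_report_bundle(out, output_dir)
    out
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.elevdisp_run <- function(x, ...) {
  cat("<elevdisp_run> tables:",
      paste(names(x)[vapply(x, is.data.frame, logical(1))],
            collapse = ", "), "\n")
  invisible(x)
}

#' Write the report tables of a pipeline run as delimited text
#'
#' One CSV per table (signal, band components, elevation fits, OLS
#' screen, stepwise, Mantel, MRM, variation partitioning, band-pair
#' beta), plus the dendrogram as newick.
#'
#' @param run An `elevdisp_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- names(run)[vapply(run, is.data.frame, logical(1))]
  for (nm in tabs) {
    utils::write.csv(run[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(run$dendrogram)) {
    write_newick(run$dendrogram, file.path(dir, "trait_dendrogram.nwk"))
  }
  invisible(dir)
}
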