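## dispersion: abundance-weighted MPD / NRI within assemblages, D_pw /
## S.E.S. D_pw between assemblages, the tip-shuffle null model, and the
## alpha/beta/gamma decomposition over elevational bands.
##
## Sign convention: NRI and S.E.S. D_pw are -1 * (observed - null mean) /
## null SD, so positive values indicate clustering (observed distances
## smaller than expected) and negative values overdispersion.

#' Abundance-weighted mean pairwise distance of one assemblage
#'
#' MPD = sum_{i<j} f_i f_j d_ij / sum_{i<j} f_i f_j over distinct
#' species pairs, with f the relative abundances.
#'
#' @param assemblage Named numeric vector mapping species to abundance
#'   (positive entries).
#' @param D Labeled symmetric distance matrix covering the species.
#' @return The weighted MPD (distance units of `D`).
#' @export
mpd_weighted <- function(assemblage, D) {
  assemblage <- assemblage[assemblage > 0]
  if (length(assemblage) < 2) {
    stop("MPD undefined for monospecific assemblage")
  }
  miss <- setdiff(names(assemblage), rownames(D))
  if (length(miss) > 0) {
    stop("species not in distance matrix: ", paste(miss, collapse = ", "))
  }
  f <- assemblage / sum(assemblage)
  Dw <- D[names(f), names(f)]
  ## pairwise form: f'Df = 2 * sum_{i<j} f_i f_j d_ij (diagonal is 0)
  num <- as.numeric(t(f) %*% Dw %*% f)
  den <- 1 - sum(f^2)
  num / den
}

#' Abundance-weighted mean pairwise distance between two assemblages
#'
#' D_pw averages the two directed sums sum_i f_i dbar_{i,k2} and
#' sum_j f_j dbar_{j,k1}, where dbar_{i,k2} is the mean distance from
#' species i of assemblage 1 to the species of assemblage 2. With the
#' (default) abundance-weighted inner mean the two directed sums
#' coincide and D_pw = f' D g; with `inner_weighted = FALSE` the inner
#' mean is unweighted across the other assemblage's species. Shared
#' species contribute zero-distance terms.
#'
#' @param a1,a2 Named numeric abundance vectors (positive entries).
#' @param D Labeled symmetric distance matrix covering both assemblages.
#' @param inner_weighted Use the other assemblage's relative abundances
#'   as inner-mean weights (default TRUE).
#' @return The between-assemblage D_pw.
#' @export
dpw <- function(a1, a2, D, inner_weighted = TRUE) {
  a1 <- a1[a1 > 0]; a2 <- a2[a2 > 0]
  if (length(a1) == 0 || length(a2) == 0) stop("empty assemblage")
  miss <- setdiff(c(names(a1), names(a2)), rownames(D))
  if (length(miss) > 0) {
    stop("species not in distance matrix: ", paste(miss, collapse = ", "))
  }
  f <- a1 / sum(a1)
  g <- a2 / sum(a2)
  Dc <- D[names(f), names(g), drop = FALSE]
  if (inner_weighted) {
    as.numeric(t(f) %*% Dc %*% g)
  } else {
    u2 <- rep(1 / length(g), length(g))
    u1 <- rep(1 / length(f), length(f))
    (sum(f * (Dc %*% u2)) + sum(g * (t(Dc) %*% u1))) / 2
  }
}

#' Tip-shuffle null permutations
#'
#' The null model relabels the species across the tips of the tree (or
#' dendrogram): each replicate is one uniform random permutation of the
#' pool's labels applied to the distance matrix, while the community
#' data are untouched. Returned as an integer matrix of permutations of
#' `seq_along(pool)`, one row per replicate.
#'
#' @param D Labeled distance matrix over the pool (used for validation).
#' @param pool Character vector: the transect-wide species pool. Must
#'   equal the labels of `D` (order free).
#' @param n Number of replicates (>= 1), ignored when `exhaustive`.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all `factorial(length(pool))`
#'   permutations exactly once (pools of <= 8 only).
#' @return Integer matrix (replicates x pool size) with attribute
#'   `pool`.
#' @export
tip_shuffle_null <- function(D, pool, n, seed, exhaustive = FALSE) {
  pool <- as.character(pool)
  if (!setequal(pool, rownames(D))) {
    stop("pool must equal the labels of D")
  }
  m <- length(pool)
  if (exhaustive) {
    if (m > 8) stop("exhaustive null limited to pools of <= 8 species")
    P <- all_permutations(m)
  } else {
    if (n < 1) stop("n must be >= 1")
    P <- with_seed(seed, {
      t(vapply(seq_len(n), function(i) sample.int(m), integer(m)))
    })
  }
  attr(P, "pool") <- pool
  P
}

## All m! permutations of 1..m, rows in lexicographic order.
all_permutations <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(m - 1L)
  out <- matrix(0L, m * nrow(sub), m)
  r <- 0L
  for (first in seq_len(m)) {
    rest <- setdiff(seq_len(m), first)
    out[r + seq_len(nrow(sub)), 1] <- first
    out[r + seq_len(nrow(sub)), -1] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

## Null distribution of a bilinear dispersion statistic
## sum_{i,j} w1_i w2_j D[pi(s1_i), pi(s2_j)] for each permutation row of
## `perms`. Pairs mapping to the same pool index contribute 0 (zero
## diagonal), so they can be included harmlessly.
bilinear_null <- function(w1, s1, w2, s2, Dp, perms) {
  grid <- expand.grid(i = seq_along(s1), j = seq_along(s2))
  w <- w1[grid$i] * w2[grid$j]
  c1 <- s1[grid$i]
  c2 <- s2[grid$j]
  P1 <- perms[, c1, drop = FALSE]
  P2 <- perms[, c2, drop = FALSE]
  vals <- matrix(Dp[cbind(as.vector(P1), as.vector(P2))], nrow(perms))
  as.vector(vals %*% w)
}

## Summarize an observed metric against its null draws into a one-row
## DispersionResult tibble. Degenerate nulls (SD ~ 0) report ses = 0
## with a flag; the rank-based two-sided p is
## 2 * min(r, n + 1 - r) / (n + 1) with r the observed value's rank
## among observed + null.
summarize_null <- function(metric, observed, null, seed) {
  n <- length(null)
  mu <- mean(null)
  sdv <- stats::sd(null)
  degenerate <- !is.finite(sdv) || sdv < 1e-12
  ses <- if (degenerate) 0 else -1 * (observed - mu) / sdv
  p <- if (degenerate) NA_real_ else {
    r <- sum(null < observed) + 1 + sum(null == observed) / 2
    min(1, 2 * min(r, n + 1 - r) / (n + 1))
  }
  tibble::tibble(
    metric = metric, observed = observed, null_mean = mu,
    null_sd = if (degenerate) 0 else sdv, ses = ses, p_value = p,
    n_null = n, seed = seed, degenerate = degenerate
  )
}

#' Net relatedness index of one assemblage
#'
#' NRI = -1 * (MPD_observed - mean MPD_null) / sd MPD_null under the
#' tip-shuffle null. Positive values indicate phylogenetic (or
#' functional) clustering, negative values overdispersion.
#'
#' @inheritParams mpd_weighted
#' @param pool Species pool over which tips are shuffled; defaults to
#'   all labels of `D` (the transect-wide pool).
#' @param n_null Number of null replicates (study default 1000).
#' @param seed Integer seed.
#' @param exhaustive Use every permutation of the pool instead of
#'   sampling (small pools only).
#' @return One-row tibble: `metric`, `observed`, `null_mean`, `null_sd`,
#'   `ses` (the NRI), `p_value`, `n_null`, `seed`, `degenerate`.
#' @export
nri <- function(assemblage, D, pool = rownames(D), n_null = 1000, seed = 1,
                exhaustive = FALSE) {
  assemblage <- assemblage[assemblage > 0]
  if (length(assemblage) < 2) {
    stop("MPD undefined for monospecific assemblage")
  }
  pool <- as.character(pool)
  Dp <- D[pool, pool]
  sp <- match(names(assemblage), pool)
  if (anyNA(sp)) {
    stop("assemblage species outside pool: ",
         paste(names(assemblage)[is.na(sp)], collapse = ", "))
  }
  f <- assemblage / sum(assemblage)
  den <- 1 - sum(f^2)
  obs <- mpd_weighted(assemblage, D)
  perms <- tip_shuffle_null(Dp, pool, n_null, seed, exhaustive = exhaustive)
  null <- bilinear_null(f, sp, f, sp, Dp, perms) / den
  summarize_null("NRI", obs, null, seed)
}

#' Standardized effect size of D_pw between two assemblages
#'
#' S.E.S. D_pw = -1 * (D_pw observed - mean D_pw null) / sd D_pw null.
#' Both assemblages share the pool and the same relabeling in every
#' replicate.
#'
#' @inheritParams dpw
#' @inheritParams nri
#' @return One-row tibble as in [nri()] with `metric = "SES.Dpw"`.
#' @export
ses_dpw <- function(a1, a2, D, pool = rownames(D), n_null = 1000, seed = 1,
                    inner_weighted = TRUE, exhaustive = FALSE) {
  a1 <- a1[a1 > 0]; a2 <- a2[a2 > 0]
  if (length(a1) == 0 || length(a2) == 0) stop("empty assemblage")
  pool <- as.character(pool)
  Dp <- D[pool, pool]
  s1 <- match(names(a1), pool)
  s2 <- match(names(a2), pool)
  if (anyNA(s1) || anyNA(s2)) {
    stop("assemblage species outside pool: ",
         paste(c(names(a1)[is.na(s1)], names(a2)[is.na(s2)]),
               collapse = ", "))
  }
  f <- a1 / sum(a1)
  g <- a2 / sum(a2)
  obs <- dpw(a1, a2, D, inner_weighted = inner_weighted)
  perms <- tip_shuffle_null(Dp, pool, n_null, seed, exhaustive = exhaustive)
  null <- if (inner_weighted) {
    bilinear_null(f, s1, g, s2, Dp, perms)
  } else {
    u1 <- rep(1 / length(f), length(f))
    u2 <- rep(1 / length(g), length(g))
    (bilinear_null(f, s1, u2, s2, Dp, perms) +
       bilinear_null(u1, s1, g, s2, Dp, perms)) / 2
  }
  summarize_null("SES.Dpw", obs, null, seed)
}

#' Alpha, beta-within and gamma dispersion of one elevational band
#'
#' The alpha component is the mean NRI over the band's plots; the
#' within-band beta component is the mean S.E.S. D_pw over all unordered
#' plot pairs; the gamma component is the NRI of the band's pooled
#' assemblage. Monospecific plots are skipped with a warning;
#' degenerate-null values are excluded from the alpha and beta means.
#'
#' @param community A `community_matrix`.
#' @param D Labeled distance matrix over the species pool.
#' @param band Band id (lower edge, m).
#' @param pool Species pool (default: labels of `D`).
#' @param n_null,seed Null-model control; per-plot and per-pair
#'   sub-seeds are derived with [derive_seed()] so results are
#'   independent of execution order.
#' @param inner_weighted Passed to [ses_dpw()].
#' @return One-row tibble: `band`, `alpha`, `beta_within`, `gamma`,
#'   `n_plots`, `n_skipped`, `n_degenerate`, `n_null`, `seed`.
#' @export
band_components <- function(community, D, band, pool = rownames(D),
                            n_null = 1000, seed = 1,
                            inner_weighted = TRUE) {
  stopifnot(inherits(community, "community_matrix"))
  sel <- community$meta$band == band
  if (!any(sel)) stop("no plots in band ", band)
  plots <- sort(community$meta$plot[sel])
  asms <- lapply(plots, function(p) plot_assemblage(community, p))
  names(asms) <- plots
  ok <- vapply(asms, function(a) length(a) >= 2, logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning("band ", band, ": skipping ", n_skipped,
            " monospecific plot(s)")
  }
  if (!any(ok)) stop("band ", band, ": no plot with >= 2 species")
  plots_ok <- plots[ok]
  nri_tbl <- purrr::map2_dfr(
    asms[plots_ok], seq_along(plots_ok),
    function(a, i) nri(a, D, pool, n_null,
                       derive_seed(seed, i))
  )
  alpha <- mean(nri_tbl$ses[!nri_tbl$degenerate])
  n_degenerate <- sum(nri_tbl$degenerate)
  beta_within <- NA_real_
  if (length(plots_ok) >= 2) {
    prs <- utils::combn(seq_along(plots_ok), 2)
    beta_tbl <- purrr::map_dfr(seq_len(ncol(prs)), function(k) {
      ses_dpw(asms[[plots_ok[prs[1, k]]]], asms[[plots_ok[prs[2, k]]]],
              D, pool, n_null, derive_seed(seed, 10000 + k),
              inner_weighted = inner_weighted)
    })
    n_degenerate <- n_degenerate + sum(beta_tbl$degenerate)
    beta_within <- mean(beta_tbl$ses[!beta_tbl$degenerate])
  }
  pooled <- pool_band(community, band)
  gamma_tbl <- nri(pooled, D, pool, n_null, derive_seed(seed, 0))
  tibble::tibble(
    band = band, alpha = alpha, beta_within = beta_within,
    gamma = gamma_tbl$ses, n_plots = length(plots_ok),
    n_skipped = n_skipped, n_degenerate = n_degenerate,
    n_null = n_null, seed = seed
  )
}

#' Band components for every elevational band of a community
#'
#' @inheritParams band_components
#' @return Tibble with one row per band (see [band_components()]), in
#'   increasing band order.
#' @export
dispersion_by_band <- function(community, D, pool = rownames(D),
                               n_null = 1000, seed = 1,
                               inner_weighted = TRUE) {
  bands <- sort(unique(community$meta$band))
  purrr::map_dfr(seq_along(bands), function(b) {
    band_components(community, D, bands[b], pool, n_null,
                    derive_seed(seed, 100000 + b),
                    inner_weighted = inner_weighted)
  })
}

#' S.E.S. D_pw between every pair of pooled elevational bands
#'
#' Band assemblages are pooled-and-summed over their plots; each
#' unordered band pair is scored with [ses_dpw()].
#'
#' @inheritParams band_components
#' @return Long-form tibble: `band1`, `band2` (band1 < band2),
#'   `observed`, `ses`, `p_value`, `degenerate`, `n_null`, `seed`.
#' @export
band_beta_matrix <- function(community, D, pool = rownames(D),
                             n_null = 1000, seed = 1,
                             inner_weighted = TRUE) {
  bands <- sort(unique(community$meta$band))
  if (length(bands) < 2) stop("need >= 2 bands")
  asms <- pool_bands(community)
  prs <- utils::combn(seq_along(bands), 2)
  purrr::map_dfr(seq_len(ncol(prs)), function(k) {
    i <- prs[1, k]; j <- prs[2, k]
    res <- ses_dpw(asms[[i]], asms[[j]], D, pool, n_null,
                   derive_seed(seed, 200000 + k),
                   inner_weighted = inner_weighted)
    tibble::tibble(band1 = bands[i], band2 = bands[j],
                   observed = res$observed, ses = res$ses,
                   p_value = res$p_value, degenerate = res$degenerate,
                   n_null = n_null, seed = seed)
  })
}

#' Convert a long band-pair table to a symmetric labeled matrix
#'
#' @param tbl Tibble with `band1`, `band2` and a value column.
#' @param value Name of the value column (default `"ses"`).
#' @return Symmetric matrix over the bands with zero diagonal.
#' @export
pair_table_to_matrix <- function(tbl, value = "ses") {
  bands <- sort(unique(c(tbl$band1, tbl$band2)))
  M <- matrix(0, length(bands), length(bands),
              dimnames = list(as.character(bands), as.character(bands)))
  for (k in seq_len(nrow(tbl))) {
    i <- as.character(tbl$band1[k]); j <- as.character(tbl$band2[k])
    M[i, j] <- M[j, i] <- tbl[[value]][k]
  }
  M
}
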