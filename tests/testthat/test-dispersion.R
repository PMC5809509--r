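d3 <- function() {
  matrix(c(0, 2, 4,
           2, 0, 6,
           4, 6, 0), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

test_that("weighted MPD matches the explicit pair sum", {
  D <- matrix(c(0, 4, 4, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(mpd_weighted(c(A = 1, B = 1), D), 4)

  a <- c(A = 2, B = 1, C = 1)
  expect_equal(mpd_weighted(a, d3()), 3.6)
  expect_equal(mpd_weighted(a, d3()), unname(naive_mpd(a, d3())))

  ## equal distances: MPD = d for any abundances
  Deq <- matrix(5, 3, 3, dimnames = dimnames(d3())); diag(Deq) <- 0
  expect_equal(mpd_weighted(c(A = 9, B = 1, C = 2), Deq), 5)

  expect_error(mpd_weighted(c(A = 3), d3()), "monospecific")
})

test_that("weighted MPD agrees with picante on random assemblages", {
  skip_if_not_installed("picante")
  set.seed(10)
  D <- random_metric_D(8, labels = sprintf("sp%01d", 1:8))
  for (rep in 1:10) {
    a <- setNames(rpois(8, 2) + c(1, 1, rep(0, 6)), rownames(D))
    samp <- matrix(a, 1, 8, dimnames = list("pl", names(a)))
    ## picante averages over ordered pairs including conspecific (d = 0)
    ## ones; our distinct-pair MPD differs by exactly 1 - sum(f^2)
    f <- a / sum(a)
    expect_equal(mpd_weighted(a, D) * (1 - sum(f^2)),
                 picante::mpd(samp, D, abundance.weighted = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("D_pw matches the directed-sum definition", {
  D <- matrix(c(0, 5, 5, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(dpw(c(A = 1), c(B = 1), D), 5)
  expect_equal(dpw(c(A = 2), c(A = 5), D), 0)

  a1 <- c(A = 3, B = 1); a2 <- c(B = 1, C = 1)
  expect_equal(dpw(a1, a2, d3()), unname(naive_dpw(a1, a2, d3())))
  expect_equal(dpw(a1, a2, d3(), inner_weighted = FALSE),
               unname(naive_dpw(a1, a2, d3(), inner_weighted = FALSE)))
  ## symmetry in the two assemblages
  expect_equal(dpw(a1, a2, d3()), dpw(a2, a1, d3()))
  expect_error(dpw(c(A = 0), a2, d3()), "empty")
})

test_that("abundance-weighted D_pw agrees with picante::comdist", {
  skip_if_not_installed("picante")
  set.seed(11)
  D <- random_metric_D(7, labels = sprintf("sp%01d", 1:7))
  samp <- rbind(k1 = rpois(7, 2) + c(1, rep(0, 6)),
                k2 = rpois(7, 2) + c(0, 1, rep(0, 5)))
  colnames(samp) <- rownames(D)
  a1 <- samp["k1", ][samp["k1", ] > 0]
  a2 <- samp["k2", ][samp["k2", ] > 0]
  expect_equal(dpw(a1, a2, D),
               as.numeric(picante::comdist(samp, D,
                                           abundance.weighted = TRUE)),
               tolerance = 1e-10)
})

test_that("tip shuffling leaves metrics unchanged under identity and
           enumerates exhaustively", {
  D <- random_metric_D(4, labels = LETTERS[1:4])
  perms <- tip_shuffle_null(D, LETTERS[1:4], n = 5, seed = 1,
                            exhaustive = TRUE)
  expect_equal(nrow(perms), 24)
  expect_equal(nrow(unique(perms)), 24)
  ## identity permutation reproduces the observed metric
  a <- c(A = 2, B = 1)
  expect_true(any(apply(perms, 1, function(p) all(p == 1:4))))
  expect_error(tip_shuffle_null(D, LETTERS[1:4], n = 0, seed = 1), "n must")
  expect_error(tip_shuffle_null(D, LETTERS[1:3], n = 5, seed = 1), "pool")
})

test_that("sampled null mean/SD converges to the exhaustive null", {
  set.seed(12)
  D <- random_metric_D(4, labels = LETTERS[1:4])
  a <- c(A = 2, B = 1, C = 1)
  f <- a / sum(a)
  ex <- exhaustive_ses(function(Dp) naive_mpd(a, Dp), D)
  res <- nri(a, D, n_null = 10000, seed = 99)
  se <- ex$sd / sqrt(res$n_null)
  expect_lt(abs(res$null_mean - ex$mean), 3 * se)
})

test_that("NRI handles degenerate and sign-forced cases", {
  ## star phylogeny: metric invariant under relabeling -> degenerate
  Deq <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(Deq) <- 0
  res <- nri(c(A = 1, B = 1), Deq, n_null = 99, seed = 1)
  expect_true(res$degenerate)
  expect_equal(res$ses, 0)
  expect_true(is.na(res$p_value))

  ## two close sisters in a pool of distant species -> clustering
  lab <- sprintf("s%01d", 1:8)
  Dc <- matrix(10, 8, 8, dimnames = list(lab, lab))
  diag(Dc) <- 0
  Dc["s1", "s2"] <- Dc["s2", "s1"] <- 0.1
  res2 <- nri(c(s1 = 1, s2 = 1), Dc, n_null = 199, seed = 2)
  expect_gt(res2$ses, 0)
})

test_that("sampled NRI equals the exhaustive-permutation value on a
           4-species pool", {
  set.seed(13)
  D <- random_metric_D(4, labels = LETTERS[1:4])
  a <- c(A = 2, B = 1)
  ex <- exhaustive_ses(function(Dp) naive_mpd(a, Dp), D)
  res <- nri(a, D, n_null = 20000, seed = 7)
  mc_se <- ex$sd / sqrt(res$n_null)
  ## ses differs by at most 3 MC standard errors propagated through the
  ## standardization
  expect_lt(abs(res$observed - naive_mpd(a, D)), 1e-12)
  expect_lt(abs(-res$ses * res$null_sd + res$null_mean -
                  (-ex$ses * ex$sd + ex$mean)), 1e-12)
  expect_lt(abs(res$ses - ex$ses), 3 * mc_se / ex$sd * 2)
  ## exhaustive mode gives the exact value
  res_ex <- nri(a, D, seed = 1, exhaustive = TRUE)
  expect_equal(res_ex$ses, ex$ses, tolerance = 1e-10)
})

test_that("S.E.S. D_pw is symmetric, flags degenerate nulls, and matches
           the exhaustive oracle", {
  set.seed(14)
  D <- random_metric_D(4, labels = LETTERS[1:4])
  a1 <- c(A = 2, B = 1); a2 <- c(C = 1, D = 3)
  r12 <- ses_dpw(a1, a2, D, n_null = 99, seed = 5)
  r21 <- ses_dpw(a2, a1, D, n_null = 99, seed = 5)
  expect_equal(r12$ses, r21$ses, tolerance = 1e-12)

  Deq <- matrix(3, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(Deq) <- 0
  rdeg <- ses_dpw(c(A = 1, B = 1), c(A = 1, B = 1), Deq,
                  n_null = 49, seed = 1)
  expect_true(rdeg$degenerate)

  ex <- exhaustive_ses(function(Dp) naive_dpw(a1, a2, Dp), D)
  res_ex <- ses_dpw(a1, a2, D, seed = 1, exhaustive = TRUE)
  expect_equal(res_ex$ses, ex$ses, tolerance = 1e-10)
})

test_that("band components compose the per-plot and per-pair operations", {
  set.seed(15)
  lab <- sprintf("s%01d", 1:6)
  D <- random_metric_D(6, labels = lab)
  df <- tibble::tribble(
    ~plot, ~species, ~abundance,
    "p1", "s1", 2, "p1", "s2", 1, "p1", "s3", 1,
    "p2", "s2", 3, "p2", "s4", 1,
    "p3", "s5", 1, "p3", "s6", 2, "p3", "s1", 1
  )
  meta <- tibble::tibble(plot = c("p1", "p2", "p3"), transect = "T",
                         elevation = c(410, 420, 480))
  comm <- community_matrix(df, meta, band_width = 100)
  seed <- 21
  bc <- band_components(comm, D, 400, n_null = 199, seed = seed)

  plots <- c("p1", "p2", "p3")
  nris <- vapply(seq_along(plots), function(i) {
    a <- comm$abund[plots[i], ]; a <- a[a > 0]
    nri(a, D, n_null = 199, seed = derive_seed(seed, i))$ses
  }, numeric(1))
  expect_equal(bc$alpha, mean(nris), tolerance = 1e-12)

  prs <- combn(3, 2)
  betas <- vapply(seq_len(ncol(prs)), function(k) {
    a1 <- comm$abund[plots[prs[1, k]], ]; a1 <- a1[a1 > 0]
    a2 <- comm$abund[plots[prs[2, k]], ]; a2 <- a2[a2 > 0]
    ses_dpw(a1, a2, D, n_null = 199,
            seed = derive_seed(seed, 10000 + k))$ses
  }, numeric(1))
  expect_equal(bc$beta_within, mean(betas), tolerance = 1e-12)

  gamma <- nri(pool_band(comm, 400), D, n_null = 199,
               seed = derive_seed(seed, 0))$ses
  expect_equal(bc$gamma, gamma, tolerance = 1e-12)
})

test_that("single-plot bands give alpha = gamma and undefined beta", {
  set.seed(16)
  lab <- sprintf("s%01d", 1:5)
  D <- random_metric_D(5, labels = lab)
  df <- tibble::tibble(plot = "p1", species = c("s1", "s2", "s3"),
                       abundance = c(2, 1, 1))
  meta <- tibble::tibble(plot = "p1", transect = "T", elevation = 100)
  comm <- community_matrix(df, meta, band_width = 100)
  bc <- band_components(comm, D, 100, n_null = 199, seed = 3)
  expect_true(is.na(bc$beta_within))
  ## pooled assemblage equals the single plot: same observed MPD
  a <- df$abundance; names(a) <- df$species
  expect_equal(nri(a, D, n_null = 199,
                   seed = derive_seed(3, 0))$ses, bc$gamma)
})

test_that("monospecific plots are skipped with a warning", {
  set.seed(17)
  lab <- sprintf("s%01d", 1:4)
  D <- random_metric_D(4, labels = lab)
  df <- tibble::tribble(~plot, ~species, ~abundance,
                        "p1", "s1", 5,
                        "p2", "s1", 2, "p2", "s2", 2)
  meta <- tibble::tibble(plot = c("p1", "p2"), transect = "T",
                         elevation = c(110, 120))
  comm <- community_matrix(df, meta, band_width = 100)
  expect_warning(bc <- band_components(comm, D, 100, n_null = 99,
                                       seed = 1), "monospecific")
  expect_equal(bc$n_skipped, 1L)
})

test_that("band beta matrix is symmetric and matches pooled ses_dpw", {
  set.seed(18)
  lab <- sprintf("s%01d", 1:6)
  D <- random_metric_D(6, labels = lab)
  df <- tidyr::expand_grid(plot = c("p1", "p2", "p3", "p4"),
                           species = lab)
  df$abundance <- rpois(nrow(df), 2) + 1
  meta <- tibble::tibble(plot = c("p1", "p2", "p3", "p4"),
                         transect = "T",
                         elevation = c(110, 120, 210, 310))
  comm <- community_matrix(df, meta, band_width = 100)
  bb <- band_beta_matrix(comm, D, n_null = 199, seed = 9)
  expect_equal(nrow(bb), 3)               # 3 unordered band pairs
  expect_true(all(bb$band1 < bb$band2))
  M <- pair_table_to_matrix(bb, "ses")
  expect_equal(M, t(M))
  ## direct recomputation of one pair with the same derived seed
  k <- 1
  direct <- ses_dpw(pool_band(comm, 100), pool_band(comm, 200), D,
                    n_null = 199, seed = derive_seed(9, 200000 + k))
  expect_equal(bb$ses[1], direct$ses, tolerance = 1e-12)
})

test_that("functional and phylogenetic ses coincide when the dendrogram
           is the phylogeny", {
  tree <- simulate_tree(10, seed = 31)
  D <- cophenetic_distance(tree)
  a <- setNames(c(2, 1, 1), tree$tip.label[1:3])
  r1 <- nri(a, D, n_null = 199, seed = 4)
  r2 <- nri(a, D, n_null = 199, seed = 4)
  expect_identical(r1, r2)
})
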