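band_df <- function(n = 12, seed = 1) {
  set.seed(seed)
  tibble::tibble(band = 100 * seq_len(n),
                 elevation = 100 * seq_len(n) + 50,
                 y = rnorm(n))
}

test_that("polynomial OLS recovers exact fits and matches the normal
           equations", {
  df <- band_df()
  df$y <- 2 * df$elevation
  fit <- suppressWarnings(ols_poly(df, "y", "elevation", 1))
  expect_equal(unname(coef(fit$model)[2]), 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  ## exact quadratic: quadratic wins on AIC
  df2 <- band_df()
  df2$y <- (df2$elevation - mean(df2$elevation))^2
  fits <- suppressWarnings(fit_elevation_models(df2, "y"))
  expect_equal(fits$quadratic$r_squared, 1, tolerance = 1e-10)
  expect_lt(fits$quadratic$aic, fits$linear$aic)
  expect_equal(fits$best, "quadratic")

  ## random data: coefficients match (X'X)^-1 X'y
  df3 <- band_df(15, seed = 3)
  fit3 <- ols_poly(df3, "y", "elevation", 2)
  xc <- df3$elevation - mean(df3$elevation)
  X <- cbind(1, xc, xc^2)
  beta <- solve(t(X) %*% X, t(X) %*% df3$y)
  expect_equal(unname(coef(fit3$model)), as.vector(beta),
               tolerance = 1e-8)
  expect_error(ols_poly(df3[1:2, ], "y", "elevation", 2), "n >=")
})

test_that("AIC differences are invariant to affine rescaling of y", {
  df <- band_df(10, seed = 4)
  f1 <- fit_elevation_models(df, "y")
  df2 <- df; df2$y <- 5 * df$y + 3
  f2 <- fit_elevation_models(df2, "y")
  expect_equal(f1$linear$aic - f1$quadratic$aic,
               f2$linear$aic - f2$quadratic$aic, tolerance = 1e-8)
  expect_equal(f1$best, f2$best)
})

test_that("the simple OLS screen reduces to squared Pearson correlation", {
  df <- band_df(10, seed = 5)
  df$x1 <- df$y                       # self-predictor: R2 = 1
  df$x2 <- rnorm(10)
  df$x2 <- df$x2 - sum(df$x2 * df$y) / sum(df$y^2) * df$y   # orthogonalized
  scr <- suppressWarnings(simple_ols_screen(df, "y", c("x1", "x2")))
  expect_equal(scr$r_squared[1], 1, tolerance = 1e-10)
  expect_equal(scr$r_squared[2], cor(df$y, df$x2)^2, tolerance = 1e-10)
  expect_equal(scr$r_squared, c(cor(df$y, df$x1)^2, cor(df$y, df$x2)^2),
               tolerance = 1e-10)
})

test_that("forward stepwise selects the generating predictor first", {
  set.seed(6)
  n <- 30
  df <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  df$y <- 3 * df$x1 + rnorm(n, 0, 1)    # R2 ~ 0.9 from x1 alone
  fit <- stepwise_forward(df, "y", c("x2", "x1", "x3"))
  expect_equal(fit$selected[1], "x1")
  expect_true("x1" %in% fit$selected)

  ## alpha_enter = 0: nothing can enter
  fit0 <- stepwise_forward(df, "y", c("x1", "x2"), alpha_enter = 0)
  expect_true(fit0$intercept_only)
  expect_error(stepwise_forward(df[1:4, ], "y", c("x1", "x2", "x3")),
               "candidates")
})

test_that("all-noise stepwise first-entry rate is near the family-wise
           bound", {
  set.seed(7)
  n <- 25
  entered <- vapply(1:200, function(r) {
    df <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                         y = rnorm(n))
    !stepwise_forward(df, "y", c("x1", "x2", "x3"))$intercept_only
  }, logical(1))
  ## 3 candidates at alpha 0.05: entry rate should be well below the
  ## Bonferroni-style bound 0.15 (and above 0)
  expect_lt(mean(entered), 0.25)
})

test_that("Mantel r hits the exact correlations and agrees with vegan", {
  set.seed(8)
  Dx <- random_metric_D(8)
  expect_equal(mantel(Dx, Dx, n_perm = 99, seed = 1)$r, 1)
  Drev <- max(Dx) - Dx; diag(Drev) <- 0
  expect_equal(mantel(Drev, Dx, n_perm = 99, seed = 1)$r, -1)

  Dy <- random_metric_D(8)
  ours <- mantel(Dy, Dx, n_perm = 999, seed = 2)
  expect_equal(ours$r, unname(vegan::mantel(Dy, Dx,
                                            permutations = 9)$statistic),
               tolerance = 1e-10)
  Dc <- matrix(1, 5, 5, dimnames = dimnames(Dx[1:5, 1:5]))
  diag(Dc) <- 0
  expect_error(mantel(Dc, Dx[1:5, 1:5]), "constant")
})

test_that("exhaustive Mantel p matches high-replicate sampling", {
  set.seed(9)
  D1 <- random_metric_D(5)
  D2 <- random_metric_D(5, labels = rownames(D1))
  dimnames(D2) <- dimnames(D1)
  ex <- mantel(D1, D2, exhaustive = TRUE)
  expect_equal(ex$n_perm, 120)
  samp <- mantel(D1, D2, n_perm = 20000, seed = 3)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / samp$n_perm)
  expect_lt(abs(samp$p_value - ex$p_value), 3 * se + 1e-4)
})

test_that("MRM reduces to Mantel for one predictor and recovers exact
           combinations", {
  set.seed(10)
  Dy <- random_metric_D(9)
  Dx <- random_metric_D(9, labels = rownames(Dy))
  dimnames(Dx) <- dimnames(Dy)
  fit <- mrm(Dy, list(x = Dx), n_perm = 99, seed = 1)
  m <- mantel(Dy, Dx, n_perm = 99, seed = 1)
  expect_equal(sqrt(fit$r_squared) * sign(fit$coefficients$estimate[2]),
               m$r, tolerance = 1e-10)

  ## exact linear combination of two predictors
  Dx2 <- random_metric_D(9, labels = rownames(Dy))
  dimnames(Dx2) <- dimnames(Dy)
  Dy2 <- 2 * Dx + 0.5 * Dx2
  fit2 <- mrm(Dy2, list(a = Dx, b = Dx2), n_perm = 99, seed = 2)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit2$coefficients$estimate,
               c(0, 2, 0.5), tolerance = 1e-8)

  ## coefficients match the normal equations on triangle vectors
  vy <- Dy[lower.tri(Dy)]
  X <- cbind(1, Dx[lower.tri(Dx)], Dx2[lower.tri(Dx2)])
  beta <- solve(t(X) %*% X, t(X) %*% vy)
  fit3 <- mrm(Dy, list(a = Dx, b = Dx2), n_perm = 99, seed = 3)
  expect_equal(fit3$coefficients$estimate, as.vector(beta),
               tolerance = 1e-8)

  ## collinear predictors are refused with the offending pair named
  expect_error(mrm(Dy, list(a = Dx, b = 2 * Dx), n_perm = 9, seed = 1),
               "collinear")
})

test_that("variation partitioning decomposes R2 into unique and shared
           fractions", {
  set.seed(11)
  n <- 30
  ## mutually orthogonal groups; y built from group A only
  M <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  df <- tibble::tibble(a1 = M[, 1], b1 = M[, 2], c1 = M[, 3],
                       c2 = M[, 4])
  df$y <- 2 * df$a1 + rnorm(n, 0, 0.02)
  vp <- variation_partition(df, "y", list(A = "a1", B = "b1",
                                          C = c("c1", "c2")))
  fr <- setNames(vp$fractions$fraction, vp$fractions$term)
  expect_lt(fr[["unique_B"]], 0.05)
  expect_lt(fr[["unique_C"]], 0.05)
  expect_gt(fr[["unique_A"]], 0.9)

  ## duplicated groups: all variance shared
  df2 <- df
  df2$b1 <- df2$a1 + rnorm(n, 0, 1e-6)
  vp2 <- variation_partition(df2, "y", list(A = "a1", B = "b1",
                                            C = c("c1", "c2")))
  fr2 <- setNames(vp2$fractions$fraction, vp2$fractions$term)
  expect_lt(abs(fr2[["unique_A"]]), 0.01)
  expect_lt(abs(fr2[["unique_B"]]), 0.01)
  expect_gt(fr2[["combined"]], 0.9)
})

test_that("variation-partition subsets match independent OLS fits and
           close the identity", {
  set.seed(12)
  n <- 25
  df <- tibble::tibble(a1 = rnorm(n), b1 = rnorm(n), c1 = rnorm(n),
                       c2 = rnorm(n))
  df$y <- df$a1 + 0.5 * df$b1 - df$c1 + rnorm(n)
  groups <- list(A = "a1", B = "b1", C = c("c1", "c2"))
  vp <- variation_partition(df, "y", groups)
  ## every subset R2 equals a direct lm fit
  for (k in seq_len(nrow(vp$subset_r2))) {
    preds <- unlist(groups[strsplit(vp$subset_r2$subset[k],
                                    "+", fixed = TRUE)[[1]]])
    ref <- summary(lm(reformulate(preds, "y"), data = df))$r.squared
    expect_equal(vp$subset_r2$r_squared[k], ref, tolerance = 1e-10)
  }
  ## unique + combined + residual = 1
  expect_equal(sum(vp$fractions$fraction), 1, tolerance = 1e-10)
})

test_that("environmental PCA and distance construction are consistent", {
  env <- simulate_environment(8, seed = 13)
  env2 <- env_pca(env, attr(env, "climate_cols"), attr(env, "topo_cols"))
  expect_true(all(c("pc1_clim", "pc1_hetero", "pc2_hetero") %in%
                    names(env2)))
  dists <- build_distances(env2)
  expect_equal(dists$dist_ele["200", "700"], 500)
  expect_equal(dists$dist_rarea["200", "300"],
               abs(env2$rarea[1] - env2$rarea[2]), tolerance = 1e-12)
  ## habitat distance matches a per-pair Euclidean loop
  H <- cbind(env2$pc1_hetero, env2$pc2_hetero)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      expect_equal(dists$dist_habit[i, j],
                   sqrt(sum((H[i, ] - H[j, ])^2)), tolerance = 1e-12)
    }
  }
  ## identical bands have zero distance everywhere
  env_const <- env2[c(1, 1), ]
  env_const$band <- c(100, 101)
  d0 <- build_distances(env_const)
  expect_equal(unname(d0$dist_clim), matrix(0, 2, 2))
})
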