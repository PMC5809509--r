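## gradient_stats: environmental PCA and distance construction,
## linear/quadratic OLS with AIC choice, simple OLS screens, forward
## stepwise regression, Mantel tests, MRM and three-set variation
## partitioning — the layer that relates the diversity components to
## the environment.

#' Derive climate and heterogeneity PC axes for a band table
#'
#' Runs two separate PCAs — one on the climatic columns and one on the
#' standard deviations of the topographic columns — after
#' standardization, and appends `pc1_clim`, `pc1_hetero` and
#' `pc2_hetero` to the table.
#'
#' @param env Data frame with one row per band.
#' @param climate_cols,topo_cols Character vectors naming the raw
#'   climatic and topographic-SD columns.
#' @return `env` with the three PC columns appended; the two
#'   `pca_result` objects are attached as attributes `pca_clim` and
#'   `pca_hetero`.
#' @export
env_pca <- function(env, climate_cols, topo_cols) {
  env <- tibble::as_tibble(env)
  miss <- setdiff(c(climate_cols, topo_cols), names(env))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(env) < 3) stop("need >= 3 bands for the environmental PCAs")
  std <- function(M) scale(as.matrix(M))
  p_clim <- pca(std(env[climate_cols]), k = 1)
  p_het <- pca(std(env[topo_cols]), k = 2)
  env$pc1_clim <- p_clim$scores[, 1]
  env$pc1_hetero <- p_het$scores[, 1]
  env$pc2_hetero <- p_het$scores[, 2]
  attr(env, "pca_clim") <- p_clim
  attr(env, "pca_hetero") <- p_het
  env
}

## Gaussian-profile AIC with k = mean parameters + 1 (variance):
## n log(RSS/n) + 2k. Only AIC *differences* are consumed, so the
## additive constant convention is fixed here once.
aic_rss <- function(rss, n, n_mean_par) {
  n * log(rss / n) + 2 * (n_mean_par + 1)
}

new_gradient_fit <- function(model, form, y, terms, data) {
  sm <- summary(model)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else {
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  }
  rss <- sum(stats::residuals(model)^2)
  structure(list(
    model = model, form = form, response = y, terms = terms,
    r_squared = sm$r.squared, F = if (is.null(fstat)) NA_real_ else
      unname(fstat[1]),
    p_value = unname(p), n = nrow(data),
    aic = aic_rss(rss, nrow(data), length(stats::coef(model)))
  ), class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat("<gradient_fit> ", x$form, ": ", equation_string(x),
      "  (R2 = ", sprintf("%.3f", x$r_squared),
      ", AIC = ", sprintf("%.2f", x$aic), ")\n", sep = "")
  invisible(x)
}

## "y = a + b x1 + c x2" rendering used in the stepwise report tables.
equation_string <- function(fit) {
  cf <- stats::coef(fit$model)
  rhs <- sprintf("%.3f", cf[1])
  for (nm in names(cf)[-1]) {
    rhs <- paste0(rhs, ifelse(cf[nm] >= 0, " + ", " - "),
                  sprintf("%.3f", abs(cf[nm])), " ", nm)
  }
  paste("y =", rhs)
}

#' Tidy a gradient fit into its coefficient table
#' @param x A `gradient_fit`.
#' @param ... Unused.
#' @method tidy gradient_fit
#' @export
tidy.gradient_fit <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std_error = cf[, 2], statistic = cf[, 3],
                 p_value = cf[, 4])
}

#' One-row model summary of a gradient fit
#' @param x A `gradient_fit`.
#' @param ... Unused.
#' @method glance gradient_fit
#' @export
glance.gradient_fit <- function(x, ...) {
  tibble::tibble(form = x$form, r_squared = x$r_squared, F = x$F,
                 p_value = x$p_value, aic = x$aic, n = x$n,
                 stars = p_stars(x$p_value),
                 equation = equation_string(x))
}

#' Polynomial (linear or quadratic) regression of a band value on
#' elevation
#'
#' Fits ordinary least squares on the centred predictor (and its square
#' for `degree = 2`). The AIC uses the Gaussian profile form
#' n log(RSS/n) + 2k with k = mean parameters + 1.
#'
#' @param data Data frame with one row per band.
#' @param y,x Column names of the response and the predictor
#'   (elevation).
#' @param degree 1 (linear) or 2 (quadratic).
#' @return A `gradient_fit`.
#' @export
ols_poly <- function(data, y, x, degree = 1) {
  data <- tibble::as_tibble(data)
  if (!all(c(y, x) %in% names(data))) stop("columns not found: ", y, ", ", x)
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2")
  n <- nrow(data)
  if (n < degree + 2) stop("need n >= degree + 2 observations")
  xc <- data[[x]] - mean(data[[x]])
  if (stats::sd(xc) == 0) stop("degenerate design: constant predictor")
  df <- data.frame(.y = data[[y]], .x = xc)
  fit <- if (degree == 1) {
    stats::lm(.y ~ .x, data = df)
  } else {
    stats::lm(.y ~ .x + I(.x^2), data = df)
  }
  if (anyNA(stats::coef(fit))) stop("degenerate (collinear) design")
  out <- new_gradient_fit(fit, if (degree == 1) "linear" else "quadratic",
                          y, x, df)
  out$degree <- degree
  out
}

#' Fit linear and quadratic elevation models and pick by AIC
#'
#' When the linear model already fits to numerical precision
#' (RSS below 1e-10 of the total sum of squares) the linear form is
#' chosen outright: log-RSS ratios of floating-point residuals are
#' meaningless and the nested quadratic cannot improve on an exact fit.
#'
#' @inheritParams ols_poly
#' @return List with `linear`, `quadratic` (both `gradient_fit`) and
#'   `best` (`"linear"` or `"quadratic"`, the lower-AIC form).
#' @export
fit_elevation_models <- function(data, y, x = "elevation") {
  lin <- ols_poly(data, y, x, 1)
  quad <- ols_poly(data, y, x, 2)
  tss <- sum((data[[y]] - mean(data[[y]]))^2)
  rss_lin <- sum(stats::residuals(lin$model)^2)
  best <- if (rss_lin <= 1e-10 * tss) {
    "linear"
  } else if (lin$aic <= quad$aic) "linear" else "quadratic"
  list(linear = lin, quadratic = quad, best = best)
}

#' Simple OLS screen of single environmental predictors
#'
#' One univariate regression per predictor; p-values from the F test.
#'
#' @param data Data frame, one row per band.
#' @param y Response column name.
#' @param predictors Character vector of predictor column names.
#' @return Tibble: `predictor`, `r_squared`, `p_value`, `stars`.
#' @export
simple_ols_screen <- function(data, y, predictors) {
  purrr::map_dfr(predictors, function(p) {
    fit <- ols_poly(data, y, p, 1)
    tibble::tibble(predictor = p, r_squared = fit$r_squared,
                   p_value = fit$p_value, stars = p_stars(fit$p_value))
  })
}

#' Forward stepwise multiple regression
#'
#' Adds, at each step, the candidate with the smallest partial-F
#' p-value, while that p-value is below `alpha_enter`; stops otherwise.
#'
#' @param data Data frame.
#' @param y Response column name.
#' @param candidates Character vector of candidate predictor columns.
#' @param alpha_enter Entry threshold on the partial-F p (default
#'   0.05).
#' @return A `gradient_fit` with extra fields `selected` (predictors in
#'   entry order) and `intercept_only` (flag set when nothing enters).
#' @export
stepwise_forward <- function(data, y, candidates, alpha_enter = 0.05) {
  data <- tibble::as_tibble(data)
  if (nrow(data) <= length(candidates) + 2) {
    stop("need n > candidates + 2")
  }
  selected <- character(0)
  remaining <- candidates
  base_form <- function(sel) {
    stats::as.formula(paste(y, "~", if (length(sel) == 0) "1" else
      paste(sel, collapse = " + ")))
  }
  current <- stats::lm(base_form(selected), data = data)
  repeat {
    if (length(remaining) == 0) break
    pvals <- vapply(remaining, function(cand) {
      ext <- stats::lm(base_form(c(selected, cand)), data = data)
      a <- stats::anova(current, ext)
      a$`Pr(>F)`[2]
    }, numeric(1))
    j <- which.min(pvals)
    if (!is.finite(pvals[j]) || pvals[j] >= alpha_enter) break
    selected <- c(selected, remaining[j])
    remaining <- remaining[-j]
    current <- stats::lm(base_form(selected), data = data)
  }
  out <- new_gradient_fit(current, "multiple", y, selected, data)
  out$selected <- selected
  out$intercept_only <- length(selected) == 0
  out
}

## Lower-triangle vector of a labeled symmetric matrix, in a fixed
## label order shared by all matrices of one analysis.
lower_vec <- function(M, labels) {
  M <- M[labels, labels]
  M[lower.tri(M)]
}

#' Simple Mantel test
#'
#' Pearson correlation between the lower triangles of two distance
#' matrices; significance by permuting the row/column labels of the
#' response matrix `Dy`. The two-sided p counts permutations with
#' `|r_perm| >= |r_obs|`, with the observed configuration included in
#' numerator and denominator.
#'
#' @param Dy,Dx Labeled symmetric distance matrices over the same
#'   items (>= 4).
#' @param n_perm Number of permutations (study default 10000).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all label permutations (small n only).
#' @return Object of class `mantel_test` with fields `r`, `p_value`,
#'   `n_perm`, `n`, `seed`.
#' @export
mantel <- function(Dy, Dx, n_perm = 10000, seed = 1, exhaustive = FALSE) {
  validate_symmetric(Dy); validate_symmetric(Dx)
  labels <- rownames(Dy)
  if (!setequal(labels, rownames(Dx))) stop("matrices share no label set")
  n <- length(labels)
  if (n < 4) stop("Mantel test needs >= 4 items")
  vy <- lower_vec(Dy, labels)
  vx <- lower_vec(Dx, labels)
  if (stats::sd(vy) == 0 || stats::sd(vx) == 0) {
    stop("constant distances: Mantel r undefined")
  }
  r_obs <- stats::cor(vy, vx)
  perms <- if (exhaustive) {
    if (n > 8) stop("exhaustive Mantel limited to <= 8 items")
    all_permutations(n)
  } else {
    with_seed(seed, t(vapply(seq_len(n_perm), function(i) sample.int(n),
                             integer(n))))
  }
  Dys <- Dy[labels, labels]
  r_perm <- vapply(seq_len(nrow(perms)), function(k) {
    p <- perms[k, ]
    stats::cor(Dys[p, p][lower.tri(Dys)], vx)
  }, numeric(1))
  if (exhaustive) {
    ## identity permutation is among the enumerated ones
    p_val <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
  } else {
    p_val <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) /
      (nrow(perms) + 1)
  }
  structure(list(r = r_obs, p_value = p_val, n_perm = nrow(perms),
                 n = n, seed = seed), class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat("<mantel_test> r = ", sprintf("%.3f", x$r), p_stars(x$p_value),
      " (p = ", sprintf("%.4g", x$p_value), ", ", x$n_perm,
      " permutations)\n", sep = "")
  invisible(x)
}

#' @method tidy mantel_test
#' @export
tidy.mantel_test <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, stars = p_stars(x$p_value),
                 n = x$n, n_perm = x$n_perm)
}

#' @method glance mantel_test
#' @export
glance.mantel_test <- function(x, ...) tidy(x)

#' Multiple regression on distance matrices (MRM)
#'
#' OLS of the response matrix's lower triangle on the predictors' lower
#' triangles; per-coefficient significance by permuting the response
#' matrix's labels and refitting, two-sided on |t|.
#'
#' @param Dy Labeled symmetric response distance matrix (>= 5 items).
#' @param Dx_list Named list of labeled predictor distance matrices.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Object of class `mrm_fit` with `coefficients` (tibble:
#'   `term`, `estimate`, `p_value`, `stars`), `r_squared`, `n`,
#'   `n_perm`, `seed`.
#' @export
mrm <- function(Dy, Dx_list, n_perm = 999, seed = 1) {
  validate_symmetric(Dy)
  if (is.null(names(Dx_list)) || any(names(Dx_list) == "")) {
    stop("Dx_list must be a named list")
  }
  labels <- rownames(Dy)
  n <- length(labels)
  if (n < 5) stop("MRM needs >= 5 items")
  X <- cbind(`(Intercept)` = 1,
             vapply(Dx_list, lower_vec, numeric(n * (n - 1) / 2),
                    labels = labels))
  kap <- kappa(X, exact = TRUE)
  if (kap > 1e8) {
    cors <- abs(stats::cor(X[, -1, drop = FALSE]))
    diag(cors) <- 0
    worst <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    stop("collinear distance predictors: ",
         paste(colnames(cors)[worst], collapse = " ~ "))
  }
  fit_t <- function(yv) {
    fit <- stats::lm.fit(X, yv)
    rss <- sum(fit$residuals^2)
    dfree <- length(yv) - ncol(X)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(diag(XtXinv) * rss / dfree)
    list(coef = fit$coefficients, t = fit$coefficients / se, rss = rss)
  }
  vy <- lower_vec(Dy, labels)
  obs <- fit_t(vy)
  r2 <- 1 - obs$rss / sum((vy - mean(vy))^2)
  Dys <- Dy[labels, labels]
  perms <- with_seed(seed, t(vapply(seq_len(n_perm),
                                    function(i) sample.int(n), integer(n))))
  exceed <- rep(0, ncol(X))
  for (k in seq_len(n_perm)) {
    p <- perms[k, ]
    tv <- fit_t(Dys[p, p][lower.tri(Dys)])$t
    exceed <- exceed + (abs(tv) >= abs(obs$t) - 1e-12)
  }
  pvals <- (1 + exceed) / (n_perm + 1)
  coefs <- tibble::tibble(term = colnames(X), estimate = unname(obs$coef),
                          p_value = unname(pvals),
                          stars = p_stars(unname(pvals)))
  structure(list(coefficients = coefs, r_squared = r2, n = n,
                 n_perm = n_perm, seed = seed), class = "mrm_fit")
}

#' @export
print.mrm_fit <- function(x, ...) {
  cat("<mrm_fit> R2 = ", sprintf("%.3f", x$r_squared), "; ",
      x$n_perm, " permutations\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @method tidy mrm_fit
#' @export
tidy.mrm_fit <- function(x, ...) x$coefficients

#' @method glance mrm_fit
#' @export
glance.mrm_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n, n_perm = x$n_perm)
}

#' Three-set variation partitioning by partial regressions
#'
#' Fits the seven nonempty unions of the three predictor groups and
#' decomposes the full model's R-squared into the unique fraction of
#' each group (R2 of all three minus R2 of the other two), a total
#' combined (shared) fraction, and the residual. Negative shared
#' fractions are reported as-is with a flag, as is standard for this
#' decomposition.
#'
#' @param data Data frame.
#' @param y Response column name.
#' @param groups Named list of three character vectors of predictor
#'   columns.
#' @return Object of class `variation_partition` with `fractions`
#'   (tibble: `term`, `fraction`), `subset_r2` (the seven R2
#'   values), `negative_shared` flag.
#' @export
variation_partition <- function(data, y, groups) {
  data <- tibble::as_tibble(data)
  if (length(groups) != 3 || is.null(names(groups))) {
    stop("groups must be a named list of three predictor sets")
  }
  all_pred <- unlist(groups)
  if (nrow(data) <= length(all_pred) + 2) {
    stop("need n > total predictors + 2")
  }
  r2_of <- function(preds) {
    fit <- stats::lm(stats::as.formula(
      paste(y, "~", paste(preds, collapse = " + "))), data = data)
    if (anyNA(stats::coef(fit))) stop("rank-deficient predictor set: ",
                                      paste(preds, collapse = ", "))
    summary(fit)$r.squared
  }
  gn <- names(groups)
  subsets <- list()
  for (k in 1:3) {
    for (comb in utils::combn(gn, k, simplify = FALSE)) {
      subsets[[paste(comb, collapse = "+")]] <-
        r2_of(unlist(groups[comb]))
    }
  }
  full <- subsets[[paste(gn, collapse = "+")]]
  uniq <- vapply(seq_along(gn), function(i) {
    others <- gn[-i]
    full - subsets[[paste(others, collapse = "+")]]
  }, numeric(1))
  names(uniq) <- gn
  combined <- full - sum(uniq)
  fractions <- tibble::tibble(
    term = c(paste0("unique_", gn), "combined", "residual"),
    fraction = c(uniq, combined, 1 - full)
  )
  structure(list(fractions = fractions,
                 subset_r2 = tibble::tibble(subset = names(subsets),
                                            r_squared =
                                              unname(unlist(subsets))),
                 full_r2 = full,
                 negative_shared = combined < 0),
            class = "variation_partition")
}

#' @export
print.variation_partition <- function(x, ...) {
  cat("<variation_partition> full R2 = ", sprintf("%.3f", x$full_r2),
      if (x$negative_shared) " (negative shared fraction)", "\n", sep = "")
  print(x$fractions)
  invisible(x)
}

#' @method tidy variation_partition
#' @export
tidy.variation_partition <- function(x, ...) x$fractions

#' @method glance variation_partition
#' @export
glance.variation_partition <- function(x, ...) {
  tibble::tibble(full_r2 = x$full_r2,
                 negative_shared = x$negative_shared)
}

#' Band-pair distance matrices for the beta-diversity analyses
#'
#' Builds the four distance matrices used against the band-pair
#' S.E.S. D_pw: elevational difference (proxy of geographic distance),
#' absolute difference of (log) regional area, Euclidean distance on
#' the climate PC1, and Euclidean distance on the two heterogeneity
#' PCs.
#'
#' @param env Data frame with columns `band`, `elevation`, `rarea`,
#'   `pc1_clim`, `pc1_hetero`, `pc2_hetero` (as from [env_pca()]).
#' @return Named list of labeled matrices: `dist_ele`, `dist_rarea`,
#'   `dist_clim`, `dist_habit`.
#' @export
build_distances <- function(env) {
  req <- c("band", "elevation", "rarea", "pc1_clim", "pc1_hetero",
           "pc2_hetero")
  miss <- setdiff(req, names(env))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  lab <- as.character(env$band)
  named_abs <- function(v) {
    M <- abs(outer(v, v, "-"))
    dimnames(M) <- list(lab, lab)
    M
  }
  M_clim <- as.matrix(stats::dist(env$pc1_clim))
  dimnames(M_clim) <- list(lab, lab)
  M_hab <- as.matrix(stats::dist(cbind(env$pc1_hetero, env$pc2_hetero)))
  dimnames(M_hab) <- list(lab, lab)
  list(dist_ele = named_abs(env$elevation),
       dist_rarea = named_abs(env$rarea),
       dist_clim = M_clim,
       dist_habit = M_hab)
}
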