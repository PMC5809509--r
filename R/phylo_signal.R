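## phylo_signal: Blomberg's K with a PIC-variance randomization test and
## Pagel's lambda by profile maximum likelihood with a likelihood-ratio
## test against lambda = 0.

#' Brownian-motion covariance matrix of a rooted tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j;
#' `C[i, i]` is the root-to-tip depth. Multiplied by the rate sigma^2
#' this is the trait covariance expected under Brownian motion.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @return Symmetric positive semidefinite matrix in tip order.
#' @export
bm_covariance <- function(tree) {
  validate_phylogeny(tree)
  ## the outermost node of the parsed newick is taken as the root; a
  ## basal polytomy (e.g. a star phylogeny) is legitimate and gives a
  ## (block-)diagonal covariance
  ape::vcv.phylo(tree)
}

#' Pagel's lambda branch-length transform of a BM covariance
#'
#' Multiplies the off-diagonal (shared-history) entries by `lam`,
#' leaving tip depths unchanged; `lam = 0` is the star-tree
#' (independence) model, `lam = 1` plain Brownian motion.
#'
#' @param C BM covariance matrix from [bm_covariance()].
#' @param lam Scalar in `[0, lambda_max(C)]`.
#' @return The transformed covariance matrix.
#' @export
lambda_transform <- function(C, lam) {
  lmax <- lambda_max(C)
  if (lam < 0 || lam > lmax + 1e-12) {
    stop("lambda out of bounds [0, ", signif(lmax, 6), "]")
  }
  Cl <- C * lam
  diag(Cl) <- diag(C)
  Cl
}

#' Largest admissible lambda for a BM covariance
#'
#' The largest multiplier keeping every off-diagonal entry no greater
#' than both corresponding diagonals (1 for contemporaneous sister tips;
#' > 1 on most ultrametric trees).
#'
#' @param C BM covariance matrix.
#' @return Scalar upper bound for the lambda transform.
#' @export
lambda_max <- function(C) {
  off <- C
  diag(off) <- 0
  if (max(off) <= 0) return(1)  # star tree: lambda is irrelevant
  d <- diag(C)
  lim <- outer(d, d, pmin) / off
  min(lim[off > 0])
}

## lambda transform without the bounds check, for the inner profile
## loop (bounds validated once by the caller)
lambda_scale <- function(C, lam) {
  Cl <- C * lam
  diag(Cl) <- diag(C)
  Cl
}

## GLS pieces under covariance V: ancestral mean, residuals, quadratic
## form and log-determinant, via one Cholesky factorization.
gls_pieces <- function(V, x) {
  R <- tryCatch(chol(V), error = function(e) stop("singular covariance"))
  one <- rep(1, length(x))
  z1 <- backsolve(R, one, transpose = TRUE)
  zx <- backsolve(R, x, transpose = TRUE)
  s11 <- sum(z1^2)
  a_hat <- sum(z1 * zx) / s11
  resid_w <- zx - a_hat * z1       # whitened residuals
  list(a_hat = a_hat, quad = sum(resid_w^2), s11 = s11,
       logdet = 2 * sum(log(diag(R))))
}

#' Blomberg's K and its randomization test
#'
#' K compares the observed ratio of tip variance to
#' phylogenetically-corrected variance with its Brownian-motion
#' expectation; K = 1 matches BM, K < 1 indicates less signal than BM.
#' Significance comes from shuffling trait values across tips and
#' comparing the variance of phylogenetically independent contrasts:
#' p = proportion of permutations (observed included) whose contrast
#' variance is less than or equal to the observed one.
#'
#' @param tree A rooted [ape::phylo] (>= 4 tips).
#' @param x Named numeric trait vector over the tips (or in tip order).
#' @param n_perm Number of randomizations for the test (default 999).
#' @param seed Integer seed.
#' @param test Compute the randomization p-value (default TRUE).
#' @return One-row tibble: `K`, `p_K`, `n_perm`, `seed`.
#' @export
blomberg_k <- function(tree, x, n_perm = 999, seed = 1, test = TRUE) {
  x <- match_tip_data(tree, x)
  n <- length(x)
  if (n < 4) stop("Blomberg's K needs >= 4 tips")
  if (stats::var(x) == 0) stop("constant trait")
  C <- bm_covariance(tree)
  g <- gls_pieces(C, x)
  mse0 <- sum((x - g$a_hat)^2) / (n - 1)
  mse <- g$quad / (n - 1)
  expected <- (sum(diag(C)) - n / g$s11) / (n - 1)
  K <- (mse0 / mse) / expected
  p_K <- NA_real_
  if (test) {
    obs_var <- stats::var(ape::pic(x, tree))
    perm_var <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      xs <- stats::setNames(sample(x), names(x))
      stats::var(ape::pic(xs, tree))
    }, numeric(1)))
    p_K <- (1 + sum(perm_var <= obs_var)) / (n_perm + 1)
  }
  tibble::tibble(K = K, p_K = p_K, n_perm = if (test) n_perm else 0L,
                 seed = seed)
}

## Align a named (or tip-ordered) trait vector with the tree's tips.
match_tip_data <- function(tree, x) {
  if (!is.null(names(x))) {
    miss <- setdiff(tree$tip.label, names(x))
    if (length(miss) > 0) {
      stop("trait values missing for tips: ", paste(miss, collapse = ", "))
    }
    x <- x[tree$tip.label]
  } else if (length(x) != length(tree$tip.label)) {
    stop("unnamed trait vector must match the number of tips")
  } else {
    names(x) <- tree$tip.label
  }
  if (anyNA(x)) stop("non-finite trait values")
  x
}

## Profile log-likelihood at a given lambda: closed-form GLS mean and
## sigma^2_hat = quad/n, logL = -(n log(2 pi sigma2) + logdet + n)/2.
lambda_loglik <- function(C, x, lam) {
  n <- length(x)
  g <- gls_pieces(lambda_scale(C, lam), x)
  sigma2 <- g$quad / n
  -0.5 * (n * log(2 * pi * sigma2) + g$logdet + n)
}

#' Pagel's lambda by profile maximum likelihood
#'
#' The lambda transform scales the shared-history part of the BM
#' covariance; lambda is estimated by bounded one-dimensional
#' optimization of the profile log-likelihood (ancestral mean and rate
#' profiled out in closed form), scanning a grid first to avoid flat
#' regions. Significance is a likelihood-ratio test of the ML fit
#' against the independence model lambda = 0 (or against lambda = 1
#' with `test_against = "one"`), referred to chi-square with 1 df; the
#' boundary-respecting 50:50 mixture is available with
#' `mixture = TRUE`.
#'
#' @inheritParams blomberg_k
#' @param upper Upper bound for lambda; default the admissible maximum
#'   ([lambda_max()]), capped at 1 when `cap_one = TRUE`.
#' @param cap_one Restrict lambda to `[0, 1]` (default TRUE, the usual
#'   reporting convention).
#' @param test_against Null hypothesis for the LR test: `"zero"`
#'   (default) or `"one"`.
#' @param mixture Use the 50:50 chi-square mixture for the boundary
#'   null (default FALSE: plain, conservative chi-square 1).
#' @return One-row tibble: `lambda`, `logL`, `logL0`, `p_lambda`,
#'   `unidentifiable` (TRUE on star trees, where the likelihood is
#'   constant in lambda).
#' @export
pagel_lambda <- function(tree, x, upper = NULL, cap_one = TRUE,
                         test_against = c("zero", "one"),
                         mixture = FALSE) {
  test_against <- match.arg(test_against)
  x <- match_tip_data(tree, x)
  n <- length(x)
  if (n < 4) stop("Pagel's lambda needs >= 4 tips")
  if (stats::var(x) == 0) stop("constant trait")
  C <- bm_covariance(tree)
  off <- C; diag(off) <- 0
  if (max(off) <= 0) {
    ll <- lambda_loglik(C, x, 0)
    return(tibble::tibble(lambda = NA_real_, logL = ll, logL0 = ll,
                          p_lambda = NA_real_, unidentifiable = TRUE))
  }
  if (is.null(upper)) {
    upper <- lambda_max(C)
    if (cap_one) upper <- min(upper, 1)
  }
  f <- function(l) lambda_loglik(C, x, l)
  ## coarse grid to bracket the optimum, then Brent within the bracket
  grid <- seq(0, upper, length.out = 21)
  gv <- vapply(grid, f, numeric(1))
  i <- which.max(gv)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, gv[1]), c(upper, gv[length(gv)]))
  best <- cand[which.max(cand[, 2]), ]
  lam_hat <- best[1]; logL <- best[2]
  ## final parabolic refinement from a rounded base point: the vertex of
  ## the local quadratic is insensitive to the floating-point noise that
  ## limits golden-section termination, making the estimate reproducible
  ## under affine rescalings of x
  h <- 1e-4
  base <- round(lam_hat, 6)
  if (base > h && base < upper - h) {
    f0 <- f(base); fp <- f(base + h); fm <- f(base - h)
    denom <- fp - 2 * f0 + fm
    if (is.finite(denom) && denom < 0) {
      step <- 0.5 * h * (fm - fp) / denom
      if (abs(step) < 2 * h) {
        lam_ref <- min(max(base + step, 0), upper)
        ll_ref <- f(lam_ref)
        if (ll_ref >= logL - 1e-9) {
          lam_hat <- lam_ref
          logL <- ll_ref
        }
      }
    }
  }
  logL0 <- if (test_against == "zero") f(0) else f(min(1, upper))
  lr <- max(0, 2 * (logL - logL0))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  if (mixture) p <- if (lr == 0) 1 else 0.5 * p
  tibble::tibble(lambda = lam_hat, logL = logL, logL0 = logL0,
                 p_lambda = p, unidentifiable = FALSE)
}

#' Phylogenetic-signal report for a trait table
#'
#' One row per trait with Blomberg's K (randomization p) and Pagel's
#' lambda (LR p), with the significance-star convention *P<0.05;
#' **P<0.01; ***P<0.001. Traits are log-transformed and standardized
#' first, matching the preprocessing used for the trait dendrogram.
#'
#' @param tree A rooted [ape::phylo].
#' @param traits Data frame with a `species` column and numeric trait
#'   columns (strictly positive).
#' @param n_perm Randomizations for the K test (default 999).
#' @param seed Integer master seed; per-trait sub-seeds are derived.
#' @param ... Passed to [pagel_lambda()].
#' @return Tibble: `trait`, `K`, `p_K`, `K_stars`, `lambda`,
#'   `p_lambda`, `lambda_stars`.
#' @export
signal_table <- function(tree, traits, n_perm = 999, seed = 1, ...) {
  Z <- preprocess_traits(traits)
  purrr::map_dfr(seq_len(ncol(Z)), function(j) {
    x <- stats::setNames(Z[, j], rownames(Z))
    k <- blomberg_k(tree, x, n_perm = n_perm,
                    seed = derive_seed(seed, j))
    l <- pagel_lambda(tree, x, ...)
    tibble::tibble(trait = colnames(Z)[j],
                   K = k$K, p_K = k$p_K, K_stars = p_stars(k$p_K),
                   lambda = l$lambda, p_lambda = l$p_lambda,
                   lambda_stars = p_stars(l$p_lambda))
  })
}
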