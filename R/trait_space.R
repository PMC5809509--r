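## trait_space: log-standardize traits, PCA, Euclidean trait distance,
## UPGMA dendrogram. The dendrogram plays the role of a "functional
## tree": its cophenetic distances feed the same dispersion metrics as
## the phylogeny.

#' Log-transform and standardize a trait table
#'
#' Each trait column is log-transformed (trait values must be strictly
#' positive: heights, leaf dimensions, onset month, seed mass) and then
#' centred and scaled to unit sample SD.
#'
#' @param traits Data frame with a `species` column and one numeric
#'   column per trait.
#' @return Numeric matrix (species x traits, rownames = species) with
#'   column means 0 and SDs 1.
#' @export
preprocess_traits <- function(traits) {
  traits <- tibble::as_tibble(traits)
  if (!"species" %in% names(traits)) stop("traits must have a species column")
  sp <- as.character(traits$species)
  if (anyDuplicated(sp)) stop("duplicate species in trait table")
  X <- as.matrix(traits[, setdiff(names(traits), "species"), drop = FALSE])
  if (!is.numeric(X)) stop("non-numeric trait columns")
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop("missing trait value: species ", sp[bad[1]], ", trait ",
         colnames(X)[bad[2]], " (no imputation is performed)")
  }
  if (any(X <= 0)) {
    bad <- which(X <= 0, arr.ind = TRUE)[1, ]
    stop("nonpositive trait value: species ", sp[bad[1]], ", trait ",
         colnames(X)[bad[2]], " (log transform requires positive values)")
  }
  L <- log(X)
  sds <- apply(L, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance trait column: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  Z <- scale(L)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  rownames(Z) <- sp
  Z
}

#' Principal component analysis with a deterministic sign convention
#'
#' Covariance PCA of an already-standardized matrix (equivalent to
#' correlation PCA of the raw log traits). Per component, the sign is
#' fixed so that the largest-magnitude loading is positive.
#'
#' @param X Numeric matrix (items x variables), typically the output of
#'   [preprocess_traits()].
#' @param k Number of components to keep. Default: the smallest k whose
#'   cumulative explained variance reaches `var_target`.
#' @param var_target Cumulative-variance threshold used when `k` is
#'   `NULL` (default 0.948).
#' @return Object of class `pca_result`: list with `scores` (items x k),
#'   `loadings` (variables x k), `var_explained` (length-k fractions of
#'   total variance), `k`.
#' @export
pca <- function(X, k = NULL, var_target = 0.948) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  frac <- ev / sum(ev)
  if (is.null(k)) {
    k <- which(cumsum(frac) >= var_target)[1]
    if (is.na(k)) k <- length(frac)
  }
  if (k < 1 || k > min(n - 1, p)) {
    stop("k must be in [1, min(rows - 1, cols)] = [1, ", min(n - 1, p), "]")
  }
  load <- fit$rotation[, seq_len(k), drop = FALSE]
  sc <- fit$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      sc[, j] <- -sc[, j]
    }
  }
  rownames(sc) <- rownames(X)
  structure(list(scores = sc, loadings = load,
                 var_explained = frac[seq_len(k)], k = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", x$k, " components; cumulative variance ",
      sprintf("%.1f%%", 100 * sum(x$var_explained)), "\n", sep = "")
  invisible(x)
}

#' Tidy a PCA result into a long loadings table
#' @param x A `pca_result`.
#' @param ... Unused.
#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) {
  tibble::tibble(
    variable = rep(rownames(x$loadings), x$k),
    component = rep(seq_len(x$k), each = nrow(x$loadings)),
    loading = as.vector(x$loadings)
  )
}

#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(k = x$k,
                 var_explained = sum(x$var_explained))
}

#' Euclidean distance between the rows of a score matrix
#'
#' @param scores Numeric matrix (items x components) with rownames.
#' @return Symmetric labeled distance matrix.
#' @export
euclidean_distance <- function(scores) {
  D <- as.matrix(stats::dist(scores, method = "euclidean"))
  validate_pairwise(D)
  D
}

#' UPGMA hierarchical clustering
#'
#' Agglomerative clustering with size-weighted (arithmetic-mean) average
#' linkage. Each merge is placed at half the between-cluster average
#' distance, so the tip-to-tip distance through the dendrogram equals
#' that average — the output is ultrametric. Ties in the minimum
#' inter-cluster distance are broken by merging the pair whose
#' (lexicographically smallest member) labels sort first, which makes
#' the merge order reproducible.
#'
#' @param D Symmetric labeled distance matrix over >= 2 items.
#' @return An ultrametric [ape::phylo] dendrogram with attribute
#'   `merge_heights` (the successive merge heights).
#' @export
upgma <- function(D) {
  validate_pairwise(D)
  n <- nrow(D)
  if (n < 2) stop("UPGMA requires at least 2 items")
  labels <- rownames(D)
  ## cluster state: newick fragment, height, size, representative label
  newick <- labels
  height <- rep(0, n)
  size <- rep(1L, n)
  rep_lab <- labels
  active <- rep(TRUE, n)
  W <- D   # running average-linkage distances between active clusters
  merge_heights <- numeric(0)
  fmt <- function(x) sprintf("%.12g", x)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL
    best_d <- Inf
    best_key <- NULL
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        d <- W[i, j]
        key <- paste(sort(c(rep_lab[i], rep_lab[j])), collapse = "\r")
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 && !is.null(best_key) &&
             key < best_key)) {
          best_d <- d
          best <- c(i, j)
          best_key <- key
        } else if (is.null(best)) {
          best_d <- d; best <- c(i, j); best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    h <- best_d / 2
    merge_heights <- c(merge_heights, h)
    kids <- c(i, j)[order(c(rep_lab[i], rep_lab[j]))]
    newick_new <- paste0(
      "(", newick[kids[1]], ":", fmt(h - height[kids[1]]), ",",
      newick[kids[2]], ":", fmt(h - height[kids[2]]), ")")
    ## size-weighted average linkage update (Lance-Williams, UPGMA)
    for (m in idx) {
      if (m == i || m == j) next
      W[i, m] <- W[m, i] <-
        (size[i] * W[i, m] + size[j] * W[j, m]) / (size[i] + size[j])
    }
    newick[i] <- newick_new
    height[i] <- h
    size[i] <- size[i] + size[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    active[j] <- FALSE
  }
  root <- which(active)
  tree <- ape::read.tree(text = paste0(newick[root], ";"))
  attr(tree, "merge_heights") <- merge_heights
  tree
}

#' Build the functional trait dendrogram from a raw trait table
#'
#' Convenience pipeline: log-standardize traits, PCA (keeping `k`
#' components), Euclidean distance on the scores, UPGMA.
#'
#' @inheritParams preprocess_traits
#' @inheritParams pca
#' @return List with `dendrogram` (ultrametric [ape::phylo]), `pca`
#'   (the `pca_result`), and `distance` (the Euclidean score distance).
#' @export
trait_dendrogram <- function(traits, k = NULL, var_target = 0.948) {
  Z <- preprocess_traits(traits)
  fit <- pca(Z, k = k, var_target = var_target)
  D <- euclidean_distance(fit$scores)
  list(dendrogram = upgma(D), pca = fit, distance = D)
}
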