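# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package implementations.

# MPD by explicit double loop over distinct species pairs.
naive_mpd <- function(assemblage, D) {
  a <- assemblage[assemblage > 0]
  f <- a / sum(a)
  sp <- names(f)
  num <- 0; den <- 0
  for (i in seq_along(sp)) {
    for (j in seq_along(sp)) {
      if (j <= i) next
      num <- num + f[i] * f[j] * D[sp[i], sp[j]]
      den <- den + f[i] * f[j]
    }
  }
  num / den
}

# D_pw by explicit evaluation of the two directed sums.
naive_dpw <- function(a1, a2, D, inner_weighted = TRUE) {
  a1 <- a1[a1 > 0]; a2 <- a2[a2 > 0]
  f <- a1 / sum(a1); g <- a2 / sum(a2)
  dir_sum <- function(w_from, sp_from, sp_to, w_to) {
    s <- 0
    for (i in seq_along(sp_from)) {
      dbar <- 0
      for (j in seq_along(sp_to)) {
        wt <- if (inner_weighted) w_to[j] else 1 / length(sp_to)
        dbar <- dbar + wt * D[sp_from[i], sp_to[j]]
      }
      s <- s + w_from[i] * dbar
    }
    s
  }
  (dir_sum(f, names(f), names(g), g) +
     dir_sum(g, names(g), names(f), f)) / 2
}

# Relabel a distance matrix by a permutation of its labels: the species
# at position i takes the tip (and therefore the distances) of the
# species at position perm[i].
relabel_D <- function(D, perm) {
  Dp <- D[perm, perm]
  dimnames(Dp) <- dimnames(D)
  Dp
}

# All permutations of 1..n as a list (independent of the package's
# generator).
perm_list <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perm_list(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Exhaustive-null standardized effect size of a metric under tip
# shuffling: metric_fun(D_relabeled) evaluated for every permutation.
exhaustive_ses <- function(metric_fun, D, observed = metric_fun(D)) {
  vals <- vapply(perm_list(nrow(D)),
                 function(p) unname(metric_fun(relabel_D(D, p))),
                 numeric(1))
  list(mean = mean(vals), sd = sd(vals),
       ses = unname(-1 * (observed - mean(vals)) / sd(vals)), null = vals)
}

# UPGMA oracle: clusters as explicit membership lists; between-cluster
# averages recomputed from the original matrix at every step (no
# Lance-Williams update). Returns tip-to-tip cophenetic matrix and the
# merge heights. Ties: lexicographically smallest (min-label) pair.
naive_upgma_coph <- function(D) {
  labels <- rownames(D)
  clusters <- as.list(labels)
  heights <- numeric(0)
  coph <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        d <- mean(D[clusters[[a]], clusters[[b]]])
        key <- paste(sort(c(min(clusters[[a]]), min(clusters[[b]]))),
                     collapse = "\r")
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 && key < best_key)) {
          best_d <- d; best <- c(a, b); best_key <- key
        }
      }
    }
    for (x in clusters[[best[1]]]) {
      for (y in clusters[[best[2]]]) {
        coph[x, y] <- coph[y, x] <- best_d
      }
    }
    heights <- c(heights, best_d / 2)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(coph = coph, heights = heights)
}

# Cophenetic distances by per-pair root-path walks (LCA oracle).
naive_cophenetic <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    path <- node
    while (node != root) {
      node <- parent_of[node]
      path <- c(path, node)
    }
    path
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    pi_ <- path_to_root(i)
    for (j in (i + 1):n) {
      pj <- path_to_root(j)
      lca <- intersect(pi_, pj)[1]
      di <- sum(len_of[pi_[seq_len(which(pi_ == lca) - 1)]])
      dj <- sum(len_of[pj[seq_len(which(pj == lca) - 1)]])
      D[i, j] <- D[j, i] <- di + dj
    }
  }
  D
}

# A metric random distance matrix: Euclidean distances between random
# points (guarantees symmetry, zero diagonal, triangle inequality).
random_metric_D <- function(n, dim = 3, labels = sprintf("t%02d", 1:n)) {
  X <- matrix(rnorm(n * dim), n, dim)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(labels, labels)
  D
}

# Tiny community fixture: plots x species counts with metadata.
toy_community <- function() {
  df <- tibble::tribble(
    ~plot, ~species, ~abundance,
    "p1", "A", 2, "p1", "B", 1,
    "p2", "A", 1, "p2", "C", 3,
    "p3", "B", 2, "p3", "C", 1, "p3", "D", 1
  )
  meta <- tibble::tibble(plot = c("p1", "p2", "p3"),
                         transect = "T1",
                         elevation = c(250, 260, 360))
  community_matrix(df, meta, band_width = 100)
}
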