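## core_data: domain containers, newick I/O, tree utilities, banding and
## band pooling. Trees are ape `phylo` objects throughout; tabular data
## are tibbles.

#' Read a rooted phylogeny with branch lengths from a newick file
#'
#' Thin validated wrapper around [ape::read.tree()]. Branch lengths are
#' required because every downstream dispersion metric consumes cophenetic
#' distances; polytomies are allowed.
#'
#' @param path Path to a file containing one newick string.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick_string(txt, src = path)
}

## Shared by read_newick() and the tests; `src` only decorates messages.
parse_newick_string <- function(txt, src = "<string>") {
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed newick in ", src,
             ": unbalanced ')' at character offset ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("malformed newick in ", src, ": ", depth,
         " unclosed '(' (string ends at offset ", length(chars), ")")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed newick in ", src)
  validate_phylogeny(tree)
  tree
}

## Invariants of the Phylogeny type: unique tips, branch lengths present
## and nonnegative. Zero-length edges are allowed (logged by callers that
## care about zero cophenetic distances).
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; lengths are required for distances")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  invisible(tree)
}

#' Write a phylogeny or dendrogram to a newick file
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Prune a phylogeny to a set of tip labels
#'
#' Retains exactly `keep`, collapsing degree-2 internal nodes with their
#' edge lengths summed, so path lengths between retained tips are
#' unchanged.
#'
#' @param tree An [ape::phylo] object.
#' @param keep Character vector of tip labels to retain.
#' @return The pruned [ape::phylo].
#' @export
prune_to_species <- function(tree, keep) {
  validate_phylogeny(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0) {
    stop("species not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Cophenetic (patristic) distance matrix of a phylogeny
#'
#' `D[i, j]` is the sum of branch lengths on the path between tips i and
#' j — the distance entering the weighted MPD and D_pw metrics.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @return A symmetric labeled matrix with zero diagonal.
#' @export
cophenetic_distance <- function(tree) {
  validate_phylogeny(tree)
  D <- ape::cophenetic.phylo(tree)
  D[order(rownames(D)), order(colnames(D)), drop = FALSE]
}

## Symmetric labeled square matrix (entries of any sign); the relaxed
## check used by the matrix-correlation layer, where standardized
## effect sizes may be negative.
validate_symmetric <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("matrix not square")
  if (is.null(rownames(D)) || !identical(rownames(D), colnames(D))) {
    stop("matrix must carry identical row/column labels")
  }
  if (any(abs(D - t(D)) > 1e-10)) stop("matrix not symmetric")
  invisible(D)
}

## PairwiseDistance invariants: square, symmetric, zero diagonal,
## nonnegative, labeled.
validate_pairwise <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("distance matrix not square")
  if (is.null(rownames(D)) || !identical(rownames(D), colnames(D))) {
    stop("distance matrix must carry identical row/column labels")
  }
  if (any(abs(D - t(D)) > 1e-10)) stop("distance matrix not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal not zero")
  if (any(D < 0)) stop("negative distances")
  invisible(D)
}

#' Build a community matrix from tabular plot data
#'
#' Accepts either long form (columns `plot`, `species`, `abundance`) or
#' wide form (a `plot` column plus one numeric column per species),
#' auto-detected from the column signature, together with per-plot
#' metadata (`plot`, `transect`, `elevation`). Plots are binned into
#' contiguous elevational bands of `band_width` metres using
#' lower-closed, upper-open intervals `[e, e + band_width)` anchored at
#' `band_origin`.
#'
#' @param df Long- or wide-form abundance table (data frame).
#' @param meta Data frame with columns `plot`, `transect`, `elevation`.
#' @param band_width Band width in metres (default 100).
#' @param band_origin Elevation at which band edges are anchored
#'   (default 0 m).
#' @return An object of class `community_matrix`: a list with `abund`
#'   (plots x species matrix of stem counts) and `meta` (a tibble with
#'   `plot`, `transect`, `elevation`, `band`; `band` is the band's lower
#'   edge in metres).
#' @export
community_matrix <- function(df, meta, band_width = 100, band_origin = 0) {
  df <- tibble::as_tibble(df)
  meta <- tibble::as_tibble(meta)
  req <- c("plot", "transect", "elevation")
  if (!all(req %in% names(meta))) {
    stop("meta must have columns: ", paste(req, collapse = ", "))
  }
  long <- if (all(c("plot", "species", "abundance") %in% names(df))) {
    df[, c("plot", "species", "abundance")]
  } else if ("plot" %in% names(df)) {
    tidyr::pivot_longer(df, -"plot", names_to = "species",
                        values_to = "abundance")
  } else {
    stop("abundance table must be long (plot, species, abundance) or wide ",
         "(plot + one column per species)")
  }
  if (any(long$abundance < 0)) stop("negative abundances")
  missing_meta <- setdiff(unique(long$plot), meta$plot)
  if (length(missing_meta) > 0) {
    stop("plots without metadata: ", paste(missing_meta, collapse = ", "))
  }
  plots <- as.character(sort(unique(long$plot)))
  species <- as.character(sort(unique(long$species)))
  abund <- matrix(0, length(plots), length(species),
                  dimnames = list(plots, species))
  abund[cbind(as.character(long$plot), as.character(long$species))] <-
    long$abundance
  meta <- meta[match(plots, as.character(meta$plot)), ]
  meta$plot <- as.character(meta$plot)
  if (band_width <= 0) stop("band_width must be positive")
  meta$band <- band_origin +
    floor((meta$elevation - band_origin) / band_width) * band_width
  structure(list(abund = abund, meta = meta,
                 band_width = band_width, band_origin = band_origin),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("<community_matrix> ", nrow(x$abund), " plots x ", ncol(x$abund),
      " species; ", length(unique(x$meta$band)), " bands (width ",
      x$band_width, " m)\n", sep = "")
  invisible(x)
}

#' Species recorded in a community but absent from a tree
#'
#' Enforces the coverage invariant between a community matrix and the
#' phylogeny (or dendrogram) used to score it. By default any species
#' missing from the tree is a hard error; with `drop_missing = TRUE` the
#' offending species are excluded with a warning instead.
#'
#' @param community A `community_matrix`.
#' @param tree An [ape::phylo].
#' @param drop_missing Drop (with a warning) rather than error.
#' @return The (possibly column-reduced) `community_matrix`.
#' @export
align_community_tree <- function(community, tree, drop_missing = FALSE) {
  stopifnot(inherits(community, "community_matrix"))
  missing <- setdiff(colnames(community$abund), tree$tip.label)
  if (length(missing) == 0) return(community)
  if (!drop_missing) {
    stop("species absent from tree: ", paste(missing, collapse = ", "),
         " (use drop_missing = TRUE to exclude them)")
  }
  warning("dropping ", length(missing), " species absent from tree: ",
          paste(missing, collapse = ", "))
  community$abund <-
    community$abund[, setdiff(colnames(community$abund), missing),
                    drop = FALSE]
  community
}

#' Pool the plots of one elevational band into a single assemblage
#'
#' Abundances are summed over the band's plots ("pooled and summed");
#' species with zero total are dropped.
#'
#' @param community A `community_matrix`.
#' @param band Band id (lower band edge, m).
#' @return Named numeric vector mapping species to pooled abundance.
#' @export
pool_band <- function(community, band) {
  stopifnot(inherits(community, "community_matrix"))
  sel <- community$meta$band == band
  if (!any(sel)) stop("no plots in band ", band)
  pooled <- colSums(community$abund[community$meta$plot[sel], ,
                                    drop = FALSE])
  pooled[pooled > 0]
}

#' All band assemblages of a community
#'
#' @param community A `community_matrix`.
#' @return Named list of pooled assemblages, one per band, in increasing
#'   band order.
#' @export
pool_bands <- function(community) {
  bands <- sort(unique(community$meta$band))
  stats::setNames(lapply(bands, function(b) pool_band(community, b)),
                  as.character(bands))
}

## One plot's assemblage as a named abundance vector (zeros dropped).
plot_assemblage <- function(community, plot) {
  v <- community$abund[plot, ]
  v[v > 0]
}
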