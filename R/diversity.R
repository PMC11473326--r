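#' Standardize a per-line trait matrix
#'
#' Centers each trait to mean 0 and scales to standard deviation 1
#' (denominator n-1), removing scale differences before distance or
#' principal-component computations.  A constant trait cannot be scaled
#' and raises an error naming it.
#'
#' @param values numeric matrix, lines in rows, traits in columns
#'   (>= 2 lines).
#' @return standardized matrix of the same shape.
#' @export
#' @examples
#' normalize_blups(cbind(a = c(1, 2, 3), b = c(10, 30, 20)))
normalize_blups <- function(values) {
  X <- as.matrix(values)
  if (nrow(X) < 2L) stop("need at least 2 lines")
  t_names <- colnames(X)
  if (is.null(t_names)) t_names <- paste0("T", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait(s) cannot be standardized: ",
         paste(t_names[sds == 0], collapse = ", "))
  Z <- scale(X)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  colnames(Z) <- t_names
  Z
}

#' Mean Euclidean distance matrix
#'
#' Root-mean-square difference over traits:
#' `d(i, j) = sqrt(mean_t (z_it - z_jt)^2)`.  Dividing the squared
#' Euclidean distance by the number of traits makes the distance scale
#' invariant to how many traits are measured, which is the convention in
#' plant-diversity work and keeps distances on standardized traits small
#' (typically below 1 for similar lines).
#'
#' @param standardized standardized per-line trait matrix
#'   (see [normalize_blups()]).
#' @return a [stats::dist] object labelled by line.
#' @export
mean_euclidean <- function(standardized) {
  Z <- as.matrix(standardized)
  d <- stats::dist(Z) / sqrt(ncol(Z))
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration with cluster-size weighting (UPGMA),
#' producing an ultrametric tree whose merge heights are the fusion
#' levels.  This is [stats::hclust()] with `method = "average"`; the
#' result additionally carries the class `lp_upgma`.
#'
#' @param dist a [stats::dist] object or symmetric distance matrix
#'   without missing entries, n >= 2.
#' @return an `hclust`/`lp_upgma` tree.
#' @export
#' @examples
#' d <- dist(c(A = 0, B = 2, C = 8))
#' upgma(d)$height
upgma <- function(dist) {
  if (!inherits(dist, "dist")) dist <- stats::as.dist(as.matrix(dist))
  if (anyNA(dist)) stop("distance matrix contains missing values")
  if (attr(dist, "Size") < 2L) stop("need at least 2 leaves")
  hc <- stats::hclust(dist, method = "average")
  class(hc) <- c("lp_upgma", "hclust")
  hc
}

#' Cut a dendrogram by the Mojena rule
#'
#' The cut-off is `mean(h) + k * sd(h)` over the fusion levels `h`
#' (standard deviation with denominator n-1).  Merges strictly above the
#' cut-off are severed; merges at exactly the cut-off are kept.  The
#' default constant `k = 1.25` follows the Milligan-Cooper
#' recommendation for the Mojena stopping rule.
#'
#' @param tree an `hclust`-like tree from [upgma()].
#' @param k_const the Mojena constant (default 1.25).
#' @return An object of class `lp_clusters`: data frame `line`,
#'   `cluster`; attributes `cutoff`, `k` (number of clusters),
#'   `k_const`, `fusion_levels`.
#' @export
#' @examples
#' d <- dist(c(A = 0, B = 2, C = 8))
#' mojena_cut(upgma(d), k_const = -0.5)
mojena_cut <- function(tree, k_const = 1.25) {
  stopifnot(inherits(tree, "hclust"))
  h <- tree$height
  if (!length(h)) {
    warning("single-leaf tree: one cluster")
    cl <- stats::setNames(1L, tree$labels)
  } else {
    s <- if (length(h) > 1) stats::sd(h) else 0
    cutoff <- mean(h) + k_const * s
    cl <- if (cutoff < min(h)) {
      stats::setNames(seq_along(tree$labels), tree$labels)
    } else {
      stats::cutree(tree, h = cutoff)
    }
  }
  out <- data.frame(line = names(cl), cluster = as.integer(cl),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("lp_clusters", "data.frame"),
            cutoff = if (length(h)) cutoff else NA_real_,
            k = length(unique(cl)), k_const = k_const,
            fusion_levels = h)
}

#' @export
print.lp_clusters <- function(x, ...) {
  cat("Mojena cut: cutoff = ", format(attr(x, "cutoff")),
      " (k_const = ", attr(x, "k_const"), "), ",
      attr(x, "k"), " clusters over ", nrow(x), " lines\n", sep = "")
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Write a UPGMA tree as Newick
#'
#' Converts the tree to a phylogeny (branch lengths = half the merge
#' distance, the ultrametric convention) and writes Newick text.
#'
#' @param tree an `hclust`-like tree.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  class(tree) <- "hclust"
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Full diversity analysis for one condition
#'
#' Chains [normalize_blups()], [mean_euclidean()], [upgma()] and
#' [mojena_cut()] on a genotypic-value matrix.
#'
#' @param values per-line genotypic-value matrix.
#' @param k_const Mojena constant passed to [mojena_cut()].
#' @return list: `standardized`, `dist`, `tree`, `clusters`.
#' @export
diversity_analysis <- function(values, k_const = 1.25) {
  Z <- normalize_blups(values)
  d <- mean_euclidean(Z)
  tree <- upgma(d)
  list(standardized = Z, dist = d, tree = tree,
       clusters = mojena_cut(tree, k_const))
}
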