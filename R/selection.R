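#' Relative trait values under stress
#'
#' Elementwise ratio of stress to non-stress genotypic values,
#' `NAP / AP`, per line and trait.  Denominators within `eps` of zero
#' abort with the offending line and trait named, since the ratio is
#' then meaningless.
#'
#' @param blup_NAP,blup_AP per-line trait matrices with identical rows
#'   (lines) and columns (traits).
#' @param eps smallest tolerated absolute denominator (default 1e-8).
#' @return matrix of unitless ratios.
#' @export
relative_trait_values <- function(blup_NAP, blup_AP, eps = 1e-8) {
  A <- as.matrix(blup_NAP); B <- as.matrix(blup_AP)
  if (!identical(dim(A), dim(B)) ||
      !identical(rownames(A), rownames(B)) ||
      !identical(colnames(A), colnames(B)))
    stop("the two conditions must share lines and traits in the same order")
  bad <- which(abs(B) < eps, arr.ind = TRUE)
  if (nrow(bad))
    stop("applied-P value too close to zero for line '",
         rownames(B)[bad[1, 1]], "', trait '", colnames(B)[bad[1, 2]], "'")
  A / B
}

#' @rdname normalize_blups
#' @export
standardize <- normalize_blups

#' Principal components with Kaiser retention
#'
#' Eigen-decomposition of the correlation matrix of a standardized
#' per-line matrix.  Components with eigenvalue >= 1 (Kaiser criterion,
#' with a small numerical tolerance) are retained.  The contribution
#' rate of component i is `eigenvalue_i / T`, its share of the total
#' variance over all `T` traits.  Eigenvector signs are arbitrary; each
#' component is oriented so the sum of its loadings is positive (first
#' non-zero loading positive when the sum vanishes), so that lines that
#' are uniformly large on positively correlated traits score positively.
#'
#' @param standardized standardized matrix (see [normalize_blups()]);
#'   more lines than traits.
#' @return An object of class `lp_pca`: `eigenvalues`, `loadings`,
#'   `scores` (lines x components), `cr` (contribution rates),
#'   `retained` (logical).
#' @export
#' @examples
#' z <- normalize_blups(matrix(rnorm(60), 20, 3))
#' p <- pca_kaiser(z)
#' sum(p$eigenvalues)  # equals the number of traits
pca_kaiser <- function(standardized) {
  Z <- as.matrix(standardized)
  if (ncol(Z) < 2L) stop("need at least 2 traits")
  if (nrow(Z) <= ncol(Z)) stop("need more lines than traits")
  R <- stats::cor(Z)
  if (anyNA(R)) stop("degenerate correlation matrix (constant trait?)")
  e <- eigen(R, symmetric = TRUE)
  V <- e$vectors
  for (i in seq_len(ncol(V))) {
    s <- sum(V[, i])
    if (s < 0 || (s == 0 && V[which(V[, i] != 0)[1], i] < 0))
      V[, i] <- -V[, i]
  }
  scores <- Z %*% V
  comp <- paste0("PC", seq_len(ncol(V)))
  dimnames(V) <- list(colnames(Z), comp)
  colnames(scores) <- comp
  structure(list(eigenvalues = stats::setNames(e$values, comp),
                 loadings = V, scores = scores,
                 cr = stats::setNames(e$values / ncol(Z), comp),
                 retained = stats::setNames(e$values >= 1 - 1e-8, comp)),
            class = "lp_pca")
}

#' @export
print.lp_pca <- function(x, ...) {
  cat("PCA on the correlation matrix:", length(x$eigenvalues),
      "components,", sum(x$retained), "retained (eigenvalue >= 1)\n")
  print(data.frame(eigenvalue = round(x$eigenvalues, 4),
                   contribution_rate = round(x$cr, 4),
                   retained = x$retained))
  invisible(x)
}

index_from_pca <- function(pca) {
  keep <- which(pca$retained)
  drop(pca$scores[, keep, drop = FALSE] %*% pca$cr[keep])
}

#' Low-phosphorus tolerance index
#'
#' LPTI summarizes, per line, how well performance is maintained under
#' stress: relative trait values (stress/non-stress genotypic value
#' ratios) are standardized, projected onto the principal components of
#' their correlation matrix, and the scores of the retained components
#' (eigenvalue >= 1) are combined as `sum_i PC_i * CR_i`, weighting each
#' score by its contribution rate.  Higher LPTI = more tolerant.
#'
#' @inheritParams relative_trait_values
#' @return named per-line vector with attribute `"pca"` (the [pca_kaiser()]
#'   object).
#' @export
compute_lpti <- function(blup_NAP, blup_AP, eps = 1e-8) {
  rel <- relative_trait_values(blup_NAP, blup_AP, eps)
  pca <- pca_kaiser(standardize(rel))
  out <- index_from_pca(pca)
  attr(out, "pca") <- pca
  out
}

#' Low-phosphorus performance index
#'
#' LPPI ranks absolute performance under stress: the stress-condition
#' genotypic values themselves are standardized and combined with the
#' same contribution-rate-weighted PCA construction as [compute_lpti()].
#' Higher LPPI = better performance under stress.
#'
#' @param blup_NAP per-line trait matrix of stress-condition genotypic
#'   values.
#' @return named per-line vector with attribute `"pca"`.
#' @export
compute_lppi <- function(blup_NAP) {
  pca <- pca_kaiser(standardize(as.matrix(blup_NAP)))
  out <- index_from_pca(pca)
  attr(out, "pca") <- pca
  out
}

#' Four-group tolerance/performance classification
#'
#' Quadrants of the (LPTI, LPPI) plane with threshold 0 (both indices
#' are centered by construction): `TG` tolerant/good performance
#' (both > 0), `TP` tolerant/poor (LPTI > 0, LPPI <= 0), `SG`
#' sensitive/good (LPTI <= 0, LPPI > 0), `SP` sensitive/poor (both
#' <= 0).  Boundary values fall on the sensitive/poor side.
#'
#' @param lpti,lppi per-line index vectors over the same lines.
#' @return factor with levels `TG`, `SG`, `TP`, `SP`, named by line.
#' @export
#' @examples
#' classify_groups(c(a = 1, b = -1), c(a = 1, b = 1))
classify_groups <- function(lpti, lppi) {
  if (length(lpti) != length(lppi))
    stop("index vectors must cover the same lines")
  if (!is.null(names(lpti)) && !is.null(names(lppi))) {
    if (!setequal(names(lpti), names(lppi)))
      stop("index vectors must cover the same lines")
    lppi <- lppi[names(lpti)]
  }
  g <- ifelse(lpti > 0 & lppi > 0, "TG",
       ifelse(lpti > 0, "TP",
       ifelse(lppi > 0, "SG", "SP")))
  factor(stats::setNames(g, names(lpti)), levels = c("TG", "SG", "TP", "SP"))
}

#' Select top and bottom lines on both indices
#'
#' Ranks lines on LPTI and LPPI separately (rank 1 = highest index) and
#' combines the two rankings by their sum; the `top_k` lines with the
#' smallest rank sum and the `bottom_k` with the largest are flagged.
#' Ties in the rank sum are broken alphabetically by line label, so
#' selection is deterministic.  `criterion` switches to a single-index
#' ranking.
#'
#' @inheritParams classify_groups
#' @param top_k,bottom_k numbers of lines to flag (each <= n).
#' @param criterion `"rank_sum"` (default), `"lpti"` or `"lppi"`.
#' @return data frame: `line`, `lpti`, `lppi`, `rank_lpti`, `rank_lppi`,
#'   `selected_top`, `selected_bottom`, ordered by the combined criterion
#'   (best first).
#' @export
select_lines <- function(lpti, lppi, top_k = 20, bottom_k = 5,
                         criterion = c("rank_sum", "lpti", "lppi")) {
  criterion <- match.arg(criterion)
  if (is.null(names(lpti)))
    names(lpti) <- paste0("L", seq_along(lpti))
  if (!is.null(names(lppi))) lppi <- lppi[names(lpti)]
  n <- length(lpti)
  if (top_k > n || bottom_k > n)
    stop("cannot select more lines than the panel contains")
  r1 <- rank(-lpti, ties.method = "average")
  r2 <- rank(-lppi, ties.method = "average")
  score <- switch(criterion, rank_sum = r1 + r2, lpti = r1, lppi = r2)
  ord <- order(score, names(lpti))
  out <- data.frame(line = names(lpti)[ord],
                    lpti = as.numeric(lpti)[ord],
                    lppi = as.numeric(lppi)[ord],
                    rank_lpti = r1[ord], rank_lppi = r2[ord],
                    selected_top = FALSE, selected_bottom = FALSE,
                    stringsAsFactors = FALSE)
  if (top_k > 0) out$selected_top[seq_len(top_k)] <- TRUE
  if (bottom_k > 0)
    out$selected_bottom[seq(n - bottom_k + 1L, n)] <- TRUE
  rownames(out) <- NULL
  out
}

#' Full index table for a panel
#'
#' Computes LPTI, LPPI, the quadrant classification and the top/bottom
#' selection in one call.
#'
#' @inheritParams relative_trait_values
#' @inheritParams select_lines
#' @return data frame (class `lp_index`): columns of [select_lines()]
#'   plus `group`; attributes `pca_lpti`, `pca_lppi`.
#' @export
index_table <- function(blup_NAP, blup_AP, top_k = 20, bottom_k = 5,
                        criterion = "rank_sum", eps = 1e-8) {
  lpti <- compute_lpti(blup_NAP, blup_AP, eps)
  lppi <- compute_lppi(blup_NAP)
  grp <- classify_groups(lpti, lppi)
  sel <- select_lines(lpti, lppi, top_k, bottom_k, criterion)
  sel$group <- as.character(grp[sel$line])
  structure(sel, class = c("lp_index", "data.frame"),
            pca_lpti = attr(lpti, "pca"), pca_lppi = attr(lppi, "pca"))
}

#' @export
print.lp_index <- function(x, ...) {
  cat("Low-P selection indices for", nrow(x), "lines;",
      sum(x$selected_top), "top and", sum(x$selected_bottom),
      "bottom lines flagged\n")
  cat("group sizes:\n")
  print(table(factor(x$group, levels = c("TG", "SG", "TP", "SP"))))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more lines\n")
  invisible(x)
}
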