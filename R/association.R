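#' Pairwise correlation matrix of genotypic values
#'
#' Pearson (or Spearman) correlations between all trait pairs of a
#' per-line genotypic-value matrix, with two-sided test p-values from
#' [stats::cor.test()].  A constant trait yields `NA` coefficients for
#' its pairs and is named in a warning rather than aborting the matrix.
#'
#' @param values numeric matrix, lines in rows, traits in columns
#'   (>= 3 lines).
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha significance level for the `significant` flag matrix.
#' @return An object of class `lp_cormat`: list with `labels`,
#'   `estimates`, `p_values`, `significant`, `method`.
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 3, 2, 5, 4))
#' cor_blup_matrix(m)$estimates
cor_blup_matrix <- function(values, method = c("pearson", "spearman"),
                            alpha = 0.01) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (nrow(values) < 3L) stop("need at least 3 lines")
  t_names <- colnames(values)
  if (is.null(t_names)) t_names <- paste0("T", seq_len(ncol(values)))
  const <- apply(values, 2, function(x) stats::sd(x) == 0)
  if (any(const))
    warning("constant trait(s), correlations undefined: ",
            paste(t_names[const], collapse = ", "))
  k <- ncol(values)
  est <- diag(1, k); pv <- matrix(NA_real_, k, k)
  dimnames(est) <- dimnames(pv) <- list(t_names, t_names)
  diag(pv) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (const[i] || const[j]) { est[i, j] <- est[j, i] <- NA_real_; next }
    ct <- suppressWarnings(
      stats::cor.test(values[, i], values[, j], method = method))
    est[i, j] <- est[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  structure(list(labels = t_names, estimates = est, p_values = pv,
                 significant = pv < alpha, method = method, alpha = alpha),
            class = "lp_cormat")
}

#' @export
print.lp_cormat <- function(x, digits = 2, ...) {
  cat(x$method, "correlation matrix (", length(x$labels), "traits )\n")
  print(round(x$estimates, digits))
  invisible(x)
}

#' Rank correlation of the same trait across conditions
#'
#' Spearman correlation between the per-line genotypic values of one
#' trait under stress and non-stress conditions.  Low values diagnose
#' cross-over genotype-by-condition interaction: the best lines under
#' one condition are not the best under the other.  Ties receive average
#' ranks.
#'
#' @param values_NAP,values_AP named per-line vectors over the same line
#'   set (>= 3 lines).
#' @return list: `estimate`, `p_value`, `n`.
#' @export
#' @examples
#' spearman_cross_condition(c(a = 1, b = 2, c = 3, d = 4, e = 5),
#'                          c(a = 3, b = 1, c = 2, d = 5, e = 4))
spearman_cross_condition <- function(values_NAP, values_AP) {
  if (is.null(names(values_NAP)) || is.null(names(values_AP)))
    stop("vectors must be named by line")
  if (!setequal(names(values_NAP), names(values_AP)) ||
      length(values_NAP) != length(values_AP))
    stop("the two conditions cover different line sets")
  values_AP <- values_AP[names(values_NAP)]
  if (length(values_NAP) < 3L) stop("need at least 3 lines")
  ct <- suppressWarnings(
    stats::cor.test(values_NAP, values_AP, method = "spearman"))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(values_NAP))
}

#' Edge list of a correlation network
#'
#' Thresholds a correlation matrix into a weighted signed edge list, the
#' machine-readable counterpart of a trait-correlation network diagram.
#'
#' @param cormat an `lp_cormat`.
#' @param min_abs minimum absolute coefficient for an edge (default 0.2).
#' @return data frame: `trait_a`, `trait_b`, `r`, `sign`, `weight`.
#' @export
correlation_network <- function(cormat, min_abs = 0.2) {
  stopifnot(inherits(cormat, "lp_cormat"))
  est <- cormat$estimates
  k <- ncol(est)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- est[i, j]
    if (!is.na(r) && abs(r) >= min_abs)
      rows[[length(rows) + 1L]] <- data.frame(
        trait_a = cormat$labels[i], trait_b = cormat$labels[j],
        r = r, sign = ifelse(r >= 0, "positive", "negative"),
        weight = abs(r), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(trait_a = character(), trait_b = character(),
                      r = numeric(), sign = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
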