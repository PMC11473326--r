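#' Variance inflation factors of a trait matrix
#'
#' `VIF_j = 1 / (1 - R2_j)`, where `R2_j` is the coefficient of
#' determination of trait `j` regressed on all other traits; for a
#' non-singular correlation matrix this equals the diagonal of its
#' inverse.  Traits involved in an exact linear dependence get `Inf`.
#' A single-column input returns `VIF = 1` by convention.
#'
#' @param trait_matrix numeric matrix, lines in rows, traits in columns;
#'   more lines than traits, no constant trait.
#' @return named vector of VIFs (>= 1, `Inf` allowed).
#' @export
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' compute_vif(cbind(a = x[, 1], b = x[, 2], ab = x[, 1] + x[, 2]))
compute_vif <- function(trait_matrix) {
  X <- as.matrix(trait_matrix)
  t_names <- colnames(X)
  if (is.null(t_names)) t_names <- paste0("T", seq_len(ncol(X)))
  if (ncol(X) == 1L) return(stats::setNames(1, t_names))
  if (nrow(X) <= ncol(X))
    stop("need more lines than traits to compute VIFs")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait(s): ", paste(t_names[sds == 0], collapse = ", "))
  R <- stats::cor(X)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (!is.null(inv) && all(is.finite(diag(inv))) &&
      rcond_ok(R)) return(stats::setNames(diag(inv), t_names))
  # singular correlation structure: fall back to per-trait R^2 via QR
  vif <- vapply(seq_len(ncol(X)), function(j) {
    others <- cbind(1, X[, -j, drop = FALSE])
    res <- stats::lm.fit(others, X[, j])$residuals
    r2 <- 1 - sum(res^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(vif, t_names)
}

rcond_ok <- function(R, tol = 1e-12) {
  is.finite(rcond(R)) && rcond(R) > tol
}

#' Prune collinear traits jointly across two conditions
#'
#' Iteratively removes the trait with the largest VIF — the maximum over
#' the two condition-specific matrices — until every remaining trait has
#' VIF at or below the threshold under both conditions.  Using the joint
#' maximum guarantees that the same traits are discarded under both
#' conditions.  Ties are broken alphabetically by trait name, so the
#' procedure is deterministic.
#'
#' @param matrix_NAP,matrix_AP per-line trait matrices with identical
#'   column (trait) sets.
#' @param threshold VIF above which a trait is considered harmfully
#'   collinear (default 10; must be >= 1).
#' @return An object of class `vif_report`: data frame with columns
#'   `trait`, `vif_NAP`, `vif_AP` (values at removal, or final values for
#'   kept traits), `removed_at_step` (`NA` for kept traits), `kept`;
#'   attributes `threshold`, `kept`, `discarded`.
#' @export
prune_traits <- function(matrix_NAP, matrix_AP, threshold = 10) {
  if (threshold < 1) stop("VIF threshold must be >= 1")
  A <- as.matrix(matrix_NAP); B <- as.matrix(matrix_AP)
  if (!setequal(colnames(A), colnames(B)))
    stop("the two conditions must carry the same trait set")
  B <- B[, colnames(A), drop = FALSE]

  traits <- colnames(A)
  rec <- data.frame(trait = traits, vif_NAP = NA_real_, vif_AP = NA_real_,
                    removed_at_step = NA_integer_, kept = TRUE,
                    stringsAsFactors = FALSE)
  keep <- traits
  step <- 0L
  repeat {
    v1 <- compute_vif(A[, keep, drop = FALSE])
    v2 <- compute_vif(B[, keep, drop = FALSE])
    joint <- pmax(v1, v2)
    if (all(joint <= threshold)) {
      rec$vif_NAP[match(keep, rec$trait)] <- v1
      rec$vif_AP[match(keep, rec$trait)] <- v2
      break
    }
    worst <- keep[joint == max(joint)]
    worst <- sort(worst)[1L]  # alphabetical tie-break
    step <- step + 1L
    i <- match(worst, rec$trait)
    rec$vif_NAP[i] <- v1[[worst]]
    rec$vif_AP[i] <- v2[[worst]]
    rec$removed_at_step[i] <- step
    rec$kept[i] <- FALSE
    keep <- setdiff(keep, worst)
    if (length(keep) == 1L) {
      rec$vif_NAP[match(keep, rec$trait)] <- 1
      rec$vif_AP[match(keep, rec$trait)] <- 1
      break
    }
  }
  structure(rec, class = c("vif_report", "data.frame"),
            threshold = threshold, kept = keep,
            discarded = setdiff(traits, keep))
}

#' @export
print.vif_report <- function(x, ...) {
  cat("VIF pruning (threshold ", attr(x, "threshold"), "): kept ",
      length(attr(x, "kept")), " of ", nrow(x), " traits\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
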