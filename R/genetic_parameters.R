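#' Broad-sense heritability on an entry-mean basis
#'
#' For a single-condition randomized-block trial with `r` replicates,
#' `h2 = var_G / (var_G + var_error / r)`.  The value is clamped to
#' `[0, 1]` (the unclamped value is kept in attribute `"raw"`), since
#' boundary-truncated variance estimates can otherwise produce degenerate
#' ratios.
#'
#' @param var_G genotypic variance (>= 0).
#' @param var_error residual variance (>= 0).
#' @param r number of replications (>= 1).
#' @return heritability in `[0, 1]`.
#' @export
#' @examples
#' heritability_entry_mean(0.31, 0.33, r = 3)   # 0.74 to two decimals
heritability_entry_mean <- function(var_G, var_error, r) {
  stopifnot(r >= 1, var_G >= 0, var_error >= 0)
  if (var_G == 0 && var_error == 0)
    stop("heritability undefined: both variance components are zero")
  h2 <- var_G / (var_G + var_error / r)
  clamp01(h2)
}

#' Broad-sense heritability across conditions (combined analysis)
#'
#' With `r` replicates and `p` conditions,
#' `h2 = var_G / (var_G + var_GxP / p + var_error / (r * p))`.
#' Larger genotype-by-condition interaction lowers the across-condition
#' heritability, reflecting cross-over rank changes.
#'
#' @inheritParams heritability_entry_mean
#' @param var_GxP genotype-by-condition interaction variance (>= 0).
#' @param p number of conditions (>= 2).
#' @return heritability in `[0, 1]`.
#' @export
#' @examples
#' heritability_combined(1.47e-3, 6.95e-4, 2.25e-3, r = 3, p = 2)  # 0.67
heritability_combined <- function(var_G, var_GxP, var_error, r, p) {
  stopifnot(r >= 1, p >= 2, var_G >= 0, var_GxP >= 0, var_error >= 0)
  if (var_G == 0 && var_GxP == 0 && var_error == 0)
    stop("heritability undefined: all variance components are zero")
  h2 <- var_G / (var_G + var_GxP / p + var_error / (r * p))
  clamp01(h2)
}

clamp01 <- function(x) {
  out <- min(max(x, 0), 1)
  attr(out, "raw") <- x
  out
}

#' Percentage reduction of the mean under phosphorus stress
#'
#' `100 * (AP - NAP) / AP`: the relative loss of the non-stress mean under
#' stress.  Negative values flag traits that increase under stress
#' (e.g. root:shoot ratio).
#'
#' @param mean_AP genotypic mean under applied P (non-zero).
#' @param mean_NAP genotypic mean under non-applied P.
#' @return signed percentage.
#' @export
#' @examples
#' percent_reduction(1701.13, 665.49)  # 60.88
percent_reduction <- function(mean_AP, mean_NAP) {
  if (mean_AP == 0) stop("mean under applied P must be non-zero")
  100 * (mean_AP - mean_NAP) / mean_AP
}

#' Residual coefficient of variation
#'
#' `100 * sqrt(var_error) / mean`: the residual standard deviation as a
#' percentage of the genotypic mean, the usual experimental-precision
#' summary for replicated trials.
#'
#' @param var_error residual variance (>= 0).
#' @param mean genotypic mean (> 0).
#' @return percentage.
#' @export
#' @examples
#' cv_percent(52250, 1048.99)  # 21.79
cv_percent <- function(var_error, mean) {
  stopifnot(var_error >= 0)
  if (mean <= 0) stop("mean must be positive for a CV")
  100 * sqrt(var_error) / mean
}

#' Summarize genotypic values of a fit
#'
#' Minimum, mean and maximum of the per-line genotypic values, together
#' with the residual CV and the entry-mean (or combined) heritability
#' computed from the fit's variance components.
#'
#' @param fit an `lp_fit` with at least one genotypic value.
#' @return A one-row data frame: `trait`, `scope`, `min`, `mean`, `max`,
#'   `cv_pct`, `h2`.
#' @export
summarize_genotypic_values <- function(fit) {
  stopifnot(inherits(fit, "lp_fit"))
  gv <- fit$genotypic_values
  if (is.null(gv) || !length(gv)) stop("fit carries no genotypic values")
  vc <- fit$varcomp
  h2 <- if (fit$scope == "combined")
    heritability_combined(vc[["var_G"]], vc[["var_GxP"]],
                          vc[["var_error"]], fit$r, fit$p)
  else heritability_entry_mean(vc[["var_G"]], vc[["var_error"]], fit$r)
  m <- mean(gv)
  data.frame(trait = fit$trait, scope = fit$scope,
             min = min(gv), mean = m, max = max(gv),
             cv_pct = if (m > 0) cv_percent(vc[["var_error"]], m) else NA_real_,
             h2 = as.numeric(h2), stringsAsFactors = FALSE)
}

#' Per-trait summary table across conditions
#'
#' Runs [fit_condition_model()] under both conditions and
#' [fit_combined_model()] for every requested trait, and assembles the
#' trial-level report: per-condition ranges, means, CVs and
#' heritabilities of the genotypic values, the percentage reduction of
#' the mean under stress, and the combined-analysis variance components
#' with their likelihood-ratio significance.
#'
#' @param table long-format phenotype table with two conditions.
#' @param traits traits to summarize; default all in the table.
#' @param stress label of the stress condition (default `"NAP"`).
#' @param alpha significance level for the random-effect LRTs.
#' @return list with elements `summary` (one row per trait x condition),
#'   `components` (per trait: per-condition and combined variance
#'   components, heritabilities and LRT p-values) and `fits` (nested list
#'   of `lp_fit` objects).
#' @export
trial_summary <- function(table, traits = NULL, stress = "NAP",
                          alpha = 0.01) {
  check_phenotypes(table)
  conds <- unique(table$condition)
  if (length(conds) != 2L) stop("exactly two conditions are required")
  if (!stress %in% conds) stop("stress condition '", stress,
                               "' not found in table")
  nonstress <- setdiff(conds, stress)
  if (is.null(traits)) traits <- unique(table$trait)

  fits <- list(); srows <- list(); crows <- list()
  for (tr in traits) {
    f_s <- fit_condition_model(table, tr, stress)
    f_n <- fit_condition_model(table, tr, nonstress)
    f_c <- fit_combined_model(table, tr)
    fits[[tr]] <- list(stress = f_s, nonstress = f_n, combined = f_c)

    red_s <- fit_condition_model(table, tr, stress, random_line = FALSE)
    red_n <- fit_condition_model(table, tr, nonstress, random_line = FALSE)
    red_c <- fit_combined_model(table, tr, random_gxp = FALSE)
    lrt_s <- lrt_random_effect(f_s, red_s, alpha)
    lrt_n <- lrt_random_effect(f_n, red_n, alpha)
    lrt_c <- lrt_random_effect(f_c, red_c, alpha)

    s1 <- summarize_genotypic_values(f_s)
    s2 <- summarize_genotypic_values(f_n)
    red <- percent_reduction(s2$mean, s1$mean)
    s1$condition <- stress; s2$condition <- nonstress
    s1$reduction_pct <- red; s2$reduction_pct <- NA_real_
    srows[[tr]] <- rbind(s1, s2)

    crows[[tr]] <- data.frame(
      trait = tr,
      varG_stress = f_s$varcomp[["var_G"]],
      varE_stress = f_s$varcomp[["var_error"]],
      h2_stress = as.numeric(heritability_entry_mean(
        f_s$varcomp[["var_G"]], f_s$varcomp[["var_error"]], f_s$r)),
      p_line_stress = lrt_s$p_value,
      varG_nonstress = f_n$varcomp[["var_G"]],
      varE_nonstress = f_n$varcomp[["var_error"]],
      h2_nonstress = as.numeric(heritability_entry_mean(
        f_n$varcomp[["var_G"]], f_n$varcomp[["var_error"]], f_n$r)),
      p_line_nonstress = lrt_n$p_value,
      varG_comb = f_c$varcomp[["var_G"]],
      varGxP_comb = f_c$varcomp[["var_GxP"]],
      varE_comb = f_c$varcomp[["var_error"]],
      h2_comb = as.numeric(heritability_combined(
        f_c$varcomp[["var_G"]], f_c$varcomp[["var_GxP"]],
        f_c$varcomp[["var_error"]], f_c$r, f_c$p)),
      p_gxp = lrt_c$p_value,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, srows)
  rownames(summary) <- NULL
  summary <- summary[, c("trait", "condition", "min", "mean", "max",
                         "cv_pct", "h2", "reduction_pct")]
  components <- do.call(rbind, crows)
  rownames(components) <- NULL
  list(summary = summary, components = components, fits = fits)
}

#' Genotypic-value matrix for one condition
#'
#' Convenience extractor: lines in rows, traits in columns, entries the
#' genotypic values (grand mean + BLUP) from per-condition fits.
#'
#' @param fits the `fits` element of [trial_summary()], or a list of
#'   per-trait lists with elements `stress`/`nonstress`.
#' @param which `"stress"` or `"nonstress"`.
#' @return numeric matrix.
#' @export
blup_matrix <- function(fits, which = c("stress", "nonstress")) {
  which <- match.arg(which)
  cols <- lapply(fits, function(f) f[[which]]$genotypic_values)
  lines <- names(cols[[1]])
  stopifnot(all(vapply(cols, function(x) identical(names(x), lines),
                       logical(1))))
  m <- do.call(cbind, cols)
  colnames(m) <- names(fits)
  m
}
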