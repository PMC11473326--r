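#' Fit the per-condition mixed model for one trait
#'
#' Fits `value ~ block + (1 | line)` by REML to the records of one trait
#' under one phosphorus condition.  Lines are random, blocks fixed.
#' Variance components are the REML estimates of the line variance
#' (`var_G`) and residual variance (`var_error`); genotypic values are
#' the estimated population mean plus the line BLUPs, i.e. shrunken line
#' means on the observable trait scale.
#'
#' Setting `random_line = FALSE` fits the fixed-effects-only null model
#' (via [stats::lm()]) with its restricted log-likelihood on the same
#' scale as the mixed fit, which is the reduced model for
#' [lrt_random_effect()].
#'
#' @param table long-format phenotype table.
#' @param trait trait label present in the table.
#' @param condition condition label present in the table.
#' @param random_line keep the random line term (default `TRUE`).
#' @return An object of class `lp_fit`; see [lp_fit-methods].
#' @seealso [fit_combined_model()], [lrt_random_effect()]
#' @export
#' @examples
#' tab <- simulate_phenotypes(sim_config(n_lines = 12, seed = 3,
#'                                       traits = "RDW"))
#' fit <- fit_condition_model(tab, "RDW", "NAP")
#' fit$varcomp
fit_condition_model <- function(table, trait, condition,
                                random_line = TRUE) {
  check_phenotypes(table)
  d <- table[table$trait == trait & table$condition == condition &
               !is.na(table$value), ]
  if (!nrow(d)) stop("no data for trait '", trait, "' under '",
                     condition, "'")
  d$line <- factor(d$line)
  d$block <- factor(d$block)
  if (nlevels(d$line) < 2L) stop("need at least 2 lines")
  if (nlevels(d$block) < 2L) stop("need at least 2 blocks")

  if (!random_line) {
    lmfit <- stats::lm(value ~ block, data = d)
    return(new_lp_fit(trait, condition,
                      varcomp = c(var_error = summary(lmfit)$sigma^2),
                      fixef = stats::coef(lmfit),
                      loglik = as.numeric(stats::logLik(lmfit, REML = TRUE)),
                      genotypic_values = NULL,
                      grand_mean = mean(stats::fitted(lmfit)),
                      n_lines = nlevels(d$line), r = nlevels(d$block),
                      p = 1L, converged = TRUE))
  }

  fit <- lme4::lmer(value ~ block + (1 | line), data = d, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE,
                      optCtrl = list(xtol_abs = 1e-12,
                                     ftol_abs = 1e-12)))
  vc <- lme4::VarCorr(fit)
  varG <- as.numeric(vc$line)
  varE <- attr(vc, "sc")^2
  mu <- mean(stats::predict(fit, re.form = NA))
  blup <- lme4::ranef(fit)$line
  gv <- stats::setNames(mu + blup[, 1], rownames(blup))

  new_lp_fit(trait, condition,
             varcomp = c(var_G = varG, var_error = varE),
             fixef = lme4::fixef(fit),
             loglik = as.numeric(stats::logLik(fit)),
             genotypic_values = gv, grand_mean = mu,
             n_lines = nlevels(d$line), r = nlevels(d$block), p = 1L,
             converged = length(fit@optinfo$conv$lme4$messages) == 0L)
}

#' Fit the combined (across-conditions) mixed model for one trait
#'
#' Fits `value ~ condition + condition:block + (1 | line) +
#' (1 | line:condition)` by REML, with condition and block-within-condition
#' fixed and the line and line-by-condition effects random.  A single
#' residual variance is assumed across conditions.  Genotypic values are
#' the grand mean plus the main line BLUP; per-condition predictions
#' (grand mean of the condition plus line plus interaction BLUPs) are
#' available via `fit$cond_values`.
#'
#' @inheritParams fit_condition_model
#' @param random_gxp keep the random line-by-condition term (default
#'   `TRUE`); `FALSE` yields the reduced model for [lrt_random_effect()].
#' @return An object of class `lp_fit` with components `var_G`,
#'   `var_GxP` and `var_error`.
#' @export
#' @examples
#' tab <- simulate_phenotypes(sim_config(n_lines = 12, seed = 3,
#'                                       traits = "RDW"))
#' fit <- fit_combined_model(tab, "RDW")
#' fit$varcomp
fit_combined_model <- function(table, trait, random_gxp = TRUE) {
  check_phenotypes(table)
  d <- table[table$trait == trait & !is.na(table$value), ]
  if (!nrow(d)) stop("no data for trait '", trait, "'")
  d$line <- factor(d$line)
  d$condition <- factor(d$condition)
  d$block <- factor(d$block)
  if (nlevels(d$condition) < 2L)
    stop("only one condition present; use fit_condition_model()")
  if (nlevels(d$line) < 2L) stop("need at least 2 lines")
  if (nlevels(d$block) < 2L) stop("need at least 2 blocks")

  form <- if (random_gxp)
    value ~ condition + condition:block + (1 | line) + (1 | line:condition)
  else
    value ~ condition + condition:block + (1 | line)
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE,
                      optCtrl = list(xtol_abs = 1e-12,
                                     ftol_abs = 1e-12)))
  vc <- lme4::VarCorr(fit)
  varG <- as.numeric(vc$line)
  varGxP <- if (random_gxp) as.numeric(vc$`line:condition`) else NULL
  varE <- attr(vc, "sc")^2
  mu <- mean(stats::predict(fit, re.form = NA))
  blup <- lme4::ranef(fit)$line
  gv <- stats::setNames(mu + blup[, 1], rownames(blup))

  cond_values <- NULL
  if (random_gxp) {
    mu_c <- tapply(stats::predict(fit, re.form = NA), d$condition, mean)
    gxp <- lme4::ranef(fit)$`line:condition`
    key <- do.call(rbind, strsplit(rownames(gxp), ":", fixed = TRUE))
    cond_values <- matrix(gv - mu, nrow = length(gv),
                          ncol = nlevels(d$condition)) +
      matrix(mu_c, nrow = length(gv), ncol = nlevels(d$condition),
             byrow = TRUE)
    dimnames(cond_values) <- list(names(gv), levels(d$condition))
    cond_values[cbind(key[, 1], key[, 2])] <-
      cond_values[cbind(key[, 1], key[, 2])] + gxp[, 1]
  }

  vcv <- if (random_gxp)
    c(var_G = varG, var_GxP = varGxP, var_error = varE)
  else c(var_G = varG, var_error = varE)
  out <- new_lp_fit(trait, "combined", varcomp = vcv,
                    fixef = lme4::fixef(fit),
                    loglik = as.numeric(stats::logLik(fit)),
                    genotypic_values = gv, grand_mean = mu,
                    n_lines = nlevels(d$line), r = nlevels(d$block),
                    p = nlevels(d$condition),
                    converged = length(fit@optinfo$conv$lme4$messages) == 0L)
  out$cond_values <- cond_values
  out
}

new_lp_fit <- function(trait, scope, varcomp, fixef, loglik,
                       genotypic_values, grand_mean, n_lines, r, p,
                       converged) {
  structure(list(trait = trait, scope = scope, varcomp = varcomp,
                 fixef = fixef, loglik = loglik,
                 genotypic_values = genotypic_values,
                 grand_mean = grand_mean, n_lines = n_lines,
                 r = r, p = p, converged = converged),
            class = "lp_fit")
}

#' Methods for mixed-model fits
#'
#' `print` shows the variance components and heritability context;
#' `coef` returns the genotypic values (grand mean + BLUP).
#'
#' @param x,object an `lp_fit`.
#' @param ... ignored.
#' @name lp_fit-methods
NULL

#' @rdname lp_fit-methods
#' @export
print.lp_fit <- function(x, ...) {
  cat("Mixed-model REML fit:", x$trait, "[", x$scope, "]\n")
  cat("  lines:", x$n_lines, " blocks:", x$r,
      if (x$p > 1) paste(" conditions:", x$p), "\n")
  cat("  variance components:\n")
  print(round(x$varcomp, 6))
  cat("  REML log-likelihood:", format(x$loglik), "\n")
  if (!x$converged) cat("  (convergence warning reported by optimizer)\n")
  invisible(x)
}

#' @rdname lp_fit-methods
#' @export
coef.lp_fit <- function(object, ...) object$genotypic_values

#' Likelihood-ratio test for a random effect
#'
#' Compares two REML fits of the same trait and data in which the reduced
#' model drops exactly one random term, using the deviance
#' `2 * (logLik_full - logLik_reduced)` referred to a chi-square with one
#' degree of freedom.  Because the null value of a variance component lies
#' on the boundary of its parameter space, the plain chi-square reference
#' is conservative; the 50:50 mixture p-value (`p_value_mixture`, half the
#' plain one for positive deviances) is reported alongside.
#'
#' @param full the fit containing the tested random term.
#' @param reduced the same fit without it (`random_line = FALSE` or
#'   `random_gxp = FALSE`).
#' @param alpha significance level for the flag (default 0.01).
#' @return A list of class `lp_lrt`: `term`, `deviance`, `df`, `p_value`,
#'   `p_value_mixture`, `significant`.
#' @export
#' @examples
#' tab <- simulate_phenotypes(sim_config(n_lines = 12, seed = 3,
#'                                       traits = "RDW"))
#' full <- fit_condition_model(tab, "RDW", "NAP")
#' red  <- fit_condition_model(tab, "RDW", "NAP", random_line = FALSE)
#' lrt_random_effect(full, red)
lrt_random_effect <- function(full, reduced, alpha = 0.01) {
  stopifnot(inherits(full, "lp_fit"), inherits(reduced, "lp_fit"))
  if (full$trait != reduced$trait || full$scope != reduced$scope)
    stop("fits are not nested: different trait or scope")
  extra <- setdiff(names(full$varcomp), names(reduced$varcomp))
  if (length(extra) != 1L ||
      length(setdiff(names(reduced$varcomp), names(full$varcomp))))
    stop("reduced model must drop exactly one random term of the full model")
  dev <- 2 * (full$loglik - reduced$loglik)
  dev <- max(dev, 0)  # guard tiny negative deviances from convergence noise
  p <- stats::pchisq(dev, df = 1, lower.tail = FALSE)
  if (dev == 0) p <- 1
  structure(list(term = extra, deviance = dev, df = 1L, p_value = p,
                 p_value_mixture = if (dev > 0) p / 2 else 1,
                 significant = p < alpha, alpha = alpha),
            class = "lp_lrt")
}

#' @export
print.lp_lrt <- function(x, ...) {
  cat("LRT for random term '", x$term, "': deviance = ",
      format(x$deviance), ", df = 1, p = ", format.pval(x$p_value),
      if (x$significant) " (significant at alpha = " else
        " (not significant at alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}
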