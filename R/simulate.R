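#' Specify a simulated trait
#'
#' Defines one trait for the phenotype generator.  The mean under the
#' non-stress (applied P) condition is given directly; the stress-condition
#' mean is derived from the percentage reduction, `mean_AP * (1 -
#' reduction_pct/100)`, so a negative reduction yields a trait that
#' increases under stress (as root:shoot ratio and root tissue density do).
#'
#' @param name trait label (unique within a configuration).
#' @param mean_AP genotypic mean under the non-stress condition (trait units).
#' @param reduction_pct percentage reduction of the mean under stress; may
#'   be negative.
#' @param var_G genetic variance shared across conditions (trait units^2).
#' @param var_GxP variance of condition-specific genetic deviations
#'   (genotype-by-P-condition interaction, trait units^2).
#' @param var_error residual (plot) variance (trait units^2).
#' @param var_block block variance; defaults to `0.25 * var_error`.
#' @return A `trait_spec` list.
#' @export
#' @examples
#' trait_spec("SDW", mean_AP = 1701, reduction_pct = 60.9,
#'            var_G = 31094, var_GxP = 120162, var_error = 53692)
trait_spec <- function(name, mean_AP, reduction_pct = 0,
                       var_G, var_GxP = 0, var_error,
                       var_block = 0.25 * var_error) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  vars <- c(var_G = var_G, var_GxP = var_GxP,
            var_error = var_error, var_block = var_block)
  if (any(!is.finite(vars)) || any(vars < 0)) {
    stop("variance components must be finite and non-negative for trait '",
         name, "'")
  }
  structure(list(name = name, mean_AP = mean_AP,
                 reduction_pct = reduction_pct,
                 var_G = var_G, var_GxP = var_GxP,
                 var_error = var_error, var_block = var_block),
            class = "trait_spec")
}

#' Mean under the stress condition implied by a trait specification
#' @param spec a [trait_spec()].
#' @return numeric mean under non-applied P.
#' @export
mean_NAP <- function(spec) {
  stopifnot(inherits(spec, "trait_spec"))
  spec$mean_AP * (1 - spec$reduction_pct / 100)
}

default_trait_specs <- function(traits = NULL) {
  p <- maize_trait_params()
  if (!is.null(traits)) {
    missing <- setdiff(traits, p$trait)
    if (length(missing))
      stop("unknown trait(s): ", paste(missing, collapse = ", "))
    p <- p[match(traits, p$trait), ]
  }
  lapply(seq_len(nrow(p)), function(i) {
    trait_spec(p$trait[i], mean_AP = p$mean_ap[i],
               reduction_pct = p$reduction_pct[i],
               var_G = p$varG_comb[i], var_GxP = p$varGxP_comb[i],
               var_error = p$varE_comb[i])
  })
}

#' Configure a simulated phenotyping trial
#'
#' Describes a randomized-block trial of inbred lines evaluated under two
#' phosphorus conditions.  The first condition label is the stress
#' condition (non-applied P), the second the non-stress condition (applied
#' P).  Trait defaults come from [maize_trait_params()], using the
#' combined-analysis variance components, so the default configuration
#' emulates the reference trial: 151 lines, 3 blocks, 13 traits.
#'
#' @param n_lines number of inbred lines (>= 2).
#' @param n_blocks number of blocks/replicates per condition (>= 2).
#' @param conditions length-2 character vector: stress label first,
#'   non-stress label second.
#' @param traits list of [trait_spec()] objects, or a character vector of
#'   trait names to draw from [maize_trait_params()]; `NULL` means all 13.
#' @param missing_rate proportion of observations set missing uniformly at
#'   random (default 0: the reference design is balanced).
#' @param seed integer seed governing all randomness of the generator.
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_lines = 20, seed = 1, traits = c("SD", "RDW"))
sim_config <- function(n_lines = 151, n_blocks = 3,
                       conditions = c("NAP", "AP"),
                       traits = NULL, missing_rate = 0, seed = 1) {
  stopifnot(n_lines >= 2, n_blocks >= 2)
  if (length(conditions) != 2L || anyDuplicated(conditions))
    stop("exactly two distinct condition labels are required")
  if (is.null(traits) || is.character(traits))
    traits <- default_trait_specs(traits)
  if (!all(vapply(traits, inherits, logical(1), "trait_spec")))
    stop("'traits' must be trait_spec objects or trait names")
  nm <- vapply(traits, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate trait names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  stopifnot(missing_rate >= 0, missing_rate < 1)
  structure(list(n_lines = as.integer(n_lines),
                 n_blocks = as.integer(n_blocks),
                 conditions = as.character(conditions),
                 traits = traits, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a long-format phenotype table
#'
#' Generates one record per line x condition x block x trait under the
#' model `value = mu_cond + block effect + g_i + gP_ic + e`, with the line
#' effect `g_i ~ N(0, var_G)` shared across conditions, independent
#' condition-specific deviations `gP_ic ~ N(0, var_GxP)`, block effects
#' `N(0, var_block)` nested in condition, and residuals `N(0, var_error)`.
#' This decomposition makes the combined-analysis variance components
#' identifiable and induces cross-over rank changes between conditions:
#' the correlation of total line effects across conditions is
#' `var_G / (var_G + var_GxP)`.
#'
#' Per-trait random streams are derived deterministically from the single
#' configuration seed, so the output is byte-identical across runs with
#' the same configuration.
#'
#' @param config a [sim_config()].
#' @return A data frame (`line`, `condition`, `block`, `trait`, `value`)
#'   with attribute `"truth"`, a list per trait holding the simulated line
#'   effects (`g`), condition deviations (`gP`) and condition means.
#' @export
#' @examples
#' tab <- simulate_phenotypes(sim_config(n_lines = 10, seed = 42,
#'                                       traits = "RDW"))
#' head(tab)
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_lines; r <- config$n_blocks
  conds <- config$conditions
  lines <- sprintf("L%03d", seq_len(n))
  blocks <- sprintf("B%d", seq_len(r))

  set.seed(config$seed)
  trait_seeds <- sample.int(.Machine$integer.max - 1L,
                            length(config$traits))

  design <- expand.grid(line = lines, block = blocks, condition = conds,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  truth <- list()
  pieces <- vector("list", length(config$traits))
  for (k in seq_along(config$traits)) {
    sp <- config$traits[[k]]
    set.seed(trait_seeds[k])
    mu <- c(mean_NAP(sp), sp$mean_AP)  # stress first, non-stress second
    names(mu) <- conds
    g <- stats::rnorm(n, 0, sqrt(sp$var_G))
    gP <- matrix(stats::rnorm(2 * n, 0, sqrt(sp$var_GxP)), nrow = n,
                 dimnames = list(lines, conds))
    b <- matrix(stats::rnorm(2 * r, 0, sqrt(sp$var_block)), nrow = r,
                dimnames = list(blocks, conds))
    e <- stats::rnorm(nrow(design), 0, sqrt(sp$var_error))

    ix_l <- match(design$line, lines)
    val <- mu[design$condition] + b[cbind(design$block, design$condition)] +
      g[ix_l] + gP[cbind(ix_l, match(design$condition, conds))] + e
    pieces[[k]] <- data.frame(design, trait = sp$name, value = unname(val),
                              stringsAsFactors = FALSE)
    truth[[sp$name]] <- list(mu = mu, g = stats::setNames(g, lines), gP = gP)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (config$missing_rate > 0) {
    set.seed(config$seed + 1L)
    drop <- stats::runif(nrow(out)) < config$missing_rate
    out$value[drop] <- NA_real_
  }
  out <- out[, c("line", "condition", "block", "trait", "value")]
  attr(out, "truth") <- truth
  out
}

#' Append derived traits at observation level
#'
#' Computes, for each line x condition x block cell that carries the
#' required component traits, the ratios and sums used in seedling
#' phenotyping: root:shoot ratio `RSR = RDW/SDW`, total dry weight
#' `TDW = RDW + SDW`, root tissue density `RTD = RDW/RV` and daily growth
#' `DG = PH/days`.  A zero (or missing) denominator yields a missing
#' value, never an infinity.  Derived traits already present in the table
#' are not recomputed.
#'
#' @param table long-format phenotype table with columns
#'   `line, condition, block, trait, value`.
#' @param days days from emergence to harvest used for `DG` (default 35).
#' @return the table with derived-trait records appended.
#' @export
compute_derived_traits <- function(table, days = 35) {
  check_phenotypes(table)
  wide <- stats::reshape(table, idvar = c("line", "condition", "block"),
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  have <- function(x) x %in% names(wide)
  ratio <- function(num, den) ifelse(is.na(den) | den == 0, NA_real_, num / den)

  new <- list()
  if (!have("RSR") && have("RDW") && have("SDW"))
    new$RSR <- ratio(wide$RDW, wide$SDW)
  if (!have("TDW") && have("RDW") && have("SDW"))
    new$TDW <- wide$RDW + wide$SDW
  if (!have("RTD") && have("RDW") && have("RV"))
    new$RTD <- ratio(wide$RDW, wide$RV)
  if (!have("DG") && have("PH"))
    new$DG <- wide$PH / days
  if (!length(new)) return(table)

  add <- do.call(rbind, lapply(names(new), function(tr) {
    data.frame(line = wide$line, condition = wide$condition,
               block = wide$block, trait = tr, value = new[[tr]],
               stringsAsFactors = FALSE)
  }))
  out <- rbind(table[, c("line", "condition", "block", "trait", "value")], add)
  rownames(out) <- NULL
  out
}

check_phenotypes <- function(table) {
  need <- c("line", "condition", "block", "trait", "value")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("phenotype table must have columns ",
         paste(need, collapse = ", "))
  invisible(table)
}
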