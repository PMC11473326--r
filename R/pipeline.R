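#' Read and validate a long-format phenotype CSV
#'
#' Expects columns `line, condition, block, trait, value` (UTF-8, header
#' row, "." decimal).  Duplicate `(line, condition, block, trait)` records
#' and tables with other than two conditions are rejected; missing values
#' (`NA` or empty) are tolerated and counted in attribute
#' `"n_missing"`.  Non-numeric values are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return validated phenotype data frame.
#' @export
ingest_phenotypes <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "condition", "block", "trait", "value")
  if (!all(need %in% names(raw)))
    stop("missing column(s): ", paste(setdiff(need, names(raw)),
                                      collapse = ", "))
  raw <- raw[, need]
  if (!nrow(raw)) stop("empty phenotype table: ", path)
  if (!is.numeric(raw$value)) {
    suppress <- suppressWarnings(as.numeric(raw$value))
    bad <- which(!is.na(raw$value) & raw$value != "" &
                   raw$value != "NA" & is.na(suppress))
    if (length(bad))
      stop("non-numeric value(s) at data row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    raw$value <- suppress
  }
  key <- do.call(paste, c(raw[c("line", "condition", "block", "trait")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicated (line, condition, block, trait) record(s) at data row(s): ",
         paste(utils::head(dup, 10), collapse = ", "))
  }
  conds <- unique(raw$condition)
  if (length(conds) != 2L)
    stop("expected exactly 2 conditions, found ", length(conds), ": ",
         paste(conds, collapse = ", "))
  attr(raw, "n_missing") <- sum(is.na(raw$value))
  raw
}

#' Run the full low-phosphorus screening analysis
#'
#' Orchestrates every stage on a phenotype table (read from `input` or
#' simulated from `config`): per-condition and combined REML fits with
#' random-effect likelihood-ratio tests, genotypic-value summaries
#' (ranges, CVs, heritabilities, stress reductions), within-condition
#' Pearson and cross-condition Spearman correlations, VIF pruning,
#' per-condition UPGMA diversity clustering with a Mojena cut, and the
#' LPTI/LPPI selection indices with four-group classification and
#' top/bottom selection.
#'
#' When `outdir` is given, the stage outputs are written as CSV
#' (`table1_summary.csv`, `table2_components.csv`,
#' `table3_correlations.csv`, `vif.csv`, `clusters.csv`, `indices.csv`,
#' `selection.csv`, plus the ingested/simulated `phenotypes.csv`), the
#' trees as Newick (`diversity_<condition>.nwk`), and a `run_log.txt`
#' echoing the settings and REML convergence per fit.  Given the same
#' seed and settings the run is fully deterministic.
#'
#' @param input path to a phenotype CSV, or a phenotype data frame;
#'   ignored when `config` is given.
#' @param config a [sim_config()] to simulate the input instead.
#' @param traits trait subset for the diversity and index stages after
#'   pruning: a character vector, or the name of a [trait_preset()]
#'   (`"paper8"`), or `NULL` to use the pruning result.
#' @param stress label of the stress condition (default `"NAP"`).
#' @param vif_threshold VIF pruning threshold (default 10).
#' @param mojena_k Mojena constant (default 1.25).
#' @param alpha significance level (default 0.01).
#' @param top_k,bottom_k selection sizes (defaults 20 and 5).
#' @param outdir output directory, created if needed; `NULL` writes
#'   nothing.
#' @return list of stage results (class `lp_pipeline`): `phenotypes`,
#'   `summary`, `components`, `fits`, `correlations` (per condition +
#'   `spearman`), `vif`, `diversity` (per condition), `indices`.
#' @export
#' @examples
#' res <- run_pipeline(config = sim_config(n_lines = 15, seed = 7,
#'                     traits = c("SD", "PH", "RDW", "RV")),
#'                     top_k = 3, bottom_k = 2)
#' res$indices
run_pipeline <- function(input = NULL, config = NULL, traits = NULL,
                         stress = "NAP", vif_threshold = 10,
                         mojena_k = 1.25, alpha = 0.01,
                         top_k = 20, bottom_k = 5, outdir = NULL) {
  log_lines <- character()
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    invisible(msg)
  }
  note("lowPmaize pipeline, package version ",
       as.character(utils::packageVersion("lowPmaize")))

  if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    tab <- simulate_phenotypes(config)
    attr(tab, "truth") <- NULL
    note("input: simulated (", config$n_lines, " lines, ",
         config$n_blocks, " blocks, ", length(config$traits),
         " traits, seed ", config$seed, ")")
  } else if (is.character(input)) {
    tab <- ingest_phenotypes(input)
    note("input: ", input, " (", attr(tab, "n_missing"),
         " missing values)")
  } else if (is.data.frame(input)) {
    tab <- check_phenotypes(input)
    note("input: in-memory table")
  } else stop("provide 'input' (path or data frame) or 'config'")

  conds <- unique(tab$condition)
  if (!stress %in% conds)
    stop("stress condition '", stress, "' not present")
  nonstress <- setdiff(conds, stress)
  note("conditions: stress = ", stress, ", non-stress = ", nonstress)

  # mixed models + genetic parameters
  ts <- trial_summary(tab, stress = stress, alpha = alpha)
  for (tr in names(ts$fits))
    for (sc in names(ts$fits[[tr]]))
      if (!ts$fits[[tr]][[sc]]$converged)
        note("REML convergence warning: ", tr, " [", sc, "]")
  note("fitted ", length(ts$fits), " traits")

  blup_s <- blup_matrix(ts$fits, "stress")
  blup_n <- blup_matrix(ts$fits, "nonstress")

  # correlation structure
  cors <- list()
  cors[[stress]] <- cor_blup_matrix(blup_s, alpha = alpha)
  cors[[nonstress]] <- cor_blup_matrix(blup_n, alpha = alpha)
  cors$spearman <- do.call(rbind, lapply(colnames(blup_s), function(tr) {
    sp <- spearman_cross_condition(blup_s[, tr], blup_n[, tr])
    data.frame(trait = tr, rho = sp$estimate, p_value = sp$p_value,
               stringsAsFactors = FALSE)
  }))

  # multicollinearity pruning, then optional preset override
  vif <- prune_traits(blup_s, blup_n, threshold = vif_threshold)
  kept <- attr(vif, "kept")
  note("VIF pruning kept ", length(kept), " traits: ",
       paste(kept, collapse = ", "))
  if (!is.null(traits)) {
    if (length(traits) == 1L && traits %in% c("paper8", "all13"))
      traits <- trait_preset(traits)
    kept <- intersect(traits, colnames(blup_s))
    note("trait set overridden to: ", paste(kept, collapse = ", "))
  }
  if (length(kept) < 2L) stop("fewer than 2 traits retained")

  # diversity per condition
  div <- list()
  div[[stress]] <- diversity_analysis(blup_s[, kept, drop = FALSE],
                                      k_const = mojena_k)
  div[[nonstress]] <- diversity_analysis(blup_n[, kept, drop = FALSE],
                                         k_const = mojena_k)
  for (cn in c(stress, nonstress))
    note("diversity [", cn, "]: ", attr(div[[cn]]$clusters, "k"),
         " clusters at cutoff ",
         format(attr(div[[cn]]$clusters, "cutoff")))

  # selection indices
  idx <- index_table(blup_s[, kept, drop = FALSE],
                     blup_n[, kept, drop = FALSE],
                     top_k = top_k, bottom_k = bottom_k)
  note("groups: ", paste(names(table(idx$group)),
                         table(idx$group), sep = "=", collapse = ", "))

  res <- structure(list(phenotypes = tab, summary = ts$summary,
                        components = ts$components, fits = ts$fits,
                        correlations = cors, vif = vif,
                        diversity = div, indices = idx,
                        settings = list(stress = stress,
                                        vif_threshold = vif_threshold,
                                        mojena_k = mojena_k, alpha = alpha,
                                        top_k = top_k, bottom_k = bottom_k,
                                        kept_traits = kept),
                        log = log_lines),
                   class = "lp_pipeline")
  if (!is.null(outdir)) write_pipeline(res, outdir)
  res
}

write_pipeline <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(outdir, f)
  wcsv <- function(x, f) utils::write.csv(x, out(f), row.names = FALSE)
  wcsv(res$phenotypes, "phenotypes.csv")
  wcsv(res$summary, "table1_summary.csv")
  wcsv(res$components, "table2_components.csv")

  # square correlation layout: stress below diagonal, non-stress above,
  # cross-condition Spearman on the diagonal
  stress <- res$settings$stress
  nonstress <- setdiff(names(res$correlations), c(stress, "spearman"))
  m <- res$correlations[[nonstress]]$estimates
  low <- res$correlations[[stress]]$estimates
  m[lower.tri(m)] <- low[lower.tri(low)]
  diag(m) <- res$correlations$spearman$rho[
    match(rownames(m), res$correlations$spearman$trait)]
  wcsv(data.frame(trait = rownames(m), round(m, 4),
                  check.names = FALSE), "table3_correlations.csv")

  wcsv(as.data.frame(res$vif), "vif.csv")
  cl <- lapply(names(res$diversity), function(cn) {
    x <- res$diversity[[cn]]$clusters
    data.frame(condition = cn, line = x$line, cluster = x$cluster,
               cutoff = attr(x, "cutoff"), k = attr(x, "k"),
               stringsAsFactors = FALSE)
  })
  wcsv(do.call(rbind, cl), "clusters.csv")
  for (cn in names(res$diversity))
    write_newick(res$diversity[[cn]]$tree,
                 out(paste0("diversity_", cn, ".nwk")))
  wcsv(as.data.frame(res$indices), "indices.csv")
  wcsv(res$indices[res$indices$selected_top | res$indices$selected_bottom,
                   c("line", "lpti", "lppi", "group",
                     "selected_top", "selected_bottom")],
       "selection.csv")
  writeLines(res$log, out("run_log.txt"))
  invisible(outdir)
}

#' @export
print.lp_pipeline <- function(x, ...) {
  cat("Low-P screening pipeline results\n")
  writeLines(paste(" ", x$log))
  invisible(x)
}
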