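#' End-to-end analysis pipeline
#'
#' Reads a case table, builds strata under the chosen scheme (always adding
#' an Overall stratum over all cases carrying the scheme's defining
#' variable), runs the four-model AIC tournament per stratum, and writes a
#' summaries table, per-stratum density curves, and a run manifest.
#'
#' @name pipeline
NULL

stratify_schemes <- c("er_category", "er_clinical_1", "er_clinical_10",
                      "esr1_quartile", "pam50", "grade", "size", "nodes",
                      "race")

# returns list(records = analysis subset, groups = named list of row-index
# vectors into that subset); the very-high ER group overlaps high
build_strata <- function(records, scheme) {
  grp <- function(f) {
    f <- droplevels(as.factor(f))
    lapply(stats::setNames(levels(f), levels(f)), function(l) which(f == l))
  }
  switch(scheme,
    er_category = {
      sub <- records[!is.na(records$er_percent), , drop = FALSE]
      ec <- assign_er_category(sub$er_percent)
      groups <- grp(ec$category)
      groups[["very_high_ge95"]] <- which(ec$very_high)
      list(records = sub, groups = groups)
    },
    er_clinical_1 = ,
    er_clinical_10 = {
      cut <- if (scheme == "er_clinical_1") 1 else 10
      sub <- records[!is.na(records$er_percent), , drop = FALSE]
      list(records = sub, groups = grp(assign_clinical_er(sub$er_percent, cut)))
    },
    esr1_quartile = {
      sub <- records[!is.na(records$esr1_raw), , drop = FALSE]
      q <- assign_quartiles(standardize_esr1(sub$esr1_raw))
      list(records = sub, groups = grp(q))
    },
    pam50 = {
      sub <- filter_pam50(records)
      list(records = sub, groups = grp(sub$pam50))
    },
    grade = ,
    size = ,
    nodes = {
      lab <- assign_tumor_characteristic_strata(records, scheme)
      sub <- records[!is.na(lab), , drop = FALSE]
      list(records = sub, groups = grp(lab[!is.na(lab)]))
    },
    race = {
      sub <- records[!is.na(records$race), , drop = FALSE]
      list(records = sub, groups = grp(sub$race))
    },
    stop("unknown stratification scheme: ", scheme, call. = FALSE)
  )
}

safe_label <- function(x) gsub("[^A-Za-z0-9_.-]+", "_", x)

#' Run the full analysis on a case table
#'
#' @param input path to a case-level CSV/TSV, or a `case_table` data.frame
#' @param stratify one of `er_category`, `er_clinical_1`, `er_clinical_10`,
#'   `esr1_quartile`, `pam50`, `grade`, `size`, `nodes`, `race`
#' @param degree SNP polynomial degree
#' @param config a [fit_config()]
#' @param out_dir output directory (created if needed); NULL skips writing
#' @param min_n smallest stratum analyzed (default 30); smaller strata are
#'   skipped with a warning
#' @param column_map forwarded to [read_cases()]
#' @param curves write per-stratum KDE curves?
#' @return (invisibly) list with `summaries` (data.frame), `comparisons`
#'   (named list of `model_comparison`), `manifest`
#' @export
run_analysis <- function(input, stratify = "er_category", degree = 2L,
                         config = fit_config(), out_dir = NULL, min_n = 30L,
                         column_map = NULL, curves = TRUE) {
  stratify <- match.arg(stratify, stratify_schemes)
  input_path <- NULL
  if (is.character(input)) {
    input_path <- input
    records <- read_cases(input, column_map = column_map)
  } else {
    records <- input
  }
  st <- build_strata(records, stratify)
  groups <- c(list(Overall = seq_len(nrow(st$records))), st$groups)
  summaries <- list(); comparisons <- list(); stratum_warnings <- list()
  for (label in names(groups)) {
    ages <- st$records$age[groups[[label]]]
    ages <- ages[is.finite(ages)]
    if (length(ages) < min_n) {
      warning(sprintf("stratum '%s' skipped: n = %d < min_n = %d",
                      label, length(ages), min_n), call. = FALSE)
      next
    }
    warns <- character(0)
    cmp <- withCallingHandlers(
      run_tournament(ages, degree = degree, config = config),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    smry <- withCallingHandlers(
      summarize_stratum(label, ages, cmp),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    message(sprintf("stratum %-18s n=%5d  delta_AIC=%9.2f  verdict=%s%s",
                    label, smry$n, smry$delta_aic, smry$verdict,
                    if (length(warns)) "  [warnings]" else ""))
    summaries[[label]] <- smry
    comparisons[[label]] <- cmp
    stratum_warnings[[label]] <- warns
  }
  if (length(summaries) == 0L)
    stop("no stratum met min_n = ", min_n, call. = FALSE)
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("agemix")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stratify = stratify, degree = degree, min_n = min_n,
    config = config[c("n_random_starts", "tol", "max_iter", "sigma_floor",
                      "truncation", "seed", "snp_starts")],
    input = if (is.null(input_path)) "<in-memory>" else input_path,
    input_md5 = if (is.null(input_path)) NA_character_ else
      unname(tools::md5sum(input_path)),
    n_input = nrow(records), n_analyzed = nrow(st$records),
    stratum_warnings = stratum_warnings
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_summaries(summaries, file.path(out_dir, "summaries.csv"))
    write_summaries(summaries, file.path(out_dir, "summaries.json"))
    if (curves) {
      for (label in names(comparisons)) {
        ages <- st$records$age[groups[[label]]]
        data.table::fwrite(density_curve(ages),
                           file.path(out_dir, paste0("curve_", safe_label(label), ".csv")))
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)
  }
  invisible(list(summaries = summaries, comparisons = comparisons,
                 manifest = manifest))
}
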