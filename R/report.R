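# Cohort-level report assembly: density and outcome tables, gated group
# comparisons, variability tests and per-group correlations.

#' Build the cohort report
#'
#' Assembles the standard summary of a specimen cohort: descriptive
#' statistics per group, a density table (mean +/- SD per group with
#' pairwise adjusted p values), gated omnibus/post hoc comparisons and
#' variability tests for each outcome variable (overall and stratified by
#' correction degree when available), and per-group Pearson correlations
#' between density and micromotion. With a single group, comparisons are
#' suppressed and only descriptives are reported. The report is a pure
#' function of the input table, so identical cohorts give identical
#' reports.
#'
#' @param records data.frame with one row per specimen. Recognized columns:
#'   a grouping column (`group_col`, default `group3`), optionally
#'   `correction_deg`, density variables (any of `subchondral_bmd`,
#'   `vault_bmd`, `global_bmd`, `subchondral_bvtv`, `vault_bvtv`,
#'   `global_bvtv`, `density_subchondral`) and outcome variables (any of
#'   `micromotion_pre/post/delta`, `rotation_pre/post/delta`,
#'   `micromotion_um`, `rotation_deg`).
#' @param group_col Name of the grouping column.
#' @param density_vars,outcome_vars Override automatic column detection.
#' @param correlation_outcome Outcome used in the correlation table
#'   (default: `micromotion_post` if present, else `micromotion_um`).
#' @param alpha Significance level (p <= alpha), default 0.05.
#' @param seg_threshold Optional segmentation threshold (mgHA/cm^3) to
#'   record in the footnotes.
#' @return A list of class `stability_report`: `descriptives`,
#'   `density_table`, `comparisons`, `by_correction`, `correlations`,
#'   `footnotes`.
#' @export
build_report <- function(records, group_col = "group3",
                         density_vars = NULL, outcome_vars = NULL,
                         correlation_outcome = NULL, alpha = 0.05,
                         seg_threshold = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data.frame", call. = FALSE)
  if (!group_col %in% names(records))
    stop(sprintf("no grouping column '%s'", group_col), call. = FALSE)
  groups <- as.character(records[[group_col]])

  density_vars <- density_vars %||%
    intersect(c("subchondral_bmd", "vault_bmd", "global_bmd",
                "subchondral_bvtv", "vault_bvtv", "global_bvtv",
                "density_subchondral"), names(records))
  outcome_vars <- outcome_vars %||%
    intersect(c("micromotion_pre", "micromotion_post", "micromotion_delta",
                "rotation_pre", "rotation_post", "rotation_delta",
                "micromotion_um", "rotation_deg"), names(records))
  all_vars <- c(density_vars, outcome_vars)
  if (!length(all_vars))
    stop("no recognized density or outcome columns", call. = FALSE)

  descriptives <- do.call(rbind, lapply(all_vars, function(v) {
    agg <- vapply(split(records[[v]], groups), function(x)
      c(mean(x), stats::sd(x), length(x)), numeric(3L))
    data.frame(variable = v, group = colnames(agg), mean = agg[1L, ],
               sd = agg[2L, ], n = as.integer(agg[3L, ]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  comparable <- length(unique(groups)) >= 2L && all(table(groups) >= 2L)

  density_table <- NULL
  if (length(density_vars)) {
    density_table <- do.call(rbind, lapply(density_vars, function(v) {
      row <- data.frame(variable = v, stringsAsFactors = FALSE)
      for (g in unique(groups)) {
        x <- records[[v]][groups == g]
        row[[g]] <- sprintf("%.3g ± %.2g", mean(x), stats::sd(x))
      }
      if (comparable) {
        cmp <- gate_and_compare(records[[v]], groups, alpha = alpha)
        for (i in seq_len(nrow(cmp$pairwise)))
          row[[sprintf("p %s vs %s", cmp$pairwise$group1[i],
                       cmp$pairwise$group2[i])]] <-
            round(cmp$pairwise$p_adj[i], 3)
      }
      row
    }))
  }

  comparisons <- by_correction <- NULL
  if (comparable && length(outcome_vars)) {
    comparisons <- lapply(stats::setNames(outcome_vars, outcome_vars),
                          function(v) {
      list(location = gate_and_compare(records[[v]], groups, alpha = alpha),
           variability = compare_variability(records[[v]], groups,
                                             alpha = alpha))
    })
    if ("correction_deg" %in% names(records)) {
      degs <- setdiff(sort(unique(records$correction_deg)), 0)
      by_correction <- lapply(stats::setNames(degs, paste0(degs, "deg")),
                              function(deg) {
        keep <- records$correction_deg %in% c(0, deg)
        sub <- records[keep, , drop = FALSE]
        gsub_ <- groups[keep]
        if (length(unique(gsub_)) < 2L || any(table(gsub_) < 2L))
          return(NULL)
        lapply(stats::setNames(outcome_vars, outcome_vars), function(v)
          list(location = gate_and_compare(sub[[v]], gsub_, alpha = alpha),
               variability = compare_variability(sub[[v]], gsub_,
                                                 alpha = alpha)))
      })
    }
  }

  correlations <- NULL
  corr_out <- correlation_outcome %||%
    if ("micromotion_post" %in% names(records)) "micromotion_post"
    else if ("micromotion_um" %in% names(records)) "micromotion_um"
    else NULL
  if (!is.null(corr_out) && length(density_vars) &&
      all(table(groups) >= 3L)) {
    correlations <- do.call(rbind, lapply(density_vars, function(dv) {
      ct <- tryCatch(correlate(records[[dv]], records[[corr_out]], groups),
                     error = function(e) NULL)
      if (is.null(ct)) return(NULL)
      cbind(density_variable = dv, outcome_variable = corr_out, ct)
    }))
  }

  footnotes <- c(
    sprintf("Significance level: p <= %.2f.", alpha),
    if (!is.null(seg_threshold))
      sprintf("Global bone segmentation threshold: %g mgHA/cm^3.",
              seg_threshold),
    "Variability compared with Brown-Forsythe (median-centred) tests.",
    if (comparable && any(table(groups) <= 5L))
      "Caution: groups with n <= 5; comparisons are low-powered.")

  structure(list(descriptives = descriptives, density_table = density_table,
                 comparisons = comparisons, by_correction = by_correction,
                 correlations = correlations, footnotes = footnotes),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n\nDescriptives:\n")
  print(x$descriptives, row.names = FALSE, digits = 3)
  if (!is.null(x$density_table)) {
    cat("\nDensity table:\n")
    print(x$density_table, row.names = FALSE)
  }
  if (!is.null(x$comparisons)) {
    cat("\nOutcome comparisons:\n")
    for (v in names(x$comparisons)) {
      cmp <- x$comparisons[[v]]
      cat(sprintf("  %s: %s omnibus p = %.3g; variability p = %.3g\n", v,
                  cmp$location$test_used, cmp$location$omnibus_p,
                  cmp$variability$omnibus_p))
    }
  }
  if (!is.null(x$correlations)) {
    cat("\nCorrelations:\n")
    print(x$correlations, row.names = FALSE, digits = 3)
  }
  cat("\n", paste(x$footnotes, collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' Flatten comparison results to a tidy table
#' @noRd
comparisons_to_df <- function(comparisons, stratum = "overall") {
  if (is.null(comparisons)) return(NULL)
  do.call(rbind, lapply(names(comparisons), function(v) {
    cmp <- comparisons[[v]]
    if (is.null(cmp)) return(NULL)
    loc <- cmp$location
    pw <- loc$pairwise
    data.frame(stratum = stratum, variable = v, test = loc$test_used,
               omnibus_p = loc$omnibus_p,
               variability_p = cmp$variability$omnibus_p,
               observed_power = loc$observed_power,
               pair = paste(pw$group1, "vs", pw$group2),
               p_raw = pw$p_raw, p_adj = pw$p_adj,
               adjustment = pw$method,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Write a report to disk as CSV tables plus a plain-text summary
#'
#' @param report A `stability_report` from [build_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "stability_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$descriptives,
                   file.path(dir, "descriptives.csv"), row.names = FALSE)
  if (!is.null(report$density_table))
    utils::write.csv(report$density_table,
                     file.path(dir, "density_table.csv"), row.names = FALSE)
  cmp <- comparisons_to_df(report$comparisons, "overall")
  if (!is.null(report$by_correction))
    for (nm in names(report$by_correction))
      cmp <- rbind(cmp, comparisons_to_df(report$by_correction[[nm]], nm))
  if (!is.null(cmp))
    utils::write.csv(cmp, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  if (!is.null(report$correlations))
    utils::write.csv(report$correlations,
                     file.path(dir, "correlations.csv"), row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(report)
  invisible(dir)
}
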