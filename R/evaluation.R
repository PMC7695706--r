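# Recovery diagnostics: compare posterior diet estimates against known
# (simulated or trial-recorded) diets.

.truth_table <- function(truth, levels, sources) {
  if (is.list(truth) && !is.data.frame(truth)) {
    truth <- do.call(rbind, truth)
  }
  if (is.null(dim(truth))) {
    if (length(levels) != 1L)
      stop("posterior has ", length(levels),
           " factor levels; supply a truth row per level")
    truth <- matrix(truth, 1L, dimnames = list(levels, names(truth)))
  }
  truth <- as.matrix(truth)
  if (is.null(colnames(truth))) stop("truth must be named by source")
  if (is.null(rownames(truth))) rownames(truth) <- levels
  missing <- setdiff(sources, colnames(truth))
  if (length(missing))
    stop("truth lacks source(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(colnames(truth), sources)
  if (length(extra))
    stop("truth names unknown source(s): ", paste(extra, collapse = ", "))
  truth
}

#' Compare a posterior to the known diet
#'
#' For every factor level and source, reports the true proportion, the
#' posterior median, the absolute error in percentage points, and whether
#' the truth falls inside the central 95% credible interval; aggregates
#' are the mean and maximum absolute error and the coverage fraction.
#'
#' @param posterior a `diet_posterior` (or its summary data.frame with
#'   columns level, source, median, q2.5, q97.5).
#' @param truth named proportion vector (single level), a levels x sources
#'   matrix, or a named list of per-level vectors.
#' @return object of class `recovery_report`: `$table` (per level/source)
#'   and `$aggregates`.
#' @export
compare_to_truth <- function(posterior, truth) {
  sm <- if (inherits(posterior, "diet_posterior")) posterior$summaries
        else as.data.frame(posterior)
  need <- c("level", "source", "median", "q2.5", "q97.5")
  if (!all(need %in% names(sm)))
    stop("posterior summary lacks column(s): ",
         paste(setdiff(need, names(sm)), collapse = ", "))
  levels <- unique(sm$level)
  sources <- unique(sm$source)
  tt <- .truth_table(truth, levels, sources)
  rows <- lapply(seq_len(nrow(sm)), function(i) {
    tr <- tt[as.character(sm$level[i]), sm$source[i]]
    data.frame(level = sm$level[i], source = sm$source[i],
               true = tr, median = sm$median[i],
               abs_error_pp = abs(sm$median[i] - tr) * 100,
               inside_95ci = sm$q2.5[i] <= tr & tr <= sm$q97.5[i],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 aggregates = list(
                   mean_abs_error_pp = mean(tab$abs_error_pp),
                   max_abs_error_pp = max(tab$abs_error_pp),
                   coverage = mean(tab$inside_95ci))),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, digits = 3, ...) {
  tab <- x$table
  tab$true <- round(tab$true, digits)
  tab$median <- round(tab$median, digits)
  tab$abs_error_pp <- round(tab$abs_error_pp, 1)
  print(tab, row.names = FALSE)
  cat(sprintf("mean |error| %.1f pp, max %.1f pp, 95%% CI coverage %.2f\n",
              x$aggregates$mean_abs_error_pp, x$aggregates$max_abs_error_pp,
              x$aggregates$coverage))
  invisible(x)
}

#' Write a recovery report as CSV
#'
#' @param report a `recovery_report`.
#' @param path output CSV path.
#' @export
write_recovery_csv <- function(report, path) {
  write.csv(report$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rank sources by posterior median
#'
#' Orders sources from largest to smallest posterior median contribution
#' (ties broken alphabetically by source name) and flags the minimum —
#' in a Bayesian mixing model no proportion can be exactly zero, so a
#' source that is truly absent from the diet shows up as the (small)
#' minimum rather than as zero.
#'
#' @param posterior a `diet_posterior`.
#' @param level factor level to rank (default: the first).
#' @return data.frame with `source`, `median`, `rank`, `is_minimum`.
#' @export
rank_sources <- function(posterior, level = NULL) {
  sm <- posterior$summaries
  if (is.null(level)) level <- sm$level[1L]
  sm <- sm[sm$level == level, , drop = FALSE]
  if (!nrow(sm)) stop("no such factor level: ", level)
  ord <- order(-sm$median, sm$source)
  out <- data.frame(source = sm$source[ord], median = sm$median[ord],
                    rank = seq_len(nrow(sm)), stringsAsFactors = FALSE)
  out$is_minimum <- out$rank == nrow(out)
  out
}
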