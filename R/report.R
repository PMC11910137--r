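# Tabular reports over benchmark results: the DR x classifier accuracy pivot,
# per-stage accuracy tables, and confusion matrices. All are pure functions
# of their input tables, so reports regenerate identically from saved TSVs.

#' Pivot a benchmark table into a DR x classifier mean-accuracy grid
#'
#' @param results A `benchmark_table` from [run_grid()] (or any data.frame
#'   with `dr`, `clf`, `accuracy` columns), typically one task.
#' @return Matrix of mean fold accuracy, DR methods in rows, classifiers in
#'   columns; `NA` where a combination failed or is absent.
#' @export
report_grid_table <- function(results) {
  need <- c("dr", "clf", "accuracy")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results missing column(s): ", paste(miss, collapse = ", "))
  agg <- stats::aggregate(accuracy ~ dr + clf, data = results, FUN = mean,
                          na.action = stats::na.pass)
  drs <- unique(results$dr); clfs <- unique(results$clf)
  out <- matrix(NA_real_, length(drs), length(clfs),
                dimnames = list(drs, clfs))
  out[cbind(match(agg$dr, drs), match(agg$clf, clfs))] <- agg$accuracy
  out
}

#' Per-stage mean accuracy table
#'
#' @param results A data.frame with `dr`, `clf`, `stage`, `accuracy` columns
#'   (e.g. a `"T_given_stage"` benchmark).
#' @return data.frame with one row per combo x stage and the mean accuracy.
#' @export
report_per_stage <- function(results) {
  need <- c("dr", "clf", "stage", "accuracy")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results missing column(s): ", paste(miss, collapse = ", "))
  out <- stats::aggregate(accuracy ~ dr + clf + stage, data = results,
                          FUN = mean, na.action = stats::na.pass)
  out[order(out$dr, out$clf, out$stage), , drop = FALSE]
}

#' Confusion matrix (counts and row-normalized rates)
#'
#' @param truth,predicted Equal-length label vectors.
#' @param levels Optional label ordering; defaults to the union of observed
#'   labels.
#' @return List with `counts` (true x predicted) and `rates` (rows normalized
#'   to their test counts).
#' @export
report_confusion <- function(truth, predicted, levels = NULL) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  levels <- levels %||% sort(unique(c(as.character(truth), as.character(predicted))))
  counts <- table(true = factor(truth, levels),
                  predicted = factor(predicted, levels))
  counts <- unclass(counts)
  rs <- rowSums(counts)
  rates <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, rates = rates)
}

#' Write a benchmark table as TSV (with config provenance header)
#'
#' @param results A `benchmark_table`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_benchmark <- function(results, path) {
  plan <- attr(results, "plan")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(plan)) {
    writeLines(sprintf("# cv_plan: n_folds=%d n_repeats=%d seed=%d",
                       plan$n_folds, plan$n_repeats, plan$seed), con)
  }
  utils::write.table(as.data.frame(results), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a benchmark TSV written by [write_benchmark()]
#' @param path TSV path.
#' @return data.frame of per-fold results.
#' @export
read_benchmark <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
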