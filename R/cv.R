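# Evaluation engine: stratified k-fold evaluation CV, nested optimization CV
# with grid search for the *_CV classifiers, benchmark runs over the
# DR x classifier grid, the output-dimensionality sweep, and the genus-level
# reference-extension procedure for environmental test sets.
#
# Preprocessing is applied once, before CV (a fixed protocol); DR and
# classifier fitting happen strictly inside each training fold, so the test
# split never influences any fitted parameter.

#' Classification accuracy
#'
#' Proportion of samples whose predicted label equals the true label,
#' between 0.0 (0%) and 1.0 (100%).
#'
#' @param predicted,truth Equal-length, nonempty label vectors.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth differ in length (", length(predicted), " vs ",
         length(truth), ")")
  }
  if (length(predicted) == 0L) stop("empty label vectors")
  mean(as.character(predicted) == as.character(truth))
}

#' Cross-validation plan
#'
#' @param n_folds Number of evaluation folds (default 10: train on nine
#'   splits, test on the tenth, rotating).
#' @param n_repeats Independent repetitions of the whole CV (10 for
#'   variance studies).
#' @param stratify_by Label field used for stratified fold assignment.
#'   Defaults: strain for taxonomy tasks, stage for the growth-stage task
#'   (resolved by [evaluate_combo()] when `NULL`).
#' @param inner_folds Folds of the nested optimization CV (grid search).
#' @param seed Integer seed controlling all fold shuffling.
#' @return A `cv_plan` object.
#' @export
cv_plan <- function(n_folds = 10L, n_repeats = 1L, stratify_by = NULL,
                    inner_folds = 3L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(n_folds = n_folds, n_repeats = as.integer(n_repeats),
                 stratify_by = stratify_by, inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Stratified fold assignment
#'
#' Every sample lands in exactly one test fold per repeat; within each
#' stratum, fold class counts are within +/-1 of proportional. Strata smaller
#' than `n_folds` trigger a warning (their samples still get folds, but some
#' folds will lack that stratum).
#'
#' @param labels Vector (or data.frame with the plan's `stratify_by` column)
#'   defining strata; use a constant vector for unstratified folds.
#' @param plan A [cv_plan()].
#' @return List of length `n_repeats`; each element an integer fold id
#'   (1..n_folds) per sample.
#' @export
make_folds <- function(labels, plan) {
  stopifnot(inherits(plan, "cv_plan"))
  y <- if (is.data.frame(labels)) {
    field <- plan$stratify_by %||% "strain"
    labels[[field]] %||% stop("labels lack stratification field: ", field)
  } else as.character(labels)
  n <- length(y)
  if (n < plan$n_folds) stop("fewer samples (", n, ") than folds (", plan$n_folds, ")")
  small <- names(which(table(y) < plan$n_folds))
  if (length(small)) {
    warning("stratification degraded: stratum smaller than n_folds: ",
            paste(small, collapse = ", "))
  }
  lapply(seq_len(plan$n_repeats), function(r) {
    with_seed(derive_seed(plan$seed, 11L, r), {
      fold <- integer(n)
      offset <- 0L
      for (lev in unique(y)) {
        idx <- which(y == lev)
        ids <- (offset + seq_along(idx) - 1L) %% plan$n_folds + 1L
        fold[idx] <- sample(ids)
        offset <- offset + length(idx)
      }
      fold
    })
  })
}

#' A DR + classifier pairing
#'
#' @param dr A [dr_spec()] (or method name, built with defaults).
#' @param clf A [clf_spec()] (or method name, built with defaults).
#' @return A `model_combo` object.
#' @export
model_combo <- function(dr, clf) {
  if (is.character(dr)) dr <- dr_spec(dr)
  if (is.character(clf)) clf <- clf_spec(clf)
  stopifnot(inherits(dr, "dr_spec"), inherits(clf, "clf_spec"))
  structure(list(dr = dr, clf = clf), class = "model_combo")
}

#' @export
print.model_combo <- function(x, ...) {
  cat(sprintf("<model_combo> %s + %s\n", x$dr$method, x$clf$method))
  invisible(x)
}

#' Grid search over classifier hyperparameters by inner cross-validation
#'
#' Re-splits the training data of one evaluation fold into `inner_folds`
#' splits and picks the candidate maximizing mean inner-CV accuracy; the
#' evaluation test split is never seen. Ties go to the first candidate in
#' declared grid order. Classifiers without a grid return an empty choice.
#'
#' @param clf A [clf_spec()].
#' @param X Training feature matrix (already DR-reduced).
#' @param y Training labels.
#' @param plan A [cv_plan()] (supplies `inner_folds` and the seed).
#' @param fold_id Integer distinguishing the RNG substream per outer fold.
#' @return List with `hyper` (named list) and `inner_accuracy`.
#' @export
nested_grid_search <- function(clf, X, y, plan, fold_id = 1L) {
  stopifnot(inherits(clf, "clf_spec"))
  if (length(clf$tunable_grid) == 0L) {
    if (grepl("_CV$", clf$method)) stop(clf$method, " has an empty tunable_grid")
    return(list(hyper = list(), inner_accuracy = NA_real_))
  }
  cand <- expand.grid(clf$tunable_grid, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  if (nrow(cand) == 1L) {
    return(list(hyper = as.list(cand[1L, , drop = FALSE]), inner_accuracy = NA_real_))
  }
  inner_plan <- cv_plan(n_folds = max(2L, plan$inner_folds),
                        seed = derive_seed(plan$seed, 13L, fold_id))
  folds <- make_folds_quiet(as.character(y), inner_plan)[[1L]]
  scores <- vapply(seq_len(nrow(cand)), function(ci) {
    hyper <- as.list(cand[ci, , drop = FALSE])
    accs <- vapply(seq_len(inner_plan$n_folds), function(f) {
      tr <- folds != f; te <- folds == f
      if (!any(te) || length(unique(y[tr])) < 2L) return(NA_real_)
      fit <- fit_classifier(clf, X[tr, , drop = FALSE], y[tr], hyper = hyper)
      accuracy(predict(fit, X[te, , drop = FALSE]), y[te])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores)  # which.max returns the first maximum: declared-order tie-break
  list(hyper = as.list(cand[best, , drop = FALSE]), inner_accuracy = scores[best])
}

make_folds_quiet <- function(labels, plan) {
  suppressWarnings(make_folds(labels, plan))
}

task_fields <- function(task) {
  switch(task,
         T_only = list(label = "strain", strat = "strain"),
         T_given_stage = list(label = "strain", strat = "strain"),
         G_step = list(label = "stage", strat = "stage"),
         genus = list(label = "genus", strat = "genus"),
         stop("unknown task: ", task))
}

#' Evaluate one DR + classifier combination by cross-validation
#'
#' Tasks:
#' * `"T_only"`: strain classification on the full dataset;
#' * `"T_given_stage"`: strain classification on the subset of one growth
#'   stage (supply `stage`), the "taxonomy given ground-truth stage" setting;
#' * `"G_step"`: growth-stage classification;
#' * `"genus"`: genus-level classification (environmental reference setting).
#'
#' Within each evaluation fold, the DR and classifier (and any grid-searched
#' hyperparameters) are fitted on the nine training splits only.
#'
#' @param combo A [model_combo()].
#' @param ds An [scrs_dataset].
#' @param task See above.
#' @param plan A [cv_plan()].
#' @param stage Growth stage for `"T_given_stage"`.
#' @param folds Optional precomputed fold assignment (list of integer vectors
#'   as from [make_folds()]) overriding the plan's own.
#' @param keep_models Keep the per-fold fitted DR/classifier parameter sets
#'   (as from [fitted_params()]) in the result.
#' @return An `eval_result`: per-fold accuracies, their mean and sd, chosen
#'   hyperparameters per fold, and raw per-fold predictions.
#' @export
evaluate_combo <- function(combo, ds, task = "T_only", plan = cv_plan(),
                           stage = NULL, folds = NULL, keep_models = FALSE) {
  stopifnot(inherits(combo, "model_combo"), inherits(ds, "scrs_dataset"))
  tf <- task_fields(task)
  if (task == "T_given_stage") {
    if (is.null(stage)) stop("T_given_stage requires `stage`")
    keep <- ds$labels$stage == stage
    if (!any(keep)) stop("no cells at stage ", stage)
    ds <- subset_cells(ds, keep)
  }
  y <- ds$labels[[tf$label]]
  X <- ds$intensities
  if (is.null(folds)) {
    plan_s <- plan
    plan_s$stratify_by <- plan$stratify_by %||% tf$strat
    folds <- make_folds(ds$labels, plan_s)
  }
  fold_acc <- numeric(0); hyper_list <- list(); models <- list()
  preds <- list()
  for (r in seq_along(folds)) {
    fr <- folds[[r]]
    for (f in sort(unique(fr))) {
      tr <- fr != f; te <- fr == f
      res <- fit_fold(combo, X, y, tr, te, plan, fold_id = (r - 1L) * 100L + f,
                      keep_models = keep_models)
      fold_acc <- c(fold_acc, res$acc)
      hyper_list[[length(hyper_list) + 1L]] <- res$hyper
      preds[[length(preds) + 1L]] <- list(repeat_i = r, fold = f,
                                          idx = which(te), truth = y[te],
                                          pred = res$pred)
      if (keep_models) models[[length(models) + 1L]] <- res$params
    }
  }
  structure(list(combo = combo, task = task, stage = stage,
                 fold_accuracies = fold_acc, mean = mean(fold_acc),
                 sd = stats::sd(fold_acc), hyper = hyper_list,
                 predictions = preds,
                 models = if (keep_models) models),
            class = "eval_result")
}

fit_fold <- function(combo, X, y, tr, te, plan, fold_id, keep_models = FALSE) {
  y_tr <- y[tr]
  dr_fit <- fit_dr_matrix(combo$dr, X[tr, , drop = FALSE],
                          if (combo$dr$supervised) y_tr else NULL)
  Z_tr <- transform_dr_matrix(dr_fit, X[tr, , drop = FALSE])
  Z_te <- transform_dr_matrix(dr_fit, X[te, , drop = FALSE])
  gs <- nested_grid_search(combo$clf, Z_tr, y_tr, plan, fold_id = fold_id)
  clf_fit <- fit_classifier(combo$clf, Z_tr, y_tr, hyper = gs$hyper)
  pred <- predict(clf_fit, Z_te)
  list(acc = accuracy(pred, y[te]), hyper = gs$hyper, pred = pred,
       params = if (keep_models) list(dr = fitted_params(dr_fit),
                                      clf = fitted_params(clf_fit)))
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s + %s | task %s%s | mean acc %.4f (sd %.4f, %d folds)\n",
              x$combo$dr$method, x$combo$clf$method, x$task,
              if (!is.null(x$stage)) paste0("/", x$stage) else "",
              x$mean, x$sd, length(x$fold_accuracies)))
  invisible(x)
}

#' Extract the numeric fitted parameters of a model
#'
#' Returns the decision-defining parameters (projection bases, coefficients,
#' support vectors, forests, weights) of a fitted DR or classifier, free of
#' environments, so two fits can be compared for exact equality — e.g. to
#' verify that permuting test-fold labels leaves training untouched.
#'
#' @param fit A `fitted_dr` or `fitted_clf`.
#' @return A list of numeric objects.
#' @export
fitted_params <- function(fit) {
  if (inherits(fit, "fitted_dr")) {
    m <- fit$spec$method
    return(switch(m,
                  NONE = list(p = fit$p),
                  KPCA = list(pcv = kernlab::pcv(fit$kpca),
                              xmatrix = kernlab::xmatrix(fit$kpca)),
                  LDA = list(scaling = unname(fit$lda$scaling),
                             means = unname(fit$lda$means),
                             prior = unname(fit$lda$prior)),
                  list(center = unname(fit$center), proj = unname(fit$proj))))
  }
  if (inherits(fit, "fitted_clf")) {
    m <- fit$spec$method
    md <- fit$model
    return(switch(m,
                  GNB = list(apriori = unname(md$apriori),
                             tables = lapply(md$tables, unname)),
                  KNN = list(train = unname(md$train),
                             cl = as.character(md$cl), K = md$K),
                  LDA = list(scaling = unname(md$scaling), means = unname(md$means),
                             prior = unname(md$prior)),
                  LR = list(wts = md$wts),
                  RF = list(forest = md$forest[c("ndbigtree", "nodestatus",
                                                 "bestvar", "xbestsplit",
                                                 "nodepred", "treemap")]),
                  NN = list(wts = md$wts),
                  # SVM variants
                  list(SV = unname(md$SV), coefs = unname(md$coefs),
                       rho = md$rho, hyper = fit$hyper)))
  }
  stop("not a fitted model")
}

#' Enumerate the benchmark grid of DR x classifier combinations
#'
#' The standard grid pairs all six DR methods with the nine non-neural
#' classifiers (54 combinations); the MLP is added only on request, matching
#' its separate treatment in benchmarking practice.
#'
#' @param include_nn Add the `NN` classifier (grid becomes 6 x 10 = 60).
#' @return `data.frame` with columns `dr`, `clf`.
#' @export
benchmark_grid <- function(include_nn = FALSE) {
  g <- expand.grid(clf = clf_methods(include_nn), dr = dr_methods(),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("dr", "clf")]
}

#' Run the DR x classifier benchmark over one or more tasks
#'
#' @param ds An [scrs_dataset].
#' @param tasks Character vector of tasks for [evaluate_combo()]; for
#'   `"T_given_stage"` every stage present is evaluated.
#' @param plan A [cv_plan()].
#' @param drs,clfs Optional lists of [dr_spec()] / [clf_spec()] overriding the
#'   default registries. Default DR output dimensionality is 35 for taxonomy
#'   tasks and 3 for the 4-class growth-stage task.
#' @param include_nn Include the MLP in the default classifier registry.
#' @param taxonomy_dim,stage_dim Default DR output dimensionalities.
#' @return A `data.frame` (class `benchmark_table`) with one row per combo x
#'   task x fold: `dr`, `clf`, `task`, `stage`, `fold`, `accuracy`, `hyper`
#'   (JSON), `error` (NA unless that combo failed; failures do not abort the
#'   run).
#' @export
run_grid <- function(ds, tasks = "T_only", plan = cv_plan(), drs = NULL,
                     clfs = NULL, include_nn = FALSE, taxonomy_dim = 35L,
                     stage_dim = 3L) {
  stopifnot(inherits(ds, "scrs_dataset"))
  rows <- list()
  for (task in tasks) {
    stages <- if (task == "T_given_stage") {
      intersect(STAGE_LEVELS, unique(ds$labels$stage))
    } else NA_character_
    out_dim <- if (task == "G_step") stage_dim else taxonomy_dim
    drs_t <- drs %||% lapply(dr_methods(), dr_spec, out_dim = out_dim)
    clfs_t <- clfs %||% lapply(clf_methods(include_nn), clf_spec, seed = plan$seed)
    for (dspec in drs_t) for (cspec in clfs_t) for (st in stages) {
      combo <- model_combo(dspec, cspec)
      res <- tryCatch(
        evaluate_combo(combo, ds, task = task, plan = plan,
                       stage = if (is.na(st)) NULL else st),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          dr = dspec$method, clf = cspec$method, task = task, stage = st,
          fold = NA_integer_, accuracy = NA_real_, hyper = NA_character_,
          error = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        nf <- length(res$fold_accuracies)
        rows[[length(rows) + 1L]] <- data.frame(
          dr = dspec$method, clf = cspec$method, task = task, stage = st,
          fold = seq_len(nf), accuracy = res$fold_accuracies,
          hyper = vapply(res$hyper, function(h) {
            as.character(jsonlite::toJSON(h, auto_unbox = TRUE))
          }, character(1)),
          error = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "plan") <- plan
  class(out) <- c("benchmark_table", class(out))
  out
}

#' Sweep DR output dimensionality for one combination
#'
#' Evaluates the combo at each requested dimensionality and applies the
#' selection rule: highest mean CV accuracy, ties resolved toward the smaller
#' (cheaper) dimensionality. Dimensionalities invalid for the DR (e.g. beyond
#' the LDA class-count bound) are skipped with a warning.
#'
#' @param ds An [scrs_dataset].
#' @param combo A [model_combo()] (its `out_dim` is overridden per sweep point).
#' @param dims Integer vector of candidate output dimensionalities.
#' @param plan A [cv_plan()].
#' @param task,stage Passed to [evaluate_combo()].
#' @return List with `results` (`data.frame`: dim, mean_accuracy, sd) and
#'   `selected` (the chosen dimensionality).
#' @export
dim_sweep <- function(ds, combo, dims, plan = cv_plan(), task = "T_only",
                      stage = NULL) {
  res <- list()
  for (d in as.integer(dims)) {
    spec_d <- combo$dr
    spec_d$out_dim <- d
    r <- tryCatch(
      evaluate_combo(model_combo(spec_d, combo$clf), ds, task = task,
                     plan = plan, stage = stage),
      error = function(e) e)
    if (inherits(r, "error")) {
      warning("dimension ", d, " skipped: ", conditionMessage(r))
    } else {
      res[[length(res) + 1L]] <- data.frame(dim = d, mean_accuracy = r$mean,
                                            sd = r$sd)
    }
  }
  if (length(res) == 0L) stop("no valid dimensionality in the sweep")
  tab <- do.call(rbind, res)
  tab <- tab[order(tab$dim), , drop = FALSE]
  best <- tab$dim[tab$mean_accuracy == max(tab$mean_accuracy)]
  list(results = tab, selected = min(best))
}

#' Extend a pure-culture reference with new strains and rebalance by genus
#'
#' Merges two datasets sharing a grid, relabels the classification target at
#' the genus level, and subsamples every genus to exactly `quota` spectra
#' (without replacement; with replacement, under a warning, only when a genus
#' has fewer than `quota`). This builds the genus-balanced extended training
#' set used when classifying environmental cells against a pure-culture
#' library.
#'
#' @param base,extra [scrs_dataset]s on a common grid.
#' @param quota Spectra per genus in the output.
#' @param seed Subsampling seed.
#' @return An [scrs_dataset] with `n_genera * quota` rows.
#' @export
extend_reference <- function(base, extra, quota = 100L, seed = 1L) {
  stopifnot(inherits(base, "scrs_dataset"), inherits(extra, "scrs_dataset"))
  if (!same_grid(base, extra)) stop("datasets are on different wavenumber grids")
  quota <- as.integer(quota)
  if (quota < 1L) stop("quota must be >= 1")
  labs <- rbind(base$labels, extra$labels)
  if (anyDuplicated(labs$cell_id)) {
    labs$cell_id <- make.unique(labs$cell_id, sep = "_dup")
  }
  ints <- rbind(base$intensities, extra$intensities)
  genera <- unique(labs$genus)
  if (any(genera == "" | is.na(genera))) stop("missing genus labels")
  pick <- with_seed(derive_seed(seed, 17L), {
    unlist(lapply(genera, function(g) {
      idx <- which(labs$genus == g)
      if (length(idx) == 0L) stop("genus with zero spectra: ", g)
      if (length(idx) >= quota) {
        sample(idx, quota)
      } else {
        warning("genus ", g, " has ", length(idx), " < quota ", quota,
                " spectra; sampling with replacement")
        sample(idx, quota, replace = TRUE)
      }
    }))
  })
  labs_out <- labs[pick, , drop = FALSE]
  labs_out$cell_id <- make.unique(labs_out$cell_id, sep = "_rep")
  scrs_dataset(base$grid, ints[pick, , drop = FALSE], labs_out)
}
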