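# Two-step growth-stage-then-taxonomy classifier ensemble (G-T).
#
# The G-step predicts each cell's growth stage (Exp/S1/S2/S3) from its
# spectrum; the T-step then predicts taxonomy with a DR + classifier
# combination trained specifically for that stage. G- and T-step model
# setups are independent. By default T-step models are trained on the
# ground-truth stage partitions of the training data (`t_train_on =
# "predicted"` instead partitions training data by the G-step's own
# predictions).

fit_pipeline <- function(combo, X, y, plan) {
  dr_fit <- fit_dr_matrix(combo$dr, X, if (combo$dr$supervised) y else NULL)
  Z <- transform_dr_matrix(dr_fit, X)
  gs <- nested_grid_search(combo$clf, Z, y, plan)
  clf_fit <- fit_classifier(combo$clf, Z, y, hyper = gs$hyper)
  structure(list(dr = dr_fit, clf = clf_fit, hyper = gs$hyper),
            class = "fitted_pipeline")
}

predict_pipeline <- function(pl, X) {
  predict(pl$clf, transform_dr_matrix(pl$dr, X))
}

#' Train the two-step growth-stage-then-taxonomy ensemble
#'
#' @param ds An [scrs_dataset] with both stage and strain labels; all four
#'   stages must be present.
#' @param g_combo [model_combo()] for the stage classifier (G-step). Default:
#'   no DR + CV-tuned RBF SVM, the strongest stage classifier in this
#'   package's benchmarks.
#' @param t_combos [model_combo()] for the per-stage taxonomy models (T-step),
#'   either one combo (recycled over stages) or a named list with one entry
#'   per stage. Default: LDA + logistic regression.
#' @param plan A [cv_plan()] (supplies inner-CV folds and seed for tuned
#'   models).
#' @param t_label Taxonomy label field for the T-step (`"strain"` or
#'   `"genus"`).
#' @param t_train_on `"truth"` (default) trains each T-step model on the rows
#'   whose true stage matches; `"predicted"` partitions training rows by the
#'   G-step's predictions.
#' @return A `gt_model` with fields `g` and `t` (one fitted pipeline per
#'   stage).
#' @export
train_gt <- function(ds, g_combo = model_combo("NONE", "SVM_RBF_CV"),
                     t_combos = model_combo(dr_spec("LDA"), clf_spec("LR")),
                     plan = cv_plan(), t_label = "strain",
                     t_train_on = c("truth", "predicted")) {
  stopifnot(inherits(ds, "scrs_dataset"))
  t_train_on <- match.arg(t_train_on)
  stages_present <- unique(ds$labels$stage)
  missing_stage <- setdiff(STAGE_LEVELS, stages_present)
  if (length(missing_stage)) {
    stop("dataset lacks stage(s): ", paste(missing_stage, collapse = ", "))
  }
  if (inherits(t_combos, "model_combo")) {
    t_combos <- stats::setNames(rep(list(t_combos), 4L), STAGE_LEVELS)
  }
  if (!all(STAGE_LEVELS %in% names(t_combos))) {
    stop("t_combos must name all four stages")
  }
  X <- ds$intensities
  g_fit <- fit_pipeline(g_combo, X, ds$labels$stage, plan)
  part_stage <- if (t_train_on == "truth") ds$labels$stage else {
    predict_pipeline(g_fit, X)
  }
  t_fits <- lapply(STAGE_LEVELS, function(s) {
    idx <- part_stage == s
    if (sum(idx) < 2L || length(unique(ds$labels[[t_label]][idx])) < 2L) {
      stop("stage ", s, " has too few training rows (", sum(idx),
           ") to fit a taxonomy model")
    }
    fit_pipeline(t_combos[[s]], X[idx, , drop = FALSE],
                 ds$labels[[t_label]][idx], plan)
  })
  names(t_fits) <- STAGE_LEVELS
  structure(list(g = g_fit, t = t_fits, t_label = t_label, grid = ds$grid),
            class = "gt_model")
}

#' Predict growth stage and taxonomy with a G-T ensemble
#'
#' Taxonomy for each cell comes from the T-step model of its *predicted*
#' stage; misrouted cells are still classified (by the wrong stage's model)
#' rather than erroring. Supplying `oracle_stage` bypasses the G-step routing
#' with known stages, which reproduces the taxonomy-given-true-stage path
#' exactly.
#'
#' @param model A `gt_model` from [train_gt()].
#' @param ds An [scrs_dataset] on the training grid.
#' @param oracle_stage Optional vector of true stages to route by.
#' @return List with `stage` (G-step predictions) and `taxonomy` (routed
#'   T-step predictions), each one label per cell.
#' @export
predict_gt <- function(model, ds, oracle_stage = NULL) {
  stopifnot(inherits(model, "gt_model"), inherits(ds, "scrs_dataset"))
  if (!same_grid(model$grid, ds)) stop("dataset grid differs from training grid")
  X <- ds$intensities
  stage_pred <- predict_pipeline(model$g, X)
  route <- if (is.null(oracle_stage)) stage_pred else as.character(oracle_stage)
  if (length(route) != nrow(X)) stop("oracle_stage length mismatch")
  tax <- character(nrow(X))
  for (s in unique(route)) {
    if (!s %in% names(model$t)) stop("no T-step model for routed stage: ", s)
    idx <- route == s
    tax[idx] <- predict_pipeline(model$t[[s]], X[idx, , drop = FALSE])
  }
  list(stage = stage_pred, taxonomy = tax)
}

#' Cross-validated evaluation of the G-T ensemble
#'
#' Evaluation folds are shared between the G- and T-steps (stratified jointly
#' by strain and stage), so per-fold joint accuracy is well defined. Reported
#' per fold: G-step stage accuracy, joint taxonomy accuracy under predicted
#' routing, taxonomy accuracy under oracle (true-stage) routing, and per-stage
#' oracle-routed taxonomy accuracy; plus the pooled stage confusion matrix.
#'
#' @inheritParams train_gt
#' @param plan A [cv_plan()].
#' @return A `gt_eval` list: `g_accuracy`, `joint_accuracy`,
#'   `oracle_accuracy` (numeric per fold), `per_stage` (stage x fold matrix of
#'   oracle-routed taxonomy accuracy), `confusion` (true stage x predicted
#'   stage counts over all test folds), `predictions` (per fold).
#' @export
evaluate_gt <- function(ds, g_combo = model_combo("NONE", "SVM_RBF_CV"),
                        t_combos = model_combo(dr_spec("LDA"), clf_spec("LR")),
                        plan = cv_plan(), t_label = "strain",
                        t_train_on = "truth") {
  stopifnot(inherits(ds, "scrs_dataset"))
  strat <- interaction(ds$labels[[t_label]], ds$labels$stage, drop = TRUE)
  folds <- make_folds_quiet(as.character(strat), plan)[[1L]]
  nf <- plan$n_folds
  g_acc <- joint_acc <- oracle_acc <- numeric(nf)
  per_stage <- matrix(NA_real_, nrow = 4L, ncol = nf,
                      dimnames = list(STAGE_LEVELS, NULL))
  confusion <- matrix(0L, 4L, 4L, dimnames = list(true = STAGE_LEVELS,
                                                  predicted = STAGE_LEVELS))
  preds <- list()
  for (f in seq_len(nf)) {
    tr <- folds != f; te <- folds == f
    model <- train_gt(subset_cells(ds, tr), g_combo, t_combos, plan,
                      t_label = t_label, t_train_on = t_train_on)
    test_ds <- subset_cells(ds, te)
    true_stage <- test_ds$labels$stage
    true_tax <- test_ds$labels[[t_label]]
    pr <- predict_gt(model, test_ds)
    pr_oracle <- predict_gt(model, test_ds, oracle_stage = true_stage)
    g_acc[f] <- accuracy(pr$stage, true_stage)
    joint_acc[f] <- accuracy(pr$taxonomy, true_tax)
    oracle_acc[f] <- accuracy(pr_oracle$taxonomy, true_tax)
    for (s in STAGE_LEVELS) {
      i <- true_stage == s
      if (any(i)) per_stage[s, f] <- accuracy(pr_oracle$taxonomy[i], true_tax[i])
    }
    confusion <- confusion + table(factor(true_stage, STAGE_LEVELS),
                                   factor(pr$stage, STAGE_LEVELS))
    preds[[f]] <- list(idx = which(te), true_stage = true_stage,
                       true_tax = true_tax, stage = pr$stage,
                       taxonomy = pr$taxonomy, oracle_taxonomy = pr_oracle$taxonomy)
  }
  structure(list(g_accuracy = g_acc, joint_accuracy = joint_acc,
                 oracle_accuracy = oracle_acc, per_stage = per_stage,
                 confusion = confusion, predictions = preds, folds = folds),
            class = "gt_eval")
}

#' @export
print.gt_eval <- function(x, ...) {
  cat(sprintf("<gt_eval> G-step %.4f | joint %.4f | oracle-routed %.4f (means over %d folds)\n",
              mean(x$g_accuracy), mean(x$joint_accuracy),
              mean(x$oracle_accuracy), length(x$g_accuracy)))
  invisible(x)
}
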