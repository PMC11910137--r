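# Evaluation engine: accuracy metric, stratified folds, nested grid search,
# combo evaluation (incl. oracle equivalence against a manual CV), the
# benchmark grid, the dimensionality sweep, and reference extension.

test_that("accuracy counts exact label matches", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(accuracy(c("a", "b", "a", "b"), c("a", "b", "a", "a")), 0.75)
  expect_equal(accuracy(c("x", "y"), c("a", "b")), 0.0)
  expect_error(accuracy("a", c("a", "b")), "length")
  expect_error(accuracy(character(0), character(0)), "empty")
})

test_that("make_folds is exhaustive, balanced, stratified and deterministic", {
  plan <- cv_plan(n_folds = 10, seed = 4)
  f <- make_folds(rep("x", 100), plan)[[1]]
  expect_equal(as.vector(table(f)), rep(10L, 10))
  f17 <- make_folds(rep("x", 17), cv_plan(n_folds = 10, seed = 4))[[1]]
  expect_lte(diff(range(table(factor(f17, levels = 1:10)))), 1L)
  # stratified 2-class 50/50 with k = 10: every fold is 5/5 (brute-force count)
  y <- rep(c("a", "b"), each = 50)
  fs <- make_folds(y, plan)[[1]]
  counts <- table(fs, y)
  expect_true(all(counts == 5L))
  expect_identical(make_folds(y, plan), make_folds(y, plan))
  # every sample in exactly one test fold per repeat
  fr <- make_folds(y, cv_plan(n_folds = 5, n_repeats = 3, seed = 1))
  for (f in fr) expect_true(all(f %in% 1:5) && length(f) == 100)
  expect_warning(make_folds(c(rep("a", 30), "rare"), plan), "rare")
  expect_error(make_folds(rep("a", 5), plan), "fewer samples")
})

test_that("nested grid search picks the generalizing candidate, ties to first", {
  # single candidate is returned untouched
  clf1 <- clf_spec("SVM_LIN_CV", tunable_grid = list(C = 5))
  toy <- small_dataset(seed = 31L)
  X <- toy$intensities[1:80, 1:10]; y <- toy$labels$stage[1:80]
  got <- nested_grid_search(clf1, X, y, cv_plan(seed = 1))
  expect_equal(got$hyper$C, 5)
  # separable toy: a vanishing C underfits, a large C fits
  set.seed(8)
  Xs <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60) + 3, 30, 2))
  ys <- rep(c("a", "b"), each = 30)
  clf2 <- clf_spec("SVM_LIN_CV", tunable_grid = list(C = c(1e-6, 100)))
  got2 <- nested_grid_search(clf2, Xs, ys, cv_plan(seed = 2))
  expect_equal(got2$hyper$C, 100)
  # exact tie -> first candidate in declared order
  clf3 <- clf_spec("SVM_LIN_CV", tunable_grid = list(C = c(10, 100)))
  got3 <- nested_grid_search(clf3, Xs, ys, cv_plan(seed = 2))
  expect_equal(got3$hyper$C, 10)
  # untuned classifiers return an empty choice; empty grids on CV methods fail
  expect_equal(nested_grid_search(clf_spec("LR"), Xs, ys, cv_plan())$hyper,
               list())
})

test_that("a memorizing classifier scores 1.0 on duplicated rows", {
  ds <- small_dataset(seed = 33L)
  idx <- rep(seq(1, 480, by = 10), each = 2)  # every row duplicated
  labs <- ds$labels[idx, ]
  labs$cell_id <- paste0("r", seq_along(idx))
  dup <- scrs_dataset(ds$grid, ds$intensities[idx, ], labs)
  combo <- model_combo(dr_spec("NONE"),
                       clf_spec("KNN", fixed_params = list(K = 1L)))
  # split each duplicate pair across the two folds: every test row has its
  # exact copy in training
  folds <- list(rep(c(1L, 2L), length(idx) / 2))
  res <- suppressWarnings(
    evaluate_combo(combo, dup, "T_only", cv_plan(n_folds = 2, seed = 5),
                   folds = folds))
  expect_equal(res$mean, 1.0)
})

test_that("NONE + classifier CV equals a manual classifier CV on the same folds", {
  ds <- small_dataset(seed = 35L, n_strains = 4L, genus_partition = c(2L, 1L, 1L),
                      spectra = 10L, n_channels = 40L)
  plan <- cv_plan(n_folds = 5, seed = 7)
  folds <- make_folds(ds$labels$strain, plan)
  res <- evaluate_combo(model_combo("NONE", "LDA"), ds, "T_only", plan,
                        folds = folds)
  manual <- vapply(1:5, function(f) {
    tr <- folds[[1]] != f; te <- folds[[1]] == f
    fit <- fit_classifier(clf_spec("LDA"), ds$intensities[tr, ],
                          ds$labels$strain[tr])
    accuracy(predict(fit, ds$intensities[te, ]), ds$labels$strain[te])
  }, numeric(1))
  expect_identical(res$fold_accuracies, manual)
})

test_that("eval results are internally consistent", {
  ds <- small_dataset(seed = 35L, n_strains = 4L, genus_partition = c(2L, 1L, 1L),
                      spectra = 10L, n_channels = 40L)
  res <- evaluate_combo(model_combo(dr_spec("PCA", out_dim = 5), clf_spec("GNB")),
                        ds, "T_only", cv_plan(n_folds = 5, seed = 2))
  expect_equal(res$mean, mean(res$fold_accuracies))
  expect_equal(res$sd, sd(res$fold_accuracies))
  expect_true(all(res$fold_accuracies >= 0 & res$fold_accuracies <= 1))
  # stored predictions recompute the fold accuracies
  recomputed <- vapply(res$predictions, function(p) accuracy(p$pred, p$truth),
                       numeric(1))
  expect_equal(recomputed, res$fold_accuracies)
})

test_that("stage filtering works and empty stages error", {
  ds <- small_dataset(seed = 35L, n_strains = 4L, genus_partition = c(2L, 1L, 1L),
                      spectra = 10L, n_channels = 40L)
  res <- suppressWarnings(
    evaluate_combo(model_combo(dr_spec("LDA", out_dim = 3), clf_spec("LR")), ds,
                   "T_given_stage", cv_plan(n_folds = 4, seed = 2), stage = "S1"))
  expect_length(res$fold_accuracies, 4L)
  expect_error(evaluate_combo(model_combo("NONE", "LR"), ds, "T_given_stage",
                              cv_plan(), stage = "nope"), "no cells")
  expect_error(evaluate_combo(model_combo("NONE", "LR"), ds, "T_given_stage",
                              cv_plan()), "requires")
})

test_that("the benchmark grid enumerates 54 combos (60 with the MLP)", {
  g <- benchmark_grid()
  expect_equal(nrow(g), 54L)
  expect_equal(nrow(unique(g)), 54L)
  expect_setequal(unique(g$dr), dr_methods())
  expect_setequal(unique(g$clf), clf_methods(include_nn = FALSE))
  expect_equal(nrow(benchmark_grid(include_nn = TRUE)), 60L)
})

test_that("run_grid covers a restricted registry and records failures", {
  ds <- small_dataset(seed = 37L, n_strains = 4L, genus_partition = c(2L, 1L, 1L),
                      spectra = 8L, n_channels = 30L)
  plan <- cv_plan(n_folds = 3, seed = 9)
  res <- suppressWarnings(run_grid(
    ds, tasks = "T_only", plan = plan,
    drs = list(dr_spec("NONE"), dr_spec("PCA", out_dim = 5)),
    clfs = list(clf_spec("GNB"), clf_spec("LDA"), clf_spec("LR"))))
  expect_equal(length(unique(paste(res$dr, res$clf))), 6L)
  expect_equal(sum(!is.na(res$accuracy)), 6L * 3L)
  # a failing combo is recorded, not fatal: LDA DR with impossible out_dim
  res2 <- suppressWarnings(run_grid(
    ds, tasks = "G_step", plan = plan, stage_dim = 10L,
    drs = list(dr_spec("LDA", out_dim = 10L), dr_spec("NONE")),
    clfs = list(clf_spec("GNB"))))
  lda_rows <- res2[res2$dr == "LDA", ]
  expect_true(all(is.na(lda_rows$accuracy)))
  expect_match(lda_rows$error[1], "at most")
  expect_true(all(!is.na(res2[res2$dr == "NONE", "accuracy"])))
})

test_that("dim_sweep applies the selection rule and skips invalid dims", {
  ds <- small_dataset(seed = 39L, n_strains = 4L, genus_partition = c(2L, 1L, 1L),
                      spectra = 8L, n_channels = 30L)
  plan <- cv_plan(n_folds = 3, seed = 2)
  # singleton sweep selects that dimension
  sw <- suppressWarnings(
    dim_sweep(ds, model_combo(dr_spec("PCA"), clf_spec("GNB")), dims = 4L,
              plan = plan))
  expect_equal(sw$selected, 4L)
  # LDA on the 4-class stage task caps at 3: dim 5 is skipped with a warning
  expect_warning(
    sw2 <- dim_sweep(ds, model_combo(dr_spec("LDA"), clf_spec("LR")),
                     dims = c(2L, 3L, 5L), plan = plan, task = "G_step"),
    "skipped")
  expect_setequal(sw2$results$dim, c(2L, 3L))
})

test_that("extend_reference merges, relabels at genus level and rebalances", {
  base_cfg <- small_config(n_strains = 8L,
                           genus_partition = c(2L, 2L, 2L, 2L),
                           spectra = 10L, n_channels = 40L, seed = 41L)
  base <- generate_dataset(make_taxonomy(base_cfg), base_cfg)
  extra_cfg <- small_config(n_strains = 2L, genus_partition = c(1L, 1L),
                            spectra = 10L, n_channels = 40L, seed = 43L)
  extra <- generate_dataset(make_taxonomy(extra_cfg), extra_cfg)
  extra$labels$genus <- paste0("new_", extra$labels$genus)
  extra$labels$strain <- paste0("new_", extra$labels$strain)
  ext <- extend_reference(base, extra, quota = 30L, seed = 1L)
  expect_equal(length(unique(ext$labels$genus)), 6L)
  expect_true(all(table(ext$labels$genus) == 30L))
  expect_identical(extend_reference(base, extra, quota = 30L, seed = 1L)$labels,
                   ext$labels)
  # quota = available for every genus -> a permutation of the input rows
  eq_cfg <- small_config(n_strains = 4L, genus_partition = rep(1L, 4L),
                         spectra = 10L, n_channels = 40L, seed = 47L)
  eq_base <- generate_dataset(make_taxonomy(eq_cfg), eq_cfg)   # 40 rows/genus
  ext_all <- extend_reference(eq_base, extra, quota = 40L, seed = 2L)
  expect_equal(sort(unname(rowSums(ext_all$intensities))),
               sort(unname(rowSums(rbind(eq_base$intensities,
                                         extra$intensities)))))
  # over-quota genera are upsampled with replacement, under a warning each
  w <- testthat::capture_warnings(
    up <- extend_reference(base, extra, quota = 100L, seed = 3L))
  expect_true(all(grepl("replacement", w)))
  expect_true(all(table(up$labels$genus) == 100L))
  bad <- extra; bad$grid <- extra$grid + 1
  expect_error(extend_reference(base, bad, quota = 10L), "grids")
})

test_that("test-fold label permutation leaves the fold's fitted model unchanged", {
  ds <- small_dataset(seed = 45L, n_strains = 4L, genus_partition = c(2L, 1L, 1L),
                      spectra = 8L, n_channels = 30L)
  plan <- cv_plan(n_folds = 2, seed = 3)
  folds <- make_folds(ds$labels$strain, plan)
  combo <- model_combo(dr_spec("PCA", out_dim = 4), clf_spec("LR"))
  r1 <- evaluate_combo(combo, ds, "T_only", plan, folds = folds,
                       keep_models = TRUE)
  ds_perm <- ds
  te1 <- folds[[1]] == 1L
  ds_perm$labels$strain[te1] <- with_seed <- sample(ds$labels$strain[te1])
  r2 <- evaluate_combo(combo, ds_perm, "T_only", plan, folds = folds,
                       keep_models = TRUE)
  expect_equal(r1$models[[1]], r2$models[[1]])   # fold-1 model: trained without fold 1
  expect_false(isTRUE(all.equal(r1$models[[2]], r2$models[[2]])))
})
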