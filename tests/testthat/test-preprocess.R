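# Preprocessing: background subtraction, Savitzky-Golay smoothing, ALS
# baseline correction, normalization, resampling, and the pipeline runner.

flat_ds <- function(rows) {
  scrs_dataset(grid = seq_len(ncol(rows)) + 500, intensities = rows,
               labels = data.frame(cell_id = paste0("c", seq_len(nrow(rows))),
                                   strain = "s", genus = "g", phylum = "p",
                                   stage = "Exp"))
}

test_that("subtract_background is elementwise and validates the grid", {
  ds <- flat_ds(matrix(c(5, 6, 7), nrow = 1))
  expect_equal(unname(subtract_background(ds, c(1, 1, 1))$intensities[1, ]),
               c(4, 5, 6))
  expect_equal(unname(subtract_background(ds, c(5, 6, 7))$intensities[1, ]),
               c(0, 0, 0))
  expect_equal(subtract_background(ds, c(0, 0, 0))$intensities, ds$intensities)
  expect_error(subtract_background(ds, c(1, 1)), "channels")
})

test_that("smoothing leaves constants unchanged and interpolates exactly at high order", {
  const <- flat_ds(matrix(3.5, nrow = 2, ncol = 30))
  expect_equal(smooth_spectra(const, 11, 3)$intensities, const$intensities)
  set.seed(1)
  wiggly <- flat_ds(matrix(rnorm(30), nrow = 1))
  # polyorder = window - 1 reproduces the input exactly
  expect_equal(smooth_spectra(wiggly, 5, 4)$intensities, wiggly$intensities,
               tolerance = 1e-8)
  expect_error(smooth_spectra(wiggly, 4, 2), "odd")
  expect_error(smooth_spectra(wiggly, 5, 5), "polyorder")
  expect_error(smooth_spectra(wiggly, 31, 2), "channels")
})

test_that("smoothing reduces deviation from a clean signal under white noise", {
  set.seed(42)
  n <- 200
  clean <- sin(seq(0, 4 * pi, length.out = n))
  noisy <- clean + rnorm(n, 0, 0.3)
  sm <- smooth_spectra(flat_ds(matrix(noisy, nrow = 1)), 11, 3)$intensities[1, ]
  expect_lt(mean((sm - clean)^2), mean((noisy - clean)^2))
})

test_that("baseline correction removes lines, preserves zero, recovers peaks", {
  x <- seq_len(100)
  line <- flat_ds(matrix(2 + 0.05 * x, nrow = 1))
  corrected <- baseline_correct(line)$intensities[1, ]
  expect_lt(max(abs(corrected)), 1e-6 * diff(range(line$intensities)))
  zero <- flat_ds(matrix(0, nrow = 1, ncol = 100))
  expect_equal(unname(baseline_correct(zero)$intensities[1, ]), rep(0, 100))
  # Gaussian peak of known height on a linear baseline
  peak <- 2.0 * exp(-0.5 * ((x - 50) / 5)^2)
  ds <- flat_ds(matrix(peak + 1 + 0.02 * x, nrow = 1))
  rec <- baseline_correct(ds)$intensities[1, ]
  expect_lt(abs(max(rec) - 2.0) / 2.0, 0.05)
})

test_that("baseline correction is near-idempotent", {
  set.seed(7)
  x <- seq_len(120)
  ds <- flat_ds(matrix(exp(-0.5 * ((x - 60) / 8)^2) + 0.5 + 0.01 * x, nrow = 1))
  once <- baseline_correct(ds)
  twice <- baseline_correct(once)
  expect_lt(max(abs(twice$intensities - once$intensities)), 0.02)
})

test_that("baseline correction rejects invalid inputs", {
  ds <- flat_ds(matrix(c(1, NA, 3), nrow = 1))
  expect_error(baseline_correct(ds), "non-finite")
  ok <- flat_ds(matrix(1:10, nrow = 1))
  expect_error(baseline_correct(ok, lam = 0), "lam")
  expect_error(baseline_correct(ok, p = 1.2), "p")
})

test_that("normalization modes behave as documented", {
  ds <- flat_ds(matrix(c(3, 4, 0, 0), nrow = 1, ncol = 4, byrow = TRUE))
  expect_equal(unname(normalize(ds, "vector_norm")$intensities[1, ]),
               c(0.6, 0.8, 0, 0))
  pos <- flat_ds(matrix(c(1, 2, 3, 4), nrow = 1))
  expect_equal(sum(normalize(pos, "area")$intensities), 1)
  expect_equal(max(normalize(pos, "max")$intensities), 1)
  zero <- flat_ds(matrix(0, nrow = 2, ncol = 3))
  expect_error(normalize(zero), "c1")
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  ds <- scrs_dataset(grid = c(0, 2), intensities = matrix(c(1, 3), nrow = 1),
                     labels = data.frame(cell_id = "c1", strain = "s",
                                         genus = "g", phylum = "p", stage = "Exp"))
  out <- resample(ds, c(0, 1, 2))
  expect_equal(unname(out$intensities[1, ]), c(1, 2, 3))
  ident <- flat_ds(matrix(rnorm(20), nrow = 2))
  expect_equal(resample(ident, ident$grid)$intensities, ident$intensities)
  # any linear spectrum resamples exactly anywhere inside the range
  lin <- flat_ds(matrix(2 * (1:20) + 1, nrow = 1))
  tg <- seq(min(lin$grid) + 0.3, max(lin$grid) - 0.3, length.out = 7)
  expect_equal(unname(resample(lin, tg)$intensities[1, ]),
               2 * (tg - 500) + 1, tolerance = 1e-12)
  expect_error(resample(ds, c(-1, 1)), "extrapolation")
})

test_that("preprocess_pipeline applies steps in order with provenance", {
  set.seed(5)
  ds <- flat_ds(matrix(abs(rnorm(60)) + 1, nrow = 2))
  expect_equal(preprocess_pipeline(ds, list()), ds)
  out <- preprocess_pipeline(ds, list(list(step = "baseline_correct", lam = 1e4),
                                      list(step = "normalize", mode = "vector_norm")))
  expect_equal(unname(sqrt(rowSums(out$intensities^2))), c(1, 1))
  prov <- attr(out, "provenance")
  expect_equal(vapply(prov, `[[`, character(1), "step"),
               c("baseline_correct", "normalize"))
  expect_error(preprocess_pipeline(ds, list(list(step = "despike"))), "unknown")
  expect_error(preprocess_pipeline(ds, list(list(step = "smooth", bogus = 1))),
               "unknown parameter")
})

test_that("all preprocessing ops preserve row count, labels and grid", {
  ds <- small_dataset(seed = 9L)
  for (out in list(subtract_background(ds, numeric(length(ds$grid))),
                   smooth_spectra(ds), baseline_correct(ds), normalize(ds))) {
    expect_equal(dim(out$intensities), dim(ds$intensities))
    expect_equal(out$labels, ds$labels)
    expect_equal(out$grid, ds$grid)
  }
})
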