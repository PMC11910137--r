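# Spectral preprocessing: background subtraction, Savitzky-Golay smoothing,
# asymmetric-least-squares (ALS) baseline correction, per-spectrum
# normalization, linear resampling, and an ordered pipeline runner. All steps
# preserve cell order and labels; only resample() changes the grid.

record_step <- function(out, input, step, params) {
  prov <- attr(input, "provenance") %||% list()
  prov[[length(prov) + 1L]] <- c(list(step = step), params)
  attr(out, "provenance") <- prov
  out
}

#' Subtract a background spectrum from every cell
#'
#' @param ds An [scrs_dataset].
#' @param background Numeric vector on the same grid as `ds`.
#' @return The background-subtracted [scrs_dataset].
#' @export
subtract_background <- function(ds, background) {
  stopifnot(inherits(ds, "scrs_dataset"))
  background <- as.numeric(background)
  if (length(background) != length(ds$grid)) {
    stop("background has ", length(background), " channels but dataset grid has ",
         length(ds$grid))
  }
  out <- scrs_dataset(ds$grid, sweep(ds$intensities, 2L, background, "-"), ds$labels)
  record_step(out, ds, "subtract_background", list())
}

#' Savitzky-Golay smoothing per spectrum
#'
#' @param ds An [scrs_dataset].
#' @param window Odd filter length in channels (> `polyorder`, <= channels).
#' @param polyorder Polynomial order of the local fit.
#' @return The smoothed [scrs_dataset].
#' @export
smooth_spectra <- function(ds, window = 11L, polyorder = 3L) {
  stopifnot(inherits(ds, "scrs_dataset"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("`window` must be odd, got ", window)
  if (polyorder >= window) stop("`polyorder` must be < window")
  if (window > length(ds$grid)) stop("`window` exceeds the number of channels")
  ints <- t(apply(ds$intensities, 1L, signal::sgolayfilt,
                  p = polyorder, n = window))
  out <- scrs_dataset(ds$grid, ints, ds$labels)
  record_step(out, ds, "smooth", list(window = window, polyorder = polyorder))
}

# ALS baseline of a single spectrum (Eilers-style asymmetric least squares):
# iteratively reweighted smoothing spline with penalty lam on the second
# difference and asymmetry p (points above the baseline get weight p).
als_baseline <- function(y, lam, p, n_iter) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2L, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  DtD <- lam * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(n_iter)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w) && it > 1L) break
    w <- w_new
  }
  z
}

#' Asymmetric-least-squares baseline correction
#'
#' Estimates a smooth baseline under each spectrum by asymmetric least
#' squares (second-difference penalty `lam`, asymmetry `p`) and subtracts it.
#'
#' @param ds An [scrs_dataset] with finite intensities.
#' @param lam Smoothness weight (> 0); larger gives a stiffer baseline.
#' @param p Asymmetry in (0, 1); small values let peaks sit above the baseline.
#' @param n_iter Reweighting iterations.
#' @return The baseline-corrected [scrs_dataset].
#' @export
baseline_correct <- function(ds, lam = 1e5, p = 0.01, n_iter = 10L) {
  stopifnot(inherits(ds, "scrs_dataset"))
  if (lam <= 0) stop("`lam` must be > 0")
  if (p <= 0 || p >= 1) stop("`p` must be in (0, 1)")
  if (any(!is.finite(ds$intensities))) stop("non-finite intensities; clean the data first")
  ints <- t(apply(ds$intensities, 1L, function(y) y - als_baseline(y, lam, p, n_iter)))
  out <- scrs_dataset(ds$grid, ints, ds$labels)
  record_step(out, ds, "baseline_correct", list(lam = lam, p = p, n_iter = n_iter))
}

#' Per-spectrum normalization
#'
#' @param ds An [scrs_dataset].
#' @param mode `"vector_norm"` (unit Euclidean norm), `"area"` (divide by the
#'   sum; sums to 1 on nonnegative input) or `"max"` (unit maximum).
#' @return The normalized [scrs_dataset].
#' @export
normalize <- function(ds, mode = c("vector_norm", "area", "max")) {
  stopifnot(inherits(ds, "scrs_dataset"))
  mode <- match.arg(mode)
  sc <- switch(mode,
               vector_norm = sqrt(rowSums(ds$intensities^2)),
               area = rowSums(ds$intensities),
               max = apply(ds$intensities, 1L, max))
  zero <- which(abs(sc) < .Machine$double.eps)
  if (length(zero)) {
    stop("cannot normalize all-zero spectrum for cell_id: ",
         paste(ds$labels$cell_id[zero], collapse = ", "))
  }
  out <- scrs_dataset(ds$grid, ds$intensities / sc, ds$labels)
  record_step(out, ds, "normalize", list(mode = mode))
}

#' Resample spectra onto a new wavenumber grid (linear interpolation)
#'
#' @param ds An [scrs_dataset].
#' @param target Strictly increasing numeric grid within the source range;
#'   extrapolation is refused.
#' @return An [scrs_dataset] on `target`.
#' @export
resample <- function(ds, target) {
  stopifnot(inherits(ds, "scrs_dataset"))
  target <- as.numeric(target)
  if (length(target) < 2L || any(diff(target) <= 0)) {
    stop("`target` must be a strictly increasing grid of length >= 2")
  }
  if (min(target) < min(ds$grid) || max(target) > max(ds$grid)) {
    stop("target grid extends beyond the source range; extrapolation refused")
  }
  ints <- t(apply(ds$intensities, 1L, function(y) {
    stats::approx(ds$grid, y, xout = target, method = "linear")$y
  }))
  out <- scrs_dataset(target, ints, ds$labels)
  record_step(out, ds, "resample", list(n_channels = length(target)))
}

#' Run an ordered preprocessing pipeline
#'
#' @param ds An [scrs_dataset].
#' @param steps A list of steps, each a list with `step` (one of
#'   `"subtract_background"`, `"smooth"`, `"baseline_correct"`, `"normalize"`,
#'   `"resample"`) plus that step's parameters. The conventional full protocol
#'   is background -> smooth -> baseline -> normalize.
#' @return The processed [scrs_dataset]; applied steps (with parameters) are
#'   recorded in `attr(, "provenance")`.
#' @export
preprocess_pipeline <- function(ds, steps = list()) {
  stopifnot(inherits(ds, "scrs_dataset"))
  known <- list(subtract_background = subtract_background,
                smooth = smooth_spectra,
                baseline_correct = baseline_correct,
                normalize = normalize,
                resample = resample)
  for (s in steps) {
    if (is.null(s$step) || !s$step %in% names(known)) {
      stop("unknown preprocessing step: ", deparse(s$step %||% "<missing>"),
           " (known: ", paste(names(known), collapse = ", "), ")")
    }
    args <- s[setdiff(names(s), "step")]
    fn <- known[[s$step]]
    ok <- setdiff(names(args), names(formals(fn)))
    if (length(ok)) stop("unknown parameter(s) for ", s$step, ": ",
                         paste(ok, collapse = ", "))
    ds <- do.call(fn, c(list(ds), args))
  }
  ds
}
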