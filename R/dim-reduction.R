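# Dimensionality reduction behind a single fit/transform interface.
#
#   NONE     identity (classifier sees full spectra)
#   PCA      principal component analysis (unsupervised, linear)
#   KPCA     kernel PCA, RBF kernel (unsupervised, nonlinear)
#   LDA      linear discriminant analysis (supervised, linear)
#   SUP_PCA  supervised PCA: leading eigenvectors of the label-kernel-weighted
#            covariance X_c' L_c X_c with L_c the centered one-hot label kernel
#   ISM_SDR  iterative spectral supervised DR: alternate (a) eigendecomposition
#            of a label-dependence-weighted scatter matrix and (b) RBF kernel
#            scale update, until the projection subspace stabilizes
#
# Supervised methods require a label field; unsupervised methods ignore it.

#' Names of the available dimensionality-reduction methods
#' @return Character vector of registry names.
#' @export
dr_methods <- function() c("NONE", "PCA", "KPCA", "LDA", "SUP_PCA", "ISM_SDR")

#' Specify a dimensionality-reduction method
#'
#' @param method One of [dr_methods()].
#' @param out_dim Target dimensionality (ignored by `NONE`). Defaults to 35,
#'   the package default for taxonomy tasks; use 3 for a 4-class
#'   growth-stage task (the LDA maximum there).
#' @param kernel_scale Positive RBF length scale for `KPCA`/`ISM_SDR`;
#'   `NULL` uses the median pairwise distance heuristic at fit time.
#' @param kernel `"rbf"` (default) or `"linear"`, for `KPCA` only.
#' @return A `dr_spec` object.
#' @export
dr_spec <- function(method, out_dim = 35L, kernel_scale = NULL, kernel = "rbf") {
  method <- match.arg(method, dr_methods())
  out_dim <- as.integer(out_dim)
  if (out_dim < 1L) stop("out_dim must be >= 1")
  if (!is.null(kernel_scale) && kernel_scale <= 0) stop("kernel_scale must be > 0")
  structure(list(method = method, out_dim = out_dim,
                 kernel_scale = kernel_scale, kernel = kernel,
                 supervised = method %in% c("LDA", "SUP_PCA", "ISM_SDR")),
            class = "dr_spec")
}

#' @export
print.dr_spec <- function(x, ...) {
  cat(sprintf("<dr_spec> %s (out_dim=%d, %s)\n", x$method, x$out_dim,
              if (x$supervised) "supervised" else "unsupervised"))
  invisible(x)
}

median_dist <- function(X, max_n = 500L) {
  n <- nrow(X)
  if (n > max_n) X <- X[seq(1L, n, length.out = max_n), , drop = FALSE]
  d <- stats::dist(X)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

# Raman channels are strongly collinear by nature (smooth bands); MASS::lda
# handles this through its tolerance but warns every time. Silence only that.
lda_quiet <- function(...) {
  withCallingHandlers(MASS::lda(...), warning = function(w) {
    if (grepl("collinear", conditionMessage(w))) invokeRestart("muffleWarning")
  })
}

fix_signs <- function(V) {
  # deterministic orientation: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

one_hot <- function(y) {
  y <- factor(y)
  Y <- matrix(0, length(y), nlevels(y))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

#' Fit a dimensionality reduction on a dataset
#'
#' @param spec A [dr_spec()].
#' @param ds An [scrs_dataset], or a numeric feature matrix.
#' @param label_field For supervised methods: `"strain"`, `"genus"` or
#'   `"stage"` when `ds` is a dataset, or a label vector when `ds` is a
#'   matrix. Ignored by unsupervised methods.
#' @return A `fitted_dr` object usable with [transform_dr()].
#' @export
fit_dr <- function(spec, ds, label_field = NULL) {
  stopifnot(inherits(spec, "dr_spec"))
  if (inherits(ds, "scrs_dataset")) {
    X <- ds$intensities
    y <- if (!is.null(label_field) && is.character(label_field) &&
             length(label_field) == 1L) {
      if (!label_field %in% names(ds$labels)) stop("unknown label field: ", label_field)
      ds$labels[[label_field]]
    } else label_field
    grid <- ds$grid
  } else {
    X <- as.matrix(ds)
    y <- label_field
    grid <- NULL
  }
  if (spec$supervised && is.null(y)) {
    stop(spec$method, " is supervised and requires a label_field")
  }
  fit <- fit_dr_matrix(spec, X, y)
  fit$grid <- grid
  fit
}

fit_dr_matrix <- function(spec, X, y = NULL) {
  p <- ncol(X)
  d <- spec$out_dim
  if (spec$method != "NONE" && d > p) {
    stop("out_dim (", d, ") exceeds the number of channels (", p, ")")
  }
  fit <- list(spec = spec, p = p)
  fit$out_dim <- if (spec$method == "NONE") p else d
  if (spec$method == "NONE") {
    # identity map
  } else if (spec$method == "PCA") {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = d)
    fit$center <- pc$center
    fit$proj <- fix_signs(pc$rotation[, seq_len(d), drop = FALSE])
  } else if (spec$method == "KPCA") {
    kern <- if (identical(spec$kernel, "linear")) kernlab::vanilladot() else {
      scale <- spec$kernel_scale %||% median_dist(X)
      kernlab::rbfdot(sigma = 1 / (2 * scale^2))
    }
    fit$kpca <- kernlab::kpca(X, kernel = kern, features = d)
    # rescale scores to the PCA convention (unit-norm feature-space loadings),
    # so a linear-kernel KPCA reproduces PCA scores exactly
    fit$kpca_scale <- sqrt(nrow(X))
  } else if (spec$method == "LDA") {
    y <- factor(y)
    k <- nlevels(y)
    if (d > k - 1L) {
      stop(sprintf("LDA admits at most n_classes - 1 = %d output dimensions for a %d-class task (requested %d)",
                   k - 1L, k, d))
    }
    fit$lda <- lda_quiet(X, grouping = y)
  } else if (spec$method == "SUP_PCA") {
    y <- factor(y)
    ctr <- colMeans(X)
    Xc <- sweep(X, 2L, ctr)
    Yc <- scale(one_hot(y), center = TRUE, scale = FALSE)
    A <- crossprod(Xc, Yc)                    # p x k
    Q <- tcrossprod(A)                        # X_c' L_c X_c with L = Y Y'
    ev <- eigen(Q, symmetric = TRUE)
    fit$center <- ctr
    fit$proj <- fix_signs(ev$vectors[, seq_len(d), drop = FALSE])
  } else if (spec$method == "ISM_SDR") {
    fit <- c(fit, ism_sdr_fit(X, y, d, spec$kernel_scale))
  }
  class(fit) <- "fitted_dr"
  fit
}

# Iterative spectral supervised DR. Objective: choose an orthonormal basis W
# maximizing the RBF-kernel dependence between projected points and the
# centered label kernel Gamma = L_c (one-hot labels). At fixed kernel, the
# first-order condition makes W the top eigenvectors of the weighted scatter
#   Phi = X_c' (A - diag(rowSums(A))) X_c,   A = Gamma * K_Z (elementwise),
# where K_Z is the RBF kernel of the projected data; the kernel scale is then
# refreshed to the median pairwise projected distance. Iterate to a fixed
# subspace (change in projector Frobenius norm < 1e-6) or 100 iterations.
ism_sdr_fit <- function(X, y, d, kernel_scale = NULL, max_iter = 100L,
                        tol = 1e-6) {
  y <- factor(y)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  Gamma <- tcrossprod(scale(one_hot(y), center = TRUE, scale = FALSE))
  pc <- stats::prcomp(Xc, center = FALSE, rank. = d)
  W <- pc$rotation[, seq_len(d), drop = FALSE]
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    Z <- Xc %*% W
    scale_it <- kernel_scale %||% median_dist(Z)
    D2 <- as.matrix(stats::dist(Z))^2
    K <- exp(-D2 / (2 * scale_it^2))
    A <- Gamma * K
    Lap <- A - diag(rowSums(A))
    Phi <- crossprod(Xc, Lap %*% Xc)
    Phi <- (Phi + t(Phi)) / 2
    ev <- eigen(Phi, symmetric = TRUE)
    W_new <- fix_signs(ev$vectors[, seq_len(d), drop = FALSE])
    delta <- norm(tcrossprod(W_new) - tcrossprod(W), type = "F")
    W <- W_new
    if (delta < tol) break
  }
  list(center = ctr, proj = W, kernel_scale_final = scale_it, iterations = iters)
}

#' Project a dataset through a fitted dimensionality reduction
#'
#' @param fit A `fitted_dr` from [fit_dr()].
#' @param ds An [scrs_dataset] on the training grid, or a feature matrix with
#'   the training dimensionality.
#' @return If `ds` is a dataset, an `scrs_features` object (list with
#'   `features` matrix of `out_dim` columns and the original `labels`);
#'   if a matrix, the projected matrix.
#' @export
transform_dr <- function(fit, ds) {
  stopifnot(inherits(fit, "fitted_dr"))
  if (inherits(ds, "scrs_dataset")) {
    if (!is.null(fit$grid) && !same_grid(fit$grid, ds)) {
      stop("dataset grid differs from the grid the DR was fitted on")
    }
    Z <- transform_dr_matrix(fit, ds$intensities)
    return(structure(list(features = Z, labels = ds$labels),
                     class = "scrs_features"))
  }
  transform_dr_matrix(fit, as.matrix(ds))
}

transform_dr_matrix <- function(fit, X) {
  if (ncol(X) != fit$p) {
    stop("feature dimensionality (", ncol(X), ") differs from training (", fit$p, ")")
  }
  m <- fit$spec$method
  if (m == "NONE") return(X)
  if (m == "KPCA") return(kernlab::predict(fit$kpca, X) / fit$kpca_scale)
  if (m == "LDA") {
    Z <- stats::predict(fit$lda, X)$x
    return(Z[, seq_len(min(fit$out_dim, ncol(Z))), drop = FALSE])
  }
  sweep(X, 2L, fit$center) %*% fit$proj
}

#' Euclidean distance between two class centroids in a reduced space
#'
#' Used to quantify how far apart a DR places two (possibly overlapping)
#' classes: supervised DR is expected to place hard-to-separate strain pairs
#' farther apart than unsupervised DR.
#'
#' @param reduced An `scrs_features` object from [transform_dr()].
#' @param label_field Column of the label table defining the classes.
#' @param class_a,class_b The two class labels.
#' @return Nonnegative distance.
#' @export
class_centroid_distance <- function(reduced, label_field, class_a, class_b) {
  stopifnot(inherits(reduced, "scrs_features"))
  y <- reduced$labels[[label_field]]
  if (is.null(y)) stop("unknown label field: ", label_field)
  ia <- y == class_a; ib <- y == class_b
  if (!any(ia)) stop("class not present: ", class_a)
  if (!any(ib)) stop("class not present: ", class_b)
  ca <- colMeans(reduced$features[ia, , drop = FALSE])
  cb <- colMeans(reduced$features[ib, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}
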