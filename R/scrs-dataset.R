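#' @keywords internal
"_PACKAGE"

#' Growth-stage labels used throughout the package
#'
#' Cells are sampled in exponential phase (`Exp`) and at the beginning (`S1`),
#' mid-point (`S2`) and end (`S3`) of the stationary phase. Spectra without a
#' known growth stage (e.g. environmental cells) carry the sentinel
#' [STAGE_UNKNOWN] instead of an empty string.
#'
#' @export
STAGE_LEVELS <- c("Exp", "S1", "S2", "S3")

#' @rdname STAGE_LEVELS
#' @export
STAGE_UNKNOWN <- "unknown"

#' Construct a validated SCRS dataset
#'
#' An `scrs_dataset` bundles an intensity matrix (cells x wavenumber channels)
#' with its shared wavenumber grid and a per-cell label table. It is the
#' container every other function in the package consumes and returns.
#'
#' @param grid Numeric vector of wavenumbers (cm^-1), strictly increasing,
#'   length >= 2.
#' @param intensities Numeric matrix, one row per cell, `length(grid)` columns.
#' @param labels `data.frame` with columns `cell_id`, `strain`, `genus`,
#'   `phylum`, `stage`; one row per cell, `cell_id` unique. `stage` must be one
#'   of [STAGE_LEVELS] or the sentinel [STAGE_UNKNOWN].
#'
#' @return An object of class `scrs_dataset`: a list with elements `grid`,
#'   `intensities` and `labels`.
#' @export
scrs_dataset <- function(grid, intensities, labels) {
  grid <- as.numeric(grid)
  if (length(grid) < 2L || any(!is.finite(grid)) || any(diff(grid) <= 0)) {
    stop("`grid` must be a strictly increasing numeric vector of length >= 2")
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) == 0L) stop("dataset must contain at least one spectrum")
  if (ncol(intensities) != length(grid)) {
    stop(sprintf("intensity matrix has %d columns but grid has %d channels",
                 ncol(intensities), length(grid)))
  }
  labels <- validate_labels(labels, n = nrow(intensities))
  rownames(intensities) <- labels$cell_id
  structure(list(grid = grid, intensities = intensities, labels = labels),
            class = "scrs_dataset")
}

validate_labels <- function(labels, n) {
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  need <- c("cell_id", "strain", "genus", "phylum", "stage")
  miss <- setdiff(need, names(labels))
  if (length(miss)) stop("labels missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(labels) != n) {
    stop(sprintf("labels have %d rows but intensity matrix has %d", nrow(labels), n))
  }
  for (col in need) labels[[col]] <- as.character(labels[[col]])
  if (anyDuplicated(labels$cell_id)) stop("duplicate cell_id in labels")
  if (any(labels$stage == "" | is.na(labels$stage))) {
    stop("stage must never be empty; use STAGE_UNKNOWN for unlabelled cells")
  }
  bad <- setdiff(unique(labels$stage), c(STAGE_LEVELS, STAGE_UNKNOWN))
  if (length(bad)) {
    stop("invalid stage label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(STAGE_LEVELS, collapse = "/"), " or '",
         STAGE_UNKNOWN, "')")
  }
  rownames(labels) <- NULL
  labels[need]
}

#' @export
print.scrs_dataset <- function(x, ...) {
  cat(sprintf("<scrs_dataset> %d cells x %d channels (%.1f-%.1f cm^-1)\n",
              nrow(x$intensities), length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  strains: %d | genera: %d | phyla: %d | stages: %s\n",
              length(unique(x$labels$strain)), length(unique(x$labels$genus)),
              length(unique(x$labels$phylum)),
              paste(sort(unique(x$labels$stage)), collapse = ",")))
  invisible(x)
}

#' @export
dim.scrs_dataset <- function(x) dim(x$intensities)

#' Subset an SCRS dataset by cell (row)
#'
#' @param ds An [scrs_dataset].
#' @param idx Integer or logical index over cells.
#' @return An [scrs_dataset] restricted to the selected cells.
#' @export
subset_cells <- function(ds, idx) {
  stopifnot(inherits(ds, "scrs_dataset"))
  ints <- ds$intensities[idx, , drop = FALSE]
  if (nrow(ints) == 0L) stop("subset selects zero cells")
  scrs_dataset(ds$grid, ints, ds$labels[idx, , drop = FALSE])
}

#' Check whether two datasets share a wavenumber grid
#' @param a,b [scrs_dataset] objects (or numeric grids).
#' @return `TRUE`/`FALSE`.
#' @keywords internal
same_grid <- function(a, b) {
  ga <- if (inherits(a, "scrs_dataset")) a$grid else as.numeric(a)
  gb <- if (inherits(b, "scrs_dataset")) b$grid else as.numeric(b)
  length(ga) == length(gb) && all(ga == gb)
}

# Deterministic sub-seed derivation: one master seed fans out to independent
# substreams (per strain x stage, per fold, ...) while staying < 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in idx) s <- (s * 48271 + as.double(k) + 1) %% 2147483629
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
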