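# On-disk format: a CSV intensity matrix whose header row carries the shared
# wavenumber grid (first column = cell_id) and a TSV label table
# (cell_id, strain, genus, phylum, stage). UTF-8, dot decimal separator.
# Values are written at full double precision so read(write(ds)) == ds.

#' Write an SCRS dataset to a CSV matrix plus TSV labels
#'
#' @param ds An [scrs_dataset].
#' @param path Output CSV path for the intensity matrix (first column
#'   `cell_id`, remaining column names are the wavenumbers).
#' @param labels_path Output TSV path for the label table.
#' @return Invisibly, `ds`.
#' @export
write_matrix <- function(ds, path, labels_path) {
  stopifnot(inherits(ds, "scrs_dataset"))
  header <- paste(c("cell_id", sprintf("%.17g", ds$grid)), collapse = ",")
  rows <- vapply(seq_len(nrow(ds$intensities)), function(i) {
    paste(c(ds$labels$cell_id[i], sprintf("%.17g", ds$intensities[i, ])),
          collapse = ",")
  }, character(1))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(c(header, rows), con)
  lcon <- file(labels_path, open = "w", encoding = "UTF-8")
  on.exit(close(lcon), add = TRUE)
  utils::write.table(ds$labels, lcon, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "")
  invisible(ds)
}

#' Read an SCRS dataset from a CSV matrix plus TSV labels
#'
#' Cells are returned in the order of the labels file; the matrix and label
#' `cell_id` sets must match exactly.
#'
#' @param path CSV intensity matrix as written by [write_matrix()].
#' @param labels_path TSV label table.
#' @return An [scrs_dataset].
#' @export
read_matrix <- function(path, labels_path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("matrix file has no data rows: ", path)
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  grid <- suppressWarnings(as.numeric(hdr[-1]))
  if (any(is.na(grid))) stop("non-numeric wavenumber in header of ", path)
  if (any(diff(grid) <= 0)) stop("wavenumber grid is not strictly increasing in ", path)
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  ncol_ok <- vapply(parts, length, integer(1)) == length(hdr)
  if (!all(ncol_ok)) stop("ragged rows in ", path)
  ids <- vapply(parts, `[[`, character(1), 1L)
  ints <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  labels <- utils::read.delim(labels_path, sep = "\t", header = TRUE,
                              colClasses = "character", encoding = "UTF-8")
  if (!setequal(ids, labels$cell_id) || nrow(labels) != length(ids)) {
    stop("cell_id mismatch between matrix and labels: ",
         length(ids), " matrix rows vs ", nrow(labels), " label rows")
  }
  ord <- match(labels$cell_id, ids)
  scrs_dataset(grid, ints[ord, , drop = FALSE], labels)
}

#' Read a directory of per-spectrum two-column text files
#'
#' Each file holds one spectrum as two whitespace- or comma-separated columns
#' (wavenumber, intensity). All files must share an identical grid; files with
#' different grids are rejected rather than silently resampled (use
#' [resample()] after reading compatible subsets). File base names become
#' `cell_id`s; taxonomy labels are unknown (`"unknown"`) and stage is the
#' [STAGE_UNKNOWN] sentinel.
#'
#' @param dir Directory of text files (`.txt`, `.csv`, `.tsv`, `.dat`).
#' @return An [scrs_dataset].
#' @export
read_two_column <- function(dir) {
  files <- list.files(dir, pattern = "\\.(txt|csv|tsv|dat)$", full.names = TRUE)
  if (length(files) == 0L) stop("no spectrum files found in ", dir)
  read_one <- function(f) {
    tab <- utils::read.table(f, header = FALSE, sep = "",
                             col.names = c("wavenumber", "intensity"),
                             colClasses = "numeric", comment.char = "#")
    if (nrow(tab) == 0L) stop("empty spectrum file: ", f)
    tab
  }
  first <- read_one(files[1])
  grid <- first$wavenumber
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("wavenumber grid not strictly increasing in ", files[1])
  }
  ints <- matrix(0, nrow = length(files), ncol = length(grid))
  ints[1, ] <- first$intensity
  for (i in seq_along(files)[-1]) {
    tab <- read_one(files[i])
    if (length(tab$wavenumber) != length(grid) || any(tab$wavenumber != grid)) {
      stop("grid in ", files[i], " differs from ", files[1],
           "; read compatible groups separately and use resample()")
    }
    ints[i, ] <- tab$intensity
  }
  ids <- sub("\\.[^.]+$", "", basename(files))
  scrs_dataset(grid, ints,
               data.frame(cell_id = ids, strain = "unknown", genus = "unknown",
                          phylum = "unknown", stage = STAGE_UNKNOWN,
                          stringsAsFactors = FALSE))
}

#' Write a synthetic-generator config as YAML
#' @param config A [synthetic_config()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  raw <- unclass(config)
  raw$stage_jitter_scale <- as.list(raw$stage_jitter_scale)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Read a synthetic-generator config from YAML
#' @param path YAML path as written by [write_config()].
#' @return A [synthetic_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$stage_jitter_scale <- unlist(raw$stage_jitter_scale)
  do.call(synthetic_config, raw)
}
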