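#' Read a multichannel sEMG recording from disk
#'
#' Two on-disk formats are supported, chosen by file extension:
#'
#' * **Delimited text** (`.csv`, `.txt`, `.tsv`): one row per time sample, one
#'   column per channel, comma-separated, with an optional header row of
#'   channel names. The sampling rate is not stored and must be supplied via
#'   `fs`.
#' * **JSON array container** (`.json`): a single object with keys `data`
#'   (channels-by-samples matrix), `fs`, and optional `channel_names`,
#'   `label`, `subject_id`, `annotations`. `fs` comes from the container; a
#'   caller-supplied `fs` must agree if given.
#'
#' Values are read exactly as stored; no scaling is applied and channel order
#' follows file column order.
#'
#' @param path Path to the file.
#' @param fs Sampling rate in Hz. Required for delimited text; optional
#'   (cross-checked) for the JSON container.
#' @return A [recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, fs = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    read_recording_json(path, fs)
  } else {
    read_recording_csv(path, fs)
  }
}

read_recording_csv <- function(path, fs) {
  if (is.null(fs)) {
    abort("Delimited-text recordings carry no sampling rate; supply `fs`.")
  }
  nf <- count.fields(path, sep = ",", blank.lines.skip = TRUE)
  if (length(nf) == 0L) abort(sprintf("'%s' is empty.", path))
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    abort(sprintf(
      "Ragged rows in '%s': row %d has %d fields, row 1 has %d.",
      path, bad, nf[bad], nf[1]))
  }
  first <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.csv(path, header = has_header,
                        colClasses = "character",
                        blank.lines.skip = TRUE, check.names = FALSE)
  mat <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  mat <- matrix(mat, nrow = nrow(df))
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Non-numeric cell in '%s' at data row %d, column %d ('%s').",
      path, idx[1], idx[2], df[[idx[2]]][idx[1]]))
  }
  nm <- if (has_header) trimws(first) else NULL
  recording(t(mat), fs = fs, channel_names = nm)
}

read_recording_json <- function(path, fs) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$data) || is.null(obj$fs)) {
    abort(sprintf("'%s' lacks required keys 'data' and 'fs'.", path))
  }
  if (!is.null(fs) && !isTRUE(all.equal(fs, obj$fs))) {
    abort(sprintf("Container fs (%g) disagrees with supplied fs (%g).",
                  obj$fs, fs))
  }
  obj$fs <- as.numeric(obj$fs)
  data <- obj$data
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  storage.mode(data) <- "double"
  ann <- obj$annotations
  if (!is.null(ann) && length(ann) == 0) ann <- NULL
  recording(data, fs = obj$fs,
            channel_names = obj$channel_names,
            label = obj$label, subject_id = obj$subject_id,
            annotations = ann)
}

#' Write a recording to disk
#'
#' The inverse of [read_recording()]: `.json` paths get the full array
#' container (matrix, fs, metadata, annotations); any other extension gets
#' delimited text (rows = time samples, columns = channels, header row of
#' channel names). Values are serialized at full double precision, so a
#' write/read round trip preserves every sample to better than 1e-12.
#'
#' @param x A [recording()].
#' @param path Output file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path) {
  stopifnot(inherits(x, "recording"))
  if (!dir.exists(dirname(path))) {
    abort(sprintf("Directory '%s' does not exist.", dirname(path)))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(data = x$data, fs = x$fs, channel_names = x$channel_names,
                label = x$label, subject_id = x$subject_id,
                annotations = x$annotations)
    jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                         digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  } else {
    tab <- t(x$data)
    colnames(tab) <- x$channel_names
    utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = TRUE),
                       path, sep = ",", row.names = FALSE, col.names = TRUE,
                       quote = FALSE)
  }
  invisible(path)
}
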