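#' Write a table as commented TSV
#'
#' Tab-separated export with optional `#`-prefixed header comment lines
#' recording parameter provenance; the dialect every reader in the package
#' accepts back.
#'
#' @param x data.frame to write.
#' @param path Output path.
#' @param comments Named character/numeric vector written as
#'   `# name: value` header lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(sprintf("# %s: %s", names(comments), as.character(comments)), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a commented TSV
#'
#' @param path Input path.
#' @return data.frame; `#` lines are skipped.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a luminescence trace and its metadata
#'
#' One file per trace with columns `time_s`, `counts`; the companion
#' metadata table carries `trace_id`, `discharge_counts`, `stimulus_time_s`
#' and `label`.
#'
#' @param path TSV file with columns `time_s`, `counts`.
#' @param meta One metadata row (data.frame or list) with
#'   `discharge_counts`, `stimulus_time_s` and optionally `label`.
#' @return A [luminescence_trace()].
#' @export
read_trace <- function(path, meta) {
  tab <- read_tsv(path)
  stopifnot(all(c("time_s", "counts") %in% names(tab)))
  luminescence_trace(tab$time_s, tab$counts,
                     discharge_counts = meta$discharge_counts,
                     stimulus_time = meta$stimulus_time_s,
                     label = if (!is.null(meta$label)) meta$label else "")
}

#' Write a luminescence trace (plus one metadata row)
#'
#' @param trace A [luminescence_trace()].
#' @param path Output TSV path for the `time_s`/`counts` table.
#' @return One-row data.frame of trace metadata (`discharge_counts`,
#'   `stimulus_time_s`, `label`), invisibly; bind rows across traces to
#'   build the metadata file.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "luminescence_trace"))
  write_tsv(data.frame(time_s = trace$times, counts = trace$counts), path)
  invisible(data.frame(discharge_counts = trace$discharge_counts,
                       stimulus_time_s = trace$stimulus_time,
                       label = trace$label, stringsAsFactors = FALSE))
}

#' Read a gene x sample count matrix
#'
#' Accepts the TSV dialect (first column `gene_id`, one column per sample)
#' or a MatrixMarket `.mtx` file with `<stem>.rownames` / `<stem>.colnames`
#' sidecar text files (one id per line; requires the Matrix package).
#'
#' @param path Path to `.tsv`/`.txt` or `.mtx`.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stop("reading MatrixMarket input requires the Matrix package")
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".rownames"))
    colnames(m) <- readLines(paste0(stem, ".colnames"))
    return(m)
  }
  tab <- read_tsv(path)
  stopifnot(names(tab)[1L] == "gene_id")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$gene_id
  m
}

#' Write a gene x sample count matrix as TSV
#'
#' @param counts Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @inheritParams write_tsv
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, comments = NULL) {
  write_tsv(cbind(data.frame(gene_id = rownames(counts)),
                  as.data.frame(counts)), path, comments = comments)
}
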