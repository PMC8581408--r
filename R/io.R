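# Plain-text interchange: counts and metadata as TSV (genes as rows, first
# column the gene id), waveform sessions as a manifest listing per-pulse
# single-column trace files plus the sampling rate.

#' Read / write a gene x sample count matrix as TSV
#'
#' First column holds gene ids, remaining columns one sample each, integer
#' cells. Comment lines starting with `#` are ignored on read and may be
#' prepended on write for provenance.
#'
#' @param path TSV file path.
#' @return `read_counts`: integer matrix with dimnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(m != round(m)) || any(m < 0)) {
    stop_fustx("counts must be nonnegative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  check_counts(m)
}

#' @rdname read_counts
#' @param counts integer matrix, genes x samples.
#' @param header optional character vector of provenance lines, written as
#'   `#`-prefixed comments.
#' @export
write_counts <- function(counts, path, header = NULL) {
  counts <- check_counts(counts)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata as TSV
#'
#' Columns: `sample_id`, `sex`, `anesthesia` (KA/Iso), `batch`,
#' `timepoint` (6h/24h), `fus` (0/1), `ce`, `mba` (empty cell allowed for
#' treated samples without a cavitation measurement).
#'
#' @param path TSV file path.
#' @return `read_metadata`: a data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "anesthesia", "batch", "timepoint", "fus",
            "ce", "mba")
  if (!all(need %in% names(df))) {
    stop_fustx("metadata must have columns: ", paste(need, collapse = ", "))
  }
  df$ce <- as.numeric(df$ce)
  df$mba <- as.numeric(df$mba)
  df$fus <- as.integer(df$fus)
  df
}

#' @rdname read_metadata
#' @param samples metadata data.frame.
#' @param header optional `#`-prefixed provenance lines.
#' @export
write_metadata <- function(samples, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(samples, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a waveform session as trace files plus a manifest
#'
#' Each pulse is written as a single-column text file of voltages; the
#' manifest is a TSV listing the trace files in acquisition order with the
#' sampling rate recorded in a `# fs=<Hz>` header line.
#'
#' @param rec a [waveform_record()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the traces.
#' @return `write_waveform_record`: the manifest path, invisibly.
#' @export
write_waveform_record <- function(rec, dir, prefix = "pulse") {
  stopifnot(inherits(rec, "waveform_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%04d.txt", prefix, seq_along(rec$pulses))
  for (i in seq_along(rec$pulses)) {
    writeLines(format(rec$pulses[[i]], digits = 15, trim = TRUE,
                      scientific = FALSE),
               file.path(dir, files[i]))
  }
  manifest <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  con <- file(manifest, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  writeLines(c("trace", files), con)
  invisible(manifest)
}

#' @rdname write_waveform_record
#' @param manifest manifest file path.
#' @param fs sampling rate override; by default taken from the manifest's
#'   `# fs=` header.
#' @return `read_waveform_record`: a [waveform_record()].
#' @export
read_waveform_record <- function(manifest, fs = NULL) {
  lines <- readLines(manifest)
  if (is.null(fs)) {
    hdr <- grep("^#\\s*fs=", lines, value = TRUE)
    if (length(hdr) == 0L) {
      stop_fustx("manifest has no '# fs=' header; supply fs explicitly")
    }
    fs <- as.numeric(sub("^#\\s*fs=", "", hdr[1L]))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2L || body[1L] != "trace") {
    stop_fustx("manifest must have a 'trace' column listing pulse files")
  }
  files <- body[-1L]
  pulses <- lapply(file.path(dirname(manifest), files), function(f) {
    if (!file.exists(f)) stop_fustx("missing trace file: ", f)
    as.numeric(readLines(f))
  })
  waveform_record(pulses, fs)
}
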