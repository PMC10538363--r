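# Sequence file I/O. Parsing and writing of FASTA/FASTQ (plain or gzip) is
# delegated to Biostrings; records are surfaced as plain character vectors.

#' Read sequence records from a FASTA or FASTQ file
#'
#' The format is auto-detected from the first record character ('>' FASTA,
#' '@' FASTQ); gzip compression is detected from the file magic. Qualities
#' are ignored. Windows line endings are tolerated.
#'
#' @param path input file.
#' @return data.frame with columns `id` (first word of the description) and
#'   `seq` (uppercase sequence).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  con <- gzfile(path, "rb")
  first <- readBin(con, "raw", 1L)
  close(con)
  if (length(first) == 0L) stop("empty sequence file: ", path)
  ch <- rawToChar(first)
  path <- normalize_line_endings(path)
  x <- tryCatch({
    if (ch == ">") Biostrings::readBStringSet(path, format = "fasta")
    else if (ch == "@") Biostrings::readBStringSet(path, format = "fastq")
    else stop("unrecognized sequence format (first character ", dQuote(ch), ")")
  }, error = function(e) {
    stop("failed to parse ", path, ": ", conditionMessage(e))
  })
  data.frame(id = sub("\\s.*$", "", names(x)),
             seq = toupper(as.character(x)),
             row.names = NULL)
}

# Biostrings' FASTQ reader chokes on CRLF; rewrite to a temp file if needed.
normalize_line_endings <- function(path) {
  con <- gzfile(path, "rb")
  probe <- readBin(con, "raw", 65536L)
  close(con)
  if (!any(probe == as.raw(13L))) return(path)
  lines <- readLines(gzfile(path), warn = FALSE)
  tmp <- tempfile(fileext = ".txt")
  writeLines(sub("\r$", "", lines), tmp)
  tmp
}

#' Write maximal unitigs to FASTA
#'
#' One record per unitig with ids `u0, u1, ...`, wrapped at 80 columns. In
#' colored mode the description carries the run-length encoded color subset
#' indices of the unitig's k-mers: `>u<id> C:<idx>:<len>[,<idx>:<len>]*`.
#'
#' @param unitigs character vector of unitig strings.
#' @param path output FASTA path (".gz" triggers compression).
#' @param color_runs optional list of run data.frames (see
#'   [encode_run_header()]), one per unitig.
#' @return `path`, invisibly.
#' @export
write_unitigs <- function(unitigs, path, color_runs = NULL) {
  x <- Biostrings::DNAStringSet(unitigs)
  ids <- paste0("u", seq_along(unitigs) - 1L)
  if (!is.null(color_runs)) {
    stopifnot(length(color_runs) == length(unitigs))
    ids <- vapply(seq_along(unitigs),
                  function(i) format_color_header(i - 1L, color_runs[[i]]), "")
  }
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = 80L,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Write sequences to FASTA / FASTQ (fixture support)
#'
#' @param seqs character vector of sequences.
#' @param path output path (".gz" triggers compression).
#' @param ids optional record ids.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, ids = NULL) {
  x <- Biostrings::BStringSet(seqs)
  names(x) <- if (is.null(ids)) paste0("s", seq_along(seqs)) else ids
  Biostrings::writeXStringSet(x, path, compress = endsWith(path, ".gz"))
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path, ids = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- if (is.null(ids)) paste0("r", seq_along(seqs)) else ids
  q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}
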