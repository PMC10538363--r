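# Read splitting: cut each sequence into super-(k-1)-mer segments (maximal
# runs of consecutive (k-1)-mers sharing one window minimizer), attach the
# flanking linking characters, and route the extended segments to groups
# (one group per minimizer value) stored in a smaller number of bucket files.

#' Split a sequence into super-(k-1)-mer segments
#'
#' Consecutive (k-1)-mers sharing the same window minimizer are grouped into
#' one segment. Segments cover the read and consecutive segments overlap on
#' exactly k - 2 characters. Computed in a single pass (rolling hashes,
#' sliding window minima, run grouping).
#'
#' @param read DNA string with `nchar(read) >= k`.
#' @param params a [min_params()] bundle.
#' @return data.frame with columns `start`, `end` (0-based, half-open
#'   interval in `read`), `text` (the segment) and `minimizer`.
#' @export
split_sequence <- function(read, params) {
  k <- params$k
  if (nchar(read) < k) {
    return(data.frame(start = integer(), end = integer(),
                      text = character(), minimizer = numeric()))
  }
  W <- window_minimizers(read, params)
  r <- rle(W)
  ends <- cumsum(r$lengths)          # last (k-1)-mer index of each run (1-based)
  starts <- ends - r$lengths + 1L    # first (k-1)-mer index
  # run over (k-1)-mers [i0, i1] spells characters [i0, i1 + k - 2] (1-based)
  data.frame(start = starts - 1L,
             end = ends + k - 2L,
             text = substring(read, starts, ends + k - 2L),
             minimizer = r$values)
}

#' Attach linking characters to segments
#'
#' Each segment S becomes a*S*b where a and b are the characters of the read
#' immediately before/after the segment; at read ends the character is simply
#' absent (no sentinel is materialized) and the corresponding link flag is
#' FALSE. Consecutive extended segments of one read overlap on exactly k
#' characters.
#'
#' @param read the source read.
#' @param segments output of [split_sequence()] on `read`.
#' @return data.frame with columns `text` (extended segment), `left_link`,
#'   `right_link` (logical) and `minimizer`.
#' @export
extend_segments <- function(read, segments) {
  if (nrow(segments) == 0L) {
    return(data.frame(text = character(), left_link = logical(),
                      right_link = logical(), minimizer = numeric()))
  }
  n <- nchar(read)
  lflag <- segments$start > 0L
  rflag <- segments$end < n
  from <- ifelse(lflag, segments$start, segments$start + 1L)  # 1-based
  to <- ifelse(rflag, segments$end + 1L, segments$end)
  data.frame(text = substring(read, from, to),
             left_link = lflag, right_link = rflag,
             minimizer = segments$minimizer)
}

#' Map a minimizer value to a bucket id
#'
#' Deterministic: the low bits (modulo) of the minimizer. All segments of one
#' group land in one bucket; a bucket may hold several groups.
#'
#' @param h minimizer value(s).
#' @param n_buckets number of buckets, a power of two.
#' @return integer bucket ids in `0:(n_buckets-1)`.
#' @export
assign_bucket <- function(h, n_buckets) {
  n_buckets <- as.integer(n_buckets)
  if (n_buckets < 1L || bitwAnd(n_buckets, n_buckets - 1L) != 0L) {
    stop("n_buckets must be a power of two >= 1")
  }
  as.integer(h %% n_buckets)
}

# split + extend one clean read; returns a data.table of extended segments
split_extend <- function(read, params, color = NA_integer_) {
  segs <- extend_segments(read, split_sequence(read, params))
  if (nrow(segs) == 0L) return(NULL)
  data.table::data.table(text = segs$text, left_link = segs$left_link,
                         right_link = segs$right_link,
                         minimizer = segs$minimizer,
                         color = rep(as.integer(color), nrow(segs)))
}

# Split a set of in-memory sequences (character vector) with one color id;
# non-ACGT characters split records into clean runs, runs shorter than k are
# dropped (counted). Returns list(segments = data.table, n_skipped_runs).
split_sequences_mem <- function(seqs, params, color = NA_integer_) {
  k <- params$k
  skipped <- 0L
  parts <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    runs <- dna_runs(seqs[[i]], min_len = 1L)
    short <- sum(nchar(runs) < k)
    skipped <- skipped + short
    runs <- runs[nchar(runs) >= k]
    if (length(runs) == 0L) next
    parts[[i]] <- data.table::rbindlist(
      lapply(runs, split_extend, params = params, color = color))
  }
  segs <- data.table::rbindlist(parts[!vapply(parts, is.null, TRUE)])
  list(segments = segs, n_skipped_runs = skipped)
}

#' Split a sequence collection into bucket files
#'
#' Reads each input file (FASTA/FASTQ, optionally gzipped), splits every
#' record into extended segments, and writes each segment to the bucket file
#' of its minimizer's group. In colored mode each file carries one color id.
#' Bucket files are versioned tab-separated tables, gzip-compressed.
#'
#' @param inputs character vector of sequence file paths; in colored mode the
#'   position in the vector is the color id (0-based).
#' @param params a [min_params()] bundle.
#' @param n_buckets number of bucket files (power of two).
#' @param tmp_dir directory for bucket files (created if needed).
#' @param colored track color ids.
#' @return list with `bucket_files` (paths, indexed 1..n_buckets),
#'   `n_segments`, `n_skipped_runs` (clean runs shorter than k),
#'   `n_skipped_reads` (records with no usable run).
#' @export
split_collection <- function(inputs, params, n_buckets = 256L,
                             tmp_dir = tempfile("unitigr_buckets_"),
                             colored = FALSE) {
  dir.create(tmp_dir, showWarnings = FALSE, recursive = TRUE)
  all <- vector("list", length(inputs))
  skipped_runs <- 0L; skipped_reads <- 0L
  for (ci in seq_along(inputs)) {
    recs <- read_sequences(inputs[[ci]])
    col <- if (colored) ci - 1L else NA_integer_
    res <- split_sequences_mem(recs$seq, params, color = col)
    skipped_runs <- skipped_runs + res$n_skipped_runs
    n_ok <- if (nrow(res$segments)) length(unique(res$segments$minimizer)) else 0L
    skipped_reads <- skipped_reads +
      sum(vapply(recs$seq, function(s) length(dna_runs(s, params$k)) == 0L, TRUE))
    all[[ci]] <- res$segments
  }
  segs <- data.table::rbindlist(all[!vapply(all, is.null, TRUE)])
  files <- file.path(tmp_dir, sprintf("bucket_%04d.tsv.gz", seq_len(n_buckets) - 1L))
  if (nrow(segs)) {
    segs[, bucket := assign_bucket(minimizer, n_buckets)]
    for (b in sort(unique(segs$bucket))) {
      write_bucket_file(segs[bucket == b,
                             c("text", "left_link", "right_link", "minimizer", "color")],
                        files[b + 1L], params)
    }
    segs[, bucket := NULL]
  }
  list(bucket_files = files, n_segments = nrow(segs),
       n_skipped_runs = skipped_runs, n_skipped_reads = skipped_reads)
}

BUCKET_FORMAT_VERSION <- 1L

write_bucket_file <- function(segments, path, params) {
  con <- gzfile(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("#unitigr-bucket\tv%d\tk=%d\tm=%d\thash=%s\tcanonical=%d",
                     BUCKET_FORMAT_VERSION, params$k, params$m,
                     params$hash_name, as.integer(params$canonical)), con)
  utils::write.table(segments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_bucket_file <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  hdr <- readLines(con, n = 1L)
  if (!startsWith(hdr, sprintf("#unitigr-bucket\tv%d", BUCKET_FORMAT_VERSION))) {
    stop("unrecognized bucket file header in ", path)
  }
  dt <- data.table::as.data.table(
    utils::read.table(con, sep = "\t", header = TRUE,
                      colClasses = c("character", "logical", "logical",
                                     "numeric", "integer")))
  dt
}
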