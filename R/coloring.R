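# Color tracking: each k-mer's normalized color set (sorted, deduplicated,
# 0-based file indices) is interned behind a dense integer subset index via a
# 128-bit hash of its delta+run-length encoding; unitig FASTA headers carry
# the per-k-mer subset indices run-length encoded; the color map persists the
# subset encodings in independently compressed chunks.

#' Create an empty color index
#'
#' @return environment holding the global hash -> subset-index map and the
#'   interned sets in first-seen order.
#' @export
color_index_new <- function() {
  env <- new.env(parent = emptyenv())
  env$by_hash <- utils::hashtab("identical", 64L)
  env$sets <- list()
  env$n <- 0L
  class(env) <- "color_index"
  env
}

#' Intern a normalized color set
#'
#' Hashes the delta+RLE byte encoding of the set with a 128-bit digest and
#' looks it up in the global map. On a miss the set is appended and receives
#' the next dense 0-based subset index; on a hit the existing index is
#' returned after a deep comparison (a differing set under an equal hash is a
#' detected collision and a hard error). Idempotent.
#'
#' @param index a [color_index_new()] environment.
#' @param colors strictly increasing integer vector of 0-based color ids.
#' @return the 0-based subset index.
#' @export
intern_color_set <- function(index, colors) {
  colors <- as.integer(colors)
  if (length(colors) == 0L || is.unsorted(colors, strictly = TRUE)) {
    stop("color set must be a nonempty strictly increasing integer vector")
  }
  enc <- encode_color_set(colors)
  h <- hash128_bytes(enc)
  hit <- utils::gethash(index$by_hash, h)
  if (!is.null(hit)) {
    if (!identical(index$sets[[hit + 1L]], colors)) {
      stop("128-bit color-set hash collision detected for index ", hit)
    }
    return(hit)
  }
  idx <- index$n
  index$n <- idx + 1L
  index$sets[[idx + 1L]] <- colors
  utils::sethash(index$by_hash, h, idx)
  idx
}

# LEB128 variable-length encoding of non-negative integers
varint_encode <- function(x) {
  out <- integer(0)
  for (v in x) {
    repeat {
      b <- v %% 128L
      v <- v %/% 128L
      if (v > 0L) out <- c(out, b + 128L) else { out <- c(out, b); break }
    }
  }
  as.raw(out)
}

varint_decode <- function(bytes, n) {
  vals <- integer(n)
  i <- 1L
  b <- as.integer(bytes)
  for (vi in seq_len(n)) {
    v <- 0L; shift <- 1L
    repeat {
      if (i > length(b)) stop("malformed varint stream: truncated")
      byte <- b[i]; i <- i + 1L
      v <- v + (byte %% 128L) * shift
      if (byte < 128L) break
      shift <- shift * 128L
    }
    vals[vi] <- v
  }
  list(values = vals, consumed = i - 1L)
}

#' Encode / decode a color set (delta + run-length, varint bytes)
#'
#' The sorted color ids are delta-encoded (first delta = first color), the
#' deltas run-length compressed into (delta, count) pairs, and everything
#' serialized as LEB128 varints prefixed by the pair count.
#' `decode_color_set(encode_color_set(C))` is the identity.
#'
#' @param colors strictly increasing integer vector of 0-based color ids.
#' @return `encode_color_set`: raw vector; `decode_color_set`: integer vector.
#' @export
encode_color_set <- function(colors) {
  colors <- as.integer(colors)
  if (length(colors) == 0L || is.unsorted(colors, strictly = TRUE) ||
      any(colors < 0L)) {
    stop("color set must be a nonempty strictly increasing vector of ids >= 0")
  }
  d <- c(colors[1L], diff(colors))
  r <- rle(d)
  varint_encode(c(length(r$values), rbind(r$values, r$lengths)))
}

#' @param bytes raw vector produced by `encode_color_set`.
#' @rdname encode_color_set
#' @export
decode_color_set <- function(bytes) {
  if (!is.raw(bytes) || length(bytes) == 0L) stop("malformed color-set encoding")
  np <- varint_decode(bytes, 1L)
  rest <- varint_decode(bytes[-seq_len(np$consumed)], 2L * np$values)
  if (np$consumed + rest$consumed != length(bytes)) {
    stop("malformed color-set encoding: trailing bytes")
  }
  m <- matrix(rest$values, nrow = 2L)
  cumsum(rep(m[1L, ], m[2L, ]))
}

#' Run-length encode per-k-mer subset indices of a unitig
#'
#' @param indices integer vector: one subset index per k-mer of the unitig.
#' @return data.frame with columns `index`, `length` (maximal runs).
#' @export
encode_run_header <- function(indices) {
  if (length(indices) == 0L) stop("a unitig has at least one k-mer")
  r <- rle(as.integer(indices))
  data.frame(index = r$values, length = r$lengths)
}

#' @param runs data.frame from `encode_run_header`.
#' @param n_kmers expected k-mer count (checked).
#' @rdname encode_run_header
#' @export
decode_run_header <- function(runs, n_kmers = NULL) {
  if (any(runs$length <= 0L)) stop("run lengths must be positive")
  if (!is.null(n_kmers) && sum(runs$length) != n_kmers) {
    stop("color runs sum to ", sum(runs$length), " but unitig has ",
         n_kmers, " k-mers")
  }
  rep(runs$index, runs$length)
}

# FASTA description grammar for colored unitigs: "u<id> C:<idx>:<len>[,...]"
format_color_header <- function(id, runs) {
  paste0("u", id, " C:",
         paste(paste0(runs$index, ":", runs$length), collapse = ","))
}

parse_color_header <- function(desc) {
  m <- regmatches(desc, regexec("^u(\\d+)\\s+C:(\\S+)$", desc))[[1L]]
  if (length(m) == 0L) stop("unparseable colored unitig header: ", desc)
  parts <- strsplit(strsplit(m[3L], ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("unparseable color runs in: ", desc)
  idx <- as.integer(vapply(parts, `[`, "", 1L))
  len <- as.integer(vapply(parts, `[`, "", 2L))
  list(id = as.integer(m[2L]), runs = data.frame(index = idx, length = len))
}

COLOR_MAP_MAGIC <- "UCMP"
COLOR_MAP_VERSION <- 1L

#' Persist / reload a color index
#'
#' The color map file stores the delta+RLE encodings of all interned sets, in
#' index order, divided into fixed-size chunks that are independently
#' gzip-compressed for faster random access. `read_color_map` restores an
#' identical index (same sets, same indices).
#'
#' @param index a `color_index`.
#' @param path output file.
#' @param sets_per_chunk chunk granularity.
#' @return `write_color_map`: `path`, invisibly; `read_color_map`: a
#'   `color_index`.
#' @export
write_color_map <- function(index, path, sets_per_chunk = 1024L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(COLOR_MAP_MAGIC, con, eos = NULL)
  writeBin(c(COLOR_MAP_VERSION, index$n, as.integer(sets_per_chunk)), con,
           size = 4L, endian = "little")
  starts <- seq(1L, max(index$n, 1L), by = sets_per_chunk)
  if (index$n == 0L) starts <- integer(0)
  writeBin(length(starts), con, size = 4L, endian = "little")
  blobs <- lapply(starts, function(s) {
    e <- min(s + sets_per_chunk - 1L, index$n)
    payload <- unlist(lapply(index$sets[s:e], function(cs) {
      enc <- encode_color_set(cs)
      c(varint_encode(length(enc)), enc)
    }))
    memCompress(payload, "gzip")
  })
  writeBin(vapply(blobs, length, 1L), con, size = 4L, endian = "little")
  for (b in blobs) writeBin(b, con)
  invisible(path)
}

#' @rdname write_color_map
#' @export
read_color_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(COLOR_MAP_MAGIC))
  if (!identical(magic, COLOR_MAP_MAGIC)) stop("not a color map file: ", path)
  hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  if (hdr[1L] != COLOR_MAP_VERSION) {
    stop("unsupported color map version ", hdr[1L])
  }
  n_sets <- hdr[2L]
  n_chunks <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  lens <- readBin(con, "integer", n_chunks, size = 4L, endian = "little")
  index <- color_index_new()
  for (ci in seq_len(n_chunks)) {
    payload <- memDecompress(readBin(con, "raw", lens[ci]), "gzip")
    i <- 1L
    while (i <= length(payload)) {
      nl <- varint_decode(payload[i:length(payload)], 1L)
      i <- i + nl$consumed
      enc <- payload[i:(i + nl$values - 1L)]
      i <- i + nl$values
      intern_color_set(index, decode_color_set(enc))
    }
  }
  if (index$n != n_sets) stop("color map corrupt: set count mismatch")
  index
}

# --- build-time color state: global k-mer -> subset index map ---------------

#' Create the per-build color state
#'
#' Holds the global [color_index_new()] plus a map from canonical k-mer to
#' interned subset index, filled in while groups are counted. A k-mer counted
#' in two groups (it carries a linking character) must produce the same color
#' set in both; this is asserted.
#'
#' @return environment of class `color_state`.
#' @export
color_state_new <- function() {
  env <- new.env(parent = emptyenv())
  env$index <- color_index_new()
  env$kmap <- utils::hashtab("identical", 1024L)
  class(env) <- "color_state"
  env
}

# intern the color sets of all rows of a filtered kmer_table
record_kmer_colors <- function(state, tbl) {
  if (!attr(tbl, "colored") || nrow(tbl) == 0L) return(invisible(state))
  for (i in seq_len(nrow(tbl))) {
    sidx <- intern_color_set(state$index, tbl$colors[[i]])
    key <- tbl$kmer[i]
    prev <- utils::gethash(state$kmap, key)
    if (is.null(prev)) utils::sethash(state$kmap, key, sidx)
    else if (prev != sidx) {
      stop("color sets of boundary k-mer ", key, " disagree between groups")
    }
  }
  invisible(state)
}

# subset indices for every k-mer of a final unitig string
unitig_color_indices <- function(state, text, k, canonical = TRUE) {
  km <- kmers_of(text, k)
  if (canonical) km <- canonicalize(km)$seq
  idx <- vapply(km, function(q) {
    v <- utils::gethash(state$kmap, q)
    if (is.null(v)) stop("output unitig contains a k-mer with no recorded ",
                         "color set")
    v
  }, 1L, USE.NAMES = FALSE)
  idx
}
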