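# Top-level construction driver: split -> count per group -> extend ->
# randomized merge -> maximal canonical unitigs (+ color annotation).

#' Build a compacted (optionally colored) de Bruijn graph
#'
#' Runs the full construction pipeline: every input sequence is split into
#' extended super-(k-1)-mer segments grouped by window minimizer; each group
#' is k-mer-counted (with abundance filtering and linking-character
#' tracking) and compacted into intermediate unitigs; intermediate unitigs
#' are joined across groups by the randomized seal-and-merge rounds into the
#' set of maximal canonical unitigs. In colored mode each input element is
#' one color (0-based, in input order) and every k-mer's deduplicated color
#' set is interned behind a dense subset index.
#'
#' @param inputs one of: a character vector of FASTA/FASTQ paths (each file =
#'   one color in colored mode), or a list of character vectors of in-memory
#'   sequences (each element = one color).
#' @param k k-mer size (>= 2).
#' @param a abundance threshold (>= 1).
#' @param m minimizer length; default [choose_m()].
#' @param hash_name minimizer hash function name (see [min_params()]).
#' @param canonical identify k-mers with reverse complements (canonical
#'   maximal unitigs). Disable for strand-specific graphs.
#' @param colored track colors.
#' @param n_buckets segment bucket count used by the disk path.
#' @param merge_buckets bucket count of the randomized merge.
#' @param seed integer seed for the randomized merge (output set is
#'   seed-independent; only round counts vary).
#' @param long_k_hash hashed k-mer keys (see [counting_params()]); default:
#'   engaged for k > 64.
#' @param use_disk_buckets route segments through bucket files under
#'   `tmp_dir` (exercises the on-disk format) instead of in memory.
#' @param tmp_dir scratch directory for the disk path.
#' @return object of class `cdbg`: unitigs (normalized, sorted), cycle flags,
#'   parameters, per-unitig color runs and the color index (colored mode),
#'   and build statistics.
#' @export
dbg_build <- function(inputs, k, a = 1L, m = NULL, hash_name = "mix",
                      canonical = TRUE, colored = FALSE, n_buckets = 256L,
                      merge_buckets = 64L, seed = 1L, long_k_hash = NULL,
                      use_disk_buckets = FALSE, tmp_dir = NULL) {
  cparams <- counting_params(k, a, canonical, long_k_hash = long_k_hash)
  mparams <- min_params(k, m, hash_name = hash_name, canonical = canonical)

  if (is.character(inputs)) {
    seq_sets <- lapply(inputs, function(p) read_sequences(p)$seq)
  } else if (is.list(inputs)) {
    seq_sets <- lapply(inputs, as.character)
  } else stop("inputs must be file paths or a list of sequence vectors")
  if (colored && length(seq_sets) < 1L) stop("colored mode needs >= 1 input set")

  skipped <- 0L
  if (use_disk_buckets) {
    if (is.null(tmp_dir)) tmp_dir <- tempfile("unitigr_buckets_")
    fa_paths <- vapply(seq_along(seq_sets), function(i) {
      p <- file.path(tmp_dir, sprintf("input_%03d.fa", i))
      dir.create(tmp_dir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(seq_sets[[i]], p)
      p
    }, "")
    sc <- split_collection(fa_paths, mparams, n_buckets = n_buckets,
                           tmp_dir = tmp_dir, colored = colored)
    skipped <- sc$n_skipped_runs
    present <- file.exists(sc$bucket_files)
    segs <- data.table::rbindlist(lapply(sc$bucket_files[present],
                                         read_bucket_file))
  } else {
    parts <- lapply(seq_along(seq_sets), function(i) {
      res <- split_sequences_mem(seq_sets[[i]], mparams,
                                 color = if (colored) i - 1L else NA_integer_)
      skipped <<- skipped + res$n_skipped_runs
      res$segments
    })
    segs <- data.table::rbindlist(parts[vapply(parts, function(p)
      !is.null(p) && nrow(p) > 0L, TRUE)])
  }

  color_state <- if (colored) color_state_new() else NULL
  if (is.null(segs) || nrow(segs) == 0L) {
    graph <- empty_cdbg(cparams, mparams, colored, seed)
    graph$stats$n_skipped_runs <- skipped
    return(graph)
  }

  proc <- process_bucket(segs, cparams, mparams, color_state = color_state)
  chains <- pair_endpoints(proc$endpoints, canonical = cparams$canonical_mode)
  merged <- run_merging(chains, proc$unitigs, k = cparams$k, seed = seed,
                        merge_buckets = merge_buckets,
                        canonical = cparams$canonical_mode)

  color_runs <- NULL
  if (colored) {
    color_runs <- lapply(seq_along(merged$unitigs), function(i) {
      encode_run_header(unitig_color_indices(color_state, merged$unitigs[i],
                                             cparams$k, canonical))
    })
  }

  structure(list(
    unitigs = merged$unitigs,
    is_cycle = merged$is_cycle,
    k = cparams$k, a = cparams$a, m = mparams$m,
    hash_name = mparams$hash_name,
    canonical = cparams$canonical_mode,
    colored = colored,
    n_colors = if (colored) length(seq_sets) else 0L,
    color_runs = color_runs,
    color_index = if (colored) color_state$index else NULL,
    seed = as.integer(seed),
    stats = list(n_segments = nrow(segs),
                 n_kmers = nrow(proc$table),
                 n_intermediate = nrow(proc$unitigs),
                 n_endpoint_records = nrow(proc$endpoints),
                 n_unitigs = length(merged$unitigs),
                 merge_rounds = merged$rounds,
                 n_skipped_runs = skipped)
  ), class = "cdbg")
}

empty_cdbg <- function(cparams, mparams, colored, seed) {
  structure(list(unitigs = character(0), is_cycle = logical(0),
                 k = cparams$k, a = cparams$a, m = mparams$m,
                 hash_name = mparams$hash_name,
                 canonical = cparams$canonical_mode, colored = colored,
                 n_colors = 0L, color_runs = NULL, color_index = NULL,
                 seed = as.integer(seed),
                 stats = list(n_segments = 0L, n_kmers = 0L,
                              n_intermediate = 0L, n_endpoint_records = 0L,
                              n_unitigs = 0L, merge_rounds = 0L,
                              n_skipped_runs = 0L)),
            class = "cdbg")
}

#' @export
print.cdbg <- function(x, ...) {
  cat("Compacted de Bruijn graph (k =", x$k, ", a =", x$a,
      if (x$canonical) ", canonical" else ", strand-specific", ")\n")
  cat("  unitigs:   ", length(x$unitigs),
      " (", sum(x$is_cycle), " cyclic)\n", sep = "")
  cat("  k-mers:    ", x$stats$n_kmers, "\n", sep = "")
  if (x$colored) {
    cat("  colors:    ", x$n_colors, " (", x$color_index$n,
        " distinct color sets)\n", sep = "")
  }
  cat("  merge:     ", x$stats$n_intermediate, " intermediate unitigs, ",
      x$stats$merge_rounds, " rounds\n", sep = "")
  invisible(x)
}

#' @export
summary.cdbg <- function(object, ...) {
  len <- nchar(object$unitigs)
  out <- list(k = object$k, a = object$a, n_unitigs = length(object$unitigs),
              n_cycles = sum(object$is_cycle),
              total_length = sum(len),
              n50 = if (length(len)) {
                sl <- sort(len, decreasing = TRUE)
                sl[which(cumsum(sl) >= sum(sl) / 2)[1L]]
              } else NA_integer_,
              stats = object$stats)
  class(out) <- "summary.cdbg"
  out
}

#' @export
print.summary.cdbg <- function(x, ...) {
  cat("k =", x$k, " a =", x$a, "\n")
  cat("unitigs:", x$n_unitigs, " (cycles:", x$n_cycles, ")\n")
  cat("total length:", x$total_length, " N50:", x$n50, "\n")
  invisible(x)
}

#' Save a built graph to disk
#'
#' Writes `<prefix>.unitigs.fa` (colored headers in colored mode),
#' `<prefix>.meta.json` (k, m, a, hash, canonical/colored flags), and in
#' colored mode `<prefix>.colors.bin` (the chunked color map).
#'
#' @param graph a `cdbg`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
save_cdbg <- function(graph, prefix) {
  write_unitigs(graph$unitigs, paste0(prefix, ".unitigs.fa"),
                color_runs = graph$color_runs)
  meta <- list(format = "unitigr-cdbg", version = 1L, k = graph$k,
               m = graph$m, a = graph$a, hash_name = graph$hash_name,
               canonical = graph$canonical, colored = graph$colored,
               n_colors = graph$n_colors,
               is_cycle = graph$is_cycle)
  jsonlite::write_json(meta, paste0(prefix, ".meta.json"), auto_unbox = TRUE)
  if (graph$colored) write_color_map(graph$color_index,
                                     paste0(prefix, ".colors.bin"))
  invisible(prefix)
}

#' Load a graph saved by [save_cdbg()]
#'
#' @param prefix the prefix passed to [save_cdbg()].
#' @return a `cdbg` object (sufficient for querying).
#' @export
load_cdbg <- function(prefix) {
  meta_path <- paste0(prefix, ".meta.json")
  if (!file.exists(meta_path)) stop("no graph metadata at ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "unitigr-cdbg")) stop("not a unitigr graph")
  fa <- read_sequences(paste0(prefix, ".unitigs.fa"))
  recs <- Biostrings::readBStringSet(paste0(prefix, ".unitigs.fa"))
  color_runs <- NULL
  color_index <- NULL
  if (isTRUE(meta$colored)) {
    parsed <- lapply(names(recs), parse_color_header)
    ord <- order(vapply(parsed, function(p) p$id, 1L))
    color_runs <- lapply(parsed[ord], function(p) p$runs)
    fa <- fa[ord, ]
    color_index <- read_color_map(paste0(prefix, ".colors.bin"))
  }
  structure(list(unitigs = fa$seq,
                 is_cycle = if (!is.null(meta$is_cycle))
                   as.logical(meta$is_cycle) else rep(FALSE, nrow(fa)),
                 k = as.integer(meta$k), a = as.integer(meta$a),
                 m = as.integer(meta$m), hash_name = meta$hash_name,
                 canonical = isTRUE(meta$canonical),
                 colored = isTRUE(meta$colored),
                 n_colors = as.integer(meta$n_colors),
                 color_runs = color_runs, color_index = color_index,
                 seed = NA_integer_,
                 stats = list()), class = "cdbg")
}
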