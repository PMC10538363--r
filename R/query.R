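# Batch sequence querying against a built graph: per-query matched-k-mer
# counts (uncolored) and per-color matched counts (colored), computed either
# through the same minimizer bucketing machinery as construction or against a
# single global table (both give identical results; tested).

# minimizer of each k-mer of s: min hash over the k-m+1 constituent m-mers
kmer_minimizers <- function(s, params) {
  k <- params$k
  if (nchar(s) < k) return(numeric())
  h <- rolling_hashes(s, params$m, params$hash_name, params$canonical)
  w <- k - params$m + 1L
  nw <- length(h) - w + 1L
  out <- h[seq_len(nw)]
  if (w > 1L) for (j in seq_len(w - 1L)) out <- pmin(out, h[(1L + j):(nw + j)])
  out
}

#' Query sequences against a compacted de Bruijn graph
#'
#' For each query, counts the positions whose (canonical) k-mer appears in
#' the graph; duplicated k-mers in a query count once per position. In
#' colored mode, additionally counts per color the matched positions whose
#' k-mer's color set contains that color. With `bucketed = TRUE`, graph and
#' query k-mers are partitioned by k-mer minimizer into buckets, counted per
#' bucket and summed, mirroring construction; the result is identical to the
#' global computation.
#'
#' @param graph a `cdbg` object ([dbg_build()]) or a path prefix accepted by
#'   [load_cdbg()].
#' @param queries character vector of query sequences (named or not), or a
#'   FASTA/FASTQ path.
#' @param bucketed use the bucket-partitioned computation.
#' @param n_buckets number of query buckets (power of two).
#' @return data.frame of class `dbg_query`: `query_id`, `total_kmers`,
#'   `matched`, `percent`, and in colored mode a `per_color` list column of
#'   named positive counts.
#' @export
query_batch <- function(graph, queries, bucketed = TRUE, n_buckets = 16L) {
  if (is.character(graph)) graph <- load_cdbg(graph)
  stopifnot(inherits(graph, "cdbg"))
  k <- graph$k
  if (is.character(queries) && length(queries) == 1L && file.exists(queries)) {
    recs <- read_sequences(queries)
    qids <- recs$id; queries <- recs$seq
  } else {
    qids <- if (!is.null(names(queries))) names(queries)
            else paste0("q", seq_along(queries))
  }
  params <- min_params(k, graph$m, hash_name = graph$hash_name,
                       canonical = graph$canonical)

  gk <- graph_kmer_index(graph)
  colored <- graph$colored

  total <- integer(length(queries))
  matched <- integer(length(queries))
  per_color <- if (colored) vector("list", length(queries)) else NULL

  gbucket <- if (bucketed) assign_bucket(gk$minim, n_buckets) else NULL

  for (qi in seq_along(queries)) {
    q <- toupper(queries[qi])
    nk <- nchar(q) - k + 1L
    total[qi] <- max(0L, nk)
    if (nk < 1L) {
      if (colored) per_color[[qi]] <- setNames(integer(0), character(0))
      next
    }
    km <- substring(q, seq_len(nk), seq_len(nk) + k - 1L)
    clean <- grepl("^[ACGT]+$", km)
    kmc <- km
    if (graph$canonical) kmc[clean] <- canonicalize(km[clean])$seq
    hit_idx <- rep(NA_integer_, nk)
    if (bucketed) {
      qb <- rep(NA_integer_, nk)
      # per-position minimizers need clean windows; compute per clean run
      m <- gregexpr("[ACGT]+", q)[[1L]]
      if (m[1L] != -1L) {
        lens <- attr(m, "match.length")
        for (ri in seq_along(m)) {
          if (lens[ri] < k) next
          sub <- substring(q, m[ri], m[ri] + lens[ri] - 1L)
          mins <- kmer_minimizers(sub, params)
          idxs <- (m[ri]):(m[ri] + lens[ri] - k)
          qb[idxs] <- assign_bucket(mins, n_buckets)
        }
      }
      for (b in unique(qb[!is.na(qb)])) {
        sel <- which(!is.na(qb) & qb == b & clean)
        pool_idx <- which(gbucket == b)
        hit_idx[sel] <- pool_idx[match(kmc[sel], gk$kmer[pool_idx])]
      }
    } else {
      hit_idx[clean] <- match(kmc[clean], gk$kmer)
    }
    hits <- !is.na(hit_idx)
    matched[qi] <- sum(hits)
    if (colored) {
      cnt <- setNames(integer(0), character(0))
      if (any(hits)) {
        sidx <- gk$sidx[hit_idx[hits]]
        tb <- table(sidx)
        acc <- new.env(parent = emptyenv())
        for (nm in names(tb)) {
          set <- graph$color_index$sets[[as.integer(nm) + 1L]]
          for (cc in set) {
            key <- as.character(cc)
            acc[[key]] <- (if (is.null(acc[[key]])) 0L else acc[[key]]) +
              as.integer(tb[[nm]])
          }
        }
        cols <- sort(as.integer(ls(acc)))
        cnt <- vapply(as.character(cols), function(key) acc[[key]], 1L)
        names(cnt) <- as.character(cols)
      }
      per_color[[qi]] <- cnt
    }
  }
  res <- data.frame(query_id = qids, total_kmers = total, matched = matched)
  res$percent <- ifelse(total > 0L, round(100 * matched / total, 2L), 0)
  if (colored) res$per_color <- I(per_color)
  class(res) <- c("dbg_query", class(res))
  res
}

# index of the graph's k-mers: canonical text, k-mer minimizer, and (colored)
# color subset index per k-mer
graph_kmer_index <- function(graph) {
  params <- min_params(graph$k, graph$m, hash_name = graph$hash_name,
                       canonical = graph$canonical)
  k <- graph$k
  kml <- lapply(graph$unitigs, kmers_of, k = k)
  km <- unlist(kml, use.names = FALSE)
  if (graph$canonical) km <- canonicalize(km)$seq
  minim <- unlist(lapply(graph$unitigs, kmer_minimizers, params = params),
                  use.names = FALSE)
  sidx <- NULL
  if (graph$colored) {
    sidx <- unlist(lapply(seq_along(graph$unitigs), function(i) {
      decode_run_header(graph$color_runs[[i]], length(kml[[i]]))
    }), use.names = FALSE)
  }
  keep <- !duplicated(km)
  list(kmer = km[keep], minim = minim[keep],
       sidx = if (!is.null(sidx)) sidx[keep] else NULL)
}

#' Write query results as CSV (uncolored reporting)
#'
#' One line per query: id, total k-mers, matched k-mers, percentage (2
#' decimals, `0.00` when the query has no k-mers). An optional threshold
#' keeps only queries with at least that match percentage.
#'
#' @param results a `dbg_query` data.frame.
#' @param path output path.
#' @param threshold optional minimum percentage (0-100).
#' @return `path`, invisibly.
#' @export
write_query_csv <- function(results, path, threshold = NULL) {
  df <- data.frame(query_id = results$query_id,
                   total_kmers = results$total_kmers,
                   matched = results$matched,
                   percent = sprintf("%.2f", ifelse(results$total_kmers > 0,
                                                    100 * results$matched /
                                                      results$total_kmers, 0)))
  if (!is.null(threshold)) df <- df[as.numeric(df$percent) >= threshold, ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write query results as JSON Lines (colored reporting)
#'
#' One JSON object per query: id, total and matched k-mer counts, and a
#' color -> count map restricted to positive counts.
#'
#' @param results a `dbg_query` data.frame with a `per_color` column.
#' @param path output path.
#' @param threshold optional minimum match percentage (0-100).
#' @return `path`, invisibly.
#' @export
write_query_jsonl <- function(results, path, threshold = NULL) {
  stopifnot(!is.null(results$per_color))
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(results))) {
    pct <- if (results$total_kmers[i] > 0)
      100 * results$matched[i] / results$total_kmers[i] else 0
    if (!is.null(threshold) && pct < threshold) next
    pc <- results$per_color[[i]]
    pc <- pc[pc > 0L]
    obj <- list(query = results$query_id[i],
                total_kmers = results$total_kmers[i],
                matched = results$matched[i],
                colors = if (length(pc)) as.list(pc) else structure(list(), names = character(0)))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}
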