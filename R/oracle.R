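# Brute-force reference oracle: exact k-mer enumeration, canonical maximal
# unitigs computed directly from the string-centric definition on the global
# k-mer set (no groups, no linking characters, no merging), the node-centric
# construction used for the equivalence check, and a naive query oracle.
# Deliberately written against its own helpers, independent of the pipeline's
# extension machinery, so that agreement between the two is informative.

.oracle_rc1 <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), NULL)[[1L]]), collapse = "")
}

# reverse complement of many k-mers via one full-sequence reversal
.oracle_rc <- function(v) {
  vapply(v, .oracle_rc1, "", USE.NAMES = FALSE)
}

# all k-mers of the cleaned runs of a set of sequences
.oracle_kmers <- function(R, k) {
  runs <- unlist(lapply(R, dna_runs, min_len = k), use.names = FALSE)
  out <- lapply(runs, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  })
  unlist(out, use.names = FALSE)
}

.oracle_canon <- function(km) {
  rc <- .oracle_rc(km)
  pmin(km, rc)
}

#' Exact (canonical) k-mer enumeration with abundance filter
#'
#' Counts every k-mer occurrence of `R` (occurrences of a k-mer and of its
#' reverse complement pooled in canonical mode; palindromes counted once per
#' occurrence) and keeps the k-mers with count >= a.
#'
#' @param R character vector of input sequences.
#' @param k k-mer size.
#' @param a abundance threshold.
#' @param canonical canonical (reverse-complement aware) counting.
#' @return named integer vector: counts indexed by (canonical) k-mer.
#' @export
enumerate_kmers <- function(R, k, a = 1L, canonical = TRUE) {
  km <- .oracle_kmers(R, k)
  if (length(km) == 0L) return(setNames(integer(0), character(0)))
  if (canonical) km <- .oracle_canon(km)
  tb <- table(km)
  cnt <- as.integer(tb)
  names(cnt) <- names(tb)
  cnt[cnt >= a]
}

# least rotation of a cyclic spelling (with (k-1)-wrap) over both strands
.oracle_cycle_norm <- function(s, k, canonical = TRUE) {
  E <- nchar(s) - (k - 1L)
  variants <- if (canonical) c(s, .oracle_rc1(s)) else s
  best <- NULL
  for (v in variants) {
    core <- substring(v, 1L, E)
    d <- paste0(core, core, substring(core, 1L, k - 1L))
    for (r in 0L:(E - 1L)) {
      cand <- substring(d, r + 1L, r + E + k - 1L)
      if (is.null(best) || cand < best) best <- cand
    }
  }
  best
}

#' Brute-force canonical maximal unitigs
#'
#' Computes the set of canonical maximal unitigs of `R` directly from the
#' definition: every k-mer with canonical abundance >= a is an edge; starting
#' from each unconsumed edge, the unitig is extended in both directions while
#' the neighboring edge is unique in the forward direction and the step
#' target has a unique backward neighbor, over the global k-mer set. Cycles
#' close when the walk returns to its seed and are reported in their least
#' rotation over both strands; linear unitigs are reported as the
#' lexicographic minimum of the spelling and its reverse complement.
#'
#' @param R character vector of input sequences.
#' @param k k-mer size.
#' @param a abundance threshold.
#' @param canonical canonical mode (identify reverse complements).
#' @return sorted character vector of normalized maximal unitigs.
#' @export
maximal_unitigs_bruteforce <- function(R, k, a = 1L, canonical = TRUE) {
  keys <- names(enumerate_kmers(R, k, a, canonical))
  n <- length(keys)
  if (n == 0L) return(character(0))
  # membership table holds both orientations (canonical mode) so probing a
  # candidate text needs no reverse complement in the walk's inner loop.
  # A value-hashed table, not an environment: environment keys would be
  # interned permanently in the symbol table.
  env <- utils::hashtab("identical", 2L * n)
  for (i in seq_len(n)) utils::sethash(env, keys[i], i)
  if (canonical) {
    rck <- .oracle_rc(keys)
    for (i in seq_len(n)) utils::sethash(env, rck[i], i)
  }

  canon1 <- function(x) if (!canonical) x else {
    rc <- .oracle_rc1(x); if (rc < x) rc else x
  }
  # oriented edge = (index, text); neighbors computed by direct string probes
  fwd_candidates <- function(txt) paste0(substring(txt, 2L, k), DNA_BASES)
  bwd_candidates <- function(txt) paste0(DNA_BASES, substring(txt, 1L, k - 1L))
  lookup <- function(cands) {
    hits <- integer(0); texts <- character(0)
    for (cand in cands) {
      id <- utils::gethash(env, cand)
      if (!is.null(id)) { hits <- c(hits, id); texts <- c(texts, cand) }
    }
    list(idx = hits, texts = texts)
  }

  used <- logical(n)
  wbuf <- character(n + 1L)
  out <- vector("list", n); nout <- 0L
  for (s in seq_len(n)) {
    if (used[s]) next
    used[s] <- TRUE
    seed_txt <- keys[s]
    walk_dir <- function(start_txt, start_idx) {
      # fills wbuf with appended edge texts; returns count and cycle flag
      cur_txt <- start_txt
      np <- 0L
      cyc <- FALSE
      repeat {
        fc <- lookup(fwd_candidates(cur_txt))
        if (length(fc$idx) != 1L) break
        nxt_txt <- fc$texts
        bc <- lookup(bwd_candidates(nxt_txt))
        if (length(bc$idx) != 1L) break
        id <- fc$idx
        if (id == start_idx && nxt_txt == start_txt) { cyc <- TRUE; break }
        if (used[id]) break
        used[id] <<- TRUE
        np <- np + 1L
        wbuf[np] <<- nxt_txt
        cur_txt <- nxt_txt
      }
      list(n = np, cycle = cyc)
    }
    rw <- walk_dir(seed_txt, s)
    rw_txt <- wbuf[seq_len(rw$n)]
    if (rw$cycle) {
      spell <- paste0(seed_txt, paste(substring(rw_txt, k, k), collapse = ""))
      nout <- nout + 1L
      out[[nout]] <- .oracle_cycle_norm(spell, k, canonical)
      next
    }
    # left extension: right extension of the reverse-complement strand
    # (canonical) or an explicit backward walk (plain mode)
    if (canonical) {
      lw <- walk_dir(.oracle_rc1(seed_txt), s)
      left_txt <- rev(.oracle_rc(wbuf[seq_len(lw$n)]))
    } else {
      cur_txt <- seed_txt
      np <- 0L
      repeat {
        bc <- lookup(bwd_candidates(cur_txt))
        if (length(bc$idx) != 1L) break
        prv_txt <- bc$texts
        fc <- lookup(fwd_candidates(prv_txt))
        if (length(fc$idx) != 1L) break
        if (used[bc$idx]) break
        used[bc$idx] <- TRUE
        np <- np + 1L
        wbuf[np] <- prv_txt
        cur_txt <- prv_txt
      }
      left_txt <- rev(wbuf[seq_len(np)])
    }
    all_txt <- c(left_txt, seed_txt, rw_txt)
    spell <- paste0(all_txt[1L],
                    paste(substring(all_txt[-1L], k, k), collapse = ""))
    nout <- nout + 1L
    out[[nout]] <- if (canonical) canon1(spell) else spell
  }
  sort(unlist(out[seq_len(nout)], use.names = FALSE))
}

#' Brute-force node-centric unitigs
#'
#' Builds the node-centric de Bruijn graph (nodes = k-mers, arcs = all
#' (k-1)-suffix/prefix overlaps between present k-mers) from explicit arc
#' lists and extends paths under the node-centric rule: an arc x -> y may be
#' walked inside a unitig only when x has out-degree 1 and y has in-degree 1.
#' Used to exercise the equivalence with the edge-centric construction.
#'
#' @inheritParams maximal_unitigs_bruteforce
#' @return sorted character vector of normalized unitigs.
#' @export
node_centric_unitigs_bruteforce <- function(R, k, a = 1L, canonical = TRUE) {
  keys <- names(enumerate_kmers(R, k, a, canonical))
  n <- length(keys)
  if (n == 0L) return(character(0))
  # oriented node table: rows 1..n forward texts, n+1..2n reverse texts
  if (canonical) {
    texts <- c(keys, .oracle_rc(keys))
    node_of <- rep(seq_len(n), 2L)
  } else {
    texts <- keys
    node_of <- seq_len(n)
  }
  N <- length(texts)
  pre <- substring(texts, 1L, k - 1L)
  suf <- substring(texts, 2L, k)
  # arcs: oriented i -> oriented j iff suf[i] == pre[j]; build by join on the
  # shared (k-1)-mer. Out/in degrees count arcs per *base* (palindromic
  # orientations collapse onto the same text and must not double-count).
  suc <- vector("list", N)
  by_pre <- split(seq_len(N), pre)
  for (i in seq_len(N)) {
    js <- by_pre[[suf[i]]]
    if (!is.null(js)) {
      js <- js[!duplicated(texts[js])]
      suc[[i]] <- js
    }
  }
  outdeg <- lengths(suc)
  prd <- vector("list", N)
  by_suf <- split(seq_len(N), suf)
  for (i in seq_len(N)) {
    js <- by_suf[[pre[i]]]
    if (!is.null(js)) prd[[i]] <- js[!duplicated(texts[js])]
  }
  indeg <- lengths(prd)

  used <- logical(n)
  out <- character(0)
  step_ok <- function(i) {
    if (outdeg[i] != 1L) return(NA_integer_)
    j <- suc[[i]][1L]
    if (indeg[j] != 1L) return(NA_integer_)
    j
  }
  for (s in seq_len(n)) {
    if (used[s]) next
    used[s] <- TRUE
    # forward walk from oriented s
    path <- s
    cur <- s
    cyc <- FALSE
    repeat {
      j <- step_ok(cur)
      if (is.na(j)) break
      if (node_of[j] == s && texts[j] == texts[s]) { cyc <- TRUE; break }
      if (used[node_of[j]]) break
      used[node_of[j]] <- TRUE
      path <- c(path, j)
      cur <- j
    }
    if (!cyc) {
      # backward walk: forward walk from the opposite orientation of s
      back <- integer(0)
      if (canonical) {
        cur <- s + n   # opposite orientation of the seed
        repeat {
          j <- step_ok(cur)
          if (is.na(j)) break
          if (used[node_of[j]]) break
          used[node_of[j]] <- TRUE
          back <- c(back, j)
          cur <- j
        }
      } else {
        cur <- s
        repeat {
          # backward arc p -> cur walkable iff outdeg(p) == 1, indeg(cur) == 1
          ps <- prd[[cur]]
          if (length(ps) != 1L) break
          p <- ps[1L]
          if (outdeg[p] != 1L) break
          if (used[node_of[p]]) break
          used[node_of[p]] <- TRUE
          back <- c(back, p)
          cur <- p
        }
      }
      if (canonical) {
        # opposite-orientation indices back to this strand, in path order
        flip <- function(i) if (i > n) i - n else i + n
        back <- vapply(rev(back), flip, 1L)
      } else {
        back <- rev(back)
      }
      path <- c(back, path)
    }
    spell <- texts[path[1L]]
    if (length(path) > 1L) {
      for (i in path[-1L]) spell <- paste0(spell, substring(texts[i], k, k))
    }
    if (cyc) {
      out <- c(out, .oracle_cycle_norm(spell, k, canonical))
    } else {
      rc <- .oracle_rc1(spell)
      out <- c(out, if (canonical && rc < spell) rc else spell)
    }
  }
  sort(out)
}

#' Naive query oracle
#'
#' Per-position membership scan of each query's (canonical) k-mers in the
#' graph k-mer set; per-color counts via per-file k-mer sets.
#'
#' @param graph_kmers character vector of the graph's (canonical) k-mers.
#' @param queries character vector of query sequences.
#' @param k k-mer size.
#' @param color_files optional list of character vectors, one per color, of
#'   the input sequences of that color.
#' @param canonical canonical mode.
#' @return data.frame with `total_kmers`, `matched`, and (colored) a
#'   `per_color` list column of named counts.
#' @export
query_oracle <- function(graph_kmers, queries, k, color_files = NULL,
                         canonical = TRUE) {
  gset <- utils::hashtab("identical", length(graph_kmers))
  for (q in graph_kmers) utils::sethash(gset, q, TRUE)
  color_sets <- NULL
  if (!is.null(color_files)) {
    color_sets <- lapply(color_files, function(seqs) {
      km <- .oracle_kmers(seqs, k)
      if (canonical) km <- .oracle_canon(km)
      unique(km)
    })
  }
  total <- integer(length(queries)); matched <- integer(length(queries))
  per_color <- vector("list", length(queries))
  for (qi in seq_along(queries)) {
    q <- queries[qi]
    nk <- nchar(q) - k + 1L
    total[qi] <- max(0L, nk)
    if (nk < 1L) { per_color[[qi]] <- integer(0); next }
    km <- substring(q, seq_len(nk), seq_len(nk) + k - 1L)
    ok <- grepl("^[ACGT]+$", km)
    kmc <- km
    kmc[ok] <- if (canonical) .oracle_canon(km[ok]) else km[ok]
    hit <- logical(nk)
    for (i in which(ok)) hit[i] <- !is.null(utils::gethash(gset, kmc[i]))
    matched[qi] <- sum(hit)
    if (!is.null(color_sets)) {
      cnt <- integer(length(color_sets))
      for (ci in seq_along(color_sets)) {
        cnt[ci] <- sum(kmc[hit] %in% color_sets[[ci]])
      }
      names(cnt) <- as.character(seq_along(color_sets) - 1L)
      per_color[[qi]] <- cnt[cnt > 0L]
    }
  }
  res <- data.frame(total_kmers = total, matched = matched)
  if (!is.null(color_sets)) res$per_color <- I(per_color)
  res
}

#' Check the defining conditions of canonical maximal unitigs
#'
#' Directly asserts, on small inputs, the four string-centric conditions: (0)
#' every unitig has length >= k and no two are reverse complements; (1) the
#' canonical k-mer set of U equals the abundance-filtered k-mer set of R; (2)
#' every (k-1)-mer occurring more than once in U (canonically) occurs only as
#' a prefix or suffix; (3) every unitig end is branching, a source, or a sink.
#' Two kinds of ends are exempt from (3): ends of cyclic unitigs (the wrap
#' makes them formally extendable; non-redundancy of cycles is enforced by
#' (2)) and palindromic end (k-1)-mers (the incoming edge reappears reversed
#' among the outgoing candidates, so the literal counts read 1 although the
#' only continuation would reuse that edge).
#'
#' @param U character vector of unitigs (cycles with their (k-1)-wrap).
#' @param R input sequences.
#' @param k k-mer size.
#' @param a abundance threshold.
#' @param is_cycle logical vector marking cyclic unitigs.
#' @param canonical canonical mode.
#' @return TRUE invisibly; stops with a message on the first violated
#'   condition.
#' @export
check_unitig_conditions <- function(U, R, k, a = 1L, is_cycle = NULL,
                                    canonical = TRUE) {
  if (is.null(is_cycle)) is_cycle <- rep(FALSE, length(U))
  norm <- if (canonical) function(v) .oracle_canon(v) else identity
  # condition 0
  if (any(nchar(U) < k)) stop("condition 0 violated: unitig shorter than k")
  if (anyDuplicated(U)) stop("condition 0 violated: duplicate unitig")
  if (canonical) {
    rcU <- .oracle_rc(U)
    hit <- match(U, rcU)
    if (any(!is.na(hit) & hit != seq_along(U))) {
      stop("condition 0 violated: two unitigs are reverse complements")
    }
  }
  # condition 1
  wantR <- names(enumerate_kmers(R, k, a, canonical))
  haveU <- names(enumerate_kmers(U, k, 1L, canonical))
  if (!setequal(wantR, haveU)) {
    stop("condition 1 violated: k-mer sets of R (filtered) and U differ")
  }
  # condition 2: canonical (k-1)-mer occurrence count in U vs placement
  q_all <- .oracle_kmers(U, k - 1L)
  q_can <- norm(q_all)
  counts <- table(q_can)
  # positions: for each unitig, prefix/suffix (k-1)-mers
  internal <- unlist(lapply(U, function(u) {
    np <- nchar(u) - (k - 1L) + 1L
    if (np <= 2L) return(character(0))
    substring(u, 2:(np - 1L), 2:(np - 1L) + k - 2L)
  }), use.names = FALSE)
  internal_can <- norm(internal)
  bad <- unique(internal_can[counts[internal_can] > 1L])
  if (length(bad) > 0L) {
    stop("condition 2 violated: branching (k-1)-mer ", bad[1L],
         " internal to a unitig")
  }
  # condition 3 (maximality), cycles exempt
  kset <- utils::hashtab("identical", length(haveU))
  for (q in haveU) utils::sethash(kset, q, TRUE)
  app_cn1 <- function(x) {
    key <- if (canonical) { rc <- .oracle_rc1(x); if (rc < x) rc else x } else x
    as.integer(!is.null(utils::gethash(kset, key)))
  }
  lin <- which(!is_cycle)
  for (i in lin) {
    u <- U[i]
    for (q in c(substring(u, 1L, k - 1L),
                substring(u, nchar(u) - k + 2L, nchar(u)))) {
      # palindromic end nodes are exempt: the incoming edge b.q reappears
      # among the outgoing candidates as its own reverse complement q.rc(b),
      # so the counts read 1 even though the only "extension" would reuse
      # that edge backwards (possible only for even k - 1)
      if (canonical && .oracle_rc1(q) == q) next
      right <- sum(vapply(DNA_BASES, function(c) app_cn1(paste0(q, c)), 1L))
      left <- sum(vapply(DNA_BASES, function(c) app_cn1(paste0(c, q)), 1L))
      if (right == 1L && left == 1L) {
        stop("condition 3 violated: end (k-1)-mer ", q,
             " of a unitig is extendable on both sides")
      }
    }
  }
  invisible(TRUE)
}
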