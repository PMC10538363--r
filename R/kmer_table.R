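# Per-group k-mer counting and bidirectional unitig extension.
#
# Counting and extension operate per *group* (one group per minimizer value):
# Lemma-1 style guarantees — every occurrence of a k-mer lands in the group(s)
# of its prefix/suffix (k-1)-mer minimizers, with its full in-read abundance —
# hold for groups, not for bucket files, which may store several groups.
# All groups are processed in one vectorized pass by keying every table
# operation on (group, k-mer).
#
# Extension bookkeeping per canonical k-mer entry:
#   hpre / hsuf: window minimizer of the prefix / suffix (k-1)-mer, oriented
#   with the stored canonical text. A k-mer "contains a linking character" in
#   its group exactly when hpre != hsuf (it straddles a segment boundary in
#   every occurrence); extension out of a group stops on the side whose
#   outward window minimizer differs from the group minimizer, and that stop
#   emits an endpoint record (the continuation lives in the other group).

#' Counting parameters
#'
#' @param k k-mer size (>= 2).
#' @param a abundance threshold (>= 1): minimum canonical occurrence count
#'   for a k-mer to enter the graph.
#' @param canonical_mode identify k-mers with their reverse complements.
#' @param long_k_hash key the counting table by the 128-bit Rabin-Karp digest
#'   of each (canonical) k-mer instead of its exact text; engages by default
#'   for k > 64. A digest collision would merge two distinct k-mers: it is
#'   detected (warning) by comparing the representative texts, but not
#'   corrected. Extension always operates on the representative texts.
#' @return list of class `counting_params`.
#' @export
counting_params <- function(k, a = 1L, canonical_mode = TRUE,
                            long_k_hash = NULL) {
  k <- as.integer(k); a <- as.integer(a)
  if (k < 2L) stop("k must be >= 2")
  if (a < 1L) stop("abundance threshold a must be >= 1")
  if (is.null(long_k_hash)) long_k_hash <- k > 64L
  structure(list(k = k, a = a, canonical_mode = isTRUE(canonical_mode),
                 long_k_hash = isTRUE(long_k_hash)),
            class = "counting_params")
}

#' Count k-mers of a set of extended segments
#'
#' Scans every extended segment and counts each k-mer occurrence into a table
#' keyed by (group minimizer, canonical k-mer), tracking abundance, whether
#' any occurrence overlaps a linking character, the oriented prefix/suffix
#' (k-1)-mer window minimizers, and (in colored mode) the deduplicated color
#' set. Segments of several groups may be passed together; entries never mix
#' across groups.
#'
#' @param segments data.table with columns `text`, `left_link`, `right_link`,
#'   `minimizer`, `color` and optionally `wmins` (precomputed per-segment
#'   window minimizers; recomputed when absent).
#' @param cparams a [counting_params()] bundle.
#' @param mparams the [min_params()] used to split the segments.
#' @return `kmer_table`: a data.table with one row per (group, k-mer), columns
#'   `gmin`, `kmer`, `ab`, `link`, `hpre`, `hsuf` and (colored) `colors`.
#' @export
count_bucket <- function(segments, cparams, mparams) {
  k <- cparams$k
  canonical <- cparams$canonical_mode
  stopifnot(k == mparams$k)
  if (is.null(segments) || nrow(segments) == 0L) {
    return(empty_kmer_table(cparams))
  }
  segments <- data.table::as.data.table(segments)
  if (!"wmins" %in% names(segments)) {
    segments[, wmins := lapply(text, window_minimizers, params = mparams)]
  }
  L <- nchar(segments$text)
  nk <- L - k + 1L
  stopifnot(all(nk >= 1L))
  seg_id <- rep(seq_len(nrow(segments)), nk)
  j <- sequence(nk)
  km <- substring(segments$text[seg_id], j, j + k - 1L)

  Wall <- unlist(segments$wmins, use.names = FALSE)
  stopifnot(length(Wall) == sum(nk + 1L))
  off <- c(0L, cumsum(nk + 1L))[seg_id]
  hpre_raw <- Wall[off + j]
  hsuf_raw <- Wall[off + j + 1L]

  link_occ <- (j == 1L & segments$left_link[seg_id]) |
    (j == nk[seg_id] & segments$right_link[seg_id])

  if (canonical) {
    cano <- canonicalize(km)
    fwd <- cano$fwd
    km <- cano$seq
    hpre <- ifelse(fwd, hpre_raw, hsuf_raw)
    hsuf <- ifelse(fwd, hsuf_raw, hpre_raw)
  } else {
    fwd <- rep(TRUE, length(km))
    hpre <- hpre_raw; hsuf <- hsuf_raw
  }

  occ <- data.table::data.table(gmin = segments$minimizer[seg_id], kmer = km,
                                link = link_occ, hpre = hpre, hsuf = hsuf,
                                color = segments$color[seg_id])
  if (cparams$long_k_hash) {
    # hashed long-k representation: aggregation key = 128-bit rolling digest
    # of the (canonical) k-mer; texts are kept as representatives
    digf <- unlist(lapply(segments$text, rk128_kmer_hashes, k = k),
                   use.names = FALSE)
    if (canonical) {
      digr <- unlist(lapply(reverse_complement(segments$text, check = FALSE),
                            function(s) rev(rk128_kmer_hashes(s, k))),
                     use.names = FALSE)
      occ$key <- ifelse(fwd, digf, digr)
    } else {
      occ$key <- digf
    }
  } else {
    occ$key <- occ$kmer
  }
  colored <- !all(is.na(occ$color))
  if (colored) {
    tbl <- occ[, list(kmer = kmer[1L], n_texts = length(unique(kmer)),
                      ab = .N, link = any(link), hpre = hpre[1L],
                      hsuf = hsuf[1L],
                      colors = list(sort(unique(color)))),
               by = c("gmin", "key")]
  } else {
    tbl <- occ[, list(kmer = kmer[1L], n_texts = length(unique(kmer)),
                      ab = .N, link = any(link), hpre = hpre[1L],
                      hsuf = hsuf[1L]),
               by = c("gmin", "key")]
  }
  if (cparams$long_k_hash && any(tbl$n_texts > 1L)) {
    warning("128-bit k-mer digest collision detected (", sum(tbl$n_texts > 1L),
            " key(s) map to multiple k-mer texts); collisions are not corrected")
  }
  tbl[, c("key", "n_texts") := NULL]
  data.table::setorder(tbl, gmin, kmer)
  attr(tbl, "cparams") <- cparams
  attr(tbl, "colored") <- colored
  class(tbl) <- c("kmer_table", class(tbl))
  tbl
}

empty_kmer_table <- function(cparams) {
  tbl <- data.table::data.table(gmin = numeric(), kmer = character(),
                                ab = integer(), link = logical(),
                                hpre = numeric(), hsuf = numeric())
  attr(tbl, "cparams") <- cparams
  attr(tbl, "colored") <- FALSE
  class(tbl) <- c("kmer_table", class(tbl))
  tbl
}

#' Filter a k-mer table at an abundance threshold
#'
#' Retains exactly the entries with abundance >= a. Because a k-mer's
#' abundance inside a group equals its abundance in the whole input, the
#' per-group filter agrees with the global one.
#'
#' @param table a `kmer_table`.
#' @param a abundance threshold.
#' @return the filtered `kmer_table`.
#' @export
filter_abundance <- function(table, a) {
  at <- attributes(table)
  out <- table[table$ab >= a, ]
  attr(out, "cparams") <- at$cparams
  attr(out, "colored") <- at$colored
  if (!inherits(out, "kmer_table")) class(out) <- c("kmer_table", class(out))
  out
}

# Precompute, for every table row and orientation, the unique right/left
# extension inside the row's group. Orientation 1 traverses the stored
# (canonical) text, orientation 2 its reverse complement. In non-canonical
# mode only orientation 1 exists and left arrays are computed explicitly.
build_extension_arrays <- function(tbl, k, canonical) {
  n <- nrow(tbl)
  keys <- tbl$kmer
  gm <- tbl$gmin
  gkey <- paste0(gm, "|", keys)
  texts <- list(keys, if (canonical) reverse_complement(keys, check = FALSE) else NULL)

  match_cand <- function(cand) {
    if (canonical) {
      cc <- canonicalize(cand)
      idx <- match(paste0(gm, "|", cc$seq), gkey)
      list(idx = idx, or = ifelse(cc$fwd, 1L, 2L))
    } else {
      list(idx = match(paste0(gm, "|", cand), gkey), or = rep(1L, length(cand)))
    }
  }

  dirs <- list()
  orients <- if (canonical) 1:2 else 1L
  for (o in orients) {
    txt <- texts[[o]]
    suf <- substring(txt, 2L, k)
    idxm <- matrix(NA_integer_, n, 4L)
    orm <- matrix(NA_integer_, n, 4L)
    for (ci in 1:4) {
      mc <- match_cand(paste0(suf, DNA_BASES[ci]))
      idxm[, ci] <- mc$idx
      orm[, ci] <- mc$or
    }
    pres <- !is.na(idxm)
    deg <- rowSums(pres)
    sel <- max.col(pres, ties.method = "first")
    pick <- cbind(seq_len(n), sel)
    nxt <- ifelse(deg == 1L, idxm[pick], NA_integer_)
    nor <- ifelse(deg == 1L, orm[pick], NA_integer_)
    dirs[[paste0("r", o)]] <- list(deg = deg, idx = nxt, or = nor)
  }
  if (!canonical) {
    pre <- substring(keys, 1L, k - 1L)
    idxm <- matrix(NA_integer_, n, 4L)
    for (ci in 1:4) idxm[, ci] <- match(paste0(gm, "|", DNA_BASES[ci], pre), gkey)
    pres <- !is.na(idxm)
    deg <- rowSums(pres)
    sel <- max.col(pres, ties.method = "first")
    nxt <- ifelse(deg == 1L, idxm[cbind(seq_len(n), sel)], NA_integer_)
    dirs$l1 <- list(deg = deg, idx = nxt, or = rep(1L, n))
  }
  dirs
}

# right-degree of oriented entry (i, o)
.rdeg <- function(arr, i, o) arr[[paste0("r", o)]]$deg[i]
# left-degree of oriented entry (i, o)
.ldeg <- function(arr, i, o, canonical) {
  if (canonical) arr[[paste0("r", 3L - o)]]$deg[i] else arr$l1$deg[i]
}

#' Build intermediate unitigs and endpoint records from segments
#'
#' Runs the per-group pipeline: k-mer counting, abundance filtering, and
#' bidirectional unitig extension. A unitig is grown right (then left) while
#' the candidate extension is unique in both directions inside the group;
#' growth on a side stops with an endpoint record when the terminal k-mer's
#' outward window minimizer leaves the group (the k-mer carries a linking
#' character and its continuation is handled by its other group). In-group
#' cycles are closed and marked. Every filtered k-mer is consumed by exactly
#' one intermediate unitig of its group.
#'
#' @param segments extended segments (see [count_bucket()]); may span groups.
#' @param cparams a [counting_params()] bundle.
#' @param mparams the matching [min_params()].
#' @param color_state optional environment from [color_state_new()]; when
#'   given, each filtered k-mer's color set is interned and recorded.
#' @return list with `unitigs` (data.table: `id`, `text`, `is_cycle`),
#'   `endpoints` (data.table: `kmer`, `id`, `side`, `orient`), and `table`
#'   (the filtered `kmer_table`).
#' @export
process_bucket <- function(segments, cparams, mparams, color_state = NULL) {
  tbl <- count_bucket(segments, cparams, mparams)
  tbl <- filter_abundance(tbl, cparams$a)
  if (!is.null(color_state)) record_kmer_colors(color_state, tbl)
  extend_table(tbl, cparams)
}

# Extension over an already counted+filtered table.
extend_table <- function(tbl, cparams) {
  k <- cparams$k
  canonical <- cparams$canonical_mode
  n <- nrow(tbl)
  empty_out <- list(
    unitigs = data.table::data.table(id = integer(), text = character(),
                                     is_cycle = logical()),
    endpoints = data.table::data.table(kmer = character(), id = integer(),
                                       side = character(), orient = integer()),
    table = tbl)
  if (n == 0L) return(empty_out)

  arr <- build_extension_arrays(tbl, k, canonical)
  gm <- tbl$gmin
  hpre <- tbl$hpre; hsuf <- tbl$hsuf
  texts1 <- tbl$kmer
  texts2 <- if (canonical) reverse_complement(texts1, check = FALSE) else texts1
  last1 <- substring(texts1, k, k)
  last2 <- substring(texts2, k, k)

  # flat successor arrays (orientation 1/2 for canonical; fwd/left for plain)
  rdeg1 <- arr$r1$deg; ridx1 <- arr$r1$idx; ror1 <- arr$r1$or
  if (canonical) {
    rdeg2 <- arr$r2$deg; ridx2 <- arr$r2$idx; ror2 <- arr$r2$or
  } else {
    ldeg1 <- arr$l1$deg; lidx1 <- arr$l1$idx
  }

  used <- logical(n)
  ord <- order(tbl$link, tbl$kmer)   # non-linking k-mers seed first

  bufcap <- n + 1L
  rid <- integer(bufcap); ror <- integer(bufcap)
  lid <- integer(bufcap); lor <- integer(bufcap)

  out_id <- integer(n); out_text <- character(n); out_cycle <- logical(n)
  nout <- 0L
  ep_kmer <- character(2L * n); ep_id <- integer(2L * n)
  ep_side <- character(2L * n); ep_or <- integer(2L * n)
  nep <- 0L

  for (s in ord) {
    if (used[s]) next
    used[s] <- TRUE

    ## ---- right walk from (s, 1) ----
    rp <- 1L; rid[1L] <- s; ror[1L] <- 1L
    rstop <- "branch"
    repeat {
      i <- rid[rp]; o <- ror[rp]
      hout <- if (o == 1L) hsuf[i] else hpre[i]
      if (hout != gm[i]) { rstop <- "link"; break }
      if (canonical && o == 2L) {
        if (rdeg2[i] != 1L) break
        jx <- ridx2[i]; jo <- ror2[i]
      } else {
        if (rdeg1[i] != 1L) break
        jx <- ridx1[i]; jo <- ror1[i]
      }
      bdeg <- if (canonical) (if (jo == 1L) rdeg2[jx] else rdeg1[jx]) else ldeg1[jx]
      if (bdeg != 1L) break
      if (jx == s && jo == 1L) { rstop <- "cycle"; break }
      if (used[jx]) break
      used[jx] <- TRUE
      rp <- rp + 1L; rid[rp] <- jx; ror[rp] <- jo
    }

    nout <- nout + 1L
    if (rstop == "cycle") {
      path_i <- rid[seq_len(rp)]; path_o <- ror[seq_len(rp)]
      out_id[nout] <- nout
      out_text[nout] <- spell_path(path_i, path_o, texts1, texts2, last1, last2)
      out_cycle[nout] <- TRUE
      next
    }

    ## ---- left walk (canonical: right walk on reverse strand) ----
    lp <- 1L; lid[1L] <- s; lor[1L] <- 2L
    lstop <- "branch"
    repeat {
      i <- lid[lp]; o <- lor[lp]
      if (canonical) {
        hout <- if (o == 1L) hsuf[i] else hpre[i]
        if (hout != gm[i]) { lstop <- "link"; break }
        if (o == 2L) {
          if (rdeg2[i] != 1L) break
          jx <- ridx2[i]; jo <- ror2[i]
        } else {
          if (rdeg1[i] != 1L) break
          jx <- ridx1[i]; jo <- ror1[i]
        }
        bdeg <- if (jo == 1L) rdeg2[jx] else rdeg1[jx]
      } else {
        if (hpre[i] != gm[i]) { lstop <- "link"; break }
        if (ldeg1[i] != 1L) break
        jx <- lidx1[i]; jo <- 1L
        bdeg <- rdeg1[jx]
      }
      if (bdeg != 1L) break
      if (used[jx]) break
      used[jx] <- TRUE
      lp <- lp + 1L; lid[lp] <- jx; lor[lp] <- jo
    }

    if (lp > 1L) {
      lpart_i <- rev(lid[2:lp])
      lpart_o <- if (canonical) 3L - rev(lor[2:lp]) else rep(1L, lp - 1L)
    } else {
      lpart_i <- integer(0); lpart_o <- integer(0)
    }
    path_i <- c(lpart_i, rid[seq_len(rp)])
    path_o <- c(lpart_o, ror[seq_len(rp)])
    np <- length(path_i)
    out_id[nout] <- nout
    out_text[nout] <- spell_path(path_i, path_o, texts1, texts2, last1, last2)
    out_cycle[nout] <- FALSE

    if (rstop == "link") {
      nep <- nep + 1L
      ep_kmer[nep] <- texts1[path_i[np]]; ep_id[nep] <- nout
      ep_side[nep] <- "right"; ep_or[nep] <- path_o[np]
    }
    if (lstop == "link") {
      nep <- nep + 1L
      ep_kmer[nep] <- texts1[path_i[1L]]; ep_id[nep] <- nout
      ep_side[nep] <- "left"; ep_or[nep] <- path_o[1L]
    }
  }

  list(unitigs = data.table::data.table(id = out_id[seq_len(nout)],
                                        text = out_text[seq_len(nout)],
                                        is_cycle = out_cycle[seq_len(nout)]),
       endpoints = data.table::data.table(kmer = ep_kmer[seq_len(nep)],
                                          id = ep_id[seq_len(nep)],
                                          side = ep_side[seq_len(nep)],
                                          orient = ep_or[seq_len(nep)]),
       table = tbl)
}

# spell the string of an oriented k-mer path
spell_path <- function(path_i, path_o, texts1, texts2, last1, last2) {
  first <- if (path_o[1L] == 1L) texts1[path_i[1L]] else texts2[path_i[1L]]
  if (length(path_i) == 1L) return(first)
  rest_i <- path_i[-1L]; rest_o <- path_o[-1L]
  ch <- ifelse(rest_o == 1L, last1[rest_i], last2[rest_i])
  paste0(first, paste(ch, collapse = ""))
}
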