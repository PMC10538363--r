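# Randomized seal-and-merge: join intermediate unitigs across groups into
# maximal unitigs. Endpoint records are paired by their shared boundary
# k-mer into 2-unitig chains; chains that share a terminal unitig id are
# concatenated when a randomized round assigns both to that id's bucket; an
# ending with no join and no placeholder is sealed; chains with both ends
# sealed are final. Orientations are tracked so unitigs present in opposite
# strands are reverse-complemented before joining.

# internal chain structure: list(ids, ors (1 fwd / 2 rc of stored text),
# l_sealed, r_sealed, cycle)

flip_chain <- function(ch) {
  ch$ids <- rev(ch$ids)
  ch$ors <- 3L - rev(ch$ors)
  sl <- ch$l_sealed; ch$l_sealed <- ch$r_sealed; ch$r_sealed <- sl
  ch
}

#' Pair endpoint records into initial merge chains
#'
#' Records are grouped by their canonical boundary k-mer; each k-mer must
#' carry exactly two records, contributed by the two groups of a
#' link-flagged k-mer. The two unitigs are oriented so that one presents the
#' boundary k-mer at its right end and the other at its left end with the
#' same spelled text (reverse-complementing one of them when the recorded
#' orientations disagree), and become a 2-element chain with both ends
#' unsealed.
#'
#' @param endpoints data.table with columns `kmer`, `id`, `side`
#'   (`"left"`/`"right"`), `orient` (1 forward / 2 reverse).
#' @return list of chains.
#' @export
pair_endpoints <- function(endpoints, canonical = TRUE) {
  if (is.null(endpoints) || nrow(endpoints) == 0L) return(list())
  endpoints <- data.table::as.data.table(endpoints)
  data.table::setorder(endpoints, kmer, id, side)
  cnt <- endpoints[, .N, by = "kmer"]
  if (any(cnt$N != 2L)) {
    bad <- cnt$kmer[cnt$N != 2L][1L]
    stop("internal consistency error: boundary k-mer ", bad, " has ",
         cnt$N[cnt$kmer == bad], " endpoint records (expected exactly 2)")
  }
  idx <- seq(1L, nrow(endpoints), by = 2L)
  chains <- vector("list", length(idx))
  palin <- endpoints$kmer == reverse_complement(endpoints$kmer, check = FALSE)
  for (ii in seq_along(idx)) {
    i1 <- idx[ii]; i2 <- i1 + 1L
    if (!canonical) {
      # strand-specific: the junction joins a right end to a left end
      sides <- endpoints$side[c(i1, i2)]
      if (setequal(sides, c("left", "right"))) {
        ri <- c(i1, i2)[sides == "right"]; li <- c(i1, i2)[sides == "left"]
        chains[[ii]] <- if (endpoints$id[ri] == endpoints$id[li]) {
          list(ids = endpoints$id[ri], ors = 1L,
               l_sealed = TRUE, r_sealed = TRUE, cycle = TRUE)
        } else {
          list(ids = c(endpoints$id[ri], endpoints$id[li]), ors = c(1L, 1L),
               l_sealed = FALSE, r_sealed = FALSE, cycle = FALSE)
        }
        next
      }
      stop("cannot pair strand-specific endpoint records at boundary k-mer ",
           endpoints$kmer[i1])
    }
    # orient record 1's unitig with the junction at its RIGHT end
    flip1 <- endpoints$side[i1] == "left"
    t1 <- if (flip1) 3L - endpoints$orient[i1] else endpoints$orient[i1]
    # orient record 2's unitig with the junction at its LEFT end
    flip2 <- endpoints$side[i2] == "right"
    t2 <- if (flip2) 3L - endpoints$orient[i2] else endpoints$orient[i2]
    if (t1 != t2 && !palin[i1]) {
      stop("cannot resolve orientations at boundary k-mer ", endpoints$kmer[i1])
    }
    if (endpoints$id[i1] == endpoints$id[i2]) {
      # both records of one unitig share the junction: it closes on itself
      chains[[ii]] <- list(ids = endpoints$id[i1], ors = 1L,
                           l_sealed = TRUE, r_sealed = TRUE, cycle = TRUE)
    } else {
      chains[[ii]] <- list(ids = c(endpoints$id[i1], endpoints$id[i2]),
                           ors = c(if (flip1) 2L else 1L, if (flip2) 2L else 1L),
                           l_sealed = FALSE, r_sealed = FALSE, cycle = FALSE)
    }
  }
  chains
}

# join c1 and c2 at shared terminal unitig `tid`; c1 reaches tid via end e1
# ("L"/"R"), c2 via e2. Returns the merged chain (possibly a closed cycle).
join_chains <- function(c1, e1, c2, e2, tid, canonical = TRUE) {
  if (!canonical) {
    # strand-specific chains cannot be reverse-complemented; a join is only
    # possible right-end-to-left-end (swap roles when needed)
    if (e1 == "L" && e2 == "R") {
      tmp <- c1; c1 <- c2; c2 <- tmp
    } else if (!(e1 == "R" && e2 == "L")) {
      stop("cannot join strand-specific chains at unitig id ", tid)
    }
  } else {
    if (e1 == "L") c1 <- flip_chain(c1)
    if (e2 == "R") c2 <- flip_chain(c2)
  }
  n1 <- length(c1$ids)
  stopifnot(c1$ids[n1] == tid, c2$ids[1L] == tid)
  if (c1$ors[n1] != c2$ors[1L]) {
    stop("orientation mismatch while joining chains at unitig id ", tid)
  }
  out <- list(ids = c(c1$ids, c2$ids[-1L]),
              ors = c(c1$ors, c2$ors[-1L]),
              l_sealed = c1$l_sealed, r_sealed = c2$r_sealed, cycle = FALSE)
  nn <- length(out$ids)
  if (nn >= 2L && out$ids[1L] == out$ids[nn]) {
    # head meets tail: the chain closes into a cycle
    if (out$ors[1L] != out$ors[nn]) {
      stop("orientation mismatch while closing cycle at unitig id ", out$ids[1L])
    }
    out$ids <- out$ids[-nn]; out$ors <- out$ors[-nn]
    out$cycle <- TRUE
  }
  out
}

#' One randomized merge round
#'
#' Every pending chain picks one of its unsealed ends uniformly at random and
#' is filed under the bucket of that end's terminal unitig id; a placeholder
#' is filed for its other end when that end is unsealed. Inside each bucket,
#' the two chains filed under the same terminal id are concatenated
#' (orientation-aware); a filed ending with no join and no placeholder is
#' sealed. Chains with both ends sealed (or closed into cycles) are moved to
#' `finalized`.
#'
#' @param state list with `chains` (pending), `finalized`, `round`,
#'   `merge_buckets`.
#' @return the updated state.
#' @export
merge_round <- function(state) {
  chains <- state$chains
  nb <- state$merge_buckets
  nc <- length(chains)
  if (nc == 0L) return(state)

  lid <- vapply(chains, function(c) c$ids[1L], 1L)
  rid <- vapply(chains, function(c) c$ids[length(c$ids)], 1L)
  lun <- !vapply(chains, function(c) c$l_sealed, TRUE)
  run <- !vapply(chains, function(c) c$r_sealed, TRUE)
  stopifnot(all(lun | run))

  pickL <- ifelse(lun & run, runif(nc) < 0.5, lun)
  akey <- ifelse(pickL, lid, rid)                    # chosen (actual) ending
  aend <- ifelse(pickL, "L", "R")
  other_un <- ifelse(pickL, run, lun)
  pkey <- ifelse(pickL, rid, lid)                    # placeholder ending
  pkey <- pkey[other_un]
  abucket <- akey %% nb
  pbucket <- pkey %% nb

  # group actual entries by (bucket, key); same key implies same bucket
  joined <- logical(nc)
  newly <- list(); nnew <- 0L
  grp <- split(seq_len(nc), akey)
  sizes <- lengths(grp)
  if (any(sizes > 2L)) {
    bad <- grp[[which(sizes > 2L)[1L]]]
    stop("internal consistency error: terminal unitig id ", akey[bad[1L]],
         " shared by ", length(bad), " chains")
  }
  for (g in grp[sizes == 2L]) {
    c1 <- g[1L]; c2 <- g[2L]
    m <- join_chains(chains[[c1]], aend[c1], chains[[c2]], aend[c2],
                     tid = akey[c1], canonical = state$canonical)
    joined[c(c1, c2)] <- TRUE
    nnew <- nnew + 1L; newly[[nnew]] <- m
  }
  # a filed ending with no partner and no placeholder in its bucket is sealed
  singles <- unlist(grp[sizes == 1L], use.names = FALSE)
  if (length(singles)) {
    ph <- paste0(pbucket, "/", pkey)
    no_ph <- !(paste0(abucket[singles], "/", akey[singles]) %in% ph)
    for (ci in singles[no_ph]) {
      if (aend[ci] == "L") chains[[ci]]$l_sealed <- TRUE
      else chains[[ci]]$r_sealed <- TRUE
    }
  }

  keep <- c(chains[!joined], newly[seq_len(nnew)])
  done <- vapply(keep, function(c) c$cycle || (c$l_sealed && c$r_sealed), TRUE)
  state$finalized <- c(state$finalized, keep[done])
  state$chains <- keep[!done]
  state$round <- state$round + 1L
  state
}

#' Run the merge rounds and assemble maximal unitigs
#'
#' Repeats [merge_round()] until no chains are pending, then spells each
#' finalized chain by reverse-complementing unitigs recorded in reverse
#' orientation and merging consecutive texts on their shared k-character
#' overlap (the duplicated boundary k-mer). Intermediate unitigs that took
#' part in no chain are emitted as they are. Cycles are reported once, in
#' their least rotation over both strands. The output set is identical for
#' every seed; only the number of rounds varies.
#'
#' @param chains initial chains from [pair_endpoints()].
#' @param unitigs data.table of intermediate unitigs (`id`, `text`,
#'   `is_cycle`).
#' @param k k-mer size.
#' @param seed integer seed for the randomized rounds.
#' @param merge_buckets number of merge buckets.
#' @param max_rounds safety cap (statistically unreachable).
#' @return list with `unitigs` (sorted normalized strings), `is_cycle`,
#'   `rounds`.
#' @export
run_merging <- function(chains, unitigs, k, seed = 1L, merge_buckets = 64L,
                        max_rounds = 512L, canonical = TRUE) {
  pre_done <- vapply(chains, function(c) c$cycle || (c$l_sealed && c$r_sealed),
                     TRUE)
  state <- list(chains = chains[!pre_done], finalized = chains[pre_done],
                round = 0L, merge_buckets = as.integer(merge_buckets),
                canonical = canonical)
  with_seed(seed, {
    while (length(state$chains) > 0L) {
      if (state$round >= max_rounds) {
        stop("unitig merging did not converge after ", max_rounds, " rounds")
      }
      state <- merge_round(state)
    }
  })

  texts <- unitigs$text[order(unitigs$id)]
  stopifnot(identical(sort(unitigs$id), seq_along(texts)))
  in_chain <- logical(length(texts))

  out <- character(0); out_cyc <- logical(0)
  for (ch in state$finalized) {
    in_chain[ch$ids] <- TRUE
    w <- texts[ch$ids]
    flip <- ch$ors == 2L
    if (any(flip)) w[flip] <- reverse_complement(w[flip], check = FALSE)
    s <- w[1L]
    if (length(w) > 1L) for (i in 2L:length(w)) s <- merge_overlap(s, w[i], k)
    if (ch$cycle) {
      L <- nchar(s)
      stopifnot(substring(s, 1L, k) == substring(s, L - k + 1L, L))
      s <- normalize_cycle(substring(s, 1L, L - 1L), k, canonical)
      out_cyc <- c(out_cyc, TRUE)
    } else {
      s <- normalize_unitig(s, k, canonical = canonical)
      out_cyc <- c(out_cyc, FALSE)
    }
    out <- c(out, s)
  }
  # unitigs untouched by any chain are final as-is
  solo <- which(!in_chain)
  cyc_flag <- unitigs$is_cycle[order(unitigs$id)]
  for (i in solo) {
    out <- c(out, normalize_unitig(texts[i], k, is_cycle = cyc_flag[i],
                                   canonical = canonical))
    out_cyc <- c(out_cyc, cyc_flag[i])
  }
  o <- order(out)
  list(unitigs = out[o], is_cycle = out_cyc[o], rounds = state$round)
}

#' Simulate the single-round join probability of a worst-case pair
#'
#' Two chains that must merge share one ending and have all four ends
#' unsealed (the worst case: their outer ends are still engaged elsewhere, so
#' no sealing helps). Each chain picks one of its two ends uniformly; the
#' pair joins in this round exactly when both pick the shared ending. The
#' theoretical probability is 1/4.
#'
#' @param n number of independent simulated pairs.
#' @param seed integer seed.
#' @return fraction of pairs joined in a single round.
#' @export
simulate_merge_pairs <- function(n, seed = 1L) {
  with_seed(seed, {
    a <- runif(n) < 0.5
    b <- runif(n) < 0.5
    mean(a & b)
  })
}

#' Simulate rounds-to-merge for worst-case pairs
#'
#' Repeats the per-round choice of [simulate_merge_pairs()] until each pair
#' has merged, with outer ends held unsealed throughout (worst case), and
#' returns the mean number of rounds. Geometric with p = 1/4: expectation 4.
#'
#' @param n number of replicate pairs.
#' @param seed integer seed.
#' @return mean number of rounds until the pair merges.
#' @export
simulate_merge_rounds <- function(n, seed = 1L) {
  with_seed(seed, {
    rounds <- numeric(n)
    pending <- seq_len(n)
    r <- 0L
    while (length(pending) > 0L) {
      r <- r + 1L
      np <- length(pending)
      ok <- (runif(np) < 0.5) & (runif(np) < 0.5)
      rounds[pending[ok]] <- r
      pending <- pending[!ok]
    }
    mean(rounds)
  })
}

# evaluate `expr` under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
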