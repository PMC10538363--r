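#' @importFrom stats runif setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Validate DNA strings
#'
#' Checks that every element is a nonempty string over the alphabet
#' \{A, C, G, T\}. Sequences containing other characters (N, IUPAC ambiguity
#' codes, lowercase) must be cleaned upstream with [dna_runs()].
#'
#' @param s character vector.
#' @param what label used in error messages.
#' @return `s`, invisibly.
#' @export
dna_assert <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) == 0L || anyNA(s)) {
    stop(what, " must be a character vector without NAs")
  }
  bad <- !grepl("^[ACGT]+$", s)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T} (first offender: ",
         substr(s[which(bad)[1L]], 1L, 40L), ")")
  }
  invisible(s)
}

#' Split a raw sequence into maximal A/C/G/T runs
#'
#' Input records may contain N or other IUPAC codes; de Bruijn construction
#' operates on clean runs only. Runs shorter than `min_len` are dropped.
#'
#' @param s single character string (any case).
#' @param min_len minimum run length to keep (usually k).
#' @return character vector of clean uppercase runs (possibly empty).
#' @export
dna_runs <- function(s, min_len = 1L) {
  s <- toupper(s)
  runs <- strsplit(s, "[^ACGT]+")[[1L]]
  runs <- runs[nzchar(runs)]
  runs[nchar(runs) >= min_len]
}

#' Reverse complement
#'
#' Vectorized reverse complement over \{A,C,G,T\} strings. An involution:
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param s character vector of DNA strings.
#' @param check validate the input alphabet (disable in hot loops).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(s, check = TRUE) {
  if (check) dna_assert(s)
  stringi::stri_reverse(chartr("ACGT", "TGCA", s))
}

#' Canonical representative of a DNA string
#'
#' The canonical form is the lexicographic minimum of the string and its
#' reverse complement; the orientation records which strand produced it.
#' Palindromes are canonical in the forward orientation.
#'
#' @param s a single DNA string.
#' @return list with `seq` (canonical string) and `orientation`
#'   (`"forward"` or `"reverse"`).
#' @export
canonical <- function(s) {
  dna_assert(s)
  stopifnot(length(s) == 1L)
  rc <- reverse_complement(s, check = FALSE)
  if (rc < s) list(seq = rc, orientation = "reverse")
  else list(seq = s, orientation = "forward")
}

# Vectorized canonicalization used throughout the pipeline.
# Returns list(seq, fwd): fwd TRUE when the input string itself is canonical
# (palindromes count as forward).
canonicalize <- function(s) {
  rc <- reverse_complement(s, check = FALSE)
  flip <- rc < s
  if (any(flip)) s[flip] <- rc[flip]
  list(seq = s, fwd = !flip)
}

#' Merge two strings on a suffix-prefix overlap
#'
#' Returns `x` concatenated with `y` minus its first `t` characters, after
#' checking that the length-`t` suffix of `x` equals the length-`t` prefix of
#' `y`. The result has length `nchar(x) + nchar(y) - t` and contains every
#' j-mer of `x` and of `y` for `j <= t + 1`.
#'
#' @param x,y DNA strings.
#' @param t overlap length (`0 <= t <= min(nchar(x), nchar(y))`).
#' @return the merged string.
#' @export
merge_overlap <- function(x, y, t) {
  stopifnot(length(x) == 1L, length(y) == 1L, t >= 0L,
            t <= nchar(x), t <= nchar(y))
  if (substring(x, nchar(x) - t + 1L, nchar(x)) != substring(y, 1L, t)) {
    stop("overlap mismatch: suffix of x != prefix of y at t = ", t)
  }
  paste0(x, substring(y, t + 1L))
}

#' Count occurrences of a pattern in a string multiset
#'
#' `occ()` counts every (possibly overlapping) occurrence of `x` in the
#' strings of `R`. `occ_cn()` adds the occurrences of the reverse complement,
#' except for palindromes (`x == reverse_complement(x)`), which are counted
#' once per occurrence.
#'
#' @param x pattern string.
#' @param R character vector (multiset of strings).
#' @return integer count.
#' @export
occ <- function(x, R) {
  stopifnot(length(x) == 1L)
  if (length(R) == 0L) return(0L)
  hits <- gregexpr(paste0("(?=", x, ")"), R, perl = TRUE)
  sum(vapply(hits, function(h) if (h[1L] == -1L) 0L else length(h), 1L))
}

#' @rdname occ
#' @export
occ_cn <- function(x, R) {
  rc <- reverse_complement(x)
  if (identical(rc, x)) occ(x, R) else occ(x, R) + occ(rc, R)
}

#' @rdname occ
#' @export
app <- function(x, R) min(1L, occ(x, R))

#' @rdname occ
#' @export
app_cn <- function(x, R) min(1L, occ_cn(x, R))

# All k-mers of one string, in order (empty when nchar(s) < k).
kmers_of <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) return(character())
  substring(s, seq_len(n), seq_len(n) + k - 1L)
}

# Canonical k-mer set (unique) of a vector of sequences.
canonical_kmer_set <- function(seqs, k) {
  km <- unlist(lapply(seqs, kmers_of, k = k), use.names = FALSE)
  if (length(km) == 0L) return(character())
  unique(canonicalize(km)$seq)
}

#' Normalize a cyclic unitig spelling
#'
#' A cyclic unitig is reported as the lexicographically least linearization
#' over all rotations of its edge cycle and both strands. The input spelling
#' must carry the (k-1)-character wrap (its first k-1 characters equal its
#' last k-1 characters).
#'
#' @param s cyclic spelling with wrap.
#' @param k k-mer size.
#' @param canonical also consider the reverse-complement strand.
#' @return normalized spelling (same length as `s`).
#' @export
normalize_cycle <- function(s, k, canonical = TRUE) {
  L <- nchar(s)
  E <- L - (k - 1L)
  stopifnot(E >= 1L)
  if (substring(s, 1L, k - 1L) != substring(s, L - k + 2L, L)) {
    stop("not a cyclic spelling: missing (k-1)-wrap")
  }
  if (E > 20000L) stop("cycle too large to normalize (", E, " edges)")
  best_rot <- function(x) {
    core <- substring(x, 1L, E)
    d <- paste0(core, core, substring(core, 1L, k))
    min(substring(d, seq_len(E), seq_len(E) + E + k - 2L))
  }
  if (canonical) min(best_rot(s), best_rot(reverse_complement(s, check = FALSE)))
  else best_rot(s)
}

# Normalize one (possibly cyclic) unitig string for set comparison/output.
normalize_unitig <- function(s, k, is_cycle = FALSE, canonical = TRUE) {
  if (is_cycle) return(normalize_cycle(s, k, canonical))
  if (!canonical) return(s)
  rc <- reverse_complement(s, check = FALSE)
  if (rc < s) rc else s
}
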