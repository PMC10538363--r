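# Rolling m-mer hashing and per-(k-1)-mer minimizer computation. m-mers are
# encoded as big-endian base-4 integers (so numeric order == lexicographic
# order), hashed by a pluggable function, and minimized over sliding windows
# of k-m consecutive m-mers (one window per (k-1)-mer).

MIX_P <- 2147483629  # prime < 2^31; all mixing stays exact in doubles

# pluggable m-mer hash functions: numeric m-mer code -> numeric hash.
# "rank" is the identity on the base-4 code (the toy hash used in worked
# examples); "mix"/"mix2" are well-mixed modular hashes used in production and
# in the hash-independence tests.
unitigr_hash_funs <- list(
  rank = function(code) code,
  mix = function(code) {
    h <- ((code %% MIX_P) * 4000037 + 1299709) %% MIX_P
    (h * 4000037 + 15485863) %% MIX_P
  },
  mix2 = function(code) {
    h <- ((code %% MIX_P) * 3999971 + 7368787) %% MIX_P
    (h * 3999971 + 32452843) %% MIX_P
  }
)

.codes_lut <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  lut
})

base_codes <- function(s) .codes_lut[utf8ToInt(s)]

# big-endian base-4 codes of all m-mers of a 0..3 code vector
mmer_codes <- function(b, m) {
  n <- length(b)
  if (n < m) return(numeric())
  v <- numeric(n - m + 1L)
  for (j in seq_len(m)) v <- v * 4 + b[j:(n - m + j)]
  v
}

#' Default minimizer length for a given k
#'
#' The minimizer length only affects how evenly work is spread over groups,
#' never the unitig output (tested); the default is
#' `max(1, min(12, k - 2))`, a standard desk-scale compromise between group
#' granularity (larger m: more, smaller groups) and window size. A
#' user-supplied `m` overrides the rule.
#'
#' @param k k-mer size (>= 2).
#' @param m optional user override, `1 <= m <= k - 1`.
#' @return the minimizer length.
#' @export
choose_m <- function(k, m = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) stop("k must be an integer >= 2")
  k <- as.integer(k)
  if (is.null(m)) return(max(1L, min(12L, k - 2L)))
  m <- as.integer(m)
  if (m < 1L || m > k - 1L) stop("m must satisfy 1 <= m <= k - 1")
  if (m > 26L) stop("m > 26 is not supported by the exact m-mer encoding")
  m
}

#' Minimizer parameter bundle
#'
#' @param k k-mer size (>= 2).
#' @param m minimizer length; defaults to [choose_m()].
#' @param hash_name one of `"mix"` (default), `"mix2"`, `"rank"`.
#' @param canonical use the canonical m-mer hash (invariant under reverse
#'   complement), required for canonical unitig construction.
#' @return list of class `min_params`.
#' @export
min_params <- function(k, m = NULL, hash_name = "mix", canonical = TRUE) {
  m <- choose_m(k, m)
  if (!hash_name %in% names(unitigr_hash_funs)) {
    stop("unknown hash_name: ", hash_name)
  }
  structure(list(k = as.integer(k), m = m, hash_name = hash_name,
                 canonical = isTRUE(canonical)),
            class = "min_params")
}

#' Rolling hashes of all m-mers of a sequence
#'
#' One hash per m-mer of `s`, left to right (`nchar(s) - m + 1` values),
#' identical to hashing each m-mer independently. With `canonical = TRUE`
#' each m-mer is replaced by its canonical form before hashing, so the hash
#' of an m-mer always equals the hash of its reverse complement.
#'
#' @param s DNA string.
#' @param m m-mer length.
#' @param hash_name hash function name (see [min_params()]).
#' @param canonical canonical-hash mode.
#' @return numeric vector of hashes (empty when `nchar(s) < m`).
#' @export
rolling_hashes <- function(s, m, hash_name = "mix", canonical = FALSE) {
  stopifnot(length(s) == 1L)
  b <- base_codes(s)
  if (anyNA(b)) stop("sequence contains characters outside {A,C,G,T}")
  code <- mmer_codes(b, m)
  if (length(code) == 0L) return(numeric())
  if (canonical) {
    rcc <- mmer_codes(rev(3L - b), m)
    code <- pmin(code, rev(rcc))
  }
  unitigr_hash_funs[[hash_name]](code)
}

#' Hash of a single m-mer under the canonical scheme
#'
#' `canonical_hash(x) == canonical_hash(reverse_complement(x))` for every
#' m-mer `x`.
#'
#' @param x a single m-mer.
#' @param hash_name hash function name.
#' @return numeric hash value.
#' @export
canonical_hash <- function(x, hash_name = "mix") {
  rolling_hashes(x, nchar(x), hash_name = hash_name, canonical = TRUE)
}

#' Window minimizers: one value per (k-1)-mer
#'
#' For each (k-1)-mer of `s`, the minimum hash over its `k - m` constituent
#' m-mers, computed in a single pass. The minimizer is a hash value only; no
#' position is tracked, so ties need no tie-breaking.
#'
#' @param s DNA string.
#' @param params a [min_params()] bundle.
#' @return numeric vector of `nchar(s) - (k - 1) + 1` minimizers (empty when
#'   `nchar(s) < k - 1`).
#' @export
window_minimizers <- function(s, params) {
  k <- params$k; m <- params$m
  if (nchar(s) < k - 1L) return(numeric())
  h <- rolling_hashes(s, m, params$hash_name, params$canonical)
  w <- k - m
  nw <- length(h) - w + 1L
  out <- h[seq_len(nw)]
  if (w > 1L) {
    for (j in seq_len(w - 1L)) out <- pmin(out, h[(1L + j):(nw + j)])
  }
  out
}
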