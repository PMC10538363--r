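# 128-bit integer arithmetic on 8x16-bit limbs (little-endian doubles) backing
# (a) the Rabin-Karp representation of k-mers for k > 64 and (b) the strong
# 128-bit hash used to intern color sets. All operations are mod 2^128.

RK_LIMBS <- 8L
RK_BASE <- 1000003          # polynomial base, < 2^20 so limb products stay exact
RK_PRIME_CODES <- c(A = 2, C = 3, G = 5, T = 7)  # one prime per base

rk_zero <- function() numeric(RK_LIMBS)

rk_carry <- function(v) {
  for (i in seq_len(RK_LIMBS - 1L)) {
    c <- floor(v[i] / 65536)
    v[i] <- v[i] - c * 65536
    v[i + 1L] <- v[i + 1L] + c
  }
  v[RK_LIMBS] <- v[RK_LIMBS] %% 65536
  v
}

rk_from_num <- function(x) {
  v <- rk_zero()
  i <- 1L
  while (x > 0 && i <= RK_LIMBS) {
    v[i] <- x %% 65536
    x <- floor(x / 65536)
    i <- i + 1L
  }
  v
}

rk_add <- function(a, b) rk_carry(a + b)

rk_sub <- function(a, b) {
  # a - b mod 2^128, limb-wise with borrow
  v <- a - b
  for (i in seq_len(RK_LIMBS - 1L)) {
    if (v[i] < 0) {
      br <- ceiling(-v[i] / 65536)
      v[i] <- v[i] + br * 65536
      v[i + 1L] <- v[i + 1L] - br
    }
  }
  v[RK_LIMBS] <- v[RK_LIMBS] %% 65536
  v
}

rk_mul_small <- function(a, s) {
  stopifnot(s >= 0, s < 2^25)
  rk_carry(a * s)
}

rk_mul <- function(a, b) {
  v <- rk_zero()
  for (i in seq_len(RK_LIMBS)) {
    if (b[i] == 0) next
    idx <- i:RK_LIMBS
    v[idx] <- v[idx] + a[seq_len(RK_LIMBS - i + 1L)] * b[i]
    v <- rk_carry(v)
  }
  v
}

rk_hex <- function(v) paste(sprintf("%04x", rev(v)), collapse = "")

rk_pow_base <- function(e) {
  v <- rk_from_num(1)
  for (i in seq_len(e)) v <- rk_mul_small(v, RK_BASE)
  v
}

#' 128-bit Rabin-Karp hash of a DNA string
#'
#' Polynomial hash over 128-bit modular arithmetic where each base carries a
#' distinct prime code (A=2, C=3, G=5, T=7):
#' `h(s) = sum_i code(s_i) * B^(n-i) mod 2^128`. Nonbijective for long
#' strings: it backs the hashed k-mer representation used when k > 64, where
#' storing exact keys is wasteful. Equal strings always hash equal; collisions
#' between distinct k-mers are possible but astronomically rare and are
#' detected (not corrected) downstream.
#'
#' @param s a single DNA string.
#' @return 32-character lowercase hex digest.
#' @seealso [rk128_kmer_hashes()] for the rolling version.
#' @export
rk128_hash <- function(s) {
  dna_assert(s)
  stopifnot(length(s) == 1L)
  codes <- RK_PRIME_CODES[strsplit(s, NULL)[[1L]]]
  h <- rk_zero()
  for (cd in codes) h <- rk_carry(rk_mul_small(h, RK_BASE) + c(cd, numeric(RK_LIMBS - 1L)))
  rk_hex(h)
}

#' Rolling 128-bit hashes of all k-mers of a sequence
#'
#' Computes the [rk128_hash()] of every k-mer of `s` in one left-to-right
#' pass: each hash is obtained from the previous one in O(1) 128-bit
#' operations (drop the leading character, append the trailing one).
#' Identical to hashing each k-mer from scratch.
#'
#' @param s DNA string.
#' @param k k-mer length (`nchar(s) >= k`).
#' @param canonical hash the canonical form of each k-mer instead of the
#'   literal k-mer (hash then invariant under reverse complement of `s`).
#' @return character vector of `nchar(s) - k + 1` hex digests.
#' @export
rk128_kmer_hashes <- function(s, k, canonical = FALSE) {
  dna_assert(s)
  n <- nchar(s) - k + 1L
  if (n < 1L) return(character())
  if (canonical) {
    km <- kmers_of(s, k)
    return(vapply(canonicalize(km)$seq, rk128_hash, "", USE.NAMES = FALSE))
  }
  codes <- RK_PRIME_CODES[strsplit(s, NULL)[[1L]]]
  powk <- rk_pow_base(k - 1L)
  out <- character(n)
  h <- rk_zero()
  for (i in seq_len(k)) h <- rk_carry(rk_mul_small(h, RK_BASE) + c(codes[i], numeric(RK_LIMBS - 1L)))
  out[1L] <- rk_hex(h)
  if (n > 1L) {
    for (i in 2L:n) {
      h <- rk_sub(h, rk_mul_small(powk, codes[i - 1L]))
      h <- rk_carry(rk_mul_small(h, RK_BASE) + c(codes[i + k - 1L], numeric(RK_LIMBS - 1L)))
      out[i] <- rk_hex(h)
    }
  }
  out
}

# Strong 128-bit digest of an integer/raw byte sequence (used to intern color
# sets). Polynomial over 2^128 with a larger base plus a length term; a deep
# compare guards the (theoretical) collisions at the call site.
hash128_bytes <- function(bytes) {
  if (is.raw(bytes)) bytes <- as.integer(bytes)
  h <- rk_from_num(length(bytes) + 1)
  for (b in bytes) {
    h <- rk_carry(rk_mul_small(h, 16777619) + c(b + 1, numeric(RK_LIMBS - 1L)))
  }
  rk_hex(h)
}
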