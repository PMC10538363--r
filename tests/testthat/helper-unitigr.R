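# Shared test helpers. Expected values are computed by deliberately naive,
# test-local code so the package implementation is checked against an
# independent route.

# naive reverse complement (character-by-character)
naive_rc <- function(s) {
  vapply(s, function(x) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(x, NULL)[[1]])), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# naive overlapping occurrence count of x in strings R
naive_occ <- function(x, R) {
  n <- nchar(x)
  sum(vapply(R, function(s) {
    L <- nchar(s)
    if (L < n) return(0L)
    sum(vapply(seq_len(L - n + 1L), function(i)
      substr(s, i, i + n - 1L) == x, TRUE))
  }, 1L))
}

naive_occ_cn <- function(x, R) {
  rc <- naive_rc(x)
  if (rc == x) naive_occ(x, R) else naive_occ(x, R) + naive_occ(rc, R)
}

# all k-mers of a string, naive
naive_kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  vapply(seq_len(L - k + 1L), function(i) substr(s, i, i + k - 1L), "")
}

naive_canon <- function(km) {
  rc <- naive_rc(km)
  ifelse(rc < km, rc, km)
}

# the toy "rank" m-mer hash: big-endian base-4 code
rank_hash <- function(mmer) {
  codes <- c(A = 0, C = 1, G = 2, T = 3)
  sum(codes[strsplit(mmer, NULL)[[1]]] * 4^((nchar(mmer) - 1):0))
}

# naive per-(k-1)-mer window minimizers of a read under the rank hash
naive_window_minimizers <- function(read, k, m, canonical = FALSE) {
  mm <- naive_kmers(read, m)
  h <- vapply(mm, function(x) {
    if (canonical) x <- min(x, naive_rc(x))
    rank_hash(x)
  }, 1)
  w <- k - m
  vapply(seq_len(length(h) - w + 1L), function(i) min(h[i:(i + w - 1L)]), 1)
}

# synthesize a kmer_table directly (extension unit tests); all entries in one
# group with non-boundary windows unless hpre/hsuf given
make_table <- function(kmers, k, canonical_mode = FALSE, gmin = 0,
                       hpre = NULL, hsuf = NULL, ab = NULL, link = NULL) {
  n <- length(kmers)
  tbl <- data.table::data.table(
    gmin = rep(gmin, n), kmer = kmers,
    ab = if (is.null(ab)) rep(1L, n) else ab,
    link = if (is.null(link)) rep(FALSE, n) else link,
    hpre = if (is.null(hpre)) rep(gmin, n) else hpre,
    hsuf = if (is.null(hsuf)) rep(gmin, n) else hsuf)
  data.table::setorder(tbl, gmin, kmer)
  attr(tbl, "cparams") <- counting_params(k, 1L, canonical_mode)
  attr(tbl, "colored") <- FALSE
  class(tbl) <- c("kmer_table", class(tbl))
  tbl
}

# build segments for count_bucket tests without invariant checking
make_segments <- function(texts, left_link, right_link, mparams,
                          minimizer = 0, color = NA_integer_) {
  data.table::data.table(
    text = texts, left_link = left_link, right_link = right_link,
    minimizer = rep_len(minimizer, length(texts)),
    color = rep_len(as.integer(color), length(texts)))
}

# normalized unitig set equality helper
expect_same_unitigs <- function(got, want, info = NULL) {
  expect_identical(got, want, info = info)
}

# standard small parameter bundle for toy (rank-hash) examples
toy_params <- function(k, m, canonical = FALSE) {
  min_params(k, m, hash_name = "rank", canonical = canonical)
}
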