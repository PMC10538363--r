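test_that("count_bucket flags linking characters and folds strands", {
  mp <- toy_params(k = 3, m = 1)
  cp <- counting_params(3, canonical_mode = FALSE)
  # one segment "ACGT" whose final T is a linking character
  segs <- make_segments("ACGT", left_link = FALSE, right_link = TRUE, mp)
  tbl <- count_bucket(segs, cp, mp)
  expect_identical(tbl$kmer[order(tbl$kmer)], c("ACG", "CGT"))
  expect_identical(tbl$link[match(c("ACG", "CGT"), tbl$kmer)], c(FALSE, TRUE))
  expect_identical(tbl$ab, c(1L, 1L))

  # canonical folding: ACG and CGT are one canonical k-mer
  cpc <- counting_params(3, canonical_mode = TRUE)
  mpc <- toy_params(k = 3, m = 1, canonical = TRUE)
  segs2 <- make_segments(c("ACG", "CGT"), left_link = FALSE, right_link = FALSE, mpc)
  tbl2 <- count_bucket(segs2, cpc, mpc)
  expect_identical(nrow(tbl2), 1L)
  expect_identical(tbl2$kmer, "ACG")
  expect_identical(tbl2$ab, 2L)
})

test_that("abundances equal brute-force strand-pooled counts over segments", {
  set.seed(3)
  for (trial in 1:8) {
    read <- random_genome(80, seed = 1600 + trial)
    k <- 7
    p <- min_params(k, 3, canonical = TRUE)
    segs <- unitigr:::split_extend(read, p)
    cp <- counting_params(k, canonical_mode = TRUE)
    tbl <- count_bucket(segs, cp, p)
    # per group: abundance of each canonical k-mer equals a naive scan of the
    # group's extended segments
    for (i in seq_len(nrow(tbl))) {
      G <- segs$text[segs$minimizer == tbl$gmin[i]]
      expect_identical(tbl$ab[i], naive_occ_cn(tbl$kmer[i], G))
    }
    # a k-mer straddles segment boundaries (link flag) iff its two end
    # (k-1)-mer minimizers differ
    h1 <- vapply(substr(tbl$kmer, 1, k - 1), function(q)
      window_minimizers(q, p), 1)
    h2 <- vapply(substr(tbl$kmer, 2, k), function(q)
      window_minimizers(q, p), 1)
    expect_identical(tbl$link, unname(h1 != h2))
    expect_identical(unname(h1), tbl$hpre)
    expect_identical(unname(h2), tbl$hsuf)
  }
})

test_that("filter_abundance keeps exactly the entries at threshold", {
  mp <- toy_params(k = 3, m = 1)
  cp <- counting_params(3, canonical_mode = FALSE)
  segs <- make_segments(c("ACGT", "ACGT", "TTTT"),
                        left_link = FALSE, right_link = FALSE, mp)
  tbl <- count_bucket(segs, cp, mp)
  expect_identical(filter_abundance(tbl, 1L)$kmer, tbl$kmer)
  f2 <- filter_abundance(tbl, 2L)
  expect_setequal(f2$kmer, c("ACG", "CGT", "TTT"))
  expect_identical(nrow(filter_abundance(tbl, 3L)), 0L)
})

test_that("extension merges unique-in-both-directions chains only", {
  # chain of three k-mers: two unique extensions then none
  res <- unitigr:::extend_table(make_table(c("ACG", "CGT", "GTA"), k = 3),
                                counting_params(3, canonical_mode = FALSE))
  expect_identical(res$unitigs$text, "ACGTA")
  expect_identical(nrow(res$endpoints), 0L)

  # forward branch: two candidates after CG -> seed stays alone
  res2 <- unitigr:::extend_table(make_table(c("ACG", "CGT", "CGA"), k = 3),
                                 counting_params(3, canonical_mode = FALSE))
  expect_setequal(res2$unitigs$text, c("ACG", "CGT", "CGA"))

  # backward branch at the target blocks the merge even if forward is unique
  res3 <- unitigr:::extend_table(make_table(c("ACG", "GCG", "CGT"), k = 3),
                                 counting_params(3, canonical_mode = FALSE))
  expect_setequal(res3$unitigs$text, c("ACG", "GCG", "CGT"))
})

test_that("extension stops with an endpoint record at group boundaries", {
  # hsuf of GTA differs from the group minimizer: the continuation lives in
  # another group, so the right end must emit a record
  tbl <- make_table(c("ACG", "CGT", "GTA"), k = 3, gmin = 5,
                    hpre = c(5, 5, 5), hsuf = c(5, 5, 9))
  res <- unitigr:::extend_table(tbl, counting_params(3, canonical_mode = FALSE))
  expect_identical(res$unitigs$text, "ACGTA")
  expect_identical(nrow(res$endpoints), 1L)
  expect_identical(res$endpoints$kmer, "GTA")
  expect_identical(res$endpoints$side, "right")

  # a lone boundary k-mer emits one record, on its outward side only
  lone <- make_table("ACG", k = 3, gmin = 5, hpre = 5, hsuf = 9)
  resL <- unitigr:::extend_table(lone, counting_params(3, canonical_mode = FALSE))
  expect_identical(resL$endpoints$side, "right")
  lone2 <- make_table("ACG", k = 3, gmin = 9, hpre = 5, hsuf = 9)
  resL2 <- unitigr:::extend_table(lone2, counting_params(3, canonical_mode = FALSE))
  expect_identical(resL2$endpoints$side, "left")
})

test_that("in-group cycles close and are reported once", {
  # circular ACGT: k-mers ACG, CGT, GTA, TAC form a cycle in one group
  res <- unitigr:::extend_table(make_table(c("ACG", "CGT", "GTA", "TAC"), k = 3),
                                counting_params(3, canonical_mode = FALSE))
  expect_identical(nrow(res$unitigs), 1L)
  expect_true(res$unitigs$is_cycle)
  expect_identical(nchar(res$unitigs$text), 6L)  # 4 edges + k - 1 wrap
  expect_identical(nrow(res$endpoints), 0L)
})

test_that("every filtered k-mer lands in exactly one intermediate unitig", {
  for (trial in 1:6) {
    g <- random_genome(500, seed = 1700 + trial)
    k <- 9
    p <- min_params(k, canonical = TRUE)
    cp <- counting_params(k, canonical_mode = TRUE)
    segs <- unitigr:::split_extend(g, p)
    proc <- process_bucket(segs, cp, p)
    got <- sort(unlist(lapply(proc$unitigs$text, function(u)
      naive_canon(naive_kmers(u, k)))))
    # boundary k-mers appear once per group; collapse per (group, kmer) rows
    want <- sort(proc$table$kmer)
    expect_identical(got, want)
  }
})
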