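# expected segmentation derived by independent enumeration: hash every m-mer,
# take window minima per (k-1)-mer, group equal consecutive minima
naive_split <- function(read, k, m, canonical = FALSE) {
  W <- naive_window_minimizers(read, k, m, canonical)
  r <- rle(W)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  data.frame(start = starts - 1L, end = ends + k - 2L,
             text = vapply(seq_along(starts), function(i)
               substr(read, starts[i], ends[i] + k - 2L), ""),
             minimizer = r$values)
}

test_that("split_sequence groups consecutive (k-1)-mers by window minimizer", {
  # the worked toy example: every (k-1)-mer run shares one minimizer and
  # consecutive segments overlap on exactly k - 2 characters
  read <- "ACGTACGT"
  p <- toy_params(k = 4, m = 2)
  segs <- split_sequence(read, p)
  expect_equal(as.data.frame(segs), naive_split(read, 4, 2))
  expect_identical(segs$text, c("ACG", "CGT", "GTA", "TACG", "CGT"))

  # single distinct m-mer: whole read is one segment
  one <- split_sequence("AAAAAA", p)
  expect_identical(one$text, "AAAAAA")

  # |read| = k: the read's two (k-1)-mers, grouped by their minima
  short <- split_sequence("ACGT", p)
  expect_equal(as.data.frame(short), naive_split("ACGT", 4, 2))

  # reads shorter than k yield no segments
  expect_identical(nrow(split_sequence("ACG", p)), 0L)

  set.seed(7)
  for (i in 1:25) {
    read <- random_genome(sample(10:120, 1), seed = 1300 + i)
    k <- sample(5:9, 1); m <- sample(2:3, 1)
    segs <- split_sequence(read, toy_params(k, m))
    expect_equal(as.data.frame(segs), naive_split(read, k, m))
    # coverage and k-2 overlaps
    expect_identical(segs$start[1], 0L)
    expect_identical(segs$end[nrow(segs)], nchar(read))
    if (nrow(segs) > 1) {
      expect_true(all(segs$end[-nrow(segs)] - segs$start[-1] == k - 2L))
    }
  }
})

test_that("extend_segments adds linking characters with k-overlaps", {
  read <- "ACGTACGT"
  p <- toy_params(k = 4, m = 2)
  segs <- split_sequence(read, p)
  ext <- extend_segments(read, segs)
  # first segment has no left link; last has no right link
  expect_false(ext$left_link[1])
  expect_false(ext$right_link[nrow(ext)])
  expect_identical(ext$text[1:2], c("ACGT", "ACGTA"))
  expect_true(ext$right_link[1] && ext$left_link[2])
  # consecutive extended segments overlap on exactly k characters
  for (i in seq_len(nrow(ext) - 1)) {
    t1 <- ext$text[i]; t2 <- ext$text[i + 1]
    expect_identical(substring(t1, nchar(t1) - 3L), substring(t2, 1L, 4L))
  }
  # single-segment read: both flags false
  ext1 <- extend_segments("AAAAAA", split_sequence("AAAAAA", p))
  expect_false(ext1$left_link[1] || ext1$right_link[1])
})

test_that("merging consecutive extended segments reconstructs the read", {
  for (i in 1:15) {
    read <- random_genome(sample(30:200, 1), seed = 1400 + i)
    k <- sample(c(7, 11, 15), 1)
    p <- min_params(k, canonical = TRUE)
    ext <- extend_segments(read, split_sequence(read, p))
    got <- ext$text[1]
    if (nrow(ext) > 1) {
      for (j in 2:nrow(ext)) got <- merge_overlap(got, ext$text[j], k)
    }
    expect_identical(got, read)
  }
})

test_that("assign_bucket is deterministic, validated and near-uniform", {
  expect_identical(assign_bucket(123456, 1L), 0L)
  expect_identical(assign_bucket(99, 16L), assign_bucket(99, 16L))
  expect_error(assign_bucket(1, 12L), "power of two")
  set.seed(9)
  h <- floor(runif(20000) * 2^31)
  tab <- table(assign_bucket(h, 16L))
  expect_identical(length(tab), 16L)
  chi <- sum((tab - 1250)^2 / 1250)
  expect_lt(chi, 50)  # chi-square df=15, generous bound
})

test_that("the three grouping guarantees hold on read-splitting output", {
  # groups built from the pipeline's split; occurrence counts by naive scan
  set.seed(13)
  for (trial in 1:6) {
    g <- random_genome(300, seed = 1500 + trial)
    reads <- sample_reads(g, 60, coverage = 1, rc_prob = 0.5,
                          seed = trial, tile_overlap = 20)
    k <- 7
    p <- min_params(k, 3, canonical = TRUE)
    ext <- data.table::rbindlist(lapply(reads, function(r)
      data.table::as.data.table(extend_segments(r, split_sequence(r, p)))))
    groups <- split(ext$text, ext$minimizer)
    kmers <- unique(naive_canon(unlist(lapply(reads, naive_kmers, k = k))))
    app_in_group <- function(x, G) {
      naive_occ(x, G) + if (naive_rc(x) != x) naive_occ(naive_rc(x), G) else 0L
    }
    for (x in kmers) {
      hits <- names(groups)[vapply(groups, function(G)
        app_in_group(x, G) > 0L, TRUE)]
      h1 <- window_minimizers(substr(x, 1, k - 1), p)
      h2 <- window_minimizers(substr(x, 2, k), p)
      # (a) at most two groups; exactly two iff the two end minimizers differ
      expect_lte(length(hits), 2L)
      expect_identical(length(hits) == 2L, h1 != h2)
      expect_setequal(as.numeric(hits), unique(c(h1, h2)))
      # (b) in-group abundance equals global abundance
      for (h in hits) {
        expect_identical(app_in_group(x, groups[[h]]), naive_occ_cn(x, reads))
      }
      # (c) if mini(x) = h, any (k-1)-overlapping k-mer is in G_h
      hx <- min(window_minimizers(x, p))
      if (h1 == h2) {
        G <- groups[[as.character(hx)]]
        for (y in kmers) {
          overlaps <- substr(x, 2, k) == substr(y, 1, k - 1) ||
            substr(y, 2, k) == substr(x, 1, k - 1) ||
            substr(naive_rc(x), 2, k) == substr(y, 1, k - 1) ||
            substr(y, 2, k) == substr(naive_rc(x), 1, k - 1)
          if (overlaps) expect_gt(app_in_group(y, G), 0L)
        }
      }
    }
  }
})

test_that("split_collection writes versioned bucket files that reload", {
  tmp <- tempfile("buckets_")
  g <- random_genome(400, seed = 33)
  fa <- tempfile(fileext = ".fa")
  write_fasta(c(g, "ACGTNNNNACGTACGTACGT", "AC"), fa)
  p <- min_params(11, canonical = TRUE)
  res <- split_collection(fa, p, n_buckets = 8L, tmp_dir = tmp)
  expect_identical(length(res$bucket_files), 8L)
  expect_gt(res$n_segments, 0L)
  expect_gt(res$n_skipped_runs, 0L)   # the "AC" read and short runs
  back <- data.table::rbindlist(lapply(
    res$bucket_files[file.exists(res$bucket_files)],
    unitigr:::read_bucket_file))
  expect_identical(nrow(back), res$n_segments)
  # all segments of one group land in one bucket
  expect_true(all(tapply(assign_bucket(back$minimizer, 8L),
                         back$minimizer, function(v) length(unique(v))) == 1L))
  # reloaded segments produce the same graph as the in-memory route
  g1 <- dbg_build(list(g), k = 11, use_disk_buckets = TRUE)
  g2 <- dbg_build(list(g), k = 11)
  expect_identical(g1$unitigs, g2$unitigs)
})
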