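test_that("intern_color_set is idempotent with dense first-seen indices", {
  idx <- color_index_new()
  expect_identical(intern_color_set(idx, c(0L, 2L)), 0L)
  expect_identical(intern_color_set(idx, c(0L, 2L)), 0L)
  expect_identical(intern_color_set(idx, 0L), 1L)
  expect_identical(intern_color_set(idx, 1L), 2L)
  expect_identical(idx$n, 3L)
  expect_error(intern_color_set(idx, c(2L, 1L)), "strictly increasing")
  expect_error(intern_color_set(idx, integer(0)), "nonempty")

  # index count equals the number of distinct sets
  idx2 <- color_index_new()
  set.seed(17)
  sets <- lapply(1:1000, function(i)
    sort(sample(0:9, sample(1:5, 1))))
  for (s in sets) intern_color_set(idx2, s)
  expect_identical(idx2$n, length(unique(lapply(sets, as.integer))))
})

test_that("color-set codec follows delta+RLE and round-trips", {
  # {0,1,2,3,5}: deltas 0,1,1,1,2 -> runs (0,1),(1,3),(2,1)
  enc <- encode_color_set(c(0L, 1L, 2L, 3L, 5L))
  expect_identical(as.integer(enc), c(3L, 0L, 1L, 1L, 3L, 2L, 1L))
  expect_identical(decode_color_set(enc), c(0L, 1L, 2L, 3L, 5L))
  # {7}: single run (7,1)
  expect_identical(as.integer(encode_color_set(7L)), c(1L, 7L, 1L))
  # varints handle large ids
  big <- c(0L, 1000L, 100000L)
  expect_identical(decode_color_set(encode_color_set(big)), big)
  expect_error(decode_color_set(as.raw(c(2, 0, 1))), "malformed")
})

test_that("run headers encode maximal runs and round-trip via FASTA grammar", {
  expect_identical(encode_run_header(c(5L, 5L, 5L)),
                   data.frame(index = 5L, length = 3L))
  expect_identical(encode_run_header(c(1L, 2L, 2L, 1L)),
                   data.frame(index = c(1L, 2L, 1L), length = c(1L, 2L, 1L)))
  expect_identical(decode_run_header(data.frame(index = c(1L, 2L),
                                                length = c(2L, 1L))),
                   c(1L, 1L, 2L))
  expect_error(decode_run_header(data.frame(index = 1L, length = 2L), 3L),
               "sum to")
  # header grammar
  hdr <- unitigr:::format_color_header(4L, data.frame(index = c(0L, 3L),
                                                      length = c(7L, 2L)))
  expect_identical(hdr, "u4 C:0:7,3:2")
  back <- unitigr:::parse_color_header(hdr)
  expect_identical(back$id, 4L)
  expect_identical(back$runs, data.frame(index = c(0L, 3L), length = c(7L, 2L)))
})

test_that("random color sets and run headers round-trip", {
  set.seed(23)
  for (i in 1:300) {
    s <- sort(sample(0:500, sample(1:20, 1)))
    expect_identical(decode_color_set(encode_color_set(s)), as.integer(s))
    idxs <- sample(0:6, sample(1:30, 1), replace = TRUE)
    r <- encode_run_header(idxs)
    expect_identical(decode_run_header(r, length(idxs)), as.integer(idxs))
  }
})

test_that("the color map file round-trips through chunked storage", {
  idx <- color_index_new()
  set.seed(29)
  for (i in 1:500) intern_color_set(idx, sort(sample(0:49, sample(1:8, 1))))
  path <- tempfile(fileext = ".colors.bin")
  write_color_map(idx, path, sets_per_chunk = 64L)
  back <- read_color_map(path)
  expect_identical(back$n, idx$n)
  expect_identical(back$sets, idx$sets)
  expect_error(suppressWarnings(read_color_map(tempfile())),
               "cannot open|not a color map")
})

test_that("k-mer color sets match per-file membership on built graphs", {
  cc <- color_collection(n_colors = 3, shared_fraction = 0.5,
                         backbone_len = 400, seed = 19)
  k <- 15
  g <- dbg_build(cc, k = k, colored = TRUE, seed = 4)
  per_file <- lapply(cc, function(seqs)
    unique(naive_canon(unlist(lapply(seqs, naive_kmers, k = k)))))
  for (i in seq_along(g$unitigs)) {
    km <- naive_canon(naive_kmers(g$unitigs[i], k))
    sidx <- decode_run_header(g$color_runs[[i]], length(km))
    for (j in seq_along(km)) {
      want <- which(vapply(per_file, function(s) km[j] %in% s, TRUE)) - 1L
      expect_identical(g$color_index$sets[[sidx[j] + 1L]], as.integer(want))
    }
  }
  # backbone unitigs carry the full color set; private unitigs a singleton;
  # unitigs crossing a color boundary would carry >= 2 runs (none here since
  # backbone and private segments are separate records)
  nsets <- vapply(g$color_runs, function(r) length(unique(r$index)), 1L)
  expect_true(all(nsets == 1L))
  expect_identical(g$color_index$n, 4L)  # {0,1,2} plus three singletons
})

test_that("unitigs spanning a color boundary carry multiple runs", {
  shared <- random_genome(120, seed = 41)
  left <- random_genome(120, seed = 42)
  right <- random_genome(120, seed = 43)
  # color 0 sees left+shared, color 1 sees shared+right: the merged unitig
  # (one non-branching path per junction side) must switch color sets
  g <- dbg_build(list(paste0(left, shared), paste0(shared, right)),
                 k = 21, colored = TRUE, seed = 5)
  nruns <- vapply(g$color_runs, nrow, 1L)
  expect_true(any(nruns >= 2L))
})
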