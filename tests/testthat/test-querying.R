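test_that("query counts matched k-mer positions, degenerate cases included", {
  g <- dbg_build(list("ACGT"), k = 3, seed = 1)  # k-mers {ACG, CGT}
  res <- query_batch(g, c(full = "ACGT", short = "AC", miss = "GGGGG"))
  expect_identical(res$total_kmers, c(2L, 0L, 3L))
  expect_identical(res$matched, c(2L, 0L, 0L))
  expect_identical(res$percent, c(100, 0, 0))
})

test_that("bucketed querying equals global querying and the naive oracle", {
  set.seed(37)
  for (trial in 1:6) {
    genome <- random_genome(1500, seed = 2000 + trial)
    k <- sample(c(9, 15, 21), 1)
    g <- dbg_build(list(genome), k = k, seed = trial)
    qs <- c(vapply(1:5, function(i) {
      st <- sample(nchar(genome) - 99, 1)
      substring(genome, st, st + 99)
    }, ""), random_genome(60, seed = 3000 + trial),
    reverse_complement(substring(genome, 11, 90)))
    rb <- query_batch(g, qs, bucketed = TRUE)
    rg <- query_batch(g, qs, bucketed = FALSE)
    expect_identical(rb$matched, rg$matched)
    orc <- query_oracle(unique(naive_canon(naive_kmers(genome, k))), qs, k)
    expect_equal(rb$matched, orc$matched)
    expect_equal(rb$total_kmers, orc$total_kmers)
  }
})

test_that("colored queries report per-color counts restricted to positives", {
  cc <- color_collection(3, 0.5, 300, seed = 31)
  k <- 15
  g <- dbg_build(cc, k = k, colored = TRUE, seed = 1)
  qs <- c(substring(attr(cc, "backbone"), 20, 140),
          substring(attr(cc, "privates")[1], 1, 80),
          random_genome(50, seed = 99))
  res <- query_batch(g, qs)
  orc <- query_oracle(unique(naive_canon(unlist(lapply(unlist(cc),
                                                       naive_kmers, k = k)))),
                      qs, k, color_files = cc)
  for (i in seq_along(qs)) {
    expect_equal(as.integer(res$per_color[[i]]),
                 as.integer(orc$per_color[[i]]))
    expect_identical(names(res$per_color[[i]]), names(orc$per_color[[i]]))
    expect_true(all(res$per_color[[i]] > 0L))
    expect_true(all(res$per_color[[i]] <= res$matched[i]))
  }
  expect_length(res$per_color[[3]], 0L)
})

test_that("CSV output formats percentages at two decimals with thresholding", {
  g <- dbg_build(list("ACGTAC"), k = 3, seed = 1)
  res <- query_batch(g, c(a = "ACGT", b = "TTTTT", c = "ACGTT"))
  path <- tempfile(fileext = ".csv")
  write_query_csv(res, path)
  lines <- readLines(path)
  expect_identical(lines[1], "query_id,total_kmers,matched,percent")
  expect_match(lines[2], "a,2,2,100.00")
  expect_match(lines[3], "b,3,0,0.00")
  expect_match(lines[4], "c,3,2,66.67")
  write_query_csv(res, path, threshold = 50)
  expect_identical(length(readLines(path)), 3L)  # header + 2 passing rows
})

test_that("JSONL output carries positive per-color counts only", {
  cc <- color_collection(2, 0.5, 200, seed = 47)
  g <- dbg_build(cc, k = 11, colored = TRUE, seed = 1)
  qs <- c(hit = substring(attr(cc, "backbone"), 1, 60),
          none = random_genome(40, seed = 7))
  res <- query_batch(g, qs)
  path <- tempfile(fileext = ".jsonl")
  write_query_jsonl(res, path)
  lines <- lapply(readLines(path), jsonlite::fromJSON)
  expect_identical(lines[[1]]$query, "hit")
  expect_identical(sort(names(lines[[1]]$colors)), c("0", "1"))
  expect_identical(lines[[1]]$colors[["0"]], lines[[1]]$matched)
  expect_length(lines[[2]]$colors, 0L)
})

test_that("querying a reloaded graph requires matching parameters", {
  g <- dbg_build(list(random_genome(300, seed = 3)), k = 11, seed = 1)
  pref <- tempfile("graph_")
  save_cdbg(g, pref)
  g2 <- load_cdbg(pref)
  q <- substring(random_genome(300, seed = 3), 5, 80)
  expect_identical(query_batch(g2, q)$matched, query_batch(g, q)$matched)
})
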