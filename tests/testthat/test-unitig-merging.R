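mk_ep <- function(kmer, id, side, orient = 1L) {
  data.table::data.table(kmer = kmer, id = id, side = side, orient = orient)
}

test_that("pair_endpoints joins the two records of each boundary k-mer", {
  # direct right-to-left join, both forward
  ch <- pair_endpoints(mk_ep(c("ACG", "ACG"), c(1L, 2L),
                             c("right", "left")))
  expect_length(ch, 1L)
  expect_identical(ch[[1]]$ids, c(1L, 2L))
  expect_identical(ch[[1]]$ors, c(1L, 1L))

  # opposite strands: the unitig recorded in reverse orientation gets flipped
  ch2 <- pair_endpoints(mk_ep(c("ACG", "ACG"), c(1L, 2L),
                              c("right", "right"), orient = c(1L, 2L)))
  expect_identical(ch2[[1]]$ors, c(1L, 2L))
  ch3 <- pair_endpoints(mk_ep(c("ACG", "ACG"), c(1L, 2L),
                              c("left", "left"), orient = c(1L, 2L)))
  expect_identical(ch3[[1]]$ors, c(2L, 1L))
  # same-side same-orientation records cannot be physical partners
  expect_error(pair_endpoints(mk_ep(c("ACG", "ACG"), c(1L, 2L),
                                    c("right", "left"), orient = c(1L, 2L))),
               "cannot resolve orientations")

  # a boundary k-mer with three records violates the grouping guarantee
  expect_error(pair_endpoints(mk_ep(rep("ACG", 3), 1:3,
                                    c("right", "left", "left"))),
               "expected exactly 2")
  # palindromic junction k-mers (even k) resolve regardless of orientation
  chp <- pair_endpoints(mk_ep(c("ACGT", "ACGT"), c(1L, 2L),
                              c("right", "right")))
  expect_identical(chp[[1]]$ids, c(1L, 2L))
})

test_that("chains spell maximal unitigs by k-overlap concatenation", {
  unitigs <- data.table::data.table(id = 1:2,
                                    text = c("ACGTA", "CGTAC"),
                                    is_cycle = FALSE)
  eps <- mk_ep(c("CGTA", "CGTA"), c(1L, 2L), c("right", "left"))
  res <- run_merging(pair_endpoints(eps), unitigs, k = 4, seed = 1)
  expect_identical(res$unitigs, "ACGTAC")

  # empty chain list: unitigs pass through normalized
  res0 <- run_merging(list(), unitigs, k = 4, seed = 1)
  expect_identical(res0$unitigs, sort(c("ACGTA", "CGTAC")))
})

test_that("a worst-case pair joins in one round about a quarter of the time", {
  npairs <- 2000L
  chains <- unlist(lapply(seq_len(npairs) - 1L, function(i) {
    base <- 3L * i
    list(list(ids = base + c(1L, 2L), ors = c(1L, 1L),
              l_sealed = FALSE, r_sealed = FALSE, cycle = FALSE),
         list(ids = base + c(2L, 3L), ors = c(1L, 1L),
              l_sealed = FALSE, r_sealed = FALSE, cycle = FALSE))
  }), recursive = FALSE)
  state <- list(chains = chains, finalized = list(), round = 0L,
                merge_buckets = 64L, canonical = TRUE)
  state <- unitigr:::with_seed(11, merge_round(state))
  all_chains <- c(state$chains, state$finalized)
  joined <- sum(vapply(all_chains, function(c) length(c$ids) == 3L, TRUE))
  expect_gt(joined / npairs, 0.25 - 0.033)
  expect_lt(joined / npairs, 0.25 + 0.033)
})

test_that("an ending with no partner and no placeholder is sealed", {
  # single chain: both ends have no partner, so after a couple of rounds both
  # ends seal and the chain finalizes
  chains <- list(list(ids = c(1L, 2L), ors = c(1L, 1L),
                      l_sealed = FALSE, r_sealed = FALSE, cycle = FALSE))
  state <- list(chains = chains, finalized = list(), round = 0L,
                merge_buckets = 64L, canonical = TRUE)
  state <- unitigr:::with_seed(5, {
    s <- state
    while (length(s$chains) > 0L) s <- merge_round(s)
    s
  })
  expect_length(state$finalized, 1L)
  expect_true(state$finalized[[1]]$l_sealed && state$finalized[[1]]$r_sealed)
  expect_lte(state$round, 8L)
})

test_that("merge output is identical across seeds, only round counts vary", {
  g <- random_genome(2500, seed = 51)
  ref <- dbg_build(list(g), k = 15, seed = 1)
  for (s in 2:10) {
    alt <- dbg_build(list(g), k = 15, seed = s)
    expect_identical(alt$unitigs, ref$unitigs)
  }
})

test_that("simulated worst-case pairs match the 1/4 geometric model", {
  frac <- simulate_merge_pairs(20000, seed = 3)
  expect_lt(abs(frac - 0.25), 0.01)
  mr <- simulate_merge_rounds(20000, seed = 3)
  expect_lt(abs(mr - 4), 0.1)
})

test_that("cross-group cycles close during merging", {
  # a circular sequence whose k-mers span several groups comes back as one
  # cyclic unitig in its least rotation
  circ <- random_genome(200, seed = 61)
  wrapped <- paste0(circ, substring(circ, 1, 14))
  g <- dbg_build(list(wrapped), k = 15, seed = 2)
  expect_identical(length(g$unitigs), 1L)
  expect_true(g$is_cycle[1])
  expect_identical(g$unitigs, maximal_unitigs_bruteforce(wrapped, 15))
})
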