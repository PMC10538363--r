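# Seeded synthetic-data generators: every generator is a pure function of its
# seed and parameters (global RNG state is saved and restored).

#' Random genome
#'
#' Uniform i.i.d. bases from a seeded generator.
#'
#' @param length genome length (0 gives an empty string).
#' @param seed integer seed.
#' @return a DNA string.
#' @export
random_genome <- function(length, seed = 1L) {
  if (length == 0L) return("")
  with_seed(seed, paste(sample(DNA_BASES, length, replace = TRUE),
                        collapse = ""))
}

#' Sample reads from a genome
#'
#' Emulates a (substitution-only) short-read data set: a deterministic tiling
#' of the genome with `tile_overlap`-character overlaps (which guarantees
#' that, with no errors and abundance threshold 1, the reads carry exactly
#' the genome's k-mers for any k <= tile_overlap + 1) plus uniformly
#' positioned random reads up to the requested extra coverage. Each read is
#' reverse-complemented with probability `rc_prob`; bases are substituted
#' uniformly at rate `error_rate`. No indels.
#'
#' @param genome DNA string.
#' @param read_len read length (clamped to the genome length).
#' @param coverage extra random-read coverage on top of the tiling (may be 0).
#' @param rc_prob per-read reverse-complement probability.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @param tile_overlap overlap of consecutive tiling reads (>= k - 1 for the
#'   closure property).
#' @return character vector of reads.
#' @export
sample_reads <- function(genome, read_len = 100L, coverage = 2,
                         rc_prob = 0.5, error_rate = 0, seed = 1L,
                         tile_overlap = 63L) {
  G <- nchar(genome)
  if (G == 0L) return(character(0))
  read_len <- min(read_len, G)
  tile_overlap <- min(tile_overlap, read_len - 1L)
  with_seed(seed, {
    stride <- max(1L, read_len - tile_overlap)
    starts <- unique(c(seq(1L, max(1L, G - read_len + 1L), by = stride),
                       G - read_len + 1L))
    n_extra <- max(0L, round(coverage * G / read_len))
    if (n_extra > 0L) {
      starts <- c(starts, sample.int(G - read_len + 1L, n_extra, replace = TRUE))
    }
    reads <- substring(genome, starts, starts + read_len - 1L)
    flip <- runif(length(reads)) < rc_prob
    if (any(flip)) reads[flip] <- reverse_complement(reads[flip], check = FALSE)
    if (error_rate > 0) {
      reads <- vapply(reads, function(r) {
        b <- strsplit(r, NULL)[[1L]]
        hit <- which(runif(length(b)) < error_rate)
        for (i in hit) b[i] <- sample(setdiff(DNA_BASES, b[i]), 1L)
        paste(b, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    reads
  })
}

#' Multi-color sequence collection
#'
#' Builds one sequence set per color: a backbone genome shared by all colors
#' plus one private segment per color, kept as separate records so that the
#' expected color-set structure is known exactly by construction (backbone
#' k-mers carry the full color set, private k-mers a singleton, up to chance
#' k-mer collisions between segments).
#'
#' @param n_colors number of colors (files).
#' @param shared_fraction fraction of each color's sequence that is backbone.
#' @param backbone_len backbone length.
#' @param seed integer seed.
#' @return list of character vectors (one per color), with attributes
#'   `backbone` and `privates`.
#' @export
color_collection <- function(n_colors = 3L, shared_fraction = 0.5,
                             backbone_len = 600L, seed = 1L) {
  stopifnot(n_colors >= 1L, shared_fraction > 0, shared_fraction <= 1)
  private_len <- max(1L, round(backbone_len * (1 - shared_fraction) /
                                 shared_fraction))
  backbone <- random_genome(backbone_len, seed = seed)
  privates <- vapply(seq_len(n_colors),
                     function(i) random_genome(private_len, seed = seed + i),
                     "")
  out <- lapply(seq_len(n_colors), function(i) c(backbone, privates[i]))
  attr(out, "backbone") <- backbone
  attr(out, "privates") <- privates
  out
}

#' Adversarial input fixtures
#'
#' Named input classes stressing known corner cases: a circular sequence
#' (linearized with a wrap of `wrap` characters, producing cyclic unitigs for
#' k <= wrap + 1), exact tandem repeats (branching (k-1)-mers), a
#' low-complexity sequence (minimizer runs collapse, segments shrink towards
#' length k-1), a palindrome-bearing sequence (s followed by its reverse
#' complement: palindromic k-mers for even k), and reads shorter than k.
#'
#' @param seed integer seed.
#' @param wrap wrap length for the circular fixture (use >= k - 1).
#' @return named list of character vectors.
#' @export
adversarial_fixtures <- function(seed = 1L, wrap = 63L) {
  circ <- random_genome(400L, seed = seed)
  circular <- paste0(circ, substring(circ, 1L, wrap))
  unit <- random_genome(40L, seed = seed + 1L)
  tandem <- paste0(random_genome(80L, seed = seed + 2L),
                   strrep(unit, 4L),
                   random_genome(80L, seed = seed + 3L))
  lowc <- paste0(strrep("AC", 60L), strrep("A", 40L), strrep("AG", 60L))
  half <- random_genome(150L, seed = seed + 4L)
  palindromic <- paste0(half, reverse_complement(half))
  shorties <- with_seed(seed + 5L, vapply(2:6, function(n)
    paste(sample(DNA_BASES, n, replace = TRUE), collapse = ""), ""))
  list(circular = circular,
       tandem_repeat = tandem,
       low_complexity = lowc,
       palindromic = palindromic,
       short_reads = c(shorties, random_genome(300L, seed = seed + 6L)))
}
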