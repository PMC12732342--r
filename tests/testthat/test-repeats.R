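test_that("planted repeats are found in every orientation", {
  set.seed(40)
  unit <- rand_dna(35L, at = 0.5)
  bg <- function(n) rand_dna(n, at = 0.5)
  # forward duplication
  s <- paste0(bg(60L), unit, bg(50L), unit, bg(55L))
  fw <- find_repeats(s, min_len = 30L, kinds = "forward")
  expect_identical(nrow(fw), 1L)
  # the maximal pair covers the planted copies (flanks may extend it by
  # a coincidental base or two)
  expect_lte(fw$pos_a, 61L)
  expect_gte(fw$pos_a + fw$length - 1L, 95L)
  expect_gte(fw$length, 35L)
  expect_equal(fw$pos_b - fw$pos_a, 85L)   # planted copy spacing
  # palindromic: a 30-mer and its reverse complement
  u30 <- rand_dna(30L, at = 0.5)
  s2 <- paste0(bg(40L), u30, bg(45L), reverse_complement(u30), bg(40L))
  pal <- find_repeats(s2, min_len = 30L, kinds = "palindromic")
  expect_identical(nrow(pal), 1L)
  expect_lte(pal$pos_a, 41L)
  expect_gte(pal$length, 30L)
})

test_that("repeat search equals the brute-force enumeration, all kinds", {
  set.seed(41)
  for (rep_i in 1:2) {
    s <- rand_dna(500L)   # AT-rich so short spurious repeats exist
    got <- find_repeats(s, min_len = 8L,
                        kinds = c("forward", "reverse", "complement",
                                  "palindromic"))
    for (k in c("forward", "reverse", "complement", "palindromic")) {
      want <- oracle_repeats(s, 8L, k)
      g <- got[got$kind == k, c("pos_a", "pos_b", "length")]
      rownames(g) <- NULL
      expect_equal(g, want, info = k)
    }
  }
})

test_that("every reported pair verifies under its kind's transform", {
  set.seed(43)
  s <- rand_dna(400L)
  got <- suppressWarnings(find_repeats(s, min_len = 7L))
  expect_gt(nrow(got), 0L)
  for (i in seq_len(nrow(got)))
    expect_true(repeat_pair_ok(s, got$kind[i], got$pos_a[i], got$pos_b[i],
                               got$length[i]))
})

test_that("palindromic pairs are stable under reverse complementation", {
  set.seed(44)
  s <- rand_dna(300L)
  n <- nchar(s)
  a <- find_repeats(s, min_len = 8L, kinds = "palindromic")
  b <- find_repeats(reverse_complement(s), min_len = 8L,
                    kinds = "palindromic")
  # map b's coordinates back: position p of a length-L block -> n - (p+L-1) + 1
  b_mapped <- data.frame(
    pos_a = pmin(n - (b$pos_b + b$length - 1L) + 1L,
                 n - (b$pos_a + b$length - 1L) + 1L),
    pos_b = pmax(n - (b$pos_b + b$length - 1L) + 1L,
                 n - (b$pos_a + b$length - 1L) + 1L),
    length = b$length)
  key <- function(d) sort(paste(d$pos_a, d$pos_b, d$length))
  expect_identical(key(a), key(b_mapped))
})

test_that("min_len below 8 warns about quadratic blow-up", {
  expect_warning(find_repeats(strrep("ACGT", 20L), min_len = 4L),
                 "min_len")
})

test_that("tandem arrays: constructed, fractional and planted cases", {
  expect_equal(find_tandem(strrep("ACGTT", 4L), min_unit = 2L,
                           max_unit = 10L)$copies, 4)
  # fractional final copy: 3.5 copies of an 8-mer
  set.seed(45)
  u8 <- "ACGGTCAT"
  s <- paste0(rand_dna(30L, 0.5), strrep(u8, 3L), substr(u8, 1L, 4L),
              rand_dna(30L, 0.5))
  tn <- find_tandem(s, min_unit = 5L, max_unit = 12L)
  hit <- tn[tn$unit_length == 8L, ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$copies, 3.5, tolerance = 0.011)
  # a mismatch within the 10% budget is tolerated
  unit <- rand_dna(40L, 0.5)
  mut <- unit
  substr(mut, 17L, 17L) <- if (substr(unit, 17, 17) == "A") "C" else "A"
  s2 <- paste0(rand_dna(25L, 0.5), unit, mut, unit, rand_dna(25L, 0.5))
  tn2 <- find_tandem(s2, min_unit = 30L, max_unit = 60L)
  expect_true(any(tn2$unit_length == 40L & tn2$copies >= 3))
})

test_that("exact periodic spans found by a brute-force check are covered", {
  set.seed(46)
  for (rep_i in 1:3) {
    s <- rand_dna(80L, at = 0.6)
    s <- paste0(s, substr(s, 30L, 49L), substr(s, 30L, 49L))  # plant one
    x <- strsplit(s, "")[[1L]]
    n <- length(x)
    tn <- find_tandem(s, min_unit = 5L, max_unit = 25L)
    for (u in 5:25) {
      for (i in seq_len(n - 2L * u + 1L)) {
        span <- i:(i + 2L * u - 1L)
        if (all(x[span[1:u]] == x[span[(u + 1L):(2L * u)]])) {
          covered <- any(tn$start <= i & tn$end >= i + 2L * u - 1L)
          expect_true(covered,
                      info = sprintf("u=%d i=%d uncovered", u, i))
        }
      }
    }
  }
})

test_that("stem-loop detector equals the exhaustive oracle", {
  set.seed(47)
  for (rep_i in 1:4) {
    arm <- rand_dna(10L, at = 0.4)
    s <- paste0(rand_dna(20L), arm, rand_dna(12L), reverse_complement(arm),
                rand_dna(20L))
    got <- best_stem_loop(s, min_stem = 5L, loop_range = c(3L, 20L))
    want <- oracle_stem_loop(s, 5L, c(3L, 20L))
    expect_false(is.null(got))
    expect_identical(c(got$stem_start, got$stem_len, got$loop_len),
                     as.integer(want))
  }
  # poly-A input has no inverted repeat at all
  expect_null(best_stem_loop(strrep("A", 100L), min_stem = 5L,
                             loop_range = c(3L, 20L)))
})

test_that("a perfect contiguous palindrome needs its loop constraint", {
  # GGGGAAATTTCCCC is its own reverse complement; with a loop of at
  # least 3 required, the optimum is the 5-bp arms GGGGA / TCCCC
  got <- best_stem_loop("GGGGAAATTTCCCC", min_stem = 4L,
                        loop_range = c(3L, 50L))
  want <- oracle_stem_loop("GGGGAAATTTCCCC", 4L, c(3L, 50L))
  expect_identical(c(got$stem_start, got$stem_len, got$loop_len),
                   as.integer(want))
  expect_identical(got$stem_len, 5L)
  expect_identical(got$loop_len, 4L)
})

test_that("control-region decomposition recovers the planted layout", {
  tb <- generate_genome(synthetic_spec(seed = 42L))
  cr <- tb$record$features[tb$record$features$name == "control region", ]
  rseq <- region_sequence(tb$record, cr$start, cr$end)
  dec <- decompose_region(rseq)
  expect_identical(dec$segments$label,
                   c("lead", "tandem_array", "at_rich", "poly_T",
                     "stem_loop"))
  expect_equal(dec$segments$start, tb$planted$start, tolerance = 0)
  expect_equal(dec$segments$end, tb$planted$end, tolerance = 0)
  # poly-T segment is exactly the planted homopolymer
  pt <- dec$segments[dec$segments$label == "poly_T", ]
  expect_identical(pt$end - pt$start + 1L,
                   tb$spec$control_region$poly_t_len)
  # all-A input: no poly-T, no tandem; a single AT-rich body
  dec2 <- decompose_region(strrep("A", 200L))
  expect_false(any(dec2$segments$label %in% c("poly_T", "tandem_array")))
  expect_true("at_rich" %in% dec2$segments$label)
})
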