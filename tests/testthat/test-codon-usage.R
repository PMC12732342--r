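code5 <- genetic_code(5)

test_that("codon counting is additive, linear and stop-free", {
  one <- count_codons(make_cds("ATG"), code5)
  expect_identical(unname(one$counts[["ATG"]]), 1L)
  expect_identical(one$total, 1L)
  g1 <- make_cds(c("ATG", "TTA", "TTA", "GGA"))
  g2 <- make_cds(c("ATT", "CCT"), gene = "g2", stop_codon = "T")
  both <- count_codons(list(g1, g2), code5)
  expect_identical(both$total, 6L)
  expect_identical(
    both$counts,
    count_codons(g1, code5)$counts + count_codons(g2, code5)$counts)
  twice <- count_codons(list(g1, g1), code5)
  expect_identical(twice$counts, 2L * count_codons(g1, code5)$counts)
  # no stop codon ever carries a count slot
  expect_false(any(c("TAA", "TAG") %in% names(both$counts)))
})

test_that("RSCU matches hand computation and family-sum invariant", {
  # Leu family {TTA:10, others 2 each} -> RSCU(TTA) = 6*10/20 = 3
  leu <- c(rep("TTA", 10L), rep(c("TTG", "CTT", "CTC", "CTA", "CTG"),
                                each = 2L))
  tab <- rscu(count_codons(make_cds(leu), code5), code5)
  expect_equal(unname(tab$rscu[["TTA"]]), 3)
  expect_equal(unname(tab$rscu[["CTC"]]), 6 * 2 / 20)
  # uniform family use -> RSCU 1 everywhere in the family
  gly <- make_cds(rep(c("GGA", "GGC", "GGG", "GGT"), each = 3L))
  tabg <- rscu(count_codons(gly, code5), code5)
  expect_equal(unname(tabg$rscu[c("GGA", "GGC", "GGG", "GGT")]),
               rep(1, 4L))
  # observed family sums equal family sizes; unobserved families are NA
  set.seed(3)
  cds <- make_cds(sample(names(code5$family_of), 200L, replace = TRUE))
  tabr <- rscu(count_codons(cds, code5), code5)
  fams <- split(names(tabr$rscu), unname(code5$family_of[names(tabr$rscu)]))
  for (f in fams) {
    if (sum(tabr$counts[f]) > 0L)
      expect_equal(sum(tabr$rscu[f]), length(f))
    else
      expect_true(all(is.na(tabr$rscu[f])))
  }
})

test_that("split-family RSCU mode treats Leu1/Leu2 and Ser1/Ser2 apart", {
  cds <- make_cds(c(rep("TTA", 3L), "TTG", rep("CTT", 2L)))
  full <- rscu(count_codons(cds, code5), code5, family_mode = "full")
  split <- rscu(count_codons(cds, code5), code5, family_mode = "split")
  expect_equal(unname(full$rscu[["TTA"]]), 6 * 3 / 6)
  expect_equal(unname(split$rscu[["TTA"]]), 2 * 3 / 4)  # UUR family of 2
})

test_that("ENc equals a direct Wright computation on random tables", {
  set.seed(8)
  sense <- names(code5$family_of)
  for (i in 1:10) {
    cds <- make_cds(sample(sense, sample(c(150L, 400L, 900L), 1L),
                           replace = TRUE))
    tab <- count_codons(cds, code5)
    got <- suppressMessages(enc(tab, code5))
    expect_equal(as.numeric(got), oracle_enc(tab$counts), tolerance = 1e-9)
  }
})

test_that("ENc hits its floor of 20 under one-codon-per-family usage", {
  picked <- vapply(code5$families, `[`, "", 1L)
  cds <- make_cds(rep(unname(picked), each = 3L))
  expect_equal(as.numeric(enc(count_codons(cds, code5), code5)), 20)
})

test_that("ENc is insensitive to doubling a large gene", {
  set.seed(12)
  # n large enough that the ~1/n finite-sample bias of the family
  # homozygosities moves ENc by well under half a codon on doubling
  cds <- make_cds(sample(names(code5$family_of), 3000L, replace = TRUE))
  e1 <- suppressMessages(enc(count_codons(cds, code5), code5))
  e2 <- suppressMessages(enc(count_codons(list(cds, cds), code5), code5))
  expect_lt(abs(as.numeric(e1) - as.numeric(e2)), 0.5)
})

test_that("ENc imputes a missing family-size class and reports it", {
  # only 2-fold and 4-fold families observed: 6- and 8-fold imputed
  cds <- make_cds(rep(c("TTT", "TTC", "ATT", "ATC", "GGA", "GGT"), 5L))
  expect_message(val <- enc(count_codons(cds, code5), code5), "imputed")
  expect_true(is.finite(as.numeric(val)))
  expect_setequal(attr(val, "imputed_classes"), c(6L, 8L))
})

test_that("GC3/GC3s/GC12 match hand counts", {
  cds <- make_cds(c("ATG", "GGC", "TTA", "CCG"))
  g <- gc3_gc3s_gc12(cds, code5)
  expect_equal(unname(g["gc3"]), 3 / 4)      # G,C,A,G third bases
  expect_equal(unname(g["gc12"]),
               (2 / 4 + 2 / 4) / 2)          # pos1 A,G,T,C; pos2 T,G,T,C
  # all families under table 5 are degenerate, so gc3s == gc3
  expect_equal(unname(g["gc3s"]), unname(g["gc3"]))
  all_gc <- make_cds(c("GGG", "CCC", "ACC"))
  g2 <- gc3_gc3s_gc12(all_gc, code5)
  expect_equal(unname(g2["gc3"]), 1)
  expect_equal(unname(g2["gc3s"]), 1)
})

test_that("expected-ENc curve evaluates exactly and peaks at 0.5", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  expect_equal(enc_expected(0.103),
               2 + 0.103 + 29 / (0.103^2 + 0.897^2))
  grid <- seq(0, 1, by = 0.01)
  expect_equal(grid[which.max(enc_expected(grid))], 0.5)
})

test_that("PR2 coordinates match hand counts and are shuffle-invariant", {
  cds <- make_cds(c("ATA", "ATT", "GGG", "GGC"))
  p <- pr2_coords(cds)
  expect_equal(unname(p["pr2_y"]), 1 / 2)    # A3=1, T3=1
  expect_equal(unname(p["pr2_x"]), 1 / 2)    # G3=1, C3=1
  all_a <- make_cds(c("ATA", "GGA", "CCA"))
  expect_equal(unname(pr2_coords(all_a)["pr2_y"]), 1)
  expect_true(is.na(pr2_coords(all_a)["pr2_x"]))
  set.seed(4)
  cds2 <- make_cds(sample(names(code5$family_of), 80L, replace = TRUE))
  shuffled <- make_cds(sample(cds2$codons))
  expect_equal(pr2_coords(cds2), pr2_coords(shuffled))
})

test_that("neutrality regression equals the closed-form OLS", {
  set.seed(6)
  idx <- data.frame(gene = paste0("g", 1:5),
                    gc3 = runif(5, 0.02, 0.2),
                    gc12 = runif(5, 0.1, 0.3))
  fit <- neutrality_fit(idx)
  want <- oracle_ols(100 * idx$gc3, 100 * idx$gc12)
  expect_equal(fit$slope, unname(want["slope"]), tolerance = 1e-9)
  expect_equal(fit$intercept, unname(want["intercept"]), tolerance = 1e-9)
  expect_equal(fit$r_squared, unname(want["r_squared"]), tolerance = 1e-9)
  # collinear points: slope 1, perfect fit
  col <- data.frame(gene = letters[1:4], gc3 = c(.1, .2, .3, .4),
                    gc12 = c(.1, .2, .3, .4))
  fit2 <- neutrality_fit(col)
  expect_equal(fit2$slope, 1)
  expect_equal(fit2$r_squared, 1)
  flat <- data.frame(gene = letters[1:3], gc3 = rep(.1, 3L),
                     gc12 = c(.1, .2, .3))
  expect_error(neutrality_fit(flat), "zero variance")
  expect_error(neutrality_fit(col[1:2, ]), "at least 3")
})

test_that("per-gene bias indices assemble consistently on a synthetic genome", {
  tb <- generate_genome(synthetic_spec(seed = 5L))
  idx <- codon_bias_indices(tb$record)
  expect_identical(nrow(idx), 13L)
  expect_true(all(idx$enc >= 20 & idx$enc <= 62))
  expect_true(all(idx$pr2_x >= 0 & idx$pr2_x <= 1, na.rm = TRUE))
  expect_equal(idx$gc12,
               (idx$gc12 * 0) +
                 vapply(extract_all_cds(tb$record), function(cds)
                   gc3_gc3s_gc12(cds, code5)[["gc12"]], 0),
               ignore_attr = TRUE)
})
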