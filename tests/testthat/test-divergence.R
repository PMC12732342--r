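code5 <- genetic_code(5)

test_that("pi on simple alignments matches hand values", {
  # two rows, length 10, one mismatch -> pi = 0.1
  a <- gene_alignment("g", c(x = "AAAAAAAAAT", y = "AAAAAAAAAA"),
                      codon_aligned = FALSE)
  prof <- pi_sliding(a, window = 10L, step = 5L)
  expect_equal(prof$mean_pi, 0.1)
  expect_equal(prof$points$pi, 0.1)
  # identical rows -> all zero
  b <- gene_alignment("g", c(x = strrep("ACGT", 30L),
                             y = strrep("ACGT", 30L),
                             z = strrep("ACGT", 30L),
                             w = strrep("ACGT", 30L)),
                      codon_aligned = FALSE)
  profb <- pi_sliding(b, window = 20L, step = 10L)
  expect_true(all(profb$points$pi == 0))
  expect_equal(profb$mean_pi, 0)
})

test_that("pi equals the brute-force pairwise oracle with gaps", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(2:6, 1L)
    L <- sample(c(60L, 200L, 600L), 1L)
    base <- strsplit(rand_dna(L), "")[[1L]]
    rows <- vapply(seq_len(n), function(i) {
      x <- base
      mut <- sample(L, ceiling(L * 0.1))
      x[mut] <- sample(c("A", "C", "G", "T"), length(mut), replace = TRUE)
      gap <- sample(L, ceiling(L * 0.03))
      x[gap] <- "-"
      paste(x, collapse = "")
    }, "")
    names(rows) <- paste0("t", seq_len(n))
    aln <- gene_alignment("g", rows, codon_aligned = FALSE)
    w <- sample(c(37L, 100L), 1L); s <- 13L
    prof <- pi_sliding(aln, window = w, step = s)
    expect_equal(prof$mean_pi, oracle_pi(rows))
    starts <- if (w >= L) 1L else seq(1L, L - w + 1L, by = s)
    want <- vapply(starts, function(st)
      oracle_pi(rows, st, min(st + w - 1L, L)), 0)
    expect_equal(prof$points$pi, want[!is.na(want)])
  }
})

test_that("NG86 site counts match the exhaustive neighbour oracle", {
  tab <- mitochar:::ng86_site_table(code5)
  expect_equal(unname(tab[["TTT"]]), 1 / 3)
  for (cod in names(tab)) {
    want <- oracle_ng86_sites(cod)
    expect_equal(unname(tab[[cod]]), unname(want["syn"]),
                 info = cod)
    # syn + nonsyn == 3 exactly for every sense codon
    expect_equal(unname(tab[[cod]]) + unname(want["nonsyn"]), 3,
                 info = cod)
  }
})

test_that("NG86 pairwise handles identity, gaps and saturation", {
  s <- paste(rep("ATGTTTGGA", 20L), collapse = "")
  pd <- ng86_pairwise(s, s, code5)
  expect_equal(pd$ka, 0)
  expect_equal(pd$ks, 0)
  expect_true(is.na(pd$ka_ks))
  expect_equal(pd$syn_sites + pd$nonsyn_sites, 3 * pd$n_codons_compared)
  # codons with gaps or ambiguity are excluded
  s2 <- sub("^ATG", "A-G", s)
  pd2 <- ng86_pairwise(s, s2, code5)
  expect_identical(pd2$n_codons_compared, 59L)
  # saturated proportions return NA distances
  expect_true(is.na(mitochar:::jukes_cantor(0.8)))
})

test_that("Jukes-Cantor correction inverts the saturation curve", {
  d0 <- c(0.01, 0.1, 0.5, 0.9)
  p <- 0.75 * (1 - exp(-4 * d0 / 3))
  expect_equal(mitochar:::jukes_cantor(p), d0, tolerance = 1e-12)
})

test_that("one-step codon differences classify as expected", {
  # TTT -> TTC is synonymous (Phe/Phe), TTT -> TTG nonsynonymous
  expect_equal(mitochar:::ng86_codon_diffs("TTT", "TTC", code5),
               c(sd = 1, nd = 0))
  expect_equal(mitochar:::ng86_codon_diffs("TTT", "TTG", code5),
               c(sd = 0, nd = 1))
  # two-hit codon: average over both orders
  d <- mitochar:::ng86_codon_diffs("TTT", "GTC", code5)
  expect_equal(unname(d["sd"] + d["nd"]), 2)
})

test_that("synonymous-only divergence gives Ka = 0 and Ks > 0", {
  set.seed(30)
  root <- make_cds(sample(names(code5$family_of), 150L, replace = TRUE))
  aln <- evolve_panel(root, n_taxa = 3L, branch_sub_rate = 0.08,
                      omega = 0, seed = 11L)
  truth <- attr(aln, "truth")
  expect_true(all(truth$accepted_nonsyn == 0L))
  for (i in 1:2) for (j in (i + 1):3) {
    pd <- ng86_pairwise(unname(aln$rows[i]), unname(aln$rows[j]), code5)
    expect_equal(pd$ka, 0)
    expect_gt(pd$ks, 0)
  }
})

test_that("panel summary is symmetric and collapses to pairwise at n=2", {
  set.seed(31)
  root <- make_cds(sample(names(code5$family_of), 120L, replace = TRUE))
  aln <- evolve_panel(root, n_taxa = 2L, branch_sub_rate = 0.05,
                      omega = 0.3, seed = 5L)
  tab <- panel_divergence(list(aln), code5)
  pd <- ng86_pairwise(unname(aln$rows[1L]), unname(aln$rows[2L]), code5)
  expect_equal(tab$mean_ka, pd$ka)
  expect_equal(tab$mean_ks, pd$ks)
  expect_equal(tab$mean_ka_ks, pd$ka_ks)
  # permuting taxa leaves the summary unchanged
  aln_perm <- gene_alignment(aln$gene, rev(aln$rows))
  tab2 <- panel_divergence(list(aln_perm), code5)
  expect_equal(tab2$mean_ka, tab$mean_ka)
  expect_equal(tab2$mean_pi, tab$mean_pi)
})

test_that("gene-specific constraint ordering is recovered from a panel", {
  set.seed(32)
  root_relaxed <- make_cds(sample(names(code5$family_of), 150L,
                                  replace = TRUE), gene = "relaxed")
  root_tight <- make_cds(sample(names(code5$family_of), 150L,
                                replace = TRUE), gene = "constrained")
  panel <- list(
    evolve_panel(root_relaxed, n_taxa = 6L, branch_sub_rate = 0.06,
                 omega = 0.5, seed = 101L),
    evolve_panel(root_tight, n_taxa = 6L, branch_sub_rate = 0.06,
                 omega = 0.05, seed = 102L))
  tab <- panel_divergence(panel, code5)
  expect_lt(tab$mean_ka_ks[tab$gene == "constrained"],
            tab$mean_ka_ks[tab$gene == "relaxed"])
  expect_identical(tab$rank_ka_ks[tab$gene == "relaxed"], 1L)
})

test_that("alignment validation rejects frame-breaking gaps", {
  expect_error(gene_alignment("g", c(a = "ATG-AA", b = "ATGAAA")),
               "frame-breaking")
  expect_error(gene_alignment("g", c(a = "ATGA", b = "ATGAAA")),
               "differ in length")
  ok <- gene_alignment("g", c(a = "ATG---", b = "ATGAAA"))
  expect_s3_class(ok, "gene_alignment")
})
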