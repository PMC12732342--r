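#' Codon usage counts over a set of coding sequences
#'
#' Counts sense codons only: terminal stops (complete or incomplete) never
#' enter the table, and internal stops have already been rejected upstream.
#'
#' @param cds_list a `coding_sequence` or list of them (e.g. from
#'   [extract_all_cds()]).
#' @param code a [genetic_code()].
#' @param scope label for the table (gene name or `"ALL_PCGS"`).
#' @return An object of class `codon_usage_table`: `scope`, `counts`
#'   (named integer over all sense codons of the code), `total`, and
#'   `aa_freq` (amino-acid usage fractions, with the conventional
#'   Leu1/Leu2 and Ser1/Ser2 reporting split).
#' @export
count_codons <- function(cds_list, code = genetic_code(5),
                         scope = "ALL_PCGS") {
  if (inherits(cds_list, "coding_sequence")) cds_list <- list(cds_list)
  if (!length(cds_list)) stop("empty CDS list", call. = FALSE)
  codons <- unlist(lapply(cds_list, `[[`, "codons"), use.names = FALSE)
  sense <- names(code$family_of)
  counts <- stats::setNames(integer(length(sense)), sense)
  tab <- table(codons)
  counts[names(tab)] <- as.integer(tab)
  aa <- aa_reporting_label(sense, code)
  aa_counts <- tapply(counts, aa, sum)
  structure(
    list(scope = scope, counts = counts, total = sum(counts),
         aa_freq = aa_counts / sum(counts), code_id = code$id),
    class = "codon_usage_table")
}

## Leu1 = CUN, Leu2 = UUR; Ser1 = AGN, Ser2 = UCN (reporting labels only)
aa_reporting_label <- function(codons, code) {
  aa <- unname(code$family_of[codons])
  lab <- aa
  lab[aa == "L"] <- ifelse(substr(codons[aa == "L"], 1, 1) == "C",
                           "Leu1", "Leu2")
  lab[aa == "S"] <- ifelse(substr(codons[aa == "S"], 1, 1) == "A",
                           "Ser1", "Ser2")
  lab
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("Codon usage [", x$scope, "]: ", x$total, " sense codons, table ",
      x$code_id, "\n", sep = "")
  top <- sort(x$counts, decreasing = TRUE)[1:5]
  cat("  most used:", paste(names(top), top, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' For codon `c` in a synonymous family of size `k` with family total `n`,
#' RSCU = `k * count(c) / n`; an unobserved family yields `NA` for all its
#' members. By default families are the full synonymous sets of the code
#' (Leu 6-fold, Ser 8-fold under table 5); `family_mode = "split"` instead
#' treats Leu1/Leu2 and Ser1/Ser2 as separate families, a sensitivity mode
#' mirroring tools that split by decoding tRNA.
#'
#' @param table a [count_codons()] result.
#' @param code a [genetic_code()].
#' @param family_mode `"full"` (default) or `"split"`.
#' @return the input table with an `rscu` element (named numeric).
#' @export
rscu <- function(table, code = genetic_code(5),
                 family_mode = c("full", "split")) {
  family_mode <- match.arg(family_mode)
  stopifnot(inherits(table, "codon_usage_table"))
  counts <- table$counts
  fam <- if (family_mode == "full") unname(code$family_of[names(counts)])
         else aa_reporting_label(names(counts), code)
  vals <- stats::setNames(rep(NA_real_, length(counts)), names(counts))
  for (g in unique(fam)) {
    idx <- fam == g
    n <- sum(counts[idx]); k <- sum(idx)
    if (n > 0) vals[idx] <- k * counts[idx] / n
  }
  table$rscu <- vals
  table$family_mode <- family_mode
  table
}

#' Effective number of codons (Wright's ENc)
#'
#' Wright's statistic generalized to the family-size classes of the active
#' code. Per family with total `n >= 2`, the codon homozygosity is
#' `F = (n * sum(p^2) - 1) / (n - 1)`; per family-size class `s`, `Fbar_s`
#' is the mean `F` over estimable families, and
#' `ENc = sum_s N_s / Fbar_s` with `N_s` the number of families in class
#' `s`. The result is clamped above at the code's sense-codon count (62 for
#' table 5). A class with no estimable family (or a non-positive mean `F`)
#' is imputed as `1/k_s` plus the mean deviation of the estimable classes
#' from their own `1/k`; the imputation is reported via `message()` and the
#' `"imputed_classes"` attribute.
#'
#' @param table a [count_codons()] result.
#' @param code a [genetic_code()].
#' @return ENc value (scalar); `NA` if no class is estimable.
#' @export
enc <- function(table, code = genetic_code(5)) {
  stopifnot(inherits(table, "codon_usage_table"))
  counts <- table$counts
  fam <- unname(code$family_of[names(counts)])
  fam_sizes <- lengths(code$families)
  F_hat <- k_of <- numeric(0)
  for (g in names(code$families)) {
    n <- sum(counts[fam == g])
    if (n < 2) next
    p <- counts[fam == g] / n
    F_val <- (n * sum(p^2) - 1) / (n - 1)
    F_hat <- c(F_hat, F_val)
    k_of <- c(k_of, fam_sizes[[g]])
  }
  classes <- sort(unique(fam_sizes))
  N_s <- as.integer(table(factor(fam_sizes, levels = classes)))
  Fbar <- vapply(classes, function(k) {
    v <- F_hat[k_of == k]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  estimable <- !is.na(Fbar) & Fbar > 0
  if (!any(estimable)) return(NA_real_)
  if (any(!estimable)) {
    dev <- mean(Fbar[estimable] - 1 / classes[estimable])
    Fbar[!estimable] <- pmin(1, pmax(1e-6, 1 / classes[!estimable] + dev))
    message("enc: imputed mean homozygosity for family-size class(es) ",
            paste(classes[!estimable], collapse = ", "),
            " of scope '", table$scope, "'")
  }
  val <- sum(N_s / Fbar)
  out <- min(val, length(code$family_of))
  if (any(!estimable))
    attr(out, "imputed_classes") <- classes[!estimable]
  out
}

#' GC content at codon positions: GC3, GC3s and GC12
#'
#' `gc3` is the GC fraction at third positions of all sense codons; `gc3s`
#' restricts to codons whose synonymous family has size >= 2 (under table 5
#' every family qualifies, so the two coincide); `gc12` is the mean of the
#' GC fractions at positions 1 and 2.
#'
#' @param cds a `coding_sequence` (or list, pooled).
#' @param code a [genetic_code()].
#' @return named numeric vector `c(gc3 = , gc3s = , gc12 = )`.
#' @export
gc3_gc3s_gc12 <- function(cds, code = genetic_code(5)) {
  if (inherits(cds, "coding_sequence")) cds <- list(cds)
  codons <- unlist(lapply(cds, `[[`, "codons"), use.names = FALSE)
  if (!length(codons)) stop("no sense codons", call. = FALSE)
  gc_at <- function(cod, pos) {
    b <- substr(cod, pos, pos)
    mean(b %in% c("G", "C"))
  }
  syn <- codons[code$family_size[codons] >= 2]
  c(gc3 = gc_at(codons, 3),
    gc3s = if (length(syn)) gc_at(syn, 3) else NA_real_,
    gc12 = (gc_at(codons, 1) + gc_at(codons, 2)) / 2)
}

#' Wright's expected ENc under pure GC3s-driven mutation pressure
#'
#' `ENc* = 2 + GC3s + 29 / (GC3s^2 + (1 - GC3s)^2)`; the reference curve of
#' the ENc plot. Genes on the curve are compatible with mutation pressure
#' alone; genes far below it indicate selection on codon usage.
#'
#' @param gc3s GC3s fraction(s) in `[0, 1]`.
#' @return expected ENc value(s).
#' @examples
#' enc_expected(0.5)  # 60.5, the curve maximum
#' @export
enc_expected <- function(gc3s) {
  stopifnot(all(gc3s >= 0 & gc3s <= 1))
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' PR2 (parity rule 2) plot coordinates of a gene
#'
#' Third-codon-position base fractions, condensed to the PR2 plane:
#' x = G3/(G3+C3), y = A3/(A3+T3). The point (0.5, 0.5) is the parity
#' expectation under strand-symmetric mutation with no selection.
#'
#' @param cds a `coding_sequence`.
#' @return named numeric vector with `a3`, `t3`, `g3`, `c3`, `pr2_x`,
#'   `pr2_y` (x or y is `NA` when its base pair is absent).
#' @export
pr2_coords <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  b <- substr(cds$codons, 3, 3)
  f <- vapply(c("A", "T", "G", "C"), function(x) mean(b == x), 0)
  gc <- f[["G"]] + f[["C"]]; at <- f[["A"]] + f[["T"]]
  c(a3 = f[["A"]], t3 = f[["T"]], g3 = f[["G"]], c3 = f[["C"]],
    pr2_x = if (gc > 0) f[["G"]] / gc else NA_real_,
    pr2_y = if (at > 0) f[["A"]] / at else NA_real_)
}

#' Per-gene codon-usage-bias indices
#'
#' One row per PCG: sense-codon count, ENc, GC3/GC3s/GC12, third-position
#' base fractions, PR2 coordinates, and Wright's expected ENc at the gene's
#' GC3s.
#'
#' @param record a [genome_record()] (or a named list of `coding_sequence`).
#' @param code a [genetic_code()].
#' @return data.frame of class `codon_bias_indices`.
#' @export
codon_bias_indices <- function(record, code = genetic_code(5)) {
  cds_list <- if (inherits(record, "genome_record"))
    extract_all_cds(record, code = code) else record
  if (!length(cds_list)) stop("no PCGs", call. = FALSE)
  rows <- lapply(cds_list, function(cds) {
    tab <- count_codons(cds, code, scope = cds$gene)
    g <- gc3_gc3s_gc12(cds, code)
    p <- pr2_coords(cds)
    e <- suppressMessages(enc(tab, code))
    data.frame(gene = cds$gene, n_codons = tab$total,
               enc = as.numeric(e), gc3 = g[["gc3"]], gc3s = g[["gc3s"]],
               gc12 = g[["gc12"]], a3 = p[["a3"]], t3 = p[["t3"]],
               g3 = p[["g3"]], c3 = p[["c3"]], pr2_x = p[["pr2_x"]],
               pr2_y = p[["pr2_y"]],
               enc_expected = enc_expected(g[["gc3s"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("codon_bias_indices", "data.frame")
  out
}

#' Neutrality-plot regression (GC12 on GC3)
#'
#' Unweighted ordinary least squares of GC12 (%) on GC3 (%) across genes.
#' A slope near 1 with strong correlation indicates mutation pressure
#' acting equally on all codon positions; a slope near 0 indicates
#' selection constraining positions 1-2 independently of position 3.
#'
#' @param indices a [codon_bias_indices()] data.frame (needs >= 3 genes).
#' @return An object of class `neutrality_fit`: `slope`, `intercept`
#'   (percent scale), `r_squared`, `points` (data.frame `gene`,
#'   `gc3_percent`, `gc12_percent`), and the underlying `lm` fit.
#' @export
neutrality_fit <- function(indices) {
  stopifnot(is.data.frame(indices), all(c("gc3", "gc12") %in% names(indices)))
  if (nrow(indices) < 3L) stop("need at least 3 genes", call. = FALSE)
  pts <- data.frame(gene = indices$gene,
                    gc3_percent = 100 * indices$gc3,
                    gc12_percent = 100 * indices$gc12,
                    stringsAsFactors = FALSE)
  if (stats::var(pts$gc3_percent) == 0)
    stop("zero variance in GC3 across genes", call. = FALSE)
  fit <- stats::lm(gc12_percent ~ gc3_percent, data = pts)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = stats::cor(pts$gc3_percent, pts$gc12_percent)^2,
         points = pts, fit = fit),
    class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf("Neutrality plot fit (%d genes): GC12 = %.4f * GC3 + %.3f, R^2 = %.4f\n",
              nrow(x$points), x$slope, x$intercept, x$r_squared))
  invisible(x)
}
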