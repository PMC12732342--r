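#' A per-gene multiple alignment
#'
#' Lightweight container for an aligned gene panel: equal-length DNA rows
#' with `-` as the gap symbol.
#'
#' @param gene gene name.
#' @param rows named character vector of aligned sequences (names = taxa).
#' @param codon_aligned whether rows are codon-aligned (length divisible by
#'   3, gap runs in multiples of 3); required for Ka/Ks.
#' @return An object of class `gene_alignment`.
#' @export
gene_alignment <- function(gene, rows, codon_aligned = TRUE) {
  stopifnot(is.character(rows), length(rows) >= 1L)
  rows <- toupper(rows)
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop("rows differ in length", call. = FALSE)
  if (codon_aligned) {
    if (L %% 3L != 0L)
      stop("codon-aligned rows must have length divisible by 3",
           call. = FALSE)
    for (r in rows) {
      runs <- rle(strsplit(r, "")[[1L]] == "-")
      if (any(runs$values & runs$lengths %% 3L != 0L))
        stop("frame-breaking gap run in codon alignment", call. = FALSE)
    }
  }
  if (is.null(names(rows)))
    names(rows) <- paste0("taxon", seq_along(rows))
  structure(list(gene = gene, taxa = names(rows), rows = rows,
                 length = L, codon_aligned = codon_aligned),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("Alignment [", x$gene, "]: ", length(x$rows), " taxa x ", x$length,
      " bp", if (x$codon_aligned) ", codon-aligned", "\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file as a gene alignment
#'
#' @param path aligned FASTA (gap symbol `-`).
#' @param gene gene name; defaults to the file name without extension.
#' @param codon_aligned see [gene_alignment()].
#' @return a `gene_alignment`.
#' @export
read_gene_alignment <- function(path, gene = NULL, codon_aligned = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  seqs <- Biostrings::readDNAStringSet(path)
  rows <- stats::setNames(as.character(seqs),
                          vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L))
  gene_alignment(gene, rows, codon_aligned = codon_aligned)
}

#' Sliding-window nucleotide diversity
#'
#' Nucleotide diversity (pi) is the mean pairwise proportion of differing
#' sites. Within each window, columns containing any gap or ambiguity in
#' any row are excluded from numerator and denominator alike (complete
#' deletion per window, the convention of the standard sliding-window
#' tools). `mean_pi` applies the same rule over the whole alignment.
#'
#' @param aln a [gene_alignment()] with at least 2 rows.
#' @param window window size in bp (default 200).
#' @param step step size in bp (default 20).
#' @return An object of class `diversity_profile`: `gene`, `window`,
#'   `step`, `points` (data.frame `midpoint`, `pi`), `mean_pi`.
#' @export
pi_sliding <- function(aln, window = 200L, step = 20L) {
  stopifnot(inherits(aln, "gene_alignment"), window > 0L, step > 0L)
  n <- length(aln$rows)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  M <- do.call(rbind, strsplit(unname(aln$rows), ""))
  good <- apply(M, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  npairs <- n * (n - 1L) / 2L
  ## per-column count of pairwise differences among rows
  col_diffs <- apply(M, 2L, function(col) {
    tb <- table(col)
    (sum(tb)^2 - sum(tb^2)) / 2
  })
  pi_of <- function(cols) {
    cols <- cols[good[cols]]
    if (!length(cols)) return(NA_real_)
    sum(col_diffs[cols]) / (npairs * length(cols))
  }
  L <- aln$length
  if (window >= L) {
    starts <- 1L
    window_eff <- L
  } else {
    starts <- seq(1L, L - window + 1L, by = step)
    window_eff <- window
  }
  pts <- data.frame(
    midpoint = starts + (window_eff - 1) / 2,
    pi = vapply(starts, function(s) pi_of(s:(s + window_eff - 1L)), 0))
  pts <- pts[!is.na(pts$pi), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(gene = aln$gene, window = as.integer(window),
                 step = as.integer(step), points = pts,
                 mean_pi = pi_of(seq_len(L))),
            class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat(sprintf("Pi profile [%s]: mean pi %.4f over %d windows (%d bp / %d bp)\n",
              x$gene, x$mean_pi, nrow(x$points), x$window, x$step))
  invisible(x)
}

## ---- NG86 machinery ---------------------------------------------------

.BASES <- c("A", "C", "G", "T")

.ng86_memo <- new.env(parent = emptyenv())

## per-codon synonymous site fraction under `code`; mutations to stop
## codons count as nonsynonymous so sites always sum to 3 per codon
ng86_site_table <- function(code) {
  sense <- names(code$family_of)
  syn_sites <- stats::setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(.BASES, substr(cod, pos, pos))) {
        alt <- cod
        substr(alt, pos, pos) <- b
        if (!alt %in% code$stops &&
            code$family_of[[alt]] == code$family_of[[cod]])
          s <- s + 1
      }
    }
    syn_sites[cod] <- s / 3
  }
  syn_sites
}

## average syn/nonsyn differences between two sense codons over all
## minimal mutational pathways, skipping pathways through stop codons;
## returns c(sd, nd) or NULL when every pathway is blocked
ng86_codon_diffs <- function(cod_a, cod_b, code) {
  pos <- which(strsplit(cod_a, "")[[1L]] != strsplit(cod_b, "")[[1L]])
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- if (d == 1L) list(pos) else
    if (d == 2L) list(pos, rev(pos)) else
      list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
           pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  acc <- matrix(NA_real_, nrow = length(perms), ncol = 2L)
  for (i in seq_along(perms)) {
    cur <- cod_a
    sd <- nd <- 0
    ok <- TRUE
    for (p in perms[[i]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cod_b, p, p)
      if (nxt %in% code$stops) { ok <- FALSE; break }
      if (code$family_of[[nxt]] == code$family_of[[cur]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (ok) acc[i, ] <- c(sd, nd)
  }
  acc <- acc[!is.na(acc[, 1L]), , drop = FALSE]
  if (!nrow(acc)) return(NULL)
  c(sd = mean(acc[, 1L]), nd = mean(acc[, 2L]))
}

## Jukes-Cantor correction; NA at saturation (p >= 3/4)
jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the
#' two sequences), resolves multi-hit codons by equal-weight averaging over
#' all minimal mutational pathways that avoid stop codons, and converts the
#' proportions with the Jukes-Cantor correction
#' `d = -(3/4) log(1 - 4p/3)`. Codon pairs containing a gap or ambiguity
#' are excluded; codon pairs whose every pathway passes through a stop are
#' excluded and counted in `n_blocked`.
#'
#' @param seq_a,seq_b codon-aligned DNA strings of equal length (or a
#'   2-row [gene_alignment()] passed as `seq_a`).
#' @param code a [genetic_code()].
#' @param taxa optional length-2 character of sequence ids.
#' @return An object of class `pairwise_divergence`: `taxon_a`, `taxon_b`,
#'   `syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`, `ps`, `pn`,
#'   `ka`, `ks`, `ka_ks` (`NA` when `ks` is 0 or saturated),
#'   `n_codons_compared`, `n_blocked`.
#' @export
ng86_pairwise <- function(seq_a, seq_b = NULL, code = genetic_code(5),
                          taxa = c("a", "b")) {
  if (inherits(seq_a, "gene_alignment")) {
    stopifnot(length(seq_a$rows) == 2L, seq_a$codon_aligned)
    taxa <- seq_a$taxa
    seq_b <- unname(seq_a$rows[2L])
    seq_a <- unname(seq_a$rows[1L])
  }
  stopifnot(nchar(seq_a) == nchar(seq_b), nchar(seq_a) %% 3L == 0L)
  memo_key <- paste0("tab", code$id)
  if (is.null(.ng86_memo[[memo_key]]))
    .ng86_memo[[memo_key]] <- ng86_site_table(code)
  site_tab <- .ng86_memo[[memo_key]]
  starts <- seq(1L, nchar(seq_a), by = 3L)
  cod_a <- substring(toupper(seq_a), starts, starts + 2L)
  cod_b <- substring(toupper(seq_b), starts, starts + 2L)
  clean <- grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b) &
    !cod_a %in% code$stops & !cod_b %in% code$stops
  cod_a <- cod_a[clean]; cod_b <- cod_b[clean]
  S <- N <- Sd <- Nd <- 0
  n_blocked <- 0L
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(cod_a)) {
    key <- paste0(cod_a[i], cod_b[i])
    if (is.null(cache[[key]]))
      cache[[key]] <- list(ng86_codon_diffs(cod_a[i], cod_b[i], code))
    res <- cache[[key]][[1L]]
    if (is.null(res)) { n_blocked <- n_blocked + 1L; next }
    s_i <- (site_tab[[cod_a[i]]] + site_tab[[cod_b[i]]]) / 2
    S <- S + s_i
    N <- N + (3 - s_i)
    Sd <- Sd + res[["sd"]]
    Nd <- Nd + res[["nd"]]
  }
  n_comp <- length(cod_a) - n_blocked
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ks <- jukes_cantor(ps)
  ka <- jukes_cantor(pn)
  structure(
    list(taxon_a = taxa[1L], taxon_b = taxa[2L],
         syn_sites = S, nonsyn_sites = N,
         syn_diffs = Sd, nonsyn_diffs = Nd, ps = ps, pn = pn,
         ka = ka, ks = ks,
         ka_ks = if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks
                 else NA_real_,
         n_codons_compared = n_comp, n_blocked = n_blocked),
    class = "pairwise_divergence")
}

#' @export
print.pairwise_divergence <- function(x, ...) {
  cat(sprintf("NG86 %s vs %s: Ka %.4f, Ks %.4f, Ka/Ks %s (%d codons)\n",
              x$taxon_a, x$taxon_b, x$ka, x$ks,
              ifelse(is.na(x$ka_ks), "NA", sprintf("%.3f", x$ka_ks)),
              x$n_codons_compared))
  invisible(x)
}

#' Panel-wide divergence summary
#'
#' Mean pairwise Ka, Ks and Ka/Ks over all unordered taxon pairs of each
#' gene alignment, plus its whole-gene nucleotide diversity; genes are
#' ranked by mean pi and by mean Ka/Ks.
#'
#' @param alignments list of [gene_alignment()] objects.
#' @param code a [genetic_code()].
#' @param window,step passed to [pi_sliding()] for `mean_pi`.
#' @return data.frame with one row per gene: `gene`, `n_taxa`, `mean_ka`,
#'   `mean_ks`, `mean_ka_ks`, `mean_pi`, `rank_pi`, `rank_ka_ks`.
#' @export
panel_divergence <- function(alignments, code = genetic_code(5),
                             window = 200L, step = 20L) {
  rows <- list()
  for (aln in alignments) {
    if (length(aln$rows) < 2L) {
      warning("gene '", aln$gene, "' has fewer than 2 taxa; skipped",
              call. = FALSE)
      next
    }
    n <- length(aln$rows)
    ka <- ks <- kk <- c()
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      pd <- ng86_pairwise(unname(aln$rows[i]), unname(aln$rows[j]),
                          code = code, taxa = aln$taxa[c(i, j)])
      ka <- c(ka, pd$ka); ks <- c(ks, pd$ks); kk <- c(kk, pd$ka_ks)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = aln$gene, n_taxa = n,
      mean_ka = mean(ka, na.rm = TRUE), mean_ks = mean(ks, na.rm = TRUE),
      mean_ka_ks = if (all(is.na(kk))) NA_real_ else mean(kk, na.rm = TRUE),
      mean_pi = pi_sliding(aln, window, step)$mean_pi,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no gene with >= 2 taxa", call. = FALSE)
  out <- do.call(rbind, rows)
  out$rank_pi <- rank(-out$mean_pi, ties.method = "first")
  out$rank_ka_ks <- rank(-out$mean_ka_ks, ties.method = "first",
                         na.last = "keep")
  rownames(out) <- NULL
  out
}
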