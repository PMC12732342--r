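#' Strand-asymmetry skews of a DNA string
#'
#' AT skew = (A - T)/(A + T), GC skew = (G - C)/(G + C). Non-ACGT symbols
#' are excluded from the counts; a zero denominator yields `NA`.
#'
#' @param seq a single DNA string.
#' @return named numeric vector `c(at_skew = , gc_skew = )`.
#' @examples
#' skews("AAT")  # at_skew 1/3
#' @export
skews <- function(seq) {
  n <- .base_counts(seq)
  at <- n["A"] + n["T"]; gc <- n["G"] + n["C"]
  c(at_skew = if (at > 0) unname((n["A"] - n["T"]) / at) else NA_real_,
    gc_skew = if (gc > 0) unname((n["G"] - n["C"]) / gc) else NA_real_)
}

.base_counts <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  cnt <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  cnt[c("A", "C", "G", "T")]
}

#' Nucleotide composition of a sequence
#'
#' AT/GC content as fractions of counted (A/C/G/T) positions plus both
#' skews; `size` is the raw sequence length including any ambiguity symbols.
#'
#' @param seq a single DNA string.
#' @param label row label carried into reports.
#' @return An object of class `composition_stats` (also a one-row list):
#'   `label`, `size`, `at_content`, `gc_content`, `at_skew`, `gc_skew`.
#' @export
composition <- function(seq, label = "sequence") {
  stopifnot(nchar(seq) > 0L)
  n <- .base_counts(seq)
  tot <- sum(n)
  if (tot == 0L) stop("sequence has no unambiguous A/C/G/T base",
                      call. = FALSE)
  sk <- skews(seq)
  structure(
    list(label = label, size = nchar(seq),
         at_content = unname((n["A"] + n["T"]) / tot),
         gc_content = unname((n["G"] + n["C"]) / tot),
         at_skew = sk[["at_skew"]], gc_skew = sk[["gc_skew"]]),
    class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("%s: %d bp, AT %.1f%%, GC %.1f%%, AT skew %.3f, GC skew %.3f\n",
              x$label, x$size, 100 * x$at_content, 100 * x$gc_content,
              x$at_skew, x$gc_skew))
  invisible(x)
}

#' Composition at one codon position across a gene set
#'
#' Concatenates the given codon position over all sense codons of all genes
#' (each on its own coding strand; stop codons never contribute) and returns
#' its composition. `size` is the number of codons, i.e. of contributing
#' positions, matching the convention of per-position composition tables.
#'
#' @param cds_set list of [extract_cds()] results.
#' @param position codon position, 1, 2 or 3.
#' @param label row label.
#' @return a `composition_stats` object; its `size` is the codon count.
#' @export
codon_position_composition <- function(cds_set, position,
                                       label = paste0("codon_pos_", position)) {
  stopifnot(position %in% 1:3)
  if (!length(cds_set)) stop("empty CDS set", call. = FALSE)
  codons <- unlist(lapply(cds_set, `[[`, "codons"), use.names = FALSE)
  bases <- substr(codons, position, position)
  out <- composition(paste(bases, collapse = ""), label = label)
  out$size <- length(codons)
  out
}

#' Region-by-region composition table of a mitogenome
#'
#' The standard descriptive table of a mitogenome paper: full genome, all
#' PCGs and their three codon positions, the same split by coding strand
#' class (J / N), concatenated tRNAs, each rRNA, and the non-coding
#' regions. PCG rows are computed on each gene's own coding strand.
#'
#' @param record a [genome_record()].
#' @param code a [genetic_code()].
#' @return data.frame with columns `region`, `size_bp`, `at_content`,
#'   `gc_content`, `at_skew`, `gc_skew` (contents as fractions).
#' @export
composition_table <- function(record, code = genetic_code(5)) {
  rows <- list(composition(record$sequence, "Full length"))
  f <- record$features
  add_pcg_rows <- function(rows, cds, tag) {
    if (!length(cds)) return(rows)
    cat_seq <- paste(vapply(cds, `[[`, "", "nucleotides"), collapse = "")
    rows[[length(rows) + 1L]] <- composition(cat_seq, tag)
    for (p in 1:3)
      rows[[length(rows) + 1L]] <- codon_position_composition(
        cds, p, sprintf("%s-%s codon", tag, c("1st", "2nd", "3rd")[p]))
    rows
  }
  cds_all <- extract_all_cds(record, code = code)
  rows <- add_pcg_rows(rows, cds_all, "PCGs")
  rows <- add_pcg_rows(rows, extract_all_cds(record, code, strand = "J"),
                       "PCGs-J strand")
  rows <- add_pcg_rows(rows, extract_all_cds(record, code, strand = "N"),
                       "PCGs-N strand")
  trna <- f[f$category == "tRNA", , drop = FALSE]
  if (nrow(trna)) {
    seqs <- mapply(region_sequence, start = trna$start, end = trna$end,
                   MoreArgs = list(record = record))
    rows[[length(rows) + 1L]] <- composition(paste(seqs, collapse = ""),
                                             "tRNAs")
  }
  singles <- f[f$category %in% c("rRNA", "control_region", "repeat_region"),
               , drop = FALSE]
  for (i in seq_len(nrow(singles)))
    rows[[length(rows) + 1L]] <- composition(
      region_sequence(record, singles$start[i], singles$end[i]),
      singles$name[i])
  data.frame(
    region = vapply(rows, `[[`, "", "label"),
    size_bp = vapply(rows, `[[`, 0, "size"),
    at_content = vapply(rows, `[[`, 0, "at_content"),
    gc_content = vapply(rows, `[[`, 0, "gc_content"),
    at_skew = vapply(rows, `[[`, 0, "at_skew"),
    gc_skew = vapply(rows, `[[`, 0, "gc_skew"),
    stringsAsFactors = FALSE)
}

## report formatting: contents 1 d.p. (percent), skews 3 d.p.
format_composition_table <- function(tab) {
  data.frame(
    region = tab$region, size_bp = tab$size_bp,
    at_percent = sprintf("%.1f", 100 * tab$at_content),
    gc_percent = sprintf("%.1f", 100 * tab$gc_content),
    at_skew = sprintf("%.3f", tab$at_skew),
    gc_skew = sprintf("%.3f", tab$gc_skew),
    stringsAsFactors = FALSE)
}
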