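#' Extract the coding sequence of a protein-coding gene
#'
#' Returns the strand-corrected coding sequence of a PCG: the genome
#' subsequence for majority (J) strand genes, its reverse complement for
#' minority (N) strand genes. Stop codons are classified as complete
#' (`TAA`/`TAG` under the active code), or incomplete: a trailing single
#' `T` (length mod 3 == 1) or trailing `TA` (mod 3 == 2), the truncated
#' stops completed by transcript polyadenylation in animal mitochondria.
#' Any other frame remainder is a validation error, as is an internal stop.
#'
#' @param record a [genome_record()].
#' @param feature a feature name or a one-row slice of `record$features`
#'   with `category == "PCG"`.
#' @param code a [genetic_code()].
#' @return An object of class `coding_sequence`: list with `gene`, `strand`,
#'   `nucleotides` (coding strand, full length), `codons` (sense codons
#'   only; the terminal stop/remainder is excluded), `start_codon`,
#'   `stop_codon` (length 1-3), `stop_class` (`"complete"`,
#'   `"incomplete_T"`, `"incomplete_TA"`) and `trimmed`.
#' @export
extract_cds <- function(record, feature, code = genetic_code(5)) {
  stopifnot(inherits(record, "genome_record"))
  if (is.character(feature)) feature <- feature_row(record, feature)
  if (feature$category != "PCG")
    stop("feature '", feature$name, "' is not a PCG", call. = FALSE)
  nt <- region_sequence(record, feature$start, feature$end)
  if (feature$strand == "N") nt <- reverse_complement(nt)
  n <- nchar(nt)
  if (n < 6L) stop("CDS '", feature$name, "' shorter than 6 bp",
                   call. = FALSE)
  rem <- n %% 3L
  if (rem == 0L) {
    last <- substr(nt, n - 2L, n)
    if (!last %in% code$stops)
      stop("CDS '", feature$name,
           "' has complete frame but no terminal stop (", last, ")",
           call. = FALSE)
    stop_codon <- last
    stop_class <- "complete"
    body <- substr(nt, 1L, n - 3L)
  } else if (rem == 1L) {
    if (substr(nt, n, n) != "T")
      stop("CDS '", feature$name,
           "' has frame remainder 1 but final base is not T", call. = FALSE)
    stop_codon <- "T"
    stop_class <- "incomplete_T"
    body <- substr(nt, 1L, n - 1L)
  } else {
    if (substr(nt, n - 1L, n) != "TA")
      stop("CDS '", feature$name,
           "' has frame remainder 2 but tail is not TA", call. = FALSE)
    stop_codon <- "TA"
    stop_class <- "incomplete_TA"
    body <- substr(nt, 1L, n - 2L)
  }
  codons <- substring(body, seq(1L, nchar(body), 3L),
                      seq(3L, nchar(body), 3L))
  internal_stop <- which(codons %in% code$stops)
  if (length(internal_stop))
    stop("internal stop codon in '", feature$name, "' at codon ",
         internal_stop[1L], " (", codons[internal_stop[1L]], ")",
         call. = FALSE)
  structure(
    list(gene = feature$name, strand = feature$strand, nucleotides = nt,
         codons = codons, start_codon = codons[1L], stop_codon = stop_codon,
         stop_class = stop_class, trimmed = stop_class != "complete"),
    class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("CDS ", x$gene, " [", x$strand, " strand]: ", nchar(x$nucleotides),
      " bp, ", length(x$codons), " sense codons, start ", x$start_codon,
      ", stop ", x$stop_codon, " (", x$stop_class, ")\n", sep = "")
  invisible(x)
}

#' Extract all protein-coding genes of a record
#'
#' @inheritParams extract_cds
#' @param strand optional strand filter, `"J"` or `"N"`.
#' @return named list of `coding_sequence` objects, in genome order.
#' @export
extract_all_cds <- function(record, code = genetic_code(5), strand = NULL) {
  f <- record$features
  keep <- f$category == "PCG"
  if (!is.null(strand)) keep <- keep & f$strand == strand
  idx <- which(keep)
  out <- lapply(idx, function(i) extract_cds(record, f$name[i], code = code))
  stats::setNames(out, f$name[idx])
}

#' Gene adjacency: overlaps and intergenic spacers
#'
#' For consecutive features in genome order (regions included), the
#' intergenic length is `start(next) - end(prev) - 1`: negative values are
#' overlaps, positive are spacers, zero is contiguity. On a circular record
#' the last feature wraps to the first.
#'
#' @param record a [genome_record()] with at least two features.
#' @return An object of class `adjacency_report`: list with `pairs`
#'   (data.frame `upstream`, `downstream`, `intergenic`), `n_overlaps`,
#'   `n_spacers`, `max_overlap`, `max_spacer` (bp; 0 when none). Ties for
#'   the maxima resolve to the first pair in genome order.
#' @export
adjacency_stats <- function(record) {
  stopifnot(inherits(record, "genome_record"))
  f <- record$features
  if (nrow(f) < 2L) stop("need at least 2 features", call. = FALSE)
  up <- f$name
  down <- c(f$name[-1L], f$name[1L])
  intergenic <- c(f$start[-1L] - f$end[-nrow(f)] - 1L,
                  f$start[1L] + record$length - f$end[nrow(f)] - 1L)
  if (record$topology != "circular") {
    up <- up[-length(up)]; down <- down[-length(down)]
    intergenic <- intergenic[-length(intergenic)]
  }
  pairs <- data.frame(upstream = up, downstream = down,
                      intergenic = as.integer(intergenic),
                      stringsAsFactors = FALSE)
  ov <- pairs$intergenic < 0L
  sp <- pairs$intergenic > 0L
  structure(
    list(pairs = pairs,
         n_overlaps = sum(ov), n_spacers = sum(sp),
         max_overlap = if (any(ov)) -min(pairs$intergenic) else 0L,
         max_spacer = if (any(sp)) max(pairs$intergenic) else 0L),
    class = "adjacency_report")
}

#' @export
print.adjacency_report <- function(x, ...) {
  cat("Adjacency: ", x$n_overlaps, " overlaps (max ", x$max_overlap,
      " bp), ", x$n_spacers, " spacers (max ", x$max_spacer, " bp) over ",
      nrow(x$pairs), " pairs\n", sep = "")
  invisible(x)
}
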