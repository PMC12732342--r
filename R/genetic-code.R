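#' Genetic code tables for mitochondrial analyses
#'
#' Builds a genetic-code object from an NCBI translation table id. The default
#' throughout the package is table 5 (invertebrate mitochondrial), under which
#' `TGA` encodes Trp, `ATA` encodes Met and `AGA`/`AGG` encode Ser, leaving
#' 62 sense codons and the two stops `TAA`/`TAG`.
#'
#' @param table_id NCBI translation table id; tables 2 (vertebrate
#'   mitochondrial) and 5 (invertebrate mitochondrial) are supported.
#' @return An object of class `genetic_code` with elements:
#'   \describe{
#'     \item{id}{the table id}
#'     \item{map}{named character vector, codon (DNA alphabet) to one-letter
#'       amino acid, `"*"` for stop}
#'     \item{stops}{character vector of stop codons}
#'     \item{families}{named list, amino acid to its synonymous codon set}
#'     \item{family_of}{named character vector, sense codon to amino acid}
#'     \item{family_size}{named integer vector, sense codon to the size of its
#'       synonymous family}
#'   }
#' @examples
#' code <- genetic_code(5)
#' code$map[["TGA"]]   # "W"
#' length(code$family_of)  # 62 sense codons
#' @export
genetic_code <- function(table_id = 5) {
  if (!table_id %in% c(2L, 5L))
    stop("unsupported translation table id: ", table_id,
         " (supported: 2, 5)", call. = FALSE)
  map <- Biostrings::getGeneticCode(as.character(table_id))
  map <- map[order(names(map))]
  stops <- names(map)[map == "*"]
  sense <- map[map != "*"]
  families <- split(names(sense), unname(sense))
  family_size <- stats::setNames(
    lengths(families)[unname(sense)], names(sense))
  structure(
    list(id = as.integer(table_id), map = map, stops = stops,
         families = families, family_of = sense,
         family_size = family_size),
    class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (NCBI table ", x$id, "): ",
      length(x$family_of), " sense codons, stops ",
      paste(x$stops, collapse = "/"), "\n", sep = "")
  sizes <- table(lengths(x$families))
  cat("Synonymous family sizes: ",
      paste(names(sizes), "-fold x", sizes, sep = "", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' Ambiguity-aware reverse complement via [Biostrings::reverseComplement()].
#' Used to place minority (N) strand genes on their coding strand.
#'
#' @param seq a single DNA string (IUPAC alphabet).
#' @return the reverse-complemented string.
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  out <- try(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq))),
    silent = TRUE)
  if (inherits(out, "try-error"))
    stop("not an IUPAC DNA string: ", substr(seq, 1, 30), call. = FALSE)
  out
}

## single-base complement lookup used by repeat search (ACGT plus N)
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
           B = "V", V = "B", D = "H", H = "D")

.complement_chars <- function(chars) {
  out <- .COMP[chars]
  if (anyNA(out)) stop("non-IUPAC symbol in sequence", call. = FALSE)
  unname(out)
}
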