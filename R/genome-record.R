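#' Construct an annotated genome record
#'
#' The central container of the package: a (usually circular) DNA sequence
#' plus an ordered table of feature annotations, mirroring the gene table of
#' an annotated mitogenome. Coordinates are 1-based and inclusive everywhere.
#'
#' @param id accession-like identifier.
#' @param sequence uppercase IUPAC DNA string.
#' @param features data.frame with columns `name`, `category` (one of
#'   `"PCG"`, `"tRNA"`, `"rRNA"`, `"control_region"`, `"repeat_region"`),
#'   `strand` (`"J"` majority / `"N"` minority), `start`, `end` and optional
#'   `anticodon` (3-letter RNA string, tRNAs only).
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `genome_record` with fields `id`, `topology`,
#'   `sequence`, `features` (sorted by start, with a `size` column) and
#'   `length`.
#' @export
genome_record <- function(id, sequence, features = empty_features(),
                          topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  features <- normalize_features(features)
  rec <- structure(
    list(id = as.character(id), topology = topology, sequence = sequence,
         features = features, length = nchar(sequence)),
    class = "genome_record")
  validate_genome_record(rec)
  rec
}

#' @rdname genome_record
#' @export
empty_features <- function() {
  data.frame(name = character(), category = character(),
             strand = character(), start = integer(), end = integer(),
             anticodon = character(), size = integer(),
             stringsAsFactors = FALSE)
}

.FEATURE_CATEGORIES <- c("PCG", "tRNA", "rRNA", "control_region",
                         "repeat_region")

normalize_features <- function(features) {
  stopifnot(is.data.frame(features))
  req <- c("name", "category", "strand", "start", "end")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols))
    stop("feature table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"anticodon" %in% names(features))
    features$anticodon <- rep(NA_character_, nrow(features))
  features$anticodon[!nzchar(features$anticodon) |
                       is.na(features$anticodon)] <- NA_character_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- !features$category %in% .FEATURE_CATEGORIES
  if (any(bad))
    stop("unknown feature category: ",
         paste(unique(features$category[bad]), collapse = ", "),
         call. = FALSE)
  bad <- !features$strand %in% c("J", "N")
  if (any(bad))
    stop("invalid strand (must be J or N): ",
         paste(unique(features$strand[bad]), collapse = ", "),
         call. = FALSE)
  if (any(!is.na(features$anticodon) & features$category != "tRNA"))
    stop("anticodon present on a non-tRNA feature", call. = FALSE)
  features <- features[order(features$start, features$end), , drop = FALSE]
  features$size <- features$end - features$start + 1L
  rownames(features) <- NULL
  features[c("name", "category", "strand", "start", "end", "anticodon",
             "size")]
}

validate_genome_record <- function(rec) {
  f <- rec$features
  if (rec$length < 1L) stop("empty sequence", call. = FALSE)
  if (nrow(f) == 0L) return(invisible(rec))
  spanning <- f$end < f$start
  if (any(spanning)) {
    if (rec$topology != "circular")
      stop("start > end on a linear record: ",
           paste(f$name[spanning], collapse = ", "), call. = FALSE)
    if (sum(spanning) > 1L)
      stop("more than one origin-spanning feature", call. = FALSE)
    ## wrapped size for the spanning feature
    rec$features$size[spanning] <-
      rec$length - f$start[spanning] + f$end[spanning] + 1L
  }
  out <- f$start < 1L | f$start > rec$length | f$end < 1L |
    f$end > rec$length
  if (any(out))
    stop("feature coordinates outside [1, ", rec$length, "]: ",
         paste(f$name[out], collapse = ", "), call. = FALSE)
  dup <- duplicated(f$name) &
    !f$category %in% c("control_region", "repeat_region")
  if (any(dup))
    stop("duplicated feature name(s): ",
         paste(unique(f$name[dup]), collapse = ", "), call. = FALSE)
  invisible(rec)
}

#' @export
print.genome_record <- function(x, ...) {
  cat(x$topology, " genome record '", x$id, "': ", x$length, " bp, ",
      nrow(x$features), " features\n", sep = "")
  if (nrow(x$features)) {
    tab <- table(x$features$category)
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Extract the region of a feature (or arbitrary coordinates)
#'
#' Returns the genome-strand subsequence for 1-based inclusive coordinates,
#' wrapping across the origin on circular records when `start > end`.
#'
#' @param record a `genome_record`.
#' @param start,end 1-based inclusive coordinates.
#' @return a DNA string.
#' @export
region_sequence <- function(record, start, end) {
  stopifnot(inherits(record, "genome_record"))
  if (start <= end) return(substr(record$sequence, start, end))
  if (record$topology != "circular")
    stop("start > end on a linear record", call. = FALSE)
  paste0(substr(record$sequence, start, record$length),
         substr(record$sequence, 1L, end))
}

feature_row <- function(record, name) {
  i <- which(record$features$name == name)
  if (!length(i)) stop("no feature named '", name, "'", call. = FALSE)
  record$features[i[1L], , drop = FALSE]
}
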