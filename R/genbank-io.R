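#' Read a single-record GenBank flat file
#'
#' Minimal GenBank parser for annotated mitogenomes: only the LOCUS,
#' FEATURES and ORIGIN blocks are interpreted. Feature keys are mapped onto
#' the package's five categories: `CDS` to `PCG`, `tRNA`, `rRNA`, and
#' `misc_feature`/`D-loop` to `control_region` or `repeat_region` by name
#' matching. `complement(...)` locations become strand `N`, plain locations
#' strand `J`. Qualifiers used: `/gene`, `/product`, `/note`, `/anticodon`,
#' `/codon_start`, `/transl_table`.
#'
#' @param path path to a single-record GenBank flat file.
#' @return a [genome_record()].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L)
    stop("format error at line 1: no LOCUS line in ", path, call. = FALSE)
  if (length(locus_i) > 1L)
    stop("multi-record GenBank file (", length(locus_i),
         " LOCUS lines): ", path, call. = FALSE)
  locus <- lines[locus_i]
  topology <- if (grepl("\\bcircular\\b", locus)) "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1L]][1L]

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) != 1L)
    stop("format error: expected exactly one ORIGIN block in ", path,
         call. = FALSE)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1L] else length(lines) + 1L

  seq_lines <- lines[(orig_i + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence))
    stop("format error at line ", orig_i, ": empty ORIGIN block",
         call. = FALSE)

  features <- empty_features()
  if (length(feat_i) == 1L && feat_i < orig_i) {
    features <- .parse_genbank_features(lines, feat_i, orig_i)
  }
  rec <- genome_record(id = id, sequence = sequence, features = features,
                       topology = topology)
  rec
}

.parse_genbank_features <- function(lines, feat_i, orig_i) {
  block <- lines[(feat_i + 1L):(orig_i - 1L)]
  ## a new feature starts with a key in columns 6-20
  is_key <- grepl("^ {5}\\S", block)
  if (!any(is_key)) return(empty_features())
  idx <- which(is_key)
  feats <- list()
  for (k in seq_along(idx)) {
    from <- idx[k]
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
    head_line <- block[from]
    parts <- strsplit(trimws(head_line), "\\s+")[[1L]]
    key <- parts[1L]
    loc <- paste(parts[-1L], collapse = "")
    quals <- .parse_qualifiers(block[seq(from + 1L, length.out = to - from)])
    if (key == "source") next
    if (grepl("join", loc))
      stop("join() locations are not supported (feature '", key, "')",
           call. = FALSE)
    strand <- if (grepl("^complement\\(", loc)) "N" else "J"
    loc2 <- gsub("complement\\(|\\)|<|>", "", loc)
    m <- regmatches(loc2, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc2))[[1L]]
    if (length(m) != 3L)
      stop("format error: cannot parse location '", loc, "' of feature '",
           key, "'", call. = FALSE)
    start <- as.integer(m[2L]); end <- as.integer(m[3L])
    name <- quals[["gene"]] %||% quals[["product"]] %||%
      quals[["note"]] %||% key
    category <- switch(key,
      CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
      "D-loop" = "control_region",
      misc_feature = ,
      repeat_region = {
        nm <- tolower(name)
        if (grepl("repeat", nm)) "repeat_region"
        else if (grepl("control|d-loop|a\\+t", nm)) "control_region"
        else NA_character_
      },
      NA_character_)
    if (is.na(category)) next  # unclassifiable auxiliary feature
    feats[[length(feats) + 1L]] <- data.frame(
      name = name, category = category, strand = strand,
      start = start, end = end,
      anticodon = quals[["anticodon"]] %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(feats)) return(empty_features())
  do.call(rbind, feats)
}

.parse_qualifiers <- function(lines) {
  lines <- trimws(lines)
  ## merge continuation lines onto their qualifier
  starts <- grepl("^/", lines)
  if (!any(starts)) return(list())
  grp <- cumsum(starts)
  merged <- vapply(split(lines[grp > 0], grp[grp > 0]),
                   paste, collapse = " ", FUN.VALUE = "")
  out <- list()
  for (q in merged) {
    m <- regmatches(q, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', q))[[1L]]
    if (length(m) == 3L) out[[m[2L]]] <- m[3L]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a

#' Write a genome record as a GenBank flat file
#'
#' Inverse of [read_genbank()] for the dialect this package reads; output is
#' byte-stable for a fixed record (no timestamps).
#'
#' @param record a [genome_record()].
#' @param path output file path.
#' @param transl_table translation table id written on CDS features.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path, transl_table = 5) {
  stopifnot(inherits(record, "genome_record"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %-16s %d bp    DNA     %s INV 01-JAN-2000",
            record$id, record$length, record$topology))
  w(sprintf("DEFINITION  %s synthetic or re-exported mitogenome record.",
            record$id))
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     source          1..%d", record$length))
  f <- record$features
  for (i in seq_len(nrow(f))) {
    key <- switch(f$category[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control_region = "misc_feature",
                  repeat_region = "misc_feature")
    loc <- sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "N") loc <- sprintf("complement(%s)", loc)
    w(sprintf("     %-15s %s", key, loc))
    if (f$category[i] %in% c("control_region", "repeat_region")) {
      w(sprintf('                     /note="%s"', f$name[i]))
    } else {
      w(sprintf('                     /gene="%s"', f$name[i]))
    }
    if (!is.na(f$anticodon[i]))
      w(sprintf('                     /anticodon="%s"', f$anticodon[i]))
    if (f$category[i] == "PCG") {
      w("                     /codon_start=1")
      w(sprintf("                     /transl_table=%d", transl_table))
    }
  }
  w("ORIGIN")
  seq <- tolower(record$sequence)
  pos <- seq(1L, nchar(seq), by = 60L)
  for (p in pos) {
    chunk <- substr(seq, p, min(p + 59L, nchar(seq)))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    w(sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  w("//")
  invisible(path)
}

#' Read a genome from FASTA plus a tab-separated feature table
#'
#' The feature table mirrors the annotation table of a published mitogenome:
#' UTF-8 TSV with header columns `name`, `category`, `strand`, `start`,
#' `end` and optional `anticodon`. Same contract as [read_genbank()].
#'
#' @param fasta path to a single-sequence FASTA file.
#' @param table path to the feature table TSV.
#' @param topology record topology, `"circular"` (default) or `"linear"`.
#' @return a [genome_record()].
#' @export
read_feature_table <- function(fasta, table,
                               topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  for (p in c(fasta, table))
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L)
    stop("FASTA must contain exactly one sequence, found ", length(seqs),
         call. = FALSE)
  tab <- utils::read.delim(table, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("name", "category", "strand", "start", "end")
  if (!all(req %in% names(tab)))
    stop("feature table lacks column(s): ",
         paste(setdiff(req, names(tab)), collapse = ", "), call. = FALSE)
  if (nrow(tab)) {
    tab$start <- as.integer(tab$start)
    tab$end <- as.integer(tab$end)
  } else {
    tab <- empty_features()
  }
  id <- strsplit(names(seqs)[1L], "\\s+")[[1L]][1L]
  genome_record(id = id, sequence = as.character(seqs[[1L]]),
                features = tab, topology = topology)
}

#' Write the annotation table of a record as TSV
#'
#' One row per feature with name, category, strand, coordinates, size, start
#' and stop codons (PCGs with readable frames only), anticodon, and the
#' intergenic length preceding each feature (negative = overlap with the
#' upstream neighbour; the first row of a circular record carries the
#' wrap-around gap). The output is byte-stable for a fixed record and is
#' re-readable by [read_feature_table()].
#'
#' @param record a [genome_record()].
#' @param path optional output path; when `NULL` the TSV is returned as a
#'   character vector of lines.
#' @param code genetic code used for start/stop classification.
#' @return the TSV lines, invisibly when `path` is given.
#' @export
write_feature_table <- function(record, path = NULL, code = genetic_code(5)) {
  stopifnot(inherits(record, "genome_record"))
  f <- record$features
  header <- paste(c("name", "category", "strand", "start", "end", "size",
                    "start_codon", "stop_codon", "anticodon", "intergenic"),
                  collapse = "\t")
  if (nrow(f) == 0L) {
    out <- header
  } else {
    intergenic <- rep(NA_integer_, nrow(f))
    if (nrow(f) >= 2L) {
      adj <- adjacency_stats(record)
      m <- match(f$name, adj$pairs$downstream)
      intergenic <- adj$pairs$intergenic[m]
    }
    starts <- stops <- rep(NA_character_, nrow(f))
    for (i in which(f$category == "PCG")) {
      cds <- tryCatch(extract_cds(record, f$name[i], code = code),
                      error = function(e) NULL)
      if (!is.null(cds)) {
        starts[i] <- cds$start_codon
        stops[i] <- cds$stop_codon
      }
    }
    rows <- paste(f$name, f$category, f$strand, f$start, f$end, f$size,
                  ifelse(is.na(starts), "", starts),
                  ifelse(is.na(stops), "", stops),
                  ifelse(is.na(f$anticodon), "", f$anticodon),
                  ifelse(is.na(intergenic), "", intergenic),
                  sep = "\t")
    out <- c(header, rows)
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
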