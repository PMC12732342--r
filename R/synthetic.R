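#' Default gene layout for the synthetic mitogenome generator
#'
#' The gene order, strands and sizes of a typical aphid mitogenome
#' (37 genes plus the repeat and control regions); features are placed
#' contiguously, so the synthetic genome length is the sum of the sizes
#' (15,659 bp for the default layout).
#'
#' @return data.frame with columns `name`, `category`, `strand`, `size`,
#'   `anticodon`.
#' @export
default_layout <- function() {
  path <- system.file("extdata", "PV837988_features.tsv",
                      package = "mitochar")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  data.frame(name = tab$name, category = tab$category, strand = tab$strand,
             size = as.integer(tab$end) - as.integer(tab$start) + 1L,
             anticodon = ifelse(is.na(tab$anticodon) | !nzchar(tab$anticodon),
                                NA_character_, tab$anticodon),
             stringsAsFactors = FALSE)
}

#' Specification for a synthetic mitogenome
#'
#' Bundles every knob of the generator. Defaults emulate an aphid
#' mitogenome: ~15.7 kb circular genome with the standard 37-gene layout,
#' AT content 0.84, codon usage skewed toward A/T-ending codons, and a
#' control region carrying a 65 bp lead, three 109 bp tandem copies, an
#' AT-rich tract, a 13 bp poly-T stretch and a 137 bp stem-loop (45 bp arms, 47 bp loop).
#'
#' @param seed integer seed; all randomness of [generate_genome()] derives
#'   from it.
#' @param layout data.frame as [default_layout()].
#' @param target_at genome AT-content target (fraction).
#' @param codon_weights named non-negative weights over sense codons; the
#'   default multiplies per-base probabilities `A = T = target_at/2`,
#'   `G = C = (1 - target_at)/2`, which makes `TTA` dominate the Leu family.
#' @param n_tandem_copies,unit_length,poly_t_len,stem_len,loop_len,lead_len
#'   control-region structure.
#' @param code a [genetic_code()].
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, layout = default_layout(),
                           target_at = 0.84, codon_weights = NULL,
                           n_tandem_copies = 3L, unit_length = 109L,
                           poly_t_len = 13L, stem_len = 45L,
                           loop_len = 47L, lead_len = 65L,
                           code = genetic_code(5)) {
  stopifnot(target_at > 0, target_at < 1,
            all(layout$size[layout$category == "PCG"] >= 6L))
  if (is.null(codon_weights)) {
    pb <- c(A = target_at / 2, T = target_at / 2,
            G = (1 - target_at) / 2, C = (1 - target_at) / 2)
    sense <- names(code$family_of)
    codon_weights <- stats::setNames(
      vapply(sense, function(cod)
        prod(pb[strsplit(cod, "")[[1L]]]), 0), sense)
  }
  if (any(codon_weights < 0) ||
      any(tapply(codon_weights[names(code$family_of)],
                 unname(code$family_of[names(codon_weights)]), sum) <= 0))
    stop("codon weights must be non-negative with a positive total per ",
         "amino-acid family", call. = FALSE)
  structure(
    list(seed = as.integer(seed), layout = layout, target_at = target_at,
         codon_weights = codon_weights,
         control_region = list(n_tandem_copies = as.integer(n_tandem_copies),
                               unit_length = as.integer(unit_length),
                               poly_t_len = as.integer(poly_t_len),
                               stem_len = as.integer(stem_len),
                               loop_len = as.integer(loop_len),
                               lead_len = as.integer(lead_len)),
         code = code),
    class = "synthetic_spec")
}

.rand_dna <- function(n, at = 0.84) {
  if (n <= 0L) return("")
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

## break T-homopolymers of length >= cap by substituting an A
.break_t_runs <- function(seq, cap) {
  x <- strsplit(seq, "")[[1L]]
  r <- rle(x == "T")
  ends <- cumsum(r$lengths)
  for (k in which(r$values & r$lengths >= cap))
    x[ends[k]] <- "A"
  paste(x, collapse = "")
}

#' Generate a synthetic annotated mitogenome with known ground truth
#'
#' Deterministic for a fixed spec seed. PCGs are built codon-by-codon from
#' the spec's codon weights (sense codons only, so internally stop-free
#' under the active code), start with a random ATN codon and end with a
#' complete `TAA` or the planted incomplete `T`/`TA` that the gene's size
#' dictates; minority-strand genes are reverse-complemented into the
#' genome. The control region carries the planted lead/tandem/AT-rich/
#' poly-T/stem-loop structure.
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `truth_bundle`: `record` (the
#'   [genome_record()]), `planted` (data.frame of control-region segments,
#'   region-relative and absolute coordinates), `codon_counts` (named list,
#'   gene to sense-codon count table), `spec`.
#' @export
generate_genome <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  code <- spec$code
  sense <- names(code$family_of)
  w <- spec$codon_weights[sense]
  starts_pool <- intersect(c("ATA", "ATT", "ATG"), sense)
  pieces <- character(nrow(spec$layout))
  codon_counts <- list()
  planted <- NULL
  pos <- 1L
  feat <- spec$layout
  feat$start <- NA_integer_; feat$end <- NA_integer_
  for (i in seq_len(nrow(feat))) {
    size <- feat$size[i]
    cat_i <- feat$category[i]
    if (cat_i == "PCG") {
      rem <- size %% 3L
      n_codons <- (size - rem) %/% 3L - (if (rem == 0L) 1L else 0L)
      start_codon <- sample(starts_pool, 1L)
      body <- sample(sense, n_codons - 1L, replace = TRUE, prob = w)
      stop_codon <- switch(as.character(rem), "0" = "TAA", "1" = "T",
                           "2" = "TA")
      cds <- paste0(paste(c(start_codon, body), collapse = ""), stop_codon)
      codon_counts[[feat$name[i]]] <- table(c(start_codon, body))
      pieces[i] <- if (feat$strand[i] == "N") reverse_complement(cds)
                   else cds
    } else if (cat_i == "control_region") {
      cr <- .build_control_region(size, spec)
      pieces[i] <- cr$seq
      planted <- cr$segments
      planted$abs_start <- planted$start + pos - 1L
      planted$abs_end <- planted$end + pos - 1L
    } else {
      pieces[i] <- .rand_dna(size, spec$target_at)
    }
    feat$start[i] <- pos
    feat$end[i] <- pos + size - 1L
    pos <- pos + size
  }
  features <- data.frame(name = feat$name, category = feat$category,
                         strand = feat$strand, start = feat$start,
                         end = feat$end, anticodon = feat$anticodon,
                         stringsAsFactors = FALSE)
  rec <- genome_record(id = sprintf("SYN%07d", spec$seed),
                       sequence = paste(pieces, collapse = ""),
                       features = features, topology = "circular")
  structure(list(record = rec, planted = planted,
                 codon_counts = codon_counts, spec = spec),
            class = "truth_bundle")
}

.build_control_region <- function(size, spec) {
  p <- spec$control_region
  at <- spec$target_at
  tandem_span <- p$n_tandem_copies * p$unit_length
  stem_span <- 2L * p$stem_len + p$loop_len
  at_rich_len <- size - p$lead_len - tandem_span - p$poly_t_len - stem_span
  if (at_rich_len < 100L)
    stop("control region too small for the requested structure ",
         "(AT-rich tract would be ", at_rich_len, " bp)", call. = FALSE)
  lead <- .break_t_runs(.rand_dna(p$lead_len, at), p$poly_t_len - 4L)
  unit <- .break_t_runs(.rand_dna(p$unit_length, at), p$poly_t_len - 4L)
  tandem <- strrep(unit, p$n_tandem_copies)
  ## pure A/T tract, T-runs broken, anchored on A at both ends so the
  ## planted poly-T stays the unique longest T-homopolymer
  at_rich <- .break_t_runs(.rand_dna(at_rich_len, 0.9999),
                           p$poly_t_len - 4L)
  substr(at_rich, 1L, 1L) <- "A"
  substr(at_rich, at_rich_len, at_rich_len) <- "A"
  poly_t <- strrep("T", p$poly_t_len)
  arm <- paste0("G", .rand_dna(p$stem_len - 1L, 0.5))
  loop <- .break_t_runs(.rand_dna(p$loop_len, at), p$poly_t_len - 4L)
  stem <- paste0(arm, loop, reverse_complement(arm))
  seq <- paste0(lead, tandem, at_rich, poly_t, stem)
  stopifnot(nchar(seq) == size)
  b <- cumsum(c(p$lead_len, tandem_span, at_rich_len, p$poly_t_len,
                stem_span))
  segments <- data.frame(
    label = c("lead", "tandem_array", "at_rich", "poly_T", "stem_loop"),
    start = c(1L, b[1L] + 1L, b[2L] + 1L, b[3L] + 1L, b[4L] + 1L),
    end = b, stringsAsFactors = FALSE)
  list(seq = seq, segments = segments)
}

#' Evolve a star-tree gene panel from a root coding sequence
#'
#' Each taxon descends independently from the root: single-base codon
#' changes are proposed at rate `branch_sub_rate` per site, synonymous
#' proposals are always accepted, nonsynonymous ones with probability
#' `omega` (capped at 1), and proposals creating stop codons are rejected.
#' Returns a gap-free codon alignment with the true accepted counts.
#'
#' @param root_cds a `coding_sequence` (e.g. from [extract_cds()]).
#' @param n_taxa number of taxa (>= 2).
#' @param branch_sub_rate expected proposals per site per branch.
#' @param omega acceptance probability for nonsynonymous proposals
#'   (the simulated dN/dS; >= 0).
#' @param seed integer seed.
#' @param code a [genetic_code()].
#' @return a [gene_alignment()] with attribute `truth`: data.frame
#'   `taxon`, `accepted_syn`, `accepted_nonsyn`.
#' @export
evolve_panel <- function(root_cds, n_taxa, branch_sub_rate, omega,
                         seed = 1L, code = genetic_code(5)) {
  stopifnot(inherits(root_cds, "coding_sequence"), n_taxa >= 2L,
            omega >= 0, branch_sub_rate >= 0)
  set.seed(as.integer(seed))
  root <- root_cds$codons
  L <- 3L * length(root)
  rows <- character(n_taxa)
  truth <- data.frame(taxon = paste0("taxon", seq_len(n_taxa)),
                      accepted_syn = 0L, accepted_nonsyn = 0L,
                      stringsAsFactors = FALSE)
  for (t in seq_len(n_taxa)) {
    cods <- root
    n_prop <- stats::rpois(1L, branch_sub_rate * L)
    if (n_prop > 0L) for (p in seq_len(n_prop)) {
      site <- sample.int(L, 1L)
      ci <- (site - 1L) %/% 3L + 1L
      pos <- (site - 1L) %% 3L + 1L
      cur <- cods[ci]
      new_base <- sample(setdiff(.BASES, substr(cur, pos, pos)), 1L)
      alt <- cur
      substr(alt, pos, pos) <- new_base
      if (alt %in% code$stops) next
      if (code$family_of[[alt]] == code$family_of[[cur]]) {
        cods[ci] <- alt
        truth$accepted_syn[t] <- truth$accepted_syn[t] + 1L
      } else if (stats::runif(1L) < min(omega, 1)) {
        cods[ci] <- alt
        truth$accepted_nonsyn[t] <- truth$accepted_nonsyn[t] + 1L
      }
    }
    rows[t] <- paste(cods, collapse = "")
  }
  aln <- gene_alignment(root_cds$gene,
                        stats::setNames(rows, truth$taxon),
                        codon_aligned = TRUE)
  attr(aln, "truth") <- truth
  aln
}
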