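#' Run the full mitogenome characterization
#'
#' Orchestrates every stage of the package on one annotated genome:
#' annotation table with adjacency, region/codon-position composition,
#' codon usage (counts, RSCU, amino-acid frequencies), per-gene bias
#' indices with ENc-plot / PR2 / neutrality plot data, genome-wide repeat
#' pairs, tandem arrays, control-region decomposition, and (optionally)
#' per-gene alignment divergence. All tabular outputs are TSV with fixed
#' number formatting and no timestamps, so re-runs are byte-identical; a
#' machine-readable `summary.json` collects the headline statistics.
#'
#' @param input path to a GenBank flat file, or a [genome_record()].
#' @param out_dir output directory (created if missing).
#' @param fasta,table alternative input: FASTA + feature-table paths
#'   (used when `input` is `NULL`).
#' @param code_id NCBI translation table id.
#' @param family_mode RSCU family mode, `"full"` or `"split"`.
#' @param min_repeat_len minimal repeat length for [find_repeats()].
#' @param window,step sliding-window parameters for [pi_sliding()].
#' @param alignments optional list of [gene_alignment()] objects (or a
#'   directory of aligned FASTA files) for the divergence stage.
#' @param verbose print progress messages.
#' @return invisibly, a list with `summary` (the JSON content as a list)
#'   and `files` (paths written).
#' @export
run_characterize <- function(input, out_dir, fasta = NULL, table = NULL,
                             code_id = 5, family_mode = "full",
                             min_repeat_len = 30L, window = 200L,
                             step = 20L, alignments = NULL,
                             verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  record <- if (inherits(input, "genome_record")) input
    else if (!is.null(input)) read_genbank(input)
    else if (!is.null(fasta) && !is.null(table))
      read_feature_table(fasta, table)
    else stop("no input: give a GenBank path, a genome_record, or ",
              "fasta + table", call. = FALSE)
  code <- genetic_code(code_id)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  emit <- function(name, lines) {
    path <- file.path(out_dir, name)
    writeLines(lines, path)
    files[[name]] <<- path
    path
  }
  tsv <- function(df) {
    c(paste(names(df), collapse = "\t"),
      do.call(paste, c(lapply(df, as.character), sep = "\t")))
  }
  say("record: ", record$id, " (", record$length, " bp)")

  ## 1. annotation table (adjacency included)
  emit("features.tsv", write_feature_table(record, code = code))
  adj <- adjacency_stats(record)

  ## 2. composition
  comp <- composition_table(record, code)
  emit("composition.tsv", tsv(format_composition_table(comp)))

  ## 3. codon usage + bias indices
  cds_all <- extract_all_cds(record, code = code)
  usage <- rscu(count_codons(cds_all, code), code,
                family_mode = family_mode)
  rscu_df <- data.frame(
    codon = names(usage$counts),
    amino_acid = aa_reporting_label(names(usage$counts), code),
    count = unname(usage$counts),
    rscu = sprintf("%.4f", unname(usage$rscu)),
    stringsAsFactors = FALSE)
  emit("rscu.tsv", tsv(rscu_df))
  aa_df <- data.frame(amino_acid = names(usage$aa_freq),
                      freq = sprintf("%.4f", unname(usage$aa_freq)),
                      stringsAsFactors = FALSE)
  emit("aa_freq.tsv", tsv(aa_df))
  idx <- codon_bias_indices(record, code)
  idx_fmt <- data.frame(
    gene = idx$gene, n_codons = idx$n_codons,
    enc = sprintf("%.2f", idx$enc),
    gc3 = sprintf("%.3f", idx$gc3), gc3s = sprintf("%.3f", idx$gc3s),
    gc12 = sprintf("%.3f", idx$gc12),
    pr2_x = sprintf("%.4f", idx$pr2_x),
    pr2_y = sprintf("%.4f", idx$pr2_y),
    enc_expected = sprintf("%.2f", idx$enc_expected),
    stringsAsFactors = FALSE)
  emit("codon_indices.tsv", tsv(idx_fmt))
  nf <- neutrality_fit(idx)
  emit("neutrality.tsv", tsv(data.frame(
    gene = nf$points$gene,
    gc3_percent = sprintf("%.3f", nf$points$gc3_percent),
    gc12_percent = sprintf("%.3f", nf$points$gc12_percent),
    stringsAsFactors = FALSE)))

  ## 4. repeats + regions
  reps <- find_repeats(record$sequence, min_len = min_repeat_len)
  emit("repeats.tsv", tsv(reps))
  f <- record$features
  regions <- f[f$category %in% c("control_region", "repeat_region"), ,
               drop = FALSE]
  tandem_rows <- decomp_rows <- list()
  for (i in seq_len(nrow(regions))) {
    rseq <- region_sequence(record, regions$start[i], regions$end[i])
    tn <- find_tandem(rseq, min_unit = 20L)
    if (nrow(tn)) {
      tn$region <- regions$name[i]
      tandem_rows[[length(tandem_rows) + 1L]] <- tn
    }
    if (nchar(rseq) >= 50L) {
      dec <- decompose_region(rseq)$segments
      dec$region <- regions$name[i]
      decomp_rows[[length(decomp_rows) + 1L]] <- dec
    }
  }
  tandem_all <- if (length(tandem_rows)) do.call(rbind, tandem_rows) else
    data.frame(unit_length = integer(), unit = character(),
               copies = numeric(), start = integer(), end = integer(),
               region = character(), stringsAsFactors = FALSE)
  tandem_all$copies <- sprintf("%.2f", as.numeric(tandem_all$copies))
  emit("tandem.tsv", tsv(tandem_all))
  decomp_all <- if (length(decomp_rows)) do.call(rbind, decomp_rows) else
    data.frame(label = character(), start = integer(), end = integer(),
               region = character(), stringsAsFactors = FALSE)
  emit("region_decomposition.tsv", tsv(decomp_all))

  ## 5. optional divergence stage
  panel <- NULL
  if (!is.null(alignments)) {
    if (is.character(alignments)) {
      paths <- list.files(alignments, pattern = "\\.(fa|fasta|fna)$",
                          full.names = TRUE)
      alignments <- lapply(paths, read_gene_alignment)
    }
    panel <- panel_divergence(alignments, code, window = window,
                              step = step)
    panel_fmt <- panel
    for (cn in c("mean_ka", "mean_ks", "mean_ka_ks", "mean_pi"))
      panel_fmt[[cn]] <- sprintf("%.4f", panel[[cn]])
    emit("divergence.tsv", tsv(panel_fmt))
  }

  summary <- list(
    id = record$id, topology = record$topology,
    total_length = record$length, n_features = nrow(record$features),
    n_pcg = sum(f$category == "PCG"), n_trna = sum(f$category == "tRNA"),
    n_rrna = sum(f$category == "rRNA"),
    pcg_total_bp = sum(f$size[f$category == "PCG"]),
    pcg_sense_codons = usage$total,
    at_content = comp$at_content[comp$region == "Full length"],
    at_skew = comp$at_skew[comp$region == "Full length"],
    gc_skew = comp$gc_skew[comp$region == "Full length"],
    n_overlaps = adj$n_overlaps, n_spacers = adj$n_spacers,
    max_overlap = adj$max_overlap, max_spacer = adj$max_spacer,
    max_rscu_codon = names(which.max(usage$rscu)),
    max_rscu = unname(max(usage$rscu, na.rm = TRUE)),
    enc_range = range(idx$enc),
    neutrality = list(slope = nf$slope, intercept = nf$intercept,
                      r_squared = nf$r_squared),
    n_repeat_pairs = nrow(reps),
    parameters = list(code_table = code$id, family_mode = family_mode,
                      min_repeat_len = min_repeat_len,
                      window = window, step = step))
  if (!is.null(panel)) summary$divergence_genes <- nrow(panel)
  path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files[["summary.json"]] <- path
  say("wrote ", length(files), " files to ", out_dir)
  invisible(list(summary = summary, files = files))
}
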