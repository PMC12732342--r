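# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately re-derive every quantity with the most naive
# algorithm available, never through the package's own code paths.

rand_dna <- function(n, at = 0.84) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

comp1 <- c(A = "T", C = "G", G = "C", T = "A")

# build a coding_sequence object directly from a codon vector
make_cds <- function(codons, gene = "toy", strand = "J",
                     stop_codon = "TAA") {
  stop_class <- switch(stop_codon, T = "incomplete_T", TA = "incomplete_TA",
                       "complete")
  structure(
    list(gene = gene, strand = strand,
         nucleotides = paste0(paste(codons, collapse = ""), stop_codon),
         codons = codons, start_codon = codons[1L], stop_codon = stop_codon,
         stop_class = stop_class, trimmed = stop_class != "complete"),
    class = "coding_sequence")
}

# a linear toy record holding one J-strand gene spanning the whole sequence
toy_record_one_gene <- function(seq, name = "g1", strand = "J",
                                category = "PCG") {
  genome_record(
    id = "TOY", sequence = seq,
    features = data.frame(name = name, category = category,
                          strand = strand, start = 1L, end = nchar(seq),
                          stringsAsFactors = FALSE),
    topology = "linear")
}

# ---- repeat oracle: O(n^2) match-matrix DP over (anti)diagonals ----------

oracle_repeats <- function(seq, min_len, kind) {
  x <- strsplit(seq, "")[[1L]]
  n <- length(x)
  tx <- if (kind %in% c("complement", "palindromic")) unname(comp1[x]) else x
  M <- outer(x, tx, "==")
  out <- list()
  if (kind %in% c("forward", "complement")) {
    for (d in 1:(n - 1)) {
      len <- 0L
      for (i in 1:(n - d)) {
        j <- i + d
        if (M[i, j]) len <- len + 1L else len <- 0L
        ends_run <- (i == n - d) || !M[i + 1L, j + 1L]
        if (len >= min_len && ends_run)
          out[[length(out) + 1L]] <- c(i - len + 1L, j - len + 1L, len)
      }
    }
  } else {
    for (cc in 3:(2 * n - 1)) {
      i_lo <- max(1L, cc - n); i_hi <- min(n, cc - 1L)
      len <- 0L
      for (i in i_lo:i_hi) {
        j <- cc - i
        if (M[i, j]) len <- len + 1L else len <- 0L
        ends_run <- (i == i_hi) || !M[i + 1L, j - 1L]
        if (len >= min_len && ends_run) {
          p <- i - len + 1L; q <- i
          if (p <= cc - q)
            out[[length(out) + 1L]] <- c(p, cc - q, len)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(pos_a = integer(), pos_b = integer(),
                      length = integer()))
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("pos_a", "pos_b", "length")
  df <- df[order(df$pos_a, df$pos_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# transform-level verification of one reported pair
repeat_pair_ok <- function(seq, kind, a, b, len) {
  sub_a <- substr(seq, a, a + len - 1L)
  sub_b <- substr(seq, b, b + len - 1L)
  tr <- function(s) {
    ch <- strsplit(s, "")[[1L]]
    switch(kind,
           forward = s,
           reverse = paste(rev(ch), collapse = ""),
           complement = paste(comp1[ch], collapse = ""),
           palindromic = paste(rev(comp1[ch]), collapse = ""))
  }
  sub_a == tr(sub_b)
}

# ---- nucleotide-diversity oracle: per-pair loops -------------------------

oracle_pi <- function(rows, from = 1L, to = nchar(rows[1L])) {
  mat <- do.call(rbind, strsplit(unname(rows), ""))[, from:to, drop = FALSE]
  keep <- apply(mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  mat <- mat[, keep, drop = FALSE]
  if (!ncol(mat)) return(NA_real_)
  n <- nrow(mat)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    vals <- c(vals, sum(mat[i, ] != mat[j, ]) / ncol(mat))
  mean(vals)
}

# ---- NG86 neighbour oracle (via Biostrings translation) ------------------

oracle_ng86_sites <- function(codon, table_id = 5) {
  gc <- Biostrings::getGeneticCode(as.character(table_id))
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (gc[[alt]] != "*" && gc[[alt]] == gc[[codon]]) syn <- syn + 1
    }
  }
  c(syn = syn / 3, nonsyn = 3 - syn / 3)
}

# ---- closed-form OLS -----------------------------------------------------

oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  r2 <- stats::cor(x, y)^2
  c(slope = slope, intercept = intercept, r_squared = r2)
}

# ---- stem-loop oracle: full (a, s, loop) enumeration ---------------------

oracle_stem_loop <- function(seq, min_stem, loop_range) {
  x <- strsplit(seq, "")[[1L]]
  n <- length(x)
  best <- NULL
  for (a in 1:n) for (s in min_stem:floor((n - loop_range[1L]) / 2)) {
    if (a + s - 1L > n) break
    for (loop in loop_range[1L]:loop_range[2L]) {
      b <- a + s + loop
      if (b + s - 1L > n) break
      arm_a <- x[a:(a + s - 1L)]
      arm_b <- x[b:(b + s - 1L)]
      if (all(arm_a == rev(comp1[arm_b]))) {
        cand <- c(a, s, loop)
        if (is.null(best) || s > best[2L] ||
            (s == best[2L] && (loop < best[3L] ||
                                 (loop == best[3L] && a < best[1L]))))
          best <- cand
      }
    }
  }
  best   # c(stem_start, stem_len, loop_len) or NULL
}

# ---- direct Wright ENc on a codon count vector ---------------------------

oracle_enc <- function(counts, table_id = 5) {
  gc <- Biostrings::getGeneticCode(as.character(table_id))
  sense <- names(gc)[gc != "*"]
  fams <- split(sense, gc[sense])
  F_by_k <- list()
  for (f in fams) {
    n <- sum(counts[f], na.rm = TRUE)
    if (n < 2) next
    p <- counts[f] / n
    p[is.na(p)] <- 0
    Fv <- (n * sum(p^2) - 1) / (n - 1)
    k <- as.character(length(f))
    F_by_k[[k]] <- c(F_by_k[[k]], Fv)
  }
  ks <- vapply(fams, length, 0L)
  total <- 0
  for (k in sort(unique(ks))) {
    Nk <- sum(ks == k)
    total <- total + Nk / mean(F_by_k[[as.character(k)]])
  }
  min(total, length(sense))
}
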