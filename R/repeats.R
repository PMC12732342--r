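#' Maximal exact repeat pairs in four orientations
#'
#' REPuter-style exact repeat search. A pair (`pos_a`, `pos_b`, `length`)
#' of kind `k` means the substring at `pos_a` equals the transform of the
#' substring at `pos_b`: identity (forward), reversed (reverse),
#' complemented (complement) or reverse-complemented (palindromic). Only
#' maximal pairs are reported: extending either occurrence by one base
#' breaks the match. Pairs are canonicalized with `pos_a <= pos_b`; the
#' trivial identity self-match is excluded.
#'
#' The scan walks match diagonals (forward/complement) and anti-diagonals
#' (reverse/palindromic) with vectorized run-length encoding; worst case
#' O(n^2), adequate for mitogenome-sized inputs.
#'
#' @param seq a DNA string.
#' @param min_len minimal repeat length (default 30, the conventional
#'   cutoff for mitogenome repeat reports).
#' @param kinds subset of `c("forward", "reverse", "complement",
#'   "palindromic")`.
#' @return data.frame with columns `kind`, `pos_a`, `pos_b`, `length`,
#'   sorted by kind, then position.
#' @export
find_repeats <- function(seq, min_len = 30L,
                         kinds = c("forward", "reverse", "complement",
                                   "palindromic")) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  n <- nchar(seq)
  stopifnot(n >= min_len)
  if (min_len < 8L)
    warning("min_len < 8 can be very slow on large inputs (quadratic ",
            "blow-up of spurious matches)", call. = FALSE)
  x <- strsplit(toupper(seq), "")[[1L]]
  cx <- .complement_chars(x)
  out <- list()
  add <- function(kind, a, b, len)
    out[[length(out) + 1L]] <<- data.frame(
      kind = kind, pos_a = a, pos_b = b, length = len,
      stringsAsFactors = FALSE)

  diag_scan <- function(y, kind, d_min) {
    ## matches between x[i] and y[i + d] along plain diagonals
    for (d in d_min:(n - min_len)) {
      m <- x[1:(n - d)] == y[(1 + d):n]
      if (sum(m) < min_len) next
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_len
      for (k in which(keep))
        add(kind, starts[k], starts[k] + d, r$lengths[k])
    }
  }
  antidiag_scan <- function(y, kind) {
    ## matches between x[i] and y[c - i] along anti-diagonals
    for (cc in (1L + min_len):(2L * n - min_len + 1L)) {
      i_lo <- max(1L, cc - n); i_hi <- min(n, cc - 1L)
      idx <- i_lo:i_hi
      m <- x[idx] == y[cc - idx]
      if (sum(m) < min_len) next
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= min_len)) {
        p <- idx[starts[k]]; q <- idx[ends[k]]
        if (p > cc - q) next        # mirror of an already-reported run
        add(kind, p, cc - q, q - p + 1L)
      }
    }
  }
  if ("forward" %in% kinds) diag_scan(x, "forward", 1L)
  if ("complement" %in% kinds) diag_scan(cx, "complement", 1L)
  if ("reverse" %in% kinds) antidiag_scan(x, "reverse")
  if ("palindromic" %in% kinds) antidiag_scan(cx, "palindromic")
  if (!length(out))
    return(data.frame(kind = character(), pos_a = integer(),
                      pos_b = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$kind, res$pos_a, res$pos_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tandem repeat arrays
#'
#' For each candidate unit length `u`, exact period-`u` match runs
#' (`seq[i] == seq[i + u]`) seed candidate arrays, which are then extended
#' unit by unit as long as adjacent units differ by at most
#' `floor(max_mismatch_frac * u)` Hamming mismatches, and finally
#' validated against the array consensus with the same per-unit budget.
#' Reports non-redundant arrays: per unit length the longest span at each
#' locus, and arrays whose unit is an exact multiple of a kept array's unit
#' over the same span are dropped.
#'
#' @param seq a DNA string.
#' @param min_unit,max_unit unit length range (bp).
#' @param min_copies minimal copy number (fractional final copies count).
#' @param max_mismatch_frac per-unit Hamming tolerance vs the consensus.
#' @return data.frame with columns `unit_length`, `unit` (consensus),
#'   `copies`, `start`, `end`.
#' @export
find_tandem <- function(seq, min_unit = 2L, max_unit = NULL,
                        min_copies = 2, max_mismatch_frac = 0.1) {
  n <- nchar(seq)
  if (is.null(max_unit)) max_unit <- floor(n / min_copies)
  max_unit <- min(max_unit, floor(n / min_copies))
  stopifnot(min_unit >= 1L, max_unit >= min_unit)
  x <- strsplit(toupper(seq), "")[[1L]]
  arrays <- list()
  ham <- function(a, b) sum(x[a:(a + attr_u - 1L)] != x[b:(b + attr_u - 1L)])
  for (u in min_unit:max_unit) {
    attr_u <- u
    budget <- floor(max_mismatch_frac * u)
    ## pigeonhole: a unit pair within budget contains an exact run this long
    seed_min <- max(4L, as.integer(ceiling((u - budget) / (budget + 1L))))
    m <- x[1:(n - u)] == x[(1 + u):n]
    if (sum(m) < seed_min) next
    seen <- character()
    for (s in .true_segments(m)) {
      if (s[2L] - s[1L] + 1L < seed_min) next
      ## anchor the unit phase at the seed and chain whole units
      a0 <- s[1L]
      while (a0 - u >= 1L && ham(a0 - u, a0) <= budget) a0 <- a0 - u
      b0 <- a0
      while (b0 + 2L * u - 1L <= n && ham(b0 + u, b0) <= budget)
        b0 <- b0 + u
      span_start <- a0; span_end <- b0 + u - 1L
      ## fractional head copy
      while (span_start > 1L && x[span_start - 1L] == x[span_start - 1L + u])
        span_start <- span_start - 1L
      if ((span_end - a0 + 1L) / u < min_copies) next
      key <- paste(a0, span_end)
      if (key %in% seen) next
      seen <- c(seen, key)
      val <- .validate_tandem(x, a0, span_end, u, max_mismatch_frac)
      if (is.null(val)) next
      ## a homopolymer is periodic at every unit length, not a tandem array
      if (length(unique(strsplit(val$unit, "")[[1L]])) == 1L) next
      head_len <- if (val$start == a0) a0 - span_start else 0L
      arr_start <- val$start - head_len
      if ((val$end - arr_start + 1L) / u < min_copies) next
      arrays[[length(arrays) + 1L]] <- data.frame(
        unit_length = u, unit = val$unit,
        copies = (val$end - arr_start + 1L) / u,
        start = arr_start, end = val$end, stringsAsFactors = FALSE)
    }
  }
  if (!length(arrays))
    return(data.frame(unit_length = integer(), unit = character(),
                      copies = numeric(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, arrays)
  ## non-redundancy: prefer longer spans, then shorter units; drop an
  ## array whose unit is a multiple of a kept array's unit on ~the same span
  res <- res[order(-(res$end - res$start), res$unit_length), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      ov <- min(res$end[i], res$end[j]) - max(res$start[i], res$start[j]) + 1L
      if (ov >= 0.9 * (res$end[i] - res$start[i] + 1L) &&
          res$unit_length[i] %% res$unit_length[j] == 0L) {
        keep[i] <- FALSE
        break
      }
    }
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## maximal TRUE segments of a logical vector, bridging FALSE gaps <= bridge
.true_segments <- function(m, bridge = 0L) {
  if (!any(m)) return(list())
  r <- rle(m)
  if (bridge > 0L && length(r$lengths) > 2L) {
    interior <- seq(2L, length(r$lengths) - 1L)
    flip <- interior[!r$values[interior] & r$lengths[interior] <= bridge]
    if (length(flip)) {
      r$values[flip] <- TRUE
      r <- rle(inverse.rle(r))
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(k) c(starts[k], ends[k]))
}

## consensus validation of a candidate array; trims failing edge units
.validate_tandem <- function(x, start, end, u, tol) {
  n_full <- (end - start + 1L) %/% u
  if (n_full < 1L) return(NULL)
  units <- vapply(seq_len(n_full), function(k)
    paste(x[(start + (k - 1L) * u):(start + k * u - 1L)], collapse = ""),
    "")
  mat <- do.call(rbind, strsplit(units, ""))
  consensus <- apply(mat, 2L, function(col)
    names(sort(table(col), decreasing = TRUE))[1L])
  budget <- floor(tol * u)
  dist <- apply(mat, 1L, function(row) sum(row != consensus))
  ok <- dist <= budget
  if (!any(ok)) return(NULL)
  first <- which(ok)[1L]; last <- rev(which(ok))[1L]
  if (any(!ok[first:last])) {   # interior break: keep the first clean block
    bad <- which(!ok[first:last])[1L] + first - 1L
    last <- bad - 1L
  }
  new_start <- start + (first - 1L) * u
  new_end <- start + last * u - 1L
  ## extend by the matched fractional tail copy
  tail_len <- 0L
  while (new_end + tail_len + 1L <= length(x) &&
         tail_len < u &&
         x[new_end + tail_len + 1L] ==
           consensus[(tail_len %% u) + 1L])
    tail_len <- tail_len + 1L
  list(unit = paste(consensus, collapse = ""), start = new_start,
       end = new_end + tail_len)
}

#' Best stem-loop (exact inverted repeat with an internal loop)
#'
#' Finds the longest exact inverted repeat whose two arms flank a loop
#' within `loop_range`; ties resolve to the smallest loop, then the
#' leftmost position. The detector is structural (exact base pairing), not
#' thermodynamic.
#'
#' @param seq a DNA string.
#' @param min_stem minimal arm length (bp).
#' @param loop_range allowed loop lengths, `c(min, max)`.
#' @return `NULL` if none, else a list with `stem_start` (5' arm start),
#'   `stem_len`, `loop_len` and `arm_b_start` (3' arm start).
#' @export
best_stem_loop <- function(seq, min_stem = 8L, loop_range = c(3L, 50L)) {
  n <- nchar(seq)
  lo <- loop_range[1L]; hi <- loop_range[2L]
  if (n < 2L * min_stem + lo) return(NULL)
  x <- strsplit(toupper(seq), "")[[1L]]
  cx <- .complement_chars(x)
  best <- NULL
  for (cc in 3L:(2L * n - 1L)) {
    i_lo <- max(1L, cc - n); i_hi <- min(n, cc - 1L)
    idx <- i_lo:i_hi
    m <- x[idx] == cx[cc - idx]
    if (sum(m) < min_stem) next
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_stem)) {
      p <- idx[starts[k]]; q <- idx[ends[k]]
      if (p > cc - q) next
      s_top <- min(q - p + 1L, (cc - 2L * p + 1L - lo) %/% 2L)
      if (s_top < min_stem) next
      for (s in seq(s_top, min_stem, by = -1L)) {
        a_min <- max(p, as.integer(ceiling((cc - 2 * s + 1 - hi) / 2)))
        a_max <- min(q - s + 1L, (cc - 2L * s + 1L - lo) %/% 2L)
        if (a_min > a_max) next
        a <- a_max                       # smallest loop at this arm length
        loop <- cc - 2L * a - 2L * s + 1L
        cand <- list(stem_start = a, stem_len = s, loop_len = loop,
                     arm_b_start = a + s + loop)
        if (is.null(best) ||
            cand$stem_len > best$stem_len ||
            (cand$stem_len == best$stem_len &&
               (cand$loop_len < best$loop_len ||
                  (cand$loop_len == best$loop_len &&
                     cand$stem_start < best$stem_start))))
          best <- cand
        break                            # only the max arm per run matters
      }
    }
  }
  best
}

#' Decompose a control region into its structural segments
#'
#' Orders the detected structural elements of a mitochondrial control
#' region: tandem arrays, the longest poly-T stretch, the best stem-loop
#' and the longest AT-rich window, each detected outside already-claimed
#' segments (priority: tandem, poly-T, stem-loop, AT-rich). The uncovered
#' prefix before the first element is labelled `lead`; remaining gaps are
#' `spacer`.
#'
#' @param seq the control-region DNA string (length >= 50).
#' @param tandem_min_unit,tandem_max_unit unit range for [find_tandem()].
#' @param min_copies minimal tandem copies.
#' @param poly_min minimal poly-T length (default 8).
#' @param at_rich_threshold minimal AT fraction of the AT-rich window
#'   (default 0.95).
#' @param at_rich_min_len minimal AT-rich window length (default 100).
#' @param min_stem,loop_range stem-loop parameters, see [best_stem_loop()].
#' @return An object of class `region_decomposition`: data.frame `segments`
#'   with columns `label`, `start`, `end` (ordered, non-overlapping).
#' @export
decompose_region <- function(seq, tandem_min_unit = 20L,
                             tandem_max_unit = NULL, min_copies = 2,
                             poly_min = 8L, at_rich_threshold = 0.95,
                             at_rich_min_len = 100L, min_stem = 8L,
                             loop_range = c(3L, 50L)) {
  n <- nchar(seq)
  stopifnot(n >= 50L)
  x <- strsplit(toupper(seq), "")[[1L]]
  segs <- data.frame(label = character(), start = integer(),
                     end = integer(), stringsAsFactors = FALSE)
  claim <- function(segs, label, start, end) {
    rbind(segs, data.frame(label = label, start = as.integer(start),
                           end = as.integer(end), stringsAsFactors = FALSE))
  }
  gaps <- function(segs) {
    if (!nrow(segs)) return(list(c(1L, n)))
    s <- segs[order(segs$start), , drop = FALSE]
    out <- list()
    cur <- 1L
    for (i in seq_len(nrow(s))) {
      if (s$start[i] > cur) out[[length(out) + 1L]] <- c(cur, s$start[i] - 1L)
      cur <- max(cur, s$end[i] + 1L)
    }
    if (cur <= n) out[[length(out) + 1L]] <- c(cur, n)
    out
  }
  ## 1. tandem arrays (greedy non-overlapping, longest first)
  tn <- find_tandem(seq, min_unit = tandem_min_unit,
                    max_unit = tandem_max_unit, min_copies = min_copies)
  if (nrow(tn)) {
    tn <- tn[order(-(tn$end - tn$start)), , drop = FALSE]
    for (i in seq_len(nrow(tn))) {
      if (!nrow(segs) ||
          all(tn$end[i] < segs$start | tn$start[i] > segs$end))
        segs <- claim(segs, "tandem_array", tn$start[i], tn$end[i])
    }
  }
  ## 2. longest poly-T outside claimed segments
  best_t <- NULL
  for (g in gaps(segs)) {
    sub <- x[g[1L]:g[2L]]
    r <- rle(sub == "T")
    if (!any(r$values & r$lengths >= poly_min)) next
    k <- which(r$values)[which.max(r$lengths[r$values])]
    if (r$lengths[k] < poly_min) next
    st <- g[1L] + sum(r$lengths[seq_len(k - 1L)])
    cand <- c(st, st + r$lengths[k] - 1L)
    if (is.null(best_t) || diff(cand) > diff(best_t)) best_t <- cand
  }
  if (!is.null(best_t))
    segs <- claim(segs, "poly_T", best_t[1L], best_t[2L])
  ## 3. best stem-loop in a remaining gap
  best_sl <- NULL; best_off <- NA_integer_
  for (g in gaps(segs)) {
    sl <- best_stem_loop(paste(x[g[1L]:g[2L]], collapse = ""),
                         min_stem = min_stem, loop_range = loop_range)
    if (!is.null(sl) &&
        (is.null(best_sl) || sl$stem_len > best_sl$stem_len)) {
      best_sl <- sl; best_off <- g[1L] - 1L
    }
  }
  if (!is.null(best_sl))
    segs <- claim(segs, "stem_loop", best_off + best_sl$stem_start,
                  best_off + best_sl$arm_b_start + best_sl$stem_len - 1L)
  ## 4. longest AT-rich window in a remaining gap
  best_at <- NULL
  for (g in gaps(segs)) {
    w <- .longest_at_window(x[g[1L]:g[2L]], at_rich_threshold,
                            at_rich_min_len)
    if (!is.null(w)) {
      cand <- c(g[1L] + w[1L] - 1L, g[1L] + w[2L] - 1L)
      if (is.null(best_at) || diff(cand) > diff(best_at)) best_at <- cand
    }
  }
  if (!is.null(best_at))
    segs <- claim(segs, "at_rich", best_at[1L], best_at[2L])
  ## 5. lead + spacers
  segs <- segs[order(segs$start), , drop = FALSE]
  filled <- segs
  for (g in gaps(segs)) {
    label <- if (nrow(segs) && g[2L] < segs$start[1L]) "lead" else "spacer"
    filled <- claim(filled, label, g[1L], g[2L])
  }
  filled <- filled[order(filled$start), , drop = FALSE]
  rownames(filled) <- NULL
  structure(list(segments = filled, region_length = n),
            class = "region_decomposition")
}

#' @export
print.region_decomposition <- function(x, ...) {
  cat("Region decomposition (", x$region_length, " bp):\n", sep = "")
  s <- x$segments
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-13s %5d-%5d (%d bp)\n", s$label[i], s$start[i],
                s$end[i], s$end[i] - s$start[i] + 1L))
  invisible(x)
}

## longest window with AT fraction >= theta and length >= min_len,
## via the nonnegative-transformed prefix-sum trick
.longest_at_window <- function(x, theta, min_len) {
  if (length(x) < min_len) return(NULL)
  w <- ifelse(x %in% c("A", "T"), 1 - theta, -theta)
  P <- c(0, cumsum(w))
  cmin <- cummin(P)
  best <- NULL
  for (j in seq_along(P)) {
    ## earliest i with P[i] <= P[j]  (cmin is non-increasing)
    i <- .bs_first_leq(cmin, P[j])
    if (!is.na(i) && j - i >= min_len &&
        (is.null(best) || j - i > best[2L] - best[1L] + 1L))
      best <- c(i, j - 1L)   # sequence window [i, j-1]
  }
  best
}

.bs_first_leq <- function(cmin, val) {
  lo <- 1L; hi <- length(cmin)
  if (cmin[1L] <= val) return(1L)
  if (cmin[hi] > val) return(NA_integer_)
  while (lo + 1L < hi) {
    mid <- (lo + hi) %/% 2L
    if (cmin[mid] <= val) hi <- mid else lo <- mid
  }
  hi
}
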