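# Tandem sub-repeat detection inside an rDNA unit (the dotplot analysis):
# exact k-mer self-matching, period inference from match offsets,
# classification into sub-repeats / microsatellites (<10 bp) / degenerate
# arrays, and attribution of unit-length variance to sub-repeat copy number.

#' Off-diagonal exact k-mer self-matches of a sequence
#'
#' All pairs of positions (i, j), i < j, carrying identical k-mers; the raw
#' material of a self-dotplot and of period inference.
#'
#' @param sequence Nucleotide string (length >= k).
#' @param k K-mer size (default 12).
#' @param max_offset Keep only pairs with `j - i <= max_offset`
#'   (default `Inf`); bounding the offset keeps the map small on long
#'   microsatellites.
#' @return Data.frame with 0-based columns `i`, `j` (k-mer start positions).
#' @export
self_match_map <- function(sequence, k = 12L, max_offset = Inf) {
  n <- nchar(sequence)
  empty <- data.frame(i = integer(), j = integer())
  if (n < k) return(empty)
  km <- kmer_starts(toupper(sequence), k)
  grp <- split(seq_along(km), km)
  grp <- grp[lengths(grp) > 1L]
  if (length(grp) == 0L) return(empty)
  pairs <- lapply(grp, function(pos) {
    cmb <- t(utils::combn(pos, 2L))
    keep <- cmb[, 2L] - cmb[, 1L] <= max_offset
    cmb[keep, , drop = FALSE]
  })
  mat <- do.call(rbind, pairs)
  if (is.null(mat) || nrow(mat) == 0L) return(empty)
  df <- data.frame(i = mat[, 1L] - 1L, j = mat[, 2L] - 1L)
  df <- df[order(df$i, df$j), ]
  rownames(df) <- NULL
  df
}

seq_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  d <- utils::adist(a, b)[1, 1]
  1 - d / max(nchar(a), nchar(b))
}

# smallest period whose multiples explain >= explain_frac of the offsets
infer_period <- function(offsets, min_period = 1L, explain_frac = 0.8) {
  cand <- sort(unique(offsets))
  cand <- cand[cand >= min_period]
  for (p in cand) {
    tol <- min(max(1, round(0.03 * p)), max(0L, (p - 1L) %/% 2L))
    r <- offsets %% p
    ok <- pmin(r, p - r) <= tol
    if (mean(ok) >= explain_frac) {
      near <- offsets[abs(offsets - round(offsets / p) * p) <= tol &
                        round(offsets / p) == 1]
      return(if (length(near)) round(median(near)) else p)
    }
  }
  round(median(cand))
}

#' Detect tandem sub-repeat arrays in a sequence
#'
#' Self-matches with offset at most `max_period` are clustered along the
#' sequence; within each cluster the period is the smallest offset whose
#' multiples explain at least 80% of the observed offsets (preventing a
#' p-periodic array from being reported as 2p). The array span is grown
#' outward by whole periods while the adjacent-copy identity stays at or
#' above `min_adjacent_identity`. Arrays with period < 10 bp are classified
#' as microsatellites; arrays whose mean adjacent-copy identity falls below
#' `degenerate_threshold` as degenerate; the rest as sub-repeats.
#' Overlapping candidates are resolved by keeping the larger span, then the
#' larger period.
#'
#' @param sequence Nucleotide string.
#' @param k Self-match k-mer size (default 12).
#' @param min_period,max_period Period search range in bp.
#' @param min_copies Minimum copy number for a reported array (default 2).
#' @param min_adjacent_identity Span-growth threshold (default 0.6).
#' @param degenerate_threshold Mean adjacent-copy identity below which an
#'   array is classified degenerate (default 0.7).
#' @param cluster_gap Positions further apart than this start a new candidate
#'   region (default 500 bp).
#' @param annotation Optional `rdna_unit_annotation`; when given, each array
#'   gets a `location_label` (`IGS`, `ITS1`, `ITS2` or `other`) by midpoint.
#' @return Data.frame of arrays: `start0`, `end0`, `period`, `copy_number`,
#'   `mean_adjacent_identity`, `klass`, `location_label`.
#' @export
detect_tandem_arrays <- function(sequence, k = 12L, min_period = 1L,
                                 max_period = 1000L, min_copies = 2,
                                 min_adjacent_identity = 0.6,
                                 degenerate_threshold = 0.7,
                                 cluster_gap = 500L, annotation = NULL) {
  empty <- data.frame(start0 = integer(), end0 = integer(),
                      period = integer(), copy_number = numeric(),
                      mean_adjacent_identity = numeric(), klass = character(),
                      location_label = character(), stringsAsFactors = FALSE)
  n <- nchar(sequence)
  if (n < k) return(empty)
  mm <- self_match_map(sequence, k = k, max_offset = max_period)
  if (nrow(mm) == 0L) return(empty)
  # cluster by position along the sequence (using match left ends)
  ord <- order(mm$i)
  mm <- mm[ord, ]
  brk <- cumsum(c(TRUE, diff(mm$i) > cluster_gap))
  rows <- list()
  for (g in unique(brk)) {
    cl <- mm[brk == g, , drop = FALSE]
    if (nrow(cl) < 3L) next
    offsets <- cl$j - cl$i
    p <- infer_period(offsets, min_period)
    if (p < min_period || p > max_period) next
    s0 <- min(cl$i); e0 <- max(cl$j) + k
    # snap the span to whole periods, then grow by adjacent-copy identity
    span <- grow_array_span(sequence, s0, e0, p, min_adjacent_identity)
    s0 <- span[[1]]; e0 <- span[[2]]
    cn <- (e0 - s0) / p
    if (cn < min_copies) next
    mai <- mean_adjacent_identity(sequence, s0, e0, p)
    klass <- if (p < 10) "microsatellite"
             else if (mai < degenerate_threshold) "degenerate"
             else "subrepeat"
    rows[[length(rows) + 1L]] <- data.frame(
      start0 = s0, end0 = e0, period = as.integer(p), copy_number = cn,
      mean_adjacent_identity = mai, klass = klass,
      location_label = NA_character_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  df <- do.call(rbind, rows)
  # resolve overlaps: larger span first, then larger period
  df <- df[order(-(df$end0 - df$start0), -df$period), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[[i]]) next
    for (j in seq_len(nrow(df))) {
      if (j == i || !keep[[j]]) next
      if (df$start0[[j]] < df$end0[[i]] && df$start0[[i]] < df$end0[[j]] &&
          (df$end0[[j]] - df$start0[[j]]) <= (df$end0[[i]] - df$start0[[i]]))
        keep[[j]] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start0), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(annotation)) {
    mid <- (df$start0 + df$end0) / 2
    iv <- annotation$intervals
    lab <- vapply(mid, function(m) {
      w <- which(iv$start0 <= m & m < iv$end0)
      if (length(w) && iv$feature[[w[[1]]]] %in% c("IGS", "ITS1", "ITS2"))
        iv$feature[[w[[1]]]] else "other"
    }, character(1))
    df$location_label <- lab
  }
  df
}

copy_at <- function(sequence, s0, p, idx)
  substring(sequence, s0 + idx * p + 1L, s0 + (idx + 1L) * p)

mean_adjacent_identity <- function(sequence, s0, e0, p) {
  ncop <- floor((e0 - s0) / p)
  if (ncop < 2L) return(0)
  ids <- vapply(seq_len(ncop - 1L) - 1L, function(i)
    seq_identity(copy_at(sequence, s0, p, i), copy_at(sequence, s0, p, i + 1L)),
    numeric(1))
  mean(ids)
}

grow_array_span <- function(sequence, s0, e0, p, min_id) {
  n <- nchar(sequence)
  # extend left while the copy before the span matches the first copy
  repeat {
    if (s0 - p < 0L) break
    left <- substring(sequence, s0 - p + 1L, s0)
    first <- substring(sequence, s0 + 1L, s0 + p)
    if (seq_identity(left, first) >= min_id) s0 <- s0 - p else break
  }
  repeat {
    if (e0 + p > n) break
    right <- substring(sequence, e0 + 1L, e0 + p)
    last <- substring(sequence, e0 - p + 1L, e0)
    if (seq_identity(right, last) >= min_id) e0 <- e0 + p else break
  }
  c(s0, e0)
}

#' Total sub-repeat content of a unit
#'
#' Sums the spans of sub-repeat-class arrays (microsatellites and degenerate
#' arrays are excluded) overall and within the IGS interval; partial overlap
#' with the IGS is counted by intersection.
#'
#' @param unit_annotation An `rdna_unit_annotation`.
#' @param arrays Array data.frame from [detect_tandem_arrays()].
#' @return List with `total_subrepeat_bp`, `igs_subrepeat_bp`,
#'   `proportion_of_igs`.
#' @export
subrepeat_totals <- function(unit_annotation, arrays) {
  sub <- arrays[arrays$klass == "subrepeat", , drop = FALSE]
  igs <- unit_annotation$intervals[
    unit_annotation$intervals$feature == "IGS", , drop = FALSE]
  igs_len <- igs$end0 - igs$start0
  if (nrow(sub) == 0L)
    return(list(total_subrepeat_bp = 0L, igs_subrepeat_bp = 0L,
                proportion_of_igs = 0))
  total <- sum(sub$end0 - sub$start0)
  inter <- pmax(0L, pmin(sub$end0, igs$end0) - pmax(sub$start0, igs$start0))
  list(total_subrepeat_bp = as.integer(total),
       igs_subrepeat_bp = as.integer(sum(inter)),
       proportion_of_igs = if (igs_len > 0) sum(inter) / igs_len else 0)
}

#' Fraction of unit-length variance explained by sub-repeat copy number
#'
#' With S_i the total sub-repeat length of unit i and L_i its total length,
#' the explained fraction is `1 - Var(L - S) / Var(L)` (sample variances,
#' clamped to `[0, 1]`). Because S is a physical component of L, this equals
#' regression R-squared when residuals are uncorrelated with S.
#'
#' @param unit_lengths Numeric vector of per-unit total lengths (>= 3).
#' @param subrepeat_totals Numeric vector of matched per-unit sub-repeat
#'   totals.
#' @return Object of class `rdna_variance_attribution`: list with `n_units`,
#'   `var_total`, `var_residual`, `fraction_explained` (NA when
#'   `Var(L) = 0`).
#' @export
variance_explained_by_subrepeats <- function(unit_lengths, subrepeat_totals) {
  if (length(unit_lengths) != length(subrepeat_totals))
    stop("unit_lengths and subrepeat_totals must be matched")
  if (length(unit_lengths) < 3L) stop("need at least 3 units")
  vL <- var(unit_lengths)
  vR <- var(unit_lengths - subrepeat_totals)
  frac <- if (vL == 0) NA_real_ else max(0, min(1, 1 - vR / vL))
  structure(list(n_units = length(unit_lengths), var_total = vL,
                 var_residual = vR, fraction_explained = frac),
            class = "rdna_variance_attribution")
}

#' @export
print.rdna_variance_attribution <- function(x, ...) {
  cat("Unit-length variance attribution to sub-repeat copy number\n")
  cat(sprintf("  units              : %d\n", x$n_units))
  cat(sprintf("  Var(length)        : %.1f bp^2\n", x$var_total))
  cat(sprintf("  Var(residual)      : %.1f bp^2\n", x$var_residual))
  if (is.na(x$fraction_explained))
    cat("  fraction explained : not applicable (no length variation)\n")
  else
    cat(sprintf("  fraction explained : %.3f\n", x$fraction_explained))
  invisible(x)
}
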