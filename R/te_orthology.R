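# Transposable-element orthology between two intergenic spacers:
# RepeatMasker records are filtered (>= 50 bp), fragmented elements are
# reconstructed (with interveners as nested children), and the two ordered
# element lists are matched by the maximum-cardinality order-preserving
# common subsequence under equal family and orientation.

#' Filter RepeatMasker records and reconstruct fragmented/nested elements
#'
#' Records shorter than `min_length` are dropped. Fragments with the same
#' repeat name and orientation whose consensus coordinates are co-linear
#' (next fragment's `repeat_begin >= previous repeat_end - join_tolerance`)
#' and whose gap on the query is occupied by other annotated elements (or is
#' at most `join_tolerance` bp) are merged into one logical element; records
#' lying inside the merged span become its nested children.
#'
#' @param rm_records Data.frame from [parse_repeatmasker_out()] (one IGS).
#' @param min_length Minimum element length in bp (default 50).
#' @param join_tolerance Consensus-coordinate slack and maximum uncovered
#'   query gap when joining fragments, bp (default 50).
#' @return Data.frame of logical elements sorted by position: `family`
#'   (class/family string), `name`, `orientation`, `start0`, `end0`,
#'   `length` (interval length), `aligned_bp` (summed fragment lengths),
#'   `n_fragments`, `fragment_ids`, `nested_in` (row index of the enclosing
#'   element or NA).
#' @export
filter_and_reconstruct <- function(rm_records, min_length = 50L,
                                   join_tolerance = 50L) {
  empty <- data.frame(family = character(), name = character(),
                      orientation = character(), start0 = integer(),
                      end0 = integer(), length = integer(),
                      aligned_bp = integer(), n_fragments = integer(),
                      fragment_ids = character(), nested_in = integer(),
                      stringsAsFactors = FALSE)
  r <- rm_records
  if (nrow(r) == 0L) return(empty)
  r$len <- r$query_end - r$query_begin + 1L
  r <- r[r$len >= min_length, , drop = FALSE]
  if (nrow(r) == 0L) return(empty)
  r <- r[order(r$query_begin), , drop = FALSE]
  r$start0 <- r$query_begin - 1L
  r$end0 <- r$query_end
  n <- nrow(r)
  comp <- seq_len(n)  # union-find-ish: merge target per fragment
  gap_covered <- function(lo, hi, exclude) {
    if (hi <= lo) return(TRUE)
    others <- r[-exclude, , drop = FALSE]
    if (nrow(others) == 0L) return(FALSE)
    cov <- IRanges::intersect(
      IRanges::IRanges(start = lo + 1L, end = hi),
      IRanges::reduce(IRanges::IRanges(start = others$start0 + 1L,
                                       end = others$end0)))
    (hi - lo) - sum(IRanges::width(cov)) <= join_tolerance
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (comp[[j]] != j) next
      same <- r$repeat_name[[j]] == r$repeat_name[[i]] &&
        r$orientation[[j]] == r$orientation[[i]]
      if (!same) next
      ci <- comp[[i]]
      # consensus co-linearity (orientation-aware)
      colinear <- if (r$orientation[[i]] == "plus")
        r$repeat_begin[[j]] >= r$repeat_end[[i]] - join_tolerance
      else r$repeat_end[[j]] <= r$repeat_begin[[i]] + join_tolerance
      if (!colinear) next
      if (gap_covered(r$end0[[i]], r$start0[[j]], c(i, j))) comp[[j]] <- ci
    }
  }
  groups <- split(seq_len(n), comp)
  rows <- lapply(groups, function(idx) {
    g <- r[idx, , drop = FALSE]
    data.frame(family = g$repeat_class_family[[1]],
               name = g$repeat_name[[1]],
               orientation = g$orientation[[1]],
               start0 = min(g$start0), end0 = max(g$end0),
               length = max(g$end0) - min(g$start0),
               aligned_bp = sum(g$len),
               n_fragments = nrow(g),
               fragment_ids = paste(
                 ifelse(is.na(g$element_id), idx, g$element_id),
                 collapse = ","),
               nested_in = NA_integer_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start0, out$end0), , drop = FALSE]
  rownames(out) <- NULL
  # nesting: an element strictly inside another (fragmented) element's span
  for (i in seq_len(nrow(out))) {
    enclosing <- which(out$start0 < out$start0[[i]] &
                         out$end0 > out$end0[[i]] & out$n_fragments > 1L)
    if (length(enclosing)) out$nested_in[[i]] <- enclosing[[1]]
  }
  out
}

# lexicographic DP on (count, matched length); token match requires equal
# family and orientation.
match_dp <- function(tok_a, tok_b, len_a, len_b) {
  na <- length(tok_a); nb <- length(tok_b)
  cnt <- matrix(0L, na + 1L, nb + 1L)
  len <- matrix(0, na + 1L, nb + 1L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      c1 <- cnt[i, j + 1L]; l1 <- len[i, j + 1L]
      c2 <- cnt[i + 1L, j]; l2 <- len[i + 1L, j]
      best_c <- c1; best_l <- l1
      if (c2 > best_c || (c2 == best_c && l2 > best_l)) {
        best_c <- c2; best_l <- l2
      }
      if (tok_a[[i]] == tok_b[[j]]) {
        c3 <- cnt[i, j] + 1L
        l3 <- len[i, j] + min(len_a[[i]], len_b[[j]])
        if (c3 > best_c || (c3 == best_c && l3 > best_l)) {
          best_c <- c3; best_l <- l3
        }
      }
      cnt[i + 1L, j + 1L] <- best_c
      len[i + 1L, j + 1L] <- best_l
    }
  }
  # backtrack
  pairs <- list()
  i <- na; j <- nb
  while (i > 0L && j > 0L) {
    if (tok_a[[i]] == tok_b[[j]] &&
        cnt[i + 1L, j + 1L] == cnt[i, j] + 1L &&
        len[i + 1L, j + 1L] == len[i, j] + min(len_a[[i]], len_b[[j]])) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
      i <- i - 1L; j <- j - 1L
    } else if (cnt[i, j + 1L] > cnt[i + 1L, j] ||
               (cnt[i, j + 1L] == cnt[i + 1L, j] &&
                  len[i, j + 1L] >= len[i + 1L, j])) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(count = cnt[na + 1L, nb + 1L],
       pairs = if (length(pairs)) do.call(rbind, rev(pairs))
               else matrix(integer(), 0L, 2L))
}

#' Match putatively orthologous TEs between two IGSs
#'
#' Maximum-cardinality order-preserving matching (a longest common
#' subsequence over element tokens) where two elements can pair only when
#' their family and orientation agree. Among maximum-cardinality solutions
#' the one maximizing the summed `min(length_A, length_B)` over pairs is
#' chosen.
#'
#' @param tes_A,tes_B Element data.frames from [filter_and_reconstruct()]
#'   (sorted by position).
#' @param by `"family"` (default; RepeatMasker class/family string) or
#'   `"name"` for strict repeat-name equality.
#' @return List of class `rdna_te_matching`: `pairs` (data.frame
#'   `index_A`, `index_B`), `count`, `matched_length_A`, `matched_length_B`.
#' @export
match_orthologous_tes <- function(tes_A, tes_B, by = c("family", "name")) {
  by <- match.arg(by)
  tok <- function(t) if (nrow(t) == 0L) character(0) else
    paste(t[[by]], t$orientation, sep = "\r")
  res <- match_dp(tok(tes_A), tok(tes_B),
                  tes_A$length %||% integer(0), tes_B$length %||% integer(0))
  pairs <- data.frame(index_A = res$pairs[, 1L], index_B = res$pairs[, 2L])
  structure(list(
    pairs = pairs, count = res$count,
    matched_length_A = if (nrow(pairs)) sum(tes_A$length[pairs$index_A])
                       else 0L,
    matched_length_B = if (nrow(pairs)) sum(tes_B$length[pairs$index_B])
                       else 0L),
    class = "rdna_te_matching")
}

#' @export
print.rdna_te_matching <- function(x, ...) {
  cat("TE orthology matching:", x$count, "pairs;",
      x$matched_length_A, "bp (A) /", x$matched_length_B, "bp (B)\n")
  invisible(x)
}

#' Summarize a TE orthology matching
#'
#' @param matching `rdna_te_matching` from [match_orthologous_tes()].
#' @param tes_A,tes_B The matched element tables.
#' @param igs_lengths Numeric vector of length 2: IGS lengths of A and B.
#' @param path Optional TSV output path.
#' @return One-row data.frame of totals: IGS lengths, TE bp and counts per
#'   side, orthologous TE bp and count.
#' @export
orthology_report <- function(matching, tes_A, tes_B, igs_lengths,
                             path = NULL) {
  df <- data.frame(
    igs_length_A = igs_lengths[[1]], igs_length_B = igs_lengths[[2]],
    n_tes_A = nrow(tes_A), n_tes_B = nrow(tes_B),
    te_bp_A = sum(tes_A$length), te_bp_B = sum(tes_B$length),
    n_orthologous = matching$count,
    orthologous_bp_A = matching$matched_length_A,
    orthologous_bp_B = matching$matched_length_B)
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
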