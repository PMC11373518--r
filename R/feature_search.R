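# Locating rDNA features (18S/5.8S/28S or a whole reference unit) on long
# reads: DUST low-complexity masking, exact k-mer seeding with diagonal
# clustering, banded extension by pairwise alignment, and HSP chaining.
# An adapter converts external BLAST tabular hits to the same FeatureHit
# table so downstream sizing is source-agnostic.

FEATURE_LEVELS <- c("F18S", "F5_8S", "F28S", "FULL_UNIT")

empty_hits <- function() {
  data.frame(read_id = character(), feature = character(),
             start = integer(), end = integer(), strand = character(),
             identity = numeric(), feature_coverage = numeric(),
             feature_start = integer(), feature_end = integer(),
             feature_length = integer(), source = character(),
             chain_members = integer(), stringsAsFactors = FALSE)
}

#' DUST low-complexity masking
#'
#' Classic DUST: over every sliding window the triplet score
#' \eqn{S = \sum_t c_t (c_t - 1) / 2} is computed from the counts \eqn{c_t}
#' of overlapping 3-mers and normalized by \eqn{l - 1} (with \eqn{l} the
#' number of triplets in the window), matching the scaling of the cited
#' masker whose level-20 default corresponds to a normalized score of 2.
#' Windows with \eqn{10 S / (l-1) > threshold} are masked and overlapping
#' masked windows are merged into intervals. Masked intervals are excluded
#' from seeding by [find_feature_hits()].
#'
#' @param sequence Nucleotide string.
#' @param window Window size in bp (default 64, the classic value).
#' @param threshold Score threshold (default 20).
#' @return Data.frame with columns `start0`, `end0` (0-based half-open);
#'   zero rows when nothing is masked.
#' @export
dust_mask <- function(sequence, window = 64L, threshold = 20L) {
  n <- nchar(sequence)
  empty <- data.frame(start0 = integer(), end0 = integer())
  if (n < 3L) return(empty)
  s <- toupper(sequence)
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  ch <- strsplit(s, "")[[1]]
  v <- unname(code[ch])
  v[is.na(v)] <- 0L  # treat ambiguity codes as A for scoring
  ntrip <- n - 2L
  trip <- v[1:ntrip] * 16L + v[2:(ntrip + 1L)] * 4L + v[3:(ntrip + 2L)] + 1L
  w <- min(window, n)
  nwin_trip <- w - 2L  # triplets per window
  counts <- integer(64L)
  score <- 0L
  cut <- threshold * (nwin_trip - 1L) / 10  # 10*S/(l-1) > threshold
  masked <- logical(max(n - w + 1L, 1L))
  for (t in 1:nwin_trip) {
    c0 <- counts[trip[[t]]]
    score <- score + c0
    counts[trip[[t]]] <- c0 + 1L
  }
  masked[[1]] <- score > cut
  if (n > w) {
    for (start in 2:(n - w + 1L)) {
      out_t <- trip[[start - 1L]]
      counts[out_t] <- counts[out_t] - 1L
      score <- score - counts[out_t]
      in_t <- trip[[start + nwin_trip - 1L]]
      score <- score + counts[in_t]
      counts[in_t] <- counts[in_t] + 1L
      masked[[start]] <- score > cut
    }
  }
  if (!any(masked)) return(empty)
  idx <- which(masked)
  # merge overlapping masked windows [i, i+w) (idx is 1-based window start)
  starts <- idx[c(TRUE, diff(idx) > w)]
  grp <- cumsum(c(TRUE, diff(idx) > w))
  ends <- tapply(idx, grp, max) + w - 1L
  data.frame(start0 = starts - 1L, end0 = as.integer(ends))
}

# collect soft-mask (lowercase) intervals of a sequence
softmask_intervals <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  low <- ch %in% letters
  if (!any(low)) return(data.frame(start0 = integer(), end0 = integer()))
  r <- rle(low)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  keep <- r$values
  data.frame(start0 = s[keep], end0 = e[keep])
}

kmer_starts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# positions (1-based starts) whose k-mer overlaps any masked interval
masked_kmer_positions <- function(n_kmers, k, mask) {
  if (nrow(mask) == 0L || n_kmers == 0L) return(logical(n_kmers))
  bad <- logical(n_kmers)
  for (i in seq_len(nrow(mask))) {
    lo <- max(1L, mask$start0[[i]] - k + 2L)
    hi <- min(n_kmers, mask$end0[[i]])
    if (lo <= hi) bad[lo:hi] <- TRUE
  }
  bad
}

align_feature <- function(ref, window_seq) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(ref)),
    subject = Biostrings::DNAString(toupper(window_seq)),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 2)
}

#' Find rDNA feature hits on a read by seed-and-extend matching
#'
#' Exact k-mer seeds (outside DUST-masked and soft-masked read intervals) are
#' clustered by alignment diagonal, and each cluster is resolved by banded
#' alignment of the feature reference against the implied read window. When a
#' cluster's seeds sit on a single diagonal and jointly cover the whole
#' reference, the hit is exact and reported without alignment. Both strands
#' are searched; hits are reported in forward-read coordinates.
#'
#' @param read One-row sequence record data.frame (or a list with `id`,`seq`).
#' @param feature_refs Named character vector of reference sequences; names
#'   are feature labels (`F18S`, `F5_8S`, `F28S`, `FULL_UNIT` or any label).
#' @param k Seed k-mer size (>= 8).
#' @param min_identity Minimum alignment identity to report, in `[0,1]`.
#' @param min_feature_coverage Minimum fraction of the reference covered.
#' @param band_frac Extension band width as a fraction of feature length.
#' @param mask Apply DUST masking to seeding (default TRUE).
#' @return FeatureHit data.frame: `read_id`, `feature`, `start`, `end`
#'   (0-based half-open on the forward read), `strand`, `identity`,
#'   `feature_coverage`, `feature_start`, `feature_end`, `feature_length`,
#'   `source`, `chain_members`.
#' @export
find_feature_hits <- function(read, feature_refs, k = 15L,
                              min_identity = 0.75,
                              min_feature_coverage = 0.5,
                              band_frac = 0.2, mask = TRUE) {
  stopifnot(k >= 8L, length(feature_refs) > 0L)
  rid <- read$id[[1]]
  rseq <- read$seq[[1]]
  rlen <- nchar(rseq)
  if (rlen < k) return(empty_hits())
  mask_iv <- if (mask) rbind(dust_mask(rseq), softmask_intervals(rseq))
             else data.frame(start0 = integer(), end0 = integer())
  out <- list()
  for (fname in names(feature_refs)) {
    ref <- toupper(feature_refs[[fname]])
    m <- nchar(ref)
    if (m < k) next
    fk <- kmer_starts(ref, k)
    ref_pos <- split(seq_along(fk), fk)  # kmer -> ref starts (1-based)
    for (strand in c("plus", "minus")) {
      sseq <- if (strand == "plus") rseq else revcomp(rseq)
      smask <- if (strand == "plus") mask_iv else {
        if (nrow(mask_iv)) data.frame(start0 = rlen - mask_iv$end0,
                                      end0 = rlen - mask_iv$start0)
        else mask_iv
      }
      rk <- kmer_starts(toupper(sseq), k)
      bad <- masked_kmer_positions(length(rk), k, smask)
      cand <- which(!bad & rk %in% names(ref_pos))
      if (length(cand) == 0L) next
      seeds <- do.call(rbind, lapply(cand, function(i) {
        cbind(read_pos = i, ref_pos = ref_pos[[rk[[i]]]])
      }))
      band <- max(32L, ceiling(band_frac * m))
      hits <- resolve_seed_clusters(seeds, sseq, ref, k, band,
                                    min_identity, min_feature_coverage)
      if (is.null(hits)) next
      # map to forward-read coordinates
      if (strand == "minus") {
        tmp_s <- rlen - hits$end
        hits$end <- rlen - hits$start
        hits$start <- tmp_s
      }
      hits$read_id <- rid
      hits$feature <- fname
      hits$strand <- strand
      hits$feature_length <- m
      hits$source <- "internal"
      hits$chain_members <- 1L
      out[[length(out) + 1L]] <- hits
    }
  }
  if (length(out) == 0L) return(empty_hits())
  res <- do.call(rbind, out)
  res <- res[order(res$feature, res$strand, res$start), ]
  rownames(res) <- NULL
  res[, names(empty_hits())]
}

# cluster seeds by diagonal and read-position proximity, then resolve each
# cluster either exactly (single full-coverage diagonal) or by alignment.
resolve_seed_clusters <- function(seeds, sseq, ref, k, band,
                                  min_identity, min_feature_coverage) {
  m <- nchar(ref)
  slen <- nchar(sseq)
  diag <- seeds[, "read_pos"] - seeds[, "ref_pos"]
  ord <- order(diag, seeds[, "read_pos"])
  seeds <- seeds[ord, , drop = FALSE]
  diag <- diag[ord]
  grp <- cumsum(c(TRUE, diff(diag) > band))
  rows <- list()
  for (g in unique(grp)) {
    sg <- seeds[grp == g, , drop = FALSE]
    # split groups separated by > m on the read (tandem copies share diagonals
    # only if offset < band, so this rarely triggers; belt and braces)
    og <- order(sg[, "read_pos"])
    sg <- sg[og, , drop = FALSE]
    sub <- cumsum(c(TRUE, diff(sg[, "read_pos"]) > m))
    for (s2 in unique(sub)) {
      cl <- sg[sub == s2, , drop = FALSE]
      row <- resolve_one_cluster(cl, sseq, ref, k, band, m, slen)
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) return(NULL)
  res <- do.call(rbind, rows)
  res <- res[res$identity >= min_identity &
               res$feature_coverage >= min_feature_coverage, , drop = FALSE]
  if (nrow(res) == 0L) return(NULL)
  res
}

resolve_one_cluster <- function(cl, sseq, ref, k, band, m, slen) {
  rp <- cl[, "read_pos"]; fp <- cl[, "ref_pos"]
  one_diag <- length(unique(rp - fp)) == 1L
  if (one_diag) {
    cov <- IRanges::reduce(IRanges::IRanges(start = fp, width = k))
    full <- length(cov) == 1L && IRanges::start(cov)[[1]] == 1L &&
      IRanges::end(cov)[[1]] == m
    if (full) {
      d <- rp[[1]] - fp[[1]]
      return(data.frame(start = d, end = d + m, identity = 1,
                        feature_coverage = 1, feature_start = 0L,
                        feature_end = m))
    }
  }
  # implied read window for the full feature, padded by the band
  lo <- max(1L, min(rp) - (min(fp) - 1L) - band)
  hi <- min(slen, max(rp) + k - 1L + (m - (max(fp) + k - 1L)) + band)
  if (hi - lo + 1L < k) return(NULL)
  aln <- align_feature(ref, substring(sseq, lo, hi))
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  alen <- Biostrings::nchar(aln)  # alignment length incl. gaps
  if (alen == 0L) return(NULL)
  ident <- Biostrings::nmatch(aln) / alen
  fs <- IRanges::start(pr) - 1L
  fe <- IRanges::end(pr)
  data.frame(start = lo - 1L + IRanges::start(sr) - 1L,
             end = lo - 1L + IRanges::end(sr),
             identity = ident,
             feature_coverage = (fe - fs) / m,
             feature_start = fs, feature_end = fe)
}

#' Chain co-linear fragment hits of the same feature
#'
#' ONT indel noise can fragment one feature match into several local hits;
#' hits of the same read, feature and strand whose read and feature intervals
#' are co-linear and separated by at most `same_feature_max_gap` bp on the
#' read are merged. Merged identity is the alignment-length-weighted mean;
#' feature coverage is recomputed from the merged feature span.
#'
#' @param hits FeatureHit data.frame (possibly several reads).
#' @param same_feature_max_gap Maximum read-coordinate gap to bridge, bp.
#' @return Chained FeatureHit data.frame; `chain_members` counts merged
#'   segments. Idempotent.
#' @export
chain_hits <- function(hits, same_feature_max_gap = 2000L) {
  if (nrow(hits) == 0L) return(hits)
  key <- paste(hits$read_id, hits$feature, hits$strand, sep = "\r")
  parts <- split(seq_len(nrow(hits)), key)
  out <- list()
  for (idx in parts) {
    h <- hits[idx, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    cur <- h[1, , drop = FALSE]
    acc_w <- (cur$feature_end - cur$feature_start)
    acc_id <- cur$identity * acc_w
    for (i in seq_len(nrow(h))[-1]) {
      nx <- h[i, , drop = FALSE]
      gap_ok <- nx$start - cur$end <= same_feature_max_gap
      colinear <- if (cur$strand == "plus")
        nx$feature_start >= cur$feature_end - 50L
      else nx$feature_end <= cur$feature_start + 50L
      if (gap_ok && colinear && nx$start >= cur$start) {
        w <- nx$feature_end - nx$feature_start
        acc_id <- acc_id + nx$identity * w
        acc_w <- acc_w + w
        cur$end <- max(cur$end, nx$end)
        cur$feature_start <- min(cur$feature_start, nx$feature_start)
        cur$feature_end <- max(cur$feature_end, nx$feature_end)
        cur$chain_members <- cur$chain_members + nx$chain_members
        cur$identity <- acc_id / acc_w
        cur$feature_coverage <-
          (cur$feature_end - cur$feature_start) / cur$feature_length
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- nx
        acc_w <- (cur$feature_end - cur$feature_start)
        acc_id <- cur$identity * acc_w
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  # residual overlapping hits of the same feature/strand that could not be
  # merged are redundant candidates: keep the better-covered one
  res <- res[order(paste(res$read_id, res$feature, res$strand, sep = "\r"),
                   -res$feature_coverage, -res$identity), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  key2 <- paste(res$read_id, res$feature, res$strand, sep = "\r")
  for (i in seq_len(nrow(res))) {
    if (!keep[[i]]) next
    j <- which(keep & key2 == key2[[i]])
    j <- j[j > i]
    if (length(j)) {
      ovl <- res$start[j] < res$end[[i]] & res$start[[i]] < res$end[j]
      keep[j[ovl]] <- FALSE
    }
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$read_id, res$feature, res$strand, res$start), ]
  rownames(res) <- NULL
  res
}

#' Convert BLAST tabular hits to FeatureHit records
#'
#' @param tabular_hits Data.frame from [parse_blast_tabular()].
#' @param feature_label_map Named character vector mapping query ids to
#'   feature labels.
#' @param feature_lengths Named integer vector of reference lengths (by
#'   feature label), used for feature coverage.
#' @param query_is_read Set TRUE when the table was produced with the read as
#'   the query and the rDNA feature as the subject (reversed convention).
#' @return FeatureHit data.frame with `source = "blast_adapter"`.
#' @export
adapt_blast_hits <- function(tabular_hits, feature_label_map,
                             feature_lengths, query_is_read = FALSE) {
  th <- tabular_hits
  if (query_is_read) {
    th[, c("query_id", "subject_id")] <- th[, c("subject_id", "query_id")]
    th[, c("query_start", "query_end", "subject_start", "subject_end")] <-
      th[, c("subject_start", "subject_end", "query_start", "query_end")]
  }
  unknown <- setdiff(unique(th$query_id), names(feature_label_map))
  if (length(unknown))
    stop("unmapped feature query ids: ", paste(unknown, collapse = ", "))
  if (nrow(th) == 0L) return(empty_hits())
  feat <- unname(feature_label_map[th$query_id])
  flen <- unname(feature_lengths[feat])
  iv <- to_internal_interval(th$subject_start, th$subject_end)
  fiv <- to_internal_interval(th$query_start, th$query_end)
  data.frame(read_id = th$subject_id, feature = feat,
             start = iv$start0, end = iv$end0, strand = iv$strand,
             identity = th$percent_identity / 100,
             feature_coverage = pmin(1, th$alignment_length / flen),
             feature_start = fiv$start0, feature_end = fiv$end0,
             feature_length = as.integer(flen),
             source = "blast_adapter",
             chain_members = 1L, stringsAsFactors = FALSE)
}

#' Scan a set of reads for rDNA features
#'
#' Convenience wrapper running [find_feature_hits()] then [chain_hits()] on
#' every read.
#'
#' @param reads Sequence record data.frame.
#' @inheritParams find_feature_hits
#' @inheritParams chain_hits
#' @return Chained FeatureHit data.frame over all reads.
#' @export
scan_reads <- function(reads, feature_refs, k = 15L, min_identity = 0.75,
                       min_feature_coverage = 0.5, band_frac = 0.2,
                       mask = TRUE, same_feature_max_gap = 2000L) {
  hits <- lapply(seq_len(nrow(reads)), function(i)
    find_feature_hits(reads[i, ], feature_refs, k = k,
                      min_identity = min_identity,
                      min_feature_coverage = min_feature_coverage,
                      band_frac = band_frac, mask = mask))
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0L) return(empty_hits())
  chain_hits(hits, same_feature_max_gap = same_feature_max_gap)
}
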