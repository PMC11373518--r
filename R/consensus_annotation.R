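# Unit extraction, rotation to the 18S start, majority-rule star-alignment
# consensus, and annotation of coding regions and spacers.

#' Extract rDNA unit copies rotated to start at the 18S gene
#'
#' One unit per adjacent pair of full-coverage 18S anchors on a read;
#' minus-strand arrays are reverse-complemented so every unit is reported in
#' plus orientation beginning at the 18S start. When more candidates exist
#' than `max_units`, selection is deterministic: longest anchor spans first,
#' then lexical read id, then position.
#'
#' @param reads Sequence record data.frame.
#' @param hits Chained FeatureHit data.frame over those reads.
#' @param max_units Maximum number of units to return (default 15).
#' @param min_anchor_coverage Anchor coverage threshold.
#' @return Data.frame with columns `source_id`, `start0`, `end0`, `strand`
#'   (provenance on the source read) and `seq` (the rotated unit).
#' @export
extract_rotated_units <- function(reads, hits, max_units = 15L,
                                  min_anchor_coverage = 0.8) {
  empty <- data.frame(source_id = character(), start0 = integer(),
                      end0 = integer(), strand = character(),
                      seq = character(), stringsAsFactors = FALSE)
  h <- hits[hits$feature == "F18S" &
              hits$feature_coverage >= min_anchor_coverage, , drop = FALSE]
  if (nrow(h) < 2L) return(empty)
  cand <- list()
  for (rid in unique(h$read_id)) {
    rseq <- reads$seq[match(rid, reads$id)]
    if (is.na(rseq)) next
    for (st in c("plus", "minus")) {
      hs <- h[h$read_id == rid & h$strand == st, , drop = FALSE]
      if (nrow(hs) < 2L) next
      hs <- hs[order(hs$start), , drop = FALSE]
      for (i in seq_len(nrow(hs) - 1L)) {
        if (st == "plus") {
          s0 <- hs$start[[i]]; e0 <- hs$start[[i + 1L]]
        } else {
          s0 <- hs$end[[i]]; e0 <- hs$end[[i + 1L]]
        }
        u <- substring(rseq, s0 + 1L, e0)
        if (st == "minus") u <- revcomp(u)
        span <- min(hs$end[[i]] - hs$start[[i]],
                    hs$end[[i + 1L]] - hs$start[[i + 1L]])
        cand[[length(cand) + 1L]] <- data.frame(
          source_id = rid, start0 = s0, end0 = e0, strand = st,
          seq = u, anchor_span = span, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0L) return(empty)
  df <- do.call(rbind, cand)
  df <- df[order(-df$anchor_span, df$source_id, df$start0), , drop = FALSE]
  df <- utils::head(df, max_units)
  rownames(df) <- NULL
  df[, c("source_id", "start0", "end0", "strand", "seq")]
}

pairwise_global <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(a)),
    subject = Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 2)
}

#' Majority-rule consensus of unit copies by star alignment
#'
#' The centre of the star is the medoid (minimal summed edit distance to the
#' others); every unit is globally aligned to it; columns are called by
#' majority with the gap as a symbol, and gap-majority columns are deleted.
#' Ties prefer the base earliest in alphabetical order, with the gap losing
#' all ties.
#'
#' @param units Character vector of unit sequences, or the data.frame from
#'   [extract_rotated_units()].
#' @return A one-row sequence record data.frame; attribute `n_units` records
#'   how many units voted, attribute `single_unit` flags the degenerate
#'   one-unit case (returned unchanged with a warning).
#' @export
build_consensus <- function(units) {
  if (is.data.frame(units)) units <- units$seq
  units <- toupper(units)
  n <- length(units)
  if (n == 0L) stop("no units to build a consensus from")
  if (n == 1L) {
    warning("single unit: returned unchanged, no consensus possible")
    rec <- new_seq_records(id = "consensus", seq = units[[1]])
    attr(rec, "n_units") <- 1L
    attr(rec, "single_unit") <- TRUE
    return(rec)
  }
  dmat <- utils::adist(units)
  centre_i <- which.min(rowSums(dmat))
  centre <- units[[centre_i]]
  m <- nchar(centre)
  # votes for centre columns: n x m matrix of characters ("-" for deletion)
  col_votes <- matrix("-", nrow = n, ncol = m)
  ins_votes <- list()  # key "pos.offset" -> character vector of votes
  for (ui in seq_len(n)) {
    if (ui == centre_i) { col_votes[ui, ] <- strsplit(centre, "")[[1]]; next }
    aln <- pairwise_global(units[[ui]], centre)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    cpos <- 0L; off <- 0L
    for (j in seq_along(sa)) {
      if (sa[[j]] != "-") {
        cpos <- cpos + 1L; off <- 0L
        col_votes[ui, cpos] <- pa[[j]]
      } else {
        off <- off + 1L
        key <- paste0(cpos, ".", off)
        ins_votes[[key]] <- c(ins_votes[[key]], pa[[j]])
      }
    }
  }
  call_column <- function(votes, n_total) {
    votes <- c(votes, rep("-", n_total - length(votes)))
    tab <- table(votes)
    # gap loses ties; bases tie-break alphabetically
    cand <- names(tab)[tab == max(tab)]
    bases <- setdiff(cand, "-")
    if (length(bases)) sort(bases)[[1]] else "-"
  }
  cons_cols <- vapply(seq_len(m), function(j)
    call_column(col_votes[, j], n), character(1))
  pieces <- character(m + 1L)
  if (length(ins_votes)) {
    keys <- names(ins_votes)
    kp <- as.integer(sub("\\..*$", "", keys))
    ko <- as.integer(sub("^.*\\.", "", keys))
    ord <- order(kp, ko)
    for (i in ord) {
      b <- call_column(ins_votes[[keys[[i]]]], n)
      if (b != "-") pieces[[kp[[i]] + 1L]] <- paste0(pieces[[kp[[i]] + 1L]], b)
    }
  }
  out <- paste0(pieces[[1]],
                paste0(ifelse(cons_cols == "-", "", cons_cols),
                       pieces[-1L], collapse = ""))
  rec <- new_seq_records(id = "consensus", seq = out)
  attr(rec, "n_units") <- n
  attr(rec, "single_unit") <- FALSE
  rec
}

#' Annotate coding regions and spacers on a consensus unit
#'
#' Each coding region (18S, 5.8S, 28S) is located by alignment of the
#' reference feature against the consensus; the spacers are the gaps:
#' ITS1 between 18S and 5.8S, ITS2 between 5.8S and 28S, and the IGS from the
#' 28S end to the unit end. Because the unit is rotated to begin at the 18S
#' start, the IGS as defined here includes both external transcribed spacers
#' (transcription start sites are not determinable from sequence alone).
#'
#' @param consensus One-row sequence record data.frame or a single string.
#' @param reference_features Named character vector with elements `F18S`,
#'   `F5_8S`, `F28S`.
#' @param min_identity Minimum identity to accept a coding-region placement
#'   (default 0.6); below it the feature is reported missing.
#' @return An object of class `rdna_unit_annotation`: list with `intervals`
#'   (data.frame seqid/feature/start0/end0/strand for 18S, ITS1, 5.8S, ITS2,
#'   28S, IGS), `lengths` (named vector), `total`.
#' @export
annotate_unit <- function(consensus, reference_features, min_identity = 0.6) {
  seq <- if (is.data.frame(consensus)) consensus$seq[[1]] else consensus
  sid <- if (is.data.frame(consensus)) consensus$id[[1]] else "unit"
  total <- nchar(seq)
  need <- c("F18S", "F5_8S", "F28S")
  if (!all(need %in% names(reference_features)))
    stop("reference_features must contain F18S, F5_8S and F28S")
  loc <- list()
  for (f in need) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(toupper(reference_features[[f]])),
      subject = Biostrings::DNAString(toupper(seq)),
      type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = FALSE),
      gapOpening = 4, gapExtension = 2)
    ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    if (!is.finite(ident) || ident < min_identity)
      stop(c(F18S = "18S", F5_8S = "5.8S", F28S = "28S")[[f]],
           " not found in unit (identity ",
           sprintf("%.2f", ident), " < ", min_identity, ")")
    sr <- Biostrings::subject(aln)
    loc[[f]] <- c(IRanges::start(sr) - 1L, IRanges::end(sr))
  }
  if (!(loc$F18S[[1]] < loc$F5_8S[[1]] && loc$F5_8S[[2]] <= loc$F28S[[1]]))
    stop("coding regions out of order: expected 18S < 5.8S < 28S")
  iv <- data.frame(
    seqid = sid,
    feature = c("18S", "ITS1", "5.8S", "ITS2", "28S", "IGS"),
    start0 = c(0L, loc$F18S[[2]], loc$F5_8S[[1]], loc$F5_8S[[2]],
               loc$F28S[[1]], loc$F28S[[2]]),
    end0 = c(loc$F18S[[2]], loc$F5_8S[[1]], loc$F5_8S[[2]],
             loc$F28S[[1]], loc$F28S[[2]], total),
    strand = "plus", stringsAsFactors = FALSE)
  if (any(iv$end0 < iv$start0)) stop("overlapping coding-region placements")
  lens <- setNames(iv$end0 - iv$start0, iv$feature)
  structure(list(intervals = iv, lengths = lens, total = total),
            class = "rdna_unit_annotation")
}

#' @export
print.rdna_unit_annotation <- function(x, ...) {
  cat("rDNA unit annotation (", x$total, " bp; IGS includes both ETS)\n",
      sep = "")
  for (i in seq_len(nrow(x$intervals)))
    cat(sprintf("  %-5s %8d..%-8d %6d bp\n", x$intervals$feature[[i]],
                x$intervals$start0[[i]], x$intervals$end0[[i]],
                x$intervals$end0[[i]] - x$intervals$start0[[i]]))
  invisible(x)
}

#' Tabulate region lengths for several annotated units
#'
#' @param annotations Named list of `rdna_unit_annotation` objects (names are
#'   species/dataset labels).
#' @param path Optional TSV output path.
#' @return Data.frame with one row per unit: `species`, `total`, `len_18S`,
#'   `len_ITS1`, `len_5.8S`, `len_ITS2`, `len_28S`, `len_IGS`.
#' @export
region_length_report <- function(annotations, path = NULL) {
  rows <- lapply(names(annotations), function(sp) {
    a <- annotations[[sp]]
    data.frame(species = sp, total = a$total,
               len_18S = a$lengths[["18S"]], len_ITS1 = a$lengths[["ITS1"]],
               len_5.8S = a$lengths[["5.8S"]], len_ITS2 = a$lengths[["ITS2"]],
               len_28S = a$lengths[["28S"]], len_IGS = a$lengths[["IGS"]],
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), total = integer(),
               len_18S = integer(), len_ITS1 = integer(),
               len_5.8S = integer(), len_ITS2 = integer(),
               len_28S = integer(), len_IGS = integer(),
               check.names = FALSE)
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
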