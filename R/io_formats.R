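#' rdnarray: rDNA repeat-unit sizing and annotation from long reads
#'
#' Tools for measuring ribosomal RNA gene repeat-unit sizes from long reads
#' spanning multiple units, building and annotating consensus units,
#' detecting tandem sub-repeats, and matching orthologous transposable
#' elements between intergenic spacers. All internal coordinates are 0-based
#' half-open on the forward strand; conversion to and from the 1-based
#' inclusive conventions of FASTA-adjacent formats happens only at I/O
#' boundaries.
#'
#' @importFrom stats density bw.nrd0 median runif rnorm rbinom setNames var
#' @importFrom utils read.table write.table head tail
#' @importFrom tools md5sum
#' @keywords internal
"_PACKAGE"

IUPAC_CHARS <- c("A","C","G","T","U","R","Y","S","W","K","M","B","D","H","V","N")

# ---------------------------------------------------------------------------
# sequence records: a data.frame with columns id, seq, qual (NA when absent)

new_seq_records <- function(id = character(), seq = character(),
                            qual = rep(NA_character_, length(id))) {
  stopifnot(length(id) == length(seq), length(qual) == length(id))
  if (anyNA(id) || any(!nzchar(id))) stop("sequence ids must be non-empty")
  bad <- !is.na(qual) & nchar(qual) != nchar(seq)
  if (any(bad)) stop("quality string length must equal sequence length")
  data.frame(id = as.character(id), seq = as.character(seq),
             qual = as.character(qual), stringsAsFactors = FALSE)
}

#' Read a FASTA file
#'
#' Parses nucleotide FASTA, preserving lowercase (soft-masked) letters. The
#' file is validated line-by-line first so that format errors can name the
#' offending line.
#'
#' @param path Path to a FASTA file (may be empty).
#' @return A data.frame with columns `id`, `seq`, `qual` (always `NA` for
#'   FASTA), one row per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    return(new_seq_records())
  in_record <- FALSE
  seq_re <- sprintf("^[%s%s-]*$", paste(IUPAC_CHARS, collapse = ""),
                    paste(tolower(IUPAC_CHARS), collapse = ""))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      if (!nzchar(trimws(substring(ln, 2))))
        stop("malformed FASTA header at line ", i, " of ", path)
      in_record <- TRUE
    } else if (nzchar(trimws(ln))) {
      if (!in_record)
        stop("sequence before first header at line ", i, " of ", path)
      if (!grepl(seq_re, trimws(ln)))
        stop("non-IUPAC characters at line ", i, " of ", path)
    }
  }
  set <- Biostrings::readBStringSet(path)  # preserves case
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  new_seq_records(id = ids, seq = as.character(set))
}

#' Write sequence records to FASTA
#'
#' @param records Data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[[i]]), con)
    s <- records$seq[[i]]
    n <- nchar(s)
    if (n > 0L) {
      starts <- seq(1L, n, by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
    }
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' Qualities are carried along for provenance only; no downstream computation
#' uses them.
#'
#' @param path Path to a FASTQ file.
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L)
    return(new_seq_records())
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  new_seq_records(id = ids, seq = as.character(set),
                  qual = as.character(S4Vectors::mcols(set)$qualities))
}

#' Write sequence records to FASTQ
#'
#' Records without qualities get a constant placeholder quality.
#' @inheritParams write_fasta
#' @export
write_fastq <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    q <- records$qual[[i]]
    if (is.na(q)) q <- strrep("I", nchar(records$seq[[i]]))
    writeLines(c(paste0("@", records$id[[i]]), records$seq[[i]], "+", q), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# BLAST tabular

BLAST_COLS <- c("query_id", "subject_id", "percent_identity",
                "alignment_length", "mismatches", "gap_opens",
                "query_start", "query_end", "subject_start", "subject_end",
                "evalue", "bitscore")

#' Parse BLAST tabular output (outfmt 6 or 7)
#'
#' The standard 12-column table. In the convention used throughout this
#' package the query is the rDNA feature sequence and the subject is the long
#' read or contig; [adapt_blast_hits()] has a flag for the reversed layout.
#'
#' @param path Path to the tabular file.
#' @param dialect `"outfmt6"` (no comments) or `"outfmt7"` (lines starting
#'   with `#` are skipped).
#' @return A data.frame with one row per hit and typed columns
#'   `query_id`, `subject_id`, `percent_identity`, `alignment_length`,
#'   `mismatches`, `gap_opens`, `query_start`, `query_end`, `subject_start`,
#'   `subject_end`, `evalue`, `bitscore`. `subject_start > subject_end`
#'   signals minus orientation and is preserved as written.
#' @export
parse_blast_tabular <- function(path, dialect = c("outfmt6", "outfmt7")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (dialect == "outfmt7") keep <- keep & !startsWith(lines, "#")
  idx <- which(keep)
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    fields <- strsplit(trimws(lines[[idx[j]]]), "[\t ]+")[[1]]
    if (length(fields) != 12L)
      stop("expected 12 columns, found ", length(fields),
           " at line ", idx[j], " of ", path)
    out[[j]] <- fields
  }
  if (length(out) == 0L) {
    df <- as.data.frame(matrix(character(), 0L, 12L),
                        stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  }
  names(df) <- BLAST_COLS
  num <- setdiff(BLAST_COLS, c("query_id", "subject_id"))
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  int <- c("alignment_length", "mismatches", "gap_opens", "query_start",
           "query_end", "subject_start", "subject_end")
  for (cn in int) df[[cn]] <- as.integer(df[[cn]])
  bad <- which(df$alignment_length < 1L | df$query_start < 1L |
                 df$subject_start < 1L | df$evalue < 0)
  if (length(bad))
    stop("invalid hit values at data line ", bad[[1]], " of ", path)
  df
}

# ---------------------------------------------------------------------------
# RepeatMasker .out

#' Parse a RepeatMasker .out annotation file
#'
#' Standard layout: header lines, then whitespace-delimited records. `C` in
#' the orientation column denotes minus orientation; minus records print the
#' repeat-consensus coordinates as `(left) end begin`, which are normalized
#' here so that `repeat_begin <= repeat_end` always, with the orientation kept
#' in its own column. Parenthesized "left" fields are dropped.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return Data.frame with columns `sw_score`, `percent_divergence`,
#'   `percent_deleted`, `percent_inserted`, `query_id`, `query_begin`,
#'   `query_end` (1-based inclusive), `orientation` (`"plus"`/`"minus"`),
#'   `repeat_name`, `repeat_class_family`, `repeat_begin`, `repeat_end`,
#'   `element_id`.
#' @export
parse_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  empty_df <- data.frame(
    sw_score = integer(), percent_divergence = numeric(),
    percent_deleted = numeric(), percent_inserted = numeric(),
    query_id = character(), query_begin = integer(), query_end = integer(),
    orientation = character(), repeat_name = character(),
    repeat_class_family = character(), repeat_begin = integer(),
    repeat_end = integer(), element_id = integer(),
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    f <- strsplit(ln, "[ \t]+")[[1]]
    # header lines start with "SW" or "score"
    if (f[[1]] %in% c("SW", "score")) next
    if (length(f) < 14L || is.na(suppressWarnings(as.integer(f[[1]]))))
      stop("unparseable RepeatMasker record at line ", i, " of ", path)
    orient <- if (f[[9]] %in% c("C", "-")) "minus" else "plus"
    strip <- function(x) as.integer(gsub("[()]", "", x))
    if (orient == "plus") {
      rb <- strip(f[[12]]); re <- strip(f[[13]])
    } else {
      # minus layout: (left) end begin
      re <- strip(f[[13]]); rb <- strip(f[[14]])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sw_score = as.integer(f[[1]]),
      percent_divergence = as.numeric(f[[2]]),
      percent_deleted = as.numeric(f[[3]]),
      percent_inserted = as.numeric(f[[4]]),
      query_id = f[[5]],
      query_begin = as.integer(f[[6]]),
      query_end = as.integer(f[[7]]),
      orientation = orient,
      repeat_name = f[[10]],
      repeat_class_family = f[[11]],
      repeat_begin = rb,
      repeat_end = re,
      element_id = if (length(f) >= 15L)
        suppressWarnings(as.integer(f[[15]])) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_df)
  df <- do.call(rbind, rows)
  if (any(df$query_begin > df$query_end))
    stop("query_begin > query_end in ", path)
  df
}

# ---------------------------------------------------------------------------
# coordinate conversion

#' Convert 1-based inclusive coordinates to internal 0-based half-open
#'
#' Swapped inputs (`start > end`) signal minus orientation; the returned
#' interval is always on the forward strand with `start0 < end0`.
#'
#' @param one_based_start,one_based_end Integer vectors of positions (>= 1).
#' @return Data.frame with columns `start0`, `end0`, `strand`.
#' @export
to_internal_interval <- function(one_based_start, one_based_end) {
  s <- as.integer(one_based_start); e <- as.integer(one_based_end)
  if (length(s) != length(e)) stop("start/end length mismatch")
  if (any(s < 1L) || any(e < 1L)) stop("positions must be >= 1")
  minus <- s > e
  lo <- ifelse(minus, e, s)
  hi <- ifelse(minus, s, e)
  data.frame(start0 = lo - 1L, end0 = hi,
             strand = ifelse(minus, "minus", "plus"),
             stringsAsFactors = FALSE)
}

#' Convert internal 0-based half-open coordinates back to 1-based inclusive
#'
#' Inverse of [to_internal_interval()]: minus-strand intervals come back with
#' start and end swapped.
#' @param start0,end0 Internal coordinates.
#' @param strand `"plus"` or `"minus"`.
#' @return Data.frame with columns `start1`, `end1`.
#' @export
from_internal_interval <- function(start0, end0, strand = "plus") {
  if (any(start0 < 0L) || any(end0 <= start0)) stop("invalid interval")
  s1 <- as.integer(start0) + 1L
  e1 <- as.integer(end0)
  minus <- strand == "minus"
  data.frame(start1 = ifelse(minus, e1, s1),
             end1 = ifelse(minus, s1, e1))
}

# ---------------------------------------------------------------------------
# GFF3

#' Write annotations as GFF3
#'
#' Annotations use the internal 0-based half-open convention and are written
#' with GFF3's 1-based inclusive coordinates.
#'
#' @param annotations Data.frame with columns `seqid`, `feature`, `start0`,
#'   `end0`, `strand` and optionally `id` (unique).
#' @param path Output path.
#' @export
write_gff3 <- function(annotations, path) {
  need <- c("seqid", "feature", "start0", "end0", "strand")
  if (!all(need %in% names(annotations)))
    stop("annotations must have columns: ", paste(need, collapse = ", "))
  if (is.null(annotations$id))
    annotations$id <- paste0(annotations$feature, "_",
                             seq_len(max(nrow(annotations), 0L)))
  if (anyDuplicated(annotations$id))
    stop("duplicate annotation IDs: ",
         paste(unique(annotations$id[duplicated(annotations$id)]),
               collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    writeLines(paste(a$seqid, "rdnarray", a$feature,
                     a$start0 + 1L, a$end0,
                     ".", if (a$strand == "minus") "-" else "+", ".",
                     paste0("ID=", a$id), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' @param path Path to a GFF3 file.
#' @return Annotation data.frame in internal coordinates (columns `seqid`,
#'   `feature`, `start0`, `end0`, `strand`, `id`).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(seqid = character(), feature = character(),
                      start0 = integer(), end0 = integer(),
                      strand = character(), id = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t")[[1]]
    if (length(f) != 9L) stop("bad GFF3 line ", i, " of ", path)
    id <- sub("^.*ID=([^;]+).*$", "\\1", f[[9]])
    data.frame(seqid = f[[1]], feature = f[[3]],
               start0 = as.integer(f[[4]]) - 1L, end0 = as.integer(f[[5]]),
               strand = if (f[[7]] == "-") "minus" else "plus",
               id = id, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# small shared helpers

#' Reverse-complement a nucleotide string
#'
#' Case-preserving, IUPAC-aware.
#' @param seq A single nucleotide string.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  if (!nzchar(seq)) return(seq)
  chartr("ACGTUacgtuRYSWKMBDHVryswkmbdhv",
         "TGCAAtgcaaYRSWMKVHDByrswmkvhdb",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}
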