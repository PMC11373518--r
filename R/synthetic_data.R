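# Simulation of tandem rDNA arrays and noisy long reads, with full truth.
# The generator emulates the structure the measurement pipeline assumes:
# head-to-tail units (18S-ITS1-5.8S-ITS2-28S-IGS), per-unit sub-repeat
# copy-number variation, TE insertions, and ONT-like substitution/indel noise.

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_substitutions <- function(seq, rate) {
  if (rate <= 0 || !nzchar(seq)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C","G","T"), C = c("A","G","T"),
                G = c("A","C","T"), T = c("A","C","G"))
    ch[hit] <- vapply(ch[hit], function(b)
      sample(alt[[b]] %||% c("A","C","G","T"), 1L), character(1))
  }
  paste(ch, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specify a tandem sub-repeat array to plant in a simulated unit
#'
#' @param period Repeat-unit size in bp (>= 1).
#' @param copies_min,copies_max Per-unit copy number is drawn uniformly from
#'   `copies_min:copies_max` (set equal for a fixed copy number).
#' @param divergence Per-copy substitution fraction from the array's master
#'   sequence, in `[0, 1)`.
#' @param location `"IGS"` or `"ITS1"`: which spacer carries the array.
#' @param offset Insertion point within that spacer's core sequence (bp).
#' @return A `subrepeat_spec` list.
#' @export
subrepeat_spec <- function(period, copies_min, copies_max = copies_min,
                           divergence = 0, location = c("IGS", "ITS1"),
                           offset = 0L) {
  location <- match.arg(location)
  stopifnot(period >= 1, copies_min >= 0, copies_max >= copies_min,
            divergence >= 0, divergence < 1, offset >= 0)
  structure(list(period = as.integer(period),
                 copies_min = as.integer(copies_min),
                 copies_max = as.integer(copies_max),
                 divergence = divergence, location = location,
                 offset = as.integer(offset)),
            class = "subrepeat_spec")
}

#' Define the architecture of one simulated rDNA unit
#'
#' Coding-region defaults mimic vertebrate magnitudes (18S 1.8 kb, 5.8S
#' 150 bp, 28S 4.5 kb); only the relative layout matters to the pipeline.
#' The spacer "core" lengths are the constant backbone into which sub-repeat
#' arrays, microsatellites and TEs are inserted.
#'
#' @param len_18s,len_its1,len_5_8s,len_its2,len_28s,len_igs_core Region
#'   lengths in bp. Defaults give a 15 kb unit with no insertions.
#' @param subrepeats List of [subrepeat_spec()] objects.
#' @param tes List of TE insertions, each a list with fields `family`,
#'   `orientation` (`"plus"`/`"minus"`), `seq` (the element sequence) and
#'   `offset` (insertion point in the IGS core).
#' @param microsatellites List of lists with fields `motif`, `copies`,
#'   `offset` (inserted in the IGS core).
#' @return A `unit_architecture` list.
#' @export
unit_architecture <- function(len_18s = 1800L, len_its1 = 1000L,
                              len_5_8s = 150L, len_its2 = 1000L,
                              len_28s = 4500L, len_igs_core = 6550L,
                              subrepeats = list(), tes = list(),
                              microsatellites = list()) {
  lens <- c(len_18s, len_its1, len_5_8s, len_its2, len_28s, len_igs_core)
  if (any(lens <= 0)) stop("all region lengths must be > 0")
  for (sr in subrepeats) {
    if (!inherits(sr, "subrepeat_spec")) stop("subrepeats must be subrepeat_spec")
    core <- if (sr$location == "IGS") len_igs_core else len_its1
    if (sr$offset > core) stop("sub-repeat offset outside its target region")
  }
  for (te in tes)
    if ((te$offset %||% 0) > len_igs_core) stop("TE offset outside IGS core")
  structure(list(len_18s = as.integer(len_18s), len_its1 = as.integer(len_its1),
                 len_5_8s = as.integer(len_5_8s), len_its2 = as.integer(len_its2),
                 len_28s = as.integer(len_28s),
                 len_igs_core = as.integer(len_igs_core),
                 subrepeats = subrepeats, tes = tes,
                 microsatellites = microsatellites),
            class = "unit_architecture")
}

#' Long-read error model
#'
#' Substitutions, single-base insertions and single-base deletions are applied
#' independently per base. Read lengths are either fixed or lognormal.
#'
#' @param substitution_rate,insertion_rate,deletion_rate Per-base
#'   probabilities in `[0, 1)`; their sum must be < 1.
#' @param read_length Either a single number (fixed length) or a list
#'   `list(meanlog=, sdlog=)` for lognormal lengths.
#' @return An `error_model` list.
#' @export
error_model <- function(substitution_rate = 0, insertion_rate = 0,
                        deletion_rate = 0, read_length = 10000) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 1)
    stop("error rates must be in [0,1) and sum to < 1")
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 read_length = read_length),
            class = "error_model")
}

build_master_regions <- function(arch) {
  list(f18s = random_dna(arch$len_18s),
       its1 = random_dna(arch$len_its1),
       f5_8s = random_dna(arch$len_5_8s),
       its2 = random_dna(arch$len_its2),
       f28s = random_dna(arch$len_28s),
       igs = random_dna(arch$len_igs_core))
}

# insert strings into a backbone at given offsets (offsets refer to the
# un-inserted backbone; insertions applied right-to-left)
insert_at <- function(backbone, pieces, offsets) {
  ord <- order(offsets, decreasing = TRUE)
  for (i in ord) {
    o <- offsets[[i]]
    backbone <- paste0(substring(backbone, 1L, o), pieces[[i]],
                       substring(backbone, o + 1L))
  }
  backbone
}

#' Simulate a genome segment carrying a tandem rDNA array
#'
#' The genome is random flank + `n_units` concatenated units + random flank.
#' All units share the same master region sequences (emulating concerted
#' evolution); only sub-repeat copy numbers are redrawn per unit. The
#' returned truth records unit boundaries, per-unit lengths and sub-repeat
#' totals, array spans, and TE placements.
#'
#' @param architecture A [unit_architecture()].
#' @param n_units Number of tandem units (>= 1).
#' @param flank_length Random flank on each side, bp.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list with elements `genome` (a one-row sequence record
#'   data.frame), `truth` (list: `units` data.frame with per-unit boundaries,
#'   lengths and sub-repeat totals; `subrepeat_arrays` data.frame;
#'   `tes` data.frame; `seed`), and `architecture`.
#' @export
simulate_locus <- function(architecture, n_units, flank_length = 2000L,
                           seed = 1L) {
  stopifnot(inherits(architecture, "unit_architecture"), n_units >= 1)
  set.seed(seed)
  arch <- architecture
  regions <- build_master_regions(arch)
  masters <- lapply(arch$subrepeats, function(sr) random_dna(sr$period))
  left <- random_dna(flank_length)
  right <- random_dna(flank_length)

  units <- character(n_units)
  unit_rows <- vector("list", n_units)
  array_rows <- list()
  te_rows <- list()
  for (u in seq_len(n_units)) {
    igs <- regions$igs
    its1 <- regions$its1
    # sub-repeat arrays, per-unit copy numbers
    igs_ins <- list(); igs_off <- integer()
    its1_ins <- list(); its1_off <- integer()
    sub_total <- 0L
    u_arrays <- list()
    for (si in seq_along(arch$subrepeats)) {
      sr <- arch$subrepeats[[si]]
      cn <- if (sr$copies_max > sr$copies_min)
        sample(sr$copies_min:sr$copies_max, 1L) else sr$copies_min
      copies <- vapply(seq_len(cn), function(i)
        mutate_substitutions(masters[[si]], sr$divergence), character(1))
      arr <- paste(copies, collapse = "")
      if (sr$location == "IGS") {
        igs_ins <- c(igs_ins, arr); igs_off <- c(igs_off, sr$offset)
      } else {
        its1_ins <- c(its1_ins, arr); its1_off <- c(its1_off, sr$offset)
      }
      sub_total <- sub_total + nchar(arr)
      u_arrays[[si]] <- data.frame(unit = u, spec = si, period = sr$period,
                                   copy_number = cn, length = nchar(arr),
                                   location = sr$location,
                                   stringsAsFactors = FALSE)
    }
    for (ms in arch$microsatellites) {
      igs_ins <- c(igs_ins, strrep(ms$motif, ms$copies))
      igs_off <- c(igs_off, ms$offset %||% 0L)
    }
    te_local <- list()
    for (ti in seq_along(arch$tes)) {
      te <- arch$tes[[ti]]
      s <- te$seq
      if (identical(te$orientation, "minus")) s <- revcomp(s)
      igs_ins <- c(igs_ins, s)
      igs_off <- c(igs_off, te$offset %||% 0L)
      te_local[[ti]] <- data.frame(unit = u, family = te$family,
                                   orientation = te$orientation %||% "plus",
                                   length = nchar(te$seq),
                                   igs_offset = te$offset %||% 0L,
                                   stringsAsFactors = FALSE)
    }
    if (length(igs_ins)) igs <- insert_at(igs, igs_ins, igs_off)
    if (length(its1_ins)) its1 <- insert_at(its1, its1_ins, its1_off)
    useq <- paste0(regions$f18s, its1, regions$f5_8s, regions$its2,
                   regions$f28s, igs)
    units[[u]] <- useq
    unit_rows[[u]] <- data.frame(unit = u, length = nchar(useq),
                                 subrepeat_bp = sub_total,
                                 stringsAsFactors = FALSE)
    array_rows <- c(array_rows, u_arrays)
    te_rows <- c(te_rows, te_local)
  }
  starts <- flank_length + c(0L, cumsum(nchar(units))[-n_units])
  units_df <- do.call(rbind, unit_rows)
  units_df$start0 <- as.integer(starts)
  units_df$end0 <- as.integer(starts + nchar(units))
  genome_seq <- paste0(left, paste(units, collapse = ""), right)
  truth <- list(
    units = units_df,
    subrepeat_arrays = if (length(array_rows)) do.call(rbind, array_rows)
      else NULL,
    tes = if (length(te_rows)) do.call(rbind, te_rows) else NULL,
    regions = list(len_18s = arch$len_18s, len_5_8s = arch$len_5_8s,
                   len_28s = arch$len_28s),
    feature_refs = c(F18S = regions$f18s, F5_8S = regions$f5_8s,
                     F28S = regions$f28s),
    seed = seed)
  list(genome = new_seq_records(id = paste0("locus_seed", seed),
                                seq = genome_seq),
       truth = truth, architecture = arch)
}

apply_errors <- function(seq, em) {
  ps <- em$substitution_rate; pi <- em$insertion_rate; pd <- em$deletion_rate
  if (ps + pi + pd == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  u <- runif(n)
  del <- u < pd
  sub <- !del & u < pd + ps
  ins <- runif(n) < pi
  alt <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  bases <- c("A", "C", "G", "T")
  if (any(sub)) {
    idx <- which(sub)
    cur <- alt[ch[idx]]
    cur[is.na(cur)] <- 1L
    shift <- sample.int(3L, length(idx), replace = TRUE)
    ch[idx] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  out <- ch
  out[del] <- ""
  if (any(ins)) {
    idx <- which(ins)
    out[idx] <- paste0(out[idx], bases[sample.int(4L, length(idx), TRUE)])
  }
  paste(out, collapse = "")
}

#' Simulate long reads over a genome
#'
#' Read start positions are uniform; strand is a fair coin; reads are
#' truncated at the genome ends. Substitutions, insertions and deletions are
#' applied independently per base after extraction.
#'
#' @param genome One-row sequence record data.frame (from [simulate_locus()]).
#' @param error_model An [error_model()].
#' @param n_reads Number of reads to draw.
#' @param seed Integer seed.
#' @param id_prefix Prefix for read ids (keep distinct when pooling reads
#'   from several simulated loci).
#' @return A list with `reads` (sequence record data.frame) and `provenance`
#'   (data.frame: read id, error-free source interval `start0`/`end0` and
#'   strand on the genome).
#' @export
simulate_reads <- function(genome, error_model, n_reads, seed = 1L,
                           id_prefix = "read") {
  stopifnot(inherits(error_model, "error_model"), n_reads >= 1)
  set.seed(seed)
  g <- genome$seq[[1]]
  glen <- nchar(g)
  rl <- error_model$read_length
  lens <- if (is.list(rl)) {
    pmax(200L, as.integer(round(stats::rlnorm(n_reads, rl$meanlog, rl$sdlog))))
  } else rep(as.integer(rl), n_reads)
  if (!is.list(rl) && lens[[1]] > glen)
    stop("requested read length ", lens[[1]], " exceeds genome length ", glen)
  lens <- pmin(lens, glen)
  starts <- vapply(lens, function(L)
    sample.int(glen - L + 1L, 1L), integer(1))  # 1-based
  strands <- ifelse(runif(n_reads) < 0.5, "plus", "minus")
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    s <- substring(g, starts[[i]], starts[[i]] + lens[[i]] - 1L)
    if (strands[[i]] == "minus") s <- revcomp(s)
    seqs[[i]] <- apply_errors(s, error_model)
  }
  ids <- sprintf("%s_%04d", id_prefix, seq_len(n_reads))
  list(reads = new_seq_records(id = ids, seq = seqs),
       provenance = data.frame(id = ids, start0 = starts - 1L,
                               end0 = starts - 1L + lens,
                               strand = strands, stringsAsFactors = FALSE))
}

#' Generate a reproducible library of labelled TE token sequences
#'
#' @param families Character vector of family labels.
#' @param lengths Integer vector (recycled) of element lengths.
#' @param seed Integer seed.
#' @return Named character vector of sequences, names are family labels.
#' @export
plant_te_library <- function(families, lengths = 300L, seed = 1L) {
  if (length(families) == 0L) stop("families must be non-empty")
  set.seed(seed)
  lengths <- rep_len(as.integer(lengths), length(families))
  setNames(vapply(lengths, random_dna, character(1)), families)
}
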