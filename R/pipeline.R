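# End-to-end orchestration: simulate (or load) reads, scan for features,
# size units, build and annotate a consensus, detect sub-repeats, attribute
# variance, and (optionally) match TEs between two RepeatMasker outputs.
# Identical config + seed gives byte-identical outputs.

#' Build a pipeline configuration
#'
#' A flat list of every tunable parameter, each defaulting to the value
#' documented in its module. Paths left `NULL` switch the corresponding
#' stage to simulated input (reads) or skip it (TE orthology).
#'
#' @param reads_path Optional FASTA/FASTQ of reads; when `NULL`, reads are
#'   simulated from `architecture`.
#' @param architecture [unit_architecture()] used for simulation and as the
#'   source of feature references when `feature_path` is `NULL`.
#' @param feature_path Optional FASTA of feature references with labels
#'   `F18S`, `F5_8S`, `F28S` in the headers.
#' @param rm_a_path,rm_b_path Optional RepeatMasker `.out` files for the TE
#'   orthology stage.
#' @param n_units,flank_length,n_reads,read_length,substitution_rate,insertion_rate,deletion_rate
#'   Simulation parameters.
#' @param anchor_feature Anchor for unit sizing (default `"F18S"`).
#' @param min_identity,min_feature_coverage,min_anchor_coverage,k,subrepeat_k,degenerate_threshold,max_units,bandwidth,size_normal_max,size_large_min
#'   Analysis thresholds; defaults as documented per stage.
#' @param seed Integer seed for every random draw.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reads_path = NULL,
                            architecture = unit_architecture(),
                            feature_path = NULL,
                            rm_a_path = NULL, rm_b_path = NULL,
                            n_units = 10L, flank_length = 2000L,
                            n_reads = 60L, read_length = 40000L,
                            substitution_rate = 0, insertion_rate = 0,
                            deletion_rate = 0,
                            anchor_feature = "F18S",
                            min_identity = 0.75,
                            min_feature_coverage = 0.5,
                            min_anchor_coverage = 0.8,
                            k = 15L, subrepeat_k = 12L,
                            degenerate_threshold = 0.7,
                            max_units = 15L, bandwidth = "auto",
                            size_normal_max = 20000, size_large_min = 30000,
                            seed = 1L, out_dir = tempfile("rdnarray_run_")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @return Character vector of violations, each naming the field and the
#'   constraint; empty when the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  in01 <- function(x) is.numeric(x) && x >= 0 && x <= 1
  chk(in01(config$min_identity), "min_identity not in [0,1]")
  chk(in01(config$min_feature_coverage), "min_feature_coverage not in [0,1]")
  chk(in01(config$min_anchor_coverage), "min_anchor_coverage not in [0,1]")
  chk(in01(config$degenerate_threshold), "degenerate_threshold not in [0,1]")
  chk(config$k >= 8, "k must be >= 8")
  chk(config$subrepeat_k >= 4, "subrepeat_k must be >= 4")
  chk(config$n_units >= 1, "n_units must be >= 1")
  chk(config$n_reads >= 1, "n_reads must be >= 1")
  chk(config$max_units >= 1, "max_units must be >= 1")
  rates <- c(config$substitution_rate, config$insertion_rate,
             config$deletion_rate)
  chk(all(rates >= 0) && all(rates < 1) && sum(rates) < 1,
      "error rates must be in [0,1) with sum < 1")
  chk(config$size_normal_max < config$size_large_min,
      "size-class bounds unordered: normal max must be < large min")
  for (p in c("reads_path", "feature_path", "rm_a_path", "rm_b_path"))
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      v <- c(v, paste0(p, ": file not found: ", config[[p]]))
  v
}

log_stage <- function(verbose, stage, ...) {
  if (verbose)
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    stage, paste(..., collapse = " ")))
}

#' Run the full rDNA analysis pipeline
#'
#' Stages: simulate (when no reads are supplied) -> scan -> size ->
#' consensus -> annotate -> subrepeats -> variance -> TE orthology (when two
#' RepeatMasker files are supplied). Every stage writes its output under
#' `config$out_dir` and the run is fully determined by config + seed.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log each stage with its effective parameters.
#' @return List with `manifest` (data.frame: file, stage, md5), `summary`
#'   (the `rdna_size_summary`), `annotation`, `arrays`, `variance`, and
#'   `te_matching` (NULL when skipped). Fails with the stage name on error.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid config: ", paste(viol, collapse = "; "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(), stage = character(),
                         md5 = character(), stringsAsFactors = FALSE)
  emit <- function(path, stage) {
    manifest <<- rbind(manifest, data.frame(
      file = basename(path), stage = stage,
      md5 = unname(md5sum(path)), stringsAsFactors = FALSE))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- input: simulate or load -------------------------------------------
  truth <- NULL
  if (is.null(config$reads_path)) {
    log_stage(verbose, "simulate", "n_units=", config$n_units,
              "n_reads=", config$n_reads, "seed=", config$seed)
    sim <- stage("simulate", {
      locus <- simulate_locus(config$architecture, config$n_units,
                              config$flank_length, seed = config$seed)
      em <- error_model(config$substitution_rate, config$insertion_rate,
                        config$deletion_rate, config$read_length)
      rd <- simulate_reads(locus$genome, em, config$n_reads,
                           seed = config$seed + 1L)
      list(locus = locus, reads = rd$reads)
    })
    reads <- sim$reads
    truth <- sim$locus$truth
    feature_refs <- truth$feature_refs
    gp <- file.path(config$out_dir, "genome.fasta")
    write_fasta(sim$locus$genome, gp); emit(gp, "simulate")
    rp <- file.path(config$out_dir, "reads.fasta")
    write_fasta(reads, rp); emit(rp, "simulate")
  } else {
    reads <- stage("load_reads", {
      if (grepl("\\.f(ast)?q$", config$reads_path)) read_fastq(config$reads_path)
      else read_fasta(config$reads_path)
    })
    if (is.null(config$feature_path))
      stop("pipeline stage 'load_reads' failed: feature_path is required ",
           "when reads are supplied", call. = FALSE)
    feats <- read_fasta(config$feature_path)
    feature_refs <- setNames(feats$seq, feats$id)
  }

  # --- scan ---------------------------------------------------------------
  log_stage(verbose, "scan", "k=", config$k,
            "min_identity=", config$min_identity)
  hits <- stage("scan", scan_reads(
    reads, feature_refs, k = config$k, min_identity = config$min_identity,
    min_feature_coverage = config$min_feature_coverage))
  hp <- file.path(config$out_dir, "hits.tsv")
  write.table(hits, hp, sep = "\t", quote = FALSE, row.names = FALSE)
  emit(hp, "scan")

  # --- size ---------------------------------------------------------------
  log_stage(verbose, "size", "anchor=", config$anchor_feature)
  obs <- stage("size", measure_all_units(
    hits, config$anchor_feature, config$min_anchor_coverage))
  summ <- stage("size", summarize_sizes(obs, config$bandwidth))
  op <- file.path(config$out_dir, "unit_observations.tsv")
  write.table(obs, op, sep = "\t", quote = FALSE, row.names = FALSE)
  emit(op, "size")
  sp <- file.path(config$out_dir, "size_summary.tsv")
  write.table(data.frame(n = summ$n, mean = summ$mean, sd = summ$sd,
                         primary_peak = summ$primary_peak,
                         bandwidth = summ$bandwidth,
                         size_class = summ$size_class),
              sp, sep = "\t", quote = FALSE, row.names = FALSE)
  emit(sp, "size")

  # --- consensus + annotation --------------------------------------------
  log_stage(verbose, "consensus", "max_units=", config$max_units)
  units <- stage("consensus", extract_rotated_units(
    reads, hits, config$max_units, config$min_anchor_coverage))
  annotation <- NULL
  arrays <- NULL
  if (nrow(units) >= 2L) {
    cons <- stage("consensus", build_consensus(units))
    cp <- file.path(config$out_dir, "consensus.fasta")
    write_fasta(cons, cp); emit(cp, "consensus")
    annotation <- stage("annotate", annotate_unit(cons, feature_refs))
    ap <- file.path(config$out_dir, "annotation.gff3")
    write_gff3(cbind(annotation$intervals,
                     id = annotation$intervals$feature), ap)
    emit(ap, "annotate")
    log_stage(verbose, "subrepeats", "k=", config$subrepeat_k)
    arrays <- stage("subrepeats", detect_tandem_arrays(
      cons$seq[[1]], k = config$subrepeat_k,
      degenerate_threshold = config$degenerate_threshold,
      annotation = annotation))
    arp <- file.path(config$out_dir, "subrepeat_arrays.tsv")
    write.table(arrays, arp, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(arp, "subrepeats")
  }

  # --- variance attribution (needs simulation truth) ----------------------
  variance <- NULL
  if (!is.null(truth) && nrow(truth$units) >= 3L &&
      !is.null(truth$units$subrepeat_bp)) {
    variance <- stage("variance", variance_explained_by_subrepeats(
      truth$units$length, truth$units$subrepeat_bp))
    vp <- file.path(config$out_dir, "variance_attribution.tsv")
    write.table(data.frame(n_units = variance$n_units,
                           var_total = variance$var_total,
                           var_residual = variance$var_residual,
                           fraction_explained = variance$fraction_explained),
                vp, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(vp, "variance")
  }

  # --- TE orthology -------------------------------------------------------
  te_matching <- NULL
  if (!is.null(config$rm_a_path) && !is.null(config$rm_b_path)) {
    log_stage(verbose, "te-ortho")
    te_matching <- stage("te-ortho", {
      a <- filter_and_reconstruct(parse_repeatmasker_out(config$rm_a_path))
      b <- filter_and_reconstruct(parse_repeatmasker_out(config$rm_b_path))
      m <- match_orthologous_tes(a, b)
      rep <- orthology_report(m, a, b, igs_lengths = c(
        if (!is.null(annotation)) annotation$lengths[["IGS"]] else NA,
        if (!is.null(annotation)) annotation$lengths[["IGS"]] else NA))
      tp <- file.path(config$out_dir, "te_orthology.tsv")
      write.table(rep, tp, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(tp, "te-ortho")
      m
    })
  }

  mp <- file.path(config$out_dir, "manifest.tsv")
  write.table(manifest, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(manifest = manifest, summary = summ, observations = obs,
       annotation = annotation, arrays = arrays, variance = variance,
       te_matching = te_matching, truth = truth)
}
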