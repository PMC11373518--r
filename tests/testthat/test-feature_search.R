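test_that("DUST masking agrees with a brute-force window oracle", {
  homo <- strrep("A", 200)
  m <- dust_mask(homo)
  expect_equal(nrow(m), 1L)
  expect_lte(m$start0[1], 1L)
  expect_gte(m$end0[1], 198L)
  oracle <- dust_oracle_windows(homo)
  expect_true(all(oracle))

  # a moderately repetitive stretch inside random sequence: masked windows
  # from the oracle must all fall inside reported intervals
  set.seed(14)
  s <- paste0(rand_seq(150), strrep("CAG", 60), rand_seq(150))
  m2 <- dust_mask(s)
  oracle2 <- dust_oracle_windows(s)
  expect_true(any(oracle2))
  covered <- rep(FALSE, nchar(s))
  for (i in seq_len(nrow(m2))) covered[(m2$start0[i] + 1):m2$end0[i]] <- TRUE
  for (w in which(oracle2)) expect_true(all(covered[w:(w + 63)]))

  # random sequence: oracle and implementation both mask nothing
  r <- rand_seq(500, seed = 15)
  expect_false(any(dust_oracle_windows(r)))
  expect_equal(nrow(dust_mask(r)), 0L)
})

test_that("a 64-mer with all distinct triplets is never masked", {
  s <- distinct_triplet_64mer()
  trips <- substring(s, 1:62, 3:64)
  expect_equal(anyDuplicated(trips), 0L)
  expect_equal(nrow(dust_mask(s)), 0L)
  expect_equal(nrow(dust_mask("")), 0L)
})

test_that("planted exact features are found with identity 1 at the exact interval", {
  ref <- rand_seq(1800, seed = 20)
  read <- data.frame(id = "r1", seq = paste0(rand_seq(500), ref, rand_seq(500)),
                     qual = NA)
  h <- find_feature_hits(read, c(F18S = ref))
  h <- h[h$feature_coverage >= 0.99, ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 500L)
  expect_equal(h$end, 2300L)
  expect_equal(h$strand, "plus")
  expect_equal(h$identity, 1)
  expect_equal(h$feature_coverage, 1)

  # reverse complement: minus strand, mirrored interval
  rc <- data.frame(id = "r1rc", seq = revcomp(read$seq), qual = NA)
  h2 <- find_feature_hits(rc, c(F18S = ref))
  h2 <- h2[h2$feature_coverage >= 0.99, ]
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "minus")
  expect_equal(h2$start, 500L)
  expect_equal(h2$end, 2300L)

  # too-short read: empty result, not an error
  tiny <- data.frame(id = "t", seq = "ACGTACGT", qual = NA)
  expect_equal(nrow(find_feature_hits(tiny, c(F18S = ref))), 0L)
})

test_that("hit identity on substituted copies matches a DP alignment oracle", {
  set.seed(23)
  ref <- rand_seq(1500)
  mutated <- rdnarray:::mutate_substitutions(ref, 0.05)
  read <- data.frame(id = "r", seq = paste0(rand_seq(400), mutated,
                                            rand_seq(400)), qual = NA)
  h <- find_feature_hits(read, c(F18S = ref))
  expect_equal(nrow(h), 1L)
  # oracle: full global alignment of the planted pair, known location
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref), Biostrings::DNAString(mutated),
    type = "global")
  oracle_id <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
  expect_lt(abs(h$identity - oracle_id), 0.02)
  expect_lt(abs(h$identity - 0.95), 0.02)
})

test_that("strand symmetry holds across random reads", {
  ref <- rand_seq(600, seed = 31)
  for (seed in 1:4) {
    set.seed(seed)
    read <- data.frame(id = "r",
                       seq = paste0(rand_seq(300), ref, rand_seq(200),
                                    revcomp(ref), rand_seq(100)), qual = NA)
    L <- nchar(read$seq)
    h <- find_feature_hits(read, c(F28S = ref))
    rc <- data.frame(id = "r", seq = revcomp(read$seq), qual = NA)
    h2 <- find_feature_hits(rc, c(F28S = ref))
    expect_equal(nrow(h), nrow(h2))
    key <- function(x) paste(sort(paste(x$start, x$end)), collapse = ";")
    mirrored <- data.frame(start = L - h2$end, end = L - h2$start)
    expect_equal(key(h), key(mirrored))
    expect_setequal(h2$strand,
                    ifelse(h$strand == "plus", "minus", "plus"))
  }
})

test_that("chaining merges co-linear fragments and is idempotent", {
  base <- data.frame(read_id = "r", feature = "F28S", strand = "plus",
                     identity = c(0.9, 0.95), feature_coverage = c(0.44, 0.53),
                     feature_start = c(0L, 2100L), feature_end = c(2000L, 4500L),
                     feature_length = 4500L, source = "internal",
                     chain_members = 1L, stringsAsFactors = FALSE)
  base$start <- c(100L, 2350L)
  base$end <- c(2200L, 4800L)
  ch <- chain_hits(base)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$chain_members, 2L)
  expect_equal(ch$start, 100L)
  expect_equal(ch$end, 4800L)
  expect_equal(ch$feature_coverage, 4500 / 4500)
  # identity is alignment-length weighted
  expect_equal(ch$identity, (0.9 * 2000 + 0.95 * 2400) / 4400)
  expect_identical(chain_hits(ch), ch)

  # anti-co-linear fragments stay separate
  anti <- base
  anti$feature_start <- c(2100L, 0L)
  anti$feature_end <- c(4500L, 2000L)
  expect_equal(nrow(chain_hits(anti)), 2L)

  # middle fragment on the opposite strand: two chains remain
  three <- base[c(1, 1, 2), ]
  three$start <- c(100L, 1000L, 2350L)
  three$end <- c(950L, 2200L, 4800L)
  three$feature_start <- c(0L, 900L, 2100L)
  three$feature_end <- c(800L, 2000L, 4500L)
  three$strand <- c("plus", "minus", "plus")
  ch3 <- chain_hits(three)
  expect_equal(nrow(ch3), 2L)

  # after chaining, no same-feature same-strand hit intervals overlap
  set.seed(41)
  for (i in 1:5) {
    n <- sample(3:6, 1)
    st <- sort(sample.int(20000L, n))
    raw <- data.frame(read_id = "r", feature = "F18S", strand = "plus",
                      start = st, end = st + sample(500:1500, n, TRUE),
                      identity = runif(n, 0.8, 1),
                      feature_coverage = runif(n, 0.2, 0.6),
                      feature_start = sample.int(1000L, n),
                      feature_end = 0L, feature_length = 1800L,
                      source = "internal", chain_members = 1L)
    raw$feature_end <- raw$feature_start + (raw$end - raw$start)
    ch <- chain_hits(raw)
    if (nrow(ch) > 1L) {
      o <- order(ch$start)
      expect_true(all(ch$start[o][-1] >= ch$end[o][-nrow(ch)]))
    }
  }
})

test_that("BLAST adapter converts coordinates, identity and coverage", {
  line <- "rDNA_18S\tread1\t95.0\t1800\t80\t5\t1\t1800\t100\t1899\t0.0\t3000"
  tab <- parse_blast_tabular(tmp_file(line), "outfmt6")
  fh <- adapt_blast_hits(tab, c(rDNA_18S = "F18S"), c(F18S = 1800L))
  expect_equal(fh$start, 99L)
  expect_equal(fh$end, 1899L)
  expect_equal(fh$strand, "plus")
  expect_equal(fh$identity, 0.95)
  expect_equal(fh$feature_coverage, 1)
  expect_equal(fh$source, "blast_adapter")

  swapped <- "rDNA_18S\tread1\t95.0\t1800\t80\t5\t1\t1800\t1899\t100\t0.0\t3000"
  fh2 <- adapt_blast_hits(parse_blast_tabular(tmp_file(swapped), "outfmt6"),
                          c(rDNA_18S = "F18S"), c(F18S = 1800L))
  expect_equal(fh2$strand, "minus")
  expect_equal(fh2$start, 99L)
  expect_equal(fh2$end, 1899L)

  expect_error(adapt_blast_hits(tab, c(other = "F18S"), c(F18S = 1800L)),
               "rDNA_18S")
})

test_that("adapter and internal matcher agree on exact-copy fixtures", {
  ref <- rand_seq(900, seed = 51)
  read <- data.frame(id = "read1",
                     seq = paste0(rand_seq(250), ref, rand_seq(250)),
                     qual = NA)
  internal <- find_feature_hits(read, c(F18S = ref))
  internal <- internal[internal$feature_coverage >= 0.99, ]
  # the equivalent BLAST line for the planted exact copy (1-based inclusive)
  line <- sprintf("q18S\tread1\t100.0\t900\t0\t0\t1\t900\t%d\t%d\t0.0\t1600",
                  251L, 1150L)
  adapted <- adapt_blast_hits(parse_blast_tabular(tmp_file(line), "outfmt6"),
                              c(q18S = "F18S"), c(F18S = 900L))
  expect_equal(adapted$start, internal$start)
  expect_equal(adapted$end, internal$end)
  expect_equal(adapted$strand, internal$strand)
  expect_equal(adapted$identity, internal$identity)
})

test_that("every planted feature instance in clean reads is found once with identity 1", {
  arch <- unit_architecture(len_igs_core = 550L)  # 9 kb units
  lo <- simulate_locus(arch, 4, 800, seed = 61)
  rd <- simulate_reads(lo$genome, error_model(read_length = 20000), 6,
                       seed = 62)
  hits <- scan_reads(rd$reads, lo$truth$feature_refs["F18S"])
  full <- hits[hits$feature_coverage >= 0.999, ]
  expect_true(all(full$identity == 1))
  # count expected full instances per read from provenance
  for (i in seq_len(nrow(rd$reads))) {
    pr <- rd$provenance[i, ]
    exp_n <- sum(lo$truth$units$start0 >= pr$start0 &
                   lo$truth$units$start0 + 1800 <= pr$end0)
    got <- sum(full$read_id == pr$id)
    expect_equal(got, exp_n)
  }
})
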