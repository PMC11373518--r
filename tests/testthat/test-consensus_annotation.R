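test_that("units are extracted between adjacent 18S anchors and rotated", {
  set.seed(101)
  ref18 <- rand_seq(300)
  unit_rest <- rand_seq(700)
  read_seq <- paste0(rand_seq(500), ref18, unit_rest, ref18, rand_seq(400))
  read <- data.frame(id = "r", seq = read_seq, qual = NA)
  hits <- chain_hits(find_feature_hits(read, c(F18S = ref18), k = 12))
  units <- extract_rotated_units(read, hits)
  expect_equal(nrow(units), 1L)
  expect_equal(nchar(units$seq), 1000L)
  expect_equal(units$start0, 500L)
  expect_true(startsWith(units$seq, ref18))

  # minus-strand array: the unit equals the rc of the source interval
  rc_read <- data.frame(id = "r", seq = revcomp(read_seq), qual = NA)
  rc_hits <- chain_hits(find_feature_hits(rc_read, c(F18S = ref18), k = 12))
  rc_units <- extract_rotated_units(rc_read, rc_hits)
  expect_equal(nrow(rc_units), 1L)
  expect_equal(rc_units$strand, "minus")
  expect_identical(rc_units$seq, units$seq)
})

test_that("unit selection caps at max_units deterministically", {
  set.seed(102)
  ref18 <- rand_seq(200)
  body <- rand_seq(300)
  # 21 anchors -> 20 candidate units on one synthetic read
  read <- data.frame(id = "r",
                     seq = paste0(strrep(paste0(ref18, body), 21), "AC"),
                     qual = NA)
  hits <- chain_hits(find_feature_hits(read, c(F18S = ref18), k = 12))
  u1 <- extract_rotated_units(read, hits, max_units = 15)
  u2 <- extract_rotated_units(read, hits, max_units = 15)
  expect_equal(nrow(u1), 15L)
  expect_identical(u1, u2)
})

test_that("majority-rule consensus calls columns correctly", {
  expect_identical(build_consensus(rep("ACGTACGT", 5))$seq, "ACGTACGT")
  expect_identical(build_consensus(c("ACGT", "ACGT", "ACTT"))$seq, "ACGT")
  expect_warning(one <- build_consensus("ACGT"), "single unit")
  expect_identical(one$seq, "ACGT")
  expect_error(build_consensus(character(0)), "no units")
})

test_that("consensus of noisy copies converges to the true unit", {
  set.seed(103)
  truth <- rand_seq(2000)
  copies <- vapply(1:15, function(i)
    rdnarray:::mutate_substitutions(truth, 0.02), character(1))
  cons <- build_consensus(copies)
  mismatch <- utils::adist(cons$seq, truth)[1, 1] / nchar(truth)
  expect_lt(mismatch, 0.001)
})

test_that("annotation recovers planted region lengths exactly on clean data", {
  arch <- unit_architecture(400L, 200L, 80L, 150L, 600L, 800L)
  lo <- simulate_locus(arch, 1, 0, seed = 104)
  ann <- annotate_unit(lo$genome$seq, lo$truth$feature_refs)
  expect_equal(unname(ann$lengths),
               c(400L, 200L, 80L, 150L, 600L, 800L),
               ignore_attr = TRUE)
  expect_equal(ann$total, 2230L)
  # partition: region lengths always sum to the total
  expect_equal(sum(ann$lengths), ann$total)
})

test_that("IGS length is the remainder after coding and internal spacers", {
  # platypus-like proportions: 38.8 kb unit, 16.5 kb of coding+ITS
  arch <- unit_architecture(1800L, 6800L, 150L, 1250L, 6500L, 22300L)
  lo <- simulate_locus(arch, 1, 0, seed = 105)
  ann <- annotate_unit(lo$genome$seq, lo$truth$feature_refs)
  expect_equal(ann$total, 38800L)
  expect_equal(unname(ann$lengths[["IGS"]]), 22300L)
})

test_that("a missing coding region is a named error", {
  arch <- unit_architecture(400L, 200L, 80L, 150L, 600L, 800L)
  lo <- simulate_locus(arch, 1, 0, seed = 106)
  refs <- lo$truth$feature_refs
  # delete the 5.8S from the unit
  u <- lo$genome$seq
  s58 <- refs[["F5_8S"]]
  u2 <- sub(s58, "", u, fixed = TRUE)
  expect_error(annotate_unit(u2, refs), "5.8S")
})

test_that("rotation start does not change the consensus on clean arrays", {
  arch <- unit_architecture(300L, 150L, 60L, 100L, 400L, 500L)
  lo <- simulate_locus(arch, 4, 300, seed = 107)
  rd <- simulate_reads(lo$genome, error_model(read_length = nchar(lo$genome$seq)),
                       2, seed = 108)
  hits <- scan_reads(rd$reads, lo$truth$feature_refs, k = 12)
  units <- extract_rotated_units(rd$reads, hits, max_units = 6)
  expect_gte(nrow(units), 2L)
  cons <- build_consensus(units)
  true_unit <- substring(lo$genome$seq, lo$truth$units$start0[1] + 1,
                         lo$truth$units$end0[1])
  expect_identical(toupper(cons$seq), toupper(true_unit))
})

test_that("region reports tabulate, sum and survive a GFF3 round trip", {
  arch <- unit_architecture(400L, 200L, 80L, 150L, 600L, 800L)
  lo <- simulate_locus(arch, 1, 0, seed = 109)
  ann <- annotate_unit(lo$genome$seq, lo$truth$feature_refs)
  rep1 <- region_length_report(list(speciesA = ann))
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$total,
               rep1$len_18S + rep1$len_ITS1 + rep1$`len_5.8S` +
                 rep1$len_ITS2 + rep1$len_28S + rep1$len_IGS)
  expect_equal(nrow(region_length_report(list())), 0L)

  # lengths recomputed from written GFF3 equal the report values
  g <- tempfile(fileext = ".gff3")
  iv <- ann$intervals
  iv$id <- iv$feature
  write_gff3(iv, g)
  back <- read_gff3(g)
  expect_equal(setNames(back$end0 - back$start0, back$feature),
               ann$lengths)
})
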