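test_that("self-match maps show tandem structure and exclude the diagonal", {
  set.seed(111)
  motif <- rand_seq(100)
  s <- paste0(rand_seq(200), strrep(motif, 10), rand_seq(200))
  mm <- self_match_map(s)
  expect_true(all(mm$i < mm$j))
  offs <- mm$j - mm$i
  inarray <- mm$i >= 200 & mm$j < 200 + 1000
  expect_true(all(offs[inarray] %% 100 == 0))

  # random sequence: k=12 chance matches are (near-)absent
  r <- rand_seq(5000, seed = 112)
  expect_lte(nrow(self_match_map(r)), 2L)
})

test_that("planted arrays are detected with their exact periods and classes", {
  set.seed(113)
  motif <- rand_seq(105)
  s <- paste0(rand_seq(400), strrep(motif, 10), rand_seq(400))
  arr <- detect_tandem_arrays(s)
  expect_equal(nrow(arr), 1L)
  expect_lte(abs(arr$period - 105L), 1L)
  expect_lt(abs(arr$copy_number - 10), 0.2)
  expect_equal(arr$klass, "subrepeat")

  ms <- paste0(rand_seq(300, seed = 114), strrep("AT", 50),
               rand_seq(300))
  arr_ms <- detect_tandem_arrays(ms)
  expect_equal(arr_ms$period, 2L)
  expect_equal(arr_ms$klass, "microsatellite")
})

test_that("diverged-copy periods agree with an autocorrelation oracle", {
  set.seed(115)
  master <- rand_seq(585)
  copies <- vapply(1:8, function(i)
    rdnarray:::mutate_substitutions(master, 0.12), character(1))
  s <- paste0(rand_seq(500), paste(copies, collapse = ""), rand_seq(500))
  arr <- detect_tandem_arrays(s)
  expect_equal(nrow(arr), 1L)
  expect_lte(abs(arr$period - 585L), 5L)
  oracle_p <- period_oracle(s, 500, 500 + 8 * 585, candidates = 500:700)
  expect_lte(abs(arr$period - oracle_p), 5L)
})

test_that("periods across the spec range are recovered with good spans", {
  for (case in list(c(10, 30, 1), c(25, 20, 2), c(60, 12, 3),
                    c(150, 8, 4), c(300, 6, 5), c(700, 4, 6))) {
    p <- case[1]; ncop <- case[2]; seed <- case[3]
    set.seed(seed)
    master <- rand_seq(p)
    copies <- vapply(seq_len(ncop), function(i)
      rdnarray:::mutate_substitutions(master, 0.10), character(1))
    s <- paste0(rand_seq(300), paste(copies, collapse = ""), rand_seq(300))
    arr <- detect_tandem_arrays(s)
    expect_gte(nrow(arr), 1L)
    best <- arr[which.max(arr$end0 - arr$start0), ]
    # period p itself, or p/m when copies subdivide evenly
    divisors <- p / seq_len(ncop)
    expect_true(min(abs(best$period - divisors)) <= max(2, 0.02 * p))
    planted_len <- ncop * p
    overlap <- min(best$end0, 300 + planted_len) - max(best$start0, 300)
    expect_gte(overlap / planted_len, 0.9)
  }
})

test_that("sub-repeat totals exclude microsatellites and clip to the IGS", {
  arch <- unit_architecture(400L, 200L, 80L, 150L, 600L, 800L)
  lo <- simulate_locus(arch, 1, 0, seed = 116)
  ann <- annotate_unit(lo$genome$seq, lo$truth$feature_refs)
  none <- detect_tandem_arrays(rand_seq(100, seed = 117))
  t0 <- subrepeat_totals(ann, none)
  expect_equal(t0$total_subrepeat_bp, 0L)
  expect_equal(t0$proportion_of_igs, 0)

  igs <- ann$intervals[ann$intervals$feature == "IGS", ]
  arrays <- data.frame(start0 = igs$start0 + 100L,
                       end0 = igs$start0 + 400L,
                       period = 50L, copy_number = 6,
                       mean_adjacent_identity = 0.95, klass = "subrepeat",
                       location_label = "IGS", stringsAsFactors = FALSE)
  t1 <- subrepeat_totals(ann, arrays)
  expect_equal(t1$total_subrepeat_bp, 300L)
  expect_equal(t1$proportion_of_igs, 300 / 800)

  # an array straddling the IGS start is counted by intersection only
  arrays2 <- arrays
  arrays2$start0 <- igs$start0 - 150L
  arrays2$end0 <- igs$start0 + 150L
  t2 <- subrepeat_totals(ann, arrays2)
  expect_equal(t2$igs_subrepeat_bp, 150L)
  expect_equal(t2$total_subrepeat_bp, 300L)

  # microsatellites never count
  msat <- arrays
  msat$klass <- "microsatellite"
  expect_equal(subrepeat_totals(ann, msat)$total_subrepeat_bp, 0L)
})

test_that("variance attribution behaves at both extremes and in between", {
  # only sub-repeat copy number varies: fraction exactly 1
  S <- c(500, 700, 900, 1100, 600)
  L <- 10000 + S
  v1 <- variance_explained_by_subrepeats(L, S)
  expect_equal(v1$fraction_explained, 1)

  # constant sub-repeat totals, other variation: fraction exactly 0
  L2 <- c(10000, 10100, 9900, 10050, 9950)
  v0 <- variance_explained_by_subrepeats(L2, rep(800, 5))
  expect_equal(v0$fraction_explained, 0)

  # planted Var(S) = 9 Var(E): fraction ~ 0.9 within Monte-Carlo spread
  set.seed(118)
  fr <- replicate(20, {
    S <- rnorm(40, 5000, 300)
    E <- rnorm(40, 2000, 100)
    variance_explained_by_subrepeats(10000 + S + E, S)$fraction_explained
  })
  expect_lt(abs(mean(fr) - 0.9), 0.03)

  # invariant under adding a constant to all unit lengths
  v_shift <- variance_explained_by_subrepeats(L + 12345, S)
  expect_equal(v_shift$fraction_explained, v1$fraction_explained)

  # degenerate: no length variation at all
  vna <- variance_explained_by_subrepeats(rep(10000, 4), rep(500, 4))
  expect_true(is.na(vna$fraction_explained))
  expect_error(variance_explained_by_subrepeats(1:2, 1:2), "at least 3")
})

test_that("simulator truth satisfies the exact variance identity", {
  arch <- unit_architecture(
    len_igs_core = 2000L,
    subrepeats = list(subrepeat_spec(100, 5, 15, location = "IGS",
                                     offset = 500)))
  lo <- simulate_locus(arch, 10, 100, seed = 119)
  tr <- lo$truth$units
  v <- variance_explained_by_subrepeats(tr$length, tr$subrepeat_bp)
  expect_equal(v$fraction_explained, 1)
  # Var(L) = period^2 * Var(cn) exactly in truth
  cn <- tr$subrepeat_bp / 100
  expect_equal(v$var_total, 100^2 * var(cn))
})

test_that("resolved arrays never overlap", {
  set.seed(120)
  s <- paste0(rand_seq(200), strrep(rand_seq(50), 8), rand_seq(100),
              strrep("AT", 40), rand_seq(600),
              strrep(rand_seq(120), 6), rand_seq(200))
  arr <- detect_tandem_arrays(s)
  if (nrow(arr) > 1L) {
    o <- order(arr$start0)
    expect_true(all(arr$start0[o][-1] >= arr$end0[o][-nrow(arr)]))
  }
})
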