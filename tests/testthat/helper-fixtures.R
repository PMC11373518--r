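# Shared fixture builders and independent oracles.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

tmp_file <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# --- brute-force DUST oracle -----------------------------------------------
# Independently recomputes the normalized triplet score for every window and
# returns the logical mask over window starts (1-based).
dust_oracle_windows <- function(seq, window = 64L, threshold = 20L) {
  n <- nchar(seq)
  if (n < 3L) return(logical(0))
  ch <- strsplit(toupper(seq), "")[[1]]
  w <- min(window, n)
  nwin <- max(n - w + 1L, 1L)
  out <- logical(nwin)
  for (s in seq_len(nwin)) {
    trip <- vapply(s:(s + w - 3L), function(i)
      paste(ch[i:(i + 2L)], collapse = ""), character(1))
    cts <- table(trip)
    S <- sum(cts * (cts - 1) / 2)
    out[[s]] <- 10 * S / (length(trip) - 1L) > threshold
  }
  out
}

# first 64 bases of the de Bruijn sequence B(4, 3): all 62 overlapping
# triplets of the linear prefix are distinct
distinct_triplet_64mer <- function() {
  k <- 4L; n <- 3L
  a <- integer(k * n)
  out <- integer(0)
  db <- function(t, p) {
    if (t > n) {
      if (n %% p == 0L) out <<- c(out, a[2:(p + 1L)])
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      db(t + 1L, p)
      j <- a[t - p + 1L] + 1L
      while (j <= k - 1L) {
        a[t + 1L] <<- j
        db(t + 1L, t)
        j <- j + 1L
      }
    }
  }
  db(1L, 1L)
  paste(c("A", "C", "G", "T")[out[1:64] + 1L], collapse = "")
}

# --- exhaustive order-preserving TE matching oracle ------------------------
te_match_bruteforce <- function(tok_a, tok_b) {
  na <- length(tok_a); nb <- length(tok_b)
  best <- 0L
  rec <- function(i, j, c) {
    if (c + min(na - i + 1L, nb - j + 1L) <= best) return()
    if (i > na || j > nb) { best <<- max(best, c); return() }
    rec(i + 1L, j, c)  # skip a[i]
    if (j <= nb) {
      for (jj in j:nb) {
        if (tok_a[[i]] == tok_b[[jj]]) rec(i + 1L, jj + 1L, c + 1L)
      }
    }
    best <<- max(best, c)
  }
  rec(1L, 1L, 0L)
  best
}

random_te_table <- function(n, families = c("LINE/L1", "SINE/Alu",
                                            "LTR/ERVL", "DNA/hAT"),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(family = sample(families, n, replace = TRUE),
             orientation = sample(c("plus", "minus"), n, replace = TRUE),
             length = sample(60:900, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# --- Hamming autocorrelation period oracle ---------------------------------
# Brute force over candidate periods: fraction of positions x in the region
# with seq[x] == seq[x + p]; the best-scoring small period is the oracle's
# period estimate.
period_oracle <- function(seq, region_start0, region_end0,
                          candidates = 2:1000) {
  ch <- strsplit(toupper(seq), "")[[1]]
  lo <- region_start0 + 1L
  hi <- region_end0
  scores <- vapply(candidates, function(p) {
    xs <- lo:(hi - p)
    if (length(xs) < 20L) return(0)
    mean(ch[xs] == ch[xs + p])
  }, numeric(1))
  # smallest candidate scoring within 2% of the best (multiples of the true
  # period score equally well)
  top <- max(scores)
  candidates[which(scores >= top - 0.02)][1]
}

# a tiny standard RepeatMasker .out fixture (plus and minus records,
# a short record below the 50 bp filter, and a fragmented LINE around a SINE)
rm_out_fixture <- function() {
  c("   SW  perc perc perc  query     position in query            matching  repeat          position in repeat",
    "score  div. del. ins.  sequence  begin  end    (left)  repeat  class/family  begin  end (left)  ID",
    "",
    "  463  1.3  0.6  1.7  IGS_A  101  1000  (9000)  +  L1MA4  LINE/L1  1  900  (5400)  1",
    "  312  2.0  0.1  0.2  IGS_A  1001  1300  (8700)  +  AluY  SINE/Alu  1  300  (12)  2",
    "  440  1.1  0.4  0.9  IGS_A  1301  3400  (6600)  +  L1MA4  LINE/L1  905  3000  (3300)  1",
    "  210  4.2  0.0  0.3  IGS_A  4000  4039  (5961)  +  MIR  SINE/MIR  1  40  (228)  3",
    "  199  5.0  0.2  0.1  IGS_A  5000  5300  (4700)  C  MLT1A  LTR/ERVL-MaLR  (0)  300  1  4")
}
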