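# The five-row column {L, L, I, -, -} is the canonical worked example of the
# gap-uniqueness rule: L pools to 0.4, I and each gap contribute 0.2.
toy5 <- div_alignment(c(a = "LA", b = "LA", c = "IA", d = "-A", e = "-A"))

test_that("gap-uniqueness frequency map matches the worked example", {
  fr <- column_frequencies(toy5, 1)
  expect_equal(sum(fr$freq), 1, tolerance = 1e-12)
  expect_equal(fr$freq[fr$token == "L"], 0.4)
  expect_equal(fr$freq[fr$token == "I"], 0.2)
  gap_freqs <- fr$freq[grepl("^gap", fr$token)]
  expect_equal(gap_freqs, c(0.2, 0.2))
  expect_equal(column_entropy(toy5, 1), 1.921928, tolerance = 1e-6)
  # hand oracle: -(0.4 log2 0.4 + 3 * 0.2 log2 0.2)
  expect_equal(column_entropy(toy5, 1),
               -(0.4 * log2(0.4) + 3 * 0.2 * log2(0.2)), tolerance = 1e-12)
})

test_that("degenerate columns behave per the definitions", {
  uni <- div_alignment(c(a = "AA", b = "AA", c = "AA"))
  expect_equal(column_entropy(uni, 1), 0)
  # all-gap column of n rows scores exactly log2 n
  gapcol <- div_alignment(c(a = "A-", b = "C-", c = "D-"))
  expect_equal(column_entropy(gapcol, 2), log2(3), tolerance = 1e-12)
  fr <- column_frequencies(gapcol, 2)
  expect_equal(fr$freq, rep(1 / 3, 3))
  # all-distinct residues score log2 n
  dist4 <- div_alignment(c(a = "AX", b = "CX", c = "DX", d = "EX"))
  expect_equal(column_entropy(dist4, 1), 2, tolerance = 1e-12)
  expect_error(column_frequencies(uni, 3), "out of range")
})

test_that("column entropy agrees with a brute-force oracle on random columns", {
  withr::with_seed(101, {
    for (rep in 1:40) {
      aln <- random_alignment(n_rows = sample(2:9, 1), n_cols = 25)
      cols <- sample(aln$n_cols, 25, replace = TRUE)
      m <- do.call(rbind, strsplit(aln$seqs, ""))
      for (cc in cols) {
        expect_equal(column_entropy(aln, cc), entropy_oracle(m[, cc]),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("entropy is bounded by log2(n) and invariant to row permutation", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      aln <- random_alignment(n_rows = sample(3:8, 1), n_cols = 20)
      prof <- entropy_profile(aln)
      expect_true(all(prof$entropy >= 0))
      expect_true(all(prof$entropy <= log2(aln$n_rows) + 1e-12))
      perm <- sample(aln$n_rows)
      aln2 <- div_alignment(
        tibble::tibble(id = aln$ids[perm], residues = aln$seqs[perm]),
        reference_id = aln$reference_id
      )
      expect_equal(entropy_profile(aln2)$entropy, prof$entropy,
                   tolerance = 1e-12)
    }
  })
})

test_that("profile coordinates skip reference gap columns", {
  aln <- div_alignment(c(ref = "A-C", o1 = "AGC", o2 = "AGT"),
                       reference_id = "ref")
  prof <- entropy_profile(aln)
  expect_equal(nrow(prof), 2L)
  expect_equal(prof$column, c(1L, 3L))
  expect_equal(prof$position, c(1L, 2L))
  # ungapped reference: profile covers every column
  aln2 <- div_alignment(c(ref = "ACD", o1 = "AC-"), reference_id = "ref")
  expect_equal(nrow(entropy_profile(aln2)), 3L)
})

test_that("smoothed entropy and local divergence obey their contracts", {
  prof <- structure(tibble::tibble(position = 1:3, column = 1:3,
                                   entropy = c(1, 2, 3)),
                    class = c("div_profile", class(tibble::tibble())))
  expect_equal(smoothed_entropy(prof, 2, 2), 2)
  expect_equal(smoothed_entropy(prof, 1, 3), 2)
  expect_equal(smoothed_entropy(prof, 2, 50), 2.5) # clipped at L
  expect_error(smoothed_entropy(prof, 5, 9), "beyond profile length")
  expect_error(smoothed_entropy(prof, 3, 1), "i <= j")

  v <- withr::with_seed(3, runif(100, 0, 3))
  # LD equals the brute-force window mean, clipped at the ends
  expect_equal(local_divergence(v, 1), mean(v[1:11]))
  expect_equal(local_divergence(v, 13), mean(v[3:23]))
  expect_equal(local_divergence(v, 100), mean(v[90:100]))
  const <- rep(1.5, 50)
  expect_equal(local_divergence(const, c(1, 25, 50)), rep(1.5, 3))
  # smoothing is bounded by the window extremes
  for (k in c(5, 40, 77)) {
    w <- v[max(1, k - 10):min(100, k + 10)]
    ld <- local_divergence(v, k)
    expect_gte(ld, min(w))
    expect_lte(ld, max(w))
  }
})

test_that("divergence feature vector matches its defining identities", {
  v <- withr::with_seed(11, runif(120, 0, 3))
  f <- divergence_features(v, ld_positions = c(1, 13))
  expect_equal(f$Nraw20, mean(v[1:20]))
  expect_equal(f$Nraw40, mean(v[1:40]))
  expect_equal(f$Nraw80_99, mean(v[80:99]))
  expect_equal(f$NCdiff, f$Nraw20 - f$Nraw80_99, tolerance = 1e-15)
  w20 <- sapply(1:101, function(s) mean(v[s:(s + 19)]))
  expect_equal(f$mu20, mean(w20))
  expect_equal(f$sigma20, sqrt(mean((w20 - mean(w20))^2)))
  expect_equal(f$N20, (f$Nraw20 - f$mu20) / f$sigma20)
  expect_equal(f$N80_99, (f$Nraw80_99 - f$mu20) / f$sigma20)
  expect_equal(f$LD_13, mean(v[3:23]))

  # block profile: high N-terminus, zero body
  vb <- c(rep(2, 20), rep(0, 100))
  fb <- divergence_features(vb, ld_positions = integer(0))
  expect_equal(fb$Nraw20, 2)
  expect_equal(fb$Nraw80_99, 0)
  expect_equal(fb$NCdiff, 2)
})

test_that("constant profiles yield zero contrasts and zero z-scores", {
  const <- rep(1.2, 120)
  warns <- capture_warnings(
    f <- divergence_features(const, ld_positions = integer(0))
  )
  expect_length(warns, 3L) # one per z-score
  expect_true(all(grepl("sigma is zero", warns)))
  expect_equal(f$NCdiff, 0)
  expect_equal(f$N20, 0)
  expect_equal(f$N40, 0)
  expect_equal(f$N80_99, 0)
})

test_that("tail window clips for 80 <= L < 99 and short proteins are refused", {
  v <- withr::with_seed(2, runif(90, 0, 2))
  f <- divergence_features(v, ld_positions = integer(0))
  expect_equal(f$Nraw80_99, mean(v[80:90]))
  expect_error(divergence_features(runif(79)), class = "divsig_short_profile")
})
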