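test_that("simulated families are valid alignments and seed-reproducible", {
  fam1 <- simulate_family("MTS", seed = 109)
  fam2 <- simulate_family("MTS", seed = 109)
  expect_identical(fam1$alignment$seqs, fam2$alignment$seqs)
  fam3 <- simulate_family("MTS", seed = 110)
  expect_false(identical(fam1$alignment$seqs, fam3$alignment$seqs))

  p <- simulation_params()
  for (lab in c("MTS", "SP", "CTP", "none")) {
    fam <- simulate_family(lab, p, seed = 7)
    aln <- fam$alignment
    expect_s3_class(aln, "div_alignment") # constructor enforces invariants
    expect_equal(aln$n_rows, p$n_species)
    expect_gte(aln$n_cols, p$length_range[1])
    expect_lte(aln$n_cols, p$length_range[2])
    # reference stays ungapped
    expect_false(grepl("-", aln$seqs[1], fixed = TRUE))
    # written + re-read family parses identically
    f <- tempfile(fileext = ".fasta")
    write_fasta(aln, f)
    back <- read_fasta(f, aligned = TRUE, reference_id = aln$reference_id)
    expect_identical(back$seqs, aln$seqs)
  }
})

test_that("no-signal families with uniform rate have flat divergence profiles", {
  p_flat <- simulation_params(rho = 1, indel_rate = 0)
  withr::with_seed(113, {
    diffs <- replicate(100, {
      fam <- simulate_family("none", p_flat)
      prof <- entropy_profile(fam$alignment)
      smoothed_entropy(prof, 1, 20) - smoothed_entropy(prof, 80, 99)
    })
  })
  expect_lt(abs(mean(diffs)), 0.05) # no systematic N-terminal elevation
})

test_that("MTS families show the N-terminal divergence elevation", {
  withr::with_seed(127, {
    elevated <- replicate(100, {
      fam <- simulate_family("MTS")
      prof <- entropy_profile(fam$alignment)
      mean(local_divergence(prof, 1:20)) > mean(local_divergence(prof, 80:99))
    })
  })
  expect_gte(mean(elevated), 0.95)
})

test_that("CTP families have a longer elevated region than MTS families", {
  # elevated-region length: number of N-terminal positions whose mean
  # divergence across families exceeds the midpoint between the body level
  # and the N-terminal peak
  elev_len <- function(label, n_fam, seed) {
    profs <- withr::with_seed(seed, {
      replicate(n_fam, {
        fam <- simulate_family(label)
        entropy_profile(fam$alignment)$entropy[1:100]
      })
    })
    m <- rowMeans(profs)
    thr <- (max(m[1:60]) + mean(m[70:100])) / 2
    max(which(m > thr))
  }
  l_mts <- elev_len("MTS", 60, seed = 131)
  l_ctp <- elev_len("CTP", 60, seed = 137)
  expect_gt(l_ctp, l_mts)
  expect_lte(l_mts, 30)  # ~20-residue signal
  expect_gte(l_ctp, 40)  # ~50-residue signal
})

test_that("N-terminal divergence increases strictly with the rate multiplier", {
  mean_n20 <- function(rho, seed) {
    p <- simulation_params(rho = rho)
    withr::with_seed(seed, {
      mean(replicate(40, {
        fam <- simulate_family("MTS", p)
        smoothed_entropy(entropy_profile(fam$alignment), 1, 20)
      }))
    })
  }
  n20 <- sapply(c(1, 2, 4), mean_n20, seed = 139)
  expect_true(all(diff(n20) > 0))
})

test_that("dataset simulation honors class counts, ids and file outputs", {
  counts <- c(MTS = 4, SP = 3, none = 5)
  dir <- file.path(tempdir(), "simds")
  ds <- simulate_dataset(counts, seed = 149, dir = dir)
  expect_equal(length(ds$families), 12L)
  expect_equal(as.integer(table(ds$labels$label)[c("MTS", "SP", "none")]),
               unname(counts))
  expect_false(anyDuplicated(ds$labels$id) > 0)
  expect_equal(length(list.files(file.path(dir, "msa"))), 12L)
  labs <- read_labels(file.path(dir, "labels.tsv"))
  expect_equal(labs$id, ds$labels$id)
  prm <- jsonlite::read_json(file.path(dir, "params.json"))
  expect_equal(prm$seed, 149L)
  # master seed reproducibility
  ds2 <- simulate_dataset(counts, seed = 149)
  expect_identical(ds2$families[["MTS_0001"]]$alignment$seqs,
                   ds$families[["MTS_0001"]]$alignment$seqs)
  # empty request
  ds0 <- simulate_dataset(c(MTS = 0), seed = 1)
  expect_equal(length(ds0$families), 0L)
  expect_equal(nrow(ds0$labels), 0L)
})

test_that("feature computation runs end-to-end on simulated data", {
  ds <- simulate_dataset(c(MTS = 6, none = 6), seed = 151)
  ft <- suppressMessages(dataset_features(ds))
  expect_equal(nrow(ft), 12L)
  expect_false(anyNA(ft[, -2]))
  expect_true(all(c("NCdiff", "N20", "pos20", "hphob40", "compf_A") %in%
                    names(ft)))
  # divergence contrast separates the classes on average
  expect_gt(mean(ft$NCdiff[ft$label == "MTS"]),
            mean(ft$NCdiff[ft$label == "none"]))
})
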