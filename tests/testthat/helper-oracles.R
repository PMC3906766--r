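# Independent brute-force oracles, deliberately written from the definitions
# with none of the package's code paths.

# Gap-aware column entropy from a counting dictionary.
entropy_oracle <- function(chars) {
  n <- length(chars)
  counts <- list()
  gap_i <- 0L
  for (ch in chars) {
    key <- if (ch == "-") {
      gap_i <- gap_i + 1L
      paste0("-", gap_i) # every gap is its own character
    } else {
      ch
    }
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  h <- 0
  for (c in counts) {
    f <- c / n
    h <- h - f * log2(f)
  }
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive global alignment: enumerate every alignment (sequence of
# match/insert/delete columns), score each with affine penalties
# (gap of length k costs open + k * ext, end gaps included), return the max.
nw_enum_score <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, moves) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score_moves(moves, ca, cb, mat, open, ext))
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) rec(i + 1L, j + 1L, c(moves, "M"))
    if (i <= length(ca)) rec(i + 1L, j, c(moves, "D"))
    if (j <= length(cb)) rec(i, j + 1L, c(moves, "I"))
  }
  rec(1L, 1L, character(0))
  best
}

score_moves <- function(moves, ca, cb, mat, open, ext) {
  s <- 0
  i <- 1L; j <- 1L
  prev <- ""
  for (m in moves) {
    if (m == "M") {
      s <- s + mat[ca[i], cb[j]]
      i <- i + 1L; j <- j + 1L
    } else {
      if (m != prev) s <- s - open
      s <- s - ext
      if (m == "D") i <- i + 1L else j <- j + 1L
    }
    prev <- m
  }
  s
}

# AUC as explicit pair counting: P(score_pos > score_neg) + 0.5 P(equal).
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# MCC as the Pearson correlation of 0/1 truth/prediction vectors.
mcc_pearson_oracle <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  r <- suppressWarnings(stats::cor(truth, pred))
  if (is.na(r)) 0 else r
}

# Independent Fayyad-Irani MDL discretizer: tries every midpoint between
# adjacent distinct values, picks the partition-entropy minimizer, applies
# the MDL inequality directly, recurses.
ent_oracle <- function(l) {
  p <- table(l)
  p <- p[p > 0] / length(l)
  -sum(p * log2(p))
}

mdl_oracle <- function(values, labels) {
  n <- length(values)
  uv <- sort(unique(values))
  if (length(uv) < 2L) return(numeric(0))
  mids <- (uv[-1] + uv[-length(uv)]) / 2
  went <- sapply(mids, function(t) {
    l <- labels[values <= t]; r <- labels[values > t]
    length(l) / n * ent_oracle(l) + length(r) / n * ent_oracle(r)
  })
  t_best <- mids[which.min(went)]
  l <- labels[values <= t_best]; r <- labels[values > t_best]
  gain <- ent_oracle(labels) - min(went)
  k <- length(unique(labels))
  k1 <- length(unique(l)); k2 <- length(unique(r))
  delta <- log2(3^k - 2) -
    (k * ent_oracle(labels) - k1 * ent_oracle(l) - k2 * ent_oracle(r))
  if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  li <- values <= t_best
  sort(c(mdl_oracle(values[li], labels[li]), t_best,
         mdl_oracle(values[!li], labels[!li])))
}

# Random gapped alignment whose reference row (first) is ungapped.
random_alignment <- function(n_rows = 5L, n_cols = 30L, gap_prob = 0.15) {
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  rows <- vapply(seq_len(n_rows), function(r) {
    ch <- sample(aas, n_cols, replace = TRUE)
    if (r > 1L) {
      gaps <- stats::runif(n_cols) < gap_prob
      ch[gaps] <- "-"
      if (all(gaps)) ch[1] <- sample(aas, 1L)
    }
    paste(ch, collapse = "")
  }, character(1))
  div_alignment(setNames(rows, paste0("s", seq_len(n_rows))))
}

# Linearly separable two-class toy features.
separable_data <- function(n_per = 20L, seed = 1L) {
  withr::with_seed(seed, {
    tibble::tibble(
      label = factor(rep(c("MTS", "none"), each = n_per),
                     levels = c("MTS", "SP", "CTP", "none")),
      f1 = c(rnorm(n_per, -3, 0.3), rnorm(n_per, 3, 0.3)),
      f2 = c(rnorm(n_per, 3, 0.3), rnorm(n_per, -3, 0.3))
    )
  })
}
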