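# Gap-aware column entropy divergence over an ortholog MSA, and the derived
# per-protein divergence features. The key convention: every gap occurrence
# in a column is its own unique character, so gappy columns score as highly
# divergent (each gap contributes frequency exactly 1/n).

#' Per-character frequencies of one alignment column
#'
#' Amino-acid characters are pooled by identity; each gap occurrence is
#' emitted as a distinct token with frequency exactly `1/n_rows`. This is the
#' frequency map underlying the divergence entropy: a column `{L, L, I, -, -}`
#' yields L at 0.4 and three tokens at 0.2 each.
#'
#' @param alignment A [div_alignment()].
#' @param col 1-based column index.
#' @return Tibble with columns `token`, `count`, `freq` (gap tokens are named
#'   `gap1`, `gap2`, ...).
#' @export
column_frequencies <- function(alignment, col) {
  stopifnot(inherits(alignment, "div_alignment"))
  if (length(col) != 1L || col < 1L || col > alignment$n_cols) {
    stop("column index ", col, " out of range [1, ", alignment$n_cols, "]",
         call. = FALSE)
  }
  chars <- substr(alignment$seqs, col, col)
  n <- alignment$n_rows
  gaps <- sum(chars == GAP_CHAR)
  res <- chars[chars != GAP_CHAR]
  out <- tibble(token = character(0), count = integer(0))
  if (length(res)) {
    tab <- table(res)
    out <- tibble(token = names(tab), count = as.integer(tab))
  }
  if (gaps > 0) {
    out <- dplyr::bind_rows(
      out, tibble(token = paste0("gap", seq_len(gaps)), count = 1L)
    )
  }
  out$freq <- out$count / n
  out
}

# Entropy in bits of a frequency vector; 0 log 0 := 0.
shannon_bits <- function(freqs) {
  f <- freqs[freqs > 0]
  -sum(f * log2(f))
}

#' Gap-aware Shannon entropy of one alignment column
#'
#' Computes `H(i) = -sum_j F(i,j) log2 F(i,j)` over the
#' [column_frequencies()] map, in bits. Because each gap is a unique
#' character, the score ranges from 0 (perfectly conserved, no gaps) to
#' `log2(n_rows)` (all characters distinct, e.g. an all-gap column).
#'
#' @inheritParams column_frequencies
#' @return Entropy in bits.
#' @examples
#' aln <- div_alignment(c(a = "L", b = "L", c = "I", d = "-", e = "-"))
#' column_entropy(aln, 1) # 1.921928
#' @export
column_entropy <- function(alignment, col) {
  shannon_bits(column_frequencies(alignment, col)$freq)
}

#' Divergence profile in reference-residue coordinates
#'
#' Computes the gap-aware column entropy for every column in which the
#' reference sequence has a residue, indexed 1..L by reference residue
#' position (columns where the reference is gapped are skipped).
#'
#' @param alignment A [div_alignment()].
#' @return A tibble of class `div_profile` with columns `position` (1-based
#'   reference residue index), `column` (MSA column), `entropy` (bits);
#'   attributes `n_rows` and `reference_id`.
#' @export
entropy_profile <- function(alignment) {
  stopifnot(inherits(alignment, "div_alignment"))
  m <- aln_matrix(alignment)
  n <- alignment$n_rows
  ref <- m[reference_row(alignment), ]
  cols <- which(ref != GAP_CHAR)
  gap_bits <- -log2(1 / n) / n # entropy contribution of one unique gap
  codes <- matrix(match(m, AA_ALLOWED), nrow = n) # gaps become NA
  vals <- vapply(cols, function(j) {
    cj <- codes[, j]
    counts <- tabulate(cj, nbins = length(AA_ALLOWED))
    gaps <- sum(is.na(cj))
    shannon_bits(counts[counts > 0] / n) + gaps * gap_bits
  }, numeric(1))
  out <- tibble(position = seq_along(cols), column = cols, entropy = vals)
  attr(out, "n_rows") <- n
  attr(out, "reference_id") <- alignment$reference_id
  class(out) <- c("div_profile", class(out))
  out
}

profile_values <- function(profile) {
  if (inherits(profile, "data.frame")) profile$entropy else as.numeric(profile)
}

#' Smoothed (window-averaged) entropy
#'
#' Arithmetic mean of the profile over the inclusive interval `[i, j]`,
#' clipped to the profile's extent. This is the smoothing operator behind all
#' interval divergence features.
#'
#' @param profile A `div_profile` (or bare numeric vector of entropies).
#' @param i,j 1-based interval bounds (inclusive); clipped to `[1, L]`.
#' @return Mean entropy over the clipped interval, in bits.
#' @export
smoothed_entropy <- function(profile, i, j) {
  v <- profile_values(profile)
  L <- length(v)
  if (j < i) stop("interval bounds must satisfy i <= j", call. = FALSE)
  lo <- max(1L, as.integer(i))
  hi <- min(L, as.integer(j))
  if (lo > L) {
    stop("interval [", i, ", ", j, "] lies beyond profile length ", L,
         call. = FALSE)
  }
  mean(v[lo:hi])
}

#' Local divergence at a position
#'
#' `LD(k)` is the smoothed entropy over the window `[k - 10, k + 10]`,
#' clipped at the sequence ends.
#'
#' @inheritParams smoothed_entropy
#' @param k 1-based reference residue position.
#' @return Local divergence in bits.
#' @export
local_divergence <- function(profile, k) {
  vapply(k, function(kk) smoothed_entropy(profile, kk - 10L, kk + 10L),
         numeric(1))
}

# Rolling means of all length-w windows fully inside [1, L].
window_means <- function(v, w) {
  L <- length(v)
  if (w > L) return(numeric(0))
  cs <- c(0, cumsum(v))
  (cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
}

#' Per-protein divergence feature vector
#'
#' Summarizes a divergence profile into the interval features used for
#' classification: raw N-terminal window means (`Nraw20` = mean entropy over
#' residues 1-20, `Nraw40` over 1-40, `Nraw80_99` over 80-99), window
#' statistics `mu20`/`sigma20`/`mu40`/`sigma40` (mean and population SD of
#' all length-20 resp. length-40 window means across the whole profile), the
#' N/C contrast `NCdiff = Nraw20 - Nraw80_99`, z-normalized scores
#' `N20 = (Nraw20 - mu20)/sigma20`, `N40 = (Nraw40 - mu40)/sigma40` and
#' `N80_99 = (Nraw80_99 - mu20)/sigma20`, plus local divergence `LD_i` at
#' the requested positions.
#'
#' Proteins shorter than 80 residues have no C-terminal normalization window
#' and raise a condition of class `divsig_short_profile`; for lengths in
#' \[80, 99) the tail window is clipped to `[80, L]`.
#'
#' @param profile A `div_profile`.
#' @param ld_positions Integer positions at which to emit `LD_i` features
#'   (default: the package's standard N-terminal grid).
#' @return One-row tibble of divergence features.
#' @export
divergence_features <- function(profile, ld_positions = default_ld_positions()) {
  v <- profile_values(profile)
  L <- length(v)
  if (L < 80L) {
    stop(structure(
      class = c("divsig_short_profile", "error", "condition"),
      list(message = paste0(
        "profile length ", L, " < 80: no C-terminal normalization window; ",
        "example should be excluded"), call = NULL)
    ))
  }
  nraw20 <- smoothed_entropy(v, 1L, 20L)
  nraw40 <- smoothed_entropy(v, 1L, 40L)
  nraw80_99 <- smoothed_entropy(v, 80L, 99L)
  w20 <- window_means(v, 20L)
  w40 <- window_means(v, 40L)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  mu20 <- mean(w20); sigma20 <- pop_sd(w20)
  mu40 <- mean(w40); sigma40 <- pop_sd(w40)
  zscore <- function(x, mu, sigma, what) {
    # guard against floating-point dust on constant profiles
    if (sigma > 1e-12 * max(1, abs(mu))) return((x - mu) / sigma)
    warning("sigma is zero for ", what, "; z-score set to 0", call. = FALSE)
    0
  }
  out <- tibble(
    Nraw20 = nraw20, Nraw40 = nraw40, Nraw80_99 = nraw80_99,
    mu20 = mu20, sigma20 = sigma20, mu40 = mu40, sigma40 = sigma40,
    NCdiff = nraw20 - nraw80_99,
    N20 = zscore(nraw20, mu20, sigma20, "N20"),
    N40 = zscore(nraw40, mu40, sigma40, "N40"),
    N80_99 = zscore(nraw80_99, mu20, sigma20, "N80_99")
  )
  ld_positions <- ld_positions[ld_positions >= 1 & ld_positions <= L]
  if (length(ld_positions)) {
    ld <- local_divergence(v, as.integer(ld_positions))
    out <- dplyr::bind_cols(
      out, tibble::as_tibble_row(setNames(ld, paste0("LD_", ld_positions)))
    )
  }
  out
}

#' Default local-divergence positions
#'
#' The N-terminal grid at which `LD_i` features are emitted by default:
#' every fourth residue over positions 1-49 plus position 13 (the most
#' informative single local-divergence position in the underlying study).
#'
#' @return Integer vector of positions.
#' @export
default_ld_positions <- function() {
  sort(unique(c(seq(1L, 49L, by = 4L), 13L)))
}
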