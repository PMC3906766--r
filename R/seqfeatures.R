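# Classical sequence features: charged-residue counts, mean Kyte-Doolittle
# hydrophobicity, and amino-acid composition over N-terminal or full-length
# windows of the (unaligned) reference protein.

seq_chars <- function(seq) {
  if (is.data.frame(seq)) seq <- seq$residues[1]
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("empty sequence", call. = FALSE)
  }
  if (grepl("-", seq, fixed = TRUE)) {
    stop("sequence contains gap characters; use the ungapped reference",
         call. = FALSE)
  }
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

window_chars <- function(seq, window = c("first20", "first40", "full")) {
  window <- match.arg(window)
  ch <- seq_chars(seq)
  n <- switch(window, first20 = 20L, first40 = 40L, full = length(ch))
  ch[seq_len(min(n, length(ch)))]
}

#' Count charged residues in an N-terminal window
#'
#' Positively charged residues are R and K; negatively charged are D and E
#' (histidine is not counted). The window is truncated if the sequence is
#' shorter.
#'
#' @param seq Sequence string (or a one-row record tibble).
#' @param window `"first20"` or `"first40"`.
#' @param polarity `"positive"` or `"negative"`.
#' @return Integer count.
#' @export
count_charged <- function(seq, window = "first20",
                          polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  ch <- window_chars(seq, window)
  set <- if (polarity == "positive") CHARGED_POSITIVE else CHARGED_NEGATIVE
  sum(ch %in% set)
}

#' Mean Kyte-Doolittle hydrophobicity of an N-terminal window
#'
#' Arithmetic mean of the per-residue hydropathy values over the window;
#' 'X' residues are excluded from both numerator and denominator.
#'
#' @inheritParams count_charged
#' @return Mean hydropathy (unitless, in \[-4.5, 4.5\]).
#' @export
mean_hydrophobicity <- function(seq, window = "first20") {
  ch <- window_chars(seq, window)
  ch <- ch[ch != "X"]
  if (length(ch) == 0L) {
    stop("window contains only 'X' residues", call. = FALSE)
  }
  mean(KD_HYDROPATHY[ch])
}

#' Amino-acid composition of a window
#'
#' Frequency of each of the 20 standard amino acids among counted residues
#' ('X' excluded); frequencies sum to 1.
#'
#' @inheritParams count_charged
#' @param window `"first20"`, `"first40"`, or `"full"`.
#' @return Named numeric vector of 20 frequencies.
#' @export
aa_composition <- function(seq, window = "full") {
  ch <- window_chars(seq, window)
  ch <- ch[ch != "X"]
  if (length(ch) == 0L) stop("empty window", call. = FALSE)
  counts <- table(factor(ch, levels = AA_STANDARD))
  setNames(as.numeric(counts) / length(ch), AA_STANDARD)
}

#' Classical feature vector for one protein
#'
#' Assembles the physico-chemical and composition features over the
#' N-terminal 20- and 40-residue windows plus full-length composition.
#' Feature names follow the `pos20, neg20, hphob20, comp20_A...comp20_Y,
#' pos40, ..., compf_A...compf_Y` convention ("f" = full length).
#'
#' @inheritParams count_charged
#' @return One-row tibble of 66 classical features.
#' @export
classical_features <- function(seq) {
  out <- list()
  for (w in c("first20", "first40")) {
    tag <- if (w == "first20") "20" else "40"
    out[[paste0("pos", tag)]] <- count_charged(seq, w, "positive")
    out[[paste0("neg", tag)]] <- count_charged(seq, w, "negative")
    out[[paste0("hphob", tag)]] <- mean_hydrophobicity(seq, w)
    comp <- aa_composition(seq, w)
    out <- c(out, setNames(as.list(comp), paste0("comp", tag, "_", names(comp))))
  }
  compf <- aa_composition(seq, "full")
  out <- c(out, setNames(as.list(compf), paste0("compf_", names(compf))))
  tibble::as_tibble_row(out)
}
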