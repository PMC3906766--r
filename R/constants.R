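# Alphabet and scale constants shared across modules.

#' The 20 standard amino acids, alphabetical one-letter codes
#' @keywords internal
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# 'X' (unknown residue) is accepted on input and treated as an ordinary 21st
# character by the entropy score, but excluded from physico-chemical counts
# and composition.
AA_ALLOWED <- c(AA_STANDARD, "X")
GAP_CHAR <- "-"

#' Sorting-signal class vocabulary, in fixed tie-break order
#'
#' Class labels for N-terminal sorting signals: mitochondrial matrix targeting
#' signal (MTS), secretory signal peptide (SP), chloroplast transit peptide
#' (CTP), or no N-terminal signal (none). The order is also the deterministic
#' tie-break order used by the majority classifier.
#'
#' @export
SIGNAL_CLASSES <- c("MTS", "SP", "CTP", "none")

#' Kyte-Doolittle hydropathy index
#'
#' Per-residue hydropathy values from the original 1982 scale, ranging from
#' -4.5 (arginine) to +4.5 (isoleucine).
#'
#' @format Named numeric vector over the 20 standard amino acids.
#' @export
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Charged-residue sets at physiological pH; histidine deliberately excluded.
CHARGED_POSITIVE <- c("R", "K")
CHARGED_NEGATIVE <- c("D", "E")

# Background amino-acid frequencies (Swiss-Prot-like averages), used by the
# synthetic family generator as the neutral composition.
BG_AA_FREQS <- c(
  A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
  Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
  L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
  S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0687
)
BG_AA_FREQS <- BG_AA_FREQS / sum(BG_AA_FREQS)
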