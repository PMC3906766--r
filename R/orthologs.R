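# Reciprocal-best-hit ortholog sets under global alignment similarity.
# Global (not local) alignment is deliberate: differences at the N- or
# C-terminus — where sorting signals live — must count against a candidate
# ortholog.

#' Global alignment scoring parameters
#'
#' Defaults: BLOSUM62, affine gap penalties (open 10, extend 1), end gaps
#' penalized — true global alignment.
#'
#' @param matrix Substitution matrix name (passed to Biostrings).
#' @param gap_open,gap_extend Non-negative gap penalties; a gap of length k
#'   costs `gap_open + k * gap_extend`.
#' @param max_length Guard against accidentally aligning huge sequences.
#' @return A list of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1,
                         max_length = 20000L) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, max_length = max_length),
            class = "align_params")
}

get_submat <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Optimal global alignment similarity score
#'
#' Needleman-Wunsch global alignment score with affine gap penalties and
#' penalized end gaps. Symmetric in its arguments.
#'
#' @param a,b Sequence strings (or one-row record tibbles).
#' @param params An [align_params()].
#' @return Numeric similarity score.
#' @export
global_align_score <- function(a, b, params = align_params()) {
  if (is.data.frame(a)) a <- a$residues[1]
  if (is.data.frame(b)) b <- b$residues[1]
  stopifnot(nzchar(a), nzchar(b))
  if (nchar(a) > params$max_length || nchar(b) > params$max_length) {
    stop("sequence longer than configured maximum (", params$max_length, ")",
         call. = FALSE)
  }
  mat <- get_submat(params$matrix)
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE
  )
}

# All-vs-all score matrix between two proteome tibbles (id, residues).
score_matrix <- function(proteome_a, proteome_b, params) {
  mat <- get_submat(params$matrix)
  a_set <- Biostrings::AAStringSet(setNames(proteome_a$residues, proteome_a$id))
  b_set <- Biostrings::AAStringSet(setNames(proteome_b$residues, proteome_b$id))
  s <- matrix(NA_real_, nrow = length(a_set), ncol = length(b_set),
              dimnames = list(proteome_a$id, proteome_b$id))
  for (i in seq_along(a_set)) {
    s[i, ] <- Biostrings::pairwiseAlignment(
      b_set, a_set[[i]], type = "global", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE
    )
  }
  s
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (P, P') is reported iff P' is the unique best-scoring match of P in
#' proteome B and P is the unique best-scoring match of P' in proteome A.
#' Ties for best hit produce no pair.
#'
#' @param proteome_a,proteome_b Record tibbles (columns `id`, `residues`)
#'   with unique ids.
#' @param params An [align_params()].
#' @return Tibble with columns `id_a`, `id_b`, `score`; a one-to-one partial
#'   matching.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b,
                                 params = align_params()) {
  stopifnot(nrow(proteome_a) > 0, nrow(proteome_b) > 0)
  s <- score_matrix(proteome_a, proteome_b, params)
  unique_argmax <- function(x) {
    m <- max(x)
    idx <- which(x == m)
    if (length(idx) == 1L) idx else NA_integer_
  }
  best_b <- apply(s, 1L, unique_argmax) # best hit in B for each A
  best_a <- apply(s, 2L, unique_argmax) # best hit in A for each B
  pairs <- list()
  for (i in seq_len(nrow(s))) {
    j <- best_b[i]
    if (!is.na(j) && !is.na(best_a[j]) && best_a[j] == i) {
      pairs[[length(pairs) + 1L]] <- tibble(
        id_a = rownames(s)[i], id_b = colnames(s)[j], score = s[i, j]
      )
    }
  }
  if (length(pairs) == 0L) {
    return(tibble(id_a = character(0), id_b = character(0),
                  score = numeric(0)))
  }
  dplyr::bind_rows(pairs)
}

#' Build ortholog sets for a reference proteome
#'
#' Runs reciprocal-best-hit matching of the reference proteome against each
#' other proteome independently, assembles per-reference-protein ortholog
#' sets (the reference plus all of its RBHs), and discards sets smaller than
#' `min_size` sequences.
#'
#' @param reference Record tibble of the reference species proteome.
#' @param others Named list of record tibbles, one per non-reference species.
#' @param params An [align_params()].
#' @param min_size Minimum total sequences per retained set (default 4).
#' @return Tibble with one row per reference protein: `id`, `size`,
#'   `retained`, `members` (list-column of per-species record tibbles).
#'   The retained sets can be materialized with [ortholog_set_records()].
#' @export
build_ortholog_sets <- function(reference, others, params = align_params(),
                                min_size = 4L) {
  stopifnot(is.list(others), length(others) > 0)
  if (is.null(names(others)) || any(names(others) == "")) {
    names(others) <- paste0("species", seq_along(others))
  }
  hits <- purrr::imap(others, function(prot, sp) {
    rb <- reciprocal_best_hits(reference, prot, params)
    if (nrow(rb) == 0L) return(NULL)
    dplyr::left_join(rb, prot[, c("id", "residues")],
                     by = c(id_b = "id")) |>
      dplyr::transmute(id = .data$id_a, species = sp,
                       member_id = .data$id_b, residues = .data$residues)
  })
  hits <- dplyr::bind_rows(hits)
  sets <- purrr::map(reference$id, function(rid) {
    mem <- hits[hits$id == rid, c("species", "member_id", "residues")]
    tibble(
      id = rid, size = nrow(mem) + 1L,
      retained = nrow(mem) + 1L >= min_size,
      members = list(mem)
    )
  })
  out <- dplyr::bind_rows(sets)
  n_drop <- sum(!out$retained)
  if (n_drop > 0) {
    message(n_drop, " ortholog set(s) with fewer than ", min_size,
            " sequences discarded")
  }
  attr(out, "reference") <- reference
  out
}

#' Unaligned records of one ortholog set
#'
#' @param sets Output of [build_ortholog_sets()].
#' @param id Reference protein id.
#' @return Record tibble (reference row first) suitable for [write_fasta()].
#' @export
ortholog_set_records <- function(sets, id) {
  row <- sets[sets$id == id, ]
  if (nrow(row) != 1L) stop("unknown ortholog set: ", id, call. = FALSE)
  ref <- attr(sets, "reference")
  ref_row <- ref[ref$id == id, c("id", "residues")]
  ref_row$species <- "reference"
  mem <- row$members[[1]]
  dplyr::bind_rows(
    ref_row[, c("id", "species", "residues")],
    tibble(id = mem$member_id, species = mem$species, residues = mem$residues)
  )
}
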