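# The ortholog MSA container ("orthoMSA"): a set of equal-length gapped rows
# with one designated reference sequence whose residue coordinates anchor all
# divergence features.

#' Construct an ortholog multiple sequence alignment
#'
#' Bundles equal-length aligned sequences with a designated reference row.
#' All divergence features are reported in the coordinate system of the
#' reference protein's residues.
#'
#' @param seqs Data frame with columns `id`, `residues` (and optionally
#'   `species`), or a named character vector of aligned sequences.
#' @param reference_id Id of the reference row. Defaults to the first row.
#' @return An object of class `div_alignment` with fields `ids`, `species`,
#'   `seqs`, `reference_id`, `n_rows`, `n_cols`.
#' @examples
#' aln <- div_alignment(c(ref = "LLIAA", o1 = "LLI--"))
#' aln$n_cols
#' @export
div_alignment <- function(seqs, reference_id = NULL) {
  if (is.character(seqs)) {
    ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
    seqs <- tibble(id = ids, residues = unname(seqs))
  }
  seqs <- as_tibble(seqs)
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  if (!"species" %in% names(seqs)) seqs$species <- seqs$id
  validate_records(seqs, aligned = TRUE)

  lens <- nchar(seqs$residues)
  if (length(unique(lens)) != 1L) {
    bad <- seqs$id[which(lens != lens[1])[1]]
    stop("unequal row lengths: record '", bad, "' has length ",
         nchar(seqs$residues[seqs$id == bad][1]), " but '", seqs$id[1],
         "' has length ", lens[1], call. = FALSE)
  }
  if (nrow(seqs) < 2L) stop("alignment needs at least 2 rows", call. = FALSE)
  all_gap <- gsub("-", "", seqs$residues) == ""
  if (any(all_gap)) {
    stop("all-gap row: '", seqs$id[all_gap][1], "'", call. = FALSE)
  }
  reference_id <- reference_id %||% seqs$id[1]
  if (sum(seqs$id == reference_id) != 1L) {
    stop("reference_id '", reference_id,
         "' must match exactly one row", call. = FALSE)
  }
  structure(
    list(
      ids = seqs$id, species = seqs$species, seqs = seqs$residues,
      reference_id = reference_id,
      n_rows = nrow(seqs), n_cols = lens[1]
    ),
    class = "div_alignment"
  )
}

#' @export
print.div_alignment <- function(x, ...) {
  cat("<div_alignment> ", x$n_rows, " rows x ", x$n_cols,
      " columns; reference: ", x$reference_id, "\n", sep = "")
  shown <- head(seq_len(x$n_rows), 6L)
  for (i in shown) {
    s <- x$seqs[i]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", x$ids[i], s))
  }
  if (x$n_rows > 6L) cat("  ... ", x$n_rows - 6L, " more rows\n", sep = "")
  invisible(x)
}

# Character matrix view (rows x columns), rownames = ids.
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

reference_row <- function(aln) {
  which(aln$ids == aln$reference_id)
}

# Ungapped reference sequence.
reference_sequence <- function(aln) {
  gsub("-", "", aln$seqs[reference_row(aln)], fixed = TRUE)
}

#' Convert an alignment to a tibble of rows
#' @param x A `div_alignment`.
#' @param ... Unused.
#' @return Tibble with columns `id`, `species`, `residues`.
#' @method as_tibble div_alignment
#' @export
as_tibble.div_alignment <- function(x, ...) {
  tibble(id = x$ids, species = x$species, residues = x$seqs)
}

# Shared record validation for aligned/unaligned sequence tables.
validate_records <- function(seqs, aligned) {
  if (nrow(seqs) == 0L) stop("no sequence records", call. = FALSE)
  if (any(seqs$id == "" | is.na(seqs$id))) stop("empty sequence id", call. = FALSE)
  if (anyDuplicated(seqs$id)) {
    stop("duplicate sequence id: '",
         seqs$id[duplicated(seqs$id)][1], "'", call. = FALSE)
  }
  if (any(seqs$residues == "")) {
    stop("empty sequence: '", seqs$id[seqs$residues == ""][1], "'",
         call. = FALSE)
  }
  ok <- c(AA_ALLOWED, if (aligned) GAP_CHAR)
  for (i in seq_len(nrow(seqs))) {
    chars <- strsplit(seqs$residues[i], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% ok)
    if (length(bad)) {
      stop("illegal residue character '", chars[bad[1]], "' at position ",
           bad[1], " of record '", seqs$id[i], "'", call. = FALSE)
    }
  }
  invisible(seqs)
}
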