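# FASTA / TSV input-output. Parsing of the FASTA container is delegated to
# Biostrings; alphabet and alignment validation is owned here so that errors
# name the offending record and position.

#' Read a FASTA file of protein sequences
#'
#' Reads unaligned protein sequences, or an alignment when `aligned = TRUE`.
#' Sequence letters are upper-cased; a trailing '*' stop character is
#' stripped; a species tag is parsed from headers of the form `id|species` or
#' `id [species]`, otherwise the species defaults to the id.
#'
#' @param path Path to a FASTA file.
#' @param aligned If `TRUE`, validate equal row lengths and return a
#'   [div_alignment()]; otherwise return a tibble of records.
#' @param reference_id Reference row id for aligned input (default: first
#'   record in the file).
#' @return A tibble with columns `id`, `species`, `residues`, or a
#'   `div_alignment` when `aligned = TRUE`.
#' @export
read_fasta <- function(path, aligned = FALSE, reference_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  if (startsWith(trimws(first), ";")) {
    stop("';' comment lines are not supported: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  parsed <- parse_headers(headers)
  residues <- unname(toupper(as.character(set)))
  residues <- sub("\\*$", "", residues)
  recs <- tibble(id = parsed$id, species = parsed$species, residues = residues)
  validate_records(recs, aligned = aligned)
  if (aligned) {
    div_alignment(recs, reference_id = reference_id)
  } else {
    recs
  }
}

parse_headers <- function(headers) {
  headers <- trimws(headers)
  # Bracketed species suffix: "ID description [Genus species]"
  bracket <- regmatches(headers, regexpr("\\[[^]]+\\]$", headers))
  ids <- vapply(strsplit(headers, "[ \t]"), `[[`, "", 1L)
  species <- character(length(headers))
  for (i in seq_along(headers)) {
    h <- headers[i]
    if (grepl("\\[[^]]+\\]$", h)) {
      species[i] <- sub("^.*\\[([^]]+)\\]$", "\\1", h)
    } else if (grepl("\\|", ids[i])) {
      parts <- strsplit(ids[i], "|", fixed = TRUE)[[1]]
      species[i] <- parts[length(parts)]
      ids[i] <- parts[1]
    } else {
      species[i] <- ids[i]
    }
  }
  list(id = ids, species = species)
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble of records (columns `id`, `residues`, optional
#'   `species`) or a [div_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "div_alignment")) seqs <- as_tibble(seqs)
  x <- Biostrings::BStringSet(setNames(seqs$residues, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a label table
#'
#' Reads a two-column TSV mapping reference protein ids to sorting-signal
#' classes (`MTS`, `SP`, `CTP`, `none`). A header row is detected and
#' skipped when its second field is not a valid class label.
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `id` (character) and `label` (factor over
#'   [SIGNAL_CLASSES]).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_names = FALSE, col_types = "cc",
                        progress = FALSE)
  if (nrow(df) == 0L) stop("empty label table: ", path, call. = FALSE)
  names(df) <- c("id", "label")
  if (!df$label[1] %in% SIGNAL_CLASSES &&
      tolower(df$label[1]) %in% c("label", "class")) {
    df <- df[-1, , drop = FALSE]
  }
  bad <- setdiff(unique(df$label), SIGNAL_CLASSES)
  if (length(bad)) {
    stop("unknown class label '", bad[1], "'; allowed labels: ",
         paste(SIGNAL_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate id in label table: '",
         df$id[duplicated(df$id)][1], "'", call. = FALSE)
  }
  tibble(id = df$id, label = factor(df$label, levels = SIGNAL_CLASSES))
}

#' Write and read feature tables
#'
#' A feature table is a tibble with columns `id`, `label` (may be `NA` for
#' unlabeled examples) and one numeric column per feature. The TSV
#' serialization keeps full double precision, so a write/read round trip is
#' lossless to well below 1e-9.
#'
#' @param features Feature tibble; all non-id/label columns must be numeric
#'   with no missing values.
#' @param path Output (or input) path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the feature tibble.
#' @export
write_feature_table <- function(features, path) {
  features <- as_tibble(features)
  if (!"id" %in% names(features)) stop("feature table needs an 'id' column")
  if (!"label" %in% names(features)) features$label <- NA_character_
  feat_cols <- setdiff(names(features), c("id", "label"))
  features <- features[, c("id", "label", feat_cols)]
  num_ok <- vapply(features[feat_cols], is.numeric, logical(1))
  if (!all(num_ok)) {
    stop("non-numeric feature column: '", feat_cols[!num_ok][1], "'")
  }
  if (length(feat_cols) && anyNA(features[feat_cols])) {
    stop("missing feature values; examples with incomplete features must be ",
         "excluded before serialization")
  }
  features$label <- as.character(features$label)
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    label = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  df$label <- factor(df$label, levels = SIGNAL_CLASSES)
  as_tibble(df)
}
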