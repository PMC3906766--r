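# Pipeline glue: one labeled feature row per ortholog MSA.

#' Compute the full feature table for a set of ortholog alignments
#'
#' For each alignment, divergence features are computed from its gap-aware
#' entropy profile and classical features from the ungapped reference
#' sequence. Proteins whose reference is shorter than 80 residues carry no
#' C-terminal normalization window and are excluded (with a message).
#'
#' @param alignments List of [div_alignment()] objects (named by reference id,
#'   or the reference ids are taken from the alignments).
#' @param labels Optional label tibble from [read_labels()]; matched by
#'   reference id. Unmatched ids get `NA` labels.
#' @param ld_positions Positions for `LD_i` features; see
#'   [divergence_features()].
#' @return Feature tibble: `id`, `label`, divergence features, classical
#'   features. Excluded ids are recorded in the `"excluded"` attribute.
#' @export
compute_features <- function(alignments, labels = NULL,
                             ld_positions = default_ld_positions()) {
  if (inherits(alignments, "div_alignment")) alignments <- list(alignments)
  rows <- list()
  excluded <- character(0)
  for (aln in alignments) {
    id <- aln$reference_id
    refseq <- reference_sequence(aln)
    prof <- entropy_profile(aln)
    row <- tryCatch(
      dplyr::bind_cols(
        tibble(id = id),
        divergence_features(prof, ld_positions = ld_positions),
        classical_features(refseq)
      ),
      divsig_short_profile = function(e) NULL
    )
    if (is.null(row)) excluded <- c(excluded, id) else rows[[id]] <- row
  }
  if (length(excluded)) {
    message(length(excluded), " protein(s) shorter than 80 residues excluded: ",
            paste(head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ...")
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) stop("no usable alignments", call. = FALSE)
  if (!is.null(labels)) {
    out <- dplyr::left_join(out, labels, by = "id")
  } else {
    out$label <- factor(NA_character_, levels = SIGNAL_CLASSES)
  }
  out <- dplyr::relocate(out, "id", "label")
  attr(out, "excluded") <- excluded
  out
}

#' Select a named feature set from a feature table
#'
#' Named subsets of the feature columns:
#' * `"div"` — divergence features (`LD_*`, raw/normalized window scores);
#' * `"classical20"` / `"classical40"` — physico-chemical + composition over
#'   the N-terminal 20 resp. 40 residues;
#' * `"classical"` — both N-terminal windows plus full-length composition;
#' * `"combo"` — divergence + classical.
#'
#' @param features Feature tibble (with `id`/`label` columns).
#' @param set Feature set name.
#' @return The feature tibble restricted to `id`, `label` and the selected
#'   feature columns.
#' @export
select_feature_set <- function(features,
                               set = c("combo", "div", "classical20",
                                       "classical40", "classical")) {
  set <- match.arg(set)
  nm <- names(features)
  div_cols <- grep("^(LD_|Nraw|mu(20|40)$|sigma(20|40)$|NCdiff$|N20$|N40$|N80_99$)",
                   nm, value = TRUE)
  c20 <- grep("^(pos20|neg20|hphob20|comp20_)", nm, value = TRUE)
  c40 <- grep("^(pos40|neg40|hphob40|comp40_)", nm, value = TRUE)
  cf <- grep("^compf_", nm, value = TRUE)
  keep <- switch(set,
    div = div_cols,
    classical20 = c20,
    classical40 = c40,
    classical = c(c20, c40, cf),
    combo = c(div_cols, c20, c40, cf)
  )
  features[, c(intersect(c("id", "label"), nm), keep)]
}

#' Names of the divergence feature columns in a feature table
#' @param features Feature tibble.
#' @return Character vector of divergence column names.
#' @export
divergence_columns <- function(features) {
  setdiff(names(select_feature_set(features, "div")), c("id", "label"))
}
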