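# Synthetic ortholog families with the statistical structure the divergence
# method assumes: an N-terminal signal region that evolves faster than the
# protein body, with class-dependent composition. Descendants evolve
# independently down a star phylogeny; substitutions are redraws from the
# class-conditional position frequencies (column heterogeneity is all the
# pipeline consumes, so no rate-matrix CTMC is needed). Indels appear only in
# non-reference rows, keeping the reference ungapped.

#' Simulation parameters for synthetic ortholog families
#'
#' @param n_species Sequences per family (reference + orthologs).
#' @param length_range Protein length drawn uniformly from this range.
#' @param signal_lengths Signal region length per class (none has no
#'   signal region).
#' @param rho Substitution-rate multiplier inside the signal region
#'   (relative to the background rate; >= 1).
#' @param background_rate Per-site substitution probability per star-tree
#'   branch outside the signal region.
#' @param indel_rate Per-site gap probability inside the signal region of
#'   non-reference rows.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(n_species = 11L,
                              length_range = c(150L, 500L),
                              signal_lengths = c(MTS = 20L, SP = 20L,
                                                 CTP = 50L, none = 0L),
                              rho = 4,
                              background_rate = 0.15,
                              indel_rate = 0.05) {
  stopifnot(n_species >= 2, rho >= 1, background_rate >= 0,
            background_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            length_range[1] <= length_range[2],
            max(signal_lengths) < length_range[1])
  structure(list(n_species = as.integer(n_species),
                 length_range = as.integer(length_range),
                 signal_lengths = signal_lengths, rho = rho,
                 background_rate = background_rate,
                 indel_rate = indel_rate),
            class = "simulation_params")
}

# Class-conditional position-specific residue frequencies. The signal-region
# biases mirror the anatomy of real signals: MTS presequences are
# arginine/lysine-rich and depleted of acidic residues; signal peptides have
# a hydrophobic h-region around positions 6-15; chloroplast transit peptides
# are serine-enriched and long.
class_freq_matrix <- function(label, L, params) {
  sl <- params$signal_lengths[[label]] %||% 0L
  freqs <- matrix(rep(BG_AA_FREQS, L), nrow = 20L,
                  dimnames = list(names(BG_AA_FREQS), NULL))
  if (sl > 0) {
    bias <- function(f, up = NULL, up_x = 1, down = NULL, down_x = 1) {
      f[up] <- f[up] * up_x
      f[down] <- f[down] * down_x
      f / sum(f)
    }
    sig <- seq_len(sl)
    if (label == "MTS") {
      freqs[, sig] <- bias(BG_AA_FREQS, up = c("R", "K"), up_x = 3,
                           down = c("D", "E"), down_x = 0.2)
    } else if (label == "SP") {
      h_region <- intersect(6:15, sig)
      freqs[, h_region] <- bias(BG_AA_FREQS, up = c("I", "L", "V", "F"),
                                up_x = 4)
    } else if (label == "CTP") {
      freqs[, sig] <- bias(BG_AA_FREQS, up = "S", up_x = 3,
                           down = c("D", "E"), down_x = 0.5)
    }
  }
  freqs
}

sample_seq <- function(freqs) {
  apply(freqs, 2L, function(f) sample(rownames(freqs), 1L, prob = f))
}

#' Simulate one labeled ortholog family
#'
#' Draws an ancestral sequence from the class-conditional position
#' frequencies, evolves `n_species - 1` orthologs independently (per-site
#' substitution probability = background rate, multiplied by `rho` inside
#' the signal region and capped at 1), adds signal-region gaps to
#' non-reference rows, and returns the family as an already-aligned
#' [div_alignment()] whose reference row is the ungapped ancestral sequence.
#'
#' @param label Class label (`"MTS"`, `"SP"`, `"CTP"`, `"none"`).
#' @param params A [simulation_params()].
#' @param seed Optional seed making the family reproducible.
#' @param id Reference protein id (default derived from the label).
#' @return A `div_family`: list with `label`, `alignment`, `params`, `seed`.
#' @export
simulate_family <- function(label, params = simulation_params(), seed = NULL,
                            id = paste0(label, "_ref")) {
  label <- match.arg(label, SIGNAL_CLASSES)
  run <- function() {
    L <- sample(params$length_range[1]:params$length_range[2], 1L)
    freqs <- class_freq_matrix(label, L, params)
    sl <- params$signal_lengths[[label]] %||% 0L
    rate <- rep(params$background_rate, L)
    if (sl > 0) {
      rate[seq_len(sl)] <- pmin(1, params$background_rate * params$rho)
    }
    ancestor <- sample_seq(freqs)
    rows <- matrix("", nrow = params$n_species, ncol = L)
    rows[1L, ] <- ancestor
    for (s in 2:params$n_species) {
      seq_s <- ancestor
      mut <- runif(L) < rate
      if (any(mut)) {
        seq_s[mut] <- vapply(which(mut), function(p) {
          sample(rownames(freqs), 1L, prob = freqs[, p])
        }, character(1))
      }
      if (sl > 0 && params$indel_rate > 0) {
        gap <- runif(sl) < params$indel_rate
        seq_s[seq_len(sl)][gap] <- GAP_CHAR
      }
      rows[s, ] <- seq_s
    }
    species <- c("reference", sprintf("sp%02d", seq_len(params$n_species - 1L)))
    ids <- c(id, paste0(id, "_", species[-1L]))
    div_alignment(
      tibble(id = ids, species = species,
             residues = apply(rows, 1L, paste, collapse = "")),
      reference_id = id
    )
  }
  aln <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(label = label, alignment = aln, params = params,
                 seed = seed),
            class = "div_family")
}

#' @export
print.div_family <- function(x, ...) {
  cat("<div_family> label ", x$label, "; ", sep = "")
  print(x$alignment)
  invisible(x)
}

#' Simulate a labeled dataset of ortholog families
#'
#' @param class_counts Named integer vector, e.g.
#'   `c(MTS = 100, SP = 100, none = 100)`.
#' @param params A [simulation_params()].
#' @param seed Master seed; per-family seeds are derived from it, so the
#'   whole dataset is reproducible.
#' @param dir Optional output directory: writes `msa/<id>.fasta` per family,
#'   `labels.tsv`, and `params.json`.
#' @return List with `families` (named list of `div_family`) and `labels`
#'   (tibble `id`, `label`).
#' @export
simulate_dataset <- function(class_counts, params = simulation_params(),
                             seed = 1L, dir = NULL) {
  stopifnot(all(names(class_counts) %in% SIGNAL_CLASSES),
            all(class_counts >= 0))
  spec <- rep(names(class_counts), times = class_counts)
  n <- length(spec)
  fam_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n))
  families <- list()
  ids <- character(n)
  for (i in seq_len(n)) {
    lab <- spec[i]
    id <- sprintf("%s_%04d", lab, sum(spec[seq_len(i)] == lab))
    ids[i] <- id
    families[[id]] <- simulate_family(lab, params, seed = fam_seeds[i],
                                      id = id)
  }
  labels <- tibble(id = ids,
                   label = factor(spec, levels = SIGNAL_CLASSES))
  if (!is.null(dir)) {
    msa_dir <- file.path(dir, "msa")
    dir.create(msa_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(families)) {
      write_fasta(families[[id]]$alignment, file.path(msa_dir,
                                                      paste0(id, ".fasta")))
    }
    readr::write_tsv(dplyr::mutate(labels, label = as.character(label)),
                     file.path(dir, "labels.tsv"), progress = FALSE)
    jsonlite::write_json(
      c(unclass(params), list(seed = seed, class_counts = as.list(class_counts))),
      file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA
    )
  }
  list(families = families, labels = labels)
}

#' Feature table of a simulated dataset
#'
#' Convenience wrapper: runs [compute_features()] over the alignments of a
#' [simulate_dataset()] result.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param ... Passed to [compute_features()].
#' @return Labeled feature tibble.
#' @export
dataset_features <- function(dataset, ...) {
  alns <- purrr::map(dataset$families, "alignment")
  compute_features(alns, labels = dataset$labels, ...)
}
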