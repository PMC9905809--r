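# Contact-frequency analysis over structure collections and the
# PB / TB / PTB surface classification, plus sequence consensus.

#' Per-position contact frequencies over a structure collection
#'
#' A groove position counts as contacting in one structure when its minimum
#' heavy-atom distance to the partner chain (peptide or TCR) is at most
#' `threshold` Angstrom (default 4). Frequencies are percentages of the
#' number of structures supplied; positions with no density in a structure
#' count as non-contacting in that structure, keeping the denominator
#' constant across positions.
#'
#' @param entries List of entries, each either a `ProcessedTemplate` (heavy
#'   vs. peptide chains are used) or a list with elements `model`
#'   (`StructureModel`), `heavy` and `partner` (chain ids). All entries must
#'   be renumbered to the common 1..`n_positions` groove frame.
#' @param threshold Contact distance cutoff in Angstrom.
#' @param n_positions Length of the groove frame (default 180, the
#'   alpha-1/alpha-2 region).
#' @return A `ContactProfile`: list with `n_structures`, `freq` (percentage
#'   per position 1..`n_positions`) and `contact_counts`.
#' @export
contact_frequency <- function(entries, threshold = 4.0, n_positions = 180) {
  if (!is.list(entries) || length(entries) == 0) {
    stop("need a non-empty list of structures")
  }
  if (threshold < 0) stop("threshold must be non-negative")
  counts <- integer(n_positions)
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    if (inherits(e, "ProcessedTemplate")) {
      hv <- role_atoms(e, "heavy")
      pt <- role_atoms(e, "peptide")
      id <- e$source_id
    } else if (is.list(e) && !is.null(e$model)) {
      hv <- chain_atoms(e$model, e$heavy)
      pt <- tryCatch(chain_atoms(e$model, e$partner), error = function(err) {
        stop("structure '", e$model$source_id, "' (entry ", k,
             ") has no partner chain '", e$partner, "'", call. = FALSE)
      })
      id <- e$model$source_id
    } else {
      stop("entry ", k, " is neither a ProcessedTemplate nor a ",
           "list(model, heavy, partner)")
    }
    d <- .residue_min_dists(hv, pt)
    pos <- as.integer(names(d))
    ok <- pos >= 1 & pos <= n_positions & d <= threshold
    counts[pos[ok]] <- counts[pos[ok]] + 1L
  }
  structure(list(n_structures = length(entries),
                 freq = 100 * counts / length(entries),
                 contact_counts = counts),
            class = "ContactProfile")
}

#' @export
print.ContactProfile <- function(x, ...) {
  cat("ContactProfile over", x$n_structures, "structures;",
      sum(x$contact_counts > 0), "of", length(x$freq),
      "positions ever in contact\n")
  invisible(x)
}

#' Classify groove positions into PB / TB / PTB surfaces
#'
#' Positions with both peptide- and TCR-contact frequencies above the cutoff
#' are dual peptide-TCR binding (`PTB`); positions contacting only one
#' partner are peptide-only (`PB`) or TCR-only (`TB`); when both frequencies
#' sit below the cutoff the larger one decides (ties favour `PB`); positions
#' never in contact are `unclassified`. A frequency exactly at the cutoff is
#' neither "greater" nor "less" and falls through to the larger-frequency
#' rule.
#'
#' @param pep_freq,tcr_freq Contact frequencies in percent, vectorised.
#' @param cutoff Classification cutoff in percent (default 10).
#' @return Character vector of labels
#'   (`"PB"`, `"TB"`, `"PTB"`, `"unclassified"`).
#' @export
classify_position <- function(pep_freq, tcr_freq, cutoff = 10) {
  n <- max(length(pep_freq), length(tcr_freq))
  pep <- rep_len(pep_freq, n); tcr <- rep_len(tcr_freq, n)
  if (any(pep < 0 | pep > 100 | tcr < 0 | tcr > 100, na.rm = TRUE) ||
      anyNA(pep) || anyNA(tcr)) {
    stop("frequencies must lie in [0, 100]")
  }
  ifelse(pep > cutoff & tcr > cutoff, "PTB",
    ifelse(pep == 0 & tcr == 0, "unclassified",
      ifelse(pep >= tcr, "PB", "TB")))
}

#' Combine peptide and TCR contact profiles into a classification table
#'
#' @param pep_profile,tcr_profile `ContactProfile` objects on the same frame.
#' @param cutoff Classification cutoff in percent.
#' @return Data frame with `position`, `pep_freq`, `tcr_freq`, `label`.
#' @export
classification_table <- function(pep_profile, tcr_profile, cutoff = 10) {
  stopifnot(length(pep_profile$freq) == length(tcr_profile$freq))
  data.frame(
    position = seq_along(pep_profile$freq),
    pep_freq = pep_profile$freq,
    tcr_freq = tcr_profile$freq,
    label = classify_position(pep_profile$freq, tcr_profile$freq, cutoff),
    stringsAsFactors = FALSE
  )
}

#' Consensus and variability across an allele set
#'
#' Each sequence is mapped onto the reference coordinate frame by pairwise
#' global alignment ([align_pair()]); at every reference position the
#' consensus score is the percentage frequency of the modal amino acid among
#' the mapped (non-gap) residues, and variability is `100 - consensus`.
#' Modal ties break alphabetically. Positions covered by no sequence are
#' reported as `NA`, not 0.
#'
#' @param sequences Named character vector (or list) of allele sequences.
#' @param reference Reference sequence (character string) defining the
#'   position frame, e.g. the most common allotype.
#' @param positions Reference positions to report (default 1..180).
#' @return A `ConsensusProfile` data frame with `position`, `modal_aa`,
#'   `consensus`, `variability`, `coverage`.
#' @export
consensus_scores <- function(sequences, reference, positions = NULL) {
  seqs <- vapply(sequences, as.character, character(1))
  if (length(seqs) < 2) stop("need at least 2 sequences")
  reference <- as.character(reference)
  if (is.null(positions)) positions <- seq_len(min(180, nchar(reference)))
  if (max(positions) > nchar(reference)) {
    stop("reference does not cover position ", max(positions))
  }

  L <- length(positions)
  tab <- matrix(0L, nrow = L, ncol = 26,
                dimnames = list(NULL, LETTERS))
  for (s in seqs) {
    m <- align_pair(reference, s)$map
    m <- m[!is.na(m$pos_a) & !is.na(m$pos_b), , drop = FALSE]
    idx <- match(m$pos_a, positions)
    ok <- !is.na(idx)
    aa <- m$aa_b[ok]
    j <- match(aa, LETTERS)
    for (i in seq_along(aa)) {
      tab[idx[ok][i], j[i]] <- tab[idx[ok][i], j[i]] + 1L
    }
  }
  cov <- rowSums(tab)
  modal <- apply(tab, 1, function(r) {
    if (sum(r) == 0) return(NA_character_)
    LETTERS[which.max(r)]          # which.max takes the first = alphabetical
  })
  cons <- ifelse(cov > 0, 100 * apply(tab, 1, max) / cov, NA_real_)
  out <- data.frame(position = positions, modal_aa = modal,
                    consensus = cons, variability = 100 - cons,
                    coverage = cov, stringsAsFactors = FALSE)
  class(out) <- c("ConsensusProfile", class(out))
  out
}
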