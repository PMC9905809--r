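# Groove definition, allele alignment, substitution construction and the
# minimal-set reduction.

#' Amino-acid chemical classes
#'
#' The five-way partition used for the contact potential and for the
#' "different chemical properties" rule of the minimal set: positive
#' \{K,R,H\}, negative \{D,E\}, polar \{S,T,N,Q,Y,C\}, hydrophobic
#' \{A,V,L,I,M,F,W\}, special \{G,P\}.
#'
#' @format Named character vector mapping one-letter codes to class names.
#' @export
AA_CLASSES <- c(
  K = "positive", R = "positive", H = "positive",
  D = "negative", E = "negative",
  S = "polar", T = "polar", N = "polar", Q = "polar", Y = "polar", C = "polar",
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic", I = "hydrophobic",
  M = "hydrophobic", F = "hydrophobic", W = "hydrophobic",
  G = "special", P = "special"
)

#' @rdname AA_CLASSES
#' @param aa One-letter amino-acid code(s); `"X"` (non-standard) maps to `NA`.
#' @export
aa_class <- function(aa) unname(AA_CLASSES[aa])

#' @rdname AA_CLASSES
#' @param from,to One-letter codes of the swapped residues.
#' @return `is_class_change()`: `TRUE` when the residues fall in different
#'   classes with a charged class (positive or negative) on at least one
#'   side -- a charged-for-neutral swap or vice versa.
#' @export
is_class_change <- function(from, to) {
  cf <- aa_class(from); ct <- aa_class(to)
  out <- !is.na(cf) & !is.na(ct) & cf != ct &
    (cf %in% c("positive", "negative") | ct %in% c("positive", "negative"))
  unname(out)
}

#' Define the peptide-binding groove on a template structure
#'
#' The groove is the set of heavy-chain positions whose minimum heavy-atom
#' distance to the bound peptide is at most `cutoff` Angstrom (default 5).
#' Minimum distances are recorded for every position so that stricter
#' per-position thresholds (e.g. the 3.5 Angstrom rule for dual-surface
#' positions) can be applied downstream.
#'
#' @param template A `ProcessedTemplate`.
#' @param cutoff Groove distance cutoff in Angstrom; must be positive.
#' @return A `GrooveDefinition`: list with `template_id`, `positions`
#'   (integer vector) and `min_dist` (named numeric over all positions).
#' @export
define_groove <- function(template, cutoff = 5.0) {
  if (!is.finite(cutoff) && !is.infinite(cutoff)) stop("bad cutoff")
  if (cutoff <= 0) stop("groove cutoff must be positive")
  hv <- role_atoms(template, "heavy")
  pt <- role_atoms(template, "peptide")
  d <- .residue_min_dists(hv, pt)
  pos <- as.integer(names(d))
  o <- order(pos)
  d <- d[o]; pos <- pos[o]
  inside <- pos[d <= cutoff]
  if (length(inside) == 0) {
    stop("no groove residue within ", cutoff,
         " Angstrom of the peptide; is the peptide chain correct?")
  }
  md <- as.numeric(d); names(md) <- pos
  structure(list(template_id = template$source_id,
                 positions = inside, min_dist = md),
            class = "GrooveDefinition")
}

#' @export
print.GrooveDefinition <- function(x, ...) {
  cat("GrooveDefinition [", x$template_id, "]: ",
      length(x$positions), " positions: ",
      paste(x$positions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Global pairwise alignment of two allele sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (BLOSUM62, gap open
#' 10, gap extend 0.5 -- the EMBOSS Needle defaults), via
#' `Biostrings::pairwiseAlignment`. Returns the per-position correspondence
#' between the two sequences, with `NA` marking gap columns.
#'
#' @param a,b Sequences (character strings, or `AAString`).
#' @param gap_open,gap_extend Affine gap penalties.
#' @return A `PairAlignment`: list with `score` and `map`, a data frame with
#'   columns `pos_a`, `pos_b`, `aa_a`, `aa_b` (one row per alignment column).
#' @export
align_pair <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend)
  sa <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  pos_a <- ifelse(sa == "-", NA_integer_, cumsum(sa != "-"))
  pos_b <- ifelse(sb == "-", NA_integer_, cumsum(sb != "-"))
  structure(list(
    score = Biostrings::score(pa),
    map = data.frame(pos_a = pos_a, pos_b = pos_b,
                     aa_a = ifelse(sa == "-", NA, sa),
                     aa_b = ifelse(sb == "-", NA, sb),
                     stringsAsFactors = FALSE)),
    class = "PairAlignment")
}

#' Construct base-to-template groove substitutions
#'
#' For every groove position where the template (groove) allele and the base
#' allele carry different residues, emits one substitution from the base
#' residue to the template residue. Positions are reported in base-allele
#' mature-protein numbering; groove positions aligned opposite a gap are
#' skipped with a warning.
#'
#' @param groove A `GrooveDefinition` in the template-allele frame.
#' @param template_allele,base_allele Sequences (character strings); named
#'   values or a `name` attribute supply allotype labels.
#' @param mapping Optional `PairAlignment` of template vs. base (computed if
#'   missing).
#' @return A `SubstitutionSet` data frame with columns `position` (base
#'   numbering), `template_position`, `from_aa`, `to_aa`, `min_dist`,
#'   `class_change`, plus attributes `template_name`, `base_name`.
#' @export
build_substitutions <- function(groove, template_allele, base_allele,
                                mapping = NULL) {
  tname <- .allele_name(template_allele, "template")
  bname <- .allele_name(base_allele, "base")
  tseq <- as.character(template_allele); bseq <- as.character(base_allele)
  if (is.null(mapping)) mapping <- align_pair(tseq, bseq)
  m <- mapping$map

  rows <- list()
  for (p in groove$positions) {
    col <- m[!is.na(m$pos_a) & m$pos_a == p, , drop = FALSE]
    if (nrow(col) == 0 || is.na(col$pos_b[1])) {
      warning("groove position ", p,
              " maps to a gap in the base allele; skipped", call. = FALSE)
      next
    }
    to <- col$aa_a[1]; from <- col$aa_b[1]
    if (from == to) next
    rows[[length(rows) + 1]] <- data.frame(
      position = col$pos_b[1], template_position = p,
      from_aa = from, to_aa = to,
      min_dist = unname(groove$min_dist[as.character(p)]),
      class_change = is_class_change(from, to),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), template_position = integer(),
               from_aa = character(), to_aa = character(),
               min_dist = numeric(), class_change = logical(),
               stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "template_name") <- tname
  attr(out, "base_name") <- bname
  class(out) <- c("SubstitutionSet", class(out))
  out
}

.allele_name <- function(x, fallback) {
  nm <- names(x)
  if (!is.null(nm) && nzchar(nm[1])) return(nm[1])
  at <- attr(x, "name")
  if (!is.null(at)) return(at)
  fallback
}

#' Render / parse compact substitution notation
#'
#' `substitution_string()` renders a `SubstitutionSet` as `"G62Q, K66N, ..."`
#' (from-residue, base position, to-residue); `parse_substitutions()` reads
#' the same notation back into a data frame.
#'
#' @param subs A `SubstitutionSet`.
#' @export
substitution_string <- function(subs) {
  paste0(subs$from_aa, subs$position, subs$to_aa, collapse = ", ")
}

#' @rdname substitution_string
#' @param s Compact string, e.g. `"G62Q,K66N"`.
#' @export
parse_substitutions <- function(s) {
  parts <- trimws(strsplit(s, ",")[[1]])
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([A-Z])(\\d+)([A-Z])$", parts))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stop("cannot parse substitution(s): ",
                     paste(parts[bad], collapse = ", "))
  out <- data.frame(
    position = as.integer(vapply(m, `[`, character(1), 3)),
    from_aa = vapply(m, `[`, character(1), 2),
    to_aa = vapply(m, `[`, character(1), 4),
    stringsAsFactors = FALSE)
  out$class_change <- is_class_change(out$from_aa, out$to_aa)
  class(out) <- c("SubstitutionSet", class(out))
  out
}

#' Apply substitutions to a base allele
#'
#' Builds the chimeric sequence by replacing the base residue with the
#' template residue at every substitution position. Each substitution's
#' `from_aa` must match the base sequence (guards against stale lists).
#'
#' @param base_allele Base sequence (character string; name gives the label).
#' @param subs A `SubstitutionSet` (possibly a masked subset).
#' @param groove_name Template-allele label for the `"GROOVE-BASE"` design
#'   name; defaults to the set's `template_name` attribute.
#' @return A `ChimeraDesign`: list with `base`, `substitutions`,
#'   `chimera_seq`, `name`.
#' @export
apply_substitutions <- function(base_allele, subs, groove_name = NULL) {
  bname <- .allele_name(base_allele, "base")
  if (is.null(groove_name)) {
    groove_name <- attr(subs, "template_name") %||% "groove"
  }
  seq <- strsplit(as.character(base_allele), "")[[1]]
  if (nrow(subs) > 0) {
    if (max(subs$position) > length(seq)) {
      stop("substitution position ", max(subs$position),
           " beyond base sequence length ", length(seq))
    }
    mism <- seq[subs$position] != subs$from_aa
    if (any(mism)) {
      stop("base residue mismatch at position(s) ",
           paste(subs$position[mism], collapse = ", "),
           ": expected ", paste(subs$from_aa[mism], collapse = ", "),
           ", found ", paste(seq[subs$position][mism], collapse = ", "))
    }
    seq[subs$position] <- subs$to_aa
  }
  structure(list(base = as.character(base_allele),
                 base_name = bname,
                 substitutions = subs,
                 chimera_seq = paste(seq, collapse = ""),
                 name = paste0(groove_name, "-", bname)),
            class = "ChimeraDesign")
}

#' @export
print.ChimeraDesign <- function(x, ...) {
  cat("ChimeraDesign ", x$name, ": ", nrow(x$substitutions),
      " substitution(s)", sep = "")
  if (nrow(x$substitutions) > 0) {
    cat(" [", substitution_string(x$substitutions), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reduce a substitution set to a minimal set
#'
#' A substitution is retained when it changes the chemical character of the
#' position (charged for neutral or vice versa -- always included) or when
#' its enrichment score among the lowest-energy variants reaches
#' `theta_enrich`. With `exclude_similar = TRUE`, swaps within the same
#' chemical class are additionally excluded regardless of enrichment.
#' Substitutions at dual peptide-TCR (PTB) positions are only ever
#' considered when the position has a heavy atom within `ptb_dist` (3.5
#' Angstrom) of the peptide.
#'
#' @param subs A `SubstitutionSet` with `min_dist` and `class_change`.
#' @param enrichment An `EnrichmentTable` (or named numeric keyed by
#'   position); must cover every substitution position.
#' @param classes Optional named character vector of surface labels keyed by
#'   position (from [classify_position()]); positions without a label are
#'   treated as non-PTB.
#' @param theta_enrich Enrichment threshold (default 0.5).
#' @param ptb_dist Stringent peptide-distance threshold for PTB positions.
#' @param exclude_similar Drop same-class swaps even when enriched.
#' @return The retained rows of `subs` (a `SubstitutionSet`).
#' @export
minimal_set <- function(subs, enrichment, classes = NULL,
                        theta_enrich = 0.5, ptb_dist = 3.5,
                        exclude_similar = FALSE) {
  if (nrow(subs) == 0) return(subs)
  e <- if (inherits(enrichment, "data.frame")) {
    stats::setNames(enrichment$score, enrichment$position)
  } else enrichment
  sc <- e[as.character(subs$position)]
  if (anyNA(sc)) {
    stop("missing enrichment entry for position(s) ",
         paste(subs$position[is.na(sc)], collapse = ", "))
  }
  similar <- aa_class(subs$from_aa) == aa_class(subs$to_aa)
  keep_chem <- subs$class_change
  keep_enrich <- sc >= theta_enrich
  if (exclude_similar) keep_enrich <- keep_enrich & !similar
  keep <- keep_chem | keep_enrich

  if (!is.null(classes)) {
    lab <- classes[as.character(subs$position)]
    is_ptb <- !is.na(lab) & lab == "PTB"
    keep <- keep & (!is_ptb | subs$min_dist <= ptb_dist)
  }
  out <- subs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
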