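# Peptide-specificity summaries (PSSM, Shannon information content, logo
# heights) and TCR-surface phylogenetics (p-distance + neighbor joining).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Position-specific scoring matrix from a binder list
#'
#' Column frequencies with a symmetric pseudocount:
#' `freq = (count + alpha) / (n + 20 * alpha)`.
#'
#' @param peptides Character vector of equal-length peptide sequences
#'   (canonical alphabet).
#' @param alpha Pseudocount (default 0.05).
#' @return A `PSSM`: list with `length`, `n`, `alpha` and `freq`
#'   (positions x 20 matrix; rows sum to 1).
#' @export
build_pssm <- function(peptides, alpha = 0.05) {
  peptides <- toupper(as.character(peptides))
  if (length(peptides) < 1) stop("need at least one peptide")
  L <- unique(nchar(peptides))
  if (length(L) != 1) {
    stop("peptides have ragged lengths: ", paste(L, collapse = ", "))
  }
  M <- do.call(rbind, strsplit(peptides, ""))
  if (!all(M %in% AA20)) {
    stop("non-canonical residue(s): ",
         paste(unique(M[!(M %in% AA20)]), collapse = ", "))
  }
  n <- length(peptides)
  freq <- t(apply(M, 2, function(col) {
    (tabulate(match(col, AA20), 20) + alpha) / (n + 20 * alpha)
  }))
  dimnames(freq) <- list(seq_len(L), AA20)
  structure(list(length = L, n = n, alpha = alpha, freq = freq),
            class = "PSSM")
}

#' Shannon information content and logo heights
#'
#' Per-position information content
#' `ic = log2(20) + sum_a f_a log2 f_a` (bits, 0 for a uniform column,
#' log2(20) for a single residue); logo heights are `freq * ic`.
#'
#' @param pssm A `PSSM` (or a bare frequency matrix with rows summing
#'   to 1).
#' @return A `LogoMatrix`: list with `ic` (bits per position) and
#'   `heights` (positions x 20).
#' @export
information_content <- function(pssm) {
  freq <- if (inherits(pssm, "PSSM")) pssm$freq else as.matrix(pssm)
  plogp <- ifelse(freq > 0, freq * log2(freq), 0)
  ic <- log2(20) + rowSums(plogp)
  structure(list(ic = ic, heights = freq * ic), class = "LogoMatrix")
}

#' p-distance over TCR-contact positions
#'
#' Pairwise fraction of TCR-binding (TB) positions at which two alleles
#' carry different residues. When a reference sequence is given, each
#' allele is first mapped onto the reference frame by global alignment;
#' otherwise positions index the sequences directly.
#'
#' @param alleles Named character vector of allele sequences.
#' @param tb_positions Integer positions of the TCR-contact surface (in the
#'   reference frame).
#' @param reference Optional reference sequence for position mapping.
#' @return A `TcrSurfaceMatrix`: list with `taxa` and symmetric distance
#'   matrix `D` (entries in [0, 1], zero diagonal).
#' @export
tcr_surface_distance <- function(alleles, tb_positions, reference = NULL) {
  seqs <- vapply(alleles, as.character, character(1))
  taxa <- names(seqs)
  if (is.null(taxa) || any(!nzchar(taxa))) {
    taxa <- paste0("allele", seq_along(seqs))
  }
  tb_positions <- sort(unique(as.integer(tb_positions)))
  res <- matrix(NA_character_, length(seqs), length(tb_positions))
  for (k in seq_along(seqs)) {
    if (is.null(reference)) {
      if (nchar(seqs[k]) < max(tb_positions)) {
        stop("allele '", taxa[k], "' does not cover position ",
             max(tb_positions))
      }
      res[k, ] <- strsplit(seqs[k], "")[[1]][tb_positions]
    } else {
      m <- align_pair(reference, seqs[k])$map
      m <- m[!is.na(m$pos_a), , drop = FALSE]
      aa <- m$aa_b[match(tb_positions, m$pos_a)]
      if (anyNA(aa)) {
        stop("allele '", taxa[k], "' has a gap at TB position(s) ",
             paste(tb_positions[is.na(aa)], collapse = ", "))
      }
      res[k, ] <- aa
    }
  }
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) {
      D[i, j] <- D[j, i] <- mean(res[i, ] != res[j, ])
    }
  }
  structure(list(taxa = taxa, D = D), class = "TcrSurfaceMatrix")
}

# move the deficit of a negative branch onto its sister branch
# (standard NJ post-processing), then floor at zero
.clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sisters <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sisters) > 0) {
      tree$edge.length[sisters[1]] <-
        tree$edge.length[sisters[1]] + tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree of a TCR-surface distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via `ape::nj`) on the p-distance
#' matrix; negative branch lengths are clamped to zero with the deficit
#' moved to the sister branch. The unrooted tree is returned as a newick
#' string with branch lengths.
#'
#' @param x A `TcrSurfaceMatrix`, `dist` or symmetric matrix.
#' @param file Optional path to also write the newick string to.
#' @return Newick string (invisibly carries the `phylo` tree as attribute
#'   `tree`).
#' @export
nj_tree <- function(x, file = NULL) {
  D <- if (inherits(x, "TcrSurfaceMatrix")) x$D else as.matrix(x)
  if (nrow(D) < 3) {
    stop("need at least 3 taxa for a neighbor-joining tree")
  }
  tree <- .clamp_negative_branches(ape::nj(D))
  nwk <- ape::write.tree(tree)
  if (!is.null(file)) writeLines(nwk, file)
  attr(nwk, "tree") <- tree
  nwk
}
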