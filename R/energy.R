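# Deterministic fixed-backbone scoring: a residue-class contact potential
# evaluated on side-chain interaction centers (C-beta proxies) of the
# template geometry. Energies are in arbitrary units; only rankings matter.
# An adapter contract lets an external all-atom scorer take this stage over.

CLASS_NAMES <- c("positive", "negative", "polar", "hydrophobic", "special")

#' Parameters of the class-pair contact potential
#'
#' The potential rewards charge complementarity and hydrophobic packing and
#' penalises like charges and steric clashes: for interaction-center pairs
#' within `contact_cutoff` Angstrom the class-pair energy applies
#' ((+,-) = -2, (+,+) = (-,-) = +2, hydrophobic-hydrophobic = -1,
#' polar-polar = polar-charged = -0.5, hydrophobic-charged = +0.5, all
#' pairs involving special residues and hydrophobic-polar = 0), and pairs
#' closer than `clash_cutoff` additionally pay `clash_penalty`.
#'
#' @param contact_cutoff Interaction-center distance cutoff (Angstrom).
#' @param clash_cutoff Clash distance (Angstrom); must be below
#'   `contact_cutoff`.
#' @param clash_penalty Energy added per clashing pair.
#' @param intra_min_separation Minimum sequence separation for intra-chain
#'   pairs entering the total energy.
#' @param class_matrix Optional symmetric 5x5 matrix (dimnames =
#'   positive/negative/polar/hydrophobic/special) overriding the default.
#' @return An `EnergyParams` list.
#' @export
default_energy_params <- function(contact_cutoff = 8.0, clash_cutoff = 3.0,
                                  clash_penalty = 10.0,
                                  intra_min_separation = 3,
                                  class_matrix = NULL) {
  if (is.null(class_matrix)) {
    M <- matrix(0, 5, 5, dimnames = list(CLASS_NAMES, CLASS_NAMES))
    M["positive", "negative"] <- M["negative", "positive"] <- -2.0
    M["positive", "positive"] <- M["negative", "negative"] <- 2.0
    M["hydrophobic", "hydrophobic"] <- -1.0
    M["polar", "polar"] <- -0.5
    M["polar", "positive"] <- M["positive", "polar"] <- -0.5
    M["polar", "negative"] <- M["negative", "polar"] <- -0.5
    M["hydrophobic", "positive"] <- M["positive", "hydrophobic"] <- 0.5
    M["hydrophobic", "negative"] <- M["negative", "hydrophobic"] <- 0.5
    class_matrix <- M
  }
  stopifnot(isTRUE(all.equal(class_matrix, t(class_matrix))),
            clash_cutoff > 0, contact_cutoff > clash_cutoff)
  structure(list(class_matrix = class_matrix,
                 contact_cutoff = contact_cutoff,
                 clash_cutoff = clash_cutoff,
                 clash_penalty = clash_penalty,
                 intra_min_separation = intra_min_separation),
            class = "EnergyParams")
}

#' Class-pair contact energy for one residue pair
#'
#' Vectorised over residues and distances. Non-standard residues (`"X"`)
#' score zero everywhere, including clashes.
#'
#' @param aa1,aa2 One-letter codes.
#' @param dist Center-center distance(s), Angstrom.
#' @param params An `EnergyParams` list.
#' @return Numeric energy (arbitrary units).
#' @export
pair_energy <- function(aa1, aa2, dist, params = default_energy_params()) {
  n <- max(length(aa1), length(aa2), length(dist))
  aa1 <- rep_len(aa1, n); aa2 <- rep_len(aa2, n); dist <- rep_len(dist, n)
  if (any(dist < 0)) stop("negative distance")
  c1 <- aa_class(aa1); c2 <- aa_class(aa2)
  e <- numeric(n)
  ok <- !is.na(c1) & !is.na(c2) & dist <= params$contact_cutoff
  if (any(ok)) {
    e[ok] <- params$class_matrix[cbind(c1[ok], c2[ok])] +
      ifelse(dist[ok] < params$clash_cutoff, params$clash_penalty, 0)
  }
  e
}

# ideal tetrahedral C-beta from backbone N, CA, C
# (bond 1.53 Angstrom, N-CA-CB = C-CA-CB = 110.5 degrees, L-chirality)
.reconstruct_cb <- function(n, ca, c, bond = 1.53, angle = 110.5) {
  b1 <- n - ca; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c - ca; b2 <- b2 / sqrt(sum(b2^2))
  u <- b1 + b2; u <- u / sqrt(sum(u^2))
  perp <- c(b2[2] * b1[3] - b2[3] * b1[2],      # b2 x b1: L-chirality
            b2[3] * b1[1] - b2[1] * b1[3],
            b2[1] * b1[2] - b2[2] * b1[1])
  perp <- perp / sqrt(sum(perp^2))
  cosT <- cos(angle * pi / 180)
  alpha <- -cosT / sum(u * b1)     # component along -u fixing both angles
  alpha <- min(1, alpha)
  beta <- sqrt(max(0, 1 - alpha^2))
  ca + bond * (-alpha * u + beta * perp)
}

#' Side-chain interaction centers of a template
#'
#' One 3-vector per residue: the C-beta coordinate when present, the
#' C-alpha for glycine, and otherwise an ideal C-beta reconstructed from
#' the backbone N, CA, C by the standard tetrahedral construction
#' (bond 1.53 Angstrom, angle 110.5 degrees). Centers depend only on the
#' template geometry (fixed backbone), never on a threaded sequence.
#'
#' @param template A `ProcessedTemplate`.
#' @return List with `groove` and `peptide` coordinate matrices (rows
#'   named by position).
#' @export
interaction_centers <- function(template) {
  one_chain <- function(atoms) {
    ids <- sort(unique(atoms$seq_id))
    out <- matrix(NA_real_, length(ids), 3,
                  dimnames = list(ids, c("x", "y", "z")))
    for (i in seq_along(ids)) {
      r <- atoms[atoms$seq_id == ids[i] & !atoms$is_h, , drop = FALSE]
      get <- function(nm) {
        k <- which(r$elety == nm)
        if (length(k) == 0) NULL else as.numeric(r[k[1], c("x", "y", "z")])
      }
      cb <- get("CB")
      if (!is.null(cb)) { out[i, ] <- cb; next }
      ca <- get("CA")
      if (r$aa[1] == "G") {
        if (is.null(ca)) stop("residue ", ids[i], " lacks CA")
        out[i, ] <- ca
        next
      }
      nn <- get("N"); cc <- get("C")
      if (is.null(nn) || is.null(ca) || is.null(cc)) {
        stop("residue ", ids[i], " (", r$aa[1],
             ") lacks backbone atoms needed to place its C-beta")
      }
      out[i, ] <- .reconstruct_cb(nn, ca, cc)
    }
    out
  }
  list(groove = one_chain(role_atoms(template, "heavy")),
       peptide = one_chain(role_atoms(template, "peptide")))
}

# pairwise distance matrix between two coordinate matrices
.dist_mat <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# Precompute geometry-derived contact pair lists for a template.
# Sequence-independent: reused across all threaded variants.
.energy_geometry <- function(template, params) {
  ctr <- interaction_centers(template)
  G <- ctr$groove; P <- ctr$peptide
  gpos <- as.integer(rownames(G)); ppos <- as.integer(rownames(P))

  Dbind <- .dist_mat(P, G)
  bind <- which(Dbind <= params$contact_cutoff, arr.ind = TRUE)
  bind_pairs <- data.frame(pep = ppos[bind[, 1]], groove = gpos[bind[, 2]],
                           dist = Dbind[bind])

  intra <- function(M, pos) {
    D <- .dist_mat(M, M)
    sep <- abs(outer(pos, pos, "-"))
    idx <- which(D <= params$contact_cutoff &
                 sep >= params$intra_min_separation &
                 upper.tri(D), arr.ind = TRUE)
    data.frame(i = pos[idx[, 1]], j = pos[idx[, 2]], dist = D[idx])
  }
  list(centers = ctr,
       bind_pairs = bind_pairs,
       intra_groove = intra(G, gpos),
       intra_pep = intra(P, ppos),
       gpos = gpos, ppos = ppos)
}

#' Thread a sequence onto the template and score it
#'
#' Fixed-backbone scoring: the groove and peptide sequences are threaded
#' onto the template's interaction centers and scored with the class-pair
#' contact potential. The binding energy `E_bind` is the sum over
#' peptide-groove center pairs within the contact cutoff; the total energy
#' adds intra-chain pairs separated by at least `intra_min_separation`
#' positions in sequence. Fully deterministic.
#'
#' @param template A `ProcessedTemplate`.
#' @param groove_seq Groove sequence (length = number of groove residues).
#' @param pep_seq Peptide sequence (length = peptide length).
#' @param params An `EnergyParams` list.
#' @param geometry Optional precomputed result of the internal geometry
#'   scan (for repeated scoring of one template).
#' @return A `VariantModel`: list with `sequence`, `pep_seq`, `E_bind`,
#'   `E_total`.
#' @export
thread_and_score <- function(template, groove_seq, pep_seq,
                             params = default_energy_params(),
                             geometry = NULL) {
  if (is.null(geometry)) geometry <- .energy_geometry(template, params)
  g <- strsplit(groove_seq, "")[[1]]
  p <- strsplit(pep_seq, "")[[1]]
  if (length(g) != length(geometry$gpos)) {
    stop("groove sequence length ", length(g), " != ",
         length(geometry$gpos), " groove residues")
  }
  if (length(p) != length(geometry$ppos)) {
    stop("peptide sequence length ", length(p), " != ",
         length(geometry$ppos), " peptide residues")
  }
  bp <- geometry$bind_pairs
  e_bind <- sum(pair_energy(p[bp$pep], g[bp$groove], bp$dist, params))
  ig <- geometry$intra_groove
  ip <- geometry$intra_pep
  e_total <- e_bind +
    sum(pair_energy(g[ig$i], g[ig$j], ig$dist, params)) +
    sum(pair_energy(p[ip$i], p[ip$j], ip$dist, params))
  structure(list(sequence = groove_seq, pep_seq = pep_seq,
                 E_bind = e_bind, E_total = e_total),
            class = "VariantModel")
}

#' Adapter contract for an external structure-based scorer
#'
#' Wraps a shell command into a scorer function usable by [score_all()].
#' The command template may contain the placeholders `{groove_seq}`,
#' `{pep_seq}` and `{template_pdb}`; it must print two numbers
#' (`E_total E_bind`) on stdout. A non-zero exit or unparsable output is
#' reported as a per-variant failure; the pipeline continues with the
#' remaining variants.
#'
#' @param command Command template string.
#' @return A function `(groove_seq, pep_seq, template) -> list(E_total,
#'   E_bind)` suitable as the `scorer` argument of [score_all()].
#' @export
make_command_scorer <- function(command) {
  force(command)
  function(groove_seq, pep_seq, template) {
    pdb <- tempfile(fileext = ".pdb")
    on.exit(unlink(pdb), add = TRUE)
    write_structure(template, pdb)
    cmd <- gsub("{groove_seq}", groove_seq, command, fixed = TRUE)
    cmd <- gsub("{pep_seq}", pep_seq, cmd, fixed = TRUE)
    cmd <- gsub("{template_pdb}", pdb, cmd, fixed = TRUE)
    out <- suppressWarnings(system(cmd, intern = TRUE))
    st <- attr(out, "status")
    if (!is.null(st) && st != 0) stop("external scorer exited with ", st)
    v <- suppressWarnings(as.numeric(strsplit(trimws(out[length(out)]),
                                              "\\s+")[[1]]))
    if (length(v) < 2 || anyNA(v[1:2])) {
      stop("external scorer output not parseable: ", out[length(out)])
    }
    list(E_total = v[1], E_bind = v[2])
  }
}
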