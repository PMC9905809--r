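# Structure input/output and geometric primitives.
#
# Structures are held as a flat atom table (one row per atom) wrapped in the
# S3 class "StructureModel"; a preprocessed design template (groove + peptide,
# renumbered from 1) is the subclass "ProcessedTemplate". Parsing of PDB and
# mmCIF files is delegated to bio3d.

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a macromolecular structure
#'
#' Reads a PDB or mmCIF file into a [StructureModel]: a flat atom table with
#' one-letter residue codes (non-standard residues become `"X"`), element
#' symbols and a hydrogen flag so that heavy-atom selections are explicit.
#' Alternate locations are resolved to the highest-occupancy atom (ties:
#' first in file order); insertion codes are resolved into a strictly
#' increasing per-chain residue numbering.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension).
#' @param source_id Identifier stored on the model; defaults to the file
#'   base name.
#' @return A `StructureModel`: list with elements `source_id` and `atoms`
#'   (data frame with columns `chain`, `role`, `seq_id`, `aa`, `resid`,
#'   `elety`, `element`, `is_h`, `x`, `y`, `z`, `o`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE)),
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (is.null(source_id)) {
    source_id <- sub("\\.[^.]*$", "", basename(path))
  }
  atoms <- .atoms_from_bio3d(raw$atom)
  model <- new_structure_model(source_id, atoms)
  if (!any(.is_protein_chain(model))) {
    stop("no protein chains in '", path,
         "' (only waters/heteroatoms found)", call. = FALSE)
  }
  model
}

# Convert a bio3d atom table to the internal representation.
.atoms_from_bio3d <- function(at) {
  if (is.null(at) || nrow(at) == 0) stop("empty structure: no atom records")
  at$chain[is.na(at$chain) | at$chain == ""] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc: keep highest occupancy per (chain, resno, insert, atom name);
  # ties broken by file order (stable order of which(...))
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  dup_keys <- unique(key[duplicated(key)])
  for (k in dup_keys) {
    idx <- which(key == k)
    best <- idx[which.max(at$o[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]

  # residue numbering: per chain, residues in file order; if insertion codes
  # are present the chain is re-sequenced from its first residue number so
  # that seq_id is strictly increasing, otherwise author numbering is kept
  seq_id <- integer(nrow(at))
  for (ch in unique(at$chain)) {
    sel <- at$chain == ch
    rk <- paste(at$resno[sel], at$insert[sel], sep = "\r")
    uk <- unique(rk)
    if (any(at$insert[sel] != "")) {
      first <- at$resno[sel][1]
      ids <- seq(first, length.out = length(uk))
    } else {
      ids <- at$resno[sel][!duplicated(rk)]
    }
    seq_id[sel] <- ids[match(rk, uk)]
  }

  element <- at$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(at))
  miss <- is.na(element) | element == ""
  if (any(miss)) {
    element[miss] <- vapply(at$elety[miss], function(e) {
      tryCatch(bio3d::atom2ele(e), error = function(err) "C",
               warning = function(w) suppressWarnings(bio3d::atom2ele(e)))
    }, character(1))
  }
  element <- toupper(element)

  aa <- suppressWarnings(bio3d::aa321(at$resid))
  aa[is.na(aa)] <- "X"
  aa[at$resid %in% WATER_RESIDUES] <- "X"

  data.frame(
    chain = at$chain,
    role = "other",
    seq_id = seq_id,
    aa = aa,
    resid = at$resid,
    elety = at$elety,
    element = element,
    is_h = element %in% c("H", "D"),
    x = at$x, y = at$y, z = at$z,
    o = at$o,
    stringsAsFactors = FALSE
  )
}

#' @rdname read_structure
#' @param source_id Structure identifier.
#' @param atoms Atom table (see [read_structure()] for columns).
#' @export
new_structure_model <- function(source_id, atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  if (anyNA(atoms[, c("x", "y", "z")]) ||
      !all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  structure(list(source_id = source_id, atoms = atoms),
            class = "StructureModel")
}

.is_protein_chain <- function(model) {
  vapply(chain_ids(model), function(ch) {
    a <- model$atoms[model$atoms$chain == ch, ]
    any(a$elety == "CA" & !(a$resid %in% WATER_RESIDUES))
  }, logical(1))
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel '", x$source_id, "': ", sep = "")
  for (ch in chain_ids(x)) {
    a <- x$atoms[x$atoms$chain == ch, ]
    cat(sprintf("[%s:%s %d res] ", ch, a$role[1],
                length(unique(a$seq_id))))
  }
  cat("\n")
  invisible(x)
}

#' Chain and residue accessors
#'
#' @param model A `StructureModel`.
#' @return `chain_ids()`: chain identifiers; `chain_atoms()`: atom table of
#'   one chain; `residue_atoms()`: atom table of one residue;
#'   `chain_sequence()`: one-letter sequence of a chain.
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' @rdname chain_ids
#' @param chain Chain identifier.
#' @export
chain_atoms <- function(model, chain) {
  a <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0) stop("no chain '", chain, "' in ", model$source_id)
  a
}

#' @rdname chain_ids
#' @param seq_id Residue number within the chain.
#' @export
residue_atoms <- function(model, chain, seq_id) {
  a <- chain_atoms(model, chain)
  r <- a[a$seq_id == seq_id, , drop = FALSE]
  if (nrow(r) == 0) stop("no residue ", seq_id, " in chain '", chain, "'")
  r
}

#' @rdname chain_ids
#' @export
chain_sequence <- function(model, chain) {
  a <- chain_atoms(model, chain)
  a <- a[!(a$resid %in% WATER_RESIDUES), , drop = FALSE]
  paste(a$aa[!duplicated(a$seq_id)], collapse = "")
}

#' Write a structure as PDB
#'
#' @param model A `StructureModel` (or `ProcessedTemplate`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$seq_id, chain = a$chain, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   o = a$o, b = rep(0, nrow(a)))
  invisible(path)
}

#' Extract and renumber the design template (groove + peptide)
#'
#' Retains the alpha-1/alpha-2 groove region of the heavy chain (its first
#' `groove_span` residues, renumbered 1..`groove_span`) and the bound peptide
#' chain (renumbered 1..n); every other chain, all waters and all cofactors
#' are dropped. This is the geometric substrate for groove definition,
#' threading and scoring.
#'
#' @param model A `StructureModel`.
#' @param heavy_chain Chain id of the MHC heavy chain.
#' @param peptide_chain Chain id of the bound peptide.
#' @param groove_span Number of heavy-chain residues to keep (default 180,
#'   the alpha-1/alpha-2 region).
#' @param skip_leading Number of leading heavy-chain residues to discard
#'   before counting (e.g. an uncleaved expression tag).
#' @param peptide_length_range Allowed peptide length; set wider to override
#'   the canonical 8-15 window.
#' @return A `ProcessedTemplate` (subclass of `StructureModel`) with exactly
#'   two chains, roles `"heavy"` and `"peptide"`, and fields `groove_len`,
#'   `pep_len`.
#' @export
preprocess_template <- function(model, heavy_chain, peptide_chain,
                                groove_span = 180, skip_leading = 0,
                                peptide_length_range = c(8, 15)) {
  hv <- chain_atoms(model, heavy_chain)
  pp <- chain_atoms(model, peptide_chain)

  take_protein <- function(a) {
    a <- a[!(a$resid %in% WATER_RESIDUES), , drop = FALSE]
    # amino-acid residues only: require a CA atom
    ca_res <- unique(a$seq_id[a$elety == "CA"])
    a[a$seq_id %in% ca_res, , drop = FALSE]
  }
  hv <- take_protein(hv)
  pp <- take_protein(pp)
  if (nrow(pp) == 0) stop("peptide chain '", peptide_chain, "' has no residues")

  hres <- unique(hv$seq_id)
  if (skip_leading > 0) hres <- hres[-seq_len(skip_leading)]
  if (length(hres) < groove_span) {
    stop("heavy chain '", heavy_chain, "' has ", length(hres),
         " residues after skipping; cannot truncate to groove_span = ",
         groove_span)
  }
  hres <- hres[seq_len(groove_span)]
  hv <- hv[hv$seq_id %in% hres, , drop = FALSE]
  hv$seq_id <- match(hv$seq_id, hres)           # renumber 1..groove_span
  hv$role <- "heavy"

  pres <- unique(pp$seq_id)
  n <- length(pres)
  if (n < peptide_length_range[1] || n > peptide_length_range[2]) {
    stop("peptide length ", n, " outside allowed range [",
         peptide_length_range[1], ", ", peptide_length_range[2], "]")
  }
  pp$seq_id <- match(pp$seq_id, pres)           # renumber 1..n
  pp$role <- "peptide"

  out <- new_structure_model(model$source_id, rbind(hv, pp))
  out$groove_len <- groove_span
  out$pep_len <- n
  class(out) <- c("ProcessedTemplate", class(out))
  out
}

#' @export
print.ProcessedTemplate <- function(x, ...) {
  cat("ProcessedTemplate '", x$source_id, "': groove ", x$groove_len,
      " res, peptide ", x$pep_len, " res (",
      chain_sequence(x, x$atoms$chain[x$atoms$role == "peptide"][1]),
      ")\n", sep = "")
  invisible(x)
}

#' @rdname chain_ids
#' @param role Chain role (`"heavy"` or `"peptide"`).
#' @export
role_atoms <- function(model, role) {
  a <- model$atoms[model$atoms$role == role, , drop = FALSE]
  if (nrow(a) == 0) stop("no chain with role '", role, "'")
  a
}

# ---- distance primitives -------------------------------------------------

# minimum Euclidean distance between two coordinate matrices (rows = points)
.min_dist_xyz <- function(A, B) {
  # |a-b|^2 = |a|^2 + |b|^2 - 2 a.b ; numerically safe for Angstrom scales
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}

.heavy_xyz <- function(atoms) {
  h <- atoms[!atoms$is_h, c("x", "y", "z"), drop = FALSE]
  as.matrix(h)
}

#' Minimum heavy-atom distance between a residue and a chain
#'
#' Hydrogens (and deuteriums) are excluded on both sides.
#'
#' @param res Atom table of a single residue (e.g. from [residue_atoms()]).
#' @param partner Atom table of the partner chain.
#' @return Minimum Euclidean distance in Angstrom.
#' @export
min_heavy_atom_distance <- function(res, partner) {
  A <- .heavy_xyz(res)
  B <- .heavy_xyz(partner)
  if (nrow(A) == 0) stop("residue has no heavy atoms")
  if (nrow(B) == 0) stop("partner chain has no heavy atoms")
  .min_dist_xyz(A, B)
}

# per-residue minimum heavy-atom distance from every residue of `atoms`
# to the chain `partner`; returns a named vector indexed by seq_id
.residue_min_dists <- function(atoms, partner) {
  A <- atoms[!atoms$is_h, , drop = FALSE]
  B <- .heavy_xyz(partner)
  if (nrow(A) == 0 || nrow(B) == 0) stop("no heavy atoms for distance scan")
  M <- as.matrix(A[, c("x", "y", "z")])
  d2 <- outer(rowSums(M^2), rowSums(B^2), "+") - 2 * tcrossprod(M, B)
  dmin <- sqrt(pmax(0, apply(d2, 1, min)))
  out <- tapply(dmin, A$seq_id, min)
  v <- as.numeric(out)
  names(v) <- names(out)
  v
}

# ---- superposition -------------------------------------------------------

# Kabsch: proper rotation R and translation mapping mov onto ref
# (both n x 3, rows paired). Returns list(R, center_mov, center_ref).
.kabsch <- function(ref, mov) {
  cm <- colMeans(mov); cr <- colMeans(ref)
  P <- sweep(mov, 2, cm); Q <- sweep(ref, 2, cr)
  H <- crossprod(P, Q)               # t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)          # P %*% R approx Q
  list(R = R, center_mov = cm, center_ref = cr)
}

.apply_fit <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$center_mov) %*% fit$R, 2, fit$center_ref, "+")
}

# pair heavy atoms of two atom tables by (role, seq_id, atom name)
.pair_atoms <- function(a_ref, a_mov, warn = TRUE, context = "atoms") {
  kr <- paste(a_ref$role, a_ref$seq_id, a_ref$elety, sep = "\r")
  km <- paste(a_mov$role, a_mov$seq_id, a_mov$elety, sep = "\r")
  common <- intersect(kr, km)
  if (warn && (length(common) < length(kr) || length(common) < length(km))) {
    miss <- union(setdiff(kr, km), setdiff(km, kr))
    warning(length(miss), " unpaired ", context,
            " dropped from RMSD selection (e.g. ",
            paste(utils::head(gsub("\r", "/", miss), 3), collapse = ", "),
            ")", call. = FALSE)
  }
  list(ref = as.matrix(a_ref[match(common, kr), c("x", "y", "z")]),
       mov = as.matrix(a_mov[match(common, km), c("x", "y", "z")]),
       keys = common)
}

#' Superpose two templates and measure RMSD
#'
#' Performs a least-squares rigid-body (Kabsch) superposition of `mov` onto
#' `ref` over the fit selection, then reports the root-mean-square deviation
#' over the measurement selection. Atoms are paired by renumbered residue id
#' and atom name; atoms missing from either structure are dropped pairwise
#' with a warning. The rotation is always proper (determinant +1).
#'
#' @param ref,mov `ProcessedTemplate` objects.
#' @param fit_selection Atoms used for the superposition; currently
#'   `"groove_CA"` (alpha-carbons of the groove).
#' @param rmsd_selection Atoms over which RMSD is reported:
#'   `"peptide_backbone"` (peptide N, CA, C, O), `"peptide_all_heavy"`, or
#'   `"all"` (all heavy atoms of groove and peptide).
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(ref, mov, fit_selection = "groove_CA",
                           rmsd_selection = c("peptide_backbone",
                                              "peptide_all_heavy", "all")) {
  fit_selection <- match.arg(fit_selection)
  rmsd_selection <- match.arg(rmsd_selection)

  fr <- role_atoms(ref, "heavy"); fm <- role_atoms(mov, "heavy")
  fr <- fr[fr$elety == "CA" & !fr$is_h, ]
  fm <- fm[fm$elety == "CA" & !fm$is_h, ]
  fit_pairs <- .pair_atoms(fr, fm, warn = FALSE)
  if (length(fit_pairs$keys) < nrow(fr) || length(fit_pairs$keys) < nrow(fm)) {
    un <- setdiff(union(fr$seq_id, fm$seq_id),
                  as.integer(sub("^heavy\r(\\d+)\r.*$", "\\1",
                                 fit_pairs$keys)))
    stop("fit selections differ; unmatched groove CA residues: ",
         paste(utils::head(un, 10), collapse = ", "))
  }
  if (nrow(fit_pairs$ref) < 3) stop("need at least 3 fit atoms")
  fit <- .kabsch(fit_pairs$ref, fit_pairs$mov)

  sel <- function(model) {
    a <- switch(rmsd_selection,
      peptide_backbone = {
        p <- role_atoms(model, "peptide")
        p[p$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
      },
      peptide_all_heavy = role_atoms(model, "peptide"),
      all = model$atoms)
    a[!a$is_h, , drop = FALSE]
  }
  mp <- .pair_atoms(sel(ref), sel(mov), context = rmsd_selection)
  if (nrow(mp$ref) == 0) stop("empty RMSD selection")
  moved <- .apply_fit(mp$mov, fit)
  sqrt(mean(rowSums((mp$ref - moved)^2)))
}
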