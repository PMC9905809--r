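# Deterministic synthetic-structure and allele-family generators with
# machine-readable planted ground truth. Toy complexes use idealised
# straight C-alpha traces (3.8 Angstrom spacing): contact geometry, not
# secondary structure, drives every computation in this package, so planted
# side-chain pseudo-atoms at exact prescribed distances are sufficient to
# exercise the full workflow without downloading real structures.
#
# Layout (before the seed-derived rigid transform): the groove trace runs
# along x at y = 0 with backbone N/C offset in +z and side-chain centers at
# +1.5 z; the peptide trace is parallel at y = 20 with centers pointing away
# (+y); an optional TCR trace sits at y = -20. A planned peptide contact
# (g, p, d) places a pseudo-atom of groove residue g exactly d Angstrom
# from the C-alpha of peptide residue p, along y; neighbouring atoms are
# strictly farther by construction, so the planted value IS the minimum
# heavy-atom distance. A planned TCR contact (g, d) adds a TCR atom d below
# the C-alpha of groove residue g.

.CA_STEP <- 3.8

#' Specification for the synthetic-complex generators
#'
#' @param seed Integer seed; drives a rigid transform of all coordinates
#'   (ground-truth distances are invariant) and any sequence sampling.
#' @param groove_len,pep_len Chain lengths (defaults 60 and 9).
#' @param groove_seq,pep_seq Optional sequences (default poly-alanine).
#' @param contact_plan Data frame `groove_pos`, `pep_pos`, `dist`, optional
#'   `atom` (pseudo-atom name, default `"SG"`; `"CB"` replaces the default
#'   side-chain center of that groove residue).
#' @param tcr_plan Optional data frame `groove_pos`, `dist` of planted
#'   TCR contacts.
#' @param tcr_len Length of the TCR pseudo-chain (only if `tcr_plan` given).
#' @param extra_chains Add a light-chain stand-in and a water chain
#'   (for preprocessing tests).
#' @return A `FixtureSpec` list.
#' @export
fixture_spec <- function(seed = 1, groove_len = 60, pep_len = 9,
                         groove_seq = NULL, pep_seq = NULL,
                         contact_plan = NULL, tcr_plan = NULL,
                         tcr_len = 10, extra_chains = FALSE) {
  if (is.null(groove_seq)) groove_seq <- strrep("A", groove_len)
  if (is.null(pep_seq)) pep_seq <- strrep("A", pep_len)
  stopifnot(nchar(groove_seq) == groove_len, nchar(pep_seq) == pep_len)
  if (!is.null(contact_plan)) {
    cp <- contact_plan
    if (is.null(cp$atom)) cp$atom <- "SG"
    if (any(cp$dist <= 0 | cp$dist > 15)) {
      stop("planned distances must lie in (0, 15] Angstrom")
    }
    if (any(cp$groove_pos < 1 | cp$groove_pos > groove_len |
            cp$pep_pos < 1 | cp$pep_pos > pep_len)) {
      stop("planned contact positions out of range")
    }
    key <- paste(cp$groove_pos, cp$pep_pos)
    if (anyDuplicated(key)) {
      stop("infeasible plan: duplicate (groove, peptide) contact ",
           "with contradictory placements")
    }
    contact_plan <- cp
  }
  if (!is.null(tcr_plan)) {
    if (any(tcr_plan$dist <= 0 | tcr_plan$dist > 15) ||
        any(tcr_plan$groove_pos < 1 | tcr_plan$groove_pos > groove_len)) {
      stop("invalid TCR plan")
    }
  }
  structure(list(seed = as.integer(seed), groove_len = groove_len,
                 pep_len = pep_len, groove_seq = groove_seq,
                 pep_seq = pep_seq, contact_plan = contact_plan,
                 tcr_plan = tcr_plan, tcr_len = tcr_len,
                 extra_chains = extra_chains),
            class = "FixtureSpec")
}

# proper rigid transform (rotation + translation) derived from the seed
.seed_transform <- function(seed) {
  a <- (seed * c(37, 101, 59)) %% 360 * pi / 180
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t),
                             0, -sin(t), cos(t)), 3, 3)
  list(R = rz(a[1]) %*% rx(a[2]) %*% rz(a[3]),
       t = c(seed %% 11, (seed * 3) %% 13, (seed * 7) %% 5))
}

.res_rows <- function(chain, role, seq_id, aa, names, offs, ca) {
  xyz <- t(vapply(offs, function(o) ca + o, numeric(3)))
  data.frame(chain = chain, role = role, seq_id = seq_id, aa = aa,
             resid = if (aa == "X") "UNK" else bio3d::aa123(aa),
             elety = names,
             element = substr(sub("^[0-9]*", "", names), 1, 1),
             is_h = FALSE,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
             stringsAsFactors = FALSE)
}

# one idealised chain along x at height y0, zig-zagging in z so that the
# C-alpha trace is planar but never collinear (keeps superposition fits
# non-degenerate); center_dir: unit y direction of the default side-chain
# center (0 = +z instead)
.ca_coord <- function(i, y0) c(.CA_STEP * i, y0, 0.5 * (-1)^i)

.trace_chain <- function(chain, role, seqchars, y0, center_dir) {
  rows <- list()
  for (i in seq_along(seqchars)) {
    ca <- .ca_coord(i, y0)
    offs <- list(N = c(-1.2, 0, 0.8), CA = c(0, 0, 0), C = c(1.2, 0, 0.8))
    if (seqchars[i] != "G") {
      offs$CB <- if (center_dir == 0) c(0, 0, 1.5) else
        c(0, 0.9 * center_dir, 1.2)
    }
    rows[[i]] <- .res_rows(chain, role, i, seqchars[i],
                           names(offs), offs, ca)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic pMHC(-TCR) complex with planted contacts
#'
#' Builds an idealised groove + peptide (+ optional TCR) complex in which
#' the minimum heavy-atom distance between each planned residue pair equals
#' the planned value exactly, and returns the machine-readable ground truth
#' alongside. Pure function of its spec: identical specs give identical
#' output (the seed only applies a rigid transform, which preserves all
#' distances).
#'
#' @param spec A [fixture_spec()].
#' @return List with `model` (a `StructureModel`, chains `A` = groove,
#'   `C` = peptide, optionally `D` = TCR, plus `B`/`W` if `extra_chains`)
#'   and `truth` (planted per-residue minimum distances and contact lists).
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  g <- strsplit(spec$groove_seq, "")[[1]]
  p <- strsplit(spec$pep_seq, "")[[1]]

  groove <- .trace_chain("A", "heavy", g, 0, center_dir = 0)
  pep <- .trace_chain("C", "peptide", p, 20, center_dir = +1)

  cp <- spec$contact_plan
  if (!is.null(cp)) {
    for (k in seq_len(nrow(cp))) {
      ca_p <- .ca_coord(cp$pep_pos[k], 20)
      pos <- ca_p - c(0, cp$dist[k], 0)
      if (cp$atom[k] == "CB") {
        groove <- groove[!(groove$seq_id == cp$groove_pos[k] &
                           groove$elety == "CB" &
                           groove$chain == "A"), ]
      }
      groove <- rbind(groove, .res_rows(
        "A", "heavy", cp$groove_pos[k], g[cp$groove_pos[k]],
        cp$atom[k], list(c(0, 0, 0)), pos))
    }
    groove <- groove[order(groove$seq_id), ]
  }

  chains <- list(groove, pep)
  if (!is.null(spec$tcr_plan)) {
    tcr <- .trace_chain("D", "tcr_beta", rep("A", spec$tcr_len), -20,
                        center_dir = -1)
    for (k in seq_len(nrow(spec$tcr_plan))) {
      gp <- spec$tcr_plan$groove_pos[k]
      pos <- .ca_coord(gp, 0) - c(0, spec$tcr_plan$dist[k], 0)
      tcr <- rbind(tcr, .res_rows("D", "tcr_beta",
                                  min(gp, spec$tcr_len), "A",
                                  "XX", list(c(0, 0, 0)), pos))
    }
    chains <- c(chains, list(tcr))
  }
  if (spec$extra_chains) {
    light <- .trace_chain("B", "light", rep("A", 8), 40, center_dir = +1)
    water <- data.frame(chain = "W", role = "other", seq_id = 1:3,
                        aa = "X", resid = "HOH", elety = "O",
                        element = "O", is_h = FALSE,
                        x = 60 + 1:3, y = 60, z = 60, o = 1,
                        stringsAsFactors = FALSE)
    chains <- c(chains, list(light, water))
  }
  atoms <- do.call(rbind, chains)

  tr <- .seed_transform(spec$seed)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(tr$R)
  atoms$x <- xyz[, 1] + tr$t[1]
  atoms$y <- xyz[, 2] + tr$t[2]
  atoms$z <- xyz[, 3] + tr$t[3]
  rownames(atoms) <- NULL

  pep_min <- if (is.null(cp)) numeric(0) else
    tapply(cp$dist, cp$groove_pos, min)
  tcr_min <- if (is.null(spec$tcr_plan)) numeric(0) else
    tapply(spec$tcr_plan$dist, spec$tcr_plan$groove_pos, min)
  list(model = new_structure_model(paste0("toy-seed", spec$seed), atoms),
       truth = list(contact_plan = cp, tcr_plan = spec$tcr_plan,
                    pep_min_dist = pep_min, tcr_min_dist = tcr_min))
}

#' Generate a synthetic allele family with planted polymorphisms
#'
#' A reference sequence (sampled from the 20 canonical residues under the
#' spec seed) plus variant alleles realised from a polymorphism plan.
#' Ground truth (modal residue, consensus, pairwise differences) is
#' tabulated directly from the plan, independently of any alignment code.
#'
#' @param n_alleles Number of alleles (>= 2), including the reference copy.
#' @param polymorphism_plan List (one element per allele, recycled) of data
#'   frames with `position`, `aa`.
#' @param seq_len Sequence length (default 180).
#' @param seed Integer seed for the reference sequence.
#' @return List with `alleles` (named character vector; first = reference),
#'   `reference` and `truth` (`residues` matrix, `modal_aa`, `consensus`,
#'   `hamming` matrix).
#' @export
make_allele_family <- function(n_alleles, polymorphism_plan = NULL,
                               seq_len = 180, seed = 1) {
  if (n_alleles < 2) stop("need at least 2 alleles")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ref <- sample(AA20, seq_len, replace = TRUE)

  seqs <- matrix(rep(ref, n_alleles), nrow = n_alleles, byrow = TRUE)
  if (!is.null(polymorphism_plan)) {
    for (k in seq_len(n_alleles)) {
      plan <- polymorphism_plan[[((k - 1) %% length(polymorphism_plan)) + 1]]
      if (is.null(plan) || nrow(plan) == 0) next
      if (any(plan$position < 1 | plan$position > seq_len)) {
        stop("polymorphism plan references positions outside 1..", seq_len)
      }
      seqs[k, plan$position] <- plan$aa
    }
  }
  alleles <- apply(seqs, 1, paste, collapse = "")
  names(alleles) <- paste0("allele", seq_len(n_alleles))

  modal <- character(seq_len)
  cons <- numeric(seq_len)
  for (pcol in seq_len(seq_len)) {
    tb <- table(seqs[, pcol])
    tb <- tb[order(-tb, names(tb))]    # modal ties break alphabetically
    modal[pcol] <- names(tb)[1]
    cons[pcol] <- 100 * tb[[1]] / n_alleles
  }
  H <- matrix(0, n_alleles, n_alleles)
  for (i in seq_len(n_alleles)) for (j in seq_len(n_alleles)) {
    H[i, j] <- sum(seqs[i, ] != seqs[j, ])
  }
  list(alleles = alleles, reference = alleles[[1]],
       truth = list(residues = seqs, modal_aa = modal, consensus = cons,
                    hamming = H))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Charge-complementary design scenario with a planted answer
#'
#' Emulates the F-pocket chemistry of a groove graft: the template peptide
#' carries a lysine anchor at P9 over a groove position that is aspartate
#' in the template allele but serine in the base (a salt-bridge-forming,
#' chemistry-changing substitution at 3.4 Angstrom from the peptide), plus
#' a neutral decoy substitution (Leu to Ile) whose interaction center lies
#' outside the contact shell. The anchor substitution is enriched among the
#' lowest-energy variants (score 1 for any pool up to half the variants);
#' the decoy is energetically silent (score 0.5 for pools of two or more,
#' 0 for the single-variant default pool).
#'
#' @param seed Integer seed (rigid-transform of the coordinates only).
#' @return List with `template` (a `ProcessedTemplate`), `model`,
#'   `groove_allele`, `base_allele`, `pep_seq`, and `truth` (anchor/decoy
#'   positions, hand-computed variant binding energies under the default
#'   potential, expected enrichment by pool fraction).
#' @export
make_design_scenario <- function(seed = 1) {
  groove_len <- 60
  gseq <- strsplit(strrep("A", groove_len), "")[[1]]
  gseq[30] <- "D"; gseq[40] <- "I"
  groove_allele <- paste(gseq, collapse = "")
  bseq <- gseq; bseq[30] <- "S"; bseq[40] <- "L"
  base_allele <- paste(bseq, collapse = "")
  pep_seq <- paste0(strrep("A", 8), "K")

  spec <- fixture_spec(
    seed = seed, groove_len = groove_len, pep_len = 9,
    groove_seq = groove_allele, pep_seq = pep_seq,
    contact_plan = data.frame(groove_pos = c(30, 40), pep_pos = c(9, 5),
                              dist = c(3.4, 4.5), atom = c("CB", "SG")))
  toy <- make_toy_complex(spec)
  template <- preprocess_template(toy$model, "A", "C",
                                  groove_span = groove_len)

  # hand-computed under the default potential (peptide-groove center pairs
  # within 8 Angstrom: anchor CB vs peptide P9/P8 centers only):
  #   anchor off: K9-S (polar/charged) -0.5, A8-S 0        -> -0.5
  #   anchor on:  K9-D (salt bridge)   -2.0, A8-D +0.5     -> -1.5
  #   decoy: center outside shell                          ->  0
  e <- c(`0` = -0.5, `1` = -1.5, `2` = -0.5, `3` = -1.5)
  list(model = toy$model, template = template,
       groove_allele = c(template_allele = groove_allele),
       base_allele = c(base_allele = base_allele),
       pep_seq = pep_seq,
       truth = list(anchor_position = 30, decoy_position = 40,
                    planted_min_dist = c(`30` = 3.4, `40` = 4.5),
                    E_bind_by_mask = e,
                    enrichment_top_half = c(`30` = 1.0, `40` = 0.5),
                    enrichment_pool1 = c(`30` = 1.0, `40` = 0.0)))
}
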