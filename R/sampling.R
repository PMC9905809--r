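# Exhaustive enumeration of substitution combinations, variant scoring,
# ranking and per-position enrichment.

#' Enumerate all substitution combinations
#'
#' Every subset of a substitution set is one variant, encoded as an integer
#' mask (bit i set = substitution i applied, little-endian; mask 0 is the
#' pure base). N substitutions give exactly 2^N masks in ascending integer
#' order.
#'
#' @param subs A `SubstitutionSet` (or anything with `nrow`).
#' @param cap Hard cap on the number of substitutions for in-memory
#'   enumeration (default 22, about 4 million variants).
#' @return Integer vector `0:(2^N - 1)` with attribute `n_subs`.
#' @export
enumerate_variants <- function(subs, cap = 22) {
  n <- if (is.data.frame(subs)) nrow(subs) else as.integer(subs)
  if (n > cap) {
    stop("2^", n, " variants exceed the enumeration cap (2^", cap,
         "); reduce the substitution set or use an external scorer ",
         "on a pre-selected subset")
  }
  masks <- 0:(2^n - 1)
  attr(masks, "n_subs") <- n
  masks
}

#' @rdname enumerate_variants
#' @param masks Integer masks.
#' @param n Number of substitutions (bits).
#' @return `mask_bits()`: logical matrix, one row per mask, one column per
#'   substitution.
#' @export
mask_bits <- function(masks, n) {
  if (n == 0) return(matrix(logical(0), nrow = length(masks), ncol = 0))
  B <- vapply(seq_len(n) - 1L,
              function(b) bitwAnd(as.integer(masks), bitwShiftL(1L, b)) != 0L,
              logical(length(masks)))
  matrix(B, nrow = length(masks), ncol = n)
}

# compact "G62Q+H74D" label for one mask
.mask_label <- function(bits, subs) {
  if (!any(bits)) return("base")
  paste0(subs$from_aa[bits], subs$position[bits], subs$to_aa[bits],
         collapse = "+")
}

#' Score and rank every substitution combination
#'
#' Threads each of the 2^N chimeric groove sequences onto the template and
#' scores it. With the internal contact potential the energy is evaluated
#' through an exact per-position decomposition (binding energy is additive
#' over substituted positions on a fixed backbone; intra-chain terms add
#' pair corrections), which reproduces [thread_and_score()] bit-exactly.
#' Variants are ranked by ascending binding energy, ties broken by
#' ascending mask integer.
#'
#' @param template A `ProcessedTemplate`.
#' @param base_groove_seq Base-allele sequence in the template groove frame
#'   (length = number of groove residues).
#' @param pep_seq Peptide sequence to hold fixed in the groove.
#' @param subs A `SubstitutionSet`; positions index the groove frame.
#' @param params An `EnergyParams` list.
#' @param scorer Optional external scorer function
#'   `(groove_seq, pep_seq, template) -> list(E_total, E_bind)` (see
#'   [make_command_scorer()]); per-variant failures are recorded and
#'   excluded from the ranking.
#' @param cap Enumeration cap (see [enumerate_variants()]).
#' @return A `RankedVariants` data frame with columns `mask`, `label`,
#'   `E_bind`, `E_total`, sorted by (`E_bind`, `mask`); attributes `subs`
#'   and `failures`.
#' @export
score_all <- function(template, base_groove_seq, pep_seq, subs,
                      params = default_energy_params(), scorer = NULL,
                      cap = 22) {
  masks <- enumerate_variants(subs, cap)
  n <- attr(masks, "n_subs")
  base <- strsplit(base_groove_seq, "")[[1]]
  if (nrow(subs) > 0) {
    if (max(subs$position) > length(base)) {
      stop("substitution position beyond groove length")
    }
    mism <- base[subs$position] != subs$from_aa
    if (any(mism)) {
      stop("base groove sequence mismatch at position(s) ",
           paste(subs$position[mism], collapse = ", "))
    }
  }
  bits <- mask_bits(masks, n)
  failures <- data.frame(mask = integer(), message = character())

  if (is.null(scorer)) {
    geom <- .energy_geometry(template, params)
    eb <- .decomposed_energies(geom, base, pep_seq, subs, params)
    E_bind <- eb$E_bind; E_total <- eb$E_total
  } else {
    E_bind <- E_total <- rep(NA_real_, length(masks))
    for (k in seq_along(masks)) {
      g <- base
      if (n > 0) g[subs$position[bits[k, ]]] <- subs$to_aa[bits[k, ]]
      res <- tryCatch(scorer(paste(g, collapse = ""), pep_seq, template),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) {
        failures <- rbind(failures,
                          data.frame(mask = masks[k], message = res))
      } else {
        E_total[k] <- res$E_total
        E_bind[k] <- res$E_bind
      }
    }
  }

  labels <- vapply(seq_along(masks),
                   function(k) .mask_label(bits[k, ], subs), character(1))
  out <- data.frame(mask = as.integer(masks), label = labels,
                    E_bind = E_bind, E_total = E_total,
                    stringsAsFactors = FALSE)
  scored <- !is.na(out$E_bind)
  out <- out[scored, , drop = FALSE]
  out <- out[order(out$E_bind, out$mask), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "subs") <- subs
  attr(out, "n_subs") <- n
  attr(out, "failures") <- failures
  class(out) <- c("RankedVariants", class(out))
  out
}

# Exact decomposition of the contact potential over masks:
#  - binding pairs (peptide fixed) are linear in the substitution bits;
#  - intra-chain pairs with one substitutable end are linear, with both
#    ends substitutable they add a bit-product interaction term.
.decomposed_energies <- function(geom, base, pep_seq, subs, params) {
  p <- strsplit(pep_seq, "")[[1]]
  n <- nrow(subs)
  masks <- 0:(2^n - 1)
  bits <- mask_bits(masks, n)
  spos <- subs$position
  pe <- function(a1, a2, d) pair_energy(a1, a2, d, params)

  bp <- geom$bind_pairs
  E_bind0 <- sum(pe(p[bp$pep], base[bp$groove], bp$dist))
  dbind <- numeric(n)
  for (i in seq_len(n)) {
    sel <- bp$groove == spos[i]
    if (any(sel)) {
      dbind[i] <- sum(pe(p[bp$pep[sel]], subs$to_aa[i], bp$dist[sel])) -
        sum(pe(p[bp$pep[sel]], subs$from_aa[i], bp$dist[sel]))
    }
  }
  E_bind <- E_bind0 + if (n > 0) as.numeric(bits %*% dbind) else 0

  ig <- geom$intra_groove
  ip <- geom$intra_pep
  e_pep_intra <- sum(pe(p[ip$i], p[ip$j], ip$dist))
  si <- match(ig$i, spos); sj <- match(ig$j, spos)
  both <- !is.na(si) & !is.na(sj)
  one_i <- !is.na(si) & is.na(sj)
  one_j <- is.na(si) & !is.na(sj)
  none <- is.na(si) & is.na(sj)

  e_g_const <- sum(pe(base[ig$i[none]], base[ig$j[none]], ig$dist[none]))
  dtot <- numeric(n)
  add_linear <- function(rows, sub_idx, other_aa) {
    for (r in rows) {
      k <- sub_idx[r]
      dtot[k] <<- dtot[k] +
        pe(subs$to_aa[k], other_aa[r], ig$dist[r]) -
        pe(subs$from_aa[k], other_aa[r], ig$dist[r])
    }
  }
  # pairs with exactly one substitutable end contribute their base value
  # to the constant and a linear switch term
  e_g_const <- e_g_const +
    sum(pe(base[ig$i[one_i]], base[ig$j[one_i]], ig$dist[one_i])) +
    sum(pe(base[ig$i[one_j]], base[ig$j[one_j]], ig$dist[one_j]))
  add_linear(which(one_i), si, base[ig$j])
  add_linear(which(one_j), sj, base[ig$i])

  E_extra <- e_pep_intra + e_g_const +
    if (n > 0) as.numeric(bits %*% dtot) else 0
  for (r in which(both)) {
    a <- si[r]; b <- sj[r]; d <- ig$dist[r]
    v00 <- pe(subs$from_aa[a], subs$from_aa[b], d)
    v10 <- pe(subs$to_aa[a], subs$from_aa[b], d)
    v01 <- pe(subs$from_aa[a], subs$to_aa[b], d)
    v11 <- pe(subs$to_aa[a], subs$to_aa[b], d)
    E_extra <- E_extra + v00 + bits[, a] * (v10 - v00) +
      bits[, b] * (v01 - v00) +
      (bits[, a] & bits[, b]) * (v11 - v10 - v01 + v00)
  }
  list(E_bind = E_bind, E_total = E_bind + E_extra)
}

#' Per-position enrichment among the lowest-energy variants
#'
#' The pool is the top `top_fraction` of the ranked variants (by binding
#' energy; pool size `max(1, ceiling(top_fraction * M))`). The enrichment
#' score of a substitution is the fraction of pool variants that carry it.
#' A score of 1 marks substitutions present in every low-energy variant;
#' scores at or near 0 mark substitutions that destabilise the complex.
#'
#' @param ranked A `RankedVariants` table from [score_all()].
#' @param subs The `SubstitutionSet` (defaults to the set stored on
#'   `ranked`).
#' @param top_fraction Fraction of variants forming the pool
#'   (default 0.025).
#' @return An `EnrichmentTable` data frame with `position`, `from_aa`,
#'   `to_aa`, `score` and attribute `pool_size`.
#' @export
enrichment <- function(ranked, subs = attr(ranked, "subs"),
                       top_fraction = 0.025) {
  if (nrow(ranked) == 0) stop("no ranked variants")
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]")
  }
  n <- attr(ranked, "n_subs")
  pool_size <- max(1L, as.integer(ceiling(top_fraction * nrow(ranked))))
  pool <- ranked$mask[seq_len(pool_size)]
  B <- mask_bits(pool, n)
  score <- if (n > 0) colMeans(B) else numeric(0)
  out <- data.frame(position = subs$position, from_aa = subs$from_aa,
                    to_aa = subs$to_aa, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "pool_size") <- pool_size
  class(out) <- c("EnrichmentTable", class(out))
  out
}
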