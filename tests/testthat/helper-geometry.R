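# Shared helpers: rigid transforms of models and an independent
# brute-force energy oracle (naive double loops over interaction centers,
# kept deliberately separate from the package's vectorised path).

rotation_from_angles <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  rz(a) %*% ry(b) %*% rz(c)
}

transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

# Independent binding-energy oracle: naive double loop over all
# peptide x groove interaction centers, reading the class matrix directly.
brute_force_ebind <- function(template, groove_seq, pep_seq,
                              params = default_energy_params()) {
  ctr <- interaction_centers(template)
  g <- strsplit(groove_seq, "")[[1]]
  p <- strsplit(pep_seq, "")[[1]]
  cls <- function(aa) chimeraMHC::aa_class(aa)
  e <- 0
  for (i in seq_len(nrow(ctr$peptide))) {
    for (j in seq_len(nrow(ctr$groove))) {
      d <- sqrt(sum((ctr$peptide[i, ] - ctr$groove[j, ])^2))
      if (d > params$contact_cutoff) next
      ci <- cls(p[i]); cj <- cls(g[j])
      if (is.na(ci) || is.na(cj)) next
      e <- e + params$class_matrix[ci, cj] +
        if (d < params$clash_cutoff) params$clash_penalty else 0
    }
  }
  e
}

# straight-line reference for the whole sampling stage: enumerate masks,
# score each variant with thread_and_score, sort, count the pool
brute_force_ranking <- function(template, base_groove_seq, pep_seq, subs,
                                params = default_energy_params()) {
  n <- nrow(subs)
  base <- strsplit(base_groove_seq, "")[[1]]
  masks <- 0:(2^n - 1)
  eb <- et <- numeric(length(masks))
  for (k in seq_along(masks)) {
    on <- bitwAnd(masks[k], bitwShiftL(1L, seq_len(n) - 1L)) != 0L
    g <- base
    g[subs$position[on]] <- subs$to_aa[on]
    vm <- thread_and_score(template, paste(g, collapse = ""), pep_seq,
                           params)
    eb[k] <- vm$E_bind; et[k] <- vm$E_total
  }
  o <- order(eb, masks)
  data.frame(mask = masks[o], E_bind = eb[o], E_total = et[o])
}

brute_force_enrichment <- function(ranked_df, n_subs, top_fraction) {
  pool_size <- max(1L, as.integer(ceiling(top_fraction * nrow(ranked_df))))
  pool <- ranked_df$mask[seq_len(pool_size)]
  vapply(seq_len(n_subs) - 1L, function(b) {
    mean(bitwAnd(as.integer(pool), bitwShiftL(1L, b)) != 0L)
  }, numeric(1))
}

# small planted complex used across tests: groove positions 3, 5, 9 touch
# the peptide inside 5 Angstrom, position 12 sits just outside
planted_spec <- function(seed = 1, groove_len = 20) {
  fixture_spec(
    seed = seed, groove_len = groove_len, pep_len = 9,
    contact_plan = data.frame(groove_pos = c(3, 5, 9, 12),
                              pep_pos = c(1, 3, 5, 7),
                              dist = c(4.9, 2.0, 4.0, 6.5)))
}

planted_template <- function(seed = 1) {
  toy <- make_toy_complex(planted_spec(seed))
  preprocess_template(toy$model, "A", "C", groove_span = 20)
}

# a 4-substitution fixture with mixed energetic effects: two positions in
# the contact shell (one stabilising, one destabilising), two silent
four_sub_case <- function(seed = 1) {
  groove_len <- 30
  gseq <- strsplit(strrep("A", groove_len), "")[[1]]
  gseq[c(10, 14, 20, 25)] <- c("D", "K", "I", "T")
  spec <- fixture_spec(
    seed = seed, groove_len = groove_len, pep_len = 9,
    groove_seq = paste(gseq, collapse = ""),
    pep_seq = "AAAAAAAAK",
    contact_plan = data.frame(
      groove_pos = c(10, 14, 20, 25),
      pep_pos = c(9, 9, 3, 5),
      dist = c(3.4, 3.6, 4.5, 4.0),
      atom = c("CB", "CB", "SG", "SG")))
  toy <- make_toy_complex(spec)
  tpl <- preprocess_template(toy$model, "A", "C", groove_span = groove_len)
  bseq <- gseq
  bseq[c(10, 14, 20, 25)] <- c("S", "A", "L", "S")
  list(template = tpl,
       base = paste(bseq, collapse = ""),
       groove = paste(gseq, collapse = ""),
       pep = "AAAAAAAAK")
}
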