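# Groove definition, allele alignment, substitution construction and
# the minimal-set rules.

test_that("the groove is exactly the planted set of proximal positions", {
  toy <- make_toy_complex(planted_spec())   # 3,5,9 within 5 A; 12 at 6.5
  tpl <- preprocess_template(toy$model, "A", "C", groove_span = 20)
  g <- define_groove(tpl, cutoff = 5)
  expect_equal(g$positions, c(3, 5, 9))
  expect_equal(unname(g$min_dist[c("3", "5", "9", "12")]),
               c(4.9, 2.0, 4.0, 6.5), tolerance = 1e-6)
})

test_that("degenerate groove cutoffs behave as limits", {
  tpl <- planted_template()
  expect_error(define_groove(tpl, cutoff = 0), "positive")
  g <- define_groove(tpl, cutoff = Inf)
  expect_equal(g$positions, 1:20)
  toy_empty <- make_toy_complex(fixture_spec(groove_len = 20, pep_len = 9))
  tpl_empty <- preprocess_template(toy_empty$model, "A", "C",
                                   groove_span = 20)
  expect_error(define_groove(tpl_empty, cutoff = 5), "no groove residue")
})

test_that("pairwise alignment maps identical and gapped sequences", {
  a <- "MAVMAPRTLVLLLSGALALTQTWAGS"
  al <- align_pair(a, a)
  m <- al$map
  expect_equal(m$pos_a, m$pos_b)
  expect_true(all(!is.na(m$pos_a)))

  b <- paste0(substr(a, 1, 9), substr(a, 11, nchar(a)))  # drop residue 10
  al2 <- align_pair(a, b)
  gaps <- sum(is.na(al2$map$pos_b))
  expect_equal(gaps, 1)
  # positions after the gap shift by one
  after <- al2$map[!is.na(al2$map$pos_a) & al2$map$pos_a > 10, ]
  expect_equal(after$pos_b, after$pos_a - 1)
})

test_that("mismatch count equals the planted difference count", {
  plan <- list(NULL, data.frame(position = c(4, 9, 15),
                                aa = c("W", "W", "W")))
  fam <- make_allele_family(2, polymorphism_plan = plan, seq_len = 40,
                            seed = 3)
  # the generator guarantees W differs from the sampled reference there
  k <- sum(strsplit(fam$alleles[[1]], "")[[1]] !=
           strsplit(fam$alleles[[2]], "")[[1]])
  al <- align_pair(fam$alleles[[1]], fam$alleles[[2]])
  m <- al$map
  expect_equal(m$pos_a, m$pos_b)    # no indels planted
  expect_equal(sum(m$aa_a != m$aa_b), k)
})

test_that("substitutions arise only at polymorphic groove positions", {
  tpl <- planted_template()
  g <- define_groove(tpl, cutoff = 5)   # positions 3, 5, 9
  base <- chain_sequence(tpl, "A")      # poly-A groove

  expect_equal(nrow(build_substitutions(g, base, base)), 0)

  bvec <- strsplit(base, "")[[1]]
  bvec[c(3, 9)] <- c("D", "K")          # groove differences
  bvec[15] <- "W"                       # non-groove difference
  b2 <- paste(bvec, collapse = "")
  subs <- build_substitutions(g, c(tmpl = base), c(base2 = b2))
  expect_equal(nrow(subs), 2)
  expect_equal(subs$position, c(3, 9))
  expect_equal(subs$from_aa, c("D", "K"))
  expect_equal(subs$to_aa, c("A", "A"))
  expect_equal(substitution_string(subs), "D3A, K9A")
  expect_equal(subs$min_dist, unname(g$min_dist[c("3", "9")]))
})

test_that("compact substitution notation round-trips", {
  s <- parse_substitutions("G62Q, K66N, H70Q")
  expect_equal(s$position, c(62, 66, 70))
  expect_equal(s$from_aa, c("G", "K", "H"))
  expect_equal(substitution_string(s), "G62Q, K66N, H70Q")
  expect_error(parse_substitutions("G62"), "cannot parse")
})

test_that("applying substitutions edits exactly the listed positions", {
  base <- c(myBase = "GAVLKDE")
  expect_equal(
    apply_substitutions(base, parse_substitutions(""))$chimera_seq,
    "GAVLKDE")
  d <- apply_substitutions(base, parse_substitutions("G1Q"),
                           groove_name = "tmpl")
  expect_equal(d$chimera_seq, "QAVLKDE")
  expect_equal(d$name, "tmpl-myBase")

  subs <- parse_substitutions("G1Q,V3I,E7D")
  ch <- apply_substitutions(base, subs)
  hamming <- sum(strsplit(ch$chimera_seq, "")[[1]] !=
                 strsplit("GAVLKDE", "")[[1]])
  expect_equal(hamming, 3)

  # involution: reversing the substitutions recovers the base exactly
  rev_subs <- subs
  rev_subs$from_aa <- subs$to_aa
  rev_subs$to_aa <- subs$from_aa
  back <- apply_substitutions(c(ch = ch$chimera_seq), rev_subs)
  expect_equal(back$chimera_seq, "GAVLKDE")

  expect_error(apply_substitutions(base, parse_substitutions("A1Q")),
               "mismatch")
})

test_that("chemical classes drive the class-change flag", {
  expect_true(is_class_change("S", "D"))    # neutral -> charged
  expect_true(is_class_change("K", "A"))    # charged -> hydrophobic
  expect_false(is_class_change("L", "I"))   # same class
  expect_false(is_class_change("A", "Q"))   # neutral -> neutral
  expect_false(is_class_change("K", "R"))   # both positive
  expect_true(is_class_change("K", "D"))    # charge swap
})

minimal_subs <- function() {
  s <- data.frame(
    position = c(10, 20, 30, 40),
    from_aa = c("S", "L", "L", "H"),
    to_aa   = c("D", "I", "I", "Q"),
    min_dist = c(3.0, 4.0, 4.0, 4.2),
    stringsAsFactors = FALSE)
  s$class_change <- is_class_change(s$from_aa, s$to_aa)
  class(s) <- c("SubstitutionSet", class(s))
  s
}

test_that("chemistry-changing swaps are always kept, low-enrichment similar swaps dropped", {
  s <- minimal_subs()
  e <- c(`10` = 0, `20` = 0.9, `30` = 0.2, `40` = 0.9)
  kept <- minimal_set(s, e)
  expect_true(10 %in% kept$position)    # charged-for-neutral, enrichment 0
  expect_true(20 %in% kept$position)    # Leu->Ile at 0.9: kept
  expect_false(30 %in% kept$position)   # Leu->Ile at 0.2: dropped
  expect_true(40 %in% kept$position)

  strict <- minimal_set(s, e, exclude_similar = TRUE)
  expect_false(20 %in% strict$position) # same-class swap excluded outright
})

test_that("PTB positions require the stringent 3.5 A peptide distance", {
  s <- minimal_subs()
  e <- c(`10` = 1, `20` = 1, `30` = 1, `40` = 1)
  cls <- c(`10` = "PB", `20` = "PTB", `30` = "PB", `40` = "PTB")
  kept <- minimal_set(s, e, classes = cls)
  expect_false(40 %in% kept$position)   # PTB at 4.2 A: dropped
  expect_false(20 %in% kept$position)   # PTB at 4.0 A: dropped
  cls2 <- c(`40` = "PTB")
  s2 <- s; s2$min_dist[4] <- 3.4
  expect_true(40 %in% minimal_set(s2, e, classes = cls2)$position)
})

test_that("minimal_set is a subset operation and idempotent", {
  s <- minimal_subs()
  e <- c(`10` = 0.6, `20` = 0.1, `30` = 0.8, `40` = 0.4)
  k1 <- minimal_set(s, e)
  expect_true(all(k1$position %in% s$position))
  k2 <- minimal_set(k1, e)
  expect_equal(k1, k2)
  expect_error(minimal_set(s, e[1:2]), "missing enrichment")
})
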