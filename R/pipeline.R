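# End-to-end orchestration: preprocess -> groove -> align -> substitutions
# -> enumerate -> score -> enrich -> minimal set, with a run manifest.

#' Default pipeline configuration
#'
#' Houses the workflow's numeric constants with their defaults: 4 Angstrom
#' contact threshold for surface classification, 5 Angstrom groove
#' definition, 3.5 Angstrom stringent threshold for dual-surface (PTB)
#' positions, 10% classification cutoff, top 2.5% enrichment pool and 0.5
#' enrichment threshold for the minimal set.
#'
#' @param ... Named overrides of any default (nested lists are merged).
#' @return Configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    heavy_chain = "A", peptide_chain = "C",
    groove_span = 180, skip_leading = 0,
    thresholds = list(contact = 4.0, groove = 5.0, ptb = 3.5,
                      classify_cutoff = 10, top_fraction = 0.025,
                      theta_enrich = 0.5),
    energy = list(contact_cutoff = 8.0, clash_cutoff = 3.0,
                  clash_penalty = 10.0, intra_min_separation = 3),
    seed = 1
  )
  .merge_config(cfg, list(...))
}

.merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [default_config()] fields;
#'   thresholds must be positive and fractions in (0, 1].
#' @return Configuration list (defaults filled in).
#' @export
read_config <- function(path) {
  cfg <- .merge_config(default_config(), yaml::read_yaml(path))
  th <- cfg$thresholds
  num <- vapply(th, is.numeric, logical(1))
  if (!all(num) || any(unlist(th[num]) <= 0)) {
    stop("all thresholds must be positive numbers")
  }
  if (th$top_fraction > 1) stop("top_fraction must lie in (0, 1]")
  cfg
}

.config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

.write_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full chimeric-design workflow
#'
#' Executes, in order: template preprocessing, groove definition, allele
#' alignment, substitution construction, exhaustive variant enumeration and
#' scoring, enrichment, and the minimal-set reduction. Every tabular output
#' carries the configuration hash; a JSON manifest records the
#' configuration, hash and artifact paths. A stage failure halts the run
#' naming the stage and the artifacts already written. With the internal
#' scorer the run is fully deterministic: re-running an identical
#' configuration reproduces identical artifacts.
#'
#' @param template A `StructureModel`/`ProcessedTemplate`, or path to a
#'   structure file of the template (groove) allele complex.
#' @param base_allele Base-allele sequence (named character string, or path
#'   to a FASTA file).
#' @param groove_allele Template-allele sequence; defaults to the sequence
#'   of the processed template structure.
#' @param out_dir Output directory (created if missing).
#' @param config Configuration list ([default_config()]) or YAML path.
#' @param tcr_entries Optional list of structures for TCR-contact
#'   classification (see [contact_frequency()]); without it no position is
#'   labelled PTB and the stringent PTB distance rule is vacuous.
#' @param scorer Optional external scorer (see [make_command_scorer()]).
#' @return Invisibly, a list with the groove definition, substitutions,
#'   ranked variants, enrichment table, minimal set and artifact paths.
#' @export
run_pipeline <- function(template, base_allele, groove_allele = NULL,
                         out_dir = ".", config = default_config(),
                         tcr_entries = NULL, scorer = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- .merge_config(default_config(), config)
  hash <- .config_hash(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  done <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           if (length(done)) paste0("; completed artifacts: ",
                                    paste(done, collapse = ", ")),
           call. = FALSE)
    })
  }
  out <- function(name) file.path(out_dir, name)

  tpl <- stage("preprocess", {
    m <- if (is.character(template)) read_structure(template) else template
    t <- if (inherits(m, "ProcessedTemplate")) m else
      preprocess_template(m, cfg$heavy_chain, cfg$peptide_chain,
                          groove_span = cfg$groove_span,
                          skip_leading = cfg$skip_leading)
    write_structure(t, out("template.pdb"))
    done <<- c(done, out("template.pdb"))
    t
  })
  heavy_id <- tpl$atoms$chain[tpl$atoms$role == "heavy"][1]
  pep_id <- tpl$atoms$chain[tpl$atoms$role == "peptide"][1]
  pep_seq <- chain_sequence(tpl, pep_id)

  if (is.character(base_allele) && length(base_allele) == 1 &&
      file.exists(base_allele)) {
    ss <- Biostrings::readAAStringSet(base_allele)
    base_allele <- stats::setNames(as.character(ss[1]), names(ss)[1])
  }
  if (is.null(groove_allele)) {
    groove_allele <- c(template_structure = chain_sequence(tpl, heavy_id))
  }

  groove <- stage("groove", {
    g <- define_groove(tpl, cutoff = cfg$thresholds$groove)
    .write_tsv(data.frame(position = as.integer(names(g$min_dist)),
                          min_dist = round(unname(g$min_dist), 4),
                          in_groove = as.integer(names(g$min_dist)) %in%
                            g$positions),
               out("groove.tsv"), hash)
    done <<- c(done, out("groove.tsv"))
    g
  })

  subs <- stage("substitutions", {
    s <- build_substitutions(groove, groove_allele, base_allele)
    .write_tsv(as.data.frame(s), out("substitutions.tsv"), hash)
    done <<- c(done, out("substitutions.tsv"))
    s
  })

  classes <- NULL
  if (!is.null(tcr_entries)) {
    classes <- stage("classification", {
      pep_prof <- contact_frequency(list(tpl),
                                    threshold = cfg$thresholds$contact,
                                    n_positions = cfg$groove_span)
      tcr_prof <- contact_frequency(tcr_entries,
                                    threshold = cfg$thresholds$contact,
                                    n_positions = cfg$groove_span)
      tab <- classification_table(pep_prof, tcr_prof,
                                  cutoff = cfg$thresholds$classify_cutoff)
      .write_tsv(tab, out("profile.tsv"), hash)
      done <<- c(done, out("profile.tsv"))
      stats::setNames(tab$label, tab$position)
    })
  }

  params <- default_energy_params(
    contact_cutoff = cfg$energy$contact_cutoff,
    clash_cutoff = cfg$energy$clash_cutoff,
    clash_penalty = cfg$energy$clash_penalty,
    intra_min_separation = cfg$energy$intra_min_separation)

  base_groove_seq <- stage("score", {
    b <- as.character(base_allele)
    if (nchar(b) < tpl$groove_len) {
      stop("base allele shorter than the groove span")
    }
    substr(b, 1, tpl$groove_len)
  })
  ranked <- stage("score", {
    r <- score_all(tpl, base_groove_seq, pep_seq, subs,
                   params = params, scorer = scorer)
    .write_tsv(as.data.frame(r), out("ranked.tsv"), hash)
    done <<- c(done, out("ranked.tsv"))
    r
  })

  enr <- stage("enrich", {
    e <- enrichment(ranked, subs,
                    top_fraction = cfg$thresholds$top_fraction)
    .write_tsv(as.data.frame(e), out("enrichment.tsv"), hash)
    done <<- c(done, out("enrichment.tsv"))
    e
  })

  mset <- stage("minimal_set", {
    m <- minimal_set(subs, enr, classes = classes,
                     theta_enrich = cfg$thresholds$theta_enrich,
                     ptb_dist = cfg$thresholds$ptb)
    .write_tsv(as.data.frame(m), out("minimal_set.tsv"), hash)
    done <<- c(done, out("minimal_set.tsv"))
    m
  })

  manifest <- list(config = cfg, config_hash = hash,
                   package_version = as.character(
                     utils::packageVersion("chimeraMHC")),
                   artifacts = done,
                   n_variants = nrow(ranked),
                   pool_size = attr(enr, "pool_size"),
                   minimal_set = if (nrow(mset)) substitution_string(mset)
                                 else "")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(template = tpl, groove = groove, substitutions = subs,
                 classes = classes, ranked = ranked, enrichment = enr,
                 minimal_set = mset, config_hash = hash,
                 artifacts = c(done, out("manifest.json"))))
}
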