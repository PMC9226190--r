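#' End-to-end pipeline
#'
#' Runs the whole post-search workflow for each evidence file: filter ->
#' identify -> source mapping -> taxonomy (species matching, diagnosis,
#' parsimony) -> binder call -> deamidation profiling, and writes a
#' per-sample report bundle with a reproducibility manifest.
#'
#' @name pipeline
NULL

#' Analysis configuration
#'
#' @param databases Ordered list of `sequence_db` objects: the primary
#'   binder database first, optional broader fallback databases after it.
#' @param contaminants Contaminant `sequence_db` (or `NULL`).
#' @param filter A [filter_config()].
#' @param digest A [digest_params()].
#' @param equivalence An [equivalence_rules()].
#' @param plausibility Optional [plausibility_filter()].
#' @param taxon_groups Named list of species vectors treated as
#'   indistinguishable groups (e.g.
#'   `list("Ovis aries/Capra hircus" = c("Ovis aries", "Capra hircus"))`).
#' @param protein_groups Optional named list of accession vectors:
#'   protein groups (typically ortholog families) within which peptide
#'   uniqueness is evaluated; see [identify_proteins()].
#' @param source_map Source-map tibble.
#' @param damage List with `B` (bootstrap replicates), `seed`,
#'   `low_n_threshold`.
#' @param binder_threshold Dominant-share threshold for [call_binder()].
#' @param iterative Re-search peptides unmatched in the primary database
#'   against the fallback databases, tagging new matches "fallback-db".
#' @param upstream Free-form metadata about the upstream spectral search
#'   (engine, version, FDR, tolerances); recorded verbatim in the
#'   manifest, never acted on.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(databases, contaminants = NULL,
                            filter = filter_config(),
                            digest = digest_params(),
                            equivalence = equivalence_rules(),
                            plausibility = NULL,
                            taxon_groups = list(),
                            protein_groups = NULL,
                            source_map = default_source_map(),
                            damage = list(B = 1000, seed = 1, low_n_threshold = 20),
                            binder_threshold = 0.6,
                            iterative = FALSE,
                            upstream = list()) {
  if (inherits(databases, "sequence_db")) databases <- list(databases)
  stopifnot(length(databases) >= 1)
  if (!is.null(damage$B) && is.null(damage$seed)) {
    abort_format("a seed is mandatory whenever bootstrap estimation is configured")
  }
  structure(list(databases = databases, contaminants = contaminants,
                 filter = filter, digest = digest, equivalence = equivalence,
                 plausibility = plausibility, taxon_groups = taxon_groups,
                 protein_groups = protein_groups,
                 source_map = source_map, damage = damage,
                 binder_threshold = binder_threshold, iterative = iterative,
                 upstream = upstream),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Paths in the YAML (`databases`, each with `path` and optional
#' `metadata` TSV; `contaminants`; `plausibility`; `source_map`) are
#' resolved relative to the YAML file.
#'
#' @param path YAML file path.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort_format("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  dbs <- lapply(y$databases, function(d) {
    meta <- if (!is.null(d$metadata)) {
      readr::read_tsv(resolve(d$metadata),
                      col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE)
    } else NULL
    read_fasta_db(resolve(d$path), metadata = meta,
                  name = d$name %||% basename(d$path))
  })
  contaminants <- if (!is.null(y$contaminants)) {
    read_fasta_db(resolve(y$contaminants), name = "contaminants",
                  is_contaminant = TRUE)
  } else NULL
  plaus <- if (!is.null(y$plausibility)) {
    read_plausibility_filter(resolve(y$plausibility))
  } else NULL
  smap <- if (!is.null(y$source_map)) read_source_map(resolve(y$source_map))
          else default_source_map()
  fl <- y$filter %||% list()
  dg <- y$digest %||% list()
  eq <- y$equivalence %||% list()
  dmg <- y$damage %||% list()
  analysis_config(
    databases = dbs, contaminants = contaminants,
    filter = filter_config(min_score = fl$min_score %||% 40,
                           min_length = fl$min_length %||% 7,
                           drop_reverse = fl$drop_reverse %||% TRUE,
                           drop_contaminants = fl$drop_contaminants %||% TRUE),
    digest = digest_params(enzyme = dg$enzyme %||% "trypsin",
                           max_missed = dg$max_missed %||% 2,
                           min_len = dg$min_len %||% 7,
                           max_len = dg$max_len %||% 30),
    equivalence = equivalence_rules(
      il_equal = eq$il_equal %||% TRUE,
      nd_conditional = eq$nd_conditional %||% TRUE,
      sa_near_oxidation = eq$sa_near_oxidation %||% TRUE,
      window = eq$window %||% 1,
      require_fragment_coverage = eq$require_fragment_coverage %||% FALSE),
    plausibility = plaus,
    taxon_groups = y$taxon_groups %||% list(),
    protein_groups = y$protein_groups,
    source_map = smap,
    damage = list(B = dmg$B %||% 1000, seed = dmg$seed %||% 1,
                  low_n_threshold = dmg$low_n_threshold %||% 20),
    binder_threshold = y$binder_threshold %||% 0.6,
    iterative = y$iterative %||% FALSE,
    upstream = y$upstream %||% list()
  )
}

# derive the target taxon for a matched species set: a singleton is its
# own target; a set equal to a configured indistinguishable group takes
# the group; anything else has no target
derive_target <- function(filtered, taxon_groups) {
  if (length(filtered) == 1) return(list(target = filtered, label = filtered))
  for (lab in names(taxon_groups)) {
    if (setequal(filtered, taxon_groups[[lab]])) {
      return(list(target = taxon_groups[[lab]], label = lab))
    }
  }
  NULL
}

#' Analyse one sample's evidence
#'
#' @param rows Evidence tibble for one sample (already read).
#' @param config An [analysis_config()].
#' @return List with `kept`, `removal_log`, `identifications`,
#'   `source_classes`, `taxon_calls`, `summaries`, `binder_call`,
#'   `deamidation` and `fallback_hits`.
#' @export
analyze_sample <- function(rows, config) {
  sid <- rows$sample_id[[1]]
  filt <- filter_evidence(rows, config$filter, config$contaminants)
  kept <- filt$kept
  if (nrow(kept) == 0) abort_format("no evidence rows survive filtering for %s", sid)
  primary_db <- config$databases[[1]]
  ids <- identify_proteins(kept, primary_db, groups = config$protein_groups)
  source_classes <- map_sources(ids, primary_db, config$source_map)

  ctxs <- observation_contexts(kept)
  peptides <- unique(kept$sequence)
  calls <- list()
  fallback_hits <- character(0)
  for (pep in peptides) {
    matches <- species_matches(pep, ctxs[[pep]], primary_db, config$digest,
                               config$equivalence)
    provenance_note <- character(0)
    if (length(matches) == 0 && config$iterative && length(config$databases) > 1) {
      for (db2 in config$databases[-1]) {
        matches <- species_matches(pep, ctxs[[pep]], db2, config$digest,
                                   config$equivalence)
        if (length(matches) > 0) {
          provenance_note <- "fallback-db"
          fallback_hits <- c(fallback_hits, pep)
          break
        }
      }
    }
    filtered <- if (!is.null(config$plausibility)) {
      intersect(matches, config$plausibility$allowed_species)
    } else matches
    tgt <- derive_target(filtered, config$taxon_groups)
    call <- diagnose(pep, matches, plausibility = config$plausibility,
                     target = tgt$target %||% character(0),
                     ctx = ctxs[[pep]], rules = config$equivalence,
                     dbs = config$databases)
    if (!is.null(tgt) && call$diagnostic) call$target_taxon <- tgt$label
    if (length(provenance_note) > 0) {
      call$notes[[1]] <- c(call$notes[[1]], provenance_note)
    }
    calls[[pep]] <- call
  }
  calls <- dplyr::bind_rows(calls)
  # confirmed taxa: every diagnostic target, as named member-species units
  confirmed <- list()
  if (nrow(calls) > 0) {
    for (lab in unique(calls$target_taxon[calls$diagnostic & !is.na(calls$target_taxon)])) {
      confirmed[[lab]] <- config$taxon_groups[[lab]] %||% lab
    }
  }
  calls <- parsimony_assign(calls, confirmed)

  summaries <- summarize_sample(sid, ids, calls, source_classes, kept,
                                config$source_map)
  binder <- if (nrow(summaries) > 0) call_binder(summaries, config$binder_threshold) else NULL

  # peptide -> source class for damage subgrouping: class of the peptide's
  # proteins (first by the class precedence used in the summaries)
  pep_class <- character(0)
  if (nrow(ids) > 0) {
    pc <- purrr::map2_dfr(ids$accession, ids$supporting_peptides, function(acc, sup) {
      tibble::tibble(peptide = unique(sup$peptide),
                     class = unname(source_classes[acc]))
    })
    pc <- pc[!duplicated(pc$peptide), ]
    pep_class <- stats::setNames(pc$class, pc$peptide)
  }
  dmg <- config$damage
  egg_classes <- c("egg_yolk", "egg_white", "egg_ambiguous", "blood_or_egg")
  collagen_classes <- c("animal_glue", "hide_glue_indicator")
  est <- list()
  for (res in c("N", "Q")) {
    est[[paste0("all_", res)]] <- try_estimate(kept, res, NULL, pep_class, dmg, "all")
    est[[paste0("egg_", res)]] <- try_estimate(kept, res, egg_classes, pep_class, dmg, "egg")
    est[[paste0("collagen_", res)]] <- try_estimate(kept, res, collagen_classes,
                                                   pep_class, dmg, "collagen")
  }
  deamidation <- dplyr::bind_rows(est[!vapply(est, is.null, logical(1))])
  if (nrow(deamidation) > 0) deamidation$sample_id <- sid

  list(sample_id = sid, kept = kept, removal_log = filt$removed,
       identifications = ids, source_classes = source_classes,
       taxon_calls = calls, summaries = summaries, binder_call = binder,
       deamidation = deamidation, fallback_hits = unique(fallback_hits))
}

try_estimate <- function(rows, residue, subgroup, pep_class, dmg, label) {
  out <- tryCatch(
    estimate_deamidation(rows, residue, subgroup = subgroup,
                         peptide_classes = pep_class, B = dmg$B,
                         seed = dmg$seed, label = label,
                         low_n_threshold = dmg$low_n_threshold %||% 20),
    binderid_format_error = function(e) NULL)
  out
}

#' Run the full pipeline over evidence files
#'
#' Writes, per sample: the Table-style report, taxon calls, deamidation
#' estimates and removal log, plus a global `manifest.json` echoing the
#' configuration, seeds and package version. On any stage error the
#' partial outputs are kept and a `FAILED` marker file names the failing
#' sample and message.
#'
#' @param config An [analysis_config()] or path to a YAML file.
#' @param evidence_paths Named character vector of evidence TSV paths
#'   (names are sample ids; unnamed paths use the file name).
#' @param out_dir Output directory.
#' @return Named list of per-sample results (from [analyze_sample()]),
#'   invisibly.
#' @export
run_pipeline <- function(config, evidence_paths, out_dir) {
  if (is.character(config)) config <- read_analysis_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(evidence_paths)) || any(!nzchar(names(evidence_paths)))) {
    names(evidence_paths) <- sub("\\.tsv$", "", basename(evidence_paths))
  }
  results <- list()
  for (sid in names(evidence_paths)) {
    res <- tryCatch({
      rows <- read_evidence(evidence_paths[[sid]], sample_id = sid)
      analyze_sample(rows, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      writeLines(sprintf("FAILED at sample %s: %s", sid, conditionMessage(res)),
                 file.path(out_dir, "FAILED"))
      rlang::abort(sprintf("pipeline failed at sample %s: %s", sid,
                           conditionMessage(res)))
    }
    results[[sid]] <- res
    safe <- gsub("[^A-Za-z0-9._-]", "_", sid)
    render_report(res$summaries, file.path(out_dir, paste0(safe, "_report.tsv")))
    write_taxon_calls(res$taxon_calls, file.path(out_dir, paste0(safe, "_taxon_calls.tsv")))
    write_identifications(res$identifications,
                          file.path(out_dir, paste0(safe, "_identifications.tsv")))
    readr::write_tsv(dplyr::select(res$removal_log, "sequence", "score", "reason"),
                     file.path(out_dir, paste0(safe, "_removal_log.tsv")),
                     progress = FALSE)
    if (nrow(res$deamidation) > 0) {
      readr::write_tsv(res$deamidation,
                       file.path(out_dir, paste0(safe, "_deamidation.tsv")),
                       progress = FALSE)
    }
  }
  binder_calls <- dplyr::bind_rows(lapply(results, function(r) {
    if (is.null(r$binder_call)) return(NULL)
    tibble::tibble(sample_id = r$binder_call$sample_id,
                   dominant_source = r$binder_call$dominant_source,
                   dominant_share = r$binder_call$dominant_share,
                   caveats = paste(r$binder_call$caveats[[1]], collapse = " | "))
  }))
  readr::write_tsv(binder_calls, file.path(out_dir, "binder_calls.tsv"),
                   progress = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("binderID")),
    config = serialize_config(config),
    evidence = as.list(evidence_paths),
    samples = names(evidence_paths)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

serialize_config <- function(config) {
  list(
    databases = lapply(config$databases, function(d) {
      list(name = attr(d, "db_name"), n_entries = nrow(d))
    }),
    contaminants = if (is.null(config$contaminants)) NULL else
      list(name = attr(config$contaminants, "db_name"),
           n_entries = nrow(config$contaminants)),
    filter = unclass(config$filter),
    digest = unclass(config$digest),
    equivalence = unclass(config$equivalence),
    plausibility = if (is.null(config$plausibility)) NULL else
      unclass(config$plausibility),
    taxon_groups = config$taxon_groups,
    protein_groups = config$protein_groups,
    damage = config$damage,
    binder_threshold = config$binder_threshold,
    iterative = config$iterative,
    upstream = config$upstream
  )
}
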