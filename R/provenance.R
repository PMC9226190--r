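#' Source attribution and per-sample binder reports
#'
#' Confident proteins are mapped to the material they signal — egg yolk
#' (vitellogenins, apolipoprotein B), egg white (lysozyme, ovalbumin,
#' ovotransferrin, ovoinhibitor), animal glue (collagen I), hide glue
#' (collagen III), wool (non-contaminant keratins) — and aggregated into
#' per-sample summaries whose peptide shares drive the binder call.
#'
#' @name provenance
NULL

#' Default source-mapping rules
#'
#' Ordered regular-expression rules over a protein's description and
#' accession; the first match wins. Explicit `source_class` metadata on a
#' database entry always takes precedence over these patterns.
#'
#' @return Tibble with columns `pattern` and `source_class`.
#' @export
default_source_map <- function() {
  tibble::tribble(
    ~pattern,                                            ~source_class,
    "vitellogenin|apolipoprotein[ -]?B",                 "egg_yolk",
    "lysozyme|ovalbumin|ovotransferrin|ovoinhibitor",    "egg_white",
    "serum albumin|albumin",                             "blood_or_egg",
    "collagen.*(\\(III\\)|type[ -]III|alpha-[0-9]\\(III\\))", "hide_glue_indicator",
    "collagen.*(\\(I\\)|type[ -]I\\b|alpha-[12]\\(I\\))", "animal_glue",
    "keratin",                                           "wool"
  )
}

#' Read a source map from TSV (columns `pattern`, `source_class`)
#' @param path TSV path.
#' @return Source-map tibble.
#' @export
read_source_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("pattern", "source_class") %in% names(tab))) {
    abort_format("source map must have columns 'pattern' and 'source_class'")
  }
  bad <- setdiff(unique(tab$source_class), SOURCE_CLASSES)
  if (length(bad) > 0) abort_format("unknown source_class '%s' in source map", bad[1])
  tab[, c("pattern", "source_class")]
}

#' Map identified proteins to source classes
#'
#' @param ids Identification tibble from [identify_proteins()].
#' @param db A `sequence_db` (entry metadata takes precedence).
#' @param map Source-map tibble; see [default_source_map()].
#' @return Named character vector: accession -> source_class.
#' @export
map_sources <- function(ids, db, map = default_source_map()) {
  out <- character(nrow(ids))
  names(out) <- ids$accession
  for (acc in ids$accession) {
    i <- match(acc, db$accession)
    meta <- if (!is.na(i)) db$source_class[[i]] else "unassigned"
    if (!meta %in% c("unassigned")) {
      out[[acc]] <- meta
      next
    }
    text <- if (!is.na(i)) paste(db$description[[i]], acc) else acc
    hit <- "other"
    for (r in seq_len(nrow(map))) {
      if (stringr::str_detect(tolower(text), stringr::regex(tolower(map$pattern[[r]])))) {
        hit <- map$source_class[[r]]
        break
      }
    }
    out[[acc]] <- hit
  }
  out
}

#' Summarise a sample's identifications per source class
#'
#' Only confident proteins contribute. A peptide shared between proteins
#' of two source classes is counted once, under the class of the protein
#' with more unique peptides (ties broken by source-map order), so the
#' per-class counts are disjoint and peptide shares sum to one.
#' `n_peptides` counts distinct peptide sequences.
#'
#' @param sample_id Sample label.
#' @param ids Identification tibble.
#' @param taxon_calls Taxon-call tibble (may be empty) used for the
#'   diagnostic-peptide counts and the taxon label.
#' @param source_classes Named accession -> class vector from
#'   [map_sources()].
#' @param rows Evidence tibble (for spectra counts).
#' @param map Source map (supplies the tie-break order).
#' @return Tibble of per-class rows: `sample_id`, `source_class`,
#'   `n_proteins`, `n_peptides`, `n_diagnostic_peptides`, `n_spectra`,
#'   `taxon`, `peptide_share`.
#' @export
summarize_sample <- function(sample_id, ids, taxon_calls, source_classes,
                             rows, map = default_source_map()) {
  conf <- ids[ids$confident, , drop = FALSE]
  if (nrow(conf) == 0) {
    return(tibble::tibble(sample_id = character(0), source_class = character(0),
                          n_proteins = integer(0), n_peptides = integer(0),
                          n_diagnostic_peptides = integer(0), n_spectra = integer(0),
                          taxon = character(0), peptide_share = numeric(0)))
  }
  class_order <- unique(c(map$source_class, SOURCE_CLASSES))
  # peptide -> class assignment with the documented precedence
  pep_tab <- purrr::map2_dfr(conf$accession, conf$supporting_peptides,
                             function(acc, sup) {
                               tibble::tibble(accession = acc,
                                              peptide = unique(sup$peptide))
                             })
  pep_tab$class <- unname(source_classes[pep_tab$accession])
  pep_tab$n_unique_of_protein <- conf$n_unique[match(pep_tab$accession, conf$accession)]
  assign_class <- pep_tab |>
    dplyr::group_by(.data$peptide) |>
    dplyr::arrange(dplyr::desc(.data$n_unique_of_protein),
                   match(.data$class, class_order), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("peptide", "class")

  spectra <- tapply(rows$msms_count, rows$sequence, sum)
  diag_peps <- if (nrow(taxon_calls) > 0) taxon_calls$peptide[taxon_calls$diagnostic] else character(0)

  total_peps <- nrow(assign_class)
  classes_present <- intersect(class_order,
                               union(assign_class$class,
                                     unname(source_classes[conf$accession])))
  out <- lapply(classes_present, function(cl) {
    peps <- assign_class$peptide[assign_class$class == cl]
    accs <- conf$accession[unname(source_classes[conf$accession]) == cl]
    # taxon label: parsimony-consistent union of targets over this class's peptides
    taxon <- NA_character_
    if (nrow(taxon_calls) > 0) {
      targets <- taxon_calls$target_taxon[taxon_calls$peptide %in% peps &
                                            !is.na(taxon_calls$target_taxon)]
      if (length(targets) > 0) {
        taxon <- paste(sort(unique(targets)), collapse = "; ")
      }
    }
    tibble::tibble(
      sample_id = sample_id,
      source_class = cl,
      n_proteins = length(accs),
      n_peptides = length(peps),
      n_diagnostic_peptides = sum(peps %in% diag_peps),
      n_spectra = as.integer(sum(spectra[peps], na.rm = TRUE)),
      taxon = taxon,
      peptide_share = length(peps) / total_peps
    )
  })
  dplyr::bind_rows(out)
}

#' Call the dominant binder for a sample
#'
#' @param summaries Per-class summary tibble from [summarize_sample()]
#'   (one sample).
#' @param threshold Minimum dominant peptide share before the call is
#'   flagged as mixed (default 0.6).
#' @return One-row tibble: `sample_id`, `dominant_source`,
#'   `dominant_share`, `secondary_sources` (list), `caveats` (list).
#' @export
call_binder <- function(summaries, threshold = 0.6) {
  if (nrow(summaries) == 0) abort_format("cannot call a binder from an empty summary")
  ord <- order(summaries$peptide_share, decreasing = TRUE)
  dom <- summaries[ord[1], ]
  secondary <- summaries$source_class[ord[-1]]
  caveats <- character(0)
  if (dom$peptide_share < threshold) {
    caveats <- c(caveats, "mixed layers / cross-layer sampling")
  }
  classes <- summaries$source_class
  if ("egg_white" %in% classes && any(c("egg_yolk", "egg_ambiguous") %in% classes)) {
    caveats <- c(caveats,
                 paste("egg-white proteins alongside yolk do not necessarily indicate",
                       "intentional use of whole egg: manual separation of yolk from",
                       "white is rarely complete"))
  }
  tibble::tibble(
    sample_id = dom$sample_id,
    dominant_source = dom$source_class,
    dominant_share = dom$peptide_share,
    secondary_sources = list(secondary),
    caveats = list(caveats)
  )
}

#' Render per-sample summaries as a report table
#'
#' Mirrors the classic per-sample summary layout (proteins / total
#' peptides / species-diagnostic peptides / MS-MS spectra / protein
#' source / taxonomic source); zero diagnostic peptides render as an
#' en dash.
#'
#' @param summaries Summary tibble (possibly several samples).
#' @param path Optional output path (TSV, or Markdown when `format =
#'   "markdown"`).
#' @param format `"tsv"` or `"markdown"`.
#' @return The rendered tibble (invisibly when written to `path`).
#' @export
render_report <- function(summaries, path = NULL, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  pretty <- c(egg_yolk = "Egg yolk", egg_white = "Egg white",
              egg_ambiguous = "Egg (ambiguous)", blood_or_egg = "Blood or egg",
              animal_glue = "Animal glue", hide_glue_indicator = "Hide glue (indicator)",
              wool = "Wool", other = "Other", unassigned = "Unassigned")
  tab <- tibble::tibble(
    Sample = summaries$sample_id,
    `Identified proteins` = summaries$n_proteins,
    `Total identified peptides` = summaries$n_peptides,
    `Species-diagnostic peptides` = ifelse(summaries$n_diagnostic_peptides == 0,
                                           "–",
                                           as.character(summaries$n_diagnostic_peptides)),
    `Matching MS/MS spectra` = summaries$n_spectra,
    `Protein source` = unname(pretty[summaries$source_class]),
    `Taxonomic source` = ifelse(is.na(summaries$taxon), "", summaries$taxon)
  )
  if (is.null(path)) return(tab)
  if (format == "tsv") {
    readr::write_tsv(tab, path, progress = FALSE)
  } else {
    header <- paste0("| ", paste(names(tab), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
    body <- apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(header, sep, body), path)
  }
  invisible(tab)
}
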