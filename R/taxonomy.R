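#' Species-diagnostic peptide assessment
#'
#' A peptide identifies a species only if its sequence, after accounting
#' for substitutions that tandem MS cannot (always) distinguish, occurs in
#' no other sequenced species — or only in species that are historically
#' or geographically implausible sources for the object. Three ambiguity
#' cases are modelled:
#'
#' * isoleucine/leucine: identical mass, never distinguishable;
#' * asparagine/aspartate and glutamine/glutamate: indistinguishable at a
#'   site unless at least one spectrum shows the non-deamidated form
#'   there (deamidation adds the same +0.984 Da as the substitution);
#' * serine/alanine: the hydroxyl distinguishing S from A can also arrive
#'   by oxidation of a nearby proline or methionine, so near an oxidised
#'   residue the pair is ambiguous unless a fragment ion localises the
#'   site.
#'
#' @name taxonomy
NULL

#' In-silico digestion parameters
#'
#' @param enzyme `"trypsin"` (cleave after K/R), `"trypsin_no_P"`
#'   (suppress cleavage before proline) or `"unspecific"` (all substrings).
#' @param max_missed Maximum internal missed cleavage sites.
#' @param min_len,max_len Peptide length bounds in residues (`max_len`
#'   mainly constrains unspecific digestion).
#' @return A `digest_params` list.
#' @export
digest_params <- function(enzyme = c("trypsin", "trypsin_no_P", "unspecific"),
                          max_missed = 2, min_len = 7, max_len = 30) {
  enzyme <- match.arg(enzyme)
  stopifnot(max_missed >= 0, min_len >= 1, min_len <= max_len)
  structure(list(enzyme = enzyme, max_missed = as.integer(max_missed),
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "digest_params")
}

#' Mass-ambiguity equivalence rules
#'
#' @param il_equal Treat I and L as indistinguishable (always true in
#'   tandem MS).
#' @param nd_conditional Treat N/D (and Q/E) as indistinguishable at a
#'   site unless a non-deamidated observation of that site exists.
#' @param sa_near_oxidation Treat S/A as indistinguishable near an
#'   oxidised residue unless fragment ions cover the site.
#' @param window Distance in residues within which an oxidised site makes
#'   an S/A site ambiguous.
#' @param oxidizable Residues whose oxidation can mimic the serine
#'   hydroxyl (default proline and methionine).
#' @param require_fragment_coverage Strict mode: a peptide is diagnostic
#'   only if every distinguishing site is covered by a fragment ion.
#'   Off by default (coverage data is optional input); when off, calls
#'   carry a warning note instead.
#' @return An `equivalence_rules` list.
#' @export
equivalence_rules <- function(il_equal = TRUE, nd_conditional = TRUE,
                              sa_near_oxidation = TRUE, window = 1,
                              oxidizable = c("P", "M"),
                              require_fragment_coverage = FALSE) {
  stopifnot(window >= 1)
  if (sa_near_oxidation && length(oxidizable) == 0) {
    abort_format("sa_near_oxidation requires a non-empty oxidizable set")
  }
  structure(list(il_equal = il_equal, nd_conditional = nd_conditional,
                 sa_near_oxidation = sa_near_oxidation,
                 window = as.integer(window), oxidizable = oxidizable,
                 require_fragment_coverage = require_fragment_coverage),
            class = "equivalence_rules")
}

#' Per-peptide observation context
#'
#' Summarises what the supporting spectra of one peptide show: which
#' sites were only ever seen deamidated, which were seen oxidised, and
#' which are bracketed by at least one fragment ion.
#'
#' @param peptide Peptide sequence.
#' @param deamidated_only_sites Integer sites (1-based) where every
#'   supporting spectrum carries deamidation.
#' @param oxidized_sites Integer sites observed oxidised.
#' @param covered_sites Integer sites covered by fragment ions, or `NULL`
#'   when coverage is unknown.
#' @return An `observation_context` list.
#' @export
observation_context <- function(peptide, deamidated_only_sites = integer(0),
                                oxidized_sites = integer(0),
                                covered_sites = NULL) {
  n <- nchar(peptide)
  idx <- c(deamidated_only_sites, oxidized_sites, covered_sites)
  if (length(idx) > 0 && (min(idx) < 1 || max(idx) > n)) {
    abort_format("observation context site index outside peptide length %d", n)
  }
  structure(list(peptide = peptide,
                 deamidated_only_sites = as.integer(deamidated_only_sites),
                 oxidized_sites = as.integer(oxidized_sites),
                 covered_sites = if (is.null(covered_sites)) NULL else as.integer(covered_sites)),
            class = "observation_context")
}

#' Build observation contexts from evidence
#'
#' A site enters `deamidated_only_sites` iff every supporting row carries
#' deamidation at that position — a single unmodified observation removes
#' it. Oxidised sites accumulate over rows. Fragment coverage is unknown
#' unless supplied via `coverage`, a named list of integer vectors keyed
#' by peptide.
#'
#' @param rows Evidence tibble.
#' @param coverage Optional named list of covered-site vectors.
#' @return Named list of [observation_context()] objects keyed by peptide.
#' @export
observation_contexts <- function(rows, coverage = NULL) {
  peps <- unique(rows$sequence)
  out <- lapply(peps, function(pep) {
    sub <- rows[rows$sequence == pep, , drop = FALSE]
    n <- nchar(pep)
    deam_all <- NULL
    oxid <- integer(0)
    for (mods in sub$modifications) {
      d <- mods$position[mods$name == "deamidation"]
      o <- mods$position[mods$name == "oxidation"]
      deam_all <- if (is.null(deam_all)) d else intersect(deam_all, d)
      oxid <- union(oxid, o)
    }
    observation_context(pep,
                        deamidated_only_sites = sort(deam_all %||% integer(0)),
                        oxidized_sites = sort(oxid[oxid > 0]),
                        covered_sites = coverage[[pep]])
  })
  names(out) <- peps
  out
}

#' In-silico digestion of a protein
#'
#' Trypsin cleaves after K or R; `trypsin_no_P` suppresses cleavage when
#' the next residue is proline. Peptides with at most `max_missed`
#' internal cleavage sites and length within bounds are returned;
#' `unspecific` returns every substring within the length bounds.
#'
#' @param sequence Protein sequence (or a one-row `sequence_db` entry).
#' @param params A [digest_params()].
#' @return Character vector of distinct peptide sequences.
#' @export
digest <- function(sequence, params = digest_params()) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1]]
  stopifnot(nzchar(sequence))
  sc <- chars(sequence)
  n <- length(sc)
  if (params$enzyme == "unspecific") {
    peps <- character(0)
    for (len in seq.int(params$min_len, min(params$max_len, n))) {
      for (s in seq_len(n - len + 1L)) {
        peps <- c(peps, substr(sequence, s, s + len - 1L))
      }
    }
    return(unique(peps))
  }
  no_p <- params$enzyme == "trypsin_no_P"
  cut_after <- which(sc %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (no_p) cut_after <- cut_after[sc[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)
  peps <- character(0)
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in seq.int(i + 1L, min(i + 1L + params$max_missed, length(bounds)))) {
      pep <- substr(sequence, bounds[i] + 1L, bounds[j])
      len <- bounds[j] - bounds[i]
      if (len >= params$min_len && len <= params$max_len) peps <- c(peps, pep)
    }
  }
  unique(peps)
}

#' Can two residues be confused at a given site?
#'
#' @param a,b Single amino-acid codes (peptide residue and candidate
#'   database residue).
#' @param site_index 1-based position within the peptide.
#' @param ctx [observation_context()] for the peptide (or `NULL`).
#' @param rules [equivalence_rules()].
#' @return TRUE when the observed spectra cannot exclude residue `b` at
#'   this site.
#' @export
sites_equivalent <- function(a, b, site_index, ctx = NULL,
                             rules = equivalence_rules()) {
  if (a == b) return(TRUE)
  pair <- sort(c(a, b))
  if (rules$il_equal && identical(pair, c("I", "L"))) return(TRUE)
  if (rules$nd_conditional &&
      (identical(pair, c("D", "N")) || identical(pair, c("E", "Q")))) {
    deam <- if (is.null(ctx)) integer(0) else ctx$deamidated_only_sites
    if (site_index %in% deam) return(TRUE)
  }
  if (rules$sa_near_oxidation && identical(pair, c("A", "S"))) {
    oxid <- if (is.null(ctx)) integer(0) else ctx$oxidized_sites
    covered <- if (is.null(ctx)) NULL else ctx$covered_sites
    near <- any(abs(oxid - site_index) <= rules$window)
    localized <- !is.null(covered) && site_index %in% covered
    if (near && !localized) return(TRUE)
  }
  FALSE
}

#' Which species could a peptide originate from?
#'
#' A species matches iff some protein of that species contains an
#' occurrence of the peptide in which every site passes
#' [sites_equivalent()], and — for tryptic enzymes — the occurrence is
#' consistent with digestion (preceded by K/R or the protein start,
#' ending in K/R or at the protein end). Terminus consistency is skipped
#' for `enzyme = "unspecific"`.
#'
#' @param peptide Peptide sequence.
#' @param ctx [observation_context()] for the peptide (or `NULL`).
#' @param dbs A `sequence_db` or list of them.
#' @param params [digest_params()] (supplies the enzyme).
#' @param rules [equivalence_rules()]; `NULL` for exact matching.
#' @param include_contaminants Also match contaminant-flagged entries
#'   (default FALSE).
#' @return Character vector of species (sorted, unique; NA species
#'   dropped).
#' @export
species_matches <- function(peptide, ctx = NULL, dbs, params = digest_params(),
                            rules = equivalence_rules(),
                            include_contaminants = FALSE) {
  if (inherits(dbs, "sequence_db")) dbs <- list(dbs)
  stopifnot(length(dbs) >= 1)
  pc <- chars(peptide)
  m <- length(pc)
  tryptic <- params$enzyme %in% c("trypsin", "trypsin_no_P")
  species <- character(0)
  for (db in dbs) {
    keep <- if (include_contaminants) rep(TRUE, nrow(db)) else !db$is_contaminant
    for (di in which(keep)) {
      sp <- db$species[[di]]
      if (is.na(sp) || sp %in% species) next
      sc <- chars(db$sequence[[di]])
      starts <- find_occurrences(pc, sc, rules, ctx)
      if (tryptic && length(starts) > 0) {
        starts <- starts[vapply(starts, function(s) {
          tryptic_consistent(sc, s, s + m - 1L,
                             no_p = identical(params$enzyme, "trypsin_no_P"))
        }, logical(1))]
      }
      if (length(starts) > 0) species <- c(species, sp)
    }
  }
  sort(unique(species))
}

#' Plausibility filter
#'
#' Restricts candidate source species on historical/geographical grounds
#' (e.g. excluding East-Asian bovids for a fifteenth-century Italian
#' panel).
#'
#' @param allowed_species Character vector of plausible species.
#' @param rationale One-line justification, recorded in every call the
#'   filter touches.
#' @return A `plausibility_filter` list.
#' @export
plausibility_filter <- function(allowed_species, rationale) {
  stopifnot(length(allowed_species) > 0, is.character(rationale))
  structure(list(allowed_species = allowed_species, rationale = rationale),
            class = "plausibility_filter")
}

#' Read a plausibility filter from TSV
#'
#' Expects columns `species` and (on any row) `rationale`.
#' @param path TSV path.
#' @return A [plausibility_filter()].
#' @export
read_plausibility_filter <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"species" %in% names(tab)) abort_format("plausibility file lacks a 'species' column")
  rationale <- if ("rationale" %in% names(tab)) {
    paste(unique(stats::na.omit(tab$rationale)), collapse = "; ")
  } else ""
  plausibility_filter(tab$species, rationale)
}

#' Diagnose a peptide's taxonomic specificity
#'
#' The plausibility filter intersects the matched species with the
#' allowed set (recording what was excluded and why); the peptide is
#' diagnostic iff the filtered set is non-empty and lies entirely within
#' the target taxon/group. In strict fragment-coverage mode every
#' distinguishing site (a site at which the peptide differs from a
#' near-miss occurrence in a non-target species) must additionally be
#' covered by a fragment ion.
#'
#' @param peptide Peptide sequence.
#' @param matches Species set from [species_matches()].
#' @param plausibility Optional [plausibility_filter()].
#' @param target Character vector of species forming the target taxon or
#'   group (e.g. `c("Ovis aries", "Capra hircus")`).
#' @param ctx [observation_context()] (or `NULL`).
#' @param rules [equivalence_rules()].
#' @param dbs Databases, needed only in strict coverage mode to find the
#'   distinguishing sites.
#' @param ambiguity_notes Optional tibble (`site`, `rule`) recording
#'   equivalence-rule applications during matching.
#' @return One-row tibble: `peptide`, `matched_species` and
#'   `matched_after_plausibility` (list columns), `diagnostic`,
#'   `target_taxon`, `notes` (list column of character).
#' @export
diagnose <- function(peptide, matches, plausibility = NULL, target,
                     ctx = NULL, rules = equivalence_rules(), dbs = NULL,
                     ambiguity_notes = NULL) {
  notes <- character(0)
  filtered <- matches
  if (!is.null(plausibility)) {
    excluded <- setdiff(matches, plausibility$allowed_species)
    filtered <- intersect(matches, plausibility$allowed_species)
    if (length(excluded) > 0) {
      notes <- c(notes, sprintf("plausibility excluded: %s (%s)",
                                paste(excluded, collapse = ", "),
                                plausibility$rationale))
    }
    if (length(filtered) == 0 && length(matches) > 0) {
      notes <- c(notes, "implausible-only matches")
    }
  }
  diagnostic <- length(filtered) > 0 && all(filtered %in% target)
  if (diagnostic) {
    if (rules$require_fragment_coverage) {
      sites <- if (is.null(dbs)) integer(0) else
        distinguishing_sites(peptide, dbs, target, ctx, rules)
      covered <- if (is.null(ctx)) NULL else ctx$covered_sites
      if (length(sites) > 0 && (is.null(covered) || !all(sites %in% covered))) {
        diagnostic <- FALSE
        notes <- c(notes, "distinguishing site(s) not covered by fragment ions")
      }
    } else {
      notes <- c(notes, "warning: fragment coverage of distinguishing sites not verified")
    }
  }
  if (!is.null(ambiguity_notes) && nrow(ambiguity_notes) > 0) {
    notes <- c(notes, sprintf("ambiguity rule %s at site %d",
                              ambiguity_notes$rule, ambiguity_notes$site))
  }
  tibble::tibble(
    peptide = peptide,
    matched_species = list(matches),
    matched_after_plausibility = list(filtered),
    diagnostic = diagnostic,
    target_taxon = if (diagnostic) paste(target, collapse = "/") else NA_character_,
    notes = list(notes)
  )
}

# sites where the peptide differs (exact comparison) from a near-miss
# occurrence (Hamming distance <= max_mismatch) in any non-target species
distinguishing_sites <- function(peptide, dbs, target, ctx, rules,
                                 max_mismatch = 2L) {
  if (inherits(dbs, "sequence_db")) dbs <- list(dbs)
  pc <- chars(peptide)
  m <- length(pc)
  sites <- integer(0)
  for (db in dbs) {
    for (di in seq_len(nrow(db))) {
      sp <- db$species[[di]]
      if (is.na(sp) || sp %in% target) next
      sc <- chars(db$sequence[[di]])
      n <- length(sc)
      if (m > n) next
      for (s in seq_len(n - m + 1L)) {
        mism <- which(pc != sc[seq.int(s, s + m - 1L)])
        if (length(mism) > 0 && length(mism) <= max_mismatch) {
          sites <- union(sites, mism)
        }
      }
    }
  }
  sort(sites)
}

#' Parsimony assignment of non-diagnostic peptides
#'
#' A non-diagnostic call whose plausible matches intersect the confirmed
#' taxa in exactly one taxon (species or indistinguishable group) is
#' assigned to that taxon with a "parsimony" note; matches resolving to a
#' confirmed group keep the group label with a "parsimony-group" note.
#'
#' @param calls Tibble of taxon calls (rows from [diagnose()]).
#' @param confirmed Named list of character vectors: taxa supported by at
#'   least one diagnostic peptide in the same sample; names are the taxon
#'   labels, elements the member species (length > 1 for groups).
#' @return `calls` with `target_taxon`/`notes` updated where parsimony
#'   applies.
#' @export
parsimony_assign <- function(calls, confirmed) {
  if (length(confirmed) == 0 || nrow(calls) == 0) return(calls)
  if (is.null(names(confirmed)) || any(!nzchar(names(confirmed)))) {
    names(confirmed) <- vapply(confirmed, paste, character(1), collapse = "/")
  }
  for (i in seq_len(nrow(calls))) {
    if (isTRUE(calls$diagnostic[[i]])) next
    matched <- calls$matched_after_plausibility[[i]]
    hit <- which(vapply(confirmed, function(u) length(intersect(matched, u)) > 0,
                        logical(1)))
    if (length(hit) != 1) next
    unit <- confirmed[[hit]]
    inter <- intersect(matched, unit)
    if (length(inter) == 1) {
      calls$target_taxon[[i]] <- inter
      calls$notes[[i]] <- c(calls$notes[[i]], "parsimony")
    } else {
      calls$target_taxon[[i]] <- names(confirmed)[hit]
      calls$notes[[i]] <- c(calls$notes[[i]], "parsimony-group")
    }
  }
  calls
}

#' Write taxon calls to TSV
#' @param calls Taxon-call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxon_calls <- function(calls, path) {
  flat <- tibble::tibble(
    peptide = calls$peptide,
    matched_species = purrr::map_chr(calls$matched_species, paste, collapse = ";"),
    matched_after_plausibility = purrr::map_chr(calls$matched_after_plausibility,
                                                paste, collapse = ";"),
    diagnostic = calls$diagnostic,
    target_taxon = calls$target_taxon,
    notes = purrr::map_chr(calls$notes, paste, collapse = " | ")
  )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
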