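#' Evidence filtering and confident protein identification
#'
#' Implements the standard palaeoproteomic confidence contract: evidence
#' rows are filtered on decoy/contaminant status, search-engine score and
#' peptide length; a protein is then considered confidently identified
#' only when at least two of its unique peptides are non-overlapping,
#' where "non-overlapping" means neither peptide's interval entirely
#' contains the other's — partial overlap does not disqualify.
#'
#' @name confidence
NULL

#' Evidence filter configuration
#'
#' Defaults follow common search-engine post-processing for degraded
#' samples: minimum peptide score 40, minimum length 7 residues, decoy
#' (reverse) and contaminant matches dropped.
#'
#' @param min_score Minimum search-engine score (dimensionless).
#' @param min_length Minimum peptide length in residues.
#' @param drop_reverse Drop decoy (reversed-sequence) matches.
#' @param drop_contaminants Drop rows explained only by contaminants.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_score = 40, min_length = 7,
                          drop_reverse = TRUE, drop_contaminants = TRUE) {
  stopifnot(is.finite(min_score), min_length >= 1)
  structure(list(min_score = min_score, min_length = as.integer(min_length),
                 drop_reverse = drop_reverse,
                 drop_contaminants = drop_contaminants),
            class = "filter_config")
}

#' Filter evidence rows
#'
#' Removal reasons are assigned with a fixed precedence so the log is
#' deterministic: `reverse` > `contaminant` > `score` > `length`. A row
#' counts as contaminant when its flag is set or when every one of its
#' protein references is a contaminant accession.
#'
#' @param rows Evidence tibble.
#' @param cfg A [filter_config()].
#' @param contaminants A `sequence_db` of contaminant entries (may have
#'   zero rows), or `NULL`.
#' @return List with `kept` (tibble) and `removed` (tibble with an extra
#'   `reason` column); `nrow(kept) + nrow(removed) == nrow(rows)`.
#' @export
filter_evidence <- function(rows, cfg = filter_config(), contaminants = NULL) {
  if (nrow(rows) == 0) {
    return(list(kept = rows, removed = dplyr::mutate(rows, reason = character(0))))
  }
  contam_acc <- if (is.null(contaminants)) character(0) else contaminants$accession
  all_contam <- purrr::map_lgl(rows$protein_refs, function(refs) {
    length(refs) > 0 && all(refs %in% contam_acc)
  })
  reason <- rep(NA_character_, nrow(rows))
  if (cfg$drop_reverse) reason[is.na(reason) & rows$is_reverse] <- "reverse"
  if (cfg$drop_contaminants) {
    reason[is.na(reason) & (rows$is_contaminant | all_contam)] <- "contaminant"
  }
  reason[is.na(reason) & rows$score < cfg$min_score] <- "score"
  reason[is.na(reason) & nchar(rows$sequence) < cfg$min_length] <- "length"
  kept <- rows[is.na(reason), , drop = FALSE]
  removed <- rows[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(kept = kept, removed = removed)
}

#' Locate peptides in a sequence database
#'
#' Every occurrence of each peptide in each protein yields one interval
#' (1-based, inclusive). Matching is exact unless `rules` (an
#' [equivalence_rules()] object) is supplied, in which case residues are
#' compared with [sites_equivalent()] using the per-peptide observation
#' context. Overlapping occurrences within one protein are all reported.
#'
#' @param peptides Character vector of peptide sequences.
#' @param db A `sequence_db`.
#' @param rules Optional [equivalence_rules()]; `NULL` for exact matching.
#' @param contexts Optional named list of [observation_context()] objects
#'   keyed by peptide sequence (used only with `rules`).
#' @param enzyme Optional digestion consistency: `"none"` (default, match
#'   anywhere), `"trypsin"` or `"trypsin_no_P"` require tryptic termini.
#' @return Tibble with columns `accession`, `peptide`, `start`, `end`.
#' @export
locate_peptides <- function(peptides, db, rules = NULL, contexts = NULL,
                            enzyme = "none") {
  peptides <- unique(peptides)
  res <- vector("list", length(peptides) * nrow(db))
  k <- 0L
  prot_chars <- lapply(db$sequence, chars)
  for (pi in seq_along(peptides)) {
    pep <- peptides[[pi]]
    ctx <- if (!is.null(contexts)) contexts[[pep]] else NULL
    pc <- chars(pep)
    m <- length(pc)
    for (di in seq_len(nrow(db))) {
      sc <- prot_chars[[di]]
      n <- length(sc)
      if (m > n) next
      starts <- find_occurrences(pc, sc, rules, ctx)
      if (enzyme %in% c("trypsin", "trypsin_no_P") && length(starts) > 0) {
        starts <- starts[vapply(starts, function(s) {
          tryptic_consistent(sc, s, s + m - 1L, no_p = identical(enzyme, "trypsin_no_P"))
        }, logical(1))]
      }
      if (length(starts) > 0) {
        k <- k + 1L
        res[[k]] <- tibble::tibble(accession = db$accession[[di]],
                                   peptide = pep,
                                   start = as.integer(starts),
                                   end = as.integer(starts + m - 1L))
      }
    }
  }
  if (k == 0L) {
    return(tibble::tibble(accession = character(0), peptide = character(0),
                          start = integer(0), end = integer(0)))
  }
  dplyr::bind_rows(res[seq_len(k)])
}

# all (overlapping) start positions where pep_chars matches prot_chars,
# exactly or site-by-site under equivalence rules
find_occurrences <- function(pep_chars, prot_chars, rules = NULL, ctx = NULL) {
  m <- length(pep_chars)
  n <- length(prot_chars)
  if (m > n) return(integer(0))
  starts <- integer(0)
  for (s in seq_len(n - m + 1L)) {
    ok <- TRUE
    for (i in seq_len(m)) {
      a <- pep_chars[[i]]
      b <- prot_chars[[s + i - 1L]]
      if (a == b) next
      if (is.null(rules) || !sites_equivalent(a, b, i, ctx, rules)) {
        ok <- FALSE
        break
      }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

# a peptide occurrence [start, end] is consistent with tryptic digestion:
# preceded by K/R or protein start, and ending in K/R or at protein end
tryptic_consistent <- function(prot_chars, start, end, no_p = FALSE) {
  n <- length(prot_chars)
  left_ok <- start == 1L ||
    (prot_chars[[start - 1L]] %in% c("K", "R") &&
       !(no_p && prot_chars[[start]] == "P"))
  right_ok <- end == n ||
    (prot_chars[[end]] %in% c("K", "R") &&
       !(no_p && prot_chars[[end + 1L]] == "P"))
  left_ok && right_ok
}

#' Two-non-overlapping-peptides rule
#'
#' TRUE iff there exist two intervals from distinct peptides such that
#' neither entirely contains the other. Containment of A in B means
#' `A.start >= B.start` and `A.end <= B.end`; equal intervals are mutual
#' containment and do not qualify; partial overlap does qualify.
#'
#' @param intervals Tibble with columns `peptide`, `start`, `end`, all
#'   referring to one protein.
#' @return Logical flag.
#' @export
has_two_non_overlapping <- function(intervals) {
  n <- nrow(intervals)
  if (n < 2) return(FALSE)
  s <- intervals$start
  e <- intervals$end
  p <- intervals$peptide
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (p[[i]] == p[[j]]) next
      a_in_b <- s[[i]] >= s[[j]] && e[[i]] <= e[[j]]
      b_in_a <- s[[j]] >= s[[i]] && e[[j]] <= e[[i]]
      if (!a_in_b && !b_in_a) return(TRUE)
    }
  }
  FALSE
}

#' Identify confidently supported proteins
#'
#' Peptides are assigned to every database protein containing them as an
#' exact substring. A peptide is unique iff it occurs in exactly one
#' protein of the analysis database, where database entries with
#' identical sequences are first collapsed so that redundant duplicates
#' do not destroy uniqueness (set `collapse_identical = FALSE` to take
#' the database literally). Confidence applies the non-overlap rule to
#' each protein's unique peptides only.
#'
#' With `groups`, uniqueness is evaluated at the protein-group level
#' instead: a peptide shared only among entries of one group (e.g. the
#' sheep/goat/cattle orthologs of one collagen chain) still counts as
#' unique to that group. This is the appropriate reading when the
#' database deliberately carries orthologous sequences from several
#' candidate species — species-level uniqueness is then ill-posed, and
#' species resolution belongs to the taxonomy step. Off by default.
#'
#' @param rows Filtered evidence tibble.
#' @param db A `sequence_db`.
#' @param collapse_identical Collapse entries with identical sequence
#'   before computing uniqueness (default TRUE).
#' @param groups Optional named list of accession vectors defining
#'   protein groups for uniqueness; accessions not listed form singleton
#'   groups.
#' @return Tibble of identifications: `accession`, `supporting_peptides`
#'   (list of per-protein tibbles `peptide`, `unique`, `start`, `end`),
#'   `n_peptides`, `n_unique`, `has_two_non_overlapping`, `confident`,
#'   `n_spectra`.
#' @export
identify_proteins <- function(rows, db, collapse_identical = TRUE,
                              groups = NULL) {
  peptides <- sort(unique(rows$sequence))
  if (length(peptides) == 0) {
    return(tibble::tibble(accession = character(0),
                          supporting_peptides = list(),
                          n_peptides = integer(0), n_unique = integer(0),
                          has_two_non_overlapping = logical(0),
                          confident = logical(0), n_spectra = integer(0)))
  }
  hits <- locate_peptides(peptides, db)
  unit <- db$accession
  if (collapse_identical) {
    # uniqueness counted over distinct protein sequences, not entries
    unit <- paste0("seq", match(db$sequence, unique(db$sequence)))
  }
  if (!is.null(groups)) {
    for (lab in names(groups)) {
      unit[db$accession %in% groups[[lab]]] <- paste0("grp_", lab)
    }
  }
  names(unit) <- db$accession
  n_units <- tapply(unit[hits$accession], hits$peptide,
                    function(g) length(unique(g)))
  hits$unique <- n_units[hits$peptide] == 1
  spectra <- tapply(rows$msms_count, rows$sequence, sum)

  out <- hits |>
    dplyr::group_by(.data$accession) |>
    dplyr::group_map(function(g, key) {
      uniq <- g[g$unique, , drop = FALSE]
      two <- has_two_non_overlapping(uniq)
      tibble::tibble(
        accession = key$accession,
        supporting_peptides = list(g[, c("peptide", "unique", "start", "end")]),
        n_peptides = length(unique(g$peptide)),
        n_unique = length(unique(uniq$peptide)),
        has_two_non_overlapping = two,
        confident = two,
        n_spectra = as.integer(sum(spectra[unique(g$peptide)], na.rm = TRUE))
      )
    }) |>
    dplyr::bind_rows()
  dplyr::arrange(out, .data$accession)
}

#' Write identifications to TSV
#' @param ids Identification tibble from [identify_proteins()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identifications <- function(ids, path) {
  flat <- dplyr::select(ids, "accession", "n_unique", "has_two_non_overlapping",
                        "confident", "n_peptides", "n_spectra")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
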