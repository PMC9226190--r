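#' Evidence tables, modified-sequence annotations and sequence databases
#'
#' The evidence dialect is the tab-separated per-PSM table written by common
#' search engines (one row per peptide-spectrum match), with the canonical
#' column spellings `Sequence`, `Modified sequence`, `Proteins`, `Score`,
#' `Intensity`, `MS/MS count`, `Raw file`, `Charge`, `Reverse`,
#' `Potential contaminant`. Marker columns use the `"+"` convention.
#' Everything downstream of the search engine consumes the tibbles built
#' here.
#'
#' @name tables_io
NULL

EVIDENCE_COLUMNS <- c("Sequence", "Modified sequence", "Proteins", "Score",
                      "Intensity", "MS/MS count", "Raw file", "Charge",
                      "Reverse", "Potential contaminant")

#' Default modification-tag vocabulary
#'
#' Maps the parenthesised tags found in annotated peptide strings to
#' canonical modification names. Tags are matched case-insensitively;
#' both the two-letter abbreviations (`"(de)"`) and full-name spellings
#' used by other search-engine versions are accepted.
#'
#' @return Named character vector: lower-case tag to canonical name.
#' @export
default_mod_vocabulary <- function() {
  c(de = "deamidation",
    deamidation = "deamidation",
    "deamidation (nq)" = "deamidation",
    ox = "oxidation",
    oxidation = "oxidation",
    "oxidation (m)" = "oxidation",
    ac = "N-term acetylation",
    "acetyl (protein n-term)" = "N-term acetylation",
    hy = "hydroxyproline",
    hydroxyproline = "hydroxyproline")
}

#' Parse an annotated ("modified") peptide sequence
#'
#' Annotated sequences are delimited by underscores and carry
#' modifications as parenthesised tags immediately after the modified
#' residue, or directly after the leading underscore for protein
#' N-terminal modifications: `"_AGN(de)LK_"`, `"_(ac)M(ox)AQK_"`.
#'
#' @param annotated Annotated peptide string.
#' @param vocabulary Named character vector mapping lower-case tags to
#'   canonical modification names; see [default_mod_vocabulary()].
#' @return A list with `sequence` (plain uppercase peptide) and
#'   `modifications`, a tibble with integer `position` (1-based residue
#'   index, 0 for the N-terminus) and `name`.
#' @export
parse_modified_sequence <- function(annotated, vocabulary = default_mod_vocabulary()) {
  stopifnot(is.character(annotated), length(annotated) == 1L)
  x <- annotated
  # strip the underscore delimiters if present
  x <- sub("^_", "", sub("_$", "", x))
  cs <- if (nzchar(x)) chars(x) else character(0)
  n_open <- sum(cs == "(")
  n_close <- sum(cs == ")")
  if (n_open != n_close) {
    abort_format("unbalanced parentheses in modified sequence '%s'", annotated)
  }
  seq_chars <- character(0)
  pos <- integer(0)
  name <- character(0)
  i <- 1L
  while (i <= length(cs)) {
    ch <- cs[[i]]
    if (ch == "(") {
      # tags may themselves contain parentheses ("Deamidation (NQ)"):
      # scan to the matching close, not the first one
      j <- i + 1L
      depth <- 1L
      while (j <= length(cs) && depth > 0L) {
        if (cs[[j]] == "(") depth <- depth + 1L
        if (cs[[j]] == ")") depth <- depth - 1L
        if (depth > 0L) j <- j + 1L
      }
      if (j > length(cs)) {
        abort_format("unbalanced parentheses in modified sequence '%s'", annotated)
      }
      tag <- paste(cs[seq.int(i + 1L, length.out = j - i - 1L)], collapse = "")
      key <- tolower(tag)
      if (!key %in% names(vocabulary)) {
        abort_format(
          "unknown modification tag '(%s)' in '%s'; known tags: %s",
          tag, annotated, paste(sort(unique(names(vocabulary))), collapse = ", "))
      }
      pos <- c(pos, length(seq_chars))
      name <- c(name, unname(vocabulary[[key]]))
      i <- j + 1L
    } else if (ch == "_") {
      abort_format("unexpected '_' inside modified sequence '%s'", annotated)
    } else {
      if (!ch %in% AA20) {
        abort_format("invalid residue '%s' in modified sequence '%s'", ch, annotated)
      }
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  list(sequence = paste(seq_chars, collapse = ""),
       modifications = tibble::tibble(position = as.integer(pos), name = name))
}

parse_marker <- function(x) {
  !is.na(x) & trimws(as.character(x)) == "+"
}

parse_numeric_cells <- function(x, column, lines) {
  raw <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & nzchar(raw) & is.na(out))
  if (length(bad) > 0) {
    abort_format("unparseable value '%s' in column '%s' at line %d",
                 raw[bad[1]], column, lines[bad[1]])
  }
  out
}

#' Read a peptide-evidence table
#'
#' Reads the tab-separated evidence dialect into a tibble with one row per
#' PSM. Marker columns (`Reverse`, `Potential contaminant`) use the `"+"`
#' convention; an empty `Intensity` cell becomes `NA`, never zero.
#' Accessions in `Proteins` are split on semicolons with order preserved.
#' Columns beyond the canonical set are preserved verbatim.
#'
#' @param path Path to the TSV file.
#' @param sample_id Label attached to every row.
#' @param vocabulary Modification-tag vocabulary for the
#'   `Modified sequence` column.
#' @return A tibble with columns `sample_id`, `raw_file`, `sequence`,
#'   `modified_sequence`, `modifications` (list of tibbles), `protein_refs`
#'   (list of character), `score`, `intensity`, `msms_count`, `charge`,
#'   `is_reverse`, `is_contaminant`, plus any extra input columns.
#' @export
read_evidence <- function(path, sample_id,
                          vocabulary = default_mod_vocabulary()) {
  if (!file.exists(path)) abort_format("evidence file not found: %s", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  missing_cols <- setdiff(EVIDENCE_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort_format("evidence table %s is missing mandatory column(s): %s",
                 path, paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    abort_format("evidence file %s contains a header but no rows", path)
  }
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1

  parsed <- purrr::map(raw[["Modified sequence"]], parse_modified_sequence,
                       vocabulary = vocabulary)
  sequences <- toupper(raw[["Sequence"]])
  stripped <- purrr::map_chr(parsed, "sequence")
  mismatch <- which(stripped != sequences)
  if (length(mismatch) > 0) {
    abort_format(
      "Modified sequence '%s' does not strip to Sequence '%s' at line %d",
      raw[["Modified sequence"]][mismatch[1]], sequences[mismatch[1]],
      lines[mismatch[1]])
  }

  intensity <- parse_numeric_cells(raw[["Intensity"]], "Intensity", lines)
  score <- parse_numeric_cells(raw[["Score"]], "Score", lines)
  msms <- parse_numeric_cells(raw[["MS/MS count"]], "MS/MS count", lines)
  charge <- parse_numeric_cells(raw[["Charge"]], "Charge", lines)

  out <- tibble::tibble(
    sample_id = sample_id,
    raw_file = raw[["Raw file"]],
    sequence = sequences,
    modified_sequence = raw[["Modified sequence"]],
    modifications = purrr::map(parsed, "modifications"),
    protein_refs = purrr::map(raw[["Proteins"]], function(p) {
      p <- trimws(p)
      if (is.na(p) || !nzchar(p)) character(0) else strsplit(p, ";", fixed = TRUE)[[1]]
    }),
    score = score,
    intensity = intensity,
    msms_count = as.integer(msms),
    charge = as.integer(charge),
    is_reverse = parse_marker(raw[["Reverse"]]),
    is_contaminant = parse_marker(raw[["Potential contaminant"]])
  )
  extra <- setdiff(names(raw), EVIDENCE_COLUMNS)
  for (col in extra) out[[col]] <- raw[[col]]
  out
}

#' Write a peptide-evidence table
#'
#' Re-emits an evidence tibble in the canonical dialect so that
#' `read_evidence(write_evidence(x))` is the identity on the canonical
#' columns.
#'
#' @param rows Evidence tibble as returned by [read_evidence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(rows, path) {
  out <- tibble::tibble(
    "Sequence" = rows$sequence,
    "Modified sequence" = rows$modified_sequence,
    "Proteins" = purrr::map_chr(rows$protein_refs, paste, collapse = ";"),
    "Score" = rows$score,
    "Intensity" = ifelse(is.na(rows$intensity), "", format(rows$intensity, trim = TRUE, scientific = FALSE)),
    "MS/MS count" = rows$msms_count,
    "Raw file" = rows$raw_file,
    "Charge" = rows$charge,
    "Reverse" = ifelse(rows$is_reverse, "+", ""),
    "Potential contaminant" = ifelse(rows$is_contaminant, "+", "")
  )
  extra <- setdiff(names(rows),
                   c("sample_id", "raw_file", "sequence", "modified_sequence",
                     "modifications", "protein_refs", "score", "intensity",
                     "msms_count", "charge", "is_reverse", "is_contaminant"))
  for (col in extra) out[[col]] <- rows[[col]]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

SOURCE_CLASSES <- c("egg_yolk", "egg_white", "egg_ambiguous", "blood_or_egg",
                    "animal_glue", "hide_glue_indicator", "wool", "other",
                    "unassigned")

#' Construct a sequence database
#'
#' @param entries Tibble with columns `accession`, `description`, `species`,
#'   `source_class`, `sequence`, `is_contaminant`.
#' @param name Database label.
#' @param metadata Free-form provenance notes (character).
#' @return A `sequence_db` tibble.
#' @export
sequence_db <- function(entries, name = "db", metadata = character()) {
  stopifnot(all(c("accession", "sequence") %in% names(entries)))
  entries$accession <- as.character(entries$accession)
  if (anyDuplicated(entries$accession)) {
    dup <- entries$accession[duplicated(entries$accession)][1]
    abort_format("duplicate accession in database '%s': %s", name, dup)
  }
  if (any(!nzchar(entries$accession))) abort_format("empty accession in database '%s'", name)
  entries$sequence <- unname(toupper(entries$sequence))
  ok <- vapply(entries$sequence, is_aa_string, logical(1), allow_x = TRUE)
  if (!all(ok)) {
    abort_format("entry %s has characters outside the amino-acid alphabet",
                 entries$accession[!ok][1])
  }
  if (is.null(entries$description)) entries$description <- ""
  if (is.null(entries$species)) entries$species <- NA_character_
  if (is.null(entries$source_class)) entries$source_class <- "unassigned"
  if (is.null(entries$is_contaminant)) entries$is_contaminant <- FALSE
  entries$source_class[is.na(entries$source_class)] <- "unassigned"
  bad <- setdiff(unique(entries$source_class), SOURCE_CLASSES)
  if (length(bad) > 0) {
    abort_format("unknown source_class '%s' (expected one of: %s)",
                 bad[1], paste(SOURCE_CLASSES, collapse = ", "))
  }
  db <- tibble::as_tibble(entries[, c("accession", "description", "species",
                                      "source_class", "sequence", "is_contaminant")])
  attr(db, "db_name") <- name
  attr(db, "db_metadata") <- metadata
  class(db) <- c("sequence_db", class(db))
  db
}

#' Read a FASTA protein database with species and source metadata
#'
#' The accession is the first whitespace-delimited token of each header
#' (a leading `sp|`/`tr|` UniProt prefix is unwrapped). Species and
#' source-class come from the `metadata` mapping where provided; otherwise
#' species is parsed from an `OS=` field in the header when present, and
#' the source class defaults to `"unassigned"`.
#'
#' @param path FASTA file path.
#' @param metadata Optional tibble/data.frame with columns `accession`,
#'   `species`, `source_class` (may cover only some entries).
#' @param name Database label.
#' @param is_contaminant Logical; mark every entry as a contaminant
#'   (use for contaminant FASTAs).
#' @return A `sequence_db` tibble.
#' @export
read_fasta_db <- function(path, metadata = NULL, name = basename(path),
                          is_contaminant = FALSE) {
  if (!file.exists(path)) abort_format("FASTA file not found: %s", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort_format("FASTA file %s contains no sequences", path)
  headers <- names(aa)
  first_token <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  accession <- vapply(first_token, function(tok) {
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && parts[1] %in% c("sp", "tr")) parts[2] else tok
  }, character(1), USE.NAMES = FALSE)
  os <- stringr::str_match(headers, "OS=([^=]+?)(?:\\s+[A-Z]{2}=|$)")[, 2]
  species <- trimws(os)
  entries <- tibble::tibble(
    accession = accession,
    description = headers,
    species = species,
    source_class = "unassigned",
    sequence = unname(as.character(aa)),
    is_contaminant = is_contaminant
  )
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    idx <- match(entries$accession, metadata$accession)
    hit <- !is.na(idx)
    if ("species" %in% names(metadata)) {
      entries$species[hit] <- metadata$species[idx[hit]]
    }
    if ("source_class" %in% names(metadata)) {
      entries$source_class[hit] <- metadata$source_class[idx[hit]]
    }
  }
  sequence_db(entries, name = name, metadata = sprintf("read from %s", path))
}

#' Write a sequence database to FASTA (plus optional metadata TSV)
#'
#' Headers are `>accession description OS=species`; when `metadata_path`
#' is given, accession/species/source_class are also written as a TSV that
#' [read_fasta_db()] accepts as its `metadata` argument.
#'
#' @param db A `sequence_db`.
#' @param path Output FASTA path.
#' @param metadata_path Optional output TSV path.
#' @return `path`, invisibly.
#' @export
write_fasta_db <- function(db, path, metadata_path = NULL) {
  aa <- Biostrings::AAStringSet(db$sequence)
  names(aa) <- ifelse(is.na(db$species) | !nzchar(db$species %||% ""),
                      db$accession,
                      paste0(db$accession, " OS=", db$species))
  Biostrings::writeXStringSet(aa, path)
  if (!is.null(metadata_path)) {
    readr::write_tsv(tibble::tibble(accession = db$accession,
                                    species = db$species,
                                    source_class = db$source_class),
                     metadata_path, progress = FALSE)
  }
  invisible(path)
}

#' Look up a database entry by accession
#' @param db A `sequence_db`.
#' @param accession Accession string.
#' @return The matching one-row tibble; error if absent.
#' @export
db_lookup <- function(db, accession) {
  i <- match(accession, db$accession)
  if (is.na(i)) abort_format("accession '%s' not found in database", accession)
  db[i, ]
}
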