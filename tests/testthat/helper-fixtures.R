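# shared fixture builders and independent brute-force oracles

# one evidence row with sensible defaults; mods is a tibble(position, name)
make_row <- function(sequence, sample_id = "S1", score = 100, intensity = 1e6,
                     msms_count = 1L, charge = 2L, protein_refs = character(0),
                     is_reverse = FALSE, is_contaminant = FALSE,
                     mods = tibble::tibble(position = integer(0), name = character(0)),
                     raw_file = "run1.raw") {
  annotated <- {
    cs <- strsplit(sequence, "")[[1]]
    out <- character(0)
    for (i in seq_along(cs)) {
      out <- c(out, cs[[i]])
      if (i %in% mods$position[mods$name == "deamidation"]) out <- c(out, "(de)")
      if (i %in% mods$position[mods$name == "oxidation"]) out <- c(out, "(ox)")
    }
    paste0("_", paste(out, collapse = ""), "_")
  }
  tibble::tibble(
    sample_id = sample_id, raw_file = raw_file, sequence = sequence,
    modified_sequence = annotated, modifications = list(mods),
    protein_refs = list(protein_refs), score = score, intensity = intensity,
    msms_count = msms_count, charge = charge,
    is_reverse = is_reverse, is_contaminant = is_contaminant
  )
}

make_rows <- function(...) dplyr::bind_rows(...)

# a small handcrafted database
tiny_db <- function() {
  sequence_db(tibble::tibble(
    accession = c("P1", "P2"),
    description = c("P1 test protein one OS=Gallus gallus",
                    "P2 test protein two OS=Ovis aries"),
    species = c("Gallus gallus", "Ovis aries"),
    source_class = "unassigned",
    sequence = c("MAGNLKGGGRWWTTYYK", "MWGNICKCCCCRQQEEHHK"),
    is_contaminant = FALSE
  ), name = "tiny")
}

# oracle: two-non-overlapping rule by exhaustive pair enumeration over a
# plain data frame, written independently of the package internals
oracle_non_overlap <- function(intervals) {
  n <- nrow(intervals)
  if (n < 2) return(FALSE)
  contains <- function(a, b) {  # a entirely inside b
    intervals$start[a] >= intervals$start[b] && intervals$end[a] <= intervals$end[b]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (intervals$peptide[i] == intervals$peptide[j]) next
      if (!contains(i, j) && !contains(j, i)) return(TRUE)
    }
  }
  FALSE
}

# random interval set on a protein of given length, from distinct or
# repeated peptide labels
random_intervals <- function(n_max = 8, protein_len = 50) {
  n <- sample.int(n_max, 1)
  start <- sample.int(protein_len, n, replace = TRUE)
  len <- sample.int(15, n, replace = TRUE)
  end <- pmin(start + len - 1L, protein_len)
  tibble::tibble(peptide = paste0("pep", sample.int(max(2, n), n, replace = TRUE)),
                 start = start, end = end)
}

# oracle: tryptic digestion by scanning ALL substrings and testing the
# cleavage conditions directly (independent of the boundary-combination
# construction used by digest())
oracle_digest <- function(sequence, max_missed = 2, min_len = 7, max_len = 30,
                          no_p = FALSE) {
  sc <- strsplit(sequence, "")[[1]]
  n <- length(sc)
  is_cut <- function(p) {  # cleavage after position p?
    p >= 1 && p < n && sc[p] %in% c("K", "R") && !(no_p && sc[p + 1] == "P")
  }
  peps <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      len <- j - i + 1
      if (len < min_len || len > max_len) next
      if (!(i == 1 || is_cut(i - 1))) next
      if (!(j == n || is_cut(j))) next
      internal <- if (j > i) sum(vapply(i:(j - 1), is_cut, logical(1))) else 0
      if (internal > max_missed) next
      peps <- c(peps, paste(sc[i:j], collapse = ""))
    }
  }
  unique(peps)
}

# random protein sequence (uniform over the 20 amino acids)
random_protein <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               len, replace = TRUE), collapse = "")
}

# oracle: naive exact substring scan for species matching (no equivalence,
# no terminus rules)
oracle_species_scan <- function(peptide, db) {
  hit <- vapply(seq_len(nrow(db)), function(i) {
    !db$is_contaminant[i] && grepl(peptide, db$sequence[i], fixed = TRUE)
  }, logical(1))
  sort(unique(db$species[hit & !is.na(db$species)]))
}

# small single-protein simulation config used across tests
basic_sim_config <- function(seed, n_peptides = 30L, n_obs = 60L,
                             pN = 0.3, pQ = 0.3, contaminant_fraction = 0,
                             reverse_fraction = 0) {
  simulation_config(
    seed = seed,
    proteins = tibble::tibble(accession = "PROT_SYN", species = "Gallus gallus",
                              source_class = "egg_yolk", n_peptides = n_peptides),
    samples = list(list(sample_id = "S1",
                        composition = c(PROT_SYN = 1), n_obs = n_obs)),
    pN = pN, pQ = pQ,
    contaminant_fraction = contaminant_fraction,
    reverse_fraction = reverse_fraction
  )
}

# divergence fixture: one base protein and four single-site variants, one
# per substitution class; returns db, truth and helpers to find the base
# peptide spanning a given site
divergence_fixture <- function(seed, n_peptides = 10L) {
  cfg <- simulation_config(
    seed = seed,
    proteins = tibble::tibble(accession = "BASE_SYN", species = "Species base",
                              source_class = "other", n_peptides = n_peptides),
    orthologs = list(list(base = "BASE_SYN", variants = list(
      list(accession = "VAR_IL", species = "Species il", divergence = c(IL = 1L)),
      list(accession = "VAR_HARD", species = "Species hard", divergence = c(hard = 1L)),
      list(accession = "VAR_ND", species = "Species nd", divergence = c(ND = 1L)),
      list(accession = "VAR_SA", species = "Species sa", divergence = c(SA_near_P = 1L))
    ))),
    samples = list(list(sample_id = "S1", composition = c(BASE_SYN = 1), n_obs = 10L))
  )
  make_proteomes(cfg)
}

# fully cleaved tryptic peptide of `sequence` containing global position
# `site`; returns list(peptide, site_in_peptide)
peptide_at_site <- function(sequence, site) {
  sc <- strsplit(sequence, "")[[1]]
  cuts <- which(sc %in% c("K", "R"))
  left <- c(0, cuts[cuts < site])
  left <- max(left)
  right <- min(cuts[cuts >= site])
  list(peptide = substr(sequence, left + 1, right),
       site_in_peptide = site - left)
}
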