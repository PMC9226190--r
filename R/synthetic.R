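#' Synthetic ground-truthed fixtures
#'
#' Generates species-divergent mini-proteomes and matching evidence
#' tables with fully known ground truth: which species carries which
#' substitution class at which site, which peptide each row came from,
#' and which residues were deamidated. Random draws use independent
#' per-component streams (sequence construction, peptide sampling,
#' deamidation, intensities, spiking) derived from one master seed, so
#' changing one knob does not reshuffle unrelated draws.
#'
#' @name synthetic_fixtures
NULL

#' Simulation configuration
#'
#' @param seed Master integer seed.
#' @param proteins Tibble with columns `accession`, `species`,
#'   `source_class`, `n_peptides` (tryptic peptides per protein).
#' @param orthologs List of ortholog groups; each is
#'   `list(base = accession, variants = list(list(accession, species,
#'   divergence)))` where `divergence` is a named integer vector over the
#'   site classes `IL`, `ND`, `SA_near_P`, `hard`. Variants share the
#'   base's source class and digestion pattern and differ only at the
#'   configured sites.
#' @param samples List of `list(sample_id, composition, n_obs)`;
#'   `composition` is a named share vector over protein accessions.
#' @param pN,pQ Per-residue deamidation probabilities; scalars, or named
#'   vectors by source class.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model.
#' @param contaminant_fraction,reverse_fraction Expected fraction of
#'   spiked contaminant / decoy rows relative to `n_obs`.
#' @param peptide_len_range Tryptic peptide length bounds used during
#'   sequence construction.
#' @param max_missed Missed cleavages allowed when sampling observed
#'   peptides.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              proteins,
                              orthologs = list(),
                              samples,
                              pN = 0.3, pQ = 0.3,
                              intensity_meanlog = 18, intensity_sdlog = 1,
                              contaminant_fraction = 0.05,
                              reverse_fraction = 0.05,
                              peptide_len_range = c(7L, 16L),
                              max_missed = 2) {
  stopifnot(all(c("accession", "species", "source_class", "n_peptides") %in% names(proteins)),
            all(unlist(c(pN, pQ)) >= 0), all(unlist(c(pN, pQ)) <= 1),
            peptide_len_range[1] >= 7)
  structure(list(seed = as.integer(seed), proteins = tibble::as_tibble(proteins),
                 orthologs = orthologs, samples = samples, pN = pN, pQ = pQ,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 contaminant_fraction = contaminant_fraction,
                 reverse_fraction = reverse_fraction,
                 peptide_len_range = as.integer(peptide_len_range),
                 max_missed = as.integer(max_missed)),
            class = "simulation_config")
}

DIVERGENCE_CLASSES <- c("IL", "ND", "SA_near_P", "hard")

# residues written by each class: (base residue, variant residue)
divergence_residues <- list(
  IL = c("I", "L"),
  ND = c("N", "D"),
  SA_near_P = c("S", "A"),
  hard = c("G", "V")
)

# one random tryptic protein: n_pep peptides, each ending in K or R,
# interiors free of K/R (and of P, reserved for SA_near_P construction).
# With ensure_nq each peptide carries at least one N and one Q, mirroring
# the N/Q-rich composition of the binder proteins the fixtures emulate
# (collagens and egg proteins) and making every peptide informative for
# deamidation profiling.
random_tryptic_sequence <- function(n_pep, len_range, ensure_nq = TRUE) {
  interior_alpha <- setdiff(AA20, c("K", "R", "P"))
  lens <- seq.int(len_range[1], len_range[2])
  peps <- vapply(seq_len(n_pep), function(i) {
    len <- lens[sample.int(length(lens), 1)]
    body <- sample(interior_alpha, len - 1L, replace = TRUE)
    if (ensure_nq) {
      slots <- sample.int(len - 1L, 2L)
      body[slots[1]] <- "N"
      body[slots[2]] <- "Q"
    }
    paste0(paste(body, collapse = ""), sample(c("K", "R"), 1))
  }, character(1))
  paste(peps, collapse = "")
}

#' Generate species-divergent mini-proteomes
#'
#' Base sequences are random tryptic proteins (cleavage sites placed so
#' every fully cleaved peptide has length at least 7); ortholog variants
#' copy the base and substitute residues at distinct peptide-interior
#' sites according to the configured divergence classes: `IL` writes I in
#' the base and L in the variant, `ND` writes N/D, `SA_near_P` writes S/A
#' with a proline placed at the following position in both, `hard` writes
#' G/V (distinguishable by mass).
#'
#' @param cfg A [simulation_config()].
#' @return List with `db` (a `sequence_db`) and `truth` (list holding the
#'   divergence site table and per-protein provenance).
#' @export
make_proteomes <- function(cfg) {
  withr::with_seed(sub_seed(cfg$seed, "sequence"), {
    base_seqs <- list()
    for (i in seq_len(nrow(cfg$proteins))) {
      acc <- cfg$proteins$accession[[i]]
      base_seqs[[acc]] <- random_tryptic_sequence(cfg$proteins$n_peptides[[i]],
                                                  cfg$peptide_len_range)
    }
    entries <- cfg$proteins
    entries$sequence <- unname(unlist(base_seqs[entries$accession]))
    entries$is_contaminant <- FALSE
    divergence_tab <- tibble::tibble(base = character(0), variant = character(0),
                                     species = character(0), site = integer(0),
                                     class = character(0), base_res = character(0),
                                     var_res = character(0))
    for (grp in cfg$orthologs) {
      base_acc <- grp$base
      if (!base_acc %in% entries$accession) {
        abort_format("ortholog base '%s' is not a configured protein", base_acc)
      }
      sc <- chars(entries$sequence[entries$accession == base_acc])
      cleavage <- which(sc %in% c("K", "R"))
      base_row <- entries[entries$accession == base_acc, ]
      # interior sites: not a cleavage residue, at least 2 residues from
      # each peptide boundary so substitutions never touch termini
      bounds <- c(0L, cleavage)
      eligible <- setdiff(seq_along(sc), cleavage)
      eligible <- eligible[vapply(eligible, function(p) {
        left <- max(bounds[bounds < p])
        right <- min(cleavage[cleavage >= p])
        (p - left) >= 2 && (right - p) >= 2
      }, logical(1))]
      # pass 1: pick sites for every variant from one shared pool
      # (pairwise distance >= 3, so SA_near_P prolines never collide with
      # another variant's site) and write the base-side residues first —
      # a variant must differ from the FINISHED base only at its own sites
      pool <- eligible
      plan <- list()
      for (var in grp$variants) {
        n_sites <- sum(var$divergence)
        if (n_sites * 2 > length(eligible)) {
          abort_format("more divergent sites (%d) than eligible positions in %s",
                       n_sites, base_acc)
        }
        sites <- integer(0)
        while (length(sites) < n_sites) {
          if (length(pool) == 0) {
            abort_format("more divergent sites (%d) than eligible positions in %s",
                         n_sites, base_acc)
          }
          s <- pool[sample.int(length(pool), 1)]
          sites <- c(sites, s)
          pool <- pool[abs(pool - s) >= 3]
        }
        sites <- sort(sites)
        classes <- rep(names(var$divergence), times = var$divergence)
        for (k in seq_along(sites)) {
          res <- divergence_residues[[classes[[k]]]]
          sc[sites[[k]]] <- res[1]
          if (classes[[k]] == "SA_near_P") sc[sites[[k]] + 1L] <- "P"
        }
        plan[[var$accession]] <- list(var = var, sites = sites, classes = classes)
      }
      entries$sequence[entries$accession == base_acc] <- paste(sc, collapse = "")
      # pass 2: each variant copies the finished base and substitutes its
      # own sites
      for (pl in plan) {
        var_sc <- sc
        for (k in seq_along(pl$sites)) {
          var_sc[pl$sites[[k]]] <- divergence_residues[[pl$classes[[k]]]][2]
        }
        divergence_tab <- dplyr::bind_rows(divergence_tab, tibble::tibble(
          base = base_acc, variant = pl$var$accession, species = pl$var$species,
          site = pl$sites, class = pl$classes,
          base_res = vapply(pl$sites, function(p) sc[[p]], character(1)),
          var_res = vapply(pl$sites, function(p) var_sc[[p]], character(1))
        ))
        entries <- dplyr::bind_rows(entries, tibble::tibble(
          accession = pl$var$accession, species = pl$var$species,
          source_class = base_row$source_class,
          n_peptides = base_row$n_peptides,
          sequence = paste(var_sc, collapse = ""),
          is_contaminant = FALSE
        ))
      }
    }
    entries$description <- paste(entries$accession, "synthetic protein OS=",
                                 entries$species)
    db <- sequence_db(entries[, c("accession", "description", "species",
                                  "source_class", "sequence", "is_contaminant")],
                      name = "synthetic_proteomes",
                      metadata = sprintf("synthetic fixture, seed %d", cfg$seed))
    list(db = db, truth = list(divergence = divergence_tab,
                               proteins = cfg$proteins))
  })
}

#' Ortholog families of a simulation configuration
#'
#' Returns the protein groups (base plus species variants) defined by a
#' configuration's ortholog plan, in the form [identify_proteins()] and
#' [analysis_config()] accept as `protein_groups`. Useful when analysing
#' generated fixtures: the database deliberately carries orthologous
#' sequences from several candidate species, so peptide uniqueness is
#' meaningful at the family level.
#'
#' @param cfg A [simulation_config()].
#' @return Named list of accession vectors (named by base accession).
#' @export
ortholog_groups <- function(cfg) {
  out <- list()
  for (grp in cfg$orthologs) {
    out[[grp$base]] <- c(grp$base,
                         vapply(grp$variants, `[[`, character(1), "accession"))
  }
  out
}

#' Built-in synthetic contaminant database
#'
#' Two synthetic entries standing in for the usual laboratory
#' contaminants (a human-keratin-like protein and a trypsin-like
#' protein). Sequences are random tryptic proteins; the database is
#' deterministic given the seed.
#'
#' @param seed Integer seed.
#' @return A `sequence_db` with `is_contaminant = TRUE` throughout.
#' @export
make_contaminant_db <- function(seed) {
  withr::with_seed(sub_seed(seed, "contaminant"), {
    entries <- tibble::tibble(
      accession = c("CON_KRT_SYN", "CON_TRYP_SYN"),
      description = c("CON_KRT_SYN synthetic keratin-like contaminant OS=Homo sapiens",
                      "CON_TRYP_SYN synthetic trypsin-like contaminant OS=Sus scrofa"),
      species = c("Homo sapiens", "Sus scrofa"),
      source_class = "other",
      sequence = c(random_tryptic_sequence(12, c(7L, 14L)),
                   random_tryptic_sequence(10, c(7L, 14L))),
      is_contaminant = TRUE
    )
    sequence_db(entries, name = "synthetic_contaminants",
                metadata = sprintf("synthetic fixture, seed %d", seed))
  })
}

deam_prob <- function(p, source_class) {
  if (is.null(names(p))) return(unname(p[1]))
  v <- unname(p[source_class])
  if (is.na(v)) 0 else v
}

annotate_deamidation <- function(pep, deam_sites) {
  cs <- chars(pep)
  out <- character(0)
  for (i in seq_along(cs)) {
    out <- c(out, cs[[i]])
    if (i %in% deam_sites) out <- c(out, "(de)")
  }
  paste0("_", paste(out, collapse = ""), "_")
}

#' Generate an evidence table from synthetic proteomes
#'
#' Samples tryptic peptides from each sample's source proteins according
#' to the configured composition; each N/Q is independently deamidated
#' with the per-source probability and annotated `"(de)"`; intensities
#' are log-normal; scores of genuine rows sit above the usual threshold
#' of 40 while spiked decoy rows sit below it. Contaminant and reverse
#' rows are appended at the configured fractions.
#'
#' @param db `sequence_db` from [make_proteomes()].
#' @param truth Ground-truth list from [make_proteomes()].
#' @param cfg The [simulation_config()].
#' @param contaminants Contaminant `sequence_db` (default built from the
#'   master seed).
#' @return List with `rows` (evidence tibble over all configured
#'   samples), `truth` (ground truth extended with per-row origin and
#'   realized deamidation events) and `contaminants`.
#' @export
make_evidence <- function(db, truth, cfg,
                          contaminants = make_contaminant_db(cfg$seed)) {
  params <- digest_params(enzyme = "trypsin", max_missed = cfg$max_missed,
                          min_len = 7, max_len = 60)
  digests <- lapply(stats::setNames(db$accession, db$accession), function(acc) {
    digest(db$sequence[db$accession == acc], params)
  })
  con_digests <- lapply(stats::setNames(contaminants$accession, contaminants$accession),
                        function(acc) {
                          digest(contaminants$sequence[contaminants$accession == acc], params)
                        })
  all_rows <- list()
  origin <- list()
  events <- list()
  sample_ids <- vapply(cfg$samples, `[[`, "", "sample_id")
  stream <- function(component, k, extra = 0) {
    as.integer((as.numeric(sub_seed(cfg$seed, component)) + k * 131 + extra) %% 2147483647)
  }
  for (smp in cfg$samples) {
    sid <- smp$sample_id
    si <- match(sid, sample_ids)
    comp <- smp$composition
    n_obs <- smp$n_obs
    src_acc <- withr::with_seed(stream("sampling", si),
      sample(names(comp), n_obs, replace = TRUE, prob = comp))
    peps <- withr::with_seed(stream("sampling", si, 7919),
      vapply(src_acc, function(acc) sample(digests[[acc]], 1), character(1)))
    cls <- db$source_class[match(src_acc, db$accession)]
    deam <- withr::with_seed(stream("deamidation", si), {
      lapply(seq_len(n_obs), function(i) {
        cs <- chars(peps[[i]])
        nsites <- which(cs == "N")
        qsites <- which(cs == "Q")
        hitN <- nsites[stats::runif(length(nsites)) < deam_prob(cfg$pN, cls[[i]])]
        hitQ <- qsites[stats::runif(length(qsites)) < deam_prob(cfg$pQ, cls[[i]])]
        sort(c(hitN, hitQ))
      })
    })
    aux <- withr::with_seed(stream("contaminant", si), {
      n_con <- stats::rbinom(1, n_obs, cfg$contaminant_fraction)
      n_rev <- stats::rbinom(1, n_obs, cfg$reverse_fraction)
      con_acc <- if (n_con > 0) sample(contaminants$accession, n_con, replace = TRUE) else character(0)
      con_pep <- vapply(con_acc, function(acc) sample(con_digests[[acc]], 1), character(1))
      rev_src <- if (n_rev > 0) sample(seq_len(n_obs), n_rev, replace = TRUE) else integer(0)
      list(con_acc = con_acc, con_pep = con_pep, rev_src = rev_src)
    })
    n_con <- length(aux$con_acc)
    n_rev <- length(aux$rev_src)
    n_total <- n_obs + n_con + n_rev
    nums <- withr::with_seed(stream("intensity", si), {
      list(intensity = stats::rlnorm(n_total, cfg$intensity_meanlog, cfg$intensity_sdlog),
           score_real = stats::runif(n_obs + n_con, 41, 150),
           score_rev = stats::runif(max(n_rev, 1), 5, 39),
           msms = 1L + stats::rpois(n_total, 1),
           charge = sample(2:3, n_total, replace = TRUE))
    })
    rev_pep <- vapply(aux$rev_src, function(i) {
      paste(rev(chars(peps[[i]])), collapse = "")
    }, character(1))
    all_pep <- c(peps, aux$con_pep, rev_pep)
    all_mod <- c(deam,
                 replicate(n_con, integer(0), simplify = FALSE),
                 replicate(n_rev, integer(0), simplify = FALSE))
    refs <- c(
      lapply(peps, function(p) db$accession[vapply(db$sequence, function(s) grepl(p, s, fixed = TRUE), logical(1))]),
      lapply(aux$con_pep, function(p) contaminants$accession[vapply(contaminants$sequence, function(s) grepl(p, s, fixed = TRUE), logical(1))]),
      lapply(aux$rev_src, function(i) paste0("REV__", src_acc[[i]]))
    )
    rows <- tibble::tibble(
      sample_id = sid,
      raw_file = paste0(sid, ".raw"),
      sequence = unname(all_pep),
      modified_sequence = vapply(seq_len(n_total), function(i) {
        annotate_deamidation(all_pep[[i]], all_mod[[i]])
      }, character(1)),
      modifications = lapply(seq_len(n_total), function(i) {
        tibble::tibble(position = as.integer(all_mod[[i]]),
                       name = rep("deamidation", length(all_mod[[i]])))
      }),
      protein_refs = unname(refs),
      score = c(nums$score_real, nums$score_rev[seq_len(n_rev)]),
      intensity = nums$intensity,
      msms_count = nums$msms,
      charge = nums$charge,
      is_reverse = c(rep(FALSE, n_obs + n_con), rep(TRUE, n_rev)),
      is_contaminant = c(rep(FALSE, n_obs), rep(TRUE, n_con), rep(FALSE, n_rev))
    )
    all_rows[[sid]] <- rows
    origin[[sid]] <- tibble::tibble(
      sample_id = sid, row = seq_len(n_total),
      origin = c(src_acc, aux$con_acc, rep("decoy", n_rev)),
      kind = c(rep("signal", n_obs), rep("contaminant", n_con), rep("reverse", n_rev))
    )
    n_events <- vapply(deam, length, integer(1))
    events[[sid]] <- tibble::tibble(
      sample_id = rep(sid, sum(n_events)),
      row = rep(seq_len(n_obs), n_events),
      position = as.integer(unlist(deam) %||% integer(0)),
      residue = as.character(unlist(lapply(seq_len(n_obs), function(i) {
        chars(peps[[i]])[deam[[i]]]
      })) %||% character(0))
    )
  }
  rows <- dplyr::bind_rows(all_rows)
  truth$origin <- dplyr::bind_rows(origin)
  truth$deamidation_events <- dplyr::bind_rows(events)
  truth$config <- cfg
  list(rows = rows, truth = truth, contaminants = contaminants)
}

#' Write a complete fixture bundle
#'
#' Emits FASTA + metadata TSV for the proteome and contaminant databases,
#' one evidence TSV per sample, and a ground-truth JSON manifest.
#'
#' @param fixture List from [make_evidence()] plus `db` (attach with
#'   `fixture$db <- proteomes$db`).
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture_bundle <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fasta = file.path(dir, "proteomes.fasta"),
    metadata = file.path(dir, "proteomes_metadata.tsv"),
    contaminants = file.path(dir, "contaminants.fasta"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_fasta_db(fixture$db, paths$fasta, paths$metadata)
  write_fasta_db(fixture$contaminants, paths$contaminants)
  for (sid in unique(fixture$rows$sample_id)) {
    p <- file.path(dir, paste0("evidence_", gsub("[^A-Za-z0-9._-]", "_", sid), ".tsv"))
    write_evidence(fixture$rows[fixture$rows$sample_id == sid, ], p)
    paths[[paste0("evidence_", sid)]] <- p
  }
  truth <- fixture$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths$truth, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Painting-scenario preset
#'
#' A two-sample end-to-end fixture emulating an egg-tempera panel
#' painting on a glue-bound ground: a paint sample dominated by chicken
#' egg-yolk proteins with a minor collagen carry-over, and a ground
#' sample dominated by sheep collagen. Sheep and goat collagens differ
#' only at I/L sites (so collagen peptides resolve to the sheep/goat
#' group at best), cattle collagen carries hard substitutions (so the
#' group is distinguishable from cattle), a duck vitellogenin ortholog
#' carries hard substitutions (so some yolk peptides are
#' chicken-diagnostic), and a bird serum-albumin ortholog is identical
#' across chicken and duck (so albumin peptides need parsimony).
#' Glutamine deamidation is substantially higher in collagen than in egg
#' proteins, emulating glue manufacture by prolonged boiling.
#'
#' @param seed Master seed.
#' @return A [simulation_config()].
#' @export
painting_scenario <- function(seed) {
  proteins <- tibble::tribble(
    ~accession,     ~species,        ~source_class,   ~n_peptides,
    "VIT1_SYN",     "Gallus gallus", "egg_yolk",      26L,
    "VIT2_SYN",     "Gallus gallus", "egg_yolk",      26L,
    "APOB_SYN",     "Gallus gallus", "egg_yolk",      20L,
    "ALBU_SYN",     "Gallus gallus", "blood_or_egg",  10L,
    "CO1A1_SHEEP_SYN", "Ovis aries", "animal_glue",   26L,
    "CO1A2_SHEEP_SYN", "Ovis aries", "animal_glue",   22L
  )
  orthologs <- list(
    list(base = "VIT2_SYN", variants = list(
      list(accession = "VIT2_DUCK_SYN", species = "Anas platyrhynchos",
           divergence = c(hard = 6L)))),
    list(base = "ALBU_SYN", variants = list(
      list(accession = "ALBU_DUCK_SYN", species = "Anas platyrhynchos",
           divergence = c(hard = 0L)))),
    list(base = "CO1A1_SHEEP_SYN", variants = list(
      list(accession = "CO1A1_GOAT_SYN", species = "Capra hircus",
           divergence = c(IL = 3L)),
      list(accession = "CO1A1_BOVIN_SYN", species = "Bos taurus",
           divergence = c(hard = 5L)))),
    list(base = "CO1A2_SHEEP_SYN", variants = list(
      list(accession = "CO1A2_GOAT_SYN", species = "Capra hircus",
           divergence = c(IL = 2L)),
      list(accession = "CO1A2_BOVIN_SYN", species = "Bos taurus",
           divergence = c(hard = 4L))))
  )
  samples <- list(
    list(sample_id = "paint",
         composition = c(VIT1_SYN = 0.30, VIT2_SYN = 0.30, APOB_SYN = 0.18,
                         ALBU_SYN = 0.10, CO1A1_SHEEP_SYN = 0.07,
                         CO1A2_SHEEP_SYN = 0.05),
         n_obs = 160L),
    list(sample_id = "ground",
         composition = c(CO1A1_SHEEP_SYN = 0.50, CO1A2_SHEEP_SYN = 0.43,
                         VIT2_SYN = 0.07),
         n_obs = 140L)
  )
  simulation_config(
    seed = seed, proteins = proteins, orthologs = orthologs, samples = samples,
    pN = c(egg_yolk = 0.25, blood_or_egg = 0.25, animal_glue = 0.45),
    pQ = c(egg_yolk = 0.30, blood_or_egg = 0.30, animal_glue = 0.70),
    contaminant_fraction = 0.05, reverse_fraction = 0.05
  )
}
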