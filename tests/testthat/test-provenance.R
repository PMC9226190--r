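test_that("source mapping follows the built-in protein-name rules with metadata precedence", {
  db <- sequence_db(tibble::tibble(
    accession = c("V2", "LYZ", "ALB", "C3", "C1", "KRT", "MYST"),
    description = c("V2 Vitellogenin-2 OS=Gallus gallus",
                    "LYZ Lysozyme C OS=Gallus gallus",
                    "ALB Serum albumin OS=Gallus gallus",
                    "C3 Collagen alpha-1(III) chain OS=Ovis aries",
                    "C1 Collagen alpha-2(I) chain OS=Ovis aries",
                    "KRT Keratin, type II microfibrillar OS=Ovis aries",
                    "MYST Uncharacterized protein"),
    species = NA_character_,
    source_class = c("unassigned", "unassigned", "unassigned", "unassigned",
                     "unassigned", "wool", "unassigned"),
    sequence = "MAAAAAAK", is_contaminant = FALSE), name = "map_test")
  ids <- tibble::tibble(accession = db$accession)
  cls <- map_sources(ids, db)
  expect_identical(unname(cls[c("V2", "LYZ", "ALB", "C3", "C1", "KRT", "MYST")]),
                   c("egg_yolk", "egg_white", "blood_or_egg",
                     "hide_glue_indicator", "animal_glue", "wool", "other"))
})

test_that("sample summaries aggregate disjoint per-class counts with correct shares", {
  # 3 egg peptides + 42 glue peptides, mirroring a ground-layer profile;
  # equal-length distinct peptides with a single terminal K each, so the
  # concatenated "proteins" contain each peptide exactly once
  egg_peps <- paste0("EGGTPT", c("A", "C", "D"), "K")
  pairs <- expand.grid(a = c("A", "C", "D", "E", "F", "G", "H"),
                       b = c("A", "C", "D", "E", "F", "G"),
                       stringsAsFactors = FALSE)
  glue_peps <- paste0("GAPGT", pairs$a, pairs$b, "K")[1:42]
  db <- sequence_db(tibble::tibble(
    accession = c("VIT", "COL"),
    description = c("VIT Vitellogenin-2", "COL Collagen alpha-1(I) chain"),
    species = c("Gallus gallus", "Ovis aries"),
    source_class = c("egg_yolk", "animal_glue"),
    sequence = c(paste(egg_peps, collapse = ""), paste(glue_peps, collapse = "")),
    is_contaminant = FALSE))
  rows <- dplyr::bind_rows(lapply(c(egg_peps, glue_peps), make_row, msms_count = 2L))
  ids <- identify_proteins(rows, db)
  cls <- map_sources(ids, db)
  summ <- summarize_sample("1:GL", ids, tibble::tibble(), cls, rows)
  glue <- summ[summ$source_class == "animal_glue", ]
  egg <- summ[summ$source_class == "egg_yolk", ]
  expect_identical(glue$n_peptides, 42L)
  expect_identical(egg$n_peptides, 3L)
  expect_equal(glue$peptide_share, 42 / 45)
  expect_equal(sum(summ$peptide_share), 1)
  expect_identical(glue$n_spectra, 84L)
  # every confident protein appears in exactly one summary row
  expect_identical(sum(summ$n_proteins), sum(ids$confident))
})

test_that("shared peptides are counted once, under the class with more unique peptides", {
  db <- sequence_db(tibble::tibble(
    accession = c("COL1", "COL3"),
    description = c("COL1 Collagen alpha-1(I) chain", "COL3 Collagen alpha-1(III) chain"),
    species = "Ovis aries",
    source_class = c("animal_glue", "hide_glue_indicator"),
    sequence = c("AAAAAAKGGGGGGKSHAREDPEPK", "CCCCCCKDDDDDDKEEEEEEKSHAREDPEPK"),
    is_contaminant = FALSE))
  rows <- dplyr::bind_rows(lapply(
    c("AAAAAAK", "GGGGGGK", "CCCCCCK", "DDDDDDK", "EEEEEEK", "SHAREDPEPK"),
    make_row))
  ids <- identify_proteins(rows, db)
  cls <- map_sources(ids, db)
  summ <- summarize_sample("S", ids, tibble::tibble(), cls, rows)
  # COL3 has 3 unique peptides vs COL1's 2: the shared peptide goes to COL3
  expect_identical(summ$n_peptides[summ$source_class == "hide_glue_indicator"], 4L)
  expect_identical(summ$n_peptides[summ$source_class == "animal_glue"], 2L)
  expect_identical(sum(summ$n_peptides), 6L)
})

test_that("an empty identification set yields an empty summary", {
  summ <- summarize_sample("S", identify_proteins(make_row("AAAK")[0, ], tiny_db()),
                           tibble::tibble(), character(0), make_row("AAAK")[0, ])
  expect_identical(nrow(summ), 0L)
})

test_that("binder calls report dominance, mixing caveats and egg-white caution", {
  summ <- tibble::tibble(
    sample_id = "S", source_class = c("animal_glue", "egg_yolk"),
    n_proteins = c(2L, 1L), n_peptides = c(42L, 3L),
    n_diagnostic_peptides = c(10L, 0L), n_spectra = c(84L, 6L),
    taxon = NA_character_, peptide_share = c(42 / 45, 3 / 45))
  call <- call_binder(summ)
  expect_identical(call$dominant_source, "animal_glue")
  expect_equal(call$dominant_share, 42 / 45)
  expect_length(call$caveats[[1]], 0)

  mixed <- summ
  mixed$peptide_share <- c(0.55, 0.45)
  expect_true(any(grepl("mixed", call_binder(mixed)$caveats[[1]])))

  eggy <- tibble::tibble(
    sample_id = "S", source_class = c("egg_yolk", "egg_white"),
    n_proteins = c(3L, 1L), n_peptides = c(50L, 20L),
    n_diagnostic_peptides = 0L, n_spectra = 10L, taxon = NA_character_,
    peptide_share = c(50 / 70, 20 / 70))
  expect_true(any(grepl("whole egg", call_binder(eggy)$caveats[[1]])))

  expect_error(call_binder(summ[0, ]), "empty")
})

test_that("binder calls are invariant to rescaling all counts", {
  summ <- tibble::tibble(
    sample_id = "S", source_class = c("animal_glue", "egg_yolk"),
    n_proteins = c(2L, 1L), n_peptides = c(42L, 3L),
    n_diagnostic_peptides = c(10L, 0L), n_spectra = c(84L, 6L),
    taxon = NA_character_, peptide_share = c(42 / 45, 3 / 45))
  scaled <- summ
  scaled$n_peptides <- scaled$n_peptides * 10L
  scaled$n_spectra <- scaled$n_spectra * 10L
  a <- call_binder(summ)
  b <- call_binder(scaled)
  expect_identical(a$dominant_source, b$dominant_source)
  expect_equal(a$dominant_share, b$dominant_share)
})

test_that("the report renders zero diagnostic peptides as an en dash", {
  summ <- tibble::tibble(
    sample_id = "1:GL", source_class = c("egg_yolk", "animal_glue"),
    n_proteins = c(1L, 2L), n_peptides = c(3L, 42L),
    n_diagnostic_peptides = c(0L, 4L), n_spectra = c(3L, 279L),
    taxon = c("Avian", "Ovis aries/Capra hircus"),
    peptide_share = c(3 / 45, 42 / 45))
  tab <- render_report(summ)
  expect_identical(tab$`Species-diagnostic peptides`, c("–", "4"))
  expect_identical(tab$`Protein source`, c("Egg yolk", "Animal glue"))
})
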