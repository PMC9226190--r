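test_that("filtering removes rows for the documented reasons with fixed precedence", {
  contam <- sequence_db(tibble::tibble(
    accession = "CON_K1", description = "keratin-like contaminant",
    species = "Homo sapiens", source_class = "other",
    sequence = "MKAAAAAAK", is_contaminant = TRUE), name = "con")
  rows <- make_rows(
    make_row("AGNLKKK", protein_refs = "P1", score = 80),                 # kept
    make_row("CCCCRRR", protein_refs = "CON_K1", score = 95),             # contaminant (refs)
    make_row("DDDDKKK", protein_refs = "P1", score = 95, is_contaminant = TRUE),
    make_row("EEEEKRK", protein_refs = "P1", score = 39.9),               # score
    make_row("FFFK", protein_refs = "P1", score = 80),                    # length
    make_row("GGGGKKK", protein_refs = "CON_K1", score = 10, is_reverse = TRUE) # reverse wins
  )
  out <- filter_evidence(rows, filter_config(), contam)
  expect_identical(nrow(out$kept) + nrow(out$removed), nrow(rows))
  expect_identical(out$kept$sequence, "AGNLKKK")
  expect_identical(out$removed$reason[match(c("CCCCRRR", "DDDDKKK", "EEEEKRK",
                                              "FFFK", "GGGGKKK"),
                                            out$removed$sequence)],
                   c("contaminant", "contaminant", "score", "length", "reverse"))
})

test_that("filtering an empty table yields empty output, not an error", {
  out <- filter_evidence(make_row("AGNLKKK")[0, ], filter_config(), NULL)
  expect_identical(nrow(out$kept), 0L)
  expect_identical(nrow(out$removed), 0L)
})

test_that("peptides are located at every occurrence, including overlapping ones", {
  db <- sequence_db(tibble::tibble(accession = "P1", description = "",
                                   species = "Sp", source_class = "unassigned",
                                   sequence = "XAGKAGK", is_contaminant = FALSE))
  iv <- locate_peptides("AGK", db)
  expect_identical(iv$start, c(2L, 5L))
  expect_identical(iv$end, c(4L, 7L))
  expect_identical(nrow(locate_peptides("WWWW", db)), 0L)
  # equivalence-aware: ALK found where the protein has AIK
  db2 <- sequence_db(tibble::tibble(accession = "P2", description = "",
                                    species = "Sp", source_class = "unassigned",
                                    sequence = "RAIKGGG", is_contaminant = FALSE))
  iv2 <- locate_peptides("ALK", db2, rules = equivalence_rules())
  expect_identical(nrow(iv2), 1L)
  expect_identical(iv2$start, 2L)
  expect_identical(nrow(locate_peptides("ALK", db2)), 0L)  # exact: no hit
})

test_that("the non-overlap rule follows containment semantics, not mere overlap", {
  iv <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    tibble::tibble(peptide = paste0("pep", seq_len(nrow(m))),
                   start = m[, 1], end = m[, 2])
  }
  expect_false(has_two_non_overlapping(iv(10, 20, 10, 25)))  # containment
  expect_true(has_two_non_overlapping(iv(10, 25, 18, 30)))   # partial overlap
  expect_false(has_two_non_overlapping(iv(10, 20)))          # single peptide
  expect_true(has_two_non_overlapping(iv(5, 15, 40, 55)))    # disjoint
  expect_false(has_two_non_overlapping(iv(10, 20, 10, 20)))  # equal = mutual containment
  # same interval from the same peptide (two occurrences) never qualifies
  same <- tibble::tibble(peptide = c("pepA", "pepA"), start = c(2, 30), end = c(8, 40))
  expect_false(has_two_non_overlapping(same))
})

test_that("the non-overlap rule agrees with the exhaustive pairwise oracle", {
  withr::with_seed(20, {
    for (i in 1:200) {
      iv <- random_intervals()
      expect_identical(has_two_non_overlapping(iv), oracle_non_overlap(iv),
                       info = paste("case", i))
    }
  })
})

test_that("protein identification applies uniqueness and the non-overlap rule", {
  db <- sequence_db(tibble::tibble(
    accession = c("A", "B"),
    description = "", species = "Sp", source_class = "unassigned",
    # A: unique peptides at two disjoint regions; B shares SHAREDSEQK with A? no:
    # SHAREDK occurs in both A and B
    sequence = c("MAAAGNLKWWWTTYYKSHAREDK", "MCCCCDDKSHAREDK"),
    is_contaminant = FALSE))
  rows <- make_rows(
    make_row("MAAAGNLK", msms_count = 2L),
    make_row("WWWTTYYK", msms_count = 3L),
    make_row("SHAREDK", msms_count = 5L)
  )
  ids <- identify_proteins(rows, db)
  a <- ids[ids$accession == "A", ]
  b <- ids[ids$accession == "B", ]
  expect_identical(a$n_unique, 2L)
  expect_true(a$confident)
  expect_identical(a$n_spectra, 10L)   # all supporting evidence incl. shared
  expect_identical(b$n_unique, 0L)     # only the shared peptide
  expect_false(b$confident)
})

test_that("nested unique peptides do not make a protein confident", {
  # three unique peptides, every pair in containment (tryptic prefixes)
  db <- sequence_db(tibble::tibble(
    accession = "A", description = "", species = "Sp",
    source_class = "unassigned",
    sequence = "MAAAKGGGKWWWKYYYYYYK", is_contaminant = FALSE))
  rows <- make_rows(make_row("MAAAK"), make_row("MAAAKGGGK"),
                    make_row("MAAAKGGGKWWWK"))
  ids <- identify_proteins(rows, db)
  expect_identical(ids$n_unique, 3L)
  expect_false(ids$confident)
  iv <- locate_peptides(rows$sequence, db)
  expect_identical(has_two_non_overlapping(iv), oracle_non_overlap(iv))
})

test_that("identifications are invariant to evidence-row order and monotone in added peptides", {
  db <- tiny_db()
  rows <- make_rows(
    make_row("MAGNLK", protein_refs = "P1"),
    make_row("WWTTYYK", protein_refs = "P1"),
    make_row("QQEEHHK", protein_refs = "P2")
  )
  ids1 <- identify_proteins(rows, db)
  ids2 <- identify_proteins(rows[sample.int(nrow(rows)), ], db)
  expect_equal(ids1, ids2)
  # adding a unique, non-overlapping peptide never revokes confidence
  p1 <- ids1[ids1$accession == "P1", ]
  expect_true(p1$confident)
  more <- dplyr::bind_rows(rows, make_row("CCCCR", protein_refs = "P2"))
  ids3 <- identify_proteins(more, db)
  expect_true(ids3$confident[ids3$accession == "P1"])
})

test_that("protein-group uniqueness rescues peptides shared within an ortholog family", {
  # two near-identical orthologs: every peptide occurs in both entries
  db <- sequence_db(tibble::tibble(
    accession = c("COL_SHEEP", "COL_GOAT"),
    description = "", species = c("Ovis aries", "Capra hircus"),
    source_class = "animal_glue",
    sequence = c("MAAAGNLKWWWTTYYKGGSPDEK", "MAAAGNLKWWWTTYYKGGSPDEK"),
    is_contaminant = FALSE))
  rows <- make_rows(make_row("MAAAGNLK"), make_row("WWWTTYYK"))
  # sequences here are identical, so default collapsing already rescues them;
  # make them differ by one residue to isolate the group option
  db2 <- sequence_db(tibble::tibble(
    accession = c("COL_SHEEP", "COL_GOAT"),
    description = "", species = c("Ovis aries", "Capra hircus"),
    source_class = "animal_glue",
    sequence = c("MAAAGNLKWWWTTYYKGGSPDEK", "MAAAGNLKWWWTTYYKGGSPDEV"),
    is_contaminant = FALSE))
  ids_plain <- identify_proteins(rows, db2)
  expect_false(any(ids_plain$confident))   # shared peptides are not unique
  ids_grp <- identify_proteins(rows, db2,
                               groups = list(COL = c("COL_SHEEP", "COL_GOAT")))
  expect_true(all(ids_grp$confident))      # unique at the family level
  expect_identical(ids_grp$n_unique, c(2L, 2L))
})

test_that("identical database entries are collapsed for uniqueness by default", {
  db <- sequence_db(tibble::tibble(
    accession = c("A", "A_dup"),
    description = "", species = "Sp", source_class = "unassigned",
    sequence = "MAAAGNLKWWWTTYYK", is_contaminant = FALSE))
  rows <- make_rows(make_row("MAAAGNLK"), make_row("WWWTTYYK"))
  ids <- identify_proteins(rows, db)
  expect_true(all(ids$confident))          # redundancy does not destroy uniqueness
  ids_literal <- identify_proteins(rows, db, collapse_identical = FALSE)
  expect_false(any(ids_literal$confident)) # the literal reading does
})
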