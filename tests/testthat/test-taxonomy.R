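test_that("tryptic digestion enumerates missed-cleavage peptides and applies length bounds", {
  p <- digest_params(max_missed = 2, min_len = 1, max_len = 30)
  expect_setequal(digest("AAAKGGGRCCC", p),
                  c("AAAK", "GGGR", "CCC", "AAAKGGGR", "GGGRCCC", "AAAKGGGRCCC"))
  p7 <- digest_params(max_missed = 2, min_len = 7, max_len = 30)
  expect_setequal(digest("AAAKGGGRCCC", p7),
                  c("AAAKGGGR", "GGGRCCC", "AAAKGGGRCCC"))
  # proline rule
  expect_setequal(digest("AGKPR", digest_params(enzyme = "trypsin_no_P",
                                                max_missed = 0, min_len = 1)),
                  "AGKPR")
  expect_setequal(digest("AGKPR", digest_params(enzyme = "trypsin",
                                                max_missed = 0, min_len = 1)),
                  c("AGK", "PR"))
})

test_that("digestion matches the all-substrings oracle on random sequences", {
  withr::with_seed(31, {
    for (i in 1:30) {
      seqc <- random_protein(sample(20:60, 1))
      for (mm in 0:2) {
        expect_setequal(
          digest(seqc, digest_params(max_missed = mm, min_len = 7, max_len = 60)),
          oracle_digest(seqc, max_missed = mm, min_len = 7, max_len = 60))
      }
      expect_setequal(
        digest(seqc, digest_params(enzyme = "trypsin_no_P", max_missed = 2,
                                   min_len = 7, max_len = 60)),
        oracle_digest(seqc, max_missed = 2, min_len = 7, max_len = 60, no_p = TRUE))
    }
  })
})

test_that("unspecific digestion returns every substring within the length window", {
  peps <- digest("ABCDEFGHIJ", digest_params(enzyme = "unspecific",
                                             min_len = 7, max_len = 8))
  expect_setequal(peps, c("ABCDEFG", "BCDEFGH", "CDEFGHI", "DEFGHIJ",
                          "ABCDEFGH", "BCDEFGHI", "CDEFGHIJ"))
})

test_that("site equivalence follows the three mass-ambiguity cases", {
  rules <- equivalence_rules()
  ctx0 <- observation_context("AGNSLK")
  # I/L: always ambiguous
  expect_true(sites_equivalent("L", "I", 2, ctx0, rules))
  expect_false(sites_equivalent("L", "I", 2, ctx0,
                                equivalence_rules(il_equal = FALSE)))
  # N/D, Q/E: ambiguous only when the site was never seen non-deamidated
  ctx_deam <- observation_context("AGNSLK", deamidated_only_sites = 3L)
  expect_true(sites_equivalent("N", "D", 3, ctx_deam, rules))
  expect_false(sites_equivalent("N", "D", 3, ctx0, rules))
  expect_true(sites_equivalent("Q", "E", 3,
                               observation_context("AGQSLK",
                                                   deamidated_only_sites = 3L),
                               rules))
  # S/A: ambiguous near an oxidised residue unless fragment ions cover the site
  ctx_ox <- observation_context("ASPGLK", oxidized_sites = 3L)
  expect_true(sites_equivalent("S", "A", 2, ctx_ox, rules))
  ctx_cov <- observation_context("ASPGLK", oxidized_sites = 3L, covered_sites = 2L)
  expect_false(sites_equivalent("S", "A", 2, ctx_cov, rules))
  expect_false(sites_equivalent("S", "A", 2, ctx0, rules))  # no oxidation nearby
  # different residues with no applicable rule never match
  expect_false(sites_equivalent("G", "V", 1, ctx0, rules))
})

test_that("species matching honours equivalence rules, terminus consistency and the oracle", {
  fx <- divergence_fixture(seed = 11)
  db <- fx$db
  rules <- equivalence_rules()
  params <- digest_params()
  base_seq <- db$sequence[db$accession == "BASE_SYN"]

  div <- fx$truth$divergence
  il <- div[div$class == "IL", ]
  hard <- div[div$class == "hard", ]
  pep_il <- peptide_at_site(base_seq, il$site)
  pep_hard <- peptide_at_site(base_seq, hard$site)

  # I/L-divergent peptide matches base and IL variant species
  m <- species_matches(pep_il$peptide, observation_context(pep_il$peptide),
                       db, params, rules)
  expect_true(all(c("Species base", "Species il") %in% m))
  # hard-substitution peptide matches only the true source species
  m2 <- species_matches(pep_hard$peptide, observation_context(pep_hard$peptide),
                        db, params, rules)
  expect_false("Species hard" %in% m2)
  expect_true("Species base" %in% m2)

  # soundness: with rules off and unspecific enzyme, equals a naive scan
  withr::with_seed(13, {
    peps <- digest(base_seq, digest_params(min_len = 7, max_len = 30))
    for (pep in sample(peps, min(10, length(peps)))) {
      expect_setequal(
        species_matches(pep, NULL, db, digest_params(enzyme = "unspecific"),
                        rules = NULL),
        oracle_species_scan(pep, db))
    }
  })
})

test_that("terminus consistency distinguishes tryptic from unspecific matching", {
  db <- sequence_db(tibble::tibble(
    accession = "P1", description = "", species = "Sp",
    source_class = "unassigned", sequence = "MAAAGGGKWWWTTK",
    is_contaminant = FALSE))
  # internal (non-tryptic) fragment: matched only under unspecific rules
  expect_identical(species_matches("AAGGGKW", NULL, db, digest_params(), NULL),
                   character(0))
  expect_identical(species_matches("AAGGGKW", NULL, db,
                                   digest_params(enzyme = "unspecific"), NULL),
                   "Sp")
})

test_that("enabling equivalence rules never shrinks the matched-species set", {
  withr::with_seed(17, {
    for (i in 1:10) {
      fx <- divergence_fixture(seed = 100 + i)
      base_seq <- fx$db$sequence[fx$db$accession == "BASE_SYN"]
      peps <- digest(base_seq, digest_params())
      pep <- peps[sample.int(length(peps), 1)]
      ctx <- observation_context(pep,
                                 deamidated_only_sites = seq_len(nchar(pep)),
                                 oxidized_sites = seq_len(nchar(pep)))
      off <- species_matches(pep, ctx, fx$db, digest_params(),
                             equivalence_rules(il_equal = FALSE,
                                               nd_conditional = FALSE,
                                               sa_near_oxidation = FALSE))
      for (rules in list(equivalence_rules(nd_conditional = FALSE,
                                           sa_near_oxidation = FALSE),
                         equivalence_rules(sa_near_oxidation = FALSE),
                         equivalence_rules())) {
        on <- species_matches(pep, ctx, fx$db, digest_params(), rules)
        expect_true(all(off %in% on))
      }
    }
  })
})

test_that("plausibility filtering drives diagnosis as in the sheep/goat collagen case", {
  matches <- c("Ovis aries", "Capra hircus", "Pantholops hodgsonii",
               "Bubalus bubalis")
  plaus <- plausibility_filter(
    c("Ovis aries", "Capra hircus", "Bos taurus", "Gallus gallus"),
    "European domesticates; 15th-century Italian panel")
  call <- diagnose("TGPPGPAGISGPPGPPGPAGK", matches, plausibility = plaus,
                   target = c("Ovis aries", "Capra hircus"))
  expect_true(call$diagnostic)
  expect_identical(call$target_taxon, "Ovis aries/Capra hircus")
  expect_setequal(call$matched_after_plausibility[[1]],
                  c("Ovis aries", "Capra hircus"))
  expect_true(any(grepl("plausibility excluded", call$notes[[1]])))

  # singleton match is diagnostic without any filter
  expect_true(diagnose("AGNLKWW", "Gallus gallus",
                       target = "Gallus gallus")$diagnostic)
  # filtered set exceeding the target is not diagnostic
  call2 <- diagnose("AGNLKWW", c("Ovis aries", "Capra hircus", "Bos taurus"),
                    plausibility = plaus, target = c("Ovis aries", "Capra hircus"))
  expect_false(call2$diagnostic)
  # implausible-only matches are flagged, never diagnostic
  call3 <- diagnose("AGNLKWW", "Pantholops hodgsonii", plausibility = plaus,
                    target = "Pantholops hodgsonii")
  expect_false(call3$diagnostic)
  expect_true(any(grepl("implausible-only", call3$notes[[1]])))
})

test_that("diagnosis is deterministic and idempotent given the same inputs", {
  matches <- c("Ovis aries", "Capra hircus")
  a <- diagnose("AAAAAAK", matches, target = matches)
  b <- diagnose("AAAAAAK", matches, target = matches)
  expect_equal(a, b)
})

test_that("parsimony assigns shared peptides to confirmed taxa only when unambiguous", {
  calls <- dplyr::bind_rows(
    diagnose("ALBPEPTIDEK", c("Gallus gallus", "Anas platyrhynchos"),
             target = character(0)),
    diagnose("COLPEPTIDEK", c("Ovis aries", "Capra hircus"),
             target = character(0)),
    diagnose("XXXPEPTIDEK", c("Bos taurus"), target = character(0))
  )
  confirmed <- list("Gallus gallus" = "Gallus gallus",
                    "Ovis aries/Capra hircus" = c("Ovis aries", "Capra hircus"))
  out <- parsimony_assign(calls, confirmed)
  expect_identical(out$target_taxon[1], "Gallus gallus")
  expect_true("parsimony" %in% out$notes[[1]])
  expect_identical(out$target_taxon[2], "Ovis aries/Capra hircus")
  expect_true("parsimony-group" %in% out$notes[[2]])
  expect_true(is.na(out$target_taxon[3]))  # nothing confirmed matches: no-op
})

test_that("strict fragment-coverage mode withholds diagnosis at uncovered distinguishing sites", {
  fx <- divergence_fixture(seed = 23)
  db <- fx$db
  hard <- fx$truth$divergence[fx$truth$divergence$class == "hard", ]
  pep <- peptide_at_site(db$sequence[db$accession == "BASE_SYN"], hard$site)
  rules_strict <- equivalence_rules(require_fragment_coverage = TRUE)
  m <- species_matches(pep$peptide, NULL, db, digest_params(), rules_strict)
  expect_false("Species hard" %in% m)
  # coverage unknown: not diagnostic in strict mode (the site separating the
  # peptide from the hard variant is not localised)
  call <- diagnose(pep$peptide, m, target = m,
                   ctx = observation_context(pep$peptide),
                   rules = rules_strict, dbs = db)
  expect_false(call$diagnostic)
  expect_true(any(grepl("not covered", call$notes[[1]])))
  # with the distinguishing site covered: diagnostic
  ctx_cov <- observation_context(pep$peptide,
                                 covered_sites = seq_len(nchar(pep$peptide)))
  call2 <- diagnose(pep$peptide, m, target = m, ctx = ctx_cov,
                    rules = rules_strict, dbs = db)
  expect_true(call2$diagnostic)
})
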