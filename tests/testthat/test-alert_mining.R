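test_that("fragment enumeration covers the hand-enumerable cases", {
  # ethane: no interior cut can produce a valid >= 2-atom piece
  f2 <- enumerate_fragments("CC")
  expect_identical(f2$pattern, "CC")
  # ethanol: parent plus both two-atom pieces from single-bond cuts
  f3 <- enumerate_fragments("CCO")
  expect_setequal(f3$pattern, c("CCO", "CO", "CC"))
  expect_identical(f3$n_atoms[match("CCO", f3$pattern)], 3L)
  # size bounds are enforced on heavy atoms
  f_min <- enumerate_fragments("CCO", min_atoms = 3L)
  expect_identical(f_min$pattern, "CCO")
  expect_error(enumerate_fragments("not_a_smiles"), "invalid")
})

test_that("recursive cleavage equals the exhaustive bond-cut oracle", {
  mols <- c("CCOc1ccccc1", "CC(C)CC(=O)O", "c1ccncc1CCN", "CC(F)(F)CCO",
            "CCSCC=C")
  for (m in mols) {
    rec <- enumerate_fragments(m)
    exh <- enumerate_fragments(m, exhaustive = TRUE)
    expect_setequal(rec$pattern, exh$pattern)
  }
})

test_that("every fragment substructure-matches its parent and rings stay intact", {
  mols <- c("CCOc1ccccc1", "CC(=O)Nc1ccccc1", "c1ccc2ccccc2c1")
  for (m in mols) {
    fr <- enumerate_fragments(m)
    hits <- dictox:::substructure_hit_matrix(fr$pattern, m)
    expect_true(all(hits[1, ]))
    # no partial rings: any aromatic fragment of an aromatic-ring parent
    # contains a full 6-ring or none of its atoms
    expect_false(any(grepl("^c1cc$", fr$pattern)))
  }
})

test_that("mined alerts count per-compound occurrences and PPV over the full set", {
  # planted design: 20 toxic share a pyridine, 20 nontoxic lack it
  tox <- paste0(c("CC", "CCC", "CCO", "CCN", "COC")[rep(1:5, 4)],
                rep(c("", "C", "CC", "O"), each = 5), "c1ccncc1")
  non <- paste0(c("CC", "CCC", "CCO", "CCN", "COC")[rep(1:5, 4)],
                rep(c("", "C", "CC", "O"), each = 5), "C(F)(F)F")
  ds <- data.frame(key = paste0("k", 1:40),
                   std_smiles = c(tox, non),
                   label = rep(c(1L, 0L), each = 20),
                   stringsAsFactors = FALSE)
  alerts <- mine_alerts(ds, min_occurrence = 5L, setting = "all_compounds")
  pyridine <- dictox:::ob_convert("c1ccncc1", to = "CAN")
  ring <- alerts[alerts$pattern == pyridine, ]
  expect_identical(nrow(ring), 1L)
  expect_identical(ring$occurrences, 20)
  expect_equal(ring$ppv, 1.0)
  # occurrence threshold is inclusive and anti-monotone
  a4 <- mine_alerts(ds, min_occurrence = 4L, setting = "all_compounds")
  a10 <- mine_alerts(ds, min_occurrence = 10L, setting = "all_compounds")
  expect_true(all(a10$pattern %in% a4$pattern))
  expect_true(nrow(a10) <= nrow(alerts))
  # toxic_only pools patterns from toxic compounds only
  at <- mine_alerts(ds, min_occurrence = 5L, setting = "toxic_only")
  expect_false(any(grepl("F", at$pattern)))
  expect_error(mine_alerts(ds[0, ], min_occurrence = 5L), "empty")
})

test_that("mixed-presence fragments get fractional PPV", {
  # shared scaffold in 8 toxic + 2 nontoxic compounds
  smis <- c(paste0(c("CC", "CCC", "CCO", "CCN", "COC", "CC(C)", "CCCC", "COCC"),
                   "c1ccncc1"),
            paste0(c("CC", "CCC"), "c1ccncc1"),
            paste0(c("CCO", "CCN", "COC", "CCCC"), "C(F)(F)F"))
  ds <- data.frame(key = paste0("k", seq_along(smis)), std_smiles = smis,
                   label = c(rep(1L, 8), rep(0L, 2), rep(0L, 4)))
  alerts <- mine_alerts(ds, min_occurrence = 5L, setting = "all_compounds")
  ring <- alerts[alerts$pattern == dictox:::ob_convert("c1ccncc1", to = "CAN"), ]
  expect_identical(ring$occurrences, 10)
  expect_equal(ring$ppv, 0.8)
})

test_that("substructure counting with the fingerprint prescreen is exact", {
  set.seed(2)
  smis <- paste0(sample(c("CC", "CCO", "CCN", "c1ccccc1", "CC(C)"), 30, TRUE),
                 sample(c("C(=O)O", "c1ccncc1", "F", "CO"), 30, TRUE))
  fr <- dictox:::enumerate_fragments_many(unique(smis))
  pats <- unique(do.call(rbind, fr)$pattern)
  fast <- dictox:::substructure_hit_matrix(pats, smis, prescreen = TRUE)
  slow <- dictox:::substructure_hit_matrix(pats, smis, prescreen = FALSE)
  expect_identical(fast, slow)
})

test_that("filter_and_merge applies the PPV, size and scaffold rules", {
  mk <- function(pattern, n_atoms, occ, pos, setting = "all_compounds") {
    data.frame(pattern = pattern, n_atoms = n_atoms, occurrences = occ,
               positives = pos, ppv = pos / occ, setting = setting,
               scheme = "binary_label", stringsAsFactors = FALSE)
  }
  a <- rbind(mk("c1ccncc1C", 7, 12, 11),        # kept
             mk("CCOCC", 5, 10, 4),             # ppv 0.4 < 0.5: dropped
             mk("CCOC", 4, 20, 20),             # 4 atoms: dropped
             mk("c1ccccc1", 6, 30, 25))         # benzene blocklist: dropped
  b <- mk("c1ccncc1C", 7, 8, 8, setting = "toxic_only")  # duplicate pattern
  out <- filter_and_merge(a, b)
  expect_identical(out$pattern, "c1ccncc1C")
  expect_identical(out$occurrences, 12)          # higher-occurrence record wins
  # boundary: ppv exactly 0.5 is kept ("below 0.5" is eliminated)
  out2 <- filter_and_merge(mk("CCOCCN", 6, 10, 5))
  expect_identical(nrow(out2), 1L)
  # raising min_ppv never adds alerts
  expect_lte(nrow(filter_and_merge(a, b, min_ppv = 0.95)), nrow(out))
})

test_that("screening lists matched alerts and skips excluded keys", {
  alerts <- data.frame(pattern = c("c1ccncc1", "C(F)(F)F"), n_atoms = c(6L, 4L),
                       occurrences = c(5, 5), positives = c(5, 5), ppv = c(1, 1),
                       setting = "all_compounds", scheme = "binary_label")
  comp <- data.frame(key = c("a", "b", "c"),
                     std_smiles = c("CCc1ccncc1", "CCO", "CC(F)(F)F"))
  out <- suppressMessages(screen_compounds(comp, alerts, exclude_keys = "c"))
  expect_identical(out$key, c("a", "b"))
  expect_identical(out$n_hits, c(1, 0))          # zero-hit row retained
  expect_identical(out$patterns[1], "c1ccncc1")
  expect_identical(attr(out, "n_skipped"), 1L)
  expect_error(screen_compounds(comp, data.frame(pattern = "][")), "invalid")
})
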