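# Cleavage-site scanner, peptide segmentation, family assignment and
# precursor scoring.

test_that("cleavage sites: dibasic and glycine-extended motifs, monobasic excluded", {
  expect_equal(nrow(find_cleavage_sites("EPEPPETGLW")), 0L)  # no K or R
  s <- find_cleavage_sites("AAAGKRAAA")
  expect_equal(s$start, 4L)
  expect_equal(s$end, 6L)
  expect_equal(s$basic_run, "KR")
  expect_true(s$amide_donor)
  expect_equal(nrow(find_cleavage_sites("AAKAA")), 0L)  # isolated K, no G
  # isolated basic with preceding G is a site (GK motif)
  g <- find_cleavage_sites("AAGKAA")
  expect_equal(g$start, 3L)
  expect_equal(g$end, 4L)
  expect_true(g$amide_donor)
  # X never matches motif letters
  expect_equal(nrow(find_cleavage_sites("AAXKAA")), 0L)
  expect_equal(nrow(find_cleavage_sites("AAKXRA")), 0L)
})

test_that("a maximal basic run with its donor glycine is one site", {
  s <- find_cleavage_sites("AAGKKRRKAA")
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 3L)
  expect_equal(s$end, 8L)
  expect_equal(s$basic_run, "KKRRK")
  expect_true(s$amide_donor)
  # restricted motif set: run must contain a configured pair
  cfg <- scanner_config(cleavage_motifs = c("KR"))
  expect_equal(nrow(find_cleavage_sites("AARKAA", cfg)), 0L)
  expect_equal(nrow(find_cleavage_sites("AAKRAA", cfg)), 1L)
  # donor G is consumed even when qualification comes from an internal pair
  cfg2 <- scanner_config(cleavage_motifs = c("KK"))
  s2 <- find_cleavage_sites("AAGKKAA", cfg2)
  expect_true(s2$amide_donor)
  expect_equal(s2$start, 3L)
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
  set.seed(101)
  for (rep in 1:300) {
    s <- random_residues(sample(30:200, 1))
    expect_identical(find_cleavage_sites(s),
                     oracle_cleavage_sites(s),
                     info = s)
  }
})

test_that("segmentation extracts the LW fragment peptide with its flags", {
  s <- paste0("MKR", "EPEPPETGLW", "KR", "AAA")
  pep <- segment_peptides(s, find_cleavage_sites(s), 0L, parent_id = "frag")
  lw <- pep[pep$mature == "EPEPPETGLW", ]
  expect_equal(nrow(lw), 1L)
  expect_false(lw$amidated)
  expect_true(lw$xp)
  expect_equal(lw$family, "LW_peptide")
  expect_true(lw$counts_toward_pass)
})

test_that("the glycine before the site is the amide donor and is consumed", {
  s <- paste0("AAA", "QFRFG", "KR", "AAA")
  pep <- segment_peptides(s, find_cleavage_sites(s), 3L, parent_id = "f")
  q <- pep[pep$mature == "QFRF", ]
  expect_equal(nrow(q), 1L)
  expect_true(q$amidated)
  expect_true(q$pyroglu)
  expect_equal(q$family, "RFamide")
  expect_false(grepl("G$", q$mature))  # donor G excluded from mature
})

test_that("over-long segments are emitted but do not count toward the pass criterion", {
  s <- paste0("AAKR", strrep("A", 25), "KRAA")
  pep <- segment_peptides(s, find_cleavage_sites(s), 0L)
  long <- pep[nchar(pep$mature) == 25L, ]
  expect_equal(nrow(long), 1L)
  expect_false(long$counts_toward_pass)
  # window large enough: same segment counts
  cfg <- scanner_config(window = 30L)
  pep2 <- segment_peptides(s, find_cleavage_sites(s, cfg), 0L, cfg)
  expect_true(pep2$counts_toward_pass[nchar(pep2$mature) == 25L])
})

test_that("terminal peptides count only when family-matched and allowed", {
  s <- paste0("AAKR", "QFSSLRF")  # terminal RF but not amidated -> unassigned
  pep <- segment_peptides(s, find_cleavage_sites(s), 0L)
  term <- pep[pep$mature == "QFSSLRF", ]
  expect_false(term$counts_toward_pass)
  s2 <- paste0("AAKR", "EPESSLW")  # terminal non-amidated LW: family match
  pep2 <- segment_peptides(s2, find_cleavage_sites(s2), 0L)
  term2 <- pep2[pep2$mature == "EPESSLW", ]
  expect_equal(term2$family, "LW_peptide")
  expect_true(term2$counts_toward_pass)
  cfg <- scanner_config(allow_terminal_peptide = FALSE)
  pep3 <- segment_peptides(s2, find_cleavage_sites(s2, cfg), 0L, cfg)
  expect_false("EPESSLW" %in% pep3$mature)
})

test_that("require_n_motif demands pyroglutamate, XP or an N-terminal site", {
  cfg <- scanner_config(require_n_motif = TRUE)
  # segment with plain N-terminus and no upstream site fails the strict rule
  s <- paste0("AAA", "FLSSF", "KR", "QFRFG", "KR")
  pep <- segment_peptides(s, find_cleavage_sites(s, cfg), 3L, cfg)
  expect_false(pep$counts_toward_pass[pep$mature == "FLSSF"])
  expect_true(pep$counts_toward_pass[pep$mature == "QFRF"])
})

test_that("family assignment follows table order, amidation state and X wildcard", {
  expect_equal(assign_family("EPEPPETGLW", FALSE), "LW_peptide")
  expect_equal(assign_family("QFRF", TRUE), "RFamide")
  expect_equal(assign_family("AAAA", FALSE), "unassigned")
  expect_equal(assign_family("QAGLW", TRUE), "GLWamide")   # X-L-W wildcard
  expect_equal(assign_family("QAPRA", TRUE), "PRXamide")
  expect_equal(assign_family("SSLW", TRUE), "GLWamide")    # amidated beats LW
  expect_equal(assign_family("SSKV", TRUE), "KVamide")
  expect_equal(assign_family("SSFR", FALSE), "unassigned") # FRamide needs amide
  # an X residue never satisfies a literal pattern position
  expect_equal(assign_family("QFRX", TRUE), "unassigned")
})

test_that("precursor scoring applies the documented weights and pass rule", {
  empty <- segment_peptides("AAA", find_cleavage_sites("AAA"), 0L)
  s0 <- score_precursor(empty)
  expect_equal(s0$score, 0)
  expect_false(s0$passes)
  # 3 identical passing amidated RFamides: one repeat group, all modified
  s <- paste0("AA", strrep("SKRQFRFGKR", 3))
  pep <- segment_peptides(s, find_cleavage_sites(s), 2L, parent_id = "p")
  sc <- score_precursor(pep)
  expect_equal(sc$n_passing, 3L)
  expect_equal(sc$n_repeat_groups, 1L)
  expect_equal(sc$n_modified, 3L)
  expect_equal(sc$score, 3 * 1.0 + 1 * 2.0 + 3 * 0.5)
  expect_true(sc$passes)
  # one passing unmodified non-amidated peptide scores exactly 1.0
  s2 <- paste0("AA", "KR", "FLSSF", "KR")
  pep2 <- segment_peptides(s2, find_cleavage_sites(s2), 2L, parent_id = "q")
  sc2 <- score_precursor(pep2)
  expect_equal(sc2$score, 1.0)
  expect_true(sc2$passes)
})

test_that("reconstruction invariant holds on random sequences", {
  set.seed(5)
  for (rep in 1:200) {
    s <- random_residues(sample(30:300, 1))
    expect_true(reconstructs(s), info = s)
  }
})

test_that("enlarging the window or motif set is monotone", {
  set.seed(17)
  for (rep in 1:50) {
    s <- random_residues(sample(50:200, 1))
    small <- scanner_config(window = 10L)
    large <- scanner_config(window = 30L)
    n_small <- sum(segment_peptides(s, find_cleavage_sites(s, small), 0L,
                                    small)$counts_toward_pass)
    n_large <- sum(segment_peptides(s, find_cleavage_sites(s, large), 0L,
                                    large)$counts_toward_pass)
    expect_gte(n_large, n_small)
    few <- scanner_config(cleavage_motifs = c("KR", "RR"))
    n_few <- nrow(find_cleavage_sites(s, few))
    n_all <- nrow(find_cleavage_sites(s))
    expect_gte(n_all, n_few)
  }
})

test_that("peptides never overlap each other or any site", {
  set.seed(23)
  for (rep in 1:50) {
    s <- random_residues(sample(50:200, 1))
    sites <- find_cleavage_sites(s)
    pep <- segment_peptides(s, sites, 0L)
    spans <- rbind(sites[, c("start", "end")], pep[, c("start", "end")])
    spans <- spans[order(spans$start), , drop = FALSE]
    if (nrow(spans) > 1L) {
      expect_true(all(spans$start[-1] > spans$end[-nrow(spans)]))
    }
  }
})

test_that("scanning starts after the signal peptide", {
  # a site inside the signal region must not create boundaries
  s <- paste0("MKRLLLLLSA", "QFRFG", "KR")
  pep <- segment_peptides(s, find_cleavage_sites(s), 10L, parent_id = "p")
  expect_equal(pep$mature, "QFRF")
  expect_equal(pep$start, 11L)
})
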