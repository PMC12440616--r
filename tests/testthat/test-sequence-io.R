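# Format round trips, validation errors and evidence-table dialects.

write_lines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

test_that("read_fasta concatenates wrapped lines, uppercases and tokenizes headers", {
  f <- write_lines(c(">p1 first protein", "MKWL", "lrfg", ">p2", "QQRF"))
  rec <- read_fasta(f)
  expect_equal(rec$id, c("p1", "p2"))
  expect_equal(rec$description, c("first protein", ""))
  expect_equal(rec$residues, c("MKWLLRFG", "QQRF"))
})

test_that("read_fasta returns an empty table for an empty file", {
  f <- write_lines(character(0))
  rec <- read_fasta(f)
  expect_s3_class(rec, "data.frame")
  expect_equal(nrow(rec), 0L)
})

test_that("read_fasta rejects illegal residues, naming record and position", {
  f <- write_lines(c(">bad", "MKBLR"))
  err <- expect_error(read_fasta(f), class = "neuropep_alphabet_error")
  expect_match(conditionMessage(err), "bad")
  expect_match(conditionMessage(err), "3")
  # X is allowed
  f2 <- write_lines(c(">okx", "MKXLR"))
  expect_equal(read_fasta(f2)$residues, "MKXLR")
})

test_that("read_fasta rejects duplicate ids", {
  f <- write_lines(c(">p1", "MKW", ">p1 again", "QRF"))
  expect_error(read_fasta(f), class = "neuropep_duplicate_id_error")
})

test_that("FASTA round trip reproduces sequences byte-identically", {
  set.seed(7)
  rec <- data.frame(id = sprintf("s%02d", 1:20),
                    description = rep(c("desc here", ""), 10),
                    residues = vapply(sample(50:300, 20), random_residues,
                                      character(1)),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".fasta")
  write_fasta(rec, f)
  back <- read_fasta(f)
  expect_identical(back$residues, rec$residues)
  expect_identical(back$id, rec$id)
  expect_identical(back$description, rec$description)
})

test_that("signal-caller rows map to has_signal and signal_end", {
  f <- write_lines(c("p1\tSP\t22", "p2\tOTHER\t-"))
  ev <- parse_evidence(f, "signal_caller")
  expect_equal(ev$table$has_signal, c(TRUE, FALSE))
  expect_equal(ev$table$signal_end, c(22L, NA_integer_))
})

test_that("tm-caller parsing counts membrane-spanning lines only", {
  f <- write_lines(c("p1\tinside\t1\t40", "p1\tTMhelix\t41\t62",
                     "p1\toutside\t63\t100", "p2\tinside\t1\t80"))
  ev <- parse_evidence(f, "tm_caller")
  tab <- ev$table
  expect_equal(tab$n_tm_regions[tab$id == "p1"], 1L)
  expect_equal(tab$n_tm_regions[tab$id == "p2"], 0L)
  expect_equal(ev$regions$start, 41L)
})

test_that("alignment rows are retained verbatim with optional description", {
  f <- write_lines(c(paste("q1", "subj1", "45.2", "100", "50", "2", "1",
                           "100", "3", "102", "1e-30", "150",
                           "FMRFamide neuropeptide precursor", sep = "\t"),
                     paste("q2", "subj2", "90", "60", "6", "0", "1", "60",
                           "1", "60", "1e-10", "80", sep = "\t")))
  ev <- parse_evidence(f, "alignment_hits")
  expect_equal(ev$table$pct_identity, c(45.2, 90))
  expect_equal(ev$table$e_value, c(1e-30, 1e-10))
  expect_equal(ev$table$description[2], "")
})

test_that("malformed evidence rows raise a located parse error; bad source a usage error", {
  f <- write_lines(c("p1\tSP\t22", "p2\tMAYBE\t9"))
  err <- expect_error(parse_evidence(f, "signal_caller"),
                      class = "neuropep_parse_error")
  expect_match(conditionMessage(err), "line 2")
  f2 <- write_lines("p1\tTMhelix\tforty\t60")
  expect_error(parse_evidence(f2, "tm_caller"), class = "neuropep_parse_error")
  expect_error(parse_evidence(f, "blast"), class = "neuropep_usage_error")
})

test_that("evidence dialects round trip through write_evidence", {
  f <- write_lines(c("p1\tSP\t22", "p2\tOTHER\t-"))
  ev <- parse_evidence(f, "signal_caller")
  f2 <- tempfile()
  write_evidence(ev, f2)
  expect_equal(parse_evidence(f2, "signal_caller")$table, ev$table)
})

test_that("orphaned evidence rows warn and are ignored rather than erroring", {
  rec <- data.frame(id = "p1", description = "", residues = "MKWLRF",
                    stringsAsFactors = FALSE)
  f <- write_lines(c("p1\tSP\t3", "ghost\tSP\t5"))
  ev <- parse_evidence(f, "signal_caller")
  expect_warning(res <- apply_prefilter(rec, list(ev),
                                        prefilter_config(require_signal = FALSE)),
                 "orphaned")
  expect_equal(res$report$id, "p1")
})

test_that("expression matrix and annotation load into profiles", {
  m <- write_lines(c("gene\tc1\tc2\tc3\tc4",
                     "g1\t5\t0\t1\t0",
                     "g2\t0\t0\t0\t0",
                     "g3\t2\t2\t2\t2"))
  a <- write_lines(c("c1\tneuronal", "c2\tneuronal",
                     "c3\tnon_neuronal", "c4\tnon_neuronal"))
  prof <- read_expression(m, a)
  expect_equal(dim(prof$means), c(3L, 4L))
  expect_equal(sort(prof$neuronal), c("c1", "c2"))
  expect_equal(unname(prof$means["g2", ]), rep(0, 4))  # all-zero row is valid
})

test_that("expression loading rejects negatives and unannotated clusters", {
  m <- write_lines(c("gene\tc1\tc2", "g1\t5\t-1"))
  a <- write_lines(c("c1\tneuronal", "c2\tnon_neuronal"))
  expect_error(read_expression(m, a), class = "neuropep_value_error")
  m2 <- write_lines(c("gene\tc1\tc2", "g1\t5\t1"))
  a2 <- write_lines("c1\tneuronal")
  expect_error(read_expression(m2, a2), class = "neuropep_schema_error")
})
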