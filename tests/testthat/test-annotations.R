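make_annotated <- function() {
  p <- toy_proteome(c(p1 = "MSTYKAAAAASSTTKKYY", p2 = "MKVLASTYKN"))
  masks <- list(p1 = c(rep(1L, 9), rep(0L, 9)), p2 = rep(0L, 10))
  sites <- data.frame(protein_id = c("p1", "p1", "p2"),
                      site_type = c("phospho_S", "ubiquitination",
                                    "phospho_T"),
                      position = c(2L, 5L, 7L),
                      score = c(0.9, 0.75, NA),
                      stringsAsFactors = FALSE)
  segments <- data.frame(protein_id = "p1",
                         segment_type = c("signal_peptide", "tm_helix"),
                         start = c(1L, 10L), end = c(4L, 15L),
                         stringsAsFactors = FALSE)
  annotateProteome(p, masks, sites, segments)
}

test_that("annotation joins enforce the joint invariants", {
  ap <- make_annotated()
  expect_s4_class(ap, "AnnotatedProteome")
  expect_equal(nrow(siteTable(ap)), 3L)
  # mask length mismatch
  p <- toy_proteome(c(p1 = "MSTYK"))
  expect_error(annotateProteome(p, list(p1 = c(1L, 0L))), "masks")
  # site on the wrong residue
  bad <- data.frame(protein_id = "p1", site_type = "phospho_S",
                    position = 1L, score = NA_real_)
  expect_error(annotateProteome(p, list(p1 = rep(0L, 5)), bad),
               "inconsistent")
  # overlapping TM helices
  seg <- data.frame(protein_id = c("p1", "p1"),
                    segment_type = "tm_helix",
                    start = c(1L, 2L), end = c(3L, 4L))
  expect_error(annotateProteome(p, list(p1 = rep(0L, 5)), segments = seg),
               "overlap")
})

test_that("site tables are validated on load, strict and lenient", {
  p <- toy_proteome(c(p1 = "MSTYKAAAAA"))
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- data.frame(protein_id = c("p1", "p1", "p1", "zz"),
                     site_type = c("phospho_S", "phospho_S", "phospho_S",
                                   "phospho_T"),
                     position = c(2L, 0L, 4L, 3L),
                     score = c(0.9, 0.9, 0.9, 0.9))
  write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSiteTable(f, p), "invalid site row")
  got <- suppressWarnings(readSiteTable(f, p, strict = FALSE))
  # only the S at position 2 survives: position 0 is out of bounds,
  # position 4 is a Y, and zz is unknown
  expect_equal(nrow(got), 1L)
  expect_equal(got$position, 2L)
  expect_equal(attr(got, "n_rejected"), 3L)
})

test_that("site serialization is canonical and round-trips", {
  sites <- data.frame(protein_id = c("b", "a", "a"),
                      site_type = c("phospho_S", "phospho_T", "phospho_S"),
                      position = c(5L, 9L, 2L),
                      score = c(0.5, 0.6, 0.7), stringsAsFactors = FALSE)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeSiteTable(sites, f1)
  back <- read.table(f1, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(back$protein_id, c("a", "a", "b"))
  expect_equal(back$position, c(2L, 9L, 5L))
  writeSiteTable(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("disorder masks load from both dialects and check lengths", {
  p <- toy_proteome(c(p1 = "MSTYK", p2 = "MK"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDisorderMasks(list(p1 = c(1L, 1L, 0L, 0L, 1L), p2 = c(0L, 1L)), f)
  m <- readDisorderMasks(f, p)
  expect_equal(m$p1, c(1L, 1L, 0L, 0L, 1L))
  expect_equal(m$p2, c(0L, 1L))
  # long per-residue dialect
  f2 <- withr::local_tempfile(fileext = ".tsv")
  d <- data.frame(protein_id = rep("p1", 5), position = 1:5,
                  state = c("*", ".", ".", "*", "."))
  write.table(d, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  m2 <- readDisorderMasks(f2, p, format = "residue")
  expect_equal(m2$p1, c(1L, 0L, 0L, 1L, 0L))
  # length mismatch rejected
  writeDisorderMasks(list(p1 = c(1L, 0L)), f)
  expect_error(readDisorderMasks(f, p), "length")
})

test_that("ubiquitination confidence band is inclusive at both ends", {
  sites <- data.frame(protein_id = "p1", site_type = "ubiquitination",
                      position = 1:5,
                      score = c(0.69, 0.70, 0.84, 0.85, 0.50),
                      stringsAsFactors = FALSE)
  kept <- filterUbiquitination(sites)
  expect_equal(kept$score, c(0.69, 0.70, 0.84))
  # other site types pass through untouched
  mixed <- rbind(sites,
                 data.frame(protein_id = "p1", site_type = "phospho_S",
                            position = 6L, score = NA_real_))
  expect_equal(sum(filterUbiquitination(mixed)$site_type == "phospho_S"), 1L)
  # missing score on a ubiquitination site
  noscore <- data.frame(protein_id = "p1", site_type = "ubiquitination",
                        position = 1L, score = NA_real_)
  expect_error(filterUbiquitination(noscore), "without a score")
  expect_equal(nrow(suppressWarnings(
    filterUbiquitination(noscore, strict = FALSE))), 0L)
})

test_that("disorder content and residue split are exact and additive", {
  expect_equal(disorderContent(c(rep(1L, 25), rep(0L, 75))), 0.25)
  expect_equal(disorderContent(rep(0L, 10)), 0)
  expect_equal(disorderContent(rep(1L, 10)), 1)
  expect_equal(splitResidues(c(1L, 1L, 0L, 0L)), c(Ld = 2, Lo = 2))
  expect_equal(splitResidues(rep(1L, 7)), c(Ld = 7, Lo = 0))
  # pooling over proteins is additive and consistent with total_aa
  masks <- list(a = c(1L, 1L, 0L), b = c(1L, 1L, 1L, 0L, 0L))
  s <- splitResidues(masks)
  expect_equal(unname(s["Ld"]), 5)
  expect_equal(sum(s), 8)
})

test_that("secretory context is derived from segment annotations", {
  ap <- make_annotated()
  ctx <- secretoryContextFor(segmentTable(ap), "p1")
  expect_true(ctx$hasSignalPeptide)
  expect_equal(ctx$signalEnd, 4L)
  expect_equal(nrow(ctx$tmSegments), 1L)
  ctx2 <- secretoryContextFor(segmentTable(ap), "p2")
  expect_false(ctx2$hasSignalPeptide)
  expect_equal(nrow(ctx2$tmSegments), 0L)
})
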