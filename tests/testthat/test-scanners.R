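test_that("O-gly scanner finds the consensus with canonical extent", {
  m <- scanOgly("APAP")
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end, m$anchor), c(1L, 4L, 2L))
  expect_equal(nrow(scanOgly("GLGLGLG")), 0L)
  m2 <- scanOgly("APAPAPAP")
  expect_equal(m2$start, c(1L, 5L))
  expect_equal(m2$end, c(4L, 8L))
  # proline runs are consumed greedily; the trailing run takes its minimum
  m3 <- scanOgly("APPPTPP")
  expect_equal(nrow(m3), 1L)
  expect_equal(c(m3$start, m3$end, m3$anchor), c(1L, 6L, 2L))
  # X never matches the literal classes but can fill the spacer
  expect_equal(nrow(scanOgly("XPAP")), 0L)
  expect_equal(nrow(scanOgly("APXAP")), 1L)
})

test_that("O-gly matches never overlap and respect locality", {
  set.seed(31)
  rich <- c("P", "A", "S", "T", "V", "G", "L", "E")
  for (i in 1:40) {
    s <- random_seq(sample(30:150, 1), alphabet = rich)
    m <- scanOgly(s)
    if (nrow(m) > 1)
      expect_true(all(m$start[-1] > m$end[-nrow(m)]))
    # concatenating with a long G spacer adds match counts
    s2 <- random_seq(sample(30:80, 1), alphabet = rich)
    joined <- paste0(s, strrep("G", 15), s2)
    expect_equal(nrow(scanOgly(joined)), nrow(m) + nrow(scanOgly(s2)))
  }
})

test_that("O-gly scanner equals the exhaustive enumeration oracle", {
  set.seed(32)
  rich <- c("P", "P", "A", "S", "T", "V", "G", "K")
  for (i in 1:300) {
    s <- random_seq(sample(10:120, 1), alphabet = rich)
    got <- scanOgly(s)
    want <- ogly_scan_oracle(s)
    expect_equal(nrow(got), nrow(want), info = s)
    if (nrow(want)) {
      expect_equal(got$start, want$start, info = s)
      expect_equal(got$end, want$end, info = s)
      expect_equal(got$anchor, want$anchor, info = s)
    }
  }
})

test_that("sequon scanner reports all overlapping N-X-S/T hits", {
  m <- scanNglySequons("ANKSA")
  expect_equal(m$anchor, 2L)
  expect_equal(nrow(scanNglySequons("ANPSA")), 0L)
  expect_equal(scanNglySequons("NNSS")$anchor, c(1L, 2L))
  # X is not proline, so it can stand in the middle, never as N or S/T
  expect_equal(nrow(scanNglySequons("NXS")), 1L)
  expect_equal(nrow(scanNglySequons("XAS")), 0L)
  expect_equal(nrow(scanNglySequons("NAX")), 0L)
})

test_that("sequon scanner equals the brute-force triple scan", {
  set.seed(33)
  rich <- c("N", "N", "S", "T", "P", "A", "G", "L")
  for (i in 1:300) {
    s <- random_seq(sample(3:100, 1), alphabet = rich)
    expect_equal(scanNglySequons(s)$anchor, ngly_scan_oracle(s), info = s)
  }
})

test_that("secretory gate counts sequons per the combination rule", {
  sq <- scanNglySequons(paste0(strrep("A", 28), "NKS",
                               strrep("G", 20), "NAT", strrep("A", 20)))
  expect_equal(sq$anchor, c(29L, 52L))
  # no signal peptide, no TM: nothing counted
  expect_equal(nrow(combineNgly(sq, secretoryContext())), 0L)
  # signal peptide only: both counted (anchors past the signal region)
  got <- combineNgly(sq, secretoryContext(TRUE, signalEnd = 20))
  expect_equal(got$anchor, c(29L, 52L))
  expect_true(all(got$kind == "ngly"))
  # TM segment covering the second anchor removes exactly it
  ctx <- secretoryContext(FALSE, tmSegments = data.frame(start = 50, end = 70))
  expect_equal(combineNgly(sq, ctx)$anchor, 29L)
  # anchors within the signal peptide are cleaved away
  sq2 <- scanNglySequons(paste0(strrep("A", 9), "NKS", strrep("A", 30)))
  expect_equal(nrow(combineNgly(sq2, secretoryContext(TRUE, signalEnd = 20))),
               0L)
  expect_equal(nrow(combineNgly(sq2, secretoryContext(TRUE, signalEnd = 20),
                                excludeSignalRegion = FALSE)), 1L)
})

test_that("gating is monotone: output is a subset of input sequons", {
  set.seed(34)
  for (i in 1:30) {
    s <- random_seq(120, alphabet = c("N", "S", "T", "A", "G", "L", "P"))
    sq <- scanNglySequons(s)
    ctx_open <- secretoryContext(TRUE)
    base <- combineNgly(sq, ctx_open)
    expect_true(all(base$anchor %in% sq$anchor))
    # adding a TM segment to an already-open gate never adds sequons
    ctx_tm <- secretoryContext(TRUE, tmSegments = data.frame(start = 60,
                                                             end = 80))
    with_tm <- combineNgly(sq, ctx_tm)
    expect_true(all(with_tm$anchor %in% base$anchor))
    # but a TM segment can open a closed gate
    closed <- combineNgly(sq, secretoryContext(FALSE))
    opened <- combineNgly(sq, secretoryContext(FALSE,
                                               tmSegments = data.frame(
                                                 start = 60, end = 80)))
    expect_equal(nrow(closed), 0L)
    expect_gte(nrow(opened), 0L)
  }
})

test_that("PEST candidates require flanks, length and composition", {
  expect_equal(nrow(scanPest("KAAAAAAAAAAAAK")), 0L)   # no D/E/P/S/T inside
  m <- scanPest(paste0("K", strrep("PEST", 3), "R"))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end, m$anchor), c(2L, 13L, 2L))
  expect_gt(m$score, 5)
  # no positively charged flank anywhere: no candidates
  expect_equal(nrow(scanPest(strrep("PEST", 10))), 0L)
  # terminal regions use the sequence ends as the opposite boundary
  m2 <- scanPest(paste0(strrep("PEST", 3), "K"))
  expect_equal(nrow(m2), 1L)
  expect_equal(c(m2$start, m2$end), c(1L, 12L))
  # shorter than 12 residues between flanks: rejected
  expect_equal(nrow(scanPest("KPESTPESTPESK")), 0L)
})

test_that("PEST scores match the published-constant oracle", {
  set.seed(35)
  for (i in 1:40) {
    region <- random_seq(sample(12:60, 1),
                         alphabet = c("P", "E", "S", "T", "D", "A", "G",
                                      "L", "Q"))
    ch <- strsplit(region, "")[[1]]
    if (!any(ch == "P") || !any(ch %in% c("D", "E")) ||
        !any(ch %in% c("S", "T"))) next
    got <- scanPest(paste0("K", region, "R"), threshold = -1e9)
    expect_equal(got$score, pest_score_oracle(region), tolerance = 1e-10)
  }
})

test_that("hydrophobic regions score below the PEST threshold", {
  region <- paste0("PES", strrep("ILVF", 5), "T")
  m <- scanPest(paste0("K", region, "K"))
  expect_equal(nrow(m), 0L)
  m2 <- scanPest(paste0("K", region, "K"), threshold = -1e9)
  expect_lt(m2$score, 5)
})
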