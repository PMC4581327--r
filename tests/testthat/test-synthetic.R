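small_cfg <- function(seed = 9, ...) {
  synthConfig(nSpecies = 2, nProteinsPerSpecies = 40,
              lengthLaw = list(min = 50, max = 800, meanlog = log(200),
                               sdlog = 0.5),
              seed = seed, ...)
}

test_that("generation is deterministic and byte-identical on disk", {
  g1 <- generateProteomes(small_cfg())
  g2 <- generateProteomes(small_cfg())
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSyntheticSet(g1, d1)
  writeSyntheticSet(g2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # a different seed changes the output
  g3 <- generateProteomes(small_cfg(seed = 10))
  expect_false(identical(as.character(aaSequences(g1$proteomes[[1]])),
                         as.character(aaSequences(g3$proteomes[[1]]))))
})

test_that("planted masks hit the target fraction with contiguous segments", {
  set.seed(51)
  expect_equal(plantDisorderMask(100, 0), integer(100))
  expect_equal(plantDisorderMask(100, 1), rep(1L, 100))
  for (i in 1:20) {
    L <- sample(60:400, 1)
    f <- runif(1, 0.05, 0.95)
    m <- plantDisorderMask(L, f)
    nd <- round(f * L)
    expect_lte(abs(sum(m) - f * L), 1)
    # contiguous segments: the run count matches the segment-law target
    r <- rle(m)
    k_expect <- min(max(1, round(nd / 30)), nd, L - nd + 1)
    expect_equal(sum(r$values == 1), k_expect)
  }
  m50 <- plantDisorderMask(100, 0.5)
  expect_lte(abs(sum(m50) - 50), 1)
})

test_that("site planting respects the enrichment ratio and its edge cases", {
  set.seed(52)
  L <- 20000
  mask <- c(rep(1L, L / 2), rep(0L, L / 2))
  seqstr <- paste(rep("S", L), collapse = "")
  expect_equal(plantSites(mask, seqstr, "phospho_S", base = 0, rho = 5),
               integer(0))
  s0 <- plantSites(rep(1L, 100), strrep("S", 100), "phospho_S",
                   base = 2, rho = 0)
  expect_equal(s0, integer(0))
  # rho = 10 over 10,000 disordered and 10,000 ordered legal residues
  pos <- plantSites(mask, seqstr, "phospho_S", base = 4, rho = 10)
  nd <- sum(pos <= L / 2); no <- sum(pos > L / 2)
  expect_gt(nd / no, 10 * 0.8)
  expect_lt(nd / no, 10 * 1.2)
  # sites only on legal residues
  seq2 <- paste(rep(c("S", "A"), L / 2), collapse = "")
  pos2 <- plantSites(rep(1L, L), seq2, "phospho_S", base = 2, rho = 1)
  expect_true(all(pos2 %% 2 == 1))
})

test_that("emitted annotations load cleanly through strict validation", {
  gen <- generateProteomes(small_cfg())
  dir <- withr::local_tempdir()
  writeSyntheticSet(gen, dir)
  for (sp in names(gen$proteomes)) {
    p <- readProteomeFasta(file.path(dir, paste0(sp, ".fasta")), sp)
    masks <- readDisorderMasks(file.path(dir, paste0(sp, "_masks.tsv")), p)
    sites <- readSiteTable(file.path(dir, paste0(sp, "_sites.tsv")), p,
                           strict = TRUE)
    segs <- readSegmentTable(file.path(dir, paste0(sp, "_segments.tsv")), p,
                             strict = TRUE)
    ap <- annotateProteome(p, masks, sites, segs)
    expect_s4_class(ap, "AnnotatedProteome")
    expect_equal(nProteins(ap), nProteins(gen$proteomes[[sp]]))
  }
})

test_that("family layout plants common, specific and duplicate structure", {
  gen <- generateProteomes(small_cfg())
  tp <- gen$truthProteins
  expect_setequal(unique(tp$category),
                  c("common", "specific", "intermediate"))
  # common families have one member in every species
  fam_span <- tapply(tp$species_id[is.na(tp$duplicate_of)],
                     tp$family_id[is.na(tp$duplicate_of)],
                     function(x) length(unique(x)))
  common_fams <- unique(tp$family_id[tp$category == "common"])
  expect_true(all(fam_span[common_fams] == 2))
  specific_fams <- unique(tp$family_id[tp$category == "specific"])
  expect_true(all(fam_span[specific_fams] == 1))
  # duplicates reference existing proteins and stay near-identical
  dup <- tp[!is.na(tp$duplicate_of), ]
  expect_gt(nrow(dup), 0)
  expect_true(all(dup$duplicate_of %in% tp$protein_id))
  seqs <- unlist(lapply(gen$proteomes, function(ap)
    as.character(aaSequences(ap))))
  names(seqs) <- unlist(lapply(gen$proteomes, proteinIds))
  for (i in seq_len(min(5, nrow(dup)))) {
    pi <- globalIdentity(seqs[[dup$protein_id[i]]],
                         seqs[[dup$duplicate_of[i]]])[["pi"]]
    expect_gt(pi, 93)
  }
})

test_that("specific families carry the planted disorder multiplier", {
  gen <- generateProteomes(synthConfig(nSpecies = 3,
                                       nProteinsPerSpecies = 150, seed = 13))
  tp <- gen$truthProteins
  res <- categoryContrast(tp$disorder_fraction, tp$category)
  expect_equal(res$ratio_s_over_c, 1.7, tolerance = 0.12)
  expect_lt(res$p_one_tailed, 0.01)
})

test_that("ubiquitination decoys fall outside the confidence band", {
  gen <- generateProteomes(small_cfg())
  ap <- gen$proteomes[[1]]
  ub <- siteTable(ap)[siteTable(ap)$site_type == "ubiquitination", ]
  truth <- gen$truthSites
  truth_ub <- truth[truth$site_type == "ubiquitination" &
                      truth$species_id == speciesId(ap), ]
  key <- paste(ub$protein_id, ub$position)
  tkey <- paste(truth_ub$protein_id, truth_ub$position)
  planted <- key %in% tkey
  expect_true(all(ub$score[planted] >= 0.69 & ub$score[planted] <= 0.84))
  if (any(!planted))
    expect_true(all(ub$score[!planted] < 0.69 | ub$score[!planted] > 0.84))
  # the band filter therefore recovers exactly the planted sites
  kept <- filterUbiquitination(siteTable(ap))
  kub <- kept[kept$site_type == "ubiquitination", ]
  expect_setequal(paste(kub$protein_id, kub$position), tkey)
})

test_that("infeasible enrichment configs are rejected with an explanation", {
  expect_error(synthConfig(enrichment = list(
    phospho_S = list(rho = 500, base = 5)), seed = 1), "infeasible")
  expect_error(synthConfig(seed = 1, nSpecies = 0), "nSpecies")
  expect_error(synthConfig(), "seed")
})
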