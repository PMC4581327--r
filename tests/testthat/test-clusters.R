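test_that("globalIdentity handles self, prefix, and disjoint pairs", {
  expect_equal(unname(globalIdentity("MKVLAMKVLA", "MKVLAMKVLA")),
               c(100, 100))
  # exact prefix: pi and pmatch 100 over the matched region
  st <- globalIdentity("MKVLA", "MKVLAGGGGG")
  expect_equal(unname(st), c(100, 100))
  # no shared residues at all
  st <- globalIdentity(strrep("A", 30), strrep("G", 30))
  expect_lte(st[["pi"]], 20)
})

test_that("alignment engine agrees with an exhaustive DP oracle on scores", {
  set.seed(21)
  params <- identityParams()
  for (i in 1:25) {
    a <- random_seq(sample(4:12, 1))
    b <- random_seq(sample(4:12, 1))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(a), Biostrings::AAStringSet(b),
      substitutionMatrix = idrptm:::.substMatrix(params$match,
                                                 params$mismatch),
      gapOpening = 0, gapExtension = -params$gap, type = "global")
    expect_equal(Biostrings::score(al), nw_score_oracle(a, b),
                 info = paste(a, b))
  }
})

test_that("percent identity of substitution-only mutants is exact", {
  set.seed(22)
  for (i in 1:10) {
    L <- sample(60:150, 1)
    a <- random_seq(L)
    ch <- strsplit(a, "")[[1]]
    nmut <- sample(1:5, 1)
    at <- sample(L, nmut)
    repl <- vapply(ch[at], function(x) sample(setdiff(AA20, x), 1),
                   character(1))
    ch[at] <- repl
    b <- paste(ch, collapse = "")
    st <- globalIdentity(a, b)
    expect_equal(st[["pi"]], 100 * (L - nmut) / L, tolerance = 1e-12)
    expect_equal(st[["pmatch"]], 100)
  }
})

test_that("clusters are single-linkage components of the threshold graph", {
  # identical pair joins; unrelated stays apart
  p <- toy_proteome(c(a = strrep("MKVLA", 20), b = strrep("MKVLA", 20),
                      c = random_seq(100)))
  cat <- buildClusters(p)
  tab <- clusterTable(cat)
  expect_equal(length(unique(tab$cluster_id)), 2L)
  expect_equal(tab$cluster_id[tab$protein_id == "a"],
               tab$cluster_id[tab$protein_id == "b"])
  # all dissimilar: all singletons
  set.seed(23)
  p2 <- toy_proteome(setNames(vapply(1:6, function(i) random_seq(80),
                                     character(1)), paste0("r", 1:6)))
  expect_equal(length(unique(clusterTable(buildClusters(p2))$cluster_id)),
               6L)
})

test_that("transitive chains merge even when the ends fall below cutoff", {
  set.seed(24)
  base <- strsplit(random_seq(100), "")[[1]]
  mutate_at <- function(ch, at) {
    ch[at] <- vapply(ch[at], function(x) sample(setdiff(AA20, x), 1),
                     character(1))
    ch
  }
  A <- paste(base, collapse = "")
  B <- paste(mutate_at(base, 1:8), collapse = "")        # 92% to A
  C <- paste(mutate_at(strsplit(B, "")[[1]], 9:16), collapse = "") # 84% to A
  p <- toy_proteome(c(A = A, B = B, C = C))
  expect_lt(globalIdentity(A, C)[["pi"]], 90)
  tab <- clusterTable(buildClusters(p))
  expect_equal(length(unique(tab$cluster_id)), 1L)
})

test_that("clustering output is a partition and refines under tightening", {
  set.seed(25)
  seqs <- setNames(vapply(1:10, function(i) random_seq(70), character(1)),
                   paste0("p", 1:10))
  # add mutated copies at ~96% identity
  for (k in 1:4) {
    ch <- strsplit(seqs[[k]], "")[[1]]
    at <- sample(70, 3)
    ch[at] <- vapply(ch[at], function(x) sample(setdiff(AA20, x), 1),
                     character(1))
    seqs[[paste0("p", k, "m")]] <- paste(ch, collapse = "")
  }
  p <- toy_proteome(seqs)
  tab90 <- clusterTable(buildClusters(p, identityParams(90, 90)))
  expect_setequal(tab90$protein_id, names(seqs))
  expect_equal(anyDuplicated(tab90$protein_id), 0L)
  tab97 <- clusterTable(buildClusters(p, identityParams(97, 90)))
  # 97% clusters refine 90% clusters: co-membership at 97 implies it at 90
  m90 <- setNames(tab90$cluster_id, tab90$protein_id)
  m97 <- setNames(tab97$cluster_id, tab97$protein_id)
  pairs <- combn(names(seqs), 2)
  together97 <- m97[pairs[1, ]] == m97[pairs[2, ]]
  together90 <- m90[pairs[1, ]] == m90[pairs[2, ]]
  expect_true(all(!together97 | together90))
})

test_that("representatives are the longest member with id tie-break", {
  p <- toy_proteome(c(short = strrep("MKVLA", 24),       # 120 aa
                      long = strrep("MKVLA", 40)))       # 200 aa, 100% id
  cat <- buildClusters(p)
  rep <- selectRepresentatives(cat, p)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$protein_id, "long")
  # tie on length: lexicographically smallest id
  p2 <- toy_proteome(c(b = strrep("MKVLA", 20), a = strrep("MKVLA", 20),
                       z = random_seq(60)))
  rep2 <- selectRepresentatives(buildClusters(p2), p2)
  expect_true("a" %in% rep2$protein_id)
  expect_false("b" %in% rep2$protein_id)
  expect_true("z" %in% rep2$protein_id)   # singleton keeps its sole member
})

test_that("redundancy content is the removed fraction", {
  expect_equal(redundancyContent(100, 90), 0.10)
  expect_equal(redundancyContent(100, 100), 0)
  expect_equal(redundancyContent(50, 25), 0.5)
  expect_error(redundancyContent(0, 0), "positive")
  expect_error(redundancyContent(10, 11), "nAfter")
})

test_that("cluster categories follow the species-membership rule", {
  asg <- data.frame(
    cluster_id = c("c1", "c2", "c2", "c2", "c2", "c3", "c3"),
    species_id = c("s1", "s1", "s2", "s3", "s4", "s1", "s2"),
    protein_id = paste0("p", 1:7), stringsAsFactors = FALSE)
  cat <- new("ClusterCatalog", assignments = asg)
  panel <- paste0("s", 1:4)
  cls <- classifyClusters(cat, panel)
  expect_equal(cls$category[cls$cluster_id == "c1"], "specific")
  expect_equal(cls$category[cls$cluster_id == "c2"], "common")
  expect_equal(cls$category[cls$cluster_id == "c3"], "intermediate")
  expect_equal(sum(table(cls$category)), nrow(cls))
  expect_error(classifyClusters(cat, paste0("s", 1:3)), "outside the panel")
})

test_that("category contrast reproduces ratio arithmetic and symmetry", {
  set.seed(26)
  xs <- 34 + rnorm(40, 0, 2); xs <- xs - mean(xs) + 34
  xc <- 20 + rnorm(40, 0, 2); xc <- xc - mean(xc) + 20
  res <- categoryContrast(c(xs, xc), rep(c("specific", "common"), each = 40))
  expect_equal(res$ratio_s_over_c, 1.7, tolerance = 1e-12)
  expect_lt(res$p_one_tailed, 0.05)
  # identical value multisets: ratio 1, p about one half
  v <- c(1, 2, 3, 4, 5)
  res2 <- categoryContrast(c(v, v), rep(c("specific", "common"), each = 5))
  expect_equal(res2$ratio_s_over_c, 1)
  expect_equal(res2$p_one_tailed, 0.5, tolerance = 0.01)
  expect_error(categoryContrast(1:3, rep("specific", 3)), "non-empty")
})

test_that("permutation p matches the exhaustive enumeration oracle", {
  set.seed(27)
  for (i in 1:5) {
    xs <- rnorm(6, 1, 1)
    xc <- rnorm(7, 0, 1)
    res <- categoryContrast(c(xs, xc),
                            rep(c("specific", "common"), c(6, 7)),
                            method = "permutation")
    expect_equal(res$p_one_tailed, perm_p_oracle(xs, xc), tolerance = 0.02)
  }
})

test_that("cluster tables round-trip through TSV", {
  asg <- data.frame(cluster_id = c("c1", "c1", "c2"),
                    species_id = c("s1", "s2", "s1"),
                    protein_id = c("p1", "p2", "p3"),
                    stringsAsFactors = FALSE)
  cat <- new("ClusterCatalog", assignments = asg)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeClusterTable(cat, f)
  expect_equal(clusterTable(readClusterTable(f)), asg)
})
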