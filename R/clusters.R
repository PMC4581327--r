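#' @include AllClasses.R AllGenerics.R proteome-io.R
NULL

#' Identity-clustering parameters
#'
#' Thresholds for the redundancy graph: a pair of proteins is linked when
#' its global percent identity (`pi`) and percent match (`pmatch`) both meet
#' the cutoffs. The 90/90 defaults reproduce the redundancy-removal setting
#' used for multi-species proteome sets; alignment scoring is a simple
#' match/mismatch/gap scheme (defaults +1/0/-1).
#'
#' @param piCutoff percent-identity threshold in (0, 100]; default 90.
#' @param pmatchCutoff percent-match threshold in (0, 100]; default 90.
#' @param match,mismatch,gap alignment scores; defaults +1, 0, -1.
#' @return a list of class `identityParams`.
#' @export
identityParams <- function(piCutoff = 90, pmatchCutoff = 90,
                           match = 1, mismatch = 0, gap = -1) {
  stopifnot(piCutoff > 0, piCutoff <= 100, pmatchCutoff > 0,
            pmatchCutoff <= 100, gap <= 0)
  structure(list(piCutoff = piCutoff, pmatchCutoff = pmatchCutoff,
                 match = match, mismatch = mismatch, gap = gap),
            class = "identityParams")
}

.substMatrix <- function(match, mismatch) {
  mat <- matrix(mismatch, 21L, 21L,
                dimnames = list(.AA_ALPHABET, .AA_ALPHABET))
  diag(mat) <- match
  # X is an unknown residue: aligning X with X earns no credit
  mat["X", "X"] <- mismatch
  mat
}

.alignPairs <- function(pattern, subjects, params) {
  Biostrings::pairwiseAlignment(
    rep(Biostrings::AAStringSet(pattern), length(subjects)),
    subjects,
    substitutionMatrix = .substMatrix(params$match, params$mismatch),
    gapOpening = 0, gapExtension = -params$gap, type = "global")
}

# Fast screen: pi upper bound = 100 * matches / residue-residue columns
# (>= the span-based pi below), pmatch = residue-residue columns / shorter.
.identityScreen <- function(pattern, subjects, params) {
  al <- .alignPairs(pattern, subjects, params)
  nm <- Biostrings::nmatch(al)
  nmm <- Biostrings::nmismatch(al)
  aligned <- nm + nmm
  shorter <- pmin(nchar(pattern), Biostrings::width(subjects))
  list(pi_ub = ifelse(aligned > 0, 100 * nm / aligned, 0),
       pmatch = 100 * aligned / shorter)
}

# Exact pi/pmatch for one pattern against many subjects.
# pi     = 100 * identical columns / columns of the aligned span (first to
#          last residue-residue column; internal gap columns count in the
#          denominator, terminal overhangs do not)
# pmatch = 100 * residue-residue columns / length of the shorter sequence
# Counting internal gaps in the pi denominator stops unrelated pairs with a
# large length difference from scoring high: a global alignment can scatter
# a short sequence's residues over a long one's mandatory gap columns, which
# would make matches/aligned-columns meaningless as an identity measure.
.identityStats <- function(pattern, subjects, params) {
  al <- .alignPairs(pattern, subjects, params)
  pa <- as.character(Biostrings::alignedPattern(al))
  sa <- as.character(Biostrings::alignedSubject(al))
  gap <- charToRaw("-")
  stats <- vapply(seq_along(pa), function(i) {
    pc <- charToRaw(pa[i]); sc <- charToRaw(sa[i])
    both <- pc != gap & sc != gap
    idx <- which(both)
    if (!length(idx)) return(c(0, 0))
    span <- idx[length(idx)] - idx[1L] + 1L
    c(100 * sum(pc[both] == sc[both]) / span, sum(both))
  }, numeric(2))
  shorter <- pmin(nchar(pattern), Biostrings::width(subjects))
  list(pi = stats[1L, ], pmatch = 100 * stats[2L, ] / shorter)
}

#' Global percent identity and percent match of two proteins
#'
#' Aligns two sequences globally (Needleman-Wunsch, scores from `params`)
#' and reports `pi` = identities / residue-residue columns x 100 and
#' `pmatch` = residue-residue columns / shorter sequence length x 100. Both
#' quantities are symmetric in the two sequences.
#'
#' @param a,b amino-acid strings (or length-1 `AAStringSet`s).
#' @param params an [identityParams()] list (only the scoring fields are
#'   used).
#' @return named numeric vector `c(pi = , pmatch = )`.
#' @examples
#' globalIdentity("MKVLA", "MKVLA")
#' globalIdentity("MKVLA", "MKVLAGGGGG")
#' @export
globalIdentity <- function(a, b, params = identityParams()) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(nzchar(a), nzchar(b))
  st <- .identityStats(a, Biostrings::AAStringSet(b), params)
  c(pi = st$pi[1], pmatch = st$pmatch[1])
}

.flattenProteomes <- function(proteomes) {
  if (is(proteomes, "Proteome")) proteomes <- list(proteomes)
  parts <- lapply(proteomes, function(p) {
    data.frame(species_id = speciesId(p), protein_id = proteinIds(p),
               sequence = as.character(aaSequences(p)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Cluster proteins by pairwise global identity
#'
#' Every pair of proteins with `pi >= piCutoff` and `pmatch >= pmatchCutoff`
#' is linked; clusters are the connected components of the resulting graph
#' (single linkage), so every protein lands in exactly one cluster and
#' unlinked proteins form singletons. Identical sequences are grouped by an
#' exact-duplicate hash before alignment, so only unique sequences are
#' aligned all-vs-all. Intended for desk-scale sets (hundreds of
#' sequences): alignment cost grows quadratically.
#'
#' @param proteomes a [Proteome-class] or list of them.
#' @param params an [identityParams()] list.
#' @return a [ClusterCatalog-class]; cluster ids are `CL` + zero-padded
#'   index, numbered by first-member input order.
#' @export
buildClusters <- function(proteomes, params = identityParams()) {
  recs <- .flattenProteomes(proteomes)
  if (nrow(recs) == 0L) stop("no records to cluster")
  n <- nrow(recs)
  # exact-duplicate shortcut: align unique sequences only
  uidx <- match(recs$sequence, recs$sequence)   # first occurrence index
  reps <- sort(unique(uidx))
  edge_from <- integer(0); edge_to <- integer(0)
  if (length(reps) > 1L) {
    useq <- Biostrings::AAStringSet(recs$sequence[reps])
    for (k in seq_len(length(reps) - 1L)) {
      sub <- useq[(k + 1L):length(reps)]
      scr <- .identityScreen(as.character(useq[[k]]), sub, params)
      cand <- which(scr$pi_ub >= params$piCutoff &
                    scr$pmatch >= params$pmatchCutoff)
      if (length(cand)) {
        st <- .identityStats(as.character(useq[[k]]), sub[cand], params)
        hit <- cand[st$pi >= params$piCutoff &
                    st$pmatch >= params$pmatchCutoff]
        if (length(hit)) {
          edge_from <- c(edge_from, rep(reps[k], length(hit)))
          edge_to <- c(edge_to, reps[k + hit])
        }
      }
    }
  }
  # duplicates link to their first occurrence
  dup <- which(uidx != seq_len(n))
  ev <- c(rbind(edge_from, edge_to))
  if (length(dup)) ev <- c(ev, c(rbind(uidx[dup], dup)))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ev)) g <- igraph::add_edges(g, ev)
  comp <- igraph::components(g)$membership
  # renumber by first appearance
  first <- match(unique(comp), comp)
  rank <- order(first)
  relabel <- match(comp, unique(comp)[rank])
  width <- max(6L, nchar(as.character(max(relabel))))
  new("ClusterCatalog",
      assignments = data.frame(
        cluster_id = sprintf(paste0("CL%0", width, "d"), relabel),
        species_id = recs$species_id,
        protein_id = recs$protein_id,
        stringsAsFactors = FALSE))
}

#' @rdname clusterTable
#' @aliases clusterTable,ClusterCatalog-method
setMethod("clusterTable", "ClusterCatalog", function(x) x@assignments)

#' Cluster membership table
#'
#' `clusterTable()` returns the assignment data.frame (`cluster_id`,
#' `species_id`, `protein_id`); `readClusterTable()` and
#' `writeClusterTable()` exchange it as TSV, so externally computed cluster
#' assignments (e.g. OrthoMCL groups) can be used wherever a
#' [ClusterCatalog-class] is accepted.
#'
#' @param x a `ClusterCatalog`.
#' @param path TSV path with columns `cluster_id`, `species_id`,
#'   `protein_id`.
#' @param catalog a `ClusterCatalog` to serialize.
#' @return `clusterTable`/`readClusterTable`: data.frame / `ClusterCatalog`;
#'   `writeClusterTable`: `path` invisibly.
#' @name clusterTable
#' @export readClusterTable writeClusterTable
readClusterTable <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, colClasses = "character")
  new("ClusterCatalog", assignments = d[c("cluster_id", "species_id",
                                          "protein_id")])
}

writeClusterTable <- function(catalog, path) {
  utils::write.table(clusterTable(catalog), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

setMethod("show", "ClusterCatalog", function(object) {
  a <- object@assignments
  cat("ClusterCatalog:", length(unique(a$cluster_id)), "clusters,",
      nrow(a), "members,", length(unique(a$species_id)), "species\n")
})

#' Select one representative protein per cluster
#'
#' The representative is the longest member; ties break to the
#' lexicographically smallest `protein_id` (then `species_id`).
#'
#' @param catalog a [ClusterCatalog-class].
#' @param proteomes the [Proteome-class] (or list) the catalog was built
#'   from; supplies sequence lengths.
#' @return data.frame `cluster_id`, `species_id`, `protein_id`, `length`,
#'   one row per cluster, in cluster-id order.
#' @export
selectRepresentatives <- function(catalog, proteomes) {
  recs <- .flattenProteomes(proteomes)
  a <- clusterTable(catalog)
  key <- paste(a$species_id, a$protein_id, sep = "\r")
  rkey <- paste(recs$species_id, recs$protein_id, sep = "\r")
  idx <- match(key, rkey)
  if (anyNA(idx))
    stop("catalog references proteins absent from the supplied proteomes")
  a$length <- nchar(recs$sequence[idx])
  a <- a[order(a$cluster_id, -a$length, a$protein_id, a$species_id), ,
         drop = FALSE]
  out <- a[!duplicated(a$cluster_id), c("cluster_id", "species_id",
                                        "protein_id", "length")]
  rownames(out) <- NULL
  out
}

#' Redundancy content of a proteome
#'
#' Fraction of sequences removed by redundancy filtering:
#' `(nBefore - nAfter) / nBefore`.
#'
#' @param nBefore record count before filtering (> 0).
#' @param nAfter record count after filtering.
#' @return numeric fraction in \\[0, 1\\].
#' @export
redundancyContent <- function(nBefore, nAfter) {
  if (any(nBefore <= 0)) stop("nBefore must be positive")
  if (any(nAfter < 0 | nAfter > nBefore))
    stop("nAfter must satisfy 0 <= nAfter <= nBefore")
  (nBefore - nAfter) / nBefore
}

#' Classify clusters as species-specific, common or intermediate
#'
#' A cluster whose members come from exactly one species (including
#' singletons) is `specific`; a cluster covering every species of the panel
#' is `common`; anything else is `intermediate` (excluded from the
#' specific/common contrast).
#'
#' @param catalog a [ClusterCatalog-class].
#' @param panel character vector of all species ids in the study.
#' @return data.frame `cluster_id`, `n_members`, `n_species`, `category`.
#' @export
classifyClusters <- function(catalog, panel) {
  a <- clusterTable(catalog)
  extra <- setdiff(unique(a$species_id), panel)
  if (length(extra))
    stop("catalog contains species outside the panel: ",
         paste(extra, collapse = ", "))
  n_members <- tapply(a$protein_id, a$cluster_id, length)
  n_species <- tapply(a$species_id, a$cluster_id,
                      function(s) length(unique(s)))
  category <- ifelse(n_species == 1L, "specific",
                     ifelse(n_species == length(unique(panel)), "common",
                            "intermediate"))
  data.frame(cluster_id = names(n_members),
             n_members = as.integer(n_members),
             n_species = as.integer(n_species),
             category = as.character(category),
             row.names = NULL, stringsAsFactors = FALSE)
}

.exhaustivePermP <- function(x, y) {
  # exact permutation p for mean(x) - mean(y), direction x > y
  pool <- c(x, y)
  idx <- utils::combn(length(pool), length(x))
  obs <- mean(x) - mean(y)
  stats <- apply(idx, 2L, function(i)
    mean(pool[i]) - mean(pool[-i]))
  mean(stats >= obs - 1e-12)
}

#' Contrast a per-protein metric between specific and common clusters
#'
#' Computes the category means, their specific/common ratio, and a
#' one-tailed p value for the alternative "specific > common". The default
#' test is Welch's unequal-variance two-sample t; `method = "permutation"`
#' uses the exact permutation distribution of the mean difference when the
#' number of arrangements is small (<= `maxExact`) and Monte Carlo sampling
#' otherwise.
#'
#' @param values numeric per-protein metric (e.g. disorder content or a
#'   per-400-residue site density).
#' @param categories character/factor parallel to `values` with levels
#'   `"specific"` and `"common"` (other labels are ignored).
#' @param method `"welch"` (default) or `"permutation"`.
#' @param nPerm Monte Carlo permutation count when exact enumeration is
#'   infeasible; default 10000.
#' @param maxExact largest number of arrangements enumerated exactly.
#' @return list with `mean_specific`, `mean_common`, `ratio_s_over_c`,
#'   `p_one_tailed`, `n_specific`, `n_common`, `method`.
#' @export
categoryContrast <- function(values, categories,
                             method = c("welch", "permutation"),
                             nPerm = 10000L, maxExact = 250000L) {
  method <- match.arg(method)
  xs <- values[categories == "specific"]
  xc <- values[categories == "common"]
  if (!length(xs) || !length(xc))
    stop("both 'specific' and 'common' categories must be non-empty")
  ms <- mean(xs); mc <- mean(xc)
  ratio <- if (mc == 0) {
    warning("mean_common is zero; ratio undefined", call. = FALSE)
    NA_real_
  } else ms / mc
  p <- if (method == "welch") {
    if (stats::sd(c(xs, xc)) == 0) 0.5
    else stats::t.test(xs, xc, alternative = "greater")$p.value
  } else {
    if (choose(length(xs) + length(xc), length(xs)) <= maxExact) {
      .exhaustivePermP(xs, xc)
    } else {
      pool <- c(xs, xc); obs <- ms - mc
      stats_mc <- replicate(nPerm, {
        i <- sample.int(length(pool), length(xs))
        mean(pool[i]) - mean(pool[-i])
      })
      (1 + sum(stats_mc >= obs - 1e-12)) / (nPerm + 1)
    }
  }
  list(mean_specific = ms, mean_common = mc, ratio_s_over_c = ratio,
       p_one_tailed = p, n_specific = length(xs), n_common = length(xc),
       method = method)
}
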