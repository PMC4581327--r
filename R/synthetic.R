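#' @include AllClasses.R annotations.R scanners.R
NULL

# Disorder-promoting residues dominate disordered segments; order-promoting
# residues dominate ordered segments. Sampling keeps all 20 letters present
# in both regions so every site type has legal residues everywhere.
.DIS_PROMOTING <- c("A", "R", "G", "Q", "S", "E", "K", "P")
.ORD_PROMOTING <- c("I", "L", "V", "C", "W", "Y", "F", "N")
.AA20 <- setdiff(.AA_ALPHABET, "X")

.regionWeights <- function(promoted) {
  w <- stats::setNames(rep(1, 20L), .AA20)
  w[promoted] <- 3
  w / sum(w)
}
.DIS_W <- .regionWeights(.DIS_PROMOTING)
.ORD_W <- .regionWeights(.ORD_PROMOTING)
.HYDROPHOBIC <- c("L", "L", "A", "V", "I", "F", "M", "W")

# Deterministic per-unit stream splitting: a small integer mix of the root
# seed and unit indices seeds each generation unit independently, so adding
# units never perturbs existing ones.
.mixSeed <- function(...) {
  v <- as.numeric(c(...))
  s <- 0
  for (x in v) s <- (s * 65599 + x + 1) %% 2147483647
  as.integer(s) + 1L
}

#' Configuration for the synthetic proteome generator
#'
#' Defaults describe a desk-scale multi-species study: 4 species x 500
#' proteins, log-normal lengths (median 350 residues) truncated to
#' \[50, 4000\], per-protein disorder fractions Beta(2, 5) (proteome mean
#' around 0.29) realized as contiguous segments, and PTM sites planted with
#' disordered/ordered density ratios taken from proteome-scale estimates
#' (S-phosphorylation 18.8, T 10.5, Y 1.3, ubiquitination 12.5).
#'
#' @param nSpecies number of species; default 4.
#' @param nProteinsPerSpecies proteins per species before duplicates;
#'   default 500.
#' @param lengthLaw list `min`, `max`, `meanlog`, `sdlog` of the truncated
#'   log-normal length distribution.
#' @param disorderLaw list `shape1`, `shape2` (Beta parameters of the
#'   per-protein disorder fraction) and `segmentMean` (mean disordered
#'   segment length, residues).
#' @param enrichment named list per site type with `rho` (planted
#'   disordered/ordered per-residue site-density ratio) and `base` (ordered
#'   region density, sites per 400 residues).
#' @param siteCountDisorderSlope when > 0, site counts are drawn first and
#'   each protein's disorder fraction is tilted by `slope * total sites`
#'   (plus Gaussian noise, sd 0.05), planting a linear disorder-vs-count
#'   relation for bin-correlation tests; `rho` is ignored in this mode.
#' @param secretory list `signalFraction` (fraction of proteins with a
#'   planted signal peptide, first 15-30 residues) and `tmLambda` (Poisson
#'   mean of TM helix count; helices are 19-23 hydrophobic residues placed
#'   in ordered regions only).
#' @param families list `commonFraction` (families with one member in every
#'   species), `specificFraction` (single-species families; the remainder
#'   becomes two-species intermediate families), `specificDisorderMult` and
#'   `specificPtmMult` (multipliers applied to specific families' disorder
#'   target and site rates), `divergence` (per-residue mutation rate between
#'   a family prototype and its members).
#' @param redundancy list `fraction` (near-duplicate records added per
#'   species, as a fraction of members) and `mutationRate` (per-residue
#'   point-mutation rate of a duplicate).
#' @param ubiquitinationDecoyRate decoy ubiquitination sites (scores outside
#'   the 0.69-0.84 band) per 400 residues, exercising the confidence filter.
#' @param seed mandatory integer root seed.
#' @return a list of class `synthConfig`.
#' @export
synthConfig <- function(nSpecies = 4L,
                        nProteinsPerSpecies = 500L,
                        lengthLaw = list(min = 50L, max = 4000L,
                                         meanlog = log(350), sdlog = 0.7),
                        disorderLaw = list(shape1 = 2, shape2 = 5,
                                           segmentMean = 30),
                        enrichment = list(
                          phospho_S = list(rho = 18.8, base = 0.5),
                          phospho_T = list(rho = 10.5, base = 0.2),
                          phospho_Y = list(rho = 1.3, base = 0.3),
                          ubiquitination = list(rho = 12.5, base = 0.25)),
                        siteCountDisorderSlope = 0,
                        secretory = list(signalFraction = 0.25,
                                         tmLambda = 0.5),
                        families = list(commonFraction = 0.3,
                                        specificFraction = 0.6,
                                        specificDisorderMult = 1.7,
                                        specificPtmMult = 2.0,
                                        divergence = 0.15),
                        redundancy = list(fraction = 0.10,
                                          mutationRate = 0.02),
                        ubiquitinationDecoyRate = 0.3,
                        seed) {
  if (missing(seed)) stop("a root seed is mandatory")
  fr <- c(secretory$signalFraction, families$commonFraction,
          families$specificFraction, redundancy$fraction,
          families$divergence, redundancy$mutationRate)
  stopifnot(all(fr >= 0 & fr <= 1),
            families$commonFraction + families$specificFraction <= 1,
            nSpecies >= 1, nProteinsPerSpecies >= 1)
  for (ty in names(enrichment)) {
    e <- enrichment[[ty]]
    if (!is.finite(e$rho) || e$rho < 0)
      stop("rho for ", ty, " must be finite and >= 0")
    mult <- max(1, families$specificPtmMult)
    legal <- .SITE_RESIDUE[[ty]]
    q_dis <- e$rho * e$base * mult / (400 * .DIS_W[[legal]])
    q_ord <- e$base * mult / (400 * .ORD_W[[legal]])
    if (max(q_dis, q_ord) > 0.9)
      stop("infeasible enrichment for ", ty, ": rho * base = ",
           e$rho * e$base, " (x", mult, " in specific families) implies a ",
           "per-legal-residue site probability of ",
           round(max(q_dis, q_ord), 2), " at the generator's composition")
  }
  structure(list(nSpecies = as.integer(nSpecies),
                 nProteinsPerSpecies = as.integer(nProteinsPerSpecies),
                 lengthLaw = lengthLaw, disorderLaw = disorderLaw,
                 enrichment = enrichment,
                 siteCountDisorderSlope = siteCountDisorderSlope,
                 secretory = secretory, families = families,
                 redundancy = redundancy,
                 ubiquitinationDecoyRate = ubiquitinationDecoyRate,
                 seed = as.integer(seed)),
            class = "synthConfig")
}

#' Plant a contiguous-segment disorder mask
#'
#' Builds a 0/1 mask of the given length whose disordered fraction equals
#' `round(targetFraction * length) / length` (exact to one residue), with
#' the disordered residues arranged as contiguous segments of mean length
#' close to `segmentMean`, separated by at least one ordered residue. Uses
#' the current RNG state; call `set.seed()` first for reproducibility.
#'
#' @param length protein length (residues).
#' @param targetFraction disorder fraction in \[0, 1\].
#' @param segmentMean mean disordered-segment length; default 30.
#' @return integer 0/1 vector of `length`.
#' @export
plantDisorderMask <- function(length, targetFraction, segmentMean = 30) {
  stopifnot(targetFraction >= 0, targetFraction <= 1, length >= 1)
  L <- as.integer(length)
  nd <- round(targetFraction * L)
  if (nd == 0L) return(integer(L))
  if (nd == L) return(rep(1L, L))
  k <- max(1L, round(nd / segmentMean))
  k <- min(k, nd, L - nd + 1L)
  seg <- if (k == 1L) nd else {
    cuts <- sort(sample.int(nd - 1L, k - 1L))
    diff(c(0L, cuts, nd))
  }
  no <- L - nd
  # k + 1 ordered gaps; interior gaps >= 1 so segments stay separate
  extra <- no - (k - 1L)
  gap_extra <- as.vector(stats::rmultinom(1L, extra, rep(1, k + 1L)))
  gaps <- gap_extra + c(0L, rep(1L, max(0L, k - 1L)), 0L)
  mask <- integer(0)
  for (i in seq_len(k)) mask <- c(mask, integer(gaps[i]), rep(1L, seg[i]))
  c(mask, integer(gaps[k + 1L]))
}

#' Plant PTM sites at controlled disordered/ordered densities
#'
#' Sites are drawn independently per legal residue (the residue the site
#' type requires: S, T, Y or K). Probabilities are scaled so the expected
#' per-residue density is `base / 400` in ordered regions and
#' `rho * base / 400` in disordered regions, which makes the planted Rd/o
#' equal `rho` in expectation regardless of composition. Probabilities are
#' capped at 1. Uses the current RNG state.
#'
#' @param mask integer 0/1 disorder mask.
#' @param sequence amino-acid string of the same length.
#' @param siteType one of `"phospho_S"`, `"phospho_T"`, `"phospho_Y"`,
#'   `"ubiquitination"`.
#' @param base ordered-region density, sites per 400 residues.
#' @param rho disordered/ordered density ratio, >= 0.
#' @return sorted integer vector of planted site positions.
#' @export
plantSites <- function(mask, sequence, siteType, base, rho) {
  legal <- .SITE_RESIDUE[[siteType]]
  chars <- strsplit(sequence, "")[[1]]
  stopifnot(length(chars) == length(mask))
  pos <- which(chars == legal)
  if (!length(pos) || base <= 0) return(integer(0))
  dis <- mask[pos] == 1L
  Ld <- sum(mask); Lo <- length(mask) - Ld
  q <- numeric(length(pos))
  nd <- sum(dis); no <- sum(!dis)
  if (nd) q[dis] <- min(1, rho * base * Ld / (400 * nd))
  if (no) q[!dis] <- min(1, base * Lo / (400 * no))
  sort(pos[stats::runif(length(pos)) < q])
}

.sampleLength <- function(law) {
  repeat {
    L <- round(stats::rlnorm(1, law$meanlog, law$sdlog))
    if (L >= law$min && L <= law$max) return(as.integer(L))
  }
}

.composeSequence <- function(mask) {
  chars <- character(length(mask))
  nd <- sum(mask == 1L)
  if (nd) chars[mask == 1L] <- sample(.AA20, nd, replace = TRUE,
                                      prob = .DIS_W)
  if (length(mask) - nd)
    chars[mask == 0L] <- sample(.AA20, length(mask) - nd, replace = TRUE,
                                prob = .ORD_W)
  chars
}

.mutate <- function(chars, mask, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    dis <- mask[hit] == 1L
    if (any(dis)) chars[hit[dis]] <- sample(.AA20, sum(dis), replace = TRUE,
                                            prob = .DIS_W)
    if (any(!dis)) chars[hit[!dis]] <- sample(.AA20, sum(!dis),
                                              replace = TRUE, prob = .ORD_W)
  }
  chars
}

# Family layout: which species each family spans, and its category.
.familyLayout <- function(config) {
  nS <- config$nSpecies
  nP <- config$nProteinsPerSpecies
  nCommon <- round(config$families$commonFraction * nP)
  nSpecific <- round(config$families$specificFraction * nP)
  nInterRounds <- if (nS >= 2) (nP - nCommon - nSpecific) %/% 2L else 0L
  nSpecific <- nP - nCommon - 2L * nInterRounds     # leftover goes specific
  fams <- list()
  add <- function(span, category)
    fams[[length(fams) + 1L]] <<- list(span = span, category = category)
  for (i in seq_len(nCommon)) add(seq_len(nS), "common")
  for (s in seq_len(nS)) for (i in seq_len(nSpecific)) add(s, "specific")
  # two-species intermediate families, round-robin partners
  for (j in seq_len(nInterRounds)) for (s in seq_len(nS))
    add(c(s, s %% nS + 1L), "intermediate")
  fams
}

.plantSecretory <- function(chars, mask, secretory) {
  L <- length(chars)
  segs <- data.frame(segment_type = character(), start = integer(),
                     end = integer(), stringsAsFactors = FALSE)
  if (stats::runif(1) < secretory$signalFraction && L >= 40L) {
    k <- sample(15:30, 1L)
    chars[1:k] <- sample(.HYDROPHOBIC, k, replace = TRUE)
    chars[1] <- "M"
    mask[1:k] <- 0L
    segs <- rbind(segs, data.frame(segment_type = "signal_peptide",
                                   start = 1L, end = k))
  }
  nTm <- stats::rpois(1, secretory$tmLambda)
  if (nTm > 0L) {
    occupied <- if (nrow(segs)) segs$end[1] else 0L
    r <- rle(mask == 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= 25L & starts > occupied)
    runs <- runs[sample.int(length(runs))]
    for (ri in utils::head(runs, nTm)) {
      len <- sample(19:23, 1L)
      s0 <- starts[ri] + sample.int(ends[ri] - starts[ri] - len + 1L, 1L)
      chars[s0:(s0 + len - 1L)] <- sample(.HYDROPHOBIC, len, replace = TRUE)
      segs <- rbind(segs, data.frame(segment_type = "tm_helix",
                                     start = s0, end = s0 + len - 1L))
    }
  }
  list(chars = chars, mask = mask, segs = segs)
}

.outOfBandScore <- function(n) {
  u <- stats::runif(n)
  ifelse(u < 0.5, stats::runif(n, 0.20, 0.68), stats::runif(n, 0.85, 0.99))
}

#' Generate a synthetic multi-species annotated proteome set
#'
#' Produces, deterministically from the config seed, a set of species-tagged
#' proteomes with planted ground truth: contiguous disorder masks whose
#' composition favors disorder-promoting residues, PTM sites planted at
#' controlled disordered/ordered density ratios (with out-of-band decoy
#' ubiquitination scores exercising the confidence filter), signal peptides
#' and TM helices, protein families shared by all species or private to one
#' (with configurable disorder/PTM multipliers for the private ones), and
#' near-duplicate records for redundancy-clustering tests.
#'
#' @param config a [synthConfig()].
#' @return list of class `synthProteomeSet` with elements `proteomes`
#'   (named list of [AnnotatedProteome-class]), `truthProteins`
#'   (data.frame: `species_id`, `protein_id`, `family_id`, `category`,
#'   `duplicate_of`, `length`, `disorder_fraction`), `truthSites`
#'   (data.frame of planted sites: `species_id`, `protein_id`, `site_type`,
#'   `position`) and `config`.
#' @export
generateProteomes <- function(config) {
  stopifnot(inherits(config, "synthConfig"))
  nS <- config$nSpecies
  sp_ids <- sprintf("sp%02d", seq_len(nS))
  groups <- rep(c("green_algae", "oomycetes", "diatom", "yellow_algae",
                  "red_algae"), length.out = nS)
  fams <- .familyLayout(config)
  slope <- config$siteCountDisorderSlope
  fcfg <- config$families

  per_species <- lapply(sp_ids, function(s)
    list(seqs = character(0), masks = list(), sites = list(),
         segs = list(), truth = list(), truth_sites = list()))
  names(per_species) <- sp_ids

  for (f in seq_along(fams)) {
    fam <- fams[[f]]
    specific <- fam$category == "specific"
    set.seed(.mixSeed(config$seed, 104729, f))
    L <- .sampleLength(config$lengthLaw)
    f0 <- stats::rbeta(1, config$disorderLaw$shape1,
                       config$disorderLaw$shape2)
    if (specific) f0 <- min(0.95, f0 * fcfg$specificDisorderMult)
    proto_mask <- plantDisorderMask(L, f0, config$disorderLaw$segmentMean)
    proto_chars <- .composeSequence(proto_mask)
    sec <- .plantSecretory(proto_chars, proto_mask, config$secretory)
    proto_chars <- sec$chars; proto_mask <- sec$mask

    for (s in fam$span) {
      set.seed(.mixSeed(config$seed, f, s))
      divergence <- if (length(fam$span) > 1L) fcfg$divergence else 0
      chars <- .mutate(proto_chars, proto_mask, divergence)
      mask <- proto_mask
      pid <- sprintf("%s_f%05d", sp_ids[s], f)
      member <- .plantMemberSites(chars, mask, config, specific, slope, f0)
      per_species[[sp_ids[s]]] <- .appendMember(
        per_species[[sp_ids[s]]], pid, chars, member$mask, member, sec$segs,
        category = fam$category, family_id = sprintf("fam%05d", f),
        sp = sp_ids[s], duplicate_of = NA_character_)
    }
  }

  # near-duplicate records
  if (config$redundancy$fraction > 0) {
    for (s in seq_len(nS)) {
      sp <- sp_ids[s]
      env <- per_species[[sp]]
      nMem <- length(env$seqs)
      nDup <- round(config$redundancy$fraction * nMem)
      if (nDup < 1L) next
      set.seed(.mixSeed(config$seed, 15485863, s))
      pick <- sample.int(nMem, nDup)
      for (i in pick) {
        pid0 <- names(env$seqs)[i]
        chars <- strsplit(env$seqs[[i]], "")[[1]]
        mask <- env$masks[[pid0]]
        set.seed(.mixSeed(config$seed, 15485863, s, i))
        chars <- .mutate(chars, mask, config$redundancy$mutationRate)
        pid <- paste0(pid0, "d")
        tr <- env$truth[[pid0]]
        member <- .plantMemberSites(chars, mask, config,
                                    tr$category == "specific", slope,
                                    tr$disorder_fraction)
        segs <- env$segs[[pid0]]
        env <- .appendMember(env, pid, chars, member$mask, member,
                             if (is.null(segs)) NULL else
                               segs[c("segment_type", "start", "end")],
                             category = tr$category,
                             family_id = tr$family_id, sp = sp,
                             duplicate_of = pid0)
      }
      per_species[[sp]] <- env
    }
  }

  proteomes <- list()
  truthP <- list(); truthS <- list()
  for (s in seq_len(nS)) {
    sp <- sp_ids[s]
    env <- per_species[[sp]]
    prot <- Proteome(unlist(env$seqs), speciesId = sp, group = groups[s])
    sites <- do.call(rbind, env$sites)
    segs <- do.call(rbind, env$segs)
    proteomes[[sp]] <- annotateProteome(prot, env$masks, sites, segs)
    truthP[[sp]] <- do.call(rbind, lapply(env$truth, as.data.frame))
    truthS[[sp]] <- do.call(rbind, env$truth_sites)
  }
  structure(list(proteomes = proteomes,
                 truthProteins = {
                   d <- do.call(rbind, truthP); rownames(d) <- NULL; d
                 },
                 truthSites = {
                   d <- do.call(rbind, truthS)
                   if (is.null(d)) d else { rownames(d) <- NULL; d }
                 },
                 config = config),
            class = "synthProteomeSet")
}

# Plant sites for one member; in slope mode the member's disorder mask is
# re-planted from a count-tilted fraction first. Returns list(mask, sites,
# truth_sites, realized_fraction).
.plantMemberSites <- function(chars, mask, config, specific, slope, f0) {
  seqstr <- paste(chars, collapse = "")
  mult <- if (specific) config$families$specificPtmMult else 1
  enr <- config$enrichment
  if (slope > 0) {
    lam <- vapply(enr, function(e) e$base * mult * length(chars) / 400,
                  numeric(1))
    counts <- stats::rpois(length(lam), lam)
    names(counts) <- names(enr)
    f <- min(0.98, max(0.02, 0.15 + slope * sum(counts) +
                         stats::rnorm(1, 0, 0.05)))
    mask <- plantDisorderMask(length(chars), f,
                              config$disorderLaw$segmentMean)
    placed <- lapply(names(enr), function(ty) {
      legal <- which(chars == .SITE_RESIDUE[[ty]])
      if (!length(legal) || counts[[ty]] == 0L) return(integer(0))
      k <- min(counts[[ty]], length(legal))
      sort(legal[sample.int(length(legal), k)])
    })
  } else {
    placed <- lapply(names(enr), function(ty)
      plantSites(mask, seqstr, ty, enr[[ty]]$base * mult, enr[[ty]]$rho))
  }
  names(placed) <- names(enr)
  rows <- lapply(names(enr), function(ty) {
    pos <- placed[[ty]]
    if (!length(pos)) return(NULL)
    score <- if (ty == "ubiquitination")
      stats::runif(length(pos), 0.69, 0.84)
    else stats::runif(length(pos), 0.5, 1)
    data.frame(site_type = ty, position = pos, score = round(score, 4))
  })
  sites <- do.call(rbind, rows)
  truth <- if (is.null(sites)) NULL else sites[c("site_type", "position")]
  # decoy ubiquitination sites with out-of-band scores
  if (config$ubiquitinationDecoyRate > 0) {
    kpos <- setdiff(which(chars == "K"), placed[["ubiquitination"]])
    if (length(kpos)) {
      q <- min(1, config$ubiquitinationDecoyRate * length(chars) /
                 (400 * length(kpos)))
      dec <- kpos[stats::runif(length(kpos)) < q]
      if (length(dec))
        sites <- rbind(sites,
                       data.frame(site_type = "ubiquitination",
                                  position = sort(dec),
                                  score = round(.outOfBandScore(length(dec)),
                                                4)))
    }
  }
  list(mask = mask, sites = sites, truth_sites = truth,
       realized_fraction = sum(mask) / length(mask))
}

.appendMember <- function(env, pid, chars, mask, member, segs, category,
                          family_id, sp, duplicate_of) {
  env$seqs[[pid]] <- paste(chars, collapse = "")
  env$masks[[pid]] <- mask
  if (!is.null(member$sites) && nrow(member$sites)) {
    st <- member$sites
    st <- data.frame(protein_id = pid, st, stringsAsFactors = FALSE)
    env$sites[[pid]] <- st[order(st$position), ]
  }
  if (!is.null(segs) && nrow(segs))
    env$segs[[pid]] <- data.frame(protein_id = pid,
                                  segs[c("segment_type", "start", "end")],
                                  stringsAsFactors = FALSE)
  env$truth[[pid]] <- list(species_id = sp, protein_id = pid,
                           family_id = family_id,
                           category = category,
                           duplicate_of = duplicate_of,
                           length = length(chars),
                           disorder_fraction = member$realized_fraction)
  if (!is.null(member$truth_sites) && nrow(member$truth_sites))
    env$truth_sites[[pid]] <- data.frame(species_id = sp, protein_id = pid,
                                         member$truth_sites,
                                         stringsAsFactors = FALSE)
  env
}

#' Write a synthetic proteome set to disk
#'
#' Emits exactly the formats the pipeline consumes: per species a FASTA
#' (`<sp>.fasta`), a site table (`<sp>_sites.tsv`), a segment table
#' (`<sp>_segments.tsv`) and a disorder-mask table (`<sp>_masks.tsv`), plus
#' the ground-truth tables `truth_proteins.tsv` and `truth_sites.tsv`.
#' Output is byte-identical across runs of the same config.
#'
#' @param set a `synthProteomeSet` from [generateProteomes()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticSet <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(set$proteomes)) {
    ap <- set$proteomes[[sp]]
    writeProteomeFasta(ap, file.path(dir, paste0(sp, ".fasta")))
    writeSiteTable(siteTable(ap), file.path(dir, paste0(sp, "_sites.tsv")))
    writeSegmentTable(segmentTable(ap),
                      file.path(dir, paste0(sp, "_segments.tsv")))
    writeDisorderMasks(disorderMasks(ap),
                       file.path(dir, paste0(sp, "_masks.tsv")))
  }
  utils::write.table(set$truthProteins, file.path(dir, "truth_proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(set$truthSites))
    utils::write.table(set$truthSites, file.path(dir, "truth_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
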