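#' @include AllClasses.R
NULL

.OGLY_FLANK <- c("A", "S", "T", "V")

.emptyMatches <- function() {
  data.frame(protein_id = character(), kind = character(),
             start = integer(), end = integer(), anchor = integer(),
             score = numeric(), stringsAsFactors = FALSE)
}

.matchFrame <- function(proteinId, kind, start, end, anchor, score = NA_real_) {
  if (!length(start)) return(.emptyMatches())
  data.frame(protein_id = proteinId, kind = kind,
             start = as.integer(start), end = as.integer(end),
             anchor = as.integer(anchor),
             score = rep_len(score, length(start)),
             stringsAsFactors = FALSE)
}

#' Scan for the plant hydroxyproline O-glycosylation consensus
#'
#' Finds occurrences of the consensus motif
#' `[A/S/T/V]-P(1,4)-X(0,10)-[A/S/T/V]-P(1,4)`:
#' a flanking residue from \{A, S, T, V\}, one to four prolines, a
#' spacer of zero to ten arbitrary residues, a second flanking residue and a
#' second proline run. Each occurrence counts as one site; the anchor is the
#' first proline. The ambiguity code `X` never matches the literal classes
#' but may fill the spacer.
#'
#' The canonical scan (`overlap = "none"`, `extent = "shortest"`) walks left
#' to right emitting non-overlapping matches, each with the smallest extent
#' compatible with the motif (proline runs are consumed within the run, the
#' spacer takes the fewest residues that let the remainder match). That
#' maximizes the number of non-overlapping occurrences. `extent = "longest"`
#' instead takes element-wise greedy repetition; `overlap = "all"` reports a
#' match at every start offset where the motif can match.
#'
#' @param sequence amino-acid string.
#' @param proteinId id stamped into the result; default `NA`.
#' @param overlap `"none"` (default, left-to-right non-overlapping) or
#'   `"all"`.
#' @param extent `"shortest"` (default) or `"longest"` per-match extent.
#' @return data.frame `protein_id`, `kind` (`"ogly"`), `start`, `end`,
#'   `anchor`, `score` (`NA`), in ascending start order.
#' @examples
#' scanOgly("APAP")       # one site, 1..4
#' scanOgly("APAPAPAP")   # two non-overlapping sites
#' @export
scanOgly <- function(sequence, proteinId = NA_character_,
                     overlap = c("none", "all"),
                     extent = c("shortest", "longest")) {
  overlap <- match.arg(overlap)
  extent <- match.arg(extent)
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  isF <- chars %in% .OGLY_FLANK
  isP <- chars == "P"
  # run of prolines starting at each position (0 when not P)
  prun <- integer(L)
  if (L) for (i in L:1) prun[i] <- if (isP[i]) 1L +
    (if (i < L) prun[i + 1L] else 0L) else 0L

  # find the canonical match starting exactly at i, or NULL
  match_at <- function(i) {
    if (!isF[i] || i + 1L > L || !isP[i + 1L]) return(NULL)
    k1max <- min(4L, prun[i + 1L])
    found <- NULL
    if (extent == "shortest") {
      for (s in 1L:(4L + 10L)) {          # s = k1 + spacer length
        hi <- min(4L, k1max, s); lo <- max(1L, s - 10L)
        if (hi < lo) next
        for (k1 in hi:lo) {               # prefer longer proline run
          x <- s - k1
          j <- i + k1 + x + 1L            # position of second flank
          if (j + 1L > L) next
          if (isF[j] && isP[j + 1L]) { found <- c(k1, x, 1L); break }
        }
        if (!is.null(found)) break
      }
    } else {
      for (k1 in seq(k1max, 1L)) {
        for (x in seq(10L, 0L)) {
          j <- i + k1 + x + 1L
          if (j + 1L > L) next
          if (isF[j] && isP[j + 1L]) {
            found <- c(k1, x, min(4L, prun[j + 1L]))
            break
          }
        }
        if (!is.null(found)) break
      }
    }
    if (is.null(found)) return(NULL)
    k1 <- found[1]; x <- found[2]; k2 <- found[3]
    c(start = i, end = i + k1 + x + 1L + k2, anchor = i + 1L)
  }

  starts <- integer(0); ends <- integer(0); anchors <- integer(0)
  i <- 1L
  while (i + 3L <= L) {                   # minimal motif length is 4
    m <- match_at(i)
    if (!is.null(m)) {
      starts <- c(starts, m[["start"]]); ends <- c(ends, m[["end"]])
      anchors <- c(anchors, m[["anchor"]])
      i <- if (overlap == "none") as.integer(m[["end"]]) + 1L else i + 1L
    } else i <- i + 1L
  }
  .matchFrame(proteinId, "ogly", starts, ends, anchors)
}

#' Scan for N-glycosylation sequons (N-X-S/T, X != P)
#'
#' Reports every position `i` with `N` at `i`, anything but proline at
#' `i + 1`, and `S` or `T` at `i + 2`. Overlapping sequons are all reported;
#' the anchor is the asparagine. `X` qualifies as the middle residue (it is
#' not proline) but never as the `N` or `S/T` literals.
#'
#' @inheritParams scanOgly
#' @return data.frame as in [scanOgly()] with `kind = "ngly_sequon"`,
#'   `end = anchor + 2`.
#' @examples
#' scanNglySequons("ANKSA")  # one sequon at 2
#' scanNglySequons("ANPSA")  # none: proline at X position
#' @export
scanNglySequons <- function(sequence, proteinId = NA_character_) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L < 3L) return(.emptyMatches())
  i <- seq_len(L - 2L)
  hit <- i[chars[i] == "N" & chars[i + 1L] != "P" &
           chars[i + 2L] %in% c("S", "T")]
  .matchFrame(proteinId, "ngly_sequon", hit, hit + 2L, hit)
}

#' Secretory context of a protein
#'
#' Holds the externally predicted signal-peptide call and transmembrane
#' helix intervals used to gate N-glycosylation sequons.
#'
#' @param hasSignalPeptide logical; signal peptide predicted.
#' @param tmSegments data.frame (or 2-column matrix) of 1-based inclusive
#'   `start`, `end` TM helix intervals; must be non-overlapping.
#' @param signalEnd last residue of the signal peptide when present;
#'   default 20.
#' @return list of class `secretoryContext`.
#' @export
secretoryContext <- function(hasSignalPeptide = FALSE,
                             tmSegments = NULL, signalEnd = 20L) {
  if (is.null(tmSegments))
    tmSegments <- data.frame(start = integer(), end = integer())
  tmSegments <- as.data.frame(tmSegments)
  names(tmSegments)[1:2] <- c("start", "end")
  if (nrow(tmSegments)) {
    tmSegments <- tmSegments[order(tmSegments$start), , drop = FALSE]
    stopifnot(all(tmSegments$start <= tmSegments$end))
    if (nrow(tmSegments) > 1L &&
        any(tmSegments$start[-1L] <= tmSegments$end[-nrow(tmSegments)]))
      stop("TM segments must be non-overlapping")
  }
  structure(list(hasSignalPeptide = isTRUE(hasSignalPeptide),
                 tmSegments = tmSegments,
                 signalEnd = as.integer(signalEnd)),
            class = "secretoryContext")
}

#' Gate N-glycosylation sequons by secretory context
#'
#' A sequon is counted as an N-glycosylation site iff the protein enters the
#' secretory pathway (signal peptide present, or — under the default gate —
#' at least one TM helix) and its anchor lies outside every TM helix.
#' Sequons whose anchor falls inside the signal peptide (residues
#' `1..signalEnd`) are additionally excluded by default, since that region
#' is cleaved from the mature protein.
#'
#' @param sequons data.frame from [scanNglySequons()] (or an external site
#'   table with an `anchor` column).
#' @param context a [secretoryContext()].
#' @param gate `"signal_or_tm"` (default) or `"signal_only"`.
#' @param excludeSignalRegion drop sequons anchored inside the signal
#'   peptide; default `TRUE`.
#' @return the counted subset of `sequons`, order preserved, with
#'   `kind = "ngly"`.
#' @export
combineNgly <- function(sequons, context,
                        gate = c("signal_or_tm", "signal_only"),
                        excludeSignalRegion = TRUE) {
  gate <- match.arg(gate)
  stopifnot(inherits(context, "secretoryContext"))
  if (!nrow(sequons)) return(.emptyMatches())
  open <- if (gate == "signal_or_tm")
    context$hasSignalPeptide || nrow(context$tmSegments) > 0L
  else context$hasSignalPeptide
  if (!open) return(.emptyMatches())
  keep <- rep(TRUE, nrow(sequons))
  tm <- context$tmSegments
  if (nrow(tm)) {
    for (k in seq_len(nrow(tm)))
      keep <- keep & !(sequons$anchor >= tm$start[k] &
                       sequons$anchor <= tm$end[k])
  }
  if (excludeSignalRegion && context$hasSignalPeptide)
    keep <- keep & sequons$anchor > context$signalEnd
  out <- sequons[keep, , drop = FALSE]
  if (!nrow(out)) return(.emptyMatches())
  out$kind <- "ngly"
  rownames(out) <- NULL
  out
}

# Average residue masses (Da, residue = amino acid minus water); X gets the
# unweighted mean of the 20 standard residues.
.AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.AA_MASS <- c(.AA_MASS, X = mean(.AA_MASS))

# Kyte-Doolittle hydropathy rescaled to 0..90 via H = 10 * (KD + 4.5);
# X (unknown) sits at the neutral midpoint 45.
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5,
         Q = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)
.KD_H <- c(10 * (.KD + 4.5), X = 45)

# Classic PEST-find score of one candidate region:
#   0.55 * (corrected DEPST mass percent) - 0.5 * hydrophobicity index,
# where the DEPST mass is reduced by one equivalent each of D-or-E, P and
# S-or-T, and the hydrophobicity index is the mole-fraction-weighted mean of
# the rescaled Kyte-Doolittle values.
.pestScore <- function(chars) {
  total <- sum(.AA_MASS[chars])
  depst <- chars[chars %in% c("D", "E", "P", "S", "T")]
  de <- if ("D" %in% depst) "D" else "E"
  st <- if ("S" %in% depst) "S" else "T"
  corrected <- sum(.AA_MASS[depst]) -
    .AA_MASS[[de]] - .AA_MASS[["P"]] - .AA_MASS[[st]]
  depst_pct <- 100 * corrected / total
  hi <- mean(.KD_H[chars])
  0.55 * depst_pct - 0.5 * hi
}

#' Scan for PEST degradation regions
#'
#' Candidate regions are the stretches between positively charged flanking
#' residues (K, R, H); sequence termini bound the first and last candidates,
#' but a sequence with no K/R/H at all yields no candidates. A candidate is
#' valid when it is at least `minLength` residues long and contains at least
#' one P, one of D/E and one of S/T. Valid candidates are scored with the
#' classic PEST-find score (see Details) and returned when the score exceeds
#' `threshold`.
#'
#' @details The score is `0.55 * DEPST - 0.5 * HI`, where `DEPST` is the
#' mass percent of D/E/P/S/T in the region after subtracting one equivalent
#' each of D-or-E, P, and S-or-T (average residue masses), and `HI` is the
#' mean Kyte-Doolittle hydropathy rescaled to 0..90. Scores above +5
#' conventionally mark potential PEST regions.
#'
#' @inheritParams scanOgly
#' @param threshold minimum score (exclusive); default 5.0.
#' @param minLength minimum inter-flank region length; default 12.
#' @return data.frame as in [scanOgly()] with `kind = "pest"`,
#'   `anchor = start` and the region score in `score`.
#' @examples
#' scanPest(paste0("K", strrep("PEST", 3), "R"))
#' @export
scanPest <- function(sequence, proteinId = NA_character_, threshold = 5.0,
                     minLength = 12L) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  flanks <- which(chars %in% c("K", "R", "H"))
  if (!length(flanks)) return(.emptyMatches())
  bounds <- c(0L, flanks, L + 1L)
  starts <- integer(0); ends <- integer(0); scores <- numeric(0)
  for (k in seq_len(length(bounds) - 1L)) {
    s <- bounds[k] + 1L; e <- bounds[k + 1L] - 1L
    if (e - s + 1L < minLength) next
    reg <- chars[s:e]
    if (!any(reg == "P") || !any(reg %in% c("D", "E")) ||
        !any(reg %in% c("S", "T"))) next
    sc <- .pestScore(reg)
    if (sc > threshold) {
      starts <- c(starts, s); ends <- c(ends, e); scores <- c(scores, sc)
    }
  }
  .matchFrame(proteinId, "pest", starts, ends, starts, scores)
}
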