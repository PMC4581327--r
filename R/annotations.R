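#' @include AllClasses.R AllGenerics.R proteome-io.R
NULL

#' Join a proteome with disorder masks and annotations
#'
#' Builds an [AnnotatedProteome-class] from a [Proteome-class], per-residue
#' disorder masks and (optionally) site and segment annotation tables. All
#' invariants are enforced: masks match sequence lengths, site positions are
#' in bounds and sit on the residue their type requires (S/T/Y for
#' phosphorylation, K for ubiquitination, N for external N-glycosylation
#' sites), and segments are in bounds with non-overlapping TM helices.
#'
#' @param proteome a [Proteome-class].
#' @param masks named list of 0/1 integer vectors (1 = disordered), one per
#'   protein; or a data.frame as returned by [readDisorderMasks()].
#' @param sites optional site annotation data.frame (`protein_id`,
#'   `site_type`, `position`, `score`).
#' @param segments optional segment annotation data.frame (`protein_id`,
#'   `segment_type`, `start`, `end`).
#' @return an [AnnotatedProteome-class].
#' @export
annotateProteome <- function(proteome, masks, sites = NULL, segments = NULL) {
  if (is.data.frame(masks))
    masks <- .masksFromFrame(masks)
  masks <- lapply(masks, function(m) as.integer(m))
  if (is.null(sites))
    sites <- data.frame(protein_id = character(), site_type = character(),
                        position = integer(), score = numeric(),
                        stringsAsFactors = FALSE)
  if (is.null(segments))
    segments <- data.frame(protein_id = character(),
                           segment_type = character(),
                           start = integer(), end = integer(),
                           stringsAsFactors = FALSE)
  new("AnnotatedProteome", speciesId = speciesId(proteome),
      group = speciesGroup(proteome), sequences = aaSequences(proteome),
      descriptions = proteome@descriptions,
      masks = masks,
      sites = sites[c("protein_id", "site_type", "position", "score")],
      segments = segments[c("protein_id", "segment_type", "start", "end")])
}

setMethod("disorderMasks", "AnnotatedProteome", function(x) x@masks)
setMethod("siteTable", "AnnotatedProteome", function(x) x@sites)
setMethod("segmentTable", "AnnotatedProteome", function(x) x@segments)

#' Read a site annotation table
#'
#' TSV with columns `protein_id`, `site_type`, `position`, `score` (score
#' may be empty). Rows are validated against the proteome: unknown protein
#' ids, out-of-bounds positions (coordinates are 1-based), unknown site
#' types and residue-type mismatches are fatal in strict mode and
#' skipped-with-a-warning in lenient mode.
#'
#' @param path TSV path.
#' @param proteome the [Proteome-class] the sites refer to.
#' @param strict abort on any invalid row (default) instead of skipping.
#' @return validated site data.frame; the number of rejected rows is
#'   attached as `attr(, "n_rejected")`.
#' @export
readSiteTable <- function(path, proteome, strict = TRUE) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  d <- d[c("protein_id", "site_type", "position", "score")]
  d$position <- as.integer(d$position)
  d$score <- as.numeric(d$score)
  validateSites(d, proteome, strict = strict)
}

#' Validate site annotations against a proteome
#'
#' @inheritParams readSiteTable
#' @param sites data.frame with columns `protein_id`, `site_type`,
#'   `position`, `score`.
#' @return see [readSiteTable()].
#' @export
validateSites <- function(sites, proteome, strict = TRUE) {
  seqs <- as.character(aaSequences(proteome))
  w <- nchar(seqs)
  bad <- rep(FALSE, nrow(sites))
  reason <- character(nrow(sites))
  unknown_type <- !sites$site_type %in% .SITE_TYPES
  bad <- bad | unknown_type; reason[unknown_type] <- "unknown site_type"
  unknown_id <- !sites$protein_id %in% names(seqs)
  bad <- bad | unknown_id; reason[unknown_id & !nzchar(reason)] <- "unknown protein_id"
  oob <- !bad & (sites$position < 1L | sites$position > w[sites$protein_id])
  bad <- bad | oob; reason[oob] <- "position out of bounds"
  chk <- !bad
  if (any(chk)) {
    res <- substring(seqs[sites$protein_id[chk]], sites$position[chk],
                     sites$position[chk])
    want <- .SITE_RESIDUE[sites$site_type[chk]]
    mism <- !is.na(want) & res != want
    bad[chk][mism] <- TRUE
    reason[chk][mism] <- "residue-type mismatch"
  }
  if (any(bad)) {
    msg <- paste0(sum(bad), " invalid site row(s): ",
                  paste(utils::head(unique(reason[bad]), 3), collapse = "; "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; skipped", call. = FALSE)
  }
  out <- sites[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write a site annotation table as TSV
#'
#' Rows are written in canonical order (`protein_id`, then `position`), so a
#' load/serialize round trip is byte-identical up to the original row order.
#'
#' @param sites site data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSiteTable <- function(sites, path) {
  sites <- sites[order(sites$protein_id, sites$position), , drop = FALSE]
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a segment annotation table
#'
#' TSV with columns `protein_id`, `segment_type`, `start`, `end` (1-based
#' inclusive). Validation mirrors [readSiteTable()].
#'
#' @inheritParams readSiteTable
#' @return validated segment data.frame.
#' @export
readSegmentTable <- function(path, proteome, strict = TRUE) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d <- d[c("protein_id", "segment_type", "start", "end")]
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  w <- Biostrings::width(aaSequences(proteome))
  names(w) <- proteinIds(proteome)
  bad <- !d$segment_type %in% .SEGMENT_TYPES |
    !d$protein_id %in% names(w)
  inb <- !bad
  bad[inb] <- d$start[inb] < 1L | d$start[inb] > d$end[inb] |
    d$end[inb] > w[d$protein_id[inb]]
  if (any(bad)) {
    msg <- paste0(sum(bad), " invalid segment row(s)")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; skipped", call. = FALSE)
  }
  out <- d[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname readSegmentTable
#' @param segments segment data.frame to serialize.
#' @export
writeSegmentTable <- function(segments, path) {
  segments <- segments[order(segments$protein_id, segments$start), ,
                       drop = FALSE]
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.masksFromFrame <- function(d) {
  m <- lapply(d$mask, function(s) as.integer(strsplit(s, "")[[1]]))
  names(m) <- d$protein_id
  m
}

#' Read per-residue disorder masks
#'
#' Two dialects are accepted. `format = "binary"` (default): TSV with
#' columns `protein_id`, `mask`, where `mask` is a string of 0/1 characters,
#' one per residue. `format = "residue"`: the long per-residue listing
#' emitted by disorder predictors — columns `protein_id`, `position`,
#' `state`, where a state of `1`, `*` or `D` marks a disordered residue —
#' normalized into binary masks at load.
#'
#' @param path TSV path.
#' @param proteome the [Proteome-class] the masks belong to; lengths are
#'   checked.
#' @param format `"binary"` or `"residue"`.
#' @return named list of integer 0/1 vectors.
#' @export
readDisorderMasks <- function(path, proteome,
                              format = c("binary", "residue")) {
  format <- match.arg(format)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (format == "binary") {
    masks <- .masksFromFrame(d)
  } else {
    d$position <- as.integer(d$position)
    dis <- d$state %in% c("1", "*", "D")
    masks <- lapply(split(seq_len(nrow(d)), d$protein_id), function(i) {
      m <- integer(max(d$position[i]))
      m[d$position[i][dis[i]]] <- 1L
      m
    })
  }
  w <- Biostrings::width(aaSequences(proteome))
  names(w) <- proteinIds(proteome)
  common <- intersect(names(masks), names(w))
  badlen <- common[vapply(common, function(i) length(masks[[i]]) != w[[i]],
                          logical(1))]
  if (length(badlen))
    stop("mask length differs from sequence length for: ",
         paste(utils::head(badlen, 5), collapse = ", "))
  masks
}

#' @rdname readDisorderMasks
#' @param masks named list of 0/1 vectors to serialize (binary dialect).
#' @export
writeDisorderMasks <- function(masks, path) {
  d <- data.frame(protein_id = names(masks),
                  mask = vapply(masks, paste, character(1), collapse = ""),
                  stringsAsFactors = FALSE)
  d <- d[order(d$protein_id), , drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep ubiquitination sites in the medium-confidence score band
#'
#' Retains ubiquitination sites whose score satisfies
#' `low <= score <= high` (both ends inclusive; defaults 0.69 and 0.84, the
#' medium-confidence band of the upstream predictor). Sites of other types
#' pass through unchanged.
#'
#' @param sites site data.frame.
#' @param low,high inclusive band limits; defaults 0.69, 0.84.
#' @param strict error on ubiquitination sites without a score (default);
#'   otherwise drop them with a warning.
#' @return filtered site data.frame.
#' @export
filterUbiquitination <- function(sites, low = 0.69, high = 0.84,
                                 strict = TRUE) {
  ub <- sites$site_type == "ubiquitination"
  noscore <- ub & is.na(sites$score)
  if (any(noscore)) {
    if (strict) stop(sum(noscore),
                     " ubiquitination site(s) without a score", call. = FALSE)
    warning(sum(noscore),
            " ubiquitination site(s) without a score; dropped", call. = FALSE)
  }
  keep <- !ub | (!is.na(sites$score) & sites$score >= low &
                 sites$score <= high)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Disorder content of proteins
#'
#' Fraction of residues called disordered: `sum(mask) / length(mask)`.
#'
#' @param masks a single 0/1 vector, or a named list of them (e.g. from
#'   [disorderMasks()]).
#' @return numeric fraction, or named vector of fractions for a list.
#' @export
disorderContent <- function(masks) {
  if (!is.list(masks)) return(sum(masks) / length(masks))
  vapply(masks, function(m) sum(m) / length(m), numeric(1))
}

#' Disordered and ordered residue counts
#'
#' @param masks as in [disorderContent()].
#' @return named numeric vector `c(Ld = , Lo = )`; for a list of masks the
#'   pooled counts over all proteins.
#' @export
splitResidues <- function(masks) {
  if (!is.list(masks)) masks <- list(masks)
  ld <- sum(vapply(masks, sum, numeric(1)))
  lt <- sum(vapply(masks, length, numeric(1)))
  c(Ld = ld, Lo = lt - ld)
}

#' Secretory context of one protein from its segment table
#'
#' Convenience bridge from segment annotations to the gate input of
#' [combineNgly()]: signal-peptide presence and end are taken from
#' `signal_peptide` rows, TM intervals from `tm_helix` rows.
#'
#' @param segments segment data.frame (possibly for many proteins).
#' @param proteinId the protein to extract.
#' @return a [secretoryContext()].
#' @export
secretoryContextFor <- function(segments, proteinId) {
  s <- segments[segments$protein_id == proteinId, , drop = FALSE]
  sp <- s[s$segment_type == "signal_peptide", , drop = FALSE]
  tm <- s[s$segment_type == "tm_helix", c("start", "end"), drop = FALSE]
  secretoryContext(hasSignalPeptide = nrow(sp) > 0L,
                   tmSegments = tm,
                   signalEnd = if (nrow(sp)) max(sp$end) else 20L)
}
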