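#' @import methods
#' @importFrom Biostrings AAStringSet width
NULL

.SPECIES_GROUPS <- c("green_algae", "oomycetes", "diatom", "yellow_algae",
                     "red_algae", "other")

.AA_ALPHABET <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

.SITE_TYPES <- c("phospho_S", "phospho_T", "phospho_Y", "ubiquitination",
                 "ngly_external")

.SEGMENT_TYPES <- c("tm_helix", "signal_peptide", "pest_external")

#' Residue a site type must sit on (NA = unconstrained)
#' @noRd
.SITE_RESIDUE <- c(phospho_S = "S", phospho_T = "T", phospho_Y = "Y",
                   ubiquitination = "K", ngly_external = "N")

#' Proteome: a species-tagged set of protein sequences
#'
#' Container for one species' protein sequence set. Sequences are stored as a
#' named [Biostrings::AAStringSet] over the 20 standard residues plus `X`
#' (ambiguity); names are the protein identifiers, unique within the species.
#'
#' @slot speciesId single string naming the species.
#' @slot group taxonomic group, one of `"green_algae"`, `"oomycetes"`,
#'   `"diatom"`, `"yellow_algae"`, `"red_algae"`, `"other"`.
#' @slot sequences named `AAStringSet`; names are protein ids.
#' @slot descriptions free-text FASTA header remainders, parallel to
#'   `sequences`.
#'
#' @seealso [Proteome()], [readProteomeFasta()], [filterByLength()],
#'   [summarizeProteome()]
#' @exportClass Proteome
setClass("Proteome",
         representation(speciesId = "character",
                        group = "character",
                        sequences = "AAStringSet",
                        descriptions = "character"))

setValidity("Proteome", function(object) {
  msg <- character()
  if (length(object@speciesId) != 1L || !nzchar(object@speciesId))
    msg <- c(msg, "speciesId must be a single non-empty string")
  if (length(object@group) != 1L || !object@group %in% .SPECIES_GROUPS)
    msg <- c(msg, paste0("group must be one of: ",
                         paste(.SPECIES_GROUPS, collapse = ", ")))
  ids <- names(object@sequences)
  if (length(object@sequences) > 0L) {
    if (is.null(ids) || any(!nzchar(ids)))
      msg <- c(msg, "all sequences must be named by a non-empty protein_id")
    else {
      if (anyDuplicated(ids))
        msg <- c(msg, paste0("duplicate protein_id: ",
                             paste(unique(ids[duplicated(ids)]), collapse = ", ")))
      if (any(grepl("\\s", ids)))
        msg <- c(msg, "protein_id must not contain whitespace")
    }
    if (any(Biostrings::width(object@sequences) < 1L))
      msg <- c(msg, "all sequences must have length >= 1")
    letters_used <- unique(strsplit(paste(as.character(object@sequences),
                                          collapse = ""), "")[[1]])
    bad <- setdiff(letters_used, .AA_ALPHABET)
    if (length(bad))
      msg <- c(msg, paste0("sequences contain letters outside the ",
                           "20-residue + X alphabet: ",
                           paste(bad, collapse = ", ")))
  }
  if (length(object@descriptions) != length(object@sequences))
    msg <- c(msg, "descriptions must be parallel to sequences")
  if (length(msg)) msg else TRUE
})

#' AnnotatedProteome: sequences joined with disorder masks and annotations
#'
#' Extends [Proteome-class] with the per-residue disorder mask and the typed
#' site/segment annotations the pipeline operates on. All coordinates are
#' 1-based inclusive.
#'
#' @slot masks named list of integer 0/1 vectors (1 = disordered), one per
#'   protein, each the length of the protein's sequence.
#' @slot sites data.frame with columns `protein_id`, `site_type`, `position`,
#'   `score` (score may be `NA`).
#' @slot segments data.frame with columns `protein_id`, `segment_type`,
#'   `start`, `end`.
#'
#' @seealso [annotateProteome()], [disorderContent()], [siteTable()],
#'   [segmentTable()], [disorderMasks()]
#' @exportClass AnnotatedProteome
setClass("AnnotatedProteome",
         contains = "Proteome",
         representation(masks = "list",
                        sites = "data.frame",
                        segments = "data.frame"))

setValidity("AnnotatedProteome", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  w <- Biostrings::width(object@sequences)
  names(w) <- ids
  if (!identical(sort(names(object@masks)), sort(ids)))
    msg <- c(msg, "masks must be named by exactly the proteome's protein ids")
  else {
    ok <- vapply(ids, function(i) {
      m <- object@masks[[i]]
      length(m) == w[[i]] && all(m %in% c(0L, 1L))
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, paste0("invalid masks (length or non-binary) for: ",
                           paste(ids[!ok], collapse = ", ")))
  }
  st <- object@sites
  need <- c("protein_id", "site_type", "position", "score")
  if (!all(need %in% names(st))) {
    msg <- c(msg, "sites must have columns protein_id, site_type, position, score")
  } else if (nrow(st)) {
    if (!all(st$site_type %in% .SITE_TYPES))
      msg <- c(msg, "unknown site_type in sites")
    if (!all(st$protein_id %in% ids))
      msg <- c(msg, "sites reference unknown protein_id")
    else if (any(st$position < 1L | st$position > w[st$protein_id]))
      msg <- c(msg, "site position out of sequence bounds")
    else {
      res <- substring(as.character(object@sequences[st$protein_id]),
                       st$position, st$position)
      want <- .SITE_RESIDUE[st$site_type]
      bad <- !is.na(want) & res != want
      if (any(bad))
        msg <- c(msg, paste0(sum(bad), " site(s) on a residue inconsistent ",
                             "with their site_type"))
    }
  }
  sg <- object@segments
  need <- c("protein_id", "segment_type", "start", "end")
  if (!all(need %in% names(sg))) {
    msg <- c(msg, "segments must have columns protein_id, segment_type, start, end")
  } else if (nrow(sg)) {
    if (!all(sg$segment_type %in% .SEGMENT_TYPES))
      msg <- c(msg, "unknown segment_type in segments")
    if (!all(sg$protein_id %in% ids))
      msg <- c(msg, "segments reference unknown protein_id")
    else if (any(sg$start < 1L | sg$start > sg$end | sg$end > w[sg$protein_id]))
      msg <- c(msg, "segment coordinates out of bounds or start > end")
    else {
      tm <- sg[sg$segment_type == "tm_helix", , drop = FALSE]
      if (nrow(tm) > 1L) {
        by_prot <- split(tm, tm$protein_id)
        overl <- vapply(by_prot, function(d) {
          d <- d[order(d$start), , drop = FALSE]
          nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])
        }, logical(1))
        if (any(overl))
          msg <- c(msg, paste0("overlapping tm_helix segments for: ",
                               paste(names(by_prot)[overl], collapse = ", ")))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ClusterCatalog: a partition of proteins into similarity clusters
#'
#' One row per cluster member; every (species_id, protein_id) pair appears in
#' exactly one cluster. Produced by [buildClusters()] or read from an
#' external assignment file (e.g. genuine OrthoMCL output) with
#' [readClusterTable()].
#'
#' @slot assignments data.frame with columns `cluster_id`, `species_id`,
#'   `protein_id`.
#'
#' @seealso [buildClusters()], [classifyClusters()], [selectRepresentatives()]
#' @exportClass ClusterCatalog
setClass("ClusterCatalog",
         representation(assignments = "data.frame"))

setValidity("ClusterCatalog", function(object) {
  a <- object@assignments
  msg <- character()
  need <- c("cluster_id", "species_id", "protein_id")
  if (!all(need %in% names(a)))
    return("assignments must have columns cluster_id, species_id, protein_id")
  if (nrow(a) == 0L)
    msg <- c(msg, "a ClusterCatalog must have at least one member")
  key <- paste(a$species_id, a$protein_id, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "each (species_id, protein_id) must belong to exactly one cluster")
  if (length(msg)) msg else TRUE
})
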