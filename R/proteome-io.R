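#' @include AllClasses.R AllGenerics.R
NULL

# Non-standard residue codes folded into X so every scanner sees a fixed
# 21-letter alphabet (B/Z ambiguity, U selenocysteine, O pyrrolysine).
.NONSTANDARD <- c("B", "Z", "U", "O")

.normalizeSequences <- function(seqs, where = "sequence input") {
  seqs <- toupper(seqs)
  seqs <- sub("\\*+$", "", seqs)
  has_ns <- grepl(paste0("[", paste(.NONSTANDARD, collapse = ""), "]"), seqs)
  if (any(has_ns)) {
    warning(sum(has_ns), " sequence(s) in ", where,
            " contain non-standard residues (B/Z/U/O); mapped to X",
            call. = FALSE)
    seqs <- chartr(paste(.NONSTANDARD, collapse = ""),
                   strrep("X", length(.NONSTANDARD)), seqs)
  }
  seqs
}

#' Construct a Proteome
#'
#' @param sequences named character vector or named
#'   [Biostrings::AAStringSet]; names are protein ids (unique, no
#'   whitespace). Sequences are uppercased, terminal `*` stop characters are
#'   stripped and non-standard residue codes (B, Z, U, O) are mapped to `X`
#'   with a warning.
#' @param speciesId single string identifying the species.
#' @param group taxonomic group label (see [Proteome-class]); default
#'   `"other"`.
#' @param descriptions optional free-text descriptions parallel to
#'   `sequences`.
#' @return a [Proteome-class] object.
#' @examples
#' Proteome(c(a = "mkv*", b = "MSSA"), "sp1", "green_algae")
#' @export
Proteome <- function(sequences, speciesId, group = "other",
                     descriptions = NULL) {
  seqs <- as.character(sequences)
  names(seqs) <- names(sequences)
  seqs <- .normalizeSequences(seqs, where = paste0("species ", speciesId))
  if (is.null(descriptions)) descriptions <- rep("", length(seqs))
  new("Proteome", speciesId = as.character(speciesId),
      group = as.character(group),
      sequences = Biostrings::AAStringSet(seqs),
      descriptions = as.character(descriptions))
}

#' Read a proteome from a FASTA file
#'
#' One protein per FASTA entry. The protein id is the first
#' whitespace-delimited token of the header; the remainder is kept as a
#' free-text description. Sequences are uppercased, terminal `*` stripped,
#' and non-standard residue codes mapped to `X`.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param speciesId species tag for the resulting [Proteome-class].
#' @param group taxonomic group label; default `"other"`.
#' @return a [Proteome-class].
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a desc", "MKV", ">b", "MSS"), f)
#' readProteomeFasta(f, "sp1")
#' @export
readProteomeFasta <- function(path, speciesId, group = "other") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA in ", path, ": sequence line before any header at line ",
         nonblank[1])
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate protein_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(raw)
  names(seqs) <- ids
  Proteome(seqs, speciesId = speciesId, group = group, descriptions = desc)
}

#' Write a proteome to FASTA
#'
#' Headers are `>protein_id description` (description omitted when empty);
#' sequences are written unwrapped so a write/read round trip is exact.
#'
#' @param proteome a [Proteome-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeProteomeFasta <- function(proteome, path) {
  ids <- proteinIds(proteome)
  desc <- proteome@descriptions
  headers <- ifelse(nzchar(desc), paste(ids, desc), ids)
  out <- Biostrings::AAStringSet(aaSequences(proteome))
  names(out) <- headers
  Biostrings::writeXStringSet(out, path, width = 20001L)
  invisible(path)
}

#' @describeIn filterByLength Retain proteins with
#'   `minLen <= length <= maxLen` (both bounds inclusive; the defaults remove
#'   sequences shorter than 50 or longer than 4000 residues). Input order is
#'   preserved. The number of removed records is attached as
#'   `attr(, "n_removed")`.
#' @param minLen minimum retained length (residues), default 50.
#' @param maxLen maximum retained length (residues), default 4000.
#' @export
setMethod("filterByLength", "Proteome", function(x, minLen = 50L,
                                                 maxLen = 4000L) {
  stopifnot(minLen <= maxLen)
  keep <- Biostrings::width(x@sequences) >= minLen &
          Biostrings::width(x@sequences) <= maxLen
  out <- x
  out@sequences <- x@sequences[keep]
  out@descriptions <- x@descriptions[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
})

#' @describeIn filterByLength On an annotated proteome the masks, sites and
#'   segments of removed proteins are dropped alongside the sequences.
#' @export
setMethod("filterByLength", "AnnotatedProteome", function(x, minLen = 50L,
                                                          maxLen = 4000L) {
  p <- callNextMethod(x, minLen = minLen, maxLen = maxLen)
  ids <- names(p@sequences)
  p@masks <- p@masks[ids]
  p@sites <- p@sites[p@sites$protein_id %in% ids, , drop = FALSE]
  p@segments <- p@segments[p@segments$protein_id %in% ids, , drop = FALSE]
  rownames(p@sites) <- NULL
  rownames(p@segments) <- NULL
  p
})

#' Summarize a proteome
#'
#' @param proteome a [Proteome-class].
#' @return data.frame with one row: `species_id`, `n_records`, `total_aa`,
#'   `mean_length` (`NA` for an empty proteome).
#' @export
summarizeProteome <- function(proteome) {
  w <- Biostrings::width(aaSequences(proteome))
  data.frame(species_id = speciesId(proteome),
             n_records = length(w),
             total_aa = sum(w),
             mean_length = if (length(w)) mean(w) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Write a per-protein length summary TSV
#'
#' Columns: `protein_id`, `species_id`, `length`.
#'
#' @param proteome a [Proteome-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeLengthTable <- function(proteome, path) {
  d <- data.frame(protein_id = proteinIds(proteome),
                  species_id = speciesId(proteome),
                  length = Biostrings::width(aaSequences(proteome)),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("proteinIds", "Proteome", function(x) names(x@sequences))
setMethod("speciesId", "Proteome", function(x) x@speciesId)
setMethod("speciesGroup", "Proteome", function(x) x@group)
setMethod("aaSequences", "Proteome", function(x) x@sequences)
setMethod("nProteins", "Proteome", function(x) length(x@sequences))
setMethod("totalAA", "Proteome",
          function(x) sum(Biostrings::width(x@sequences)))

setMethod("show", "Proteome", function(object) {
  cat("Proteome of", object@speciesId, "(", object@group, ")\n")
  cat("  ", nProteins(object), "proteins,", totalAA(object), "residues\n")
})

setMethod("show", "AnnotatedProteome", function(object) {
  callNextMethod()
  cat("  sites:", nrow(object@sites),
      "| segments:", nrow(object@segments),
      "| mean disorder:",
      if (nProteins(object))
        round(mean(vapply(object@masks, mean, numeric(1))), 3) else NA, "\n")
})
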