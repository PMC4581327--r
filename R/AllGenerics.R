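#' @include AllClasses.R
NULL

#' Accessors for Proteome and AnnotatedProteome objects
#'
#' Small accessor family: `proteinIds()` returns the protein identifiers,
#' `speciesId()` the species tag, `speciesGroup()` the taxonomic group,
#' `aaSequences()` the named [Biostrings::AAStringSet], `nProteins()` the
#' record count and `totalAA()` the summed residue count.
#'
#' @param x a [Proteome-class] or [AnnotatedProteome-class] object.
#' @return `proteinIds`: character vector; `speciesId`, `speciesGroup`:
#'   single string; `aaSequences`: `AAStringSet`; `nProteins`, `totalAA`:
#'   integer/numeric scalar.
#' @examples
#' p <- Proteome(c(a = "MKV", b = "MSSA"), "sp1")
#' proteinIds(p)
#' totalAA(p)
#' @name proteome-accessors
NULL

#' @rdname proteome-accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname proteome-accessors
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

#' @rdname proteome-accessors
#' @export
setGeneric("speciesGroup", function(x) standardGeneric("speciesGroup"))

#' @rdname proteome-accessors
#' @export
setGeneric("aaSequences", function(x) standardGeneric("aaSequences"))

#' @rdname proteome-accessors
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @rdname proteome-accessors
#' @export
setGeneric("totalAA", function(x) standardGeneric("totalAA"))

#' Accessors for annotation slots
#'
#' `disorderMasks()` returns the named list of per-residue 0/1 disorder
#' vectors, `siteTable()` the site annotation data.frame and `segmentTable()`
#' the segment annotation data.frame of an [AnnotatedProteome-class].
#'
#' @param x an `AnnotatedProteome`.
#' @return list or data.frame as described above.
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
setGeneric("disorderMasks", function(x) standardGeneric("disorderMasks"))

#' @rdname annotation-accessors
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname annotation-accessors
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname clusterTable
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' Filter a proteome by sequence length
#'
#' @param x object to filter.
#' @param ... further arguments (`minLen`, `maxLen`).
#' @export
setGeneric("filterByLength", function(x, ...) standardGeneric("filterByLength"))
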