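#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' @param x an [IgrSet] or [AnnotatedGenome].
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("igrId", function(x) standardGeneric("igrId"))

#' @rdname accessors
#' @export
setGeneric("igrSequences", function(x) standardGeneric("igrSequences"))

#' @rdname accessors
#' @export
setGeneric("igrRanges", function(x) standardGeneric("igrRanges"))

#' @rdname accessors
#' @export
setGeneric("rnaFamilies", function(x) standardGeneric("rnaFamilies"))

#' @rdname accessors
#' @export
setGeneric("rnaFamilies<-", function(x, value) standardGeneric("rnaFamilies<-"))

#' @rdname accessors
#' @export
setGeneric("isSelected", function(x) standardGeneric("isSelected"))

#' @rdname accessors
#' @export
setGeneric("isSelected<-", function(x, value) standardGeneric("isSelected<-"))

#' @rdname accessors
#' @export
setGeneric("decisionValue", function(x) standardGeneric("decisionValue"))

#' @rdname accessors
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))

#' @rdname accessors
#' @export
setGeneric("rnaAnnotations", function(x) standardGeneric("rnaAnnotations"))

#' @rdname accessors
#' @export
setGeneric("contigSequences", function(x) standardGeneric("contigSequences"))

#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Percentage of G and C nucleotides in a sequence
#'
#' Computes 100 x (number of `G` plus number of `C`, case-insensitive)
#' divided by the total number of characters. IUPAC ambiguity codes and `N`
#' count in the denominator only: a partially ambiguous base is never
#' credited as G or C.
#'
#' @param x a character vector of nucleotide strings, a
#'   [Biostrings::DNAStringSet], or an [IgrSet] (returns the stored
#'   per-IGR values).
#' @return numeric vector of GC percentages in `[0, 100]`.
#' @examples
#' gcPercent(c("ATGC", "GGCC", "GCNN"))
#' @export
setGeneric("gcPercent", function(x) standardGeneric("gcPercent"))

#' @rdname gcPercent
#' @export
setGeneric("igrLength", function(x) standardGeneric("igrLength"))
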