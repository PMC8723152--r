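#' @include AllGenerics.R
NULL

## Internal constructor: `ranges` must already carry igr_id and gc_percent
## is recomputed here so interval and sequence can never disagree.
.IgrSet <- function(ranges, seqs, rnaFamilies = NULL) {
  n <- length(ranges)
  if (is.null(rnaFamilies))
    rnaFamilies <- IRanges::CharacterList(rep(list(character()), n))
  mc <- S4Vectors::mcols(ranges)
  defaults <- list(upstream_locus = ".", upstream_strand = ".",
                   downstream_locus = ".", downstream_strand = ".",
                   terminal = FALSE, wraps = FALSE,
                   selected = FALSE, decision = NA_real_)
  for (col in names(defaults))
    if (!col %in% colnames(mc)) mc[[col]] <- rep(defaults[[col]], n)
  mc$gc_percent <- if (n) gcPercent(seqs) else numeric()
  S4Vectors::mcols(ranges) <- mc[, .IGR_MCOLS]
  names(seqs) <- mc$igr_id
  new("IgrSet", ranges = ranges, seqs = seqs, rnaFamilies = rnaFamilies)
}

#' @rdname accessors
#' @export
setMethod("igrId", "IgrSet", function(x) S4Vectors::mcols(x@ranges)$igr_id)

#' @rdname accessors
#' @export
setMethod("igrSequences", "IgrSet", function(x) x@seqs)

#' @rdname accessors
#' @export
setMethod("igrRanges", "IgrSet", function(x) x@ranges)

#' @rdname accessors
#' @export
setMethod("rnaFamilies", "IgrSet", function(x) {
  stats::setNames(x@rnaFamilies, igrId(x))
})

#' @rdname accessors
#' @export
setReplaceMethod("rnaFamilies", "IgrSet", function(x, value) {
  stopifnot(length(value) == length(x))
  x@rnaFamilies <- IRanges::CharacterList(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("isSelected", "IgrSet", function(x) {
  stats::setNames(S4Vectors::mcols(x@ranges)$selected, igrId(x))
})

#' @rdname accessors
#' @export
setReplaceMethod("isSelected", "IgrSet", function(x, value) {
  S4Vectors::mcols(x@ranges)$selected <- as.logical(value)
  x
})

#' @rdname accessors
#' @export
setMethod("decisionValue", "IgrSet", function(x) {
  stats::setNames(S4Vectors::mcols(x@ranges)$decision, igrId(x))
})

#' @rdname gcPercent
#' @export
setMethod("gcPercent", "IgrSet", function(x) {
  stats::setNames(S4Vectors::mcols(x@ranges)$gc_percent, igrId(x))
})

#' @rdname gcPercent
#' @export
setMethod("igrLength", "IgrSet", function(x) {
  stats::setNames(GenomicRanges::width(x@ranges), igrId(x))
})

#' @export
setMethod("length", "IgrSet", function(x) length(x@ranges))

#' @export
setMethod("[", "IgrSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, igrId(x))
  new("IgrSet", ranges = x@ranges[i], seqs = x@seqs[i],
      rnaFamilies = x@rnaFamilies[i])
})

setMethod("show", "IgrSet", function(object) {
  n <- length(object)
  lab <- sum(lengths(object@rnaFamilies) > 0)
  sel <- sum(S4Vectors::mcols(object@ranges)$selected)
  cat("IgrSet with", n, "intergenic regions\n")
  if (n) {
    cat(sprintf("  length: %d-%d nt | GC: %.1f-%.1f%%\n",
                min(GenomicRanges::width(object@ranges)),
                max(GenomicRanges::width(object@ranges)),
                min(gcPercent(object)), max(gcPercent(object))))
    cat(sprintf("  %d labeled with known RNA families | %d selected\n",
                lab, sel))
  }
  invisible(object)
})

#' Tabular view of an IgrSet
#'
#' One row per IGR with the columns persisted by [writeIgrTable()]:
#' coordinates are 1-based closed and `rna_families` is a comma-joined
#' string (empty when the IGR carries no known RNA).
#'
#' @param x an [IgrSet].
#' @param ... ignored.
#' @return a `data.frame`.
#' @export
setMethod("as.data.frame", "IgrSet", function(x, ...) {
  mc <- S4Vectors::mcols(x@ranges)
  data.frame(
    igr_id = mc$igr_id,
    contig = as.character(GenomicRanges::seqnames(x@ranges)),
    start = GenomicRanges::start(x@ranges),
    end = GenomicRanges::end(x@ranges),
    length = GenomicRanges::width(x@ranges),
    gc_percent = mc$gc_percent,
    upstream_locus = mc$upstream_locus,
    upstream_strand = mc$upstream_strand,
    downstream_locus = mc$downstream_locus,
    downstream_strand = mc$downstream_strand,
    rna_families = vapply(x@rnaFamilies, paste, "", collapse = ","),
    terminal = mc$terminal,
    wraps = mc$wraps,
    selected = mc$selected,
    decision = mc$decision,
    stringsAsFactors = FALSE
  )
})

#' @rdname accessors
#' @export
setMethod("geneFeatures", "AnnotatedGenome", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("rnaAnnotations", "AnnotatedGenome", function(x) x@rnas)

#' @rdname accessors
#' @export
setMethod("contigSequences", "AnnotatedGenome", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("topology", "AnnotatedGenome", function(x) x@topology)

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome:", length(object@sequences), "contig(s),",
      sum(Biostrings::width(object@sequences)), "nt\n")
  cat("  ", sum(S4Vectors::mcols(object@genes)$kind == "CDS"),
      "CDS features |", length(object@rnas), "known RNA annotation(s)\n")
  invisible(object)
})

setMethod("show", "IgrClassifier", function(object) {
  cat("IgrClassifier (RBF-kernel SVM on %GC and length)\n")
  cat(sprintf("  C = %g, gamma = %g (%s), positive weight w = %g\n",
              object@C, object@gamma, object@gammaMode, object@weight))
  cat(sprintf("  trained on %d known-RNA and %d background IGRs; %d support vectors\n",
              object@nPositive, object@nNegative, nrow(object@supportVectors)))
  invisible(object)
})

setMethod("show", "SearchBundle", function(object) {
  cat("SearchBundle", object@bundleId, "with", nrow(object@manifest),
      "candidate(s)\n  archive:", object@path, "\n")
  invisible(object)
})
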