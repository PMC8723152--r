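#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom Biostrings DNAStringSet width letterFrequency
NULL

#' AnnotatedGenome: a genome assembly with its feature annotations
#'
#' Container for one bacterial genome assembly: the contig sequences, the
#' protein-coding (and other) gene features, any known structured-RNA
#' annotations, and the per-contig topology. Only features with
#' `kind == "CDS"` delimit intergenic regions; everything else (tRNA, rRNA,
#' ncRNA, plain `gene` records) is treated as intergenic content so that
#' annotated RNAs can serve as positive training labels.
#'
#' @slot sequences [Biostrings::DNAStringSet] named by contig ID (the first
#'   whitespace-delimited token of the FASTA header). Upper-cased on ingest.
#' @slot genes [GenomicRanges::GRanges] with metadata columns `kind`
#'   (`"CDS"` or `"other"`), `locus_tag` and `product`; 1-based closed
#'   coordinates, sorted by (contig, start, end).
#' @slot rnas [GenomicRanges::GRanges] of known structured-RNA annotations
#'   with a `family` metadata column (e.g. an Rfam name).
#' @slot topology named character vector, `"linear"` or `"circular"` per
#'   contig.
#'
#' @seealso [readGenome()], [readRnaAnnotations()], [extractIgrs()]
#' @export
setClass("AnnotatedGenome",
  representation(
    sequences = "DNAStringSet",
    genes = "GRanges",
    rnas = "GRanges",
    topology = "character"
  )
)

setValidity("AnnotatedGenome", function(object) {
  msgs <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    msgs <- c(msgs, "contig IDs must be present and unique")
  lens <- setNames(Biostrings::width(object@sequences), ids)
  for (gr in list(object@genes, object@rnas)) {
    if (length(gr) == 0L) next
    ctg <- as.character(GenomicRanges::seqnames(gr))
    bad <- setdiff(unique(ctg), ids)
    if (length(bad))
      msgs <- c(msgs, paste0("feature contig not in assembly: ",
                             paste(bad, collapse = ", ")))
    ok <- ctg %in% ids
    if (any(GenomicRanges::end(gr)[ok] > lens[ctg[ok]]))
      msgs <- c(msgs, "feature end exceeds contig length")
    if (any(GenomicRanges::start(gr) < 1L))
      msgs <- c(msgs, "feature start below 1")
  }
  if (!all(object@topology %in% c("linear", "circular")))
    msgs <- c(msgs, "topology must be 'linear' or 'circular'")
  if (!setequal(names(object@topology), ids))
    msgs <- c(msgs, "topology must name every contig")
  if (length(msgs)) msgs else TRUE
})

#' IgrSet: intergenic regions with classifier features and labels
#'
#' The central container of the pipeline: a set of intergenic regions
#' (IGRs), each carrying its genomic interval, nucleotide sequence, %GC
#' content, flanking-gene context, known-RNA family labels, and selection
#' state. An IGR spanning the origin of a circular contig is stored with
#' `end > contig length` (unwrapped coordinates) and `wraps == TRUE`; its
#' sequence is the origin-crossing concatenation.
#'
#' Metadata columns of `ranges`: `igr_id` (deterministic,
#' `<contig>_<1-based start>`), `gc_percent`, `upstream_locus`,
#' `upstream_strand`, `downstream_locus`, `downstream_strand` (the sentinel
#' `"."` marks a linear contig edge), `terminal`, `wraps`, `selected`, and
#' `decision` (SVM decision value, `NA` before scoring).
#'
#' @slot ranges [GenomicRanges::GRanges], 1-based closed, one row per IGR.
#' @slot seqs [Biostrings::DNAStringSet] named by `igr_id`, parallel to
#'   `ranges`.
#' @slot rnaFamilies [IRanges::CharacterList] of known-RNA family labels,
#'   parallel to `ranges`; empty elements mark unannotated IGRs.
#'
#' @seealso [extractIgrs()], [labelIgrs()], [selectCandidates()]
#' @export
setClass("IgrSet",
  representation(
    ranges = "GRanges",
    seqs = "DNAStringSet",
    rnaFamilies = "CharacterList"
  )
)

.IGR_MCOLS <- c("igr_id", "gc_percent", "upstream_locus", "upstream_strand",
                "downstream_locus", "downstream_strand", "terminal", "wraps",
                "selected", "decision")

setValidity("IgrSet", function(object) {
  msgs <- character()
  n <- length(object@ranges)
  if (length(object@seqs) != n || length(object@rnaFamilies) != n)
    msgs <- c(msgs, "ranges, seqs and rnaFamilies must be parallel")
  miss <- setdiff(.IGR_MCOLS, colnames(S4Vectors::mcols(object@ranges)))
  if (length(miss))
    msgs <- c(msgs, paste0("missing metadata columns: ",
                           paste(miss, collapse = ", ")))
  else {
    ids <- S4Vectors::mcols(object@ranges)$igr_id
    if (anyDuplicated(ids)) msgs <- c(msgs, "igr_id values must be unique")
    if (!identical(names(object@seqs), as.character(ids)) && n > 0L)
      msgs <- c(msgs, "seqs must be named by igr_id")
    if (any(GenomicRanges::width(object@ranges) != Biostrings::width(object@seqs)))
      msgs <- c(msgs, "interval width must equal sequence length")
    gc <- S4Vectors::mcols(object@ranges)$gc_percent
    if (any(gc < 0 | gc > 100, na.rm = TRUE))
      msgs <- c(msgs, "gc_percent must lie in [0, 100]")
  }
  if (length(msgs)) msgs else TRUE
})

#' IgrClassifier: per-genome RBF-kernel SVM over (%GC, length)
#'
#' A support-vector classifier with a radial basis-function kernel trained
#' de novo for one genome on two features — IGR %GC content and nucleotide
#' length — with presence/absence of a known structured RNA as the class
#' label. The trained state (support vectors in standardized feature space,
#' dual coefficients, intercept) is stored explicitly so the decision
#' function can be re-evaluated by any runtime; [writeClassifierJSON()]
#' serializes it losslessly.
#'
#' The decision function is
#' \deqn{d(x) = \sum_i \alpha_i \exp(-\gamma \|z(x) - s_i\|^2) - \rho}
#' where \eqn{z(x)} standardizes raw features by `center` and `scale`.
#' Positive values indicate similarity to known-RNA IGRs.
#'
#' @slot C positive cost (regularization) parameter.
#' @slot gamma RBF width in standardized feature space.
#' @slot gammaMode `"auto"` (half the reciprocal of the mean per-feature
#'   variance after scaling, i.e. 0.5) or `"fixed"`.
#' @slot weight positive-class weight multiplier `w`; the effective class
#'   weights are `w * n_negative / n_positive` for the RNA class and 1 for
#'   the background class.
#' @slot center,scale numeric(2): feature means and standard deviations
#'   (`gc_percent`, `length`) over all training IGRs.
#' @slot logLength logical; whether length entered the model as log10.
#' @slot supportVectors matrix of support vectors, standardized space.
#' @slot coefs dual coefficients (positive rows favour the RNA class).
#' @slot rho decision-function intercept.
#' @slot nPositive,nNegative training class counts.
#'
#' @seealso [trainClassifier()], [decisionValues()], [decisionGrid()]
#' @export
setClass("IgrClassifier",
  representation(
    C = "numeric",
    gamma = "numeric",
    gammaMode = "character",
    weight = "numeric",
    center = "numeric",
    scale = "numeric",
    logLength = "logical",
    supportVectors = "matrix",
    coefs = "numeric",
    rho = "numeric",
    nPositive = "integer",
    nNegative = "integer"
  )
)

setValidity("IgrClassifier", function(object) {
  msgs <- character()
  if (object@C <= 0 || object@gamma <= 0 || object@weight <= 0)
    msgs <- c(msgs, "C, gamma and weight must be positive")
  if (any(object@scale <= 0))
    msgs <- c(msgs, "feature scale (sd) must be positive")
  if (length(object@center) != 2L || length(object@scale) != 2L)
    msgs <- c(msgs, "center and scale must have length 2")
  if (nrow(object@supportVectors) != length(object@coefs))
    msgs <- c(msgs, "one dual coefficient per support vector required")
  if (length(msgs)) msgs else TRUE
})

#' SearchBundle: a packaged homology-search hand-off
#'
#' Description of a portable archive prepared by [exportBundle()]: one
#' FASTA per candidate IGR (each the query of an independent homology
#' search), a shell-script template with `{DB}`, `{CPUS}` and `{EVALUE}`
#' placeholders, and a TSV manifest of member metadata.
#'
#' @slot bundleId character scalar.
#' @slot path path of the written `.tar.gz` archive.
#' @slot manifest data.frame, one row per FASTA member.
#' @export
setClass("SearchBundle",
  representation(bundleId = "character", path = "character",
                 manifest = "data.frame")
)

setValidity("SearchBundle", function(object) {
  if (anyDuplicated(object@manifest$igr_id))
    "manifest igr_id values must be unique" else TRUE
})

#' SimConfig: parameters of the synthetic-genome simulator
#'
#' Defines the study conditions the simulator emulates: protein-coding
#' genes with one GC composition, background IGRs with another, and a
#' planted cluster of structured-RNA-like IGRs with elevated GC and length.
#' A subset of the planted RNAs is emitted as known (labeled) families; the
#' rest are left unannotated as discoverable candidates. See
#' [simulateGenome()] for the generated files and [separationMetric()] for
#' the background-versus-planted cluster separation implied by a
#' configuration.
#'
#' @slot seed integer RNG seed; the whole simulation is reproducible from it.
#' @slot nContigs,nGenesPerContig layout: each contig alternates gene and
#'   IGR blocks (`nGenesPerContig` genes enclose `nGenesPerContig - 1` IGRs).
#' @slot geneLengthRange integer(2), uniform gene length bounds (nt).
#' @slot codingGcMean,codingGcSd per-gene target GC (%), normal.
#' @slot bgIgrLengthMean,bgIgrLengthSd background IGR length (nt), normal
#'   truncated below at 30 nt.
#' @slot bgIgrGcMean,bgIgrGcSd background IGR GC (%), normal truncated
#'   to (1, 99).
#' @slot nPlantedRna number of planted structured-RNA IGRs across the genome.
#' @slot rnaGcMean,rnaGcSd,rnaLengthMean,rnaLengthSd planted RNA segment
#'   GC (%) and length (nt) distributions; length truncated below at 60 nt.
#' @slot fractionLabeled fraction of planted RNAs written to the BED file
#'   as known families (`SYN_k`); the remainder are unlabeled candidates.
#' @slot topology `"linear"` or `"circular"`, applied to every contig.
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    nContigs = "integer",
    nGenesPerContig = "integer",
    geneLengthRange = "integer",
    codingGcMean = "numeric", codingGcSd = "numeric",
    bgIgrLengthMean = "numeric", bgIgrLengthSd = "numeric",
    bgIgrGcMean = "numeric", bgIgrGcSd = "numeric",
    nPlantedRna = "integer",
    rnaGcMean = "numeric", rnaGcSd = "numeric",
    rnaLengthMean = "numeric", rnaLengthSd = "numeric",
    fractionLabeled = "numeric",
    topology = "character"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  sds <- c(object@codingGcSd, object@bgIgrLengthSd, object@bgIgrGcSd,
           object@rnaGcSd, object@rnaLengthSd)
  if (any(sds <= 0)) msgs <- c(msgs, "all standard deviations must be > 0")
  gcs <- c(object@codingGcMean, object@bgIgrGcMean, object@rnaGcMean)
  if (any(gcs <= 0 | gcs >= 100))
    msgs <- c(msgs, "GC means must lie in (0, 100)")
  if (object@fractionLabeled < 0 || object@fractionLabeled > 1)
    msgs <- c(msgs, "fractionLabeled must lie in [0, 1]")
  if (!object@topology %in% c("linear", "circular"))
    msgs <- c(msgs, "topology must be 'linear' or 'circular'")
  if (object@nGenesPerContig < 2L)
    msgs <- c(msgs, "need at least 2 genes per contig to form an IGR")
  if (object@nPlantedRna > (object@nGenesPerContig - 1L) * object@nContigs)
    msgs <- c(msgs, "more planted RNAs than IGR slots")
  if (length(msgs)) msgs else TRUE
})
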