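#' @include genome-io.R
NULL

#' @rdname gcPercent
#' @export
setMethod("gcPercent", "character", function(x) {
  if (any(!nzchar(x)))
    stop("gc_percent is undefined for an empty sequence")
  gcPercent(Biostrings::DNAStringSet(toupper(x)))
})

#' @rdname gcPercent
#' @export
setMethod("gcPercent", "DNAStringSet", function(x) {
  w <- Biostrings::width(x)
  if (any(w == 0L))
    stop("gc_percent is undefined for an empty sequence")
  as.numeric(100 * Biostrings::letterFrequency(x, "GC") / w)
})

#' Extract intergenic regions from an annotated genome
#'
#' Computes, per contig, the complement of the union of all protein-coding
#' (CDS) spans — CDS intervals are merged across strands first, so
#' overlapping or nested genes never create spurious gaps — and returns
#' every remaining maximal interval as an IGR with its sequence, %GC and
#' flanking-gene context attached. Non-CDS features (tRNA, rRNA, ncRNA)
#' do not delimit IGRs; annotated RNAs therefore remain inside IGRs where
#' they can serve as positive training labels for [trainClassifier()].
#'
#' On a circular contig the two gaps abutting the origin are joined into a
#' single IGR whose sequence wraps; it is stored with unwrapped
#' coordinates (`end` exceeds the contig length) and `wraps = TRUE`.
#' IGRs touching the edge of a linear contig are flagged `terminal`
#' (flanking-gene sentinel `"."`); draft assemblies truncate genes at
#' contig edges, so they are kept unless `dropTerminal = TRUE`.
#'
#' Zero-length gaps between abutting or overlapping genes yield no IGR.
#' No minimum-length filter is applied at extraction: length selection is
#' the classifier's job.
#'
#' @param genome an [AnnotatedGenome].
#' @param dropTerminal drop IGRs touching a linear contig edge.
#' @return an [IgrSet]; IGR IDs are `<contig>_<1-based start>`.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(chrA = paste(rep("ACGT", 250),
#'                                                 collapse = "")))
#' genes <- GenomicRanges::GRanges("chrA",
#'   IRanges::IRanges(c(101, 601), c(400, 900)), strand = "+",
#'   kind = "CDS", locus_tag = c("g1", "g2"), product = NA_character_)
#' gnm <- new("AnnotatedGenome", sequences = seqs, genes = genes,
#'            rnas = GenomicRanges::GRanges(family = character()),
#'            topology = c(chrA = "linear"))
#' extractIgrs(gnm)
#' @export
extractIgrs <- function(genome, dropTerminal = FALSE) {
  stopifnot(is(genome, "AnnotatedGenome"))
  rows <- list()
  seqs <- list()
  for (contig in names(genome@sequences)) {
    len <- Biostrings::width(genome@sequences[contig])
    circular <- genome@topology[[contig]] == "circular"
    onCtg <- as.character(GenomicRanges::seqnames(genome@genes)) == contig
    cds <- genome@genes[onCtg &
                          S4Vectors::mcols(genome@genes)$kind == "CDS"]
    cdsIR <- IRanges::reduce(IRanges::IRanges(GenomicRanges::start(cds),
                                              GenomicRanges::end(cds)))
    gapIR <- if (length(cdsIR)) IRanges::gaps(cdsIR, start = 1L, end = len)
             else IRanges::IRanges(1L, len)
    if (!length(gapIR)) next
    st <- IRanges::start(gapIR); en <- IRanges::end(gapIR)
    wraps <- rep(FALSE, length(gapIR))
    if (circular && length(cdsIR) && length(gapIR) &&
        st[1] == 1L && en[length(en)] == len) {
      if (length(gapIR) == 1L) {
        ## no CDS boundary interrupts the gap ring; keep it linear-like
      } else {
        joinStart <- st[length(st)]
        joinEnd <- len + en[1]
        st <- c(st[-c(1L, length(st))], joinStart)
        en <- c(en[-c(1L, length(en))], joinEnd)
        wraps <- c(rep(FALSE, length(st) - 1L), TRUE)
      }
    }
    ord <- order(st)
    st <- st[ord]; en <- en[ord]; wraps <- wraps[ord]

    terminal <- !circular & (st == 1L | en == len)
    if (dropTerminal) {
      keep <- !terminal
      st <- st[keep]; en <- en[keep]
      wraps <- wraps[keep]; terminal <- terminal[keep]
    }
    if (!length(st)) next

    cstart <- GenomicRanges::start(cds); cend <- GenomicRanges::end(cds)
    ctag <- S4Vectors::mcols(cds)$locus_tag
    cstr <- as.character(GenomicRanges::strand(cds))
    pickUp <- function(s, wrap) {
      cand <- if (wrap) seq_along(cstart) else which(cend < s)
      if (!length(cand)) return(c(".", "."))
      i <- cand[which.max(cend[cand])]
      c(ctag[i], cstr[i])
    }
    pickDown <- function(e, wrap) {
      eMod <- if (wrap) e - len else e
      cand <- if (wrap) seq_along(cstart) else which(cstart > eMod)
      if (!length(cand)) return(c(".", "."))
      i <- cand[which.min(cstart[cand])]
      c(ctag[i], cstr[i])
    }
    up <- do.call(cbind, mapply(pickUp, st, wraps, SIMPLIFY = FALSE))
    down <- do.call(cbind, mapply(pickDown, en, wraps, SIMPLIFY = FALSE))
    up[, terminal & st == 1L] <- "."
    down[, terminal & en == len] <- "."

    plainSeq <- as.character(Biostrings::extractAt(
      genome@sequences[[contig]],
      IRanges::IRanges(st, pmin(en, len))))
    wrapTail <- which(wraps)
    for (k in wrapTail)
      plainSeq[k] <- paste0(plainSeq[k],
                            as.character(Biostrings::subseq(
                              genome@sequences[[contig]], 1L, en[k] - len)))
    rows[[length(rows) + 1L]] <- data.frame(
      contig = contig, start = st, end = en,
      igr_id = paste0(contig, "_", st),
      upstream_locus = up[1, ], upstream_strand = up[2, ],
      downstream_locus = down[1, ], downstream_strand = down[2, ],
      terminal = terminal, wraps = wraps, stringsAsFactors = FALSE)
    seqs[[length(seqs) + 1L]] <- plainSeq
  }
  if (!length(rows)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      igr_id = character(), upstream_locus = character(),
      upstream_strand = character(), downstream_locus = character(),
      downstream_strand = character(), terminal = logical(),
      wraps = logical())
    return(.IgrSet(gr, Biostrings::DNAStringSet()))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    igr_id = df$igr_id, upstream_locus = df$upstream_locus,
    upstream_strand = df$upstream_strand,
    downstream_locus = df$downstream_locus,
    downstream_strand = df$downstream_strand,
    terminal = df$terminal, wraps = df$wraps)
  S4Vectors::metadata(gr)$contigLengths <-
    stats::setNames(Biostrings::width(genome@sequences),
                    names(genome@sequences))
  .IgrSet(gr, Biostrings::DNAStringSet(unlist(seqs)))
}

#' Label IGRs with overlapping known-RNA families
#'
#' An IGR gains family `F` when the fraction of the RNA annotation's
#' length that falls inside the IGR reaches `minOverlapFraction`
#' (default 0.5, compared with `>=`). The fraction is taken over the
#' annotation, not the IGR, so an annotation slightly overhanging a
#' flanking gene still labels its IGR. Labeling ignores strand: an IGR is
#' a double-stranded genomic interval. One IGR may carry several families;
#' an RNA lying entirely inside a CDS labels nothing.
#'
#' @param igrs an [IgrSet].
#' @param rnas a `GRanges` with a `family` column (as returned by
#'   [readRnaAnnotations()]) or an [AnnotatedGenome] carrying one.
#' @param minOverlapFraction required overlap as a fraction of the RNA
#'   annotation length, in `[0, 1]`.
#' @return the [IgrSet] with `rnaFamilies` replaced by the computed labels.
#' @export
labelIgrs <- function(igrs, rnas, minOverlapFraction = 0.5) {
  stopifnot(is(igrs, "IgrSet"))
  if (is(rnas, "AnnotatedGenome")) rnas <- rnas@rnas
  fams <- rep(list(character()), length(igrs))
  if (length(rnas) && length(igrs)) {
    pieces <- .igrPieces(igrs)
    hits <- GenomicRanges::findOverlaps(pieces, rnas, ignore.strand = TRUE)
    if (length(hits)) {
      ov <- GenomicRanges::width(GenomicRanges::pintersect(
        pieces[S4Vectors::from(hits)], rnas[S4Vectors::to(hits)],
        ignore.strand = TRUE))
      igrIdx <- S4Vectors::mcols(pieces)$igr_index[S4Vectors::from(hits)]
      rnaIdx <- S4Vectors::to(hits)
      ## a wrapped IGR contributes two pieces; sum overlap per (IGR, RNA)
      key <- paste(igrIdx, rnaIdx)
      tot <- tapply(ov, key, sum)
      ids <- do.call(rbind, strsplit(names(tot), " "))
      iIdx <- as.integer(ids[, 1]); rIdx <- as.integer(ids[, 2])
      frac <- as.numeric(tot) / GenomicRanges::width(rnas)[rIdx]
      pass <- frac >= minOverlapFraction
      for (j in which(pass)) {
        i <- iIdx[j]
        fams[[i]] <- union(fams[[i]],
                           S4Vectors::mcols(rnas)$family[rIdx[j]])
      }
      fams <- lapply(fams, sort)
    }
  }
  igrs@rnaFamilies <- IRanges::CharacterList(fams)
  igrs
}

## Split each IGR into genuine genomic pieces (an origin-spanning IGR
## becomes two), tagged with the index of the parent IGR. Contig lengths
## travel in metadata(ranges)$contigLengths, set by extractIgrs().
.igrPieces <- function(igrs) {
  gr <- igrs@ranges
  wraps <- S4Vectors::mcols(gr)$wraps
  contig <- as.character(GenomicRanges::seqnames(gr))
  lens <- S4Vectors::metadata(gr)$contigLengths
  pieces <- list(); idx <- list()
  plain <- which(!wraps)
  if (length(plain)) {
    pieces[[1]] <- GenomicRanges::GRanges(
      contig[plain], IRanges::IRanges(GenomicRanges::start(gr)[plain],
                                      GenomicRanges::end(gr)[plain]))
    idx[[1]] <- plain
  }
  for (i in which(wraps)) {
    if (is.null(lens) || is.na(lens[contig[i]]))
      stop("contig length unavailable for origin-spanning IGR ",
           S4Vectors::mcols(gr)$igr_id[i],
           "; label IGRs before serializing the set")
    L <- lens[[contig[i]]]
    pieces[[length(pieces) + 1L]] <- GenomicRanges::GRanges(
      contig[i],
      IRanges::IRanges(c(GenomicRanges::start(gr)[i], 1L),
                       c(L, GenomicRanges::end(gr)[i] - L)))
    idx[[length(idx) + 1L]] <- c(i, i)
  }
  out <- do.call(c, pieces)
  S4Vectors::mcols(out)$igr_index <- unlist(idx)
  out
}
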