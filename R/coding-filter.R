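#' @include svm-enrichment.R
NULL

#' Read a protein-homology hit table (BLAST tabular format)
#'
#' Parses a BLASTX result in tabular format (`-outfmt 6`: qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue
#' bitscore) where the query IDs are IGR IDs and query coordinates are
#' IGR-local, 1-based closed. Minus-frame hits (reported with
#' `qstart > qend`) are flipped so that `start <= end` always holds, and
#' hits weaker than `evalueMax` are dropped. When `igrIds` is given, hits
#' whose query is not among them are skipped with a warning (a hit table
#' may be stale relative to the candidate set).
#'
#' @param path hit table path.
#' @param evalueMax maximum e-value retained.
#' @param igrIds optional character vector of valid IGR IDs.
#' @return a `data.frame` with columns `igr_id`, `start`, `end` (1-based
#'   closed, IGR-local), `subject_id`, `pident`, `evalue`, `bitscore`,
#'   `frame` (`"+"` or `"-"`).
#' @export
readHits <- function(path, evalueMax = 1e-5, igrIds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  if (!any(keep))
    return(data.frame(igr_id = character(), start = integer(),
                      end = integer(), subject_id = character(),
                      pident = numeric(), evalue = numeric(),
                      bitscore = numeric(), frame = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(fields) < 12L
  if (any(bad))
    stop("malformed hit-table line ", which(keep)[which(bad)[1]], " in ",
         path, ": expected 12 tab-separated columns")
  col <- function(i) vapply(fields, `[`, "", i)
  qstart <- as.integer(col(7)); qend <- as.integer(col(8))
  evalue <- as.numeric(col(11))
  if (any(is.na(qstart) | is.na(qend) | is.na(evalue)))
    stop("malformed hit-table line ",
         which(keep)[which(is.na(qstart) | is.na(qend) |
                             is.na(evalue))[1]], " in ", path,
         ": non-numeric coordinates or e-value")
  df <- data.frame(
    igr_id = col(1),
    start = pmin(qstart, qend), end = pmax(qstart, qend),
    subject_id = col(2), pident = as.numeric(col(3)),
    evalue = evalue, bitscore = as.numeric(col(12)),
    frame = ifelse(qstart <= qend, "+", "-"),
    stringsAsFactors = FALSE)
  df <- df[df$evalue <= evalueMax, , drop = FALSE]
  if (!is.null(igrIds)) {
    unknown <- !df$igr_id %in% igrIds
    if (any(unknown)) {
      warning("skipping ", sum(unknown),
              " hit(s) on unknown IGR ID(s): ",
              paste(utils::head(unique(df$igr_id[unknown]), 5),
                    collapse = ", "))
      df <- df[!unknown, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  df
}

#' Remove protein-homology hit intervals from candidate IGRs
#'
#' Implements the coding screen: within each selected IGR, homology hit
#' intervals (optionally expanded by `pad` nucleotides on each side,
#' clamped to the IGR) are merged by union and subtracted; each remaining
#' maximal interval becomes a fragment IGR with recomputed sequence,
#' length and %GC. Fragment IDs append the ordinal (`<igr_id>.1`, ...);
#' an IGR untouched by any hit passes through unchanged under its
#' original ID. Genomic coordinates are preserved by offsetting into the
#' parent interval. An IGR whose hits cover it entirely yields no
#' fragment and thus disappears from the returned set.
#'
#' @param igrs an [IgrSet] (typically the selected candidates).
#' @param hits hit table from [readHits()].
#' @param pad nucleotides added to each side of every hit before merging.
#' @return an [IgrSet] of fragments; `rnaFamilies`, flank context and
#'   selection state are inherited from the parent.
#' @seealso [refilter()]
#' @export
subtractHits <- function(igrs, hits, pad = 0L) {
  stopifnot(is(igrs, "IgrSet"), pad >= 0L)
  if (nrow(hits) == 0L) return(igrs)
  extra <- setdiff(unique(hits$igr_id), igrId(igrs))
  if (length(extra))
    warning("ignoring hits on IGR(s) not in the set: ",
            paste(utils::head(extra, 5), collapse = ", "))
  keepIdx <- integer(); frag <- list(); fragSeq <- list()
  ids <- igrId(igrs)
  mc <- S4Vectors::mcols(igrs@ranges)
  for (i in seq_along(igrs)) {
    h <- hits[hits$igr_id == ids[i], , drop = FALSE]
    L <- Biostrings::width(igrs@seqs)[i]
    if (nrow(h) == 0L) { keepIdx <- c(keepIdx, i); next }
    hr <- IRanges::reduce(IRanges::IRanges(
      pmax(1L, h$start - pad), pmin(L, h$end + pad)))
    gapIR <- IRanges::gaps(hr, start = 1L, end = L)
    if (identical(length(gapIR), 1L) &&
        IRanges::start(gapIR) == 1L && IRanges::end(gapIR) == L) {
      keepIdx <- c(keepIdx, i); next
    }
    for (k in seq_along(gapIR)) {
      s <- IRanges::start(gapIR)[k]; e <- IRanges::end(gapIR)[k]
      frag[[length(frag) + 1L]] <- data.frame(
        parent = i, ordinal = k, local_start = s, local_end = e,
        stringsAsFactors = FALSE)
      fragSeq[[length(fragSeq) + 1L]] <-
        as.character(Biostrings::subseq(igrs@seqs[[i]], s, e))
    }
  }
  pieces <- list(igrs[keepIdx])
  if (length(frag)) {
    fd <- do.call(rbind, frag)
    p <- fd$parent
    gr <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(igrs@ranges))[p],
      IRanges::IRanges(
        GenomicRanges::start(igrs@ranges)[p] + fd$local_start - 1L,
        GenomicRanges::start(igrs@ranges)[p] + fd$local_end - 1L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      igr_id = paste0(ids[p], ".", fd$ordinal),
      upstream_locus = mc$upstream_locus[p],
      upstream_strand = mc$upstream_strand[p],
      downstream_locus = mc$downstream_locus[p],
      downstream_strand = mc$downstream_strand[p],
      terminal = mc$terminal[p], wraps = mc$wraps[p],
      selected = mc$selected[p], decision = rep(NA_real_, nrow(fd)))
    S4Vectors::metadata(gr) <- S4Vectors::metadata(igrs@ranges)
    fragments <- .IgrSet(gr, Biostrings::DNAStringSet(unlist(fragSeq)),
                         igrs@rnaFamilies[p])
    S4Vectors::mcols(fragments@ranges)$selected <- mc$selected[p]
    pieces[[2]] <- fragments
  }
  out <- .bindIgrSets(pieces)
  ord <- order(as.character(GenomicRanges::seqnames(out@ranges)),
               GenomicRanges::start(out@ranges), igrId(out))
  out[ord]
}

.bindIgrSets <- function(sets) {
  sets <- sets[vapply(sets, length, 0L) > 0L]
  if (!length(sets)) return(.emptyIgrSet())
  gr <- do.call(c, lapply(sets, function(s) s@ranges))
  sq <- do.call(c, lapply(sets, function(s) s@seqs))
  fam <- do.call(c, lapply(sets, function(s) as.list(s@rnaFamilies)))
  new("IgrSet", ranges = gr, seqs = sq,
      rnaFamilies = IRanges::CharacterList(fam))
}

.emptyIgrSet <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    igr_id = character(), gc_percent = numeric(),
    upstream_locus = character(), upstream_strand = character(),
    downstream_locus = character(), downstream_strand = character(),
    terminal = logical(), wraps = logical(), selected = logical(),
    decision = numeric())
  new("IgrSet", ranges = gr, seqs = Biostrings::DNAStringSet(),
      rnaFamilies = IRanges::CharacterList())
}

#' Re-apply the selection criteria after coding subtraction
#'
#' A fragment survives only if it is at least `minLength` nucleotides
#' long *and* the genome's trained classifier still gives its
#' (%GC, length) a positive decision value. Surviving fragments replace
#' their parent in the candidate set; when none of an IGR's fragments
#' survive, the parent is discarded in its entirety. The operation is
#' idempotent: a surviving fragment's features do not change, so a second
#' pass removes nothing.
#'
#' @param fragments an [IgrSet] from [subtractHits()].
#' @param model the genome's [IgrClassifier].
#' @param minLength hard minimum fragment length (nt).
#' @return the surviving [IgrSet], decision values refreshed.
#' @export
refilter <- function(fragments, model, minLength = 50L) {
  stopifnot(is(fragments, "IgrSet"), is(model, "IgrClassifier"))
  if (!length(fragments)) return(fragments)
  d <- decisionValues(model, fragments)
  S4Vectors::mcols(fragments@ranges)$decision <- d
  keep <- GenomicRanges::width(fragments@ranges) >= minLength & d > 0
  out <- fragments[which(keep)]
  S4Vectors::mcols(out@ranges)$selected <- rep(TRUE, length(out))
  out
}
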