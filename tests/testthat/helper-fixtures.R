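## Shared builders and independent oracles for the test suite.

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Construct an AnnotatedGenome directly from sequences and a CDS table.
makeGenome <- function(contigs, cds = NULL, rnas = NULL,
                       topology = "linear") {
  seqs <- Biostrings::DNAStringSet(contigs)
  if (is.null(cds) || nrow(cds) == 0L) {
    genes <- GenomicRanges::GRanges()
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      kind = character(), locus_tag = character(), product = character())
  } else {
    if (is.null(cds$kind)) cds$kind <- "CDS"
    if (is.null(cds$strand)) cds$strand <- "+"
    if (is.null(cds$tag)) cds$tag <- paste0("g", seq_len(nrow(cds)))
    cds <- cds[order(cds$contig, cds$start, cds$end), , drop = FALSE]
    genes <- GenomicRanges::GRanges(
      cds$contig, IRanges::IRanges(cds$start, cds$end),
      strand = cds$strand)
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      kind = cds$kind, locus_tag = cds$tag,
      product = rep(NA_character_, nrow(cds)))
  }
  if (is.null(rnas)) {
    rnas <- GenomicRanges::GRanges()
    S4Vectors::mcols(rnas) <- S4Vectors::DataFrame(family = character())
  }
  topo <- rep(topology, length.out = length(seqs))
  names(topo) <- names(seqs)
  new("AnnotatedGenome", sequences = seqs, genes = genes, rnas = rnas,
      topology = topo)
}

## Per-base boolean-mask oracle for IGR extraction on one contig:
## marks every base covered by a CDS and returns the uncovered runs,
## joining the two origin-flanking runs on a circular contig.
maskOracleIgrs <- function(len, starts, ends, circular = FALSE) {
  covered <- logical(len)
  for (i in seq_along(starts))
    covered[starts[i]:ends[i]] <- TRUE
  if (all(covered))
    return(data.frame(start = integer(), end = integer(),
                      wraps = logical()))
  r <- rle(covered)
  runEnd <- cumsum(r$lengths)
  runStart <- runEnd - r$lengths + 1L
  free <- which(!r$values)
  out <- data.frame(start = runStart[free], end = runEnd[free],
                    wraps = FALSE)
  if (circular && any(covered) &&
      nrow(out) >= 2L && out$start[1] == 1L && out$end[nrow(out)] == len) {
    joined <- data.frame(start = out$start[nrow(out)],
                         end = len + out$end[1], wraps = TRUE)
    out <- rbind(out[-c(1L, nrow(out)), , drop = FALSE], joined)
    out <- out[order(out$start), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

## Per-base mask oracle for hit subtraction within a local interval.
maskOracleSubtract <- function(len, starts, ends, pad = 0L) {
  hit <- logical(len)
  for (i in seq_along(starts)) {
    s <- max(1L, starts[i] - pad)
    e <- min(len, ends[i] + pad)
    hit[s:e] <- TRUE
  }
  if (all(hit)) return(data.frame(start = integer(), end = integer()))
  r <- rle(hit)
  runEnd <- cumsum(r$lengths)
  runStart <- runEnd - r$lengths + 1L
  free <- which(!r$values)
  data.frame(start = runStart[free], end = runEnd[free])
}

## Naive two-pass GC oracle.
naiveGc <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

## Build an IgrSet directly from target features: each IGR's sequence is
## an unshuffled run of G then A realizing the requested GC% and length.
makeFeatureIgrs <- function(gc, len, labeled = rep(FALSE, length(gc)),
                            family = "KNOWN") {
  n <- length(gc)
  stopifnot(length(len) == n, length(labeled) == n)
  ngc <- round(gc / 100 * len)
  seqs <- vapply(seq_len(n), function(i)
    paste0(strrep("G", ngc[i]), strrep("A", len[i] - ngc[i])), "")
  starts <- cumsum(c(1L, utils::head(len + 10L, -1L)))
  gr <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(starts, width = len))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    igr_id = paste0("chrT_", starts),
    upstream_locus = ".", upstream_strand = ".",
    downstream_locus = ".", downstream_strand = ".",
    terminal = FALSE, wraps = FALSE, selected = FALSE,
    decision = NA_real_)
  fams <- lapply(labeled, function(l) if (l) family else character())
  igrsieve:::.IgrSet(gr, Biostrings::DNAStringSet(seqs),
                     IRanges::CharacterList(fams))
}

## Randomized-arrangement extraction check: each case is one contig of a
## shared genome (random gene count, lengths, overlaps, either topology),
## so a single extractIgrs() call exercises all of them; the per-base
## mask oracle and the length-conservation identity run per contig.
## Returns the number of disagreeing cases.
extractionOracleMismatches <- function(nCases, seed) {
  set.seed(seed)
  cases <- lapply(seq_len(nCases), function(case) {
    len <- sample(200:2000, 1)
    n <- sample(1:8, 1)
    starts <- sort(sample(seq_len(len), n, replace = TRUE))
    list(contig = sprintf("case%04d", case), len = len, starts = starts,
         ends = pmin(len, starts + sample(10:400, n, replace = TRUE)),
         circular = runif(1) < 0.5)
  })
  contigs <- vapply(cases, function(cs) randSeq(cs$len), "")
  names(contigs) <- vapply(cases, `[[`, "", "contig")
  cds <- do.call(rbind, lapply(cases, function(cs)
    data.frame(contig = cs$contig, start = cs$starts, end = cs$ends)))
  topo <- ifelse(vapply(cases, `[[`, TRUE, "circular"),
                 "circular", "linear")
  names(topo) <- names(contigs)
  gnm <- makeGenome(contigs, cds, topology = topo)
  got <- as.data.frame(extractIgrs(gnm))
  gotByContig <- split(got, got$contig)
  mismatches <- 0L
  for (cs in cases) {
    g <- gotByContig[[cs$contig]]
    if (is.null(g)) g <- got[0, , drop = FALSE]
    want <- maskOracleIgrs(cs$len, cs$starts, cs$ends, cs$circular)
    if (!identical(unname(g$start), want$start) ||
        !identical(unname(g$end), want$end) ||
        !identical(unname(g$wraps), want$wraps))
      mismatches <- mismatches + 1L
    merged <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(cs$starts, cs$ends))))
    if (merged + sum(g$length) != cs$len) mismatches <- mismatches + 1L
  }
  mismatches
}

## Randomized hit-subtraction check against the per-base mask oracle.
## All cases share one IgrSet and one subtractHits() call; each case has
## its own pad, applied by running pads in batches. Hits are generated
## through simulateHits()/readHits(), so minus-frame normalization is
## exercised on the way in. Returns the number of disagreeing cases.
subtractionOracleMismatches <- function(nCases, seed) {
  set.seed(seed)
  L <- sample(60:600, nCases, replace = TRUE)
  pads <- sample(0:15, nCases, replace = TRUE)
  igrs <- makeFeatureIgrs(rep(50, nCases), L)
  ids <- igrId(igrs)
  reqs <- do.call(rbind, lapply(seq_len(nCases), function(i) {
    n <- sample(1:5, 1)
    s <- sample(seq_len(L[i]), n, replace = TRUE)
    data.frame(igr_id = ids[i], start = s,
               end = pmin(L[i], s + sample(5:120, n, replace = TRUE)),
               minus = runif(n) < 0.3)
  }))
  hitPath <- tempfile(fileext = ".tsv")
  on.exit(unlink(hitPath))
  simulateHits(reqs, hitPath)
  hits <- readHits(hitPath)
  mismatches <- 0L
  g0 <- GenomicRanges::start(igrRanges(igrs))
  names(g0) <- ids
  for (pad in unique(pads)) {
    inBatch <- ids[pads == pad]
    sub <- igrs[inBatch]
    frags <- as.data.frame(subtractHits(
      sub, hits[hits$igr_id %in% inBatch, , drop = FALSE], pad = pad))
    parent <- sub("\\.[0-9]+$", "", frags$igr_id)
    for (id in inBatch) {
      i <- match(id, ids)
      f <- frags[parent == id, , drop = FALSE]
      h <- reqs[reqs$igr_id == id, , drop = FALSE]
      want <- maskOracleSubtract(L[i], h$start, h$end, pad)
      ok <- identical(unname(f$start) - g0[[id]] + 1L, want$start) &&
        identical(unname(f$end) - g0[[id]] + 1L, want$end)
      cover <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(
        pmax(1L, h$start - pad), pmin(L[i], h$end + pad)))))
      if (!ok || cover + sum(f$length) != L[i])
        mismatches <- mismatches + 1L
    }
  }
  mismatches
}

## Two well-separated Gaussian clusters in (%GC, length) feature space.
plantedClusterIgrs <- function(nPos = 30L, nNeg = 300L, seed = 1L,
                               posGc = 55, negGc = 32, posLen = 260,
                               negLen = 120) {
  set.seed(seed)
  gc <- pmin(95, pmax(5, c(rnorm(nPos, posGc, 4), rnorm(nNeg, negGc, 5))))
  len <- pmax(30L, as.integer(round(c(rnorm(nPos, posLen, 40),
                                      rnorm(nNeg, negLen, 40)))))
  makeFeatureIgrs(gc, len, labeled = c(rep(TRUE, nPos), rep(FALSE, nNeg)))
}

## A small, fast simulator configuration for interface-level tests.
quickSimConfig <- function(seed = 1L, ...) {
  simConfig(seed = seed, nContigs = 1L, nGenesPerContig = 61L,
            geneLengthRange = c(150L, 350L), nPlantedRna = 16L, ...)
}
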