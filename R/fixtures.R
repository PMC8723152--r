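#' @include motif-prep.R
NULL

#' Construct a simulator configuration
#'
#' Returns a [SimConfig] describing the synthetic study conditions: three
#' contigs tiled as gene/IGR blocks, ~50% GC protein-coding genes,
#' AT-rich background IGRs (32% GC, ~120 nt), and 60 planted
#' structured-RNA IGRs whose embedded RNA segment is GC-rich (55%) and
#' long (~220 nt), half of them emitted as known (labeled) families and
#' half left unannotated as discoverable candidates. Under these defaults
#' the background and planted clusters sit well over four pooled standard
#' deviations apart in (%GC, length) space — the "strong separation"
#' regime in which the GC/length enrichment approach is applicable; see
#' [separationMetric()].
#'
#' @param seed RNG seed; every downstream file is reproducible from it.
#' @param ... any [SimConfig] slot to override, by name.
#' @return a validated [SimConfig].
#' @examples
#' cfg <- simConfig(seed = 42, nPlantedRna = 10L, nGenesPerContig = 30L)
#' separationMetric(cfg)
#' @export
simConfig <- function(seed = 1L, ...) {
  cfg <- new("SimConfig",
    seed = as.integer(seed),
    nContigs = 3L,
    nGenesPerContig = 121L,
    geneLengthRange = c(300L, 900L),
    codingGcMean = 50, codingGcSd = 3,
    bgIgrLengthMean = 120, bgIgrLengthSd = 50,
    bgIgrGcMean = 32, bgIgrGcSd = 5,
    nPlantedRna = 60L,
    rnaGcMean = 55, rnaGcSd = 4,
    rnaLengthMean = 220, rnaLengthSd = 40,
    fractionLabeled = 0.5,
    topology = "linear")
  dots <- list(...)
  intSlots <- c("nContigs", "nGenesPerContig", "geneLengthRange",
                "nPlantedRna")
  for (nm in names(dots)) {
    value <- if (nm %in% intSlots) as.integer(dots[[nm]]) else dots[[nm]]
    methods::slot(cfg, nm) <- value
  }
  validObject(cfg)
  cfg
}

#' Background-versus-planted cluster separation implied by a SimConfig
#'
#' Computes the Mahalanobis distance (diagonal pooled covariance) between
#' the background-IGR and planted-IGR cluster centres in (%GC, length)
#' feature space. Means and variances account for the short background
#' flanks around each planted RNA segment and for the per-base binomial
#' sampling noise of realized GC content, so the value predicts the
#' separation actually observed in simulated data.
#'
#' @param config a [SimConfig].
#' @return a single number (pooled standard deviations).
#' @export
separationMetric <- function(config) {
  stopifnot(is(config, "SimConfig"))
  flankTotal <- 40                       # two U(10,30) flanks, mean 20 each
  pLen <- config@rnaLengthMean + flankTotal
  pGc <- (config@rnaLengthMean * config@rnaGcMean +
            flankTotal * config@bgIgrGcMean) / pLen
  binomVar <- function(gc, L) (gc / 100) * (1 - gc / 100) / L * 1e4
  vGcBg <- config@bgIgrGcSd^2 + binomVar(config@bgIgrGcMean,
                                         config@bgIgrLengthMean)
  vGcP <- config@rnaGcSd^2 + binomVar(pGc, pLen)
  vLenBg <- config@bgIgrLengthSd^2
  vLenP <- config@rnaLengthSd^2 + 2 * (20^2 / 12)
  dGc <- (pGc - config@bgIgrGcMean)^2 / ((vGcBg + vGcP) / 2)
  dLen <- (pLen - config@bgIgrLengthMean)^2 / ((vLenBg + vLenP) / 2)
  sqrt(dGc + dLen)
}

## Draw a nucleotide string of length L with per-base GC probability p.
.drawSeq <- function(L, p) {
  gc <- stats::runif(L) < p
  half <- stats::runif(L) < 0.5
  paste(ifelse(gc, ifelse(half, "G", "C"), ifelse(half, "A", "T")),
        collapse = "")
}

.truncNorm <- function(n, mean, sd, lower, upper = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}

#' Simulate a synthetic genome with known ground truth
#'
#' Writes a complete, self-consistent input set for the pipeline: a
#' multi-contig FASTA, a GFF3 of protein-coding genes, a BED of the
#' labeled planted RNAs (families `SYN_k`), and a truth table listing
#' every planted RNA IGR — labeled or not — with its coordinates. Each
#' contig alternates gene and IGR blocks; gene sequences are drawn with
#' per-base GC probability from the coding distribution, background IGRs
#' from the background distribution, and planted IGRs consist of a
#' GC-rich RNA segment flanked by two short (10-30 nt) background-
#' composition spacers. Output is byte-reproducible from `config@seed`.
#'
#' @param config a [SimConfig].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the four file `paths`, the planted-RNA
#'   `truth` data.frame, and a `layout` data.frame describing every gene
#'   and IGR block (column `type`: `gene`, `background`, `planted`).
#' @export
simulateGenome <- function(config, dir) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  set.seed(config@seed)

  nSlots <- (config@nGenesPerContig - 1L) * config@nContigs
  planted <- sort(sample.int(nSlots, config@nPlantedRna))
  nLab <- round(config@fractionLabeled * config@nPlantedRna)
  labeled <- sort(sample(planted, nLab))

  contigs <- character(config@nContigs)
  layout <- list(); truth <- list(); gff <- character(); bed <- character()
  slot <- 0L; rnaIdx <- 0L
  for (ci in seq_len(config@nContigs)) {
    contig <- sprintf("ctg%02d", ci)
    pos <- 1L
    blocks <- character()
    for (gi in seq_len(config@nGenesPerContig)) {
      gLen <- sample(config@geneLengthRange[1]:config@geneLengthRange[2], 1L)
      gGc <- .truncNorm(1L, config@codingGcMean, config@codingGcSd, 5, 95)
      gSeq <- .drawSeq(gLen, gGc / 100)
      tag <- sprintf("%s_g%03d", contig, gi)
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      gff <- c(gff, paste(contig, "igrsieve-sim", "CDS", pos,
                          pos + gLen - 1L, ".", strand, "0",
                          paste0("ID=", tag, ";locus_tag=", tag),
                          sep = "\t"))
      layout[[length(layout) + 1L]] <- data.frame(
        contig = contig, start = pos, end = pos + gLen - 1L,
        type = "gene", id = tag, stringsAsFactors = FALSE)
      blocks <- c(blocks, gSeq)
      pos <- pos + gLen
      if (gi == config@nGenesPerContig) break
      slot <- slot + 1L
      if (slot %in% planted) {
        rnaIdx <- rnaIdx + 1L
        fam <- sprintf("SYN_%03d", rnaIdx)
        fl <- sample(10:30, 2L, replace = TRUE)
        rLen <- as.integer(round(.truncNorm(1L, config@rnaLengthMean,
                                            config@rnaLengthSd, 60)))
        rGc <- .truncNorm(1L, config@rnaGcMean, config@rnaGcSd, 1, 99)
        fGc <- .truncNorm(2L, config@bgIgrGcMean, config@bgIgrGcSd, 1, 99)
        iSeq <- paste0(.drawSeq(fl[1], fGc[1] / 100),
                       .drawSeq(rLen, rGc / 100),
                       .drawSeq(fl[2], fGc[2] / 100))
        iLen <- fl[1] + rLen + fl[2]
        rnaStart <- pos + fl[1]
        rnaEnd <- rnaStart + rLen - 1L
        isLab <- slot %in% labeled
        if (isLab)
          bed <- c(bed, paste(contig, rnaStart - 1L, rnaEnd, fam, "0",
                              "+", sep = "\t"))
        truth[[length(truth) + 1L]] <- data.frame(
          family = fam, contig = contig, igr_id = paste0(contig, "_", pos),
          igr_start = pos, igr_end = pos + iLen - 1L,
          rna_start = rnaStart, rna_end = rnaEnd, labeled = isLab,
          stringsAsFactors = FALSE)
        type <- "planted"; id <- fam
      } else {
        iLen <- as.integer(round(.truncNorm(1L, config@bgIgrLengthMean,
                                            config@bgIgrLengthSd, 30)))
        iGc <- .truncNorm(1L, config@bgIgrGcMean, config@bgIgrGcSd, 1, 99)
        iSeq <- .drawSeq(iLen, iGc / 100)
        type <- "background"; id <- paste0(contig, "_", pos)
      }
      layout[[length(layout) + 1L]] <- data.frame(
        contig = contig, start = pos, end = pos + iLen - 1L,
        type = type, id = id, stringsAsFactors = FALSE)
      blocks <- c(blocks, iSeq)
      pos <- pos + iLen
    }
    contigs[ci] <- paste(blocks, collapse = "")
  }

  paths <- list(fasta = file.path(dir, "genome.fasta"),
                gff3 = file.path(dir, "genes.gff3"),
                bed = file.path(dir, "known_rnas.bed"),
                truth = file.path(dir, "truth.tsv"))
  seqs <- Biostrings::DNAStringSet(contigs)
  names(seqs) <- sprintf("ctg%02d synthetic contig", seq_len(config@nContigs))
  Biostrings::writeXStringSet(seqs, paths$fasta, width = 70L)
  writeLines(c("##gff-version 3", gff), paths$gff3)
  writeLines(bed, paths$bed)
  truthDf <- do.call(rbind, truth)
  utils::write.table(truthDf, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, truth = truthDf,
                 layout = do.call(rbind, layout)))
}

#' Fabricate a protein-homology hit table
#'
#' Turns requested hit intervals into BLAST tabular (`-outfmt 6`) rows for
#' exercising [readHits()] and [subtractHits()] without running a real
#' search. Coordinates are IGR-local and 1-based closed; rows requested
#' with `minus = TRUE` are written with swapped query coordinates, the way
#' a minus-frame translated hit is reported.
#'
#' @param requests a data.frame with columns `igr_id`, `start`, `end`,
#'   and optionally `evalue` (default 1e-30), `minus` (default FALSE) and
#'   `subject` (default `"synthetic_protein"`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
simulateHits <- function(requests, path) {
  stopifnot(all(c("igr_id", "start", "end") %in% names(requests)))
  n <- nrow(requests)
  evalue <- if ("evalue" %in% names(requests)) requests$evalue
            else rep(1e-30, n)
  minus <- if ("minus" %in% names(requests)) requests$minus
           else rep(FALSE, n)
  subject <- if ("subject" %in% names(requests)) requests$subject
             else rep("synthetic_protein", n)
  qs <- ifelse(minus, requests$end, requests$start)
  qe <- ifelse(minus, requests$start, requests$end)
  aa <- pmax(1L, (requests$end - requests$start + 1L) %/% 3L)
  rows <- paste(requests$igr_id, subject, "40.0", aa, "0", "0",
                qs, qe, "1", aa, format(evalue, scientific = TRUE),
                "100.0", sep = "\t")
  writeLines(rows, path)
  invisible(path)
}
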