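#' @include igr-set.R
NULL

#' Read a genome assembly and its gene annotations
#'
#' Loads contig sequences from a (multi-)FASTA file and protein-coding gene
#' annotations from either a GFF3 file or a GenBank flat file, returning an
#' [AnnotatedGenome]. Contig identity is the first whitespace-delimited
#' token of the FASTA header; annotation contig IDs must resolve against
#' those tokens. Sequences are upper-cased on ingest. Features whose type
#' is `CDS` get `kind = "CDS"` and are the only features that later delimit
#' intergenic regions; all other types (tRNA, rRNA, ncRNA, `gene`, ...) get
#' `kind = "other"`.
#'
#' For GenBank input the per-record topology (`circular` on the LOCUS line)
#' is honoured; otherwise contigs default to `topology`, which may be a
#' single value or a named per-contig vector.
#'
#' @param fastaPath path to the genome FASTA.
#' @param annotationPath path to the annotation file.
#' @param format `"gff3"` or `"genbank"`.
#' @param topology default contig topology, `"linear"` or `"circular"`;
#'   a named vector overrides per contig.
#' @return an [AnnotatedGenome] with features sorted by
#'   (contig, start, end). Known-RNA annotations start empty; attach them
#'   with [readRnaAnnotations()].
#' @seealso [extractIgrs()]
#' @export
readGenome <- function(fastaPath, annotationPath,
                       format = c("gff3", "genbank"),
                       topology = "linear") {
  format <- match.arg(format)
  for (p in c(fastaPath, annotationPath))
    if (!file.exists(p)) stop("file not found: ", p)
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig IDs in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))

  gbTopology <- NULL
  if (format == "gff3") {
    genes <- .readGff3Features(annotationPath)
  } else {
    gb <- .parseGenBank(annotationPath)
    genes <- gb$features
    gbTopology <- gb$topology
  }

  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(genes))),
                 names(seqs))
  if (length(bad))
    stop("annotation contig ID(s) absent from FASTA: ",
         paste(bad, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  over <- GenomicRanges::end(genes) >
    lens[as.character(GenomicRanges::seqnames(genes))]
  if (any(over))
    stop("feature end beyond contig length for: ",
         paste(utils::head(S4Vectors::mcols(genes)$locus_tag[over], 5),
               collapse = ", "))

  topo <- rep(topology[[1]], length(seqs))
  names(topo) <- names(seqs)
  if (!is.null(names(topology)))
    topo[names(topology)] <- topology
  if (!is.null(gbTopology)) {
    known <- intersect(names(gbTopology), names(topo))
    topo[known] <- gbTopology[known]
  }

  genes <- genes[order(as.character(GenomicRanges::seqnames(genes)),
                       GenomicRanges::start(genes),
                       GenomicRanges::end(genes))]
  new("AnnotatedGenome", sequences = seqs, genes = genes,
      rnas = GenomicRanges::GRanges(family = character()), topology = topo)
}

.readGff3Features <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 8))
    stop("malformed GFF3 line ", which(body)[which(nfield < 8)[1]],
         " in ", path, ": expected >= 8 tab-separated fields")
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  locus <- if ("locus_tag" %in% colnames(mc)) mc$locus_tag else mc$ID
  if (is.null(locus)) locus <- rep(NA_character_, length(gr))
  prod <- if ("product" %in% colnames(mc)) mc$product
          else rep(NA_character_, length(gr))
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)),
    strand = GenomicRanges::strand(gr)
  )
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    kind = ifelse(as.character(mc$type) == "CDS", "CDS", "other"),
    locus_tag = as.character(locus),
    product = as.character(prod)
  )
  out
}

## Minimal GenBank flat-file reader: LOCUS name/length/topology, the
## feature table (key, location, /locus_tag, /product) and nothing else.
## Compound locations (join, complement) are flattened to their envelope.
.parseGenBank <- function(path) {
  lines <- readLines(path)
  locusAt <- grep("^LOCUS", lines)
  if (!length(locusAt)) stop("no LOCUS line in GenBank file: ", path)
  ends <- c(locusAt[-1] - 1L, length(lines))
  feats <- list(); topo <- character()
  for (r in seq_along(locusAt)) {
    rec <- lines[locusAt[r]:ends[r]]
    loc <- strsplit(trimws(rec[1]), "\\s+")[[1]]
    contig <- loc[2]
    topo[contig] <- if ("circular" %in% loc) "circular" else "linear"
    fStart <- grep("^FEATURES", rec)
    if (!length(fStart)) next
    fEnd <- grep("^(ORIGIN|CONTIG|//)", rec)
    fEnd <- if (length(fEnd)) min(fEnd[fEnd > fStart]) - 1L else length(rec)
    ftab <- rec[(fStart + 1L):fEnd]
    isKey <- grepl("^ {5}\\S", ftab)
    keyIdx <- which(isKey)
    if (!length(keyIdx)) next
    blockEnd <- c(keyIdx[-1] - 1L, length(ftab))
    for (b in seq_along(keyIdx)) {
      block <- ftab[keyIdx[b]:blockEnd[b]]
      head <- strsplit(trimws(block[1]), "\\s+")[[1]]
      key <- head[1]
      if (key == "source") next
      qualAt <- grep("^\\s+/", block)
      locEnd <- if (length(qualAt)) qualAt[1] - 1L else length(block)
      locStr <- paste(c(head[-1], trimws(block[seq_len(locEnd)][-1])),
                      collapse = "")
      pos <- as.integer(unlist(regmatches(locStr,
                                          gregexpr("[0-9]+", locStr))))
      if (!length(pos)) next
      qual <- function(name) {
        m <- regmatches(block, regexpr(paste0("/", name,
                                              "=\"?[^\"]*"), block))
        if (!length(m)) return(NA_character_)
        sub(paste0("/", name, "=\"?"), "", m[1])
      }
      feats[[length(feats) + 1L]] <- data.frame(
        contig = contig, start = min(pos), end = max(pos),
        strand = if (grepl("complement", locStr)) "-" else "+",
        kind = if (key == "CDS") "CDS" else "other",
        locus_tag = qual("locus_tag"), product = qual("product"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(feats)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      kind = character(), locus_tag = character(), product = character())
    return(list(features = gr, topology = topo))
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    kind = df$kind, locus_tag = df$locus_tag, product = df$product)
  list(features = gr, topology = topo)
}

#' Read known structured-RNA annotations
#'
#' Parses Rfam-style RNA annotations from BED (0-based half-open, family in
#' the name column) or GFF3 (1-based closed, family from a configurable
#' attribute, default `Name`) into a `GRanges` with a `family` metadata
#' column, sorted by (contig, start). When `genome` is supplied the
#' annotations are validated against it and attached, and the updated
#' [AnnotatedGenome] is returned instead.
#'
#' An empty file yields an empty result: a genome with no known RNAs is
#' readable, but classifier training will fail downstream for lack of
#' positive labels.
#'
#' @param path annotation file.
#' @param format `"bed"` or `"gff3"`.
#' @param nameAttribute GFF3 attribute holding the family name.
#' @param genome optional [AnnotatedGenome] for contig validation.
#' @return `GRanges` with `family`, or the updated `genome`.
#' @export
readRnaAnnotations <- function(path, format = c("bed", "gff3"),
                               nameAttribute = "Name", genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  if (!any(keep)) {
    rnas <- GenomicRanges::GRanges()
    S4Vectors::mcols(rnas) <- S4Vectors::DataFrame(family = character())
  } else if (format == "bed") {
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    short <- lengths(fields) < 4L
    if (any(short))
      stop("malformed BED line ", which(keep)[which(short)[1]], " in ",
           path, ": need at least 4 columns (chrom, start, end, name)")
    df <- data.frame(
      contig = vapply(fields, `[`, "", 1L),
      start0 = suppressWarnings(as.integer(vapply(fields, `[`, "", 2L))),
      end = suppressWarnings(as.integer(vapply(fields, `[`, "", 3L))),
      family = vapply(fields, `[`, "", 4L),
      strand = vapply(fields, function(f)
        if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "*", ""),
      stringsAsFactors = FALSE
    )
    bad <- is.na(df$start0) | is.na(df$end) | df$start0 < 0 |
      df$end <= df$start0
    if (any(bad))
      stop("malformed BED line ", which(keep)[which(bad)[1]], " in ", path,
           ": invalid coordinates")
    rnas <- GenomicRanges::GRanges(
      df$contig, IRanges::IRanges(df$start0 + 1L, df$end),
      strand = df$strand)
    S4Vectors::mcols(rnas) <- S4Vectors::DataFrame(family = df$family)
  } else {
    nfield <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
    if (any(nfield < 8))
      stop("malformed GFF3 line ", which(keep)[which(nfield < 8)[1]],
           " in ", path)
    gr <- rtracklayer::import(path, format = "gff3")
    fam <- S4Vectors::mcols(gr)[[nameAttribute]]
    if (is.null(fam))
      stop("GFF3 attribute '", nameAttribute, "' not present in ", path)
    rnas <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr),
      IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)),
      strand = GenomicRanges::strand(gr))
    S4Vectors::mcols(rnas) <- S4Vectors::DataFrame(family = as.character(fam))
  }
  rnas <- rnas[order(as.character(GenomicRanges::seqnames(rnas)),
                     GenomicRanges::start(rnas))]
  if (is.null(genome)) return(rnas)
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(rnas))),
                 names(genome@sequences))
  if (length(bad))
    stop("RNA annotation contig ID(s) absent from genome: ",
         paste(bad, collapse = ", "))
  genome@rnas <- rnas
  validObject(genome)
  genome
}

#' Write and re-read the IGR table
#'
#' Persists an [IgrSet] as a TSV with 1-based closed coordinates; the
#' companion FASTA (see [writeCandidateFasta()]) carries the sequences, so
#' the pair is sufficient to reconstruct the set.
#'
#' @param igrs an [IgrSet].
#' @param path output TSV path.
#' @return `writeIgrTable` returns `path` invisibly; `readIgrTable`
#'   returns an [IgrSet].
#' @export
writeIgrTable <- function(igrs, path) {
  df <- as.data.frame(igrs)
  df$gc_percent <- sprintf("%.6f", df$gc_percent)
  df$decision <- ifelse(is.na(df$decision), "NA",
                        sprintf("%.10g", df$decision))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeIgrTable
#' @param fastaPath FASTA holding the sequences of every IGR in the table,
#'   as written by [writeCandidateFasta()].
#' @export
readIgrTable <- function(path, fastaPath) {
  for (p in c(path, fastaPath))
    if (!file.exists(p)) stop("file not found: ", p)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = list(rna_families = "character",
                                            upstream_locus = "character",
                                            downstream_locus = "character"))
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  miss <- setdiff(df$igr_id, names(seqs))
  if (length(miss))
    stop("IGR(s) in table missing from FASTA: ",
         paste(utils::head(miss, 5), collapse = ", "))
  seqs <- seqs[df$igr_id]
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    igr_id = df$igr_id,
    upstream_locus = df$upstream_locus,
    upstream_strand = df$upstream_strand,
    downstream_locus = df$downstream_locus,
    downstream_strand = df$downstream_strand,
    terminal = df$terminal, wraps = df$wraps,
    selected = df$selected, decision = as.numeric(df$decision)
  )
  fams <- strsplit(df$rna_families, ",", fixed = TRUE)
  fams[is.na(df$rna_families) | df$rna_families == ""] <- list(character())
  out <- .IgrSet(gr, seqs, IRanges::CharacterList(fams))
  S4Vectors::mcols(out@ranges)$decision <- as.numeric(df$decision)
  S4Vectors::mcols(out@ranges)$selected <- df$selected
  out
}

#' Write features or IGRs as GFF3
#'
#' `writeFeatureGff3` emits the gene features of an [AnnotatedGenome];
#' `writeIgrGff3` emits IGR intervals (type `intergenic_region`). Both use
#' GFF3's native 1-based closed convention, so coordinates round-trip
#' exactly through [readGenome()].
#'
#' @param genome an [AnnotatedGenome].
#' @param igrs an [IgrSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureGff3 <- function(genome, path) {
  g <- genome@genes
  mc <- S4Vectors::mcols(g)
  type <- ifelse(mc$kind == "CDS", "CDS", "gene")
  attrs <- paste0("ID=", mc$locus_tag, ";locus_tag=", mc$locus_tag)
  hasProd <- !is.na(mc$product)
  attrs[hasProd] <- paste0(attrs[hasProd], ";product=", mc$product[hasProd])
  writeLines(c("##gff-version 3",
               paste(as.character(GenomicRanges::seqnames(g)), "igrsieve",
                     type, GenomicRanges::start(g), GenomicRanges::end(g),
                     ".", as.character(GenomicRanges::strand(g)), ".",
                     attrs, sep = "\t")), path)
  invisible(path)
}

#' @rdname writeFeatureGff3
#' @export
writeIgrGff3 <- function(igrs, path) {
  df <- as.data.frame(igrs)
  attrs <- paste0("ID=", df$igr_id, ";gc_percent=",
                  sprintf("%.1f", as.numeric(df$gc_percent)),
                  ";selected=", tolower(df$selected))
  has <- nzchar(df$rna_families)
  attrs[has] <- paste0(attrs[has], ";rna_families=", df$rna_families[has])
  writeLines(c("##gff-version 3",
               paste(df$contig, "igrsieve", "intergenic_region",
                     df$start, df$end, ".", ".", ".", attrs, sep = "\t")),
             path)
  invisible(path)
}
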