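#' @include coding-filter.R
NULL

#' Collapse candidates with identical nucleotide sequences
#'
#' Exact, case-insensitive duplicate sequences are collapsed to a single
#' representative before homology search, since identical queries yield
#' identical draft motifs. The survivor of each duplicate group is the
#' lexicographically smallest ID — an arbitrary but deterministic rule.
#' Reverse-complement duplicates are not collapsed unless
#' `revcomp = TRUE`.
#'
#' @param x an [IgrSet], a named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param revcomp also collapse reverse-complement duplicates (the
#'   survivor keeps its own orientation).
#' @return a list with `kept` (same class as `x`, duplicates removed) and
#'   `mapping` (named character vector, removed ID -> kept ID; empty when
#'   nothing was collapsed).
#' @export
dedupIdentical <- function(x, revcomp = FALSE) {
  if (is(x, "IgrSet")) {
    seqs <- stats::setNames(as.character(x@seqs), igrId(x))
  } else if (is(x, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(x), names(x))
  } else seqs <- x
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique IDs")
  up <- toupper(seqs)
  key <- up
  if (revcomp) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(up)))
    key <- pmin(up, rc)
  }
  groups <- split(names(seqs), key)
  keepIds <- sort(vapply(groups, function(ids) min(ids), ""))
  mapping <- character()
  for (ids in groups) {
    if (length(ids) > 1L) {
      srv <- min(ids)
      dropped <- setdiff(ids, srv)
      mapping[dropped] <- srv
    }
  }
  keepIds <- names(seqs)[names(seqs) %in% keepIds]  # original order
  kept <- if (is(x, "IgrSet") || is(x, "DNAStringSet")) x[keepIds]
          else seqs[keepIds]
  list(kept = kept, mapping = mapping)
}

#' Write candidate IGRs as FASTA
#'
#' Headers carry the candidate's provenance:
#' `>{igr_id} contig={contig} coords={start}-{end} gc={gc} len={length}`
#' with 1-based closed coordinates and GC rounded to one decimal place.
#'
#' @param igrs an [IgrSet].
#' @param path output FASTA path.
#' @param lineWidth sequence wrap width.
#' @return `path`, invisibly.
#' @export
writeCandidateFasta <- function(igrs, path, lineWidth = 60L) {
  df <- as.data.frame(igrs)
  out <- igrs@seqs
  names(out) <- sprintf("%s contig=%s coords=%d-%d gc=%.1f len=%d",
                        df$igr_id, df$contig, df$start, df$end,
                        as.numeric(df$gc_percent), df$length)
  Biostrings::writeXStringSet(out, path, width = lineWidth)
  invisible(path)
}

#' Package candidates into a portable homology-search bundle
#'
#' Builds a `.tar.gz` archive ready for hand-off to a compute cluster:
#' one FASTA per candidate IGR (each candidate seeds an independent
#' homology search), a shell-script template with `{DB}`, `{CPUS}` and
#' `{EVALUE}` placeholders (substituted from `templateConfig` where
#' provided, left verbatim otherwise), and a TSV manifest of member
#' metadata. The scripts are inert templates: nothing in this package
#' executes them. Member order is sorted and file mtimes fixed, so
#' identical inputs produce byte-identical archives.
#'
#' @param igrs a non-empty [IgrSet] of final candidates.
#' @param outPath output archive path (`.tar.gz`).
#' @param templateConfig named list/character of placeholder values, e.g.
#'   `list(EVALUE = "1e-5", CPUS = "8")`.
#' @param bundleId identifier recorded in the manifest; defaults to the
#'   archive basename.
#' @return a [SearchBundle].
#' @export
exportBundle <- function(igrs, outPath, templateConfig = list(),
                         bundleId = NULL) {
  stopifnot(is(igrs, "IgrSet"))
  if (!length(igrs)) stop("cannot export an empty candidate set")
  if (is.null(bundleId))
    bundleId <- sub("\\.tar\\.gz$", "", basename(outPath))
  staging <- file.path(tempfile("bundle"), bundleId)
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(dirname(staging), recursive = TRUE), add = TRUE)

  df <- as.data.frame(igrs)
  ord <- order(df$igr_id)
  df <- df[ord, , drop = FALSE]
  igrs <- igrs[df$igr_id]
  fastaNames <- paste0(gsub("[^A-Za-z0-9._-]", "_", df$igr_id), ".fasta")
  for (i in seq_len(nrow(df)))
    writeCandidateFasta(igrs[i], file.path(staging, fastaNames[i]))

  template <- readLines(system.file("templates", "search_template.sh",
                                    package = "igrsieve", mustWork = TRUE))
  for (key in names(templateConfig))
    template <- gsub(paste0("{", key, "}"),
                     as.character(templateConfig[[key]]),
                     template, fixed = TRUE)
  writeLines(template, file.path(staging, "run_search.sh"))

  manifest <- data.frame(
    bundle_id = bundleId, igr_id = df$igr_id, fasta = fastaNames,
    contig = df$contig, start = df$start, end = df$end,
    length = df$length, gc_percent = sprintf("%.1f", df$gc_percent),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(staging, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  members <- c(sort(fastaNames), "manifest.tsv", "run_search.sh")
  epoch <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  for (m in c(".", members))
    Sys.setFileTime(file.path(staging, m), epoch)
  owd <- setwd(dirname(staging))
  on.exit(setwd(owd), add = TRUE, after = FALSE)
  outPath <- if (grepl("^(/|~)", outPath)) outPath
             else file.path(owd, outPath)
  utils::tar(outPath, file.path(bundleId, members), tar = "internal",
             compression = "gzip")
  new("SearchBundle", bundleId = bundleId, path = outPath,
      manifest = manifest)
}
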