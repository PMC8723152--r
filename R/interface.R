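#' @include fixtures.R
NULL

.CONFIG_DEFAULTS <- list(
  fasta = NULL, annotation = NULL, annotation_format = "gff3",
  rna = NULL, rna_format = "bed", rna_name_attribute = "Name",
  topology = "linear", drop_terminal = FALSE,
  min_overlap_fraction = 0.5,
  C = 1.0, gamma_mode = "auto", gamma = 0.5, w = 1.0,
  min_positives = 5L, log_length = FALSE,
  hits = NULL, evalue_max = 1e-5, min_fragment_length = 50L, hit_pad = 0L,
  dedup_revcomp = FALSE,
  seed = 1L, outdir = "igrsieve_out", sim = list())

#' Assemble a pipeline run configuration
#'
#' Merges, in increasing precedence: the documented defaults, an optional
#' YAML file, and direct `...` overrides. Every pipeline parameter has a
#' default, so an empty call is a valid configuration. [cliRun()]
#' serializes the effective configuration into the output directory for
#' provenance.
#'
#' @param path optional YAML file.
#' @param ... named overrides of any configuration key.
#' @return a named list of class `igrsieve_config`.
#' @export
runConfig <- function(path = NULL, ...) {
  cfg <- .CONFIG_DEFAULTS
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    fromFile <- yaml::read_yaml(path)
    unknown <- setdiff(names(fromFile), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(fromFile)] <- fromFile
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "igrsieve_config")
}

.artifact <- function(cfg, name) file.path(cfg$outdir, name)

.require_artifact <- function(cfg, name, producer) {
  p <- .artifact(cfg, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "'; run the '", producer,
         "' stage first")
  p
}

.appendLog <- function(cfg, stage, counts) {
  line <- jsonlite::toJSON(c(list(stage = stage), counts),
                           auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = .artifact(cfg, "log.jsonl"),
      append = TRUE)
  message("[", stage, "] ",
          paste(names(counts), unlist(counts), sep = "=", collapse = " "))
}

#' Run one pipeline stage
#'
#' Drives the pipeline through its file artifacts: each stage reads what
#' the previous stage wrote under `config$outdir` and writes its own
#' outputs there, so any stage can be re-run from files alone. Stages:
#'
#' * `simulate` - write a synthetic genome (+ annotations + truth) from
#'   the `sim` configuration block.
#' * `extract` - read genome and annotations, extract and label IGRs;
#'   writes `igrs.tsv` / `igrs.fasta`.
#' * `train` - fit the per-genome classifier; writes `model.json`.
#' * `select` - score all IGRs and flag candidates; writes `scored.tsv`,
#'   `scored.fasta` and `selected.fasta`.
#' * `filter` - subtract protein-homology hits (`config$hits`, optional)
#'   and re-apply the selection criteria; writes `filtered.tsv/fasta`.
#' * `bundle` - deduplicate identical sequences and package the
#'   candidates; writes `candidates.fasta` and `bundle.tar.gz`.
#' * `plot` - render the %GC-versus-length genome plot with the decision
#'   boundary; writes `genome_plot.png`.
#'
#' A JSON-lines log of per-stage counts accumulates in `log.jsonl`, and
#' the effective configuration is stored as `config.yaml`.
#'
#' @param subcommand one of `"simulate"`, `"extract"`, `"train"`,
#'   `"select"`, `"filter"`, `"bundle"`, `"plot"`.
#' @param config a configuration from [runConfig()].
#' @return invisibly, the stage's primary object (an [IgrSet],
#'   [IgrClassifier], [SearchBundle], plot, or simulation description).
#' @export
cliRun <- function(subcommand = c("simulate", "extract", "train", "select",
                                  "filter", "bundle", "plot"),
                   config = runConfig()) {
  subcommand <- match.arg(subcommand)
  cfg <- config
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  writeLines(yaml::as.yaml(unclass(cfg)), .artifact(cfg, "config.yaml"))

  if (subcommand == "simulate") {
    sim <- do.call(simConfig, c(list(seed = cfg$seed), cfg$sim))
    res <- simulateGenome(sim, cfg$outdir)
    .appendLog(cfg, "simulate",
               list(contigs = sim@nContigs,
                    genes = sim@nContigs * sim@nGenesPerContig,
                    planted_rnas = sim@nPlantedRna,
                    labeled_rnas = sum(res$truth$labeled)))
    return(invisible(res))
  }

  if (subcommand == "extract") {
    fasta <- cfg$fasta
    annot <- cfg$annotation
    rna <- cfg$rna
    if (is.null(fasta) && file.exists(.artifact(cfg, "genome.fasta"))) {
      fasta <- .artifact(cfg, "genome.fasta")
      annot <- .artifact(cfg, "genes.gff3")
      if (is.null(rna)) rna <- .artifact(cfg, "known_rnas.bed")
    }
    if (is.null(fasta))
      stop("no genome input: set 'fasta'/'annotation' or run the ",
           "'simulate' stage first")
    topo <- cfg$topology
    if (is.list(topo)) topo <- unlist(topo)
    genome <- readGenome(fasta, annot, format = cfg$annotation_format,
                         topology = topo)
    igrs <- extractIgrs(genome, dropTerminal = isTRUE(cfg$drop_terminal))
    nLabeled <- 0L
    if (!is.null(rna) && file.exists(rna)) {
      rnas <- readRnaAnnotations(rna, format = cfg$rna_format,
                                 nameAttribute = cfg$rna_name_attribute,
                                 genome = genome)
      igrs <- labelIgrs(igrs, rnas,
                        minOverlapFraction = cfg$min_overlap_fraction)
      nLabeled <- sum(lengths(igrs@rnaFamilies) > 0)
    }
    writeIgrTable(igrs, .artifact(cfg, "igrs.tsv"))
    writeCandidateFasta(igrs, .artifact(cfg, "igrs.fasta"))
    .appendLog(cfg, "extract",
               list(igrs_extracted = length(igrs), igrs_labeled = nLabeled))
    return(invisible(igrs))
  }

  if (subcommand == "train") {
    igrs <- readIgrTable(.require_artifact(cfg, "igrs.tsv", "extract"),
                         .require_artifact(cfg, "igrs.fasta", "extract"))
    model <- trainClassifier(igrs, C = cfg$C, gammaMode = cfg$gamma_mode,
                             gamma = cfg$gamma, w = cfg$w,
                             minPositives = cfg$min_positives,
                             logLength = isTRUE(cfg$log_length))
    writeClassifierJSON(model, .artifact(cfg, "model.json"))
    .appendLog(cfg, "train",
               list(n_positive = model@nPositive,
                    n_negative = model@nNegative,
                    support_vectors = nrow(model@supportVectors)))
    return(invisible(model))
  }

  if (subcommand == "select") {
    igrs <- readIgrTable(.require_artifact(cfg, "igrs.tsv", "extract"),
                         .require_artifact(cfg, "igrs.fasta", "extract"))
    model <- readClassifierJSON(
      .require_artifact(cfg, "model.json", "train"))
    scored <- selectCandidates(model, igrs)
    writeIgrTable(scored, .artifact(cfg, "scored.tsv"))
    writeCandidateFasta(scored, .artifact(cfg, "scored.fasta"))
    sel <- scored[which(isSelected(scored))]
    writeCandidateFasta(sel, .artifact(cfg, "selected.fasta"))
    .appendLog(cfg, "select",
               list(igrs_scored = length(scored),
                    igrs_selected = length(sel)))
    return(invisible(scored))
  }

  if (subcommand == "filter") {
    scored <- readIgrTable(.require_artifact(cfg, "scored.tsv", "select"),
                           .require_artifact(cfg, "scored.fasta", "select"))
    model <- readClassifierJSON(
      .require_artifact(cfg, "model.json", "train"))
    sel <- scored[which(isSelected(scored))]
    hitsPath <- cfg$hits
    if (is.null(hitsPath) && file.exists(.artifact(cfg, "hits.tsv")))
      hitsPath <- .artifact(cfg, "hits.tsv")
    if (!is.null(hitsPath)) {
      hits <- readHits(hitsPath, evalueMax = cfg$evalue_max,
                       igrIds = igrId(sel))
      fragments <- subtractHits(sel, hits, pad = cfg$hit_pad)
    } else {
      hits <- NULL
      fragments <- sel
    }
    surv <- refilter(fragments, model,
                     minLength = cfg$min_fragment_length)
    writeIgrTable(surv, .artifact(cfg, "filtered.tsv"))
    writeCandidateFasta(surv, .artifact(cfg, "filtered.fasta"))
    .appendLog(cfg, "filter",
               list(candidates_in = length(sel),
                    hits_applied = if (is.null(hits)) 0L else nrow(hits),
                    fragments = length(fragments),
                    candidates_surviving = length(surv)))
    return(invisible(surv))
  }

  if (subcommand == "bundle") {
    surv <- readIgrTable(
      .require_artifact(cfg, "filtered.tsv", "filter"),
      .require_artifact(cfg, "filtered.fasta", "filter"))
    if (!length(surv)) stop("no surviving candidates to bundle")
    dd <- dedupIdentical(surv, revcomp = isTRUE(cfg$dedup_revcomp))
    writeCandidateFasta(dd$kept, .artifact(cfg, "candidates.fasta"))
    bundle <- exportBundle(dd$kept, .artifact(cfg, "bundle.tar.gz"),
                           templateConfig = list(EVALUE = cfg$evalue_max))
    .appendLog(cfg, "bundle",
               list(candidates_in = length(surv),
                    duplicates_removed = length(dd$mapping),
                    bundle_members = nrow(bundle@manifest)))
    return(invisible(bundle))
  }

  ## plot
  src <- if (file.exists(.artifact(cfg, "scored.tsv"))) "scored"
         else "igrs"
  igrs <- readIgrTable(.require_artifact(cfg, paste0(src, ".tsv"),
                                         "extract"),
                       .require_artifact(cfg, paste0(src, ".fasta"),
                                         "extract"))
  model <- if (file.exists(.artifact(cfg, "model.json")))
    readClassifierJSON(.artifact(cfg, "model.json")) else NULL
  p <- plotGenome(igrs, model, .artifact(cfg, "genome_plot.png"))
  .appendLog(cfg, "plot", list(igrs_plotted = length(igrs),
                               with_model = !is.null(model)))
  invisible(p)
}

#' Plot IGRs by length and %GC content
#'
#' The diagnostic scatter used to judge whether a genome suits the
#' GC/length enrichment approach: each IGR is a point (length on x, %GC
#' on y), IGRs carrying known RNA families are drawn distinctly and
#' annotated with their family names, and — when a trained model is
#' supplied — the classifier's selection region is overlaid as the
#' level-0 contour of the decision function, with selected candidates
#' highlighted. Suitable genomes show the known-RNA cluster standing
#' clear of the bulk of unannotated IGRs.
#'
#' @param igrs a non-empty [IgrSet].
#' @param model an [IgrClassifier], or `NULL` for a plain scatter.
#' @param out output image path (`.png`, `.svg` or `.pdf`).
#' @param width,height device size in inches.
#' @return the ggplot object, invisibly.
#' @export
plotGenome <- function(igrs, model = NULL, out, width = 8, height = 6) {
  stopifnot(is(igrs, "IgrSet"), length(igrs) > 0)
  df <- as.data.frame(igrs)
  df$status <- ifelse(nzchar(df$rna_families), "known RNA",
                      ifelse(df$selected, "selected candidate",
                             "unannotated"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = length, y = gc_percent)) +
    ggplot2::geom_point(ggplot2::aes(colour = status, shape = status),
                        size = 2, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      "known RNA" = "#d62728", "selected candidate" = "#1f77b4",
      "unannotated" = "grey55")) +
    ggplot2::scale_shape_manual(values = c(
      "known RNA" = 17, "selected candidate" = 16, "unannotated" = 1)) +
    ggplot2::labs(x = "IGR length (nt)", y = "GC content (%)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_bw()
  lab <- df[nzchar(df$rna_families), , drop = FALSE]
  if (nrow(lab))
    p <- p + ggplot2::geom_text(
      data = lab, ggplot2::aes(label = rna_families),
      size = 2.3, vjust = -0.9, colour = "#d62728", check_overlap = TRUE)
  if (!is.null(model)) {
    pad <- function(r) r + c(-1, 1) * 0.05 * diff(r)
    grid <- decisionGrid(model, pad(range(df$gc_percent)),
                         pad(range(df$length)), resolution = 120L)
    gdf <- expand.grid(gc = attr(grid, "gc"), length = attr(grid, "length"))
    gdf$d <- as.vector(grid)
    p <- p + ggplot2::geom_contour(
      data = gdf, ggplot2::aes(x = length, y = gc, z = d),
      breaks = 0, colour = "black", linewidth = 0.5)
  }
  ext <- tolower(tools::file_ext(out))
  if (ext == "png") {
    grDevices::png(out, width = width, height = height, units = "in",
                   res = 150, type = "cairo")
  } else if (ext == "svg") {
    grDevices::svg(out, width = width, height = height)
  } else {
    grDevices::pdf(out, width = width, height = height)
  }
  print(p)
  grDevices::dev.off()
  invisible(p)
}
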