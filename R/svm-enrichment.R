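#' @include igr-extraction.R
NULL

.featureMatrix <- function(igrs, logLength = FALSE) {
  len <- as.numeric(GenomicRanges::width(igrs@ranges))
  if (logLength) len <- log10(len)
  cbind(gc_percent = gcPercent(igrs), length = len)
}

.standardize <- function(x, center, scale) {
  sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
}

#' Train the per-genome RBF-SVM enrichment classifier
#'
#' Fits a support-vector classifier with a radial basis-function kernel to
#' the genome's IGRs, using %GC content and nucleotide length as the two
#' features and presence/absence of a known structured-RNA family as the
#' class label. The classifier is an enrichment device, not a predictive
#' model: its job is to carve out the contiguous region of the GC-versus-
#' length plane occupied by known-RNA IGRs so that unannotated IGRs falling
#' inside it can be prioritized. It is trained de novo for every genome;
#' no cross-validation or hyperparameter search is performed, and users
#' are expected to inspect the plotted region ([plotGenome()]).
#'
#' Features are standardized to zero mean and unit variance over all
#' training IGRs. With `gammaMode = "auto"`, gamma is set to half the
#' reciprocal of the mean per-feature variance of the scaled features —
#' i.e. 0.5 after unit-variance scaling. Class weights are
#' `w * n_negative / n_positive` for the RNA class and 1 for the
#' background, so `w` is the single knob that grows (`w > 1`) or shrinks
#' (`w < 1`) the selected region. Training rows are sorted by
#' (contig, start) before fitting, making the fit reproducible.
#'
#' @param igrs a labeled [IgrSet] (see [labelIgrs()]).
#' @param C cost parameter, positive.
#' @param gammaMode `"auto"` or `"fixed"`.
#' @param gamma RBF width used when `gammaMode = "fixed"`.
#' @param w positive-class weight multiplier.
#' @param minPositives minimum number of labeled (and of unlabeled) IGRs
#'   required to attempt training.
#' @param logLength model `log10(length)` instead of raw length.
#' @return an [IgrClassifier].
#' @export
trainClassifier <- function(igrs, C = 1.0, gammaMode = c("auto", "fixed"),
                            gamma = 0.5, w = 1.0, minPositives = 5L,
                            logLength = FALSE) {
  stopifnot(is(igrs, "IgrSet"))
  gammaMode <- match.arg(gammaMode)
  if (C <= 0 || w <= 0) stop("C and w must be positive")
  ord <- order(as.character(GenomicRanges::seqnames(igrs@ranges)),
               GenomicRanges::start(igrs@ranges))
  igrs <- igrs[ord]
  pos <- lengths(igrs@rnaFamilies) > 0
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos < minPositives)
    stop("only ", nPos, " IGRs carry a known RNA family (minimum ",
         minPositives, "); this genome cannot train the enrichment ",
         "classifier - ideal genomes show strong separation between ",
         "known-RNA IGRs and the bulk of unannotated IGRs")
  if (nNeg < minPositives)
    stop("only ", nNeg, " unannotated IGRs (minimum ", minPositives, ")")
  feat <- .featureMatrix(igrs, logLength)
  center <- colMeans(feat)
  scale <- apply(feat, 2L, stats::sd)
  if (any(scale == 0))
    stop("degenerate feature (zero variance): ",
         paste(colnames(feat)[scale == 0], collapse = ", "))
  z <- .standardize(feat, center, scale)
  if (gammaMode == "auto")
    gamma <- 1 / (2 * mean(apply(z, 2L, stats::var)))
  y <- factor(ifelse(pos, "rna", "background"),
              levels = c("rna", "background"))
  fit <- e1071::svm(z, y, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE,
                    class.weights = c(rna = w * nNeg / nPos,
                                      background = 1))
  ## libsvm orients the binary decision function by the class of the
  ## first training row, not by factor levels; normalize so that positive
  ## d(x) always favours the "rna" class.
  orient <- colnames(attr(stats::predict(fit, z[1L, , drop = FALSE],
                                         decision.values = TRUE),
                          "decision.values"))
  flip <- if (identical(orient, "background/rna")) -1 else 1
  new(Class = "IgrClassifier", C = C, gamma = gamma, gammaMode = gammaMode,
      weight = w, center = center, scale = scale, logLength = logLength,
      supportVectors = unname(fit$SV),
      coefs = flip * as.numeric(fit$coefs),
      rho = flip * as.numeric(fit$rho), nPositive = as.integer(nPos),
      nNegative = as.integer(nNeg))
}

#' Evaluate the classifier decision function
#'
#' Computes \eqn{d(x) = \sum_i \alpha_i \exp(-\gamma\|z(x)-s_i\|^2) - \rho}
#' for raw-unit feature rows; positive values indicate similarity to
#' known-RNA IGRs. Evaluation uses only the stored trained state, so a
#' model reloaded from JSON scores identically.
#'
#' @param model an [IgrClassifier].
#' @param x an [IgrSet], or a numeric matrix/vector of raw features with
#'   columns (%GC, length in nt).
#' @return numeric vector of decision values.
#' @export
decisionValues <- function(model, x) {
  stopifnot(is(model, "IgrClassifier"))
  if (is(x, "IgrSet")) {
    feat <- .featureMatrix(x, model@logLength)
  } else {
    feat <- rbind(x)
    if (ncol(feat) != 2L) stop("feature matrix must have 2 columns")
    if (model@logLength) feat[, 2L] <- log10(feat[, 2L])
  }
  z <- .standardize(feat, model@center, model@scale)
  sv <- model@supportVectors
  d2 <- outer(rowSums(z^2), rowSums(sv^2), "+") - 2 * z %*% t(sv)
  as.numeric(exp(-model@gamma * pmax(d2, 0)) %*% model@coefs - model@rho)
}

#' Select candidate IGRs with the trained classifier
#'
#' Scores every IGR with the decision function and marks as selected the
#' unannotated IGRs with a strictly positive decision value — the
#' canonical SVM margin, not a tuned probability cutoff. IGRs already
#' carrying a known RNA family are scored but never selected: they are
#' knowns, not candidates.
#'
#' @param model an [IgrClassifier] trained on this genome's IGRs.
#' @param igrs an [IgrSet].
#' @return the [IgrSet] with the `decision` column filled and `selected`
#'   set on qualifying IGRs.
#' @seealso [trainClassifier()], [refilter()]
#' @export
selectCandidates <- function(model, igrs) {
  stopifnot(is(igrs, "IgrSet"))
  d <- decisionValues(model, igrs)
  S4Vectors::mcols(igrs@ranges)$decision <- d
  S4Vectors::mcols(igrs@ranges)$selected <-
    lengths(igrs@rnaFamilies) == 0L & d > 0
  igrs
}

#' Decision values on a regular feature grid
#'
#' Evaluates the decision function over a `resolution x resolution` grid
#' spanning the given raw-unit ranges, for drawing the selection region as
#' the level-0 contour in [plotGenome()]. Rows index %GC, columns index
#' length; grid coordinates are attached as attributes `gc` and `length`.
#'
#' @param model an [IgrClassifier].
#' @param gcRange,lengthRange numeric(2) raw-unit bounds.
#' @param resolution grid points per axis.
#' @return a numeric matrix with attributes `gc` and `length`.
#' @export
decisionGrid <- function(model, gcRange, lengthRange, resolution = 200L) {
  stopifnot(length(gcRange) == 2L, length(lengthRange) == 2L,
            resolution >= 2L)
  gc <- seq(gcRange[1], gcRange[2], length.out = resolution)
  len <- seq(lengthRange[1], lengthRange[2], length.out = resolution)
  pts <- cbind(rep(gc, times = resolution), rep(len, each = resolution))
  m <- matrix(decisionValues(model, pts), nrow = resolution,
              ncol = resolution)
  attr(m, "gc") <- gc
  attr(m, "length") <- len
  m
}

#' Serialize a trained classifier to JSON
#'
#' Writes hyperparameters, feature scaling and the trained state (support
#' vectors, dual coefficients, intercept) as a JSON document, so that any
#' runtime can re-evaluate the decision function. `readClassifierJSON`
#' restores a model that scores identically to the original.
#'
#' @param model an [IgrClassifier].
#' @param path JSON file path.
#' @return `writeClassifierJSON` returns `path` invisibly;
#'   `readClassifierJSON` returns an [IgrClassifier].
#' @export
writeClassifierJSON <- function(model, path) {
  doc <- list(
    model_type = "svm_rbf",
    C = model@C, gamma = model@gamma, gamma_mode = model@gammaMode,
    positive_class_weight = model@weight,
    feature_names = c("gc_percent", "length"),
    log_length = model@logLength,
    feature_means = as.numeric(model@center),
    feature_sds = as.numeric(model@scale),
    support_vectors = unname(model@supportVectors),
    dual_coefs = model@coefs, rho = model@rho,
    n_positive = model@nPositive, n_negative = model@nNegative)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeClassifierJSON
#' @export
readClassifierJSON <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$model_type, "svm_rbf"))
    stop("not a serialized RBF-SVM model: ", path)
  new(Class = "IgrClassifier", C = doc$C, gamma = doc$gamma,
      gammaMode = doc$gamma_mode, weight = doc$positive_class_weight,
      center = stats::setNames(doc$feature_means, doc$feature_names),
      scale = stats::setNames(doc$feature_sds, doc$feature_names),
      logLength = doc$log_length,
      supportVectors = rbind(doc$support_vectors),
      coefs = doc$dual_coefs, rho = doc$rho,
      nPositive = as.integer(doc$n_positive),
      nNegative = as.integer(doc$n_negative))
}
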