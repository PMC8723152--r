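test_that("gcPercent follows the stated denominator rule", {
  expect_equal(gcPercent("ATGC"), 50.0)
  expect_equal(gcPercent("GGCC"), 100.0)
  expect_equal(gcPercent("ATAT"), 0.0)
  ## ambiguity codes and N count in the denominator only
  expect_equal(gcPercent("GCNN"), 50.0)
  expect_equal(gcPercent("gcnn"), 50.0)
  expect_equal(gcPercent("GRYSWC"), 100 * 2 / 6)
  expect_error(gcPercent(""), "empty")
})

test_that("gcPercent equals naive counting on random IUPAC strings", {
  set.seed(11)
  iupac <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V")
  strs <- vapply(sample(1:80, 200, replace = TRUE),
                 randSeq, "", alphabet = iupac)
  expect_equal(gcPercent(strs), vapply(strs, naiveGc, 0, USE.NAMES = FALSE))
})

test_that("linear extraction complements merged CDS spans", {
  gnm <- makeGenome(c(chrA = randSeq(1000)),
                    data.frame(contig = "chrA",
                               start = c(101, 601), end = c(400, 900),
                               tag = c("g1", "g2")))
  igrs <- extractIgrs(gnm)
  df <- as.data.frame(igrs)
  expect_identical(df$start, c(1L, 401L, 901L))
  expect_identical(df$end, c(100L, 600L, 1000L))
  expect_identical(df$terminal, c(TRUE, FALSE, TRUE))
  expect_identical(df$igr_id, paste0("chrA_", c(1, 401, 901)))
  ## flanking context: middle IGR sits between g1 and g2
  expect_identical(df$upstream_locus[2], "g1")
  expect_identical(df$downstream_locus[2], "g2")
  ## edge sentinels
  expect_identical(df$upstream_locus[1], ".")
  expect_identical(df$downstream_locus[3], ".")
  ## sequences match the contig slices
  expect_identical(as.character(igrSequences(igrs)[[2]]),
                   substr(as.character(contigSequences(gnm)[[1]]),
                          401, 600))
  expect_length(extractIgrs(gnm, dropTerminal = TRUE), 1L)
})

test_that("overlapping and abutting CDS merge before complementing", {
  gnm <- makeGenome(c(chrA = randSeq(1000)),
                    data.frame(contig = "chrA",
                               start = c(101, 351), end = c(400, 700),
                               strand = c("+", "-")))
  df <- as.data.frame(extractIgrs(gnm))
  expect_identical(nrow(df), 2L)
  expect_identical(df$start, c(1L, 701L))
  ## abutting genes leave no zero-length IGR
  gnm2 <- makeGenome(c(chrA = randSeq(600)),
                     data.frame(contig = "chrA",
                                start = c(101, 301), end = c(300, 500)))
  expect_identical(as.data.frame(extractIgrs(gnm2))$start, c(1L, 501L))
})

test_that("a circular contig joins the origin-spanning gap into one wrapped IGR", {
  seq <- randSeq(1000)
  gnm <- makeGenome(c(chrC = seq),
                    data.frame(contig = "chrC", start = 201, end = 800),
                    topology = "circular")
  igrs <- extractIgrs(gnm)
  expect_length(igrs, 1L)
  df <- as.data.frame(igrs)
  expect_identical(df$start, 801L)
  expect_identical(df$end, 1200L)
  expect_identical(df$length, 400L)
  expect_true(df$wraps)
  expect_false(df$terminal)
  expect_identical(as.character(igrSequences(igrs)[[1]]),
                   paste0(substr(seq, 801, 1000), substr(seq, 1, 200)))
})

test_that("a contig without CDS is one whole-contig IGR", {
  gnm <- makeGenome(c(chrA = randSeq(500)), cds = NULL)
  df <- as.data.frame(extractIgrs(gnm))
  expect_identical(df$start, 1L)
  expect_identical(df$end, 500L)
  expect_true(df$terminal)
})

test_that("extraction matches the per-base mask oracle and conserves length", {
  expect_identical(extractionOracleMismatches(150L, seed = 101), 0L)
})

test_that("labeling follows the RNA-overlap fraction rule", {
  gnm <- makeGenome(c(chrA = randSeq(1000)),
                    data.frame(contig = "chrA",
                               start = c(101, 601), end = c(400, 600 + 20),
                               tag = c("g1", "g2")))
  igrs <- extractIgrs(gnm)  # middle IGR [401, 600]
  mkRna <- function(start, end, family = "TPP", strand = "+") {
    gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(start, end),
                                 strand = strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(family = family)
    gr
  }
  ## containment: fraction 1.0
  lab <- labelIgrs(igrs, mkRna(451, 550))
  expect_identical(unname(rnaFamilies(lab)[["chrA_401"]]), "TPP")
  ## boundary: half the 40-nt RNA inside -> labeled at >= 0.5
  lab <- labelIgrs(igrs, mkRna(381, 420))
  expect_identical(unname(rnaFamilies(lab)[["chrA_401"]]), "TPP")
  ## just under the threshold (20 of 42 nt inside)
  lab <- labelIgrs(igrs, mkRna(379, 420))
  expect_length(rnaFamilies(lab)[["chrA_401"]], 0L)
  ## RNA entirely inside a CDS labels nothing
  lab <- labelIgrs(igrs, mkRna(150, 250))
  expect_true(all(lengths(rnaFamilies(lab)) == 0L))
  ## strand-blind
  lab <- labelIgrs(igrs, mkRna(451, 550, strand = "-"))
  expect_identical(unname(rnaFamilies(lab)[["chrA_401"]]), "TPP")
  ## multiple families accumulate, sorted
  two <- c(mkRna(451, 500, "TPP"), mkRna(520, 560, "SAM"))
  lab <- labelIgrs(igrs, two)
  expect_identical(unname(rnaFamilies(lab)[["chrA_401"]]),
                   c("SAM", "TPP"))
})

test_that("labeling is monotone in the overlap threshold", {
  set.seed(7)
  gnm <- makeGenome(c(chrA = randSeq(5000)),
                    data.frame(contig = "chrA",
                               start = seq(201, 4201, by = 500),
                               end = seq(400, 4400, by = 500)))
  igrs <- extractIgrs(gnm)
  rna <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(sort(sample(4500, 12)), width = 80))
  S4Vectors::mcols(rna) <- S4Vectors::DataFrame(
    family = paste0("F", 1:12))
  prev <- NULL
  for (th in c(0.9, 0.7, 0.5, 0.3, 0.1)) {
    cur <- rnaFamilies(labelIgrs(igrs, rna, minOverlapFraction = th))
    if (!is.null(prev))
      for (i in seq_along(cur))
        expect_true(all(prev[[i]] %in% cur[[i]]))
    prev <- cur
  }
})

test_that("a wrapped IGR can be labeled across the origin", {
  seq <- randSeq(1000)
  gnm <- makeGenome(c(chrC = seq),
                    data.frame(contig = "chrC", start = 201, end = 800),
                    topology = "circular")
  igrs <- extractIgrs(gnm)
  rna <- GenomicRanges::GRanges("chrC", IRanges::IRanges(951, 1000))
  S4Vectors::mcols(rna) <- S4Vectors::DataFrame(family = "ORIG")
  ## RNA [951, 1000] + wrap piece [1, 50]: both halves are IGR content
  rna2 <- GenomicRanges::GRanges("chrC", IRanges::IRanges(1, 50))
  S4Vectors::mcols(rna2) <- S4Vectors::DataFrame(family = "ORIG2")
  lab <- labelIgrs(igrs, c(rna, rna2))
  expect_setequal(unname(lab@rnaFamilies[[1]]), c("ORIG", "ORIG2"))
})
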