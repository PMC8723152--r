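test_that("GFF3 features land on internal coordinates with CDS/other kinds", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c("chrA extra header text" = randSeq(1000))),
    fa)
  gff <- file.path(dir, "g.gff3")
  writeLines(c(
    "##gff-version 3",
    "chrA\tsrc\tCDS\t101\t400\t.\t+\t0\tID=g1;locus_tag=g1",
    "chrA\tsrc\ttRNA\t500\t575\t.\t-\t.\tID=t1;locus_tag=t1",
    "chrA\tsrc\tCDS\t601\t900\t.\t-\t0\tID=g2;locus_tag=g2"), gff)
  gnm <- readGenome(fa, gff, format = "gff3")

  expect_identical(names(contigSequences(gnm)), "chrA")
  g <- geneFeatures(gnm)
  expect_identical(GenomicRanges::start(g), c(101L, 500L, 601L))
  expect_identical(GenomicRanges::end(g), c(400L, 575L, 900L))
  expect_identical(S4Vectors::mcols(g)$kind, c("CDS", "other", "CDS"))
  expect_identical(as.character(GenomicRanges::strand(g)),
                   c("+", "-", "-"))
})

test_that("annotations referencing unknown contigs or overrunning them fail", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chrA = randSeq(300))), fa)
  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3",
               "chrB\tsrc\tCDS\t1\t100\t.\t+\t0\tID=x;locus_tag=x"), gff)
  expect_error(readGenome(fa, gff), "chrB")
  writeLines(c("##gff-version 3",
               "chrA\tsrc\tCDS\t200\t400\t.\t+\t0\tID=x;locus_tag=x"), gff)
  expect_error(readGenome(fa, gff), "beyond contig length")
  expect_error(readGenome(file.path(dir, "absent.fa"), gff), "not found")
})

test_that("GenBank flat files yield sorted features and contig topology", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(pXY1 = randSeq(900))), fa)
  gbk <- file.path(dir, "g.gbk")
  writeLines(c(
    "LOCUS       pXY1                 900 bp    DNA     circular BCT 01-JAN-2020",
    "FEATURES             Location/Qualifiers",
    "     source          1..900",
    "     CDS             complement(401..700)",
    "                     /locus_tag=\"pXY1_02\"",
    "                     /product=\"hypothetical protein\"",
    "     CDS             51..350",
    "                     /locus_tag=\"pXY1_01\"",
    "     tRNA            720..795",
    "                     /locus_tag=\"pXY1_t1\"",
    "ORIGIN",
    "//"), gbk)
  gnm <- readGenome(fa, gbk, format = "genbank")
  g <- geneFeatures(gnm)
  expect_identical(S4Vectors::mcols(g)$locus_tag,
                   c("pXY1_01", "pXY1_02", "pXY1_t1"))
  expect_identical(GenomicRanges::start(g), c(51L, 401L, 720L))
  expect_identical(S4Vectors::mcols(g)$kind, c("CDS", "CDS", "other"))
  expect_identical(as.character(GenomicRanges::strand(g))[2], "-")
  expect_identical(unname(topology(gnm)["pXY1"]), "circular")
})

test_that("BED and GFF3 RNA annotations map to the same internal interval", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "r.bed")
  writeLines("chrA\t500\t600\tTPP\t0\t+", bed)
  fromBed <- readRnaAnnotations(bed, format = "bed")
  expect_identical(GenomicRanges::start(fromBed), 501L)
  expect_identical(GenomicRanges::end(fromBed), 600L)
  expect_identical(S4Vectors::mcols(fromBed)$family, "TPP")

  gff <- file.path(dir, "r.gff3")
  writeLines(c("##gff-version 3",
               "chrA\tRfam\tncRNA\t501\t600\t.\t+\t.\tName=TPP"), gff)
  fromGff <- readRnaAnnotations(gff, format = "gff3")
  expect_identical(GenomicRanges::start(fromGff), 501L)
  expect_identical(GenomicRanges::end(fromGff), 600L)
  expect_identical(S4Vectors::mcols(fromGff)$family, "TPP")

  empty <- file.path(dir, "empty.bed")
  writeLines(character(), empty)
  expect_length(readRnaAnnotations(empty, format = "bed"), 0L)

  writeLines(c("chrA\t500\t600\tTPP", "chrA\tbroken"), bed)
  expect_error(readRnaAnnotations(bed, format = "bed"), "line 2")
})

test_that("RNA annotations attached to a genome are contig-validated", {
  gnm <- makeGenome(c(chrA = randSeq(400)),
                    data.frame(contig = "chrA", start = 50, end = 150))
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "r.bed")
  writeLines("chrZ\t10\t60\tSAM\t0\t-", bed)
  expect_error(readRnaAnnotations(bed, genome = gnm), "chrZ")
  writeLines("chrA\t200\t260\tSAM\t0\t-", bed)
  gnm2 <- readRnaAnnotations(bed, genome = gnm)
  expect_s4_class(gnm2, "AnnotatedGenome")
  expect_length(rnaAnnotations(gnm2), 1L)
})

test_that("the IGR table round-trips every field through TSV + FASTA", {
  gnm <- makeGenome(c(chrA = randSeq(1200)),
                    data.frame(contig = "chrA",
                               start = c(101, 601), end = c(400, 900)))
  igrs <- extractIgrs(gnm)
  igrs@rnaFamilies[[2]] <- c("SAM", "TPP")
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "igrs.tsv")
  fa <- file.path(dir, "igrs.fasta")
  writeIgrTable(igrs, tsv)
  writeCandidateFasta(igrs, fa)

  tab <- read.table(tsv, sep = "\t", header = TRUE,
                    colClasses = list(rna_families = "character"))
  expect_identical(tab$rna_families[2], "SAM,TPP")
  expect_identical(tab$rna_families[1], "")

  back <- readIgrTable(tsv, fa)
  expect_identical(as.data.frame(back), as.data.frame(igrs))
  expect_identical(as.character(igrSequences(back)),
                   as.character(igrSequences(igrs)))
})

test_that("GFF3 write/read reproduces feature coordinates and is order-insensitive", {
  cds <- data.frame(contig = "chrA",
                    start = c(11L, 205L, 507L), end = c(160L, 420L, 890L),
                    strand = c("+", "-", "+"),
                    tag = c("gA", "gB", "gC"))
  gnm <- makeGenome(c(chrA = randSeq(1000)), cds)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "genes.gff3")
  writeFeatureGff3(gnm, out)
  fa <- file.path(dir, "g.fasta")
  Biostrings::writeXStringSet(contigSequences(gnm), fa)
  back <- readGenome(fa, out, format = "gff3")
  expect_identical(GenomicRanges::start(geneFeatures(back)), cds$start)
  expect_identical(GenomicRanges::end(geneFeatures(back)), cds$end)

  ## shuffle annotation body lines: parsed result is identical
  lines <- readLines(out)
  shuffled <- c(lines[1], lines[c(4, 2, 3)])
  out2 <- file.path(dir, "shuffled.gff3")
  writeLines(shuffled, out2)
  back2 <- readGenome(fa, out2, format = "gff3")
  expect_identical(geneFeatures(back2), geneFeatures(back))
})
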