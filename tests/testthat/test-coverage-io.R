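test_that("bedGraph rasterization does length-weighted averaging", {
  f <- withr::local_tempfile(fileext = ".bedGraph")

  # single record covering [0,100) with value 5 at step 10: ten bins of 5
  writeBedGraphLines(f, "chr1", 0L, 100L, 5)
  tr <- readCoverageBedGraph(f, c(chr1 = 100), 10L)
  expect_equal(trackValues(tr)$chr1, rep(5, 10))

  # [0,15)=2 then [15,20)=4: bin0 = 2, bin1 = (2*5 + 4*5)/10 = 3
  writeBedGraphLines(f, "chr1", c(0L, 15L), c(15L, 20L), c(2, 4))
  tr <- readCoverageBedGraph(f, c(chr1 = 20), 10L)
  expect_equal(trackValues(tr)$chr1, c(2, 3))

  # no records at all: all-zero track
  writeLines(character(), f)
  tr <- readCoverageBedGraph(f, c(chr1 = 50), 10L)
  expect_equal(trackValues(tr)$chr1, rep(0, 5))
})

test_that("bedGraph validation rejects out-of-bounds and overlapping records", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeBedGraphLines(f, "chr1", 0L, 120L, 1)
  expect_error(readCoverageBedGraph(f, c(chr1 = 100), 10L), "beyond")
  writeBedGraphLines(f, "chr1", c(0L, 5L), c(10L, 15L), c(1, 2))
  expect_error(readCoverageBedGraph(f, c(chr1 = 100), 10L), "overlapping")
  writeBedGraphLines(f, "chrX", 0L, 10L, 1)
  expect_error(readCoverageBedGraph(f, c(chr1 = 100), 10L), "absent")
})

test_that("rasterization conserves mass on random bedGraphs", {
  set.seed(42)
  for (rep in 1:25) {
    len <- sample(50:400, 1)
    step <- sample(c(1L, 5L, 10L, 25L), 1)
    cuts <- sort(sample(0:len, sample(2:8, 1)))
    s <- cuts[-length(cuts)]; e <- cuts[-1]
    keep <- e > s & stats::runif(length(s)) > 0.3   # leave gaps
    s <- s[keep]; e <- e[keep]
    if (!length(s)) next
    v <- round(stats::rnorm(length(s), 5, 3), 3)
    f <- withr::local_tempfile(fileext = ".bedGraph")
    writeBedGraphLines(f, "chr1", s, e, v)
    tr <- readCoverageBedGraph(f, c(chr1 = len), step)
    widths <- nucdis:::.binWidths(len, step)
    expect_equal(sum(trackValues(tr)$chr1 * widths), sum(v * (e - s)),
                 tolerance = 1e-12)
  }
})

test_that("bedGraph writing round-trips a track", {
  tr <- makeTrack(c(0, 0, 2.5, 2.5, -1, 7), step = 10L)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeCoverageBedGraph(tr, f)
  back <- readCoverageBedGraph(f, trackSeqlengths(tr), 10L)
  expect_equal(trackValues(back), trackValues(tr))
})

test_that("GFF3 and BED annotations convert to 0-based half-open intervals", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=geneA",
               "chr1\tsrc\texon\t101\t150\t.\t+\t.\tID=exon1",
               "chr1\tsrc\tgene\t301\t450\t.\t-\t.\tID=geneB"), gff)
  genes <- readGeneAnnotation(gff, "gff3")
  gi <- geneIntervals(genes)
  expect_equal(gi$gene_id, c("geneA", "geneB"))
  expect_equal(gi$start, c(100L, 300L))   # 1-based closed -> 0-based half-open
  expect_equal(gi$end, c(200L, 450L))
  expect_equal(gi$strand, c("+", "-"))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tgeneA\t0\t-", bed)
  gi <- geneIntervals(readGeneAnnotation(bed, "bed"))
  expect_equal(gi$start, 100L)
  expect_equal(gi$end, 200L)
  expect_equal(gi$strand, "-")
})

test_that("annotation validation: duplicates error, empty file warns", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=dup",
               "chr1\tsrc\tgene\t21\t30\t.\t+\t.\tID=dup"), gff)
  expect_error(readGeneAnnotation(gff, "gff3"), "duplicate")
  writeLines("##gff-version 3", gff)
  expect_warning(genes <- readGeneAnnotation(gff, "gff3"), "empty")
  expect_length(genes, 0)
})

test_that("annotation round-trips through GFF3", {
  genes <- makeGenes("chr2", c(100L, 400L), c(250L, 900L), c("+", "-"),
                     ids = c("a1", "b2"))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeGeneAnnotationGFF3(genes, f)
  back <- readGeneAnnotation(f, "gff3")
  expect_equal(geneIntervals(back), geneIntervals(genes))
})

test_that("gene tables round-trip losslessly, including missing values", {
  m <- matrix(c(1.23456789012345e-7, -2.5, NA, 0.1, pi, 2/3), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  tab <- occupancyTable(m, c("log2_ip_over_input", "linear"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGeneTable(tab, f)
  back <- readGeneTable(f)
  expect_identical(occupancyMatrix(back), m)
  expect_identical(unname(sampleTags(back)),
                   c("log2_ip_over_input", "linear"))
})

test_that("gene table parse errors carry line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "g1\t1.0", "g2\t1.0\t9"), f)
  expect_error(readGeneTable(f), "line 3")
  writeLines(c("id\ts1", "g1\t1.0"), f)
  expect_error(readGeneTable(f), "gene_id")
})
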