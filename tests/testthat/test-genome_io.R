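test_that("read_fasta normalizes records and round-trips with write_fasta", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(">a\nACGT", f)
  g <- read_fasta(f)
  expect_identical(unname(g), "ACGT")
  expect_identical(names(g), "a")

  writeLines(">a desc here\nacgu\nACGT", f)
  g <- read_fasta(f)
  expect_identical(unname(g), "ACGTACGT")
  expect_identical(names(g), "a")

  writeLines(">amb\nACRT", f)
  expect_error(read_fasta(f), "non-ACGTN")
  expect_identical(unname(read_fasta(f, ambiguity = "mask_n")), "ACNT")

  set.seed(11)
  seqs <- stats::setNames(
    vapply(1:50, function(i) random_dna_str(sample(20:200, 1)), character(1)),
    sprintf("rec%02d", 1:50))
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
})

test_that("empty FASTA yields an empty collection with a warning", {
  f <- withr::local_tempfile(fileext = ".fa")
  file.create(f)
  expect_warning(g <- read_fasta(f), "empty")
  expect_length(g, 0)
})

test_that("read_gene_models splices, translates and derives junctions", {
  f <- withr::local_tempfile(fileext = ".gff3")
  genome <- c(chr1 = paste0("TTTT", "ATGAAATGA", "TTTTTT"))
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t5\t13\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t5\t13\t.\t+\t.\tID=g1.t1;Parent=g1",
               "chr1\tx\tCDS\t5\t13\t.\t+\t0\tID=c1;Parent=g1.t1"), f)
  m <- read_gene_models(f, genome)
  expect_length(m, 1)
  expect_identical(m$g1$protein, "MK")
  expect_identical(m$g1$intron_junctions, integer(0))

  # two-exon gene split after codon 1, with a 20-nt intron
  intron <- paste0("GT", strrep("C", 16), "AG")
  genome2 <- c(chr1 = paste0("TT", "ATG", intron, "AAATGA", "TTTT"))
  writeLines(c("##gff-version 3",
               "chr1\tx\tmRNA\t3\t31\t.\t+\t.\tID=t2",
               sprintf("chr1\tx\tCDS\t3\t5\t.\t+\t0\tID=c1;Parent=t2"),
               sprintf("chr1\tx\tCDS\t26\t31\t.\t+\t0\tID=c2;Parent=t2")), f)
  m2 <- read_gene_models(f, genome2)
  expect_identical(m2$t2$protein, "MK")
  expect_identical(m2$t2$intron_junctions, 1L)

  # minus strand: protein equals translation of revcomp of spliced exons
  genome3 <- c(chr1 = paste0("TT", revcomp("ATGAAATGA"), "TT"))
  writeLines(c("##gff-version 3",
               "chr1\tx\tmRNA\t3\t11\t.\t-\t.\tID=t3",
               "chr1\tx\tCDS\t3\t11\t.\t-\t0\tID=c3;Parent=t3"), f)
  m3 <- read_gene_models(f, genome3)
  expect_identical(m3$t3$protein, "MK")
})

test_that("non-functional parents are rejected with a warning", {
  f <- withr::local_tempfile(fileext = ".gff3")
  genome <- c(chr1 = paste0("ATGTAAAAATGA", strrep("T", 10)))  # internal stop
  writeLines(c("##gff-version 3",
               "chr1\tx\tCDS\t1\t12\t.\t+\t0\tID=bad1"), f)
  expect_warning(m <- read_gene_models(f, genome), "internal stop")
  expect_length(m, 0)

  genome2 <- c(chr1 = paste0("ATGAAAT", strrep("T", 10)))      # length % 3 != 0
  writeLines(c("##gff-version 3",
               "chr1\tx\tCDS\t1\t7\t.\t+\t0\tID=bad2"), f)
  expect_warning(m2 <- read_gene_models(f, genome2), "divisible by 3")
  expect_length(m2, 0)
})

test_that("build_intergenic hard-masks exactly the masked bases", {
  set.seed(21)
  g <- c(s1 = random_dna_str(30))
  expect_identical(build_intergenic(g), g)

  # gene interval [11, 20]: exactly 10 Ns at those positions
  masked <- build_intergenic(g, mask_track("s1", 11, 20, "gene"))
  expect_identical(substr(masked[["s1"]], 11, 20), strrep("N", 10))
  expect_identical(substr(masked[["s1"]], 1, 10), substr(g[["s1"]], 1, 10))
  expect_identical(substr(masked[["s1"]], 21, 30), substr(g[["s1"]], 21, 30))
  expect_identical(nchar(masked), nchar(g))

  # random disjoint masks: N count equals summed mask length; idempotent
  g2 <- c(s1 = random_dna_str(2000))
  st <- seq(1, by = 100, length.out = 20) + sample(0:30, 20, replace = TRUE)
  en <- st + sample(5:40, 20, replace = TRUE)
  mk <- mask_track("s1", st, en, "repeat")
  m1 <- build_intergenic(g2, repeat_mask = mk)
  n_count <- nchar(gsub("[^N]", "", m1[["s1"]]))
  expect_identical(n_count, sum(IRanges::width(GenomicRanges::ranges(mk))))
  expect_identical(build_intergenic(m1, repeat_mask = mk), m1)

  expect_error(build_intergenic(g, mask_track("s1", 25, 40, "gene")),
               "out of range")
  expect_error(build_intergenic(g, mask_track("nope", 1, 5, "gene")),
               "unknown sequence")
})

test_that("pseudogene calls round-trip through GFF3", {
  calls <- data.frame(
    call_id = c("psg0001", "psg0002"), seq_id = "chr1", strand = c("+", "-"),
    start = c(5L, 100L), end = c(10L, 220L), parent_id = c("gA", "gB"),
    class = c("processed", "fragment"), total_score = c(55, 12),
    coverage = c(0.91, 0.4), n_stops = c(2L, 0L), n_frameshifts = c(1L, 0L),
    polyA = c(TRUE, FALSE), ka = c(0.11, NA), ks = c(0.12, NA),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_calls_gff3(calls, f)
  gr <- rtracklayer::import(f, format = "gff3")
  expect_identical(GenomicRanges::start(gr), c(5L, 100L))
  expect_identical(GenomicRanges::end(gr), c(10L, 220L))
  expect_identical(as.character(gr$type), rep("pseudogene", 2))
  expect_identical(as.character(gr$ID), calls$call_id)
  expect_identical(as.character(gr$class), calls$class)
  expect_identical(as.character(gr$n_stops), c("2", "0"))
  expect_identical(as.character(gr$polyA), c("true", "false"))

  back <- read_annotation(f)
  expect_identical(back$start, calls$start)
  expect_identical(back$end, calls$end)
  expect_identical(back$id, calls$call_id)

  write_calls_gff3(calls[0, ], f)
  expect_identical(readLines(f), "##gff-version 3")
})

test_that("translation of accepted gene models never has internal stops", {
  set.seed(31)
  for (i in 1:10) {
    fx <- make_genome_with_gene(plen = 40, n_exons = sample(1:3, 1),
                                strand = sample(c("+", "-"), 1))
    expect_false(grepl("*", fx$model$protein, fixed = TRUE))
    # splicing the recorded exon intervals reproduces the CDS
    ex <- fx$model$exons
    sp <- paste(substring(fx$genome[[1]], ex$start, ex$end), collapse = "")
    if (fx$model$strand == "-") sp <- revcomp(sp)
    expect_identical(sp, fx$cds)
  }
})
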