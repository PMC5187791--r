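test_that("poly-A detection finds downstream A-rich windows strand-awarely", {
  set.seed(83)
  elem <- random_dna_str(300, gc = 0.6)
  g <- c(c1 = paste0(random_dna_str(100, gc = 0.6), elem, strrep("A", 30),
                     random_dna_str(100, gc = 0.6)))
  pa <- detect_polyA(g, "c1", 101, 400, "+")
  expect_true(pa$polyA)
  expect_lte(pa$start, 405)
  expect_gte(pa$end, 425)

  # GC-rich downstream sequence: no signal
  g2 <- c(c1 = paste0(random_dna_str(100), elem, strrep("GC", 60)))
  expect_false(detect_polyA(g2, "c1", 101, 400, "+")$polyA)

  # minus strand: poly-T upstream in forward coordinates
  g3 <- c(c1 = paste0(random_dna_str(100, gc = 0.6), strrep("T", 30), elem,
                      random_dna_str(60, gc = 0.6)))
  expect_true(detect_polyA(g3, "c1", 131, 430, "-")$polyA)
  expect_false(detect_polyA(g3, "c1", 131, 430, "+")$polyA)
})

test_that("poly-A boundary sits exactly at the threshold fraction", {
  # a 20-nt window with 16 A (fraction 0.8) is a tail; 15 A is not
  cfg <- classify_params()
  base <- strrep("G", 60)
  mk <- function(n_a) {
    w <- c(rep("A", n_a), rep("G", 20 - n_a))
    paste(w, collapse = "")  # A-run then G: fraction n_a/20 in the window
  }
  g_yes <- c(c1 = paste0(base, mk(16), base))
  g_no <- c(c1 = paste0(base, mk(15), base))
  # element ends right before the constructed window; only that window is
  # A-rich
  expect_true(detect_polyA(g_yes, "c1", 1, 60, "+", cfg)$polyA)
  expect_false(detect_polyA(g_no, "c1", 1, 60, "+", cfg)$polyA)
})

test_that("target-site duplications are detected and rare under the null", {
  set.seed(89)
  tsd <- random_dna_str(12)
  elem <- random_dna_str(400, gc = 0.55)
  g <- c(c1 = paste0(random_dna_str(150), tsd, elem, tsd,
                     random_dna_str(150)))
  d <- detect_direct_repeats(g, "c1", 163, 562)
  expect_true(d$tsd)
  expect_identical(d$kmer, tsd)

  # no TSD implanted: not detected
  g2 <- c(c1 = paste0(random_dna_str(150), elem, random_dna_str(150)))
  expect_false(detect_direct_repeats(g2, "c1", 151, 550)$tsd)

  # Monte-Carlo null: false-positive rate at defaults stays low
  set.seed(97)
  fp <- 0
  for (i in 1:200) {
    gg <- c(c1 = random_dna_str(1200))
    fp <- fp + detect_direct_repeats(gg, "c1", 500, 700)$tsd
  }
  expect_lte(fp / 200, 0.05)
})

test_that("intron status distinguishes intron loss from retention", {
  set.seed(101)
  fx <- make_genome_with_gene(plen = 120, n_exons = 3, intron_len = 70)
  # intronless (spliced) copy of the 3-exon parent
  body <- substr(fx$cds, 1, nchar(fx$cds) - 3)
  g1 <- c(cc = paste0(random_dna_str(200), body, random_dna_str(200)))
  al1 <- global_align(fx$model, fake_locus("cc", "+", "parentA", 201,
                                           200 + nchar(body)), g1)
  expect_identical(intron_status(al1, fx$model), "introns_absent")

  # genomic copy retaining both introns
  gen_copy <- substr(fx$genome[[1]], fx$gene_start, fx$gene_end)
  g2 <- c(cc = paste0(random_dna_str(200), gen_copy, random_dna_str(200)))
  al2 <- global_align(fx$model, fake_locus("cc", "+", "parentA", 201,
                                           200 + nchar(gen_copy)), g2)
  expect_identical(intron_status(al2, fx$model), "introns_present")

  # single-exon parent: parent_intronless regardless of the alignment
  fx1 <- make_genome_with_gene(plen = 60, n_exons = 1)
  b1 <- substr(fx1$cds, 1, nchar(fx1$cds) - 3)
  g3 <- c(cc = paste0(random_dna_str(200), b1, random_dna_str(200)))
  al3 <- global_align(fx1$model, fake_locus("cc", "+", "parentA", 201,
                                            200 + nchar(b1)), g3)
  expect_identical(intron_status(al3, fx1$model), "parent_intronless")
})

test_that("classification applies the coverage, intron and poly-A rules", {
  set.seed(103)
  fx <- make_genome_with_gene(plen = 100, n_exons = 2)
  body <- substr(fx$cds, 1, nchar(fx$cds) - 3)
  g <- c(cc = paste0(random_dna_str(200), body, random_dna_str(200)))
  loc <- fake_locus("cc", "+", "parentA", 201, 200 + nchar(body))
  al <- global_align(fx$model, loc, g)
  no_pa <- list(polyA = FALSE)
  no_dr <- list(tsd = FALSE)

  # full-coverage intronless copy of an intron-bearing parent: processed
  expect_identical(classify_call(al, fx$model, no_pa, no_dr)$class,
                   "processed")

  # low coverage dominates: fragment
  al_frag <- al
  al_frag$coverage <- 0.40
  expect_identical(classify_call(al_frag, fx$model, no_pa, no_dr)$class,
                   "fragment")

  # intron retention: duplicated
  gen_copy <- substr(fx$genome[[1]], fx$gene_start, fx$gene_end)
  g2 <- c(cc = paste0(random_dna_str(200), gen_copy, random_dna_str(200)))
  al2 <- global_align(fx$model, fake_locus("cc", "+", "parentA", 201,
                                           200 + nchar(gen_copy)), g2)
  c2 <- classify_call(al2, fx$model, no_pa, no_dr)
  expect_identical(c2$class, "duplicated")
  expect_true(c2$no_disablement)   # clean copy, introns retained

  # intronless parent needs the poly-A signal to be called processed
  fx1 <- make_genome_with_gene(plen = 80, n_exons = 1)
  b1 <- substr(fx1$cds, 1, nchar(fx1$cds) - 3)
  g3 <- c(cc = paste0(random_dna_str(200), b1, random_dna_str(200)))
  al3 <- global_align(fx1$model, fake_locus("cc", "+", "parentA", 201,
                                            200 + nchar(b1)), g3)
  expect_identical(classify_call(al3, fx1$model, no_pa, no_dr)$class,
                   "duplicated")
  expect_identical(classify_call(al3, fx1$model, list(polyA = TRUE),
                                 no_dr)$class, "processed")
})
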