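# plant a pseudogene body into random flanks and realign it to its parent
realign_fixture <- function(body, model, flankL = 200, flankR = 200,
                            strand = "+", params = align_params()) {
  ins <- if (strand == "+") body else revcomp(body)
  g <- c(chrR = paste0(random_dna_str(flankL), ins, random_dna_str(flankR)))
  locus <- fake_locus("chrR", strand, model$gene_id,
                      flankL + 1, flankL + nchar(ins))
  global_align(model, locus, g, params)
}

test_that("self-alignment of an intronless copy is clean and complete", {
  set.seed(41)
  fx <- make_genome_with_gene(plen = 80)
  body <- substr(fx$cds, 1, nchar(fx$cds) - 3)
  al <- realign_fixture(body, fx$model)
  expect_equal(al$coverage, 1.0)
  expect_equal(al$identity, 1.0)
  expect_identical(al$n_premature_stops, 0L)
  expect_identical(al$n_frameshifts, 0L)
  expect_identical(al$n_indel_events, 0L)
  expect_identical(nrow(al$intron_gaps), 0L)
  expect_equal(al$g_start, 201)
  expect_equal(al$g_end, 200 + nchar(body))
})

test_that("a planted TAA is reported as one premature stop at its codon", {
  set.seed(43)
  fx <- make_genome_with_gene(plen = 80)
  body <- substr(fx$cds, 1, nchar(fx$cds) - 3)
  codon <- 37
  substr(body, 3 * (codon - 1) + 1, 3 * codon) <- "TAA"
  al <- realign_fixture(body, fx$model)
  expect_identical(al$n_premature_stops, 1L)
  expect_identical(al$n_frameshifts, 0L)
  d <- al$disablements[al$disablements$kind == "premature_stop", ]
  expect_equal(d$protein_pos, codon)
  expect_equal(d$genomic_pos, 200 + 3 * (codon - 1) + 1)
})

test_that("a 1-nt deletion is reported as one frameshift, frame restored", {
  set.seed(47)
  fx <- make_genome_with_gene(plen = 80)
  body <- substr(fx$cds, 1, nchar(fx$cds) - 3)
  del_at <- 3 * 39 + 2
  body2 <- paste0(substr(body, 1, del_at - 1),
                  substr(body, del_at + 1, nchar(body)))
  al <- realign_fixture(body2, fx$model)
  expect_identical(al$n_frameshifts, 1L)
  expect_identical(al$n_premature_stops, 0L)
  expect_gt(al$identity, 0.9)
  expect_equal(al$coverage, 1.0)
})

test_that("intron retention is recovered as an intron gap at the junction", {
  set.seed(53)
  fx <- make_genome_with_gene(plen = 100, n_exons = 2, intron_len = 80)
  # genomic copy including the intron
  ex <- fx$model$exons
  body <- substr(fx$genome[[1]], fx$gene_start, fx$gene_end)
  al <- realign_fixture(body, fx$model)
  expect_equal(al$coverage, 1.0)
  expect_identical(nrow(al$intron_gaps), 1L)
  j <- fx$model$intron_junctions
  expect_lte(abs(al$intron_gaps$q_pos - j), 2)
  expect_equal(al$intron_gaps$g_end - al$intron_gaps$g_start + 1, 80)
})

test_that("truncated copies report strand-aware 5'/3' truncation", {
  set.seed(59)
  fx <- make_genome_with_gene(plen = 90)
  full <- substr(fx$cds, 1, nchar(fx$cds) - 3)
  al <- realign_fixture(full, fx$model)
  tr <- detect_truncations(al, fx$model)
  expect_false(tr$five_prime$truncated)
  expect_false(tr$three_prime$truncated)

  miss30 <- substr(full, 91, nchar(full))     # first 30 codons removed
  g <- c(chrR = paste0(random_dna_str(200), miss30, random_dna_str(200)))
  al5 <- global_align(fx$model,
                      fake_locus("chrR", "+", "parentA", 201,
                                 200 + nchar(miss30)), g)
  tr5 <- detect_truncations(al5, fx$model)
  expect_true(tr5$five_prime$truncated)
  expect_identical(tr5$five_prime$aa, 30L)

  # the reverse-complemented genome with a minus-strand locus reports the
  # same truncation relative to the parent reading direction
  L <- nchar(g[[1]])
  grc <- c(chrR = revcomp(g[[1]]))
  al5m <- global_align(fx$model,
                       fake_locus("chrR", "-", "parentA",
                                  L - (200 + nchar(miss30)) + 1, L - 200),
                       grc)
  tr5m <- detect_truncations(al5m, fx$model)
  expect_identical(tr5m$five_prime$aa, 30L)
  expect_equal(al5m$score, al5$score)
})

test_that("minus-strand alignment mirrors scores and coordinates", {
  set.seed(61)
  fx <- make_genome_with_gene(plen = 70)
  body <- substr(fx$cds, 1, nchar(fx$cds) - 3)
  substr(body, 100, 102) <- "TAA"
  g <- c(chrR = paste0(random_dna_str(150), body, random_dna_str(150)))
  alp <- global_align(fx$model,
                      fake_locus("chrR", "+", "parentA", 151,
                                 150 + nchar(body)), g)
  L <- nchar(g[[1]])
  grc <- c(chrR = revcomp(g[[1]]))
  alm <- global_align(fx$model,
                      fake_locus("chrR", "-", "parentA",
                                 L - (150 + nchar(body)) + 1, L - 150), grc)
  expect_equal(alm$score, alp$score)
  expect_identical(alm$n_premature_stops, alp$n_premature_stops)
  expect_equal(alm$g_start, L - alp$g_end + 1)
  expect_equal(alm$g_end, L - alp$g_start + 1)
})

test_that("on clean inputs the DP reduces to protein-level global alignment", {
  set.seed(67)
  p <- align_params()
  for (rep in 1:5) {
    plen <- 40
    cds <- make_cds(plen)
    body <- substr(cds, 1, 3 * plen)
    prot <- translate_frame(body, "+", 0)
    # two conservative interior substitutions at the protein level
    body2 <- body
    for (cp in sample(5:35, 2)) {
      substr(body2, 3 * (cp - 1) + 1, 3 * cp) <- sample(SENSE, 1)
    }
    r <- pseudoscan:::.glocal_align_cpp(prot, body2, p$substitution_matrix,
                                        p$gap_open, p$gap_extend,
                                        p$frameshift_penalty, p$stop_penalty,
                                        p$intron_open, p$min_intron,
                                        p$splice_bonus)
    nw <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prot),
      Biostrings::AAString(translate_frame(body2, "+", 0)),
      type = "global", substitutionMatrix = p$substitution_matrix,
      gapOpening = p$gap_open, gapExtension = p$gap_extend,
      scoreOnly = TRUE)
    expect_gte(r$score, nw)       # local never scores below global
    if (r$q_start == 1 && r$q_end == plen) expect_equal(r$score, nw)
  }
})

test_that("DP optimum equals the naive enumeration oracle on small instances", {
  set.seed(71)
  p <- align_params(min_intron = 10)
  for (rep in 1:25) {
    prot <- random_protein(sample(4:12, 1))
    dna <- random_dna_str(sample(15:50, 1))
    r <- pseudoscan:::.glocal_align_cpp(prot, dna, p$substitution_matrix,
                                        p$gap_open, p$gap_extend,
                                        p$frameshift_penalty, p$stop_penalty,
                                        p$intron_open, p$min_intron,
                                        p$splice_bonus)
    expect_equal(r$score, oracle_glocal_score(prot, dna, p))
  }
})

test_that("column counts on the optimal path match the reported counts", {
  set.seed(73)
  fx <- make_genome_with_gene(plen = 120)
  body <- substr(fx$cds, 1, nchar(fx$cds) - 3)
  substr(body, 61, 63) <- "TGA"
  substr(body, 181, 183) <- "TAG"
  al <- realign_fixture(body, fx$model)
  expect_identical(al$n_premature_stops, sum(al$columns$stop))
  expect_identical(al$n_frameshifts, sum(al$columns$type == 2L))
  rl <- rle(al$columns$type)
  expect_identical(al$n_indel_events, sum(rl$values %in% c(3L, 4L)))
})
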