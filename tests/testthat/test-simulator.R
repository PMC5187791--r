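small_cfg <- function(...) {
  sim_config(genome_length = 60000, n_genes = 4, n_processed = 3,
             n_duplicated = 3, min_spacer = 200, ...)
}

test_that("simulation is fully deterministic under a fixed seed", {
  s1 <- simulate_genome(small_cfg(seed = 5))
  s2 <- simulate_genome(small_cfg(seed = 5))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$models, s2$models)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_sim(s1, d1); p2 <- write_sim(s2, d2)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[nm])),
                     unname(tools::md5sum(p2[nm])))
  }
})

test_that("zero implants yield genes and background only", {
  s <- simulate_genome(sim_config(genome_length = 30000, n_genes = 3,
                                  n_processed = 0, n_duplicated = 0,
                                  seed = 2))
  expect_identical(nrow(s$truth), 0L)
  expect_length(s$models, 3)
  expect_identical(nchar(s$genome[[1]]), 30000L)
})

test_that("background composition tracks the configured GC content", {
  s <- simulate_genome(sim_config(genome_length = 100000, n_genes = 0,
                                  n_processed = 0, n_duplicated = 0,
                                  gc_content = 0.40, seed = 3))
  gc <- nchar(gsub("[^GC]", "", s$genome[[1]])) / 100000
  se <- sqrt(0.4 * 0.6 / 100000)
  expect_lt(abs(gc - 0.40), 3 * se)
})

test_that("class-specific truth postconditions hold for every implant", {
  s <- simulate_genome(sim_config(genome_length = 250000, n_genes = 10,
                                  n_processed = 8, n_duplicated = 8,
                                  n_unitary = 2, n_fragments = 4, seed = 7))
  tr <- s$truth
  expect_identical(nrow(tr), 22L)
  # locations pairwise disjoint and within bounds
  o <- order(tr$start)
  expect_true(all(tr$start[o][-1] > tr$end[o][-nrow(tr)]))
  expect_true(all(tr$start >= 1 & tr$end <= nchar(s$genome[[1]])))
  # processed: poly-A and TSD flags, no induced structural disablement
  pr <- tr[tr$class == "processed", ]
  expect_true(all(pr$polyA) && all(pr$tsd))
  # duplicated/unitary: at least one induced disablement
  du <- tr[tr$class %in% c("duplicated", "unitary"), ]
  expect_true(all(du$n_stops_induced + du$n_frameshifts_induced >= 1))
  # unitary parents are absent from the emitted annotation
  un <- tr[tr$class == "unitary", ]
  expect_false(any(un$parent_id %in% names(s$models)))
  expect_true(all(tr$parent_id[tr$class != "unitary"] %in% names(s$models)))
  # fragments cover less than the classification threshold by construction
  fr <- tr[tr$class == "fragment", ]
  for (i in seq_len(nrow(fr))) {
    plen <- nchar(s$models[[fr$parent_id[i]]]$protein)
    expect_lt((fr$end[i] - fr$start[i] + 1) / (3 * plen), 0.70)
  }
})

test_that("processed implants splice out introns and carry exact TSDs", {
  cfg <- sim_config(truncation_5prime_prob = 0, divergence = 0,
                    indel_rate = 0, seed = 11)
  set.seed(11)
  tpl <- pseudoscan:::make_parent_template("gX", cfg)
  im <- implant_processed(tpl, cfg)
  # no intron sequence survives in the implant: the body is the spliced CDS
  body <- substr(im$block, im$core_rel[1], im$core_rel[2])
  expect_identical(body, tpl$cds)
  # flanking TSDs are identical k-mers
  k <- im$core_rel[1] - 1
  expect_identical(substr(im$block, 1, k),
                   substr(im$block, nchar(im$block) - k + 1,
                          nchar(im$block)))
  # poly-A tail directly downstream of the body
  pa <- substr(im$block, im$polyA_rel[1], im$polyA_rel[2])
  expect_identical(unique(strsplit(pa, "")[[1]]), "A")

  # forced truncation is recorded and shortens the implant
  cfg2 <- sim_config(truncation_5prime_prob = 1, divergence = 0,
                     indel_rate = 0, seed = 12)
  set.seed(12)
  im2 <- implant_processed(tpl, cfg2)
  expect_true(im2$truncated5)
  expect_lt(im2$core_rel[2] - im2$core_rel[1] + 1, nchar(tpl$cds))
})

test_that("duplicated implants retain introns and carry a forced disablement", {
  cfg <- sim_config(divergence = 0, indel_rate = 0, seed = 13)
  set.seed(13)
  tpl <- pseudoscan:::make_parent_template("gY", cfg)
  im <- implant_duplicated(tpl, cfg)
  expect_gte(im$n_stops + im$n_fs, 1)
  # at divergence 0 with one forced stop: exactly one codon differs
  if (im$n_stops == 1) {
    d <- mapply(function(a, b) a != b,
                strsplit(tpl$block, "")[[1]], strsplit(im$block, "")[[1]])
    expect_lte(sum(d), 3)
    expect_gte(sum(d), 1)
  } else {
    expect_identical(nchar(im$block), nchar(tpl$block) - 1L)
  }
  # every intron is present verbatim at divergence 0
  n_ex <- nrow(tpl$exon_offsets)
  if (n_ex > 1) {
    for (i in seq_len(n_ex - 1)) {
      intr <- substr(tpl$block, tpl$exon_offsets[i, 2] + 1,
                     tpl$exon_offsets[i + 1, 1] - 1)
      expect_true(grepl(intr, im$block, fixed = TRUE))
    }
  }
})

test_that("mutation honours its rates and selection modes", {
  set.seed(17)
  s <- random_dna_str(10000)
  expect_identical(mutate_seq(s, 0, 0)$seq, s)

  m <- mutate_seq(s, 0.05, 0)
  mm <- mean(strsplit(s, "")[[1]] != strsplit(m$seq, "")[[1]])
  se <- sqrt(0.05 * 0.95 / 10000)
  # applied substitutions can collide on a site, but the observed mismatch
  # fraction stays within binomial noise of the target
  expect_lt(abs(mm - 0.05), 4 * se)

  mi <- mutate_seq(s, 0, 0.002)
  expect_gt(mi$n_indel, 0)
  expect_false(nchar(mi$seq) == nchar(s) && identical(mi$seq, s))
})

test_that("infeasible packing is rejected with guidance", {
  expect_error(simulate_genome(sim_config(genome_length = 5000, n_genes = 5,
                                          seed = 1)),
               "genome_length")
})
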