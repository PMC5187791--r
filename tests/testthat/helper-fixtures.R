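# programmatic fixtures: tiny genes, genomes and loci built in code

SENSE <- local({
  b <- c("T", "C", "A", "G")
  all <- apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1,
               paste, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
})

# a CDS of `plen` amino acids (ATG + plen-1 sense codons + TAA stop)
make_cds <- function(plen) {
  paste0("ATG", paste(sample(SENSE, plen - 1, replace = TRUE), collapse = ""),
         "TAA")
}

# a genome holding one gene (optionally multi-exon) with random flanks
make_genome_with_gene <- function(plen = 60, n_exons = 1, intron_len = 60,
                                  flank = 300, strand = "+",
                                  seq_id = "chrT", gene_id = "parentA") {
  cds <- make_cds(plen)
  total <- nchar(cds)
  cuts <- if (n_exons > 1) {
    3 * sort(sample(seq_len(plen - 1), n_exons - 1))
  } else integer(0)
  bounds <- c(0, cuts, total)
  introns <- replicate(max(0, n_exons - 1), {
    paste0("GT", random_dna_str(intron_len - 4), "AG")
  })
  parts <- character(0)
  ex_rel <- matrix(0L, n_exons, 2)
  pos <- 1L
  for (i in seq_len(n_exons)) {
    w <- bounds[i + 1] - bounds[i]
    parts <- c(parts, substr(cds, bounds[i] + 1, bounds[i + 1]))
    ex_rel[i, ] <- c(pos, pos + w - 1L)
    pos <- pos + w
    if (i < n_exons) {
      parts <- c(parts, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  block <- paste(parts, collapse = "")
  bfwd <- if (strand == "+") block else revcomp(block)
  blen <- nchar(bfwd)
  gstart <- flank + 1L
  ex_fwd <- t(apply(ex_rel, 1, function(r) {
    if (strand == "+") gstart + r - 1L
    else c(gstart + blen - r[2], gstart + blen - r[1])
  }))
  genome <- stats::setNames(
    paste0(random_dna_str(flank), bfwd, random_dna_str(flank)), seq_id)
  protein <- substr(translate_frame(cds, "+", 0), 1, plen)
  junctions <- if (n_exons > 1) as.integer(cuts / 3) else integer(0)
  model <- gene_model(gene_id, seq_id, strand,
                      data.frame(start = ex_fwd[, 1], end = ex_fwd[, 2]),
                      cds, protein, junctions)
  list(genome = genome, model = model, cds = cds, protein = protein,
       gene_start = gstart, gene_end = gstart + blen - 1L)
}

# minimal hand-built candidate locus for realignment tests
fake_locus <- function(seq_id, strand, parent_id, start, end, score = 100) {
  structure(list(locus_id = "locusT", seq_id = seq_id, strand = strand,
                 parent_id = parent_id,
                 segments = data.frame(query_id = parent_id, seq_id = seq_id,
                                       strand = strand, t_start = start,
                                       t_end = end, q_start = 1, q_end = 1,
                                       raw_score = score, identity = 1),
                 span = c(start = start, end = end),
                 total_score = score, identity = 1),
            class = "candidate_locus")
}

# a hit-table row builder
make_hit <- function(query_id, t_start, t_end, raw_score,
                     q_start = 1, q_end = (t_end - t_start + 1) %/% 3,
                     seq_id = "chrT", strand = "+", frame = 0,
                     identity = 0.9) {
  data.frame(query_id = query_id, seq_id = seq_id, strand = strand,
             frame = frame, q_start = q_start, q_end = q_end,
             t_start = t_start, t_end = t_end, raw_score = raw_score,
             bit_score = raw_score / 2, evalue = 1e-10, identity = identity,
             stringsAsFactors = FALSE)
}
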