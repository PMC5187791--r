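#' Configuration of the synthetic-genome simulator
#'
#' The generator emulates the study conditions used throughout the package's
#' validation: i.i.d. background DNA at a given GC content, multi-exon
#' parent genes with valid ORFs and GT..AG introns, and implanted
#' pseudogenes of each formation class at a configurable neutral divergence
#' -- processed (intronless, poly-A-tailed, TSD-flanked, optionally
#' 5'-truncated), duplicated (intron-retaining with a forced premature stop
#' or frameshift), unitary (duplicated-style copy whose parent is removed
#' from the emitted annotation) and short fragments.
#'
#' @param genome_length total length (nt) of the simulated sequence.
#' @param seq_id name of the simulated sequence.
#' @param n_genes number of emitted parent genes.
#' @param exons_per_gene integer range of exon counts.
#' @param exon_len,intron_len nt ranges (exon lengths are rounded to codon
#'   multiples so intron junctions are codon-aligned).
#' @param min_cds_len minimum CDS length (nt, incl. stop codon); short draws
#'   are padded so every parent has at least ~200 codons.
#' @param gc_content background GC fraction.
#' @param n_processed,n_duplicated,n_unitary,n_fragments implant counts.
#' @param divergence expected substitutions per site applied to implants.
#' @param indel_rate indel events per site (1-3 nt each).
#' @param truncation_5prime_prob,truncation_max_fraction probability and
#'   maximal extent of 5' truncation of processed implants.
#' @param polyA_len,tsd_len nt ranges of the poly-A tail and the target-site
#'   duplication.
#' @param fragment_coverage range of parent coverage for fragment implants
#'   (kept below the fragment classification threshold).
#' @param min_spacer minimum intergenic spacer (nt) between placed blocks.
#' @param seed integer seed; the same seed yields byte-identical outputs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000, seq_id = "chrS",
                       n_genes = 20, exons_per_gene = c(2, 4),
                       exon_len = c(150, 400), intron_len = c(60, 200),
                       min_cds_len = 603, gc_content = 0.40,
                       n_processed = 20, n_duplicated = 20,
                       n_unitary = 0, n_fragments = 0,
                       divergence = 0.05, indel_rate = 0.002,
                       truncation_5prime_prob = 0.3,
                       truncation_max_fraction = 0.25,
                       polyA_len = c(20, 40), tsd_len = c(8, 16),
                       fragment_coverage = c(0.20, 0.55),
                       min_spacer = 300, seed = 1) {
  stopifnot_scalar_num(gc_content, "gc_content", 0, 1)
  stopifnot_scalar_num(divergence, "divergence", 0, 1)
  stopifnot_scalar_num(indel_rate, "indel_rate", 0, 1)
  stopifnot_scalar_num(truncation_5prime_prob, "truncation_5prime_prob", 0, 1)
  if (max(fragment_coverage) >= 0.7)
    stop("fragment_coverage must stay below 0.7", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

SENSE_CODONS <- local({
  b <- c("T", "C", "A", "G")
  all <- apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1,
               paste, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
})

sample_range <- function(r) if (r[1] >= r[2]) r[1] else sample(r[1]:r[2], 1)

#' Apply neutral or purifying point mutations and small indels
#'
#' Per-site substitution with probability `divergence`, uniform over the
#' three alternative bases in neutral mode; in purifying mode (for in-frame
#' coding sequence) nonsynonymous substitutions are accepted with
#' probability 0.1 only, emulating selective constraint. Indels of 1-3 nt
#' occur at `indel_rate` per site. Deterministic given the RNG state.
#'
#' @param seq DNA string (an in-frame CDS when `selection_mode` is
#'   `"purifying"`).
#' @param divergence substitution probability per site.
#' @param indel_rate indel event probability per site.
#' @param selection_mode `"neutral"` or `"purifying"`.
#' @return list with `seq`, `n_sub`, `n_indel`.
#' @export
mutate_seq <- function(seq, divergence, indel_rate = 0,
                       selection_mode = c("neutral", "purifying")) {
  selection_mode <- match.arg(selection_mode)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  n_sub <- 0L
  if (divergence > 0 && n > 0) {
    idx <- which(stats::runif(n) < divergence)
    for (i in idx) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
      if (selection_mode == "purifying") {
        cs <- ((i - 1) %/% 3) * 3 + 1
        if (cs + 2 <= n) {
          old <- paste(chars[cs:(cs + 2)], collapse = "")
          nw <- chars; nw[i] <- alt
          new <- paste(nw[cs:(cs + 2)], collapse = "")
          if (.translate_cpp(old) != .translate_cpp(new) &&
              stats::runif(1) >= 0.1) next
        }
      }
      chars[i] <- alt
      n_sub <- n_sub + 1L
    }
  }
  n_indel <- 0L
  if (indel_rate > 0 && length(chars) > 0) {
    pos <- which(stats::runif(length(chars)) < indel_rate)
    for (p in rev(pos)) {
      len <- sample(1:3, 1)
      if (stats::runif(1) < 0.5) {      # deletion
        hi <- min(p + len - 1, length(chars))
        chars <- chars[-(p:hi)]
      } else {                          # insertion
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        chars <- append(chars, ins, after = p)
      }
      n_indel <- n_indel + 1L
    }
  }
  list(seq = paste(chars, collapse = ""), n_sub = n_sub, n_indel = n_indel)
}

# a parent gene template in sense orientation: CDS with valid ORF, exon
# lengths rounded to codon multiples, GT..AG introns at codon boundaries
make_parent_template <- function(id, cfg) {
  n_ex <- sample_range(cfg$exons_per_gene)
  ex_len <- vapply(seq_len(n_ex), function(i) {
    3 * max(1, round(sample_range(cfg$exon_len) / 3))
  }, numeric(1))
  deficit <- cfg$min_cds_len - sum(ex_len)
  if (deficit > 0) ex_len[n_ex] <- ex_len[n_ex] + 3 * ceiling(deficit / 3)
  total <- sum(ex_len)
  plen <- total / 3 - 1
  cds <- paste0("ATG",
                paste(sample(SENSE_CODONS, plen - 1, replace = TRUE),
                      collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1))
  introns <- if (n_ex > 1) {
    vapply(seq_len(n_ex - 1), function(i) {
      len <- max(8, sample_range(cfg$intron_len))
      paste0("GT", random_dna(len - 4, cfg$gc_content), "AG")
    }, character(1))
  } else character(0)
  parts <- character(0)
  ex_off <- matrix(0L, nrow = n_ex, ncol = 2)
  pos <- 1L
  cum <- cumsum(ex_len)
  for (i in seq_len(n_ex)) {
    s <- if (i == 1) 1 else cum[i - 1] + 1
    exon_seq <- substr(cds, s, cum[i])
    parts <- c(parts, exon_seq)
    ex_off[i, ] <- c(pos, pos + ex_len[i] - 1L)
    pos <- pos + ex_len[i]
    if (i < n_ex) {
      parts <- c(parts, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  block <- paste(parts, collapse = "")
  junctions <- if (n_ex > 1) as.integer(cum[-n_ex] / 3) else integer(0)
  list(id = id, cds = cds,
       protein = substr(.translate_cpp(cds), 1, plen),
       block = block, exon_offsets = ex_off, exon_len = ex_len,
       junctions = junctions[junctions >= 1 & junctions <= plen - 1])
}

# force one disablement (premature stop or 1-nt exonic deletion) into a
# gene-block copy; returns the modified block and the induced counts
force_disablement <- function(tpl) {
  plen <- nchar(tpl$protein)
  codon <- sample(5:(plen - 5), 1)
  cds_pos <- 3 * (codon - 1) + 1
  cum <- cumsum(tpl$exon_len)
  ex <- which(cds_pos <= cum)[1]
  within <- cds_pos - (if (ex == 1) 0 else cum[ex - 1])
  bpos <- tpl$exon_offsets[ex, 1] + within - 1
  block <- tpl$block
  if (stats::runif(1) < 0.5) {
    substr(block, bpos, bpos + 2) <- "TAA"
    list(block = block, n_stops = 1L, n_fs = 0L, stop_pos = bpos)
  } else {
    block <- paste0(substr(block, 1, bpos - 1),
                    substr(block, bpos + 1, nchar(block)))
    list(block = block, n_stops = 0L, n_fs = 1L, stop_pos = NA_integer_)
  }
}

#' Construct a processed-pseudogene implant
#'
#' A spliced copy of the parent mRNA: no introns, optional 5' truncation,
#' neutral mutations, a 3' poly-A tail, and identical target-site
#' duplications flanking the whole insertion.
#'
#' @param tpl a parent template (internal) or [gene_model()]-like list with
#'   `cds`.
#' @param cfg a [sim_config()].
#' @return implant description (block in sense orientation, relative core /
#'   poly-A intervals, truth fields).
#' @export
implant_processed <- function(tpl, cfg) {
  body <- tpl$cds
  truncated <- stats::runif(1) < cfg$truncation_5prime_prob
  if (truncated) {
    cut <- floor(stats::runif(1, 0.05, cfg$truncation_max_fraction) *
                   nchar(body))
    body <- substr(body, cut + 1, nchar(body))
  }
  mut <- mutate_seq(body, cfg$divergence, cfg$indel_rate)
  polyA <- strrep("A", sample_range(cfg$polyA_len))
  tsd <- random_dna(sample_range(cfg$tsd_len), cfg$gc_content)
  k <- nchar(tsd); bl <- nchar(mut$seq)
  list(class = "processed", parent_id = tpl$id,
       block = paste0(tsd, mut$seq, polyA, tsd),
       core_rel = c(k + 1, k + bl),
       polyA_rel = c(k + bl + 1, k + bl + nchar(polyA)),
       n_stops = 0L, n_fs = 0L, polyA = TRUE, tsd = TRUE,
       truncated5 = truncated)
}

#' Construct a duplicated-pseudogene implant
#'
#' A full genomic copy of the parent including its introns, neutrally
#' mutated, with at least one forced disablement (premature stop
#' substitution or 1-nt exonic deletion) recorded in the truth.
#'
#' @inheritParams implant_processed
#' @return implant description.
#' @export
implant_duplicated <- function(tpl, cfg) {
  forced <- force_disablement(tpl)
  mut <- mutate_seq(forced$block, cfg$divergence, 0)
  block <- mut$seq
  if (forced$n_stops > 0) {
    # neutral substitutions must not silently revert the forced stop
    p <- forced$stop_pos
    if (!substr(block, p, p + 2) %in% STOP_CODONS)
      substr(block, p, p + 2) <- "TAA"
  }
  block <- mutate_seq(block, 0, cfg$indel_rate)$seq
  list(class = "duplicated", parent_id = tpl$id, block = block,
       core_rel = c(1, nchar(block)), polyA_rel = NULL,
       n_stops = forced$n_stops, n_fs = forced$n_fs,
       polyA = FALSE, tsd = FALSE, truncated5 = FALSE)
}

#' Construct a unitary-pseudogene implant
#'
#' Identical in structure to a duplicated implant, but the parent gene is
#' removed from the emitted annotation so no functional counterpart
#' remains; the truth still records the element for evaluation accounting.
#'
#' @inheritParams implant_processed
#' @return implant description with class `unitary`.
#' @export
implant_unitary <- function(tpl, cfg) {
  out <- implant_duplicated(tpl, cfg)
  out$class <- "unitary"
  out
}

#' Construct a fragment implant
#'
#' A contiguous sub-segment of the parent CDS covering less than the
#' fragment classification threshold, neutrally mutated.
#'
#' @inheritParams implant_processed
#' @return implant description with class `fragment`.
#' @export
implant_fragment <- function(tpl, cfg) {
  plen <- nchar(tpl$protein)
  cov <- stats::runif(1, cfg$fragment_coverage[1], cfg$fragment_coverage[2])
  seg <- max(10, floor(cov * plen))
  if (seg < 1) stop("zero-length fragment requested", call. = FALSE)
  s <- sample(seq_len(plen - seg + 1), 1)
  segment <- substr(tpl$cds, 3 * (s - 1) + 1, 3 * (s + seg - 1))
  mut <- mutate_seq(segment, cfg$divergence, cfg$indel_rate)
  list(class = "fragment", parent_id = tpl$id, block = mut$seq,
       core_rel = c(1, nchar(mut$seq)), polyA_rel = NULL,
       n_stops = 0L, n_fs = 0L, polyA = FALSE, tsd = FALSE,
       truncated5 = FALSE)
}

# map a relative interval within a block to forward-strand coordinates given
# the block's absolute start and orientation
rel_to_fwd <- function(rel, abs_start, block_len, strand) {
  if (is.null(rel)) return(NULL)
  if (strand == "+") c(abs_start + rel[1] - 1, abs_start + rel[2] - 1)
  else c(abs_start + block_len - rel[2], abs_start + block_len - rel[1])
}

#' Simulate an annotated genome with implanted pseudogenes
#'
#' Generates background DNA, places parent genes and pseudogene implants of
#' every class without overlap (random order, random strands, randomized
#' intergenic spacers), and returns the genome, the emitted parent gene
#' models and a machine-readable truth table. Unitary parents are excluded
#' from the emitted models. The same seed yields byte-identical output.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_genome`: list with `genome` (named
#'   character), `models` (list of [gene_model()]), `truth` (data frame)
#'   and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  n_parent_tpl <- config$n_genes + config$n_unitary
  tpls <- lapply(seq_len(n_parent_tpl), function(i) {
    make_parent_template(sprintf("gene%03d", i), config)
  })
  emitted <- tpls[seq_len(config$n_genes)]
  unitary_tpls <- if (config$n_unitary > 0)
    tpls[config$n_genes + seq_len(config$n_unitary)] else list()

  pick <- function(n) {
    if (n == 0 || length(emitted) == 0) return(list())
    emitted[sample(seq_along(emitted), n, replace = TRUE)]
  }
  implants <- c(
    lapply(pick(config$n_processed), implant_processed, cfg = config),
    lapply(pick(config$n_duplicated), implant_duplicated, cfg = config),
    lapply(unitary_tpls, implant_unitary, cfg = config),
    lapply(pick(config$n_fragments), implant_fragment, cfg = config))

  blocks <- c(
    lapply(emitted, function(t) list(kind = "gene", tpl = t,
                                     seq = t$block)),
    lapply(implants, function(im) list(kind = "implant", im = im,
                                       seq = im$block)))
  n_blocks <- length(blocks)
  total_block <- sum(vapply(blocks, function(b) nchar(b$seq), numeric(1)))
  slack <- config$genome_length - total_block -
    (n_blocks + 1) * config$min_spacer
  if (slack < 0)
    stop("blocks do not fit; increase genome_length (need at least ",
         total_block + (n_blocks + 1) * config$min_spacer, " nt)",
         call. = FALSE)
  ord <- sample(n_blocks)
  props <- diff(c(0, sort(stats::runif(n_blocks)), 1))
  spacers <- config$min_spacer + floor(props * slack)
  strands <- sample(c("+", "-"), n_blocks, replace = TRUE)

  pieces <- character(0)
  pos <- 0L
  models <- list()
  truth <- list()
  for (bi in seq_len(n_blocks)) {
    sp <- random_dna(spacers[bi], config$gc_content)
    pieces <- c(pieces, sp)
    pos <- pos + nchar(sp)
    b <- blocks[[ord[bi]]]
    strand <- strands[bi]
    bseq <- if (strand == "+") b$seq else revcomp(b$seq)
    abs_start <- pos + 1L
    blen <- nchar(bseq)
    if (b$kind == "gene") {
      t <- b$tpl
      ex <- t$exon_offsets
      fwd <- t(apply(ex, 1, function(r) {
        rel_to_fwd(r, abs_start, blen, strand)
      }))
      models[[t$id]] <- gene_model(
        t$id, config$seq_id, strand,
        data.frame(start = fwd[, 1], end = fwd[, 2]),
        t$cds, t$protein, t$junctions)
    } else {
      im <- b$im
      core <- rel_to_fwd(im$core_rel, abs_start, blen, strand)
      pa <- rel_to_fwd(im$polyA_rel, abs_start, blen, strand)
      truth[[length(truth) + 1]] <- data.frame(
        element_id = sprintf("pg%03d", length(truth) + 1),
        class = im$class, seq_id = config$seq_id,
        start = core[1], end = core[2], strand = strand,
        parent_id = im$parent_id,
        divergence = config$divergence,
        n_stops_induced = im$n_stops, n_frameshifts_induced = im$n_fs,
        polyA = im$polyA, tsd = im$tsd, truncated5 = im$truncated5,
        context_start = abs_start, context_end = abs_start + blen - 1L,
        stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, bseq)
    pos <- pos + blen
  }
  tail_len <- config$genome_length - pos
  pieces <- c(pieces, random_dna(tail_len, config$gc_content))
  genome <- stats::setNames(paste(pieces, collapse = ""), config$seq_id)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(element_id = character(0), class = character(0),
               seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), parent_id = character(0),
               divergence = numeric(0), n_stops_induced = integer(0),
               n_frameshifts_induced = integer(0), polyA = logical(0),
               tsd = logical(0), truncated5 = logical(0),
               context_start = integer(0), context_end = integer(0),
               stringsAsFactors = FALSE)
  structure(list(genome = genome, models = models, truth = truth,
                 config = config),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %s: %d nt, %d parent genes, %d implants (%s)\n",
              names(x$genome), nchar(x$genome), length(x$models),
              nrow(x$truth),
              paste(sprintf("%s=%d", names(table(x$truth$class)),
                            table(x$truth$class)), collapse = ", ")))
  invisible(x)
}

#' Write a simulated genome to disk
#'
#' Emits the genome FASTA, the parent gene models GFF3, the parent protein
#' FASTA, and the truth TSV.
#'
#' @param sim a `sim_genome`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "parents.gff3"),
             proteins = file.path(dir, "proteins.fa"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(sim$genome, paths["genome"])
  write_gene_models_gff3(sim$models, paths["genes"])
  write_fasta(stats::setNames(
    vapply(sim$models, function(m) m$protein, character(1)),
    names(sim$models)), paths["proteins"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
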