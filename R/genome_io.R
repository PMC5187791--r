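#' Read a FASTA file of DNA sequences
#'
#' Residues are uppercased and `U` is mapped to `T`. IUPAC ambiguity codes
#' other than `N` are either rejected (default) or mapped to `N`.
#'
#' @param path path to a FASTA file.
#' @param ambiguity `"reject"` to error on non-ACGTN residues, `"mask_n"` to
#'   replace them with `N`.
#' @return a named character vector of sequences (a genome).
#' @export
read_fasta <- function(path, ambiguity = c("reject", "mask_n")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path), error = function(e) {
    if (file.size(path) == 0) return(NULL)
    stop("malformed FASTA in '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  if (is.null(set) || length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- gsub("[ACGTN]", "", seqs)
  if (any(nchar(bad) > 0)) {
    offender <- which(nchar(bad) > 0)[1]
    if (ambiguity == "reject")
      stop(sprintf("non-ACGTN residues ('%s') in record '%s'",
                   substr(bad[offender], 1, 5), names(seqs)[offender]),
           call. = FALSE)
    for (i in which(nchar(bad) > 0))
      seqs[i] <- gsub("[^ACGTN]", "N", seqs[i])
  }
  if (anyDuplicated(names(seqs)))
    stop("duplicated sequence ids in '", path, "'", call. = FALSE)
  seqs
}

#' Write DNA sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a parent gene model
#'
#' Coordinates are 1-based inclusive on the forward strand; exons are sorted
#' and disjoint. `intron_junctions` are amino-acid indices after which a
#' parent intron occurs, strictly increasing in (0, protein length).
#'
#' @param gene_id,seq_id,strand identity and location of the gene.
#' @param exons data frame with columns `start`, `end` (forward-strand,
#'   coding order is reversed internally on `-`).
#' @param cds spliced coding sequence (sense strand, including the terminal
#'   stop codon when present).
#' @param protein translated protein (no terminal stop).
#' @param intron_junctions integer vector of junction positions (aa).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, exons, cds, protein,
                       intron_junctions = integer(0)) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons of '", gene_id, "' overlap", call. = FALSE)
  ij <- as.integer(intron_junctions)
  if (length(ij) && (any(diff(ij) <= 0) || any(ij <= 0) || any(ij >= nchar(protein))))
    stop("invalid intron junctions for '", gene_id, "'", call. = FALSE)
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 exons = exons, cds = cds, protein = protein,
                 intron_junctions = ij),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %d exon(s), %d aa\n",
              x$gene_id, x$seq_id, min(x$exons$start), max(x$exons$end),
              x$strand, nrow(x$exons), nchar(x$protein)))
  invisible(x)
}

gene_span <- function(model) {
  c(start = min(model$exons$start), end = max(model$exons$end))
}

#' Read parent gene models from GFF3
#'
#' CDS features are grouped by their `Parent` attribute (falling back to
#' `ID`), spliced in coding order, reverse-complemented on `-`, and
#' translated with the standard genetic code. Records whose CDS length is
#' not divisible by 3, or whose translation contains an internal stop, are
#' rejected with a warning: parents must be functional genes.
#'
#' @param path path to a GFF3 file with gene/mRNA/CDS (or exon) features.
#' @param genome named character vector of sequences (see [read_fasta()]).
#' @return a named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  cds <- gr[typ == "CDS"]
  if (length(cds) == 0) cds <- gr[typ == "exon"]
  if (length(cds) == 0) stop("no CDS or exon features in '", path, "'", call. = FALSE)
  parent <- vapply(seq_along(cds), function(i) {
    p <- cds$Parent[[i]]
    if (length(p)) p[1] else cds$ID[i] %||% NA_character_
  }, character(1))
  # map transcripts to gene ids where an mRNA layer exists
  tx <- gr[typ %in% c("mRNA", "transcript")]
  tx2gene <- if (length(tx)) {
    stats::setNames(vapply(seq_along(tx), function(i) {
      p <- tx$Parent[[i]]
      if (length(p)) p[1] else tx$ID[i]
    }, character(1)), tx$ID)
  } else character(0)
  models <- list()
  for (key in unique(parent)) {
    rows <- which(parent == key)
    sid <- as.character(GenomicRanges::seqnames(cds))[rows[1]]
    strand <- as.character(GenomicRanges::strand(cds))[rows[1]]
    if (!strand %in% c("+", "-")) strand <- "+"
    ex <- data.frame(start = GenomicRanges::start(cds)[rows],
                     end = GenomicRanges::end(cds)[rows])
    ex <- ex[order(ex$start), , drop = FALSE]
    gid <- unname(tx2gene[key] %||% key)
    if (is.na(gid)) gid <- key
    if (!sid %in% names(genome)) {
      warning("sequence '", sid, "' of gene '", gid, "' not in genome; skipped")
      next
    }
    pieces <- substring(genome[[sid]], ex$start, ex$end)
    spliced <- paste(pieces, collapse = "")
    if (strand == "-") spliced <- revcomp(spliced)
    if (nchar(spliced) %% 3 != 0) {
      warning("CDS length of '", gid, "' not divisible by 3; rejected")
      next
    }
    aa <- .translate_cpp(spliced)
    n <- nchar(aa)
    if (substr(aa, n, n) == "*") {
      aa <- substr(aa, 1, n - 1)
      n <- n - 1
    }
    if (grepl("*", aa, fixed = TRUE)) {
      warning("internal stop codon in declared parent '", gid, "'; rejected")
      next
    }
    widths <- ex$end - ex$start + 1
    if (strand == "-") widths <- rev(widths)
    cum <- cumsum(widths)
    ij <- if (length(cum) > 1) {
      j <- as.integer(round(cum[-length(cum)] / 3))
      j[j >= 1 & j <= n - 1]
    } else integer(0)
    models[[gid]] <- gene_model(gid, sid, strand, ex, spliced, aa, unique(ij))
  }
  models
}

#' Mask track constructor
#'
#' @param seq_id,start,end interval coordinates (1-based inclusive).
#' @param kind `"gene"` or `"repeat"`.
#' @return a [GenomicRanges::GRanges] with a `kind` column, reduced to
#'   disjoint intervals.
#' @export
mask_track <- function(seq_id, start, end, kind = c("gene", "repeat")) {
  kind <- match.arg(kind)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seq_id, IRanges::IRanges(start = start, end = end)))
  gr$kind <- kind
  gr
}

#' Gene mask derived from a set of parent gene models
#'
#' @param models list of [gene_model()] objects.
#' @return a `GRanges` mask covering each gene span (exons and introns).
#' @export
gene_mask_from_models <- function(models) {
  if (length(models) == 0)
    return(GenomicRanges::GRanges())
  sid <- vapply(models, function(m) m$seq_id, character(1))
  sp <- vapply(models, function(m) gene_span(m), numeric(2))
  mask_track(sid, sp["start", ], sp["end", ], kind = "gene")
}

#' Derive the intergenic search space by hard-masking
#'
#' Every base inside a gene or repeat interval is substituted with `N`; all
#' other bases and all lengths are unchanged. Masking is idempotent.
#'
#' @param genome named character vector of sequences.
#' @param gene_mask,repeat_mask `GRanges` masks (either may be `NULL`).
#' @return the masked genome.
#' @export
build_intergenic <- function(genome, gene_mask = NULL, repeat_mask = NULL) {
  masks <- c(if (!is.null(gene_mask)) list(gene_mask),
             if (!is.null(repeat_mask)) list(repeat_mask))
  if (length(masks) == 0) return(genome)
  all <- do.call(c, lapply(masks, function(m) {
    GenomicRanges::granges(m)
  }))
  for (sid in unique(as.character(GenomicRanges::seqnames(all)))) {
    if (!sid %in% names(genome))
      stop("mask refers to unknown sequence '", sid, "'", call. = FALSE)
    iv <- IRanges::reduce(GenomicRanges::ranges(
      all[GenomicRanges::seqnames(all) == sid]))
    st <- IRanges::start(iv); en <- IRanges::end(iv)
    L <- nchar(genome[[sid]])
    if (any(st < 1) || any(en > L)) {
      b <- which(st < 1 | en > L)[1]
      stop(sprintf("mask interval [%d, %d] out of range for '%s' (length %d)",
                   st[b], en[b], sid, L), call. = FALSE)
    }
    s <- genome[[sid]]
    for (i in seq_along(st))
      substr(s, st[i], en[i]) <- strrep("N", en[i] - st[i] + 1)
    genome[[sid]] <- s
  }
  genome
}

#' Write pseudogene calls as GFF3
#'
#' Coordinates are emitted 1-based inclusive with feature type `pseudogene`;
#' attributes carry the parent, class, disablement counts, coverage, poly-A
#' status and Ka/Ks.
#'
#' @param calls data frame of calls as produced by [predict_pseudogenes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_gff3 <- function(calls, path) {
  lines <- "##gff-version 3"
  if (!is.null(calls) && nrow(calls) > 0) {
    fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
    attrs <- sprintf(
      "ID=%s;parent_id=%s;class=%s;n_stops=%d;n_frameshifts=%d;coverage=%s;polyA=%s;ka=%s;ks=%s",
      calls$call_id, calls$parent_id, calls$class,
      calls$n_stops, calls$n_frameshifts, fmt(calls$coverage),
      ifelse(calls$polyA, "true", "false"), fmt(calls$ka), fmt(calls$ks))
    lines <- c(lines, sprintf("%s\tpseudoscan\tpseudogene\t%d\t%d\t%.1f\t%s\t.\t%s",
                              calls$seq_id, calls$start, calls$end,
                              calls$total_score %||% 0, calls$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a pseudogene annotation (GFF3 or BED) as a call table
#'
#' @param path path to a GFF3 or BED file.
#' @return data frame with columns `id`, `seq_id`, `start`, `end`, `strand`
#'   (1-based inclusive) plus any `class` attribute present.
#' @export
read_annotation <- function(path) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  id <- if (!is.null(gr$ID)) as.character(gr$ID)
        else if (!is.null(gr$name)) as.character(gr$name)
        else sprintf("feat%05d", seq_along(gr))
  id[is.na(id)] <- sprintf("feat%05d", which(is.na(id)))
  out <- data.frame(id = id,
                    seq_id = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$class)) out$class <- as.character(gr$class)
  out
}

#' Write parent gene models as GFF3 (gene/mRNA/CDS)
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    sp <- gene_span(m)
    lines <- c(lines,
      sprintf("%s\tpseudoscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              m$seq_id, sp["start"], sp["end"], m$strand, m$gene_id),
      sprintf("%s\tpseudoscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              m$seq_id, sp["start"], sp["end"], m$strand, m$gene_id, m$gene_id))
    ex <- m$exons
    for (i in seq_len(nrow(ex)))
      lines <- c(lines,
        sprintf("%s\tpseudoscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s.t1",
                m$seq_id, ex$start[i], ex$end[i], m$strand, m$gene_id, i,
                m$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}
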