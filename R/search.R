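#' Translate one frame of a DNA sequence
#'
#' Standard genetic code; codons containing `N` (or any non-ACGT character)
#' translate to `X`, stop codons to `*`, and a trailing partial codon is
#' dropped.
#'
#' @param dna DNA string.
#' @param strand `"+"` or `"-"` (the reverse complement is translated on `-`).
#' @param frame 0, 1 or 2.
#' @return an amino-acid string.
#' @export
translate_frame <- function(dna, strand = "+", frame = 0) {
  stopifnot(frame %in% 0:2, strand %in% c("+", "-"))
  if (strand == "-") dna <- revcomp(dna)
  if (frame > 0) dna <- substr(dna, frame + 1, nchar(dna))
  .translate_cpp(dna)
}

#' Best local alignment of two amino-acid strings
#'
#' Smith-Waterman optimum under the configured substitution matrix and
#' affine gaps. Positions of `X` score 0 against everything; `*` scores the
#' matrix's stop score.
#'
#' @param query,target non-empty amino-acid strings.
#' @param params a [search_params()] object.
#' @return list with `score`, `q_start`, `q_end`, `t_start`, `t_end`
#'   (1-based inclusive; 0 when the best alignment is empty), `identity`
#'   and `n_cols`.
#' @export
local_align <- function(query, target, params = search_params()) {
  if (!nzchar(query) || !nzchar(target))
    stop("query and target must be non-empty", call. = FALSE)
  r <- .sw_align_cpp(query, target, params$substitution_matrix,
                     params$gap_open, params$gap_extend)
  r$identity <- if (r$n_cols > 0) r$n_ident / r$n_cols else 0
  r
}

#' Karlin-Altschul E-value of a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length (aa) and `n`
#' the total translated search-space length (aa, masked positions excluded).
#'
#' @param raw_score raw alignment score.
#' @param query_len query length in aa.
#' @param search_space_len translated search-space length in aa.
#' @param params a [search_params()] object carrying the calibration.
#' @return the expected number of chance hits at or above `raw_score`.
#' @export
evalue <- function(raw_score, query_len, search_space_len,
                   params = search_params()) {
  if (any(query_len <= 0) || any(search_space_len <= 0))
    stop("query and search-space lengths must be positive", call. = FALSE)
  params$karlin_k * query_len * search_space_len *
    exp(-params$karlin_lambda * raw_score)
}

# raw score above which E < evalue_max; seeded windows are pre-filtered a
# little below it and the exact E-value filter is applied afterwards
min_significant_score <- function(query_len, search_space_len, params) {
  (log(params$karlin_k * query_len * search_space_len) -
     log(params$evalue_max)) / params$karlin_lambda
}

# map an interval of frame translation coordinates (aa) back to
# forward-strand genomic nt; L is the sequence length
frame_to_genomic <- function(aa_start, aa_end, strand, frame, L) {
  nt_s <- frame + 3 * (aa_start - 1) + 1
  nt_e <- frame + 3 * aa_end
  if (strand == "+") cbind(start = nt_s, end = nt_e)
  else cbind(start = L - nt_e + 1, end = L - nt_s + 1)
}

empty_hits <- function() {
  data.frame(query_id = character(0), seq_id = character(0),
             strand = character(0), frame = integer(0),
             q_start = integer(0), q_end = integer(0),
             t_start = integer(0), t_end = integer(0),
             raw_score = numeric(0), bit_score = numeric(0),
             evalue = numeric(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

#' Translated homology search of parent proteins against intergenic DNA
#'
#' Finds local alignments of every parent protein against all six translated
#' frames of each (masked) sequence, using exact amino-acid seed words
#' followed by windowed Smith-Waterman extension, and retains hits with
#' `E < evalue_max`. Genomic coordinates are reported on the forward strand.
#'
#' @param parents list of [gene_model()] objects (or a named character
#'   vector of protein sequences).
#' @param intergenic named character vector of gene- and repeat-masked
#'   sequences.
#' @param params a [search_params()] object.
#' @return data frame of hits: `query_id`, `seq_id`, `strand`, `frame`,
#'   `q_start`/`q_end` (aa), `t_start`/`t_end` (nt, forward strand),
#'   `raw_score`, `bit_score`, `evalue`, `identity`.
#' @export
search_hits <- function(parents, intergenic, params = search_params()) {
  if (length(parents) == 0) {
    warning("empty parent set; no hits")
    return(empty_hits())
  }
  prots <- if (is.character(parents)) as.list(parents)
           else lapply(parents, function(m) m$protein)
  if (is.null(names(prots)) && !is.character(parents))
    names(prots) <- vapply(parents, function(m) m$gene_id, character(1))
  n_unmasked <- sum(vapply(intergenic, function(s) {
    nchar(gsub("N", "", s, fixed = TRUE))
  }, numeric(1)))
  n_space <- max(1, 2 * n_unmasked)  # six frames of ~len/3 aa each, per strand
  out <- list()
  for (sid in names(intergenic)) {
    L <- nchar(intergenic[[sid]])
    for (strand in c("+", "-")) {
      for (frame in 0:2) {
        tr <- translate_frame(intergenic[[sid]], strand, frame)
        if (!nzchar(tr)) next
        for (qid in names(prots)) {
          q <- prots[[qid]]
          min_s <- 0.9 * min_significant_score(nchar(q), n_space, params)
          h <- .seeded_search_cpp(q, tr, params$seed_word_size,
                                  params$substitution_matrix,
                                  params$gap_open, params$gap_extend,
                                  min_s, params$diag_slack,
                                  params$max_seed_gap, params$window_pad,
                                  params$max_hits_per_window,
                                  params$min_seeds)
          if (nrow(h) == 0) next
          g <- frame_to_genomic(h$t_start, h$t_end, strand, frame, L)
          ev <- evalue(h$raw_score, nchar(q), n_space, params)
          keep <- ev < params$evalue_max
          if (!any(keep)) next
          out[[length(out) + 1]] <- data.frame(
            query_id = qid, seq_id = sid, strand = strand, frame = frame,
            q_start = h$q_start[keep], q_end = h$q_end[keep],
            t_start = g[keep, "start"], t_end = g[keep, "end"],
            raw_score = h$raw_score[keep],
            bit_score = (params$karlin_lambda * h$raw_score[keep] -
                           log(params$karlin_k)) / log(2),
            evalue = ev[keep],
            identity = ifelse(h$n_cols[keep] > 0,
                              h$n_ident[keep] / h$n_cols[keep], 0),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$query_id, hits$seq_id, hits$strand, hits$frame,
                     hits$t_start, hits$t_end), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Export hits in a BLAST outfmt-6-like TSV layout
#'
#' @param hits hit table from [search_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("query_id", "seq_id", "strand", "frame", "q_start", "q_end",
            "t_start", "t_end", "raw_score", "bit_score", "evalue", "identity")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
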