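#' Disablement-aware realignment of a candidate locus to its parent protein
#'
#' Dynamic program over codon matches/substitutions, codon gaps in either
#' sequence, 1- and 2-nt frameshifts (realised as 1/2/4/5-nt codons), and
#' intron skips of at least `min_intron` nt with a GT..AG splice bonus.
#' Premature stops and frameshifts on the optimal path are counted, not
#' forbidden. The alignment is local at both ends; unaligned parent ends are
#' reported as 5'/3' truncation by [detect_truncations()].
#'
#' @param parent a [gene_model()].
#' @param locus a `candidate_locus` with `parent_id == parent$gene_id`, or
#'   `NULL` if `window` is given directly.
#' @param genome named character vector of (unmasked) sequences.
#' @param params an [align_params()] object.
#' @param window optional `c(start, end)` genomic window overriding the
#'   locus span plus flank.
#' @return an object of class `global_alignment` with the aligned columns,
#'   disablement counts and positions, coverage, identity and intron gaps
#'   (all genomic coordinates forward-strand, 1-based inclusive).
#' @export
global_align <- function(parent, locus, genome, params = align_params(),
                         window = NULL) {
  if (!is.null(locus) && locus$parent_id != parent$gene_id)
    stop("locus parent does not match the given parent", call. = FALSE)
  sid <- if (!is.null(locus)) locus$seq_id else parent$seq_id
  strand <- if (!is.null(locus)) locus$strand else "+"
  L <- nchar(genome[[sid]])
  if (is.null(window)) {
    ws <- locus$span[["start"]] - params$flank
    we <- locus$span[["end"]] + params$flank
  } else {
    ws <- window[1]; we <- window[2]
    if (ws < 1 || we > L) warning("alignment window clipped to sequence bounds")
  }
  ws <- max(1, ws); we <- min(L, we)
  if (we < ws) stop("empty alignment window", call. = FALSE)
  wseq <- substr(genome[[sid]], ws, we)
  if (strand == "-") wseq <- revcomp(wseq)
  r <- .glocal_align_cpp(parent$protein, wseq, params$substitution_matrix,
                         params$gap_open, params$gap_extend,
                         params$frameshift_penalty, params$stop_penalty,
                         params$intron_open, params$min_intron,
                         params$splice_bonus)
  cols <- trim_weak_segments(r$columns, parent$protein, params)
  # map window coordinates to forward-strand genomic coordinates
  to_fwd <- function(t1, t2) {
    if (strand == "+") cbind(start = ws + t1 - 1, end = ws + t2 - 1)
    else cbind(start = we - t2 + 1, end = we - t1 + 1)
  }
  if (nrow(cols) > 0) {
    g <- to_fwd(cols$t_start, cols$t_end)
    cols$g_start <- as.integer(g[, "start"])
    cols$g_end <- as.integer(g[, "end"])
  } else {
    cols$g_start <- integer(0); cols$g_end <- integer(0)
  }
  plen <- nchar(parent$protein)
  qp <- cols$q_pos[!is.na(cols$q_pos)]
  q_start <- if (length(qp)) min(qp) else 0L
  q_end <- if (length(qp)) max(qp) else 0L
  aligned_aa <- if (q_end > 0) q_end - q_start + 1 else 0
  pc <- cols$type %in% c(1L, 2L, 4L)           # protein-consuming columns
  stops <- cols$type == 1L & cols$stop
  fss <- cols$type == 2L
  intr <- cols$type == 5L
  dis <- rbind(
    if (any(stops)) data.frame(kind = "premature_stop",
                               genomic_pos = cols$g_start[stops],
                               protein_pos = cols$q_pos[stops]),
    if (any(fss)) data.frame(kind = "frameshift",
                             genomic_pos = cols$g_start[fss],
                             protein_pos = cols$q_pos[fss]))
  if (is.null(dis))
    dis <- data.frame(kind = character(0), genomic_pos = integer(0),
                      protein_pos = integer(0))
  gs <- cols$g_start[!is.na(cols$g_start)]
  ge <- cols$g_end[!is.na(cols$g_end)]
  structure(list(
    parent_id = parent$gene_id,
    locus_id = if (!is.null(locus)) locus$locus_id else NA_character_,
    seq_id = sid, strand = strand, score = r$score,
    q_start = q_start, q_end = q_end,
    g_start = if (length(gs)) min(gs) else 0L,
    g_end = if (length(ge)) max(ge) else 0L,
    window = c(start = ws, end = we),
    columns = cols,
    n_premature_stops = sum(stops),
    n_frameshifts = sum(fss),
    n_indel_events = {  # distinct gap runs in either sequence
      rl <- rle(cols$type)
      sum(rl$values %in% c(3L, 4L))
    },
    coverage = aligned_aa / plen,
    identity = if (any(pc)) sum(cols$ident[pc]) / sum(pc) else 0,
    intron_gaps = data.frame(g_start = cols$g_start[intr],
                             g_end = cols$g_end[intr],
                             q_pos = cols$q_pos[intr]),
    disablements = dis),
    class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf(
    "<global_alignment> %s vs %s %s:%d-%d(%s) score=%.0f cov=%.2f id=%.2f stops=%d fs=%d introns=%d\n",
    x$parent_id, x$locus_id, x$seq_id, x$g_start, x$g_end, x$strand, x$score,
    x$coverage, x$identity, x$n_premature_stops, x$n_frameshifts,
    nrow(x$intron_gaps)))
  invisible(x)
}

# per-column alignment scores (codon units), used for segment trimming
column_scores <- function(cols, protein, params) {
  n <- nrow(cols)
  if (n == 0) return(numeric(0))
  sc <- numeric(n)
  mat <- params$substitution_matrix
  prev_type <- 0L
  for (i in seq_len(n)) {
    ty <- cols$type[i]
    sc[i] <- switch(as.character(ty),
      "1" = if (cols$stop[i]) params$stop_penalty else {
        p <- substring(protein, cols$q_pos[i], cols$q_pos[i])
        a <- cols$aa[i]
        if (a == "X" || p == "X") 0 else mat[p, a]
      },
      "2" = params$frameshift_penalty,
      "3" = ,
      "4" = -params$gap_extend - (if (prev_type != ty) params$gap_open else 0),
      "5" = params$intron_open)
    prev_type <- ty
  }
  sc
}

# drop weak terminal exon segments (across intron gaps) so that lucky
# short matches in flanking DNA, reachable via a cheap intron skip, do not
# inflate the reported span
trim_weak_segments <- function(cols, protein, params) {
  if (nrow(cols) == 0 || !any(cols$type == 5L)) return(cols)
  sc <- column_scores(cols, protein, params)
  seg_id <- cumsum(cols$type == 5L) - (cols$type == 5L)  # intron joins left seg
  seg_ids <- unique(seg_id)
  seg_score <- vapply(seg_ids, function(s) {
    sum(sc[seg_id == s & cols$type != 5L])
  }, numeric(1))
  lo <- 1L; hi <- length(seg_ids)
  while (lo < hi && seg_score[lo] < params$min_exon_score) lo <- lo + 1L
  while (hi > lo && seg_score[hi] < params$min_exon_score) hi <- hi - 1L
  keep <- seg_id %in% seg_ids[lo:hi]
  # drop intron columns left dangling at either end
  w <- which(keep)
  if (length(w)) {
    while (length(w) && cols$type[w[1]] == 5L) w <- w[-1]
    while (length(w) && cols$type[w[length(w)]] == 5L) w <- w[-length(w)]
  }
  out <- cols[w, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report unaligned parent ends as truncation
#'
#' Lengths are relative to the parent reading direction (strand-aware,
#' because the alignment is computed on the sense strand of the locus).
#'
#' @param alignment a `global_alignment`.
#' @param parent the [gene_model()] it was computed against.
#' @return list with `five_prime` and `three_prime`, each a list of
#'   `truncated` (flag) and `aa` (count).
#' @export
detect_truncations <- function(alignment, parent) {
  plen <- nchar(parent$protein)
  five <- if (alignment$q_end > 0) alignment$q_start - 1 else plen
  three <- if (alignment$q_end > 0) plen - alignment$q_end else 0L
  list(five_prime = list(truncated = five > 0, aa = as.integer(five)),
       three_prime = list(truncated = three > 0, aa = as.integer(three)))
}

#' Human-readable three-row dump of an alignment (debugging aid)
#'
#' @param alignment a `global_alignment`.
#' @param parent the parent [gene_model()].
#' @param width residues per block.
#' @return character vector of text lines, invisibly; printed when
#'   `print = TRUE`.
#' @param print whether to cat the block to the console.
#' @export
format_alignment <- function(alignment, parent, width = 60, print = FALSE) {
  cols <- alignment$columns
  if (nrow(cols) == 0) return(invisible(character(0)))
  p <- ifelse(is.na(cols$q_pos), "-",
              substring(parent$protein, cols$q_pos, cols$q_pos))
  mid <- ifelse(cols$type == 1L & cols$ident, "|",
                ifelse(cols$type == 2L, "!",
                       ifelse(cols$type == 5L, "~", " ")))
  a <- ifelse(cols$type == 5L, sprintf("[%d nt]", cols$g_end - cols$g_start + 1),
              cols$aa)
  lines <- character(0)
  for (ofs in seq(1, length(p), by = width)) {
    i <- ofs:min(ofs + width - 1, length(p))
    lines <- c(lines, paste(p[i], collapse = ""), paste(mid[i], collapse = ""),
               paste(a[i], collapse = ""), "")
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
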