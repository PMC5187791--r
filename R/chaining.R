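#' Remove hits overlapping annotated gene regions
#'
#' A hit whose genomic interval overlaps an annotated gene interval by one
#' base or more is discarded; the remainder is retained.
#'
#' @param hits hit table from [search_hits()].
#' @param gene_mask `GRanges` of gene intervals (may be `NULL`).
#' @return the filtered hit table.
#' @export
remove_gene_overlaps <- function(hits, gene_mask = NULL) {
  if (is.null(gene_mask) || length(gene_mask) == 0 || nrow(hits) == 0)
    return(hits)
  gr <- GenomicRanges::GRanges(hits$seq_id,
                               IRanges::IRanges(hits$t_start, hits$t_end))
  ov <- GenomicRanges::countOverlaps(gr, gene_mask) > 0
  out <- hits[!ov, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact maximum-weight disjoint subset of intervals (weighted interval
# scheduling); returns the row indices kept, sorted by start
max_weight_disjoint <- function(start, end, weight) {
  n <- length(start)
  if (n <= 1) return(seq_len(n))
  o <- order(end, start, -weight)
  s <- start[o]; e <- end[o]; w <- weight[o]
  p <- findInterval(s - 1, e)          # rightmost j with e[j] < s[i]
  dp <- numeric(n + 1)
  take <- logical(n)
  for (i in seq_len(n)) {
    incl <- w[i] + dp[p[i] + 1]
    if (incl >= dp[i]) { dp[i + 1] <- incl; take[i] <- TRUE }
    else dp[i + 1] <- dp[i]
  }
  kept <- integer(0)
  i <- n
  while (i >= 1) {
    if (take[i]) { kept <- c(kept, o[i]); i <- p[i] }
    else i <- i - 1
  }
  sort(kept)
}

#' Partition overlapping hits of one query into disjoint pseudo-exons
#'
#' Among genomically overlapping hits of the same query on the same
#' sequence, the maximum-total-score pairwise-disjoint subset survives
#' (exact, by weighted interval scheduling); overlapped rivals are dropped.
#' The surviving "disjoint hits" resemble pseudogene exons.
#'
#' @param hits hit table.
#' @return the disjoint hit table.
#' @export
partition_disjoint <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  keep <- unlist(lapply(split(seq_len(nrow(hits)),
                              paste(hits$query_id, hits$seq_id, sep = "\r")),
                        function(idx) {
    idx[max_weight_disjoint(hits$t_start[idx], hits$t_end[idx],
                            hits$raw_score[idx])]
  }), use.names = FALSE)
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$query_id, out$seq_id, out$t_start, out$t_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

new_locus <- function(segments, locus_id = NA_character_) {
  segments <- segments[order(segments$t_start), , drop = FALSE]
  w <- segments$q_end - segments$q_start + 1
  structure(list(
    locus_id = locus_id,
    seq_id = segments$seq_id[1],
    strand = segments$strand[1],
    parent_id = segments$query_id[1],
    segments = segments,
    span = c(start = min(segments$t_start), end = max(segments$t_end)),
    total_score = sum(segments$raw_score),
    identity = sum(segments$identity * w) / sum(w)),
    class = "candidate_locus")
}

#' @export
print.candidate_locus <- function(x, ...) {
  cat(sprintf("<candidate_locus> %s %s:%d-%d(%s) parent=%s segments=%d score=%.0f\n",
              x$locus_id, x$seq_id, x$span["start"], x$span["end"], x$strand,
              x$parent_id, nrow(x$segments), x$total_score))
  invisible(x)
}

#' Merge adjacent colinear hits of one parent into candidate loci
#'
#' Disjoint hits of the same query on the same sequence and strand whose
#' genomic gap is at most `max_merge_gap` and whose protein order is
#' colinear with the strand (allowing `max_protein_overlap` aa of overlap)
#' are merged into a single candidate locus; others become separate loci.
#' Hits on opposite strands never merge.
#'
#' @param hits disjoint hit table (output of [partition_disjoint()]).
#' @param params a [chain_params()] object.
#' @return list of `candidate_locus` objects.
#' @export
merge_adjacent <- function(hits, params = chain_params()) {
  if (nrow(hits) == 0) return(list())
  loci <- list()
  groups <- split(seq_len(nrow(hits)),
                  paste(hits$query_id, hits$seq_id, hits$strand, sep = "\r"))
  for (idx in groups) {
    h <- hits[idx[order(hits$t_start[idx])], , drop = FALSE]
    chain_start <- 1
    flush <- function(a, b) loci[[length(loci) + 1]] <<- new_locus(h[a:b, ])
    if (nrow(h) > 1) {
      for (i in 2:nrow(h)) {
        gap_ok <- h$t_start[i] - h$t_end[i - 1] - 1 <= params$max_merge_gap
        colinear <- if (h$strand[i] == "+") {
          h$q_start[i] >= h$q_end[i - 1] + 1 - params$max_protein_overlap &&
            h$q_start[i] >= h$q_start[i - 1]
        } else {
          h$q_end[i] <= h$q_start[i - 1] - 1 + params$max_protein_overlap &&
            h$q_end[i] <= h$q_end[i - 1]
        }
        if (!(gap_ok && colinear)) {
          flush(chain_start, i - 1)
          chain_start <- i
        }
      }
    }
    flush(chain_start, nrow(h))
  }
  loci
}

loci_overlap <- function(a, b) {
  a$seq_id == b$seq_id &&
    intersect_len(a$span["start"], a$span["end"],
                  b$span["start"], b$span["end"]) > 0
}

#' Enforce a unique parent per genomic locus
#'
#' Among genomically overlapping loci from different parents, only the
#' highest-total-score locus survives (the "top hit" of the parents); ties
#' are broken by higher identity, then lexicographically smaller parent id,
#' so the outcome is deterministic under input permutation.
#'
#' @param loci list of `candidate_locus` objects.
#' @return the surviving loci, re-identified in genomic order.
#' @export
assign_best_parent <- function(loci) {
  if (length(loci) <= 1) {
    kept <- loci
  } else {
    score <- vapply(loci, function(l) l$total_score, numeric(1))
    ident <- vapply(loci, function(l) l$identity, numeric(1))
    pid <- vapply(loci, function(l) l$parent_id, character(1))
    sid <- vapply(loci, function(l) l$seq_id, character(1))
    st <- vapply(loci, function(l) l$span[["start"]], numeric(1))
    o <- order(-score, -ident, pid, sid, st)
    kept <- list()
    for (i in o) {
      cand <- loci[[i]]
      if (!any(vapply(kept, function(k) loci_overlap(k, cand), logical(1))))
        kept[[length(kept) + 1]] <- cand
    }
  }
  if (length(kept) == 0) return(list())
  sid <- vapply(kept, function(l) l$seq_id, character(1))
  st <- vapply(kept, function(l) l$span[["start"]], numeric(1))
  kept <- kept[order(sid, st)]
  for (i in seq_along(kept)) kept[[i]]$locus_id <- sprintf("locus%04d", i)
  kept
}

#' Full chaining pass: hits to candidate loci
#'
#' Removes residual gene overlaps, partitions hits into disjoint
#' pseudo-exons, merges colinear hits of one parent, and assigns a unique
#' parent per locus.
#'
#' @param hits hit table from [search_hits()].
#' @param gene_mask optional `GRanges` of gene intervals.
#' @param params a [chain_params()] object.
#' @return list of `candidate_locus` objects.
#' @export
chain_hits <- function(hits, gene_mask = NULL, params = chain_params()) {
  hits <- remove_gene_overlaps(hits, gene_mask)
  hits <- partition_disjoint(hits)
  assign_best_parent(merge_adjacent(hits, params))
}
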