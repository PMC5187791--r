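#' Overlap fraction between a predicted and a known interval
#'
#' Length of the intersection divided by the known interval's length (the
#' default denominator; the known element is the reference being
#' recovered). Intervals on different sequences overlap by 0 by contract.
#'
#' @param pred,known lists or one-row data frames with `seq_id`, `start`,
#'   `end`.
#' @param params an [overlap_params()] object.
#' @return the overlap fraction in `[0, 1]` (can exceed 1 in
#'   `predicted_length` mode when the prediction is nested).
#' @export
overlap_fraction <- function(pred, known, params = overlap_params()) {
  if (pred$seq_id != known$seq_id) return(0)
  inter <- intersect_len(pred$start, pred$end, known$start, known$end)
  lk <- known$end - known$start + 1
  lp <- pred$end - pred$start + 1
  switch(params$denominator,
         known_length = inter / lk,
         predicted_length = inter / lp,
         reciprocal = min(inter / lk, inter / lp))
}

#' Match predicted pseudogenes to known pseudogenes one-to-one
#'
#' A predicted and a known pseudogene are declared the same when they
#' overlap uniquely by strictly more than `min_overlap_fraction` of the
#' known element. "Uniquely" is enforced as a one-to-one pairing assigned
#' greedily by descending overlap; ties prefer the smaller known start
#' coordinate, so the pairing is deterministic. Strand is ignored.
#'
#' @param predicted,known data frames with `id`, `seq_id`, `start`, `end`.
#' @param params an [overlap_params()] object.
#' @return data frame with `pred_id`, `known_id`, `fraction`.
#' @export
match_predictions <- function(predicted, known, params = overlap_params()) {
  empty <- data.frame(pred_id = character(0), known_id = character(0),
                      fraction = numeric(0), stringsAsFactors = FALSE)
  if (nrow(predicted) == 0 || nrow(known) == 0) return(empty)
  gp <- GenomicRanges::GRanges(predicted$seq_id,
                               IRanges::IRanges(predicted$start, predicted$end))
  gk <- GenomicRanges::GRanges(known$seq_id,
                               IRanges::IRanges(known$start, known$end))
  ov <- GenomicRanges::findOverlaps(gp, gk)
  if (length(ov) == 0) return(empty)
  pi <- S4Vectors::queryHits(ov); ki <- S4Vectors::subjectHits(ov)
  inter <- intersect_len(predicted$start[pi], predicted$end[pi],
                         known$start[ki], known$end[ki])
  lk <- known$end[ki] - known$start[ki] + 1
  lp <- predicted$end[pi] - predicted$start[pi] + 1
  frac <- switch(params$denominator,
                 known_length = inter / lk,
                 predicted_length = inter / lp,
                 reciprocal = pmin(inter / lk, inter / lp))
  keep <- frac > params$min_overlap_fraction
  if (!any(keep)) return(empty)
  pi <- pi[keep]; ki <- ki[keep]; frac <- frac[keep]
  o <- order(-frac, known$start[ki], predicted$start[pi],
             known$id[ki], predicted$id[pi])
  used_p <- logical(nrow(predicted)); used_k <- logical(nrow(known))
  rows <- integer(0)
  for (r in o) {
    if (used_p[pi[r]] || used_k[ki[r]]) next
    used_p[pi[r]] <- TRUE; used_k[ki[r]] <- TRUE
    rows <- c(rows, r)
  }
  data.frame(pred_id = predicted$id[pi[rows]],
             known_id = known$id[ki[rows]],
             fraction = frac[rows], stringsAsFactors = FALSE)
}

#' Evaluation report from a pairing
#'
#' Percentages are `100 * matched / denominator` with the denominator being
#' all known pseudogenes, or the known set minus unitary pseudogenes
#' (unitary elements have no surviving parent and are invisible to
#' homology-based prediction). Full precision is retained; display values
#' are rounded to one decimal, half up.
#'
#' @param matching pairing from [match_predictions()].
#' @param known,predicted the two call tables.
#' @param unitary_ids ids of known pseudogenes that are unitary.
#' @return an object of class `evaluation_report`.
#' @export
summarize_evaluation <- function(matching, known, predicted,
                                 unitary_ids = character(0)) {
  if (!all(unitary_ids %in% known$id))
    stop("unitary ids must be a subset of known ids", call. = FALSE)
  n_known <- nrow(known); n_pred <- nrow(predicted); n_matched <- nrow(matching)
  n_unitary <- length(unique(unitary_ids))
  matched_excl <- sum(!matching$known_id %in% unitary_ids)
  pct <- if (n_known > 0) 100 * n_matched / n_known else 0
  pct_excl <- if (n_known - n_unitary > 0)
    100 * matched_excl / (n_known - n_unitary) else 0
  breakdown <- NULL
  if (!is.null(predicted$class) && n_pred > 0) {
    counts <- table(factor(predicted$class,
                           levels = c("processed", "duplicated", "fragment")))
    breakdown <- data.frame(class = names(counts),
                            n = as.integer(counts),
                            pct = 100 * as.integer(counts) / n_pred,
                            pct_display = round_half_up(
                              100 * as.integer(counts) / n_pred, 1),
                            stringsAsFactors = FALSE)
  }
  structure(list(n_known = n_known, n_predicted = n_pred,
                 n_matched = n_matched,
                 pct_known_identified = pct,
                 pct_known_identified_display = round_half_up(pct, 1),
                 n_known_unitary = n_unitary,
                 pct_known_identified_excl_unitary = pct_excl,
                 pct_known_identified_excl_unitary_display =
                   round_half_up(pct_excl, 1),
                 matches = matching,
                 class_breakdown = breakdown),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d/%d known identified (%.1f%%)",
              x$n_matched, x$n_known, x$pct_known_identified_display))
  if (x$n_known_unitary > 0)
    cat(sprintf("; excl. %d unitary: %.1f%%", x$n_known_unitary,
                x$pct_known_identified_excl_unitary_display))
  cat("\n")
  if (!is.null(x$class_breakdown)) {
    b <- x$class_breakdown
    cat(paste(sprintf("  %s: %d (%.1f%%)", b$class, b$n, b$pct_display),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Compare the known-pseudogene recovery of several tools
#'
#' For each pair of tools, reports the number of known pseudogenes
#' identified in common and the Dice similarity
#' `2 * |common| / (|A| + |B|)`; also reports union and per-tool unique
#' counts across all tools.
#'
#' @param matchings named list of pairings (each from
#'   [match_predictions()] against the same known set).
#' @return list with `pairwise` (data frame), `n_union`, `unique_counts`.
#' @export
compare_toolsets <- function(matchings) {
  stopifnot(length(matchings) >= 2, !is.null(names(matchings)))
  ids <- lapply(matchings, function(m) unique(m$known_id))
  tools <- names(matchings)
  pairs <- utils::combn(tools, 2)
  pw <- data.frame(tool_a = pairs[1, ], tool_b = pairs[2, ],
                   n_a = NA_integer_, n_b = NA_integer_,
                   n_common = NA_integer_, dice = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pw))) {
    a <- ids[[pw$tool_a[i]]]; b <- ids[[pw$tool_b[i]]]
    pw$n_a[i] <- length(a); pw$n_b[i] <- length(b)
    pw$n_common[i] <- length(intersect(a, b))
    pw$dice[i] <- if (length(a) + length(b) > 0)
      2 * pw$n_common[i] / (length(a) + length(b)) else NA_real_
  }
  all_ids <- unlist(ids, use.names = FALSE)
  uniq <- vapply(tools, function(t) {
    others <- unlist(ids[setdiff(tools, t)], use.names = FALSE)
    sum(!ids[[t]] %in% others)
  }, integer(1))
  list(pairwise = pw, n_union = length(unique(all_ids)),
       unique_counts = uniq)
}

#' Compare raw call sets of several tools by mutual overlap
#'
#' Calls of two tools are identified with each other by the same unique
#' >60%-overlap criterion (reciprocal denominator), then Dice similarity is
#' computed on the call counts.
#'
#' @param call_sets named list of call tables (`id`, `seq_id`, `start`,
#'   `end`).
#' @param params an [overlap_params()] object; the denominator is forced to
#'   `reciprocal` for symmetry.
#' @return data frame of pairwise common counts and Dice similarities.
#' @export
compare_call_sets <- function(call_sets, params = overlap_params()) {
  stopifnot(length(call_sets) >= 2, !is.null(names(call_sets)))
  params$denominator <- "reciprocal"
  tools <- names(call_sets)
  pairs <- utils::combn(tools, 2)
  out <- data.frame(tool_a = pairs[1, ], tool_b = pairs[2, ],
                    n_a = NA_integer_, n_b = NA_integer_,
                    n_common = NA_integer_, dice = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    a <- call_sets[[out$tool_a[i]]]; b <- call_sets[[out$tool_b[i]]]
    m <- match_predictions(a, b, params)
    out$n_a[i] <- nrow(a); out$n_b[i] <- nrow(b)
    out$n_common[i] <- nrow(m)
    out$dice[i] <- if (nrow(a) + nrow(b) > 0)
      2 * nrow(m) / (nrow(a) + nrow(b)) else NA_real_
  }
  out
}

#' Table-style evaluation row(s) for one or more tools
#'
#' @param reports named list of `evaluation_report` objects.
#' @param parents_associated optional named integer vector (distinct parent
#'   genes associated with each tool's calls).
#' @return data frame mirroring the columns tool, total predicted, parents
#'   associated, known identified, percentage.
#' @export
evaluation_table <- function(reports, parents_associated = NULL) {
  data.frame(
    tool = names(reports),
    n_total_predicted = vapply(reports, function(r) r$n_predicted, integer(1)),
    n_parents = if (is.null(parents_associated)) NA_integer_
                else as.integer(parents_associated[names(reports)]),
    n_known_identified = vapply(reports, function(r) r$n_matched, integer(1)),
    pct_known_identified = vapply(reports, function(r)
      r$pct_known_identified_display, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
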