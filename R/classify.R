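#' Detect a poly-A tail signal downstream of a call's 3' end
#'
#' True iff, within `polyA_window` nt downstream of the strand-aware 3' end,
#' there is a `polyA_min_run_window`-nt window whose A fraction (T fraction
#' on `-`) is at least `polyA_min_fraction`. The best such window is
#' reported in forward-strand coordinates.
#'
#' @param genome named character vector of sequences.
#' @param seq_id,start,end,strand location of the call.
#' @param params a [classify_params()] object.
#' @return list with `polyA` (flag), `start`, `end`, `fraction`.
#' @export
detect_polyA <- function(genome, seq_id, start, end, strand = "+",
                         params = classify_params()) {
  s <- genome[[seq_id]]
  L <- nchar(s)
  w <- params$polyA_window
  rw <- params$polyA_min_run_window
  if (strand == "+") {
    lo <- end + 1; hi <- min(L, end + w)
    base <- "A"
  } else {
    lo <- max(1, start - w); hi <- start - 1
    base <- "T"
  }
  if (hi < lo || hi - lo + 1 < rw) {
    if (hi < lo) warning("3' end at sequence boundary; no poly-A search space")
    return(list(polyA = FALSE, start = NA_integer_, end = NA_integer_,
                fraction = NA_real_))
  }
  region <- strsplit(substr(s, lo, hi), "", fixed = TRUE)[[1]] == base
  cs <- c(0, cumsum(region))
  n_win <- length(region) - rw + 1
  frac <- (cs[(rw + 1):(rw + n_win)] - cs[1:n_win]) / rw
  best <- which.max(frac)
  ws <- lo + best - 1L
  we <- lo + best + rw - 2L
  if (frac[best] >= params$polyA_min_fraction) {
    # extend the reported interval over the maximal surrounding base run
    while (ws > max(1, lo - params$polyA_window) &&
           substr(s, ws - 1, ws - 1) == base) ws <- ws - 1L
    while (we < min(nchar(s), hi + params$polyA_window) &&
           substr(s, we + 1, we + 1) == base) we <- we + 1L
  }
  list(polyA = frac[best] >= params$polyA_min_fraction,
       start = ws, end = we, fraction = frac[best])
}

#' Detect target-site duplications (direct repeats) flanking an insertion
#'
#' True iff an identical k-mer (`repeat_flank_min <= k <= repeat_flank_max`)
#' ends within `flank_slop` nt of the insertion's left boundary and recurs
#' starting within `flank_slop` nt of its right boundary. When a poly-A
#' interval is supplied, the insertion boundary is extended past it, since
#' the duplicated target site flanks the whole retro-insertion.
#'
#' @param genome named character vector of sequences.
#' @param seq_id,start,end call location (core element interval).
#' @param params a [classify_params()] object.
#' @param polyA optional result of [detect_polyA()].
#' @return list with `tsd` (flag), `kmer`, `k`.
#' @export
detect_direct_repeats <- function(genome, seq_id, start, end,
                                  params = classify_params(), polyA = NULL) {
  s <- genome[[seq_id]]
  L <- nchar(s)
  left <- start; right <- end
  pa_side <- 0L   # 0 none, +1 poly-A downstream (fwd), -1 upstream
  if (!is.null(polyA) && isTRUE(polyA$polyA)) {
    if (polyA$start >= start) { right <- max(right, polyA$end); pa_side <- 1L }
    else { left <- min(left, polyA$start); pa_side <- -1L }
  }
  slop <- params$flank_slop
  kmin <- params$repeat_flank_min
  kmax <- params$repeat_flank_max
  found <- function(kmer, k) list(tsd = TRUE, kmer = kmer, k = k)
  # stage 1: both copies anchored tightly at the insertion boundaries
  for (k in kmax:kmin) {
    for (a in 0:slop) {
      us <- left - a - k
      if (us < 1) next
      up <- substr(s, us, left - a - 1)
      if (grepl("N", up, fixed = TRUE)) next
      for (b in 0:slop) {
        de <- right + b + k
        if (de > L) next
        if (up == substr(s, right + b + 1, de)) return(found(up, k))
      }
    }
  }
  # stage 2: allow for alignment end-clipping (boundaries up to slack_in nt
  # inside the true insertion) and for a diverged poly-A blurring one side;
  # only k >= 8 to keep the chance-match rate low
  slack_in <- 18L
  k2min <- max(8L, kmin)
  if (kmax >= k2min) {
    right_ext <- if (pa_side == 1L) params$polyA_window else slop
    left_ext <- if (pa_side == -1L) params$polyA_window else slop
    for (k in kmax:k2min) {
      if (pa_side >= 0L) {  # anchor upstream, scan downstream window
        for (e in (left - slack_in - 1):(left + slop - 1)) {
          us <- e - k + 1
          if (us < 1 || e > L) next
          up <- substr(s, us, e)
          if (grepl("N", up, fixed = TRUE)) next
          win <- substr(s, max(1, right - 3),
                        min(L, right + slack_in + right_ext + k))
          if (grepl(up, win, fixed = TRUE)) return(found(up, k))
        }
      } else {              # poly-A upstream: anchor downstream, scan left
        for (ds in (right + 1 - slop):(right + 1 + slack_in)) {
          de <- ds + k - 1
          if (ds < 1 || de > L) next
          dn <- substr(s, ds, de)
          if (grepl("N", dn, fixed = TRUE)) next
          win <- substr(s, max(1, left - slack_in - left_ext - k),
                        min(L, left + 3))
          if (grepl(dn, win, fixed = TRUE)) return(found(dn, k))
        }
      }
    }
  }
  list(tsd = FALSE, kmer = NA_character_, k = NA_integer_)
}

#' Intron status of an alignment relative to its parent's exon structure
#'
#' @param alignment a `global_alignment`.
#' @param parent the parent [gene_model()].
#' @param params an [align_params()] object (for the junction tolerance).
#' @return `"parent_intronless"` when the parent has no intron junctions;
#'   `"introns_present"` when at least one covered junction has an intron
#'   gap within `junction_tol` aa; `"introns_absent"` otherwise (the
#'   alignment is contiguous at every covered junction).
#' @export
intron_status <- function(alignment, parent, params = align_params()) {
  ij <- parent$intron_junctions
  if (length(ij) == 0) return("parent_intronless")
  covered <- ij[ij >= alignment$q_start & ij + 1 <= alignment$q_end]
  if (length(covered) == 0 || nrow(alignment$intron_gaps) == 0)
    return("introns_absent")
  gap_pos <- alignment$intron_gaps$q_pos
  hit <- vapply(covered, function(j) {
    any(abs(gap_pos - j) <= params$junction_tol)
  }, logical(1))
  if (any(hit)) "introns_present" else "introns_absent"
}

#' Classify a validated candidate as processed, duplicated or fragment
#'
#' Fragments cover less than `fragment_max_coverage` of the parent protein.
#' Otherwise a call is processed when the alignment shows intron loss at the
#' parent's junctions, or when the parent is intronless and a poly-A tail is
#' present (poly-A verification exists precisely because some parents have
#' no introns); everything else is duplicated. Candidates with no
#' disablement and full intron retention are still emitted (duplicated)
#' with a `no_disablement` flag.
#'
#' @param alignment a `global_alignment`.
#' @param parent the parent [gene_model()].
#' @param polyA result of [detect_polyA()].
#' @param direct_repeats result of [detect_direct_repeats()].
#' @param params a [classify_params()] object.
#' @param align_params an [align_params()] object.
#' @return list with `class` (one of `processed`, `duplicated`, `fragment`),
#'   `intron_status` and `no_disablement`.
#' @export
classify_call <- function(alignment, parent, polyA, direct_repeats,
                          params = classify_params(),
                          align_params = pseudoscan::align_params()) {
  st <- intron_status(alignment, parent, align_params)
  n_dis <- alignment$n_premature_stops + alignment$n_frameshifts +
    alignment$n_indel_events
  cls <- if (alignment$coverage < params$fragment_max_coverage) {
    "fragment"
  } else if (st == "introns_absent") {
    "processed"
  } else if (st == "parent_intronless" && isTRUE(polyA$polyA)) {
    "processed"
  } else {
    "duplicated"
  }
  list(class = cls, intron_status = st,
       no_disablement = cls != "fragment" && n_dis == 0)
}
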