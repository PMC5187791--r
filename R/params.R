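#' Default substitution matrix for translated search and realignment
#'
#' BLOSUM62 with two conventions for translated frames: `X` (ambiguous or
#' masked codons) scores 0 against everything, and `*` (a stop codon in a
#' translated frame) scores -4 against everything, so stops are penalised but
#' not rewarded during local search; their detection belongs to realignment.
#'
#' @param stop_score score of `*` against any residue.
#' @return a named numeric substitution matrix.
#' @export
default_search_matrix <- function(stop_score = -4) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0
  m[, "X"] <- 0
  m["*", ] <- stop_score
  m[, "*"] <- stop_score
  m
}

#' Parameters of the translated homology search
#'
#' @param substitution_matrix named substitution matrix (default
#'   [default_search_matrix()]).
#' @param gap_open,gap_extend affine gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param evalue_max E-value significance threshold; hits at or above it are
#'   discarded (default `1e-5`).
#' @param karlin_lambda,karlin_k Karlin-Altschul calibration constants.
#'   Defaults are the published values for gapped BLOSUM62 with 11/1 gaps, so
#'   E-values approximate, not replicate, NCBI tBLASTn.
#' @param seed_word_size exact amino-acid seed length of the heuristic search.
#' @param diag_slack,max_seed_gap seed clustering tolerances (aa).
#' @param window_pad extra target residues aligned around a seed cluster.
#' @param max_hits_per_window cap on mask-and-research iterations per window.
#' @param min_seeds minimum seed words per cluster before Smith-Waterman
#'   extension; isolated chance seeds are skipped.
#' @return an object of class `search_params`.
#' @export
search_params <- function(substitution_matrix = default_search_matrix(),
                          gap_open = 11, gap_extend = 1,
                          evalue_max = 1e-5,
                          karlin_lambda = 0.267, karlin_k = 0.041,
                          seed_word_size = 4,
                          diag_slack = 40, max_seed_gap = 200,
                          window_pad = 50, max_hits_per_window = 4,
                          min_seeds = 2) {
  stopifnot_scalar_num(evalue_max, "evalue_max", lo = 1e-300)
  stopifnot_scalar_num(gap_open, "gap_open", lo = 0)
  stopifnot_scalar_num(gap_extend, "gap_extend", lo = 0)
  stopifnot_scalar_num(karlin_lambda, "karlin_lambda", lo = 1e-6)
  stopifnot_scalar_num(karlin_k, "karlin_k", lo = 1e-9)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 evalue_max = evalue_max,
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k,
                 seed_word_size = as.integer(seed_word_size),
                 diag_slack = as.integer(diag_slack),
                 max_seed_gap = as.integer(max_seed_gap),
                 window_pad = as.integer(window_pad),
                 max_hits_per_window = as.integer(max_hits_per_window),
                 min_seeds = as.integer(min_seeds)),
            class = "search_params")
}

#' Parameters of hit chaining
#'
#' @param max_merge_gap maximum genomic distance (nt) between two disjoint
#'   hits of the same parent for them to merge into one candidate locus.
#'   The default, 5000 nt, accommodates lost introns and small insertions
#'   without bridging unrelated loci.
#' @param max_protein_overlap protein overlap (aa) tolerated between merged
#'   segments.
#' @return an object of class `chain_params`.
#' @export
chain_params <- function(max_merge_gap = 5000, max_protein_overlap = 10) {
  stopifnot_scalar_num(max_merge_gap, "max_merge_gap", lo = 0)
  stopifnot_scalar_num(max_protein_overlap, "max_protein_overlap", lo = 0)
  structure(list(max_merge_gap = as.integer(max_merge_gap),
                 max_protein_overlap = as.integer(max_protein_overlap)),
            class = "chain_params")
}

#' Parameters of disablement-aware global realignment
#'
#' Scoring defaults: BLOSUM62 in codon units; `frameshift_penalty` -15 per
#' 1/2/4/5-nt codon, `stop_penalty` -10 per stop codon traversed,
#' `intron_open` -8 with free extension beyond `min_intron` nt and a
#' `splice_bonus` of +4 split between a GT donor and an AG acceptor.
#'
#' @param substitution_matrix named substitution matrix.
#' @param gap_open,gap_extend affine codon-gap penalties.
#' @param frameshift_penalty score added for each frameshift codon (negative).
#' @param stop_penalty score of a stop codon aligned to a parent residue.
#' @param intron_open cost of opening an intron skip (negative).
#' @param min_intron minimum genomic gap (nt) treated as an intron; shorter
#'   gaps are ordinary indels. Must be >= 4.
#' @param splice_bonus score added when an intron skip has GT..AG boundaries.
#' @param flank nt of genomic context re-aligned on each side of a candidate.
#' @param junction_tol tolerance (aa) when matching intron gaps to annotated
#'   parent intron junctions.
#' @param min_exon_score terminal alignment segments (separated from the
#'   rest by an intron gap) scoring below this are trimmed; prevents cheap
#'   intron skips from telescoping the alignment into flanking DNA.
#' @return an object of class `align_params`.
#' @export
align_params <- function(substitution_matrix = default_search_matrix(),
                         gap_open = 11, gap_extend = 1,
                         frameshift_penalty = -15, stop_penalty = -10,
                         intron_open = -8, min_intron = 40, splice_bonus = 4,
                         flank = 300, junction_tol = 10, min_exon_score = 20) {
  if (min_intron < 4) stop("'min_intron' must be >= 4", call. = FALSE)
  stopifnot_scalar_num(frameshift_penalty, "frameshift_penalty", hi = 0)
  stopifnot_scalar_num(stop_penalty, "stop_penalty", hi = 0)
  stopifnot_scalar_num(intron_open, "intron_open", hi = 0)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 frameshift_penalty = frameshift_penalty,
                 stop_penalty = stop_penalty,
                 intron_open = intron_open,
                 min_intron = as.integer(min_intron),
                 splice_bonus = splice_bonus,
                 flank = as.integer(flank),
                 junction_tol = as.integer(junction_tol),
                 min_exon_score = min_exon_score),
            class = "align_params")
}

#' Parameters of pseudogene classification
#'
#' @param fragment_max_coverage calls covering less than this fraction of
#'   their parent protein are fragments (default 0.70, the common
#'   pseudogene-pipeline convention).
#' @param polyA_window nt downstream of the 3' end searched for a poly-A tail.
#' @param polyA_min_run_window width (nt) of the scanned A-rich window.
#' @param polyA_min_fraction minimum A fraction (T on -) within that window.
#' @param repeat_flank_min,repeat_flank_max k-mer sizes considered as
#'   target-site duplications.
#' @param flank_slop nt of positional slack allowed between a TSD copy and
#'   the insertion boundary.
#' @return an object of class `classify_params`.
#' @export
classify_params <- function(fragment_max_coverage = 0.70,
                            polyA_window = 50, polyA_min_run_window = 20,
                            polyA_min_fraction = 0.8,
                            repeat_flank_min = 5, repeat_flank_max = 20,
                            flank_slop = 2) {
  stopifnot_scalar_num(fragment_max_coverage, "fragment_max_coverage", 0, 1)
  stopifnot_scalar_num(polyA_min_fraction, "polyA_min_fraction", 0, 1)
  stopifnot_scalar_num(polyA_window, "polyA_window", lo = 1)
  stopifnot_scalar_num(polyA_min_run_window, "polyA_min_run_window", lo = 1)
  structure(list(fragment_max_coverage = fragment_max_coverage,
                 polyA_window = as.integer(polyA_window),
                 polyA_min_run_window = as.integer(polyA_min_run_window),
                 polyA_min_fraction = polyA_min_fraction,
                 repeat_flank_min = as.integer(repeat_flank_min),
                 repeat_flank_max = as.integer(repeat_flank_max),
                 flank_slop = as.integer(flank_slop)),
            class = "classify_params")
}

#' Parameters of overlap-based evaluation
#'
#' @param min_overlap_fraction strict lower bound on the overlap fraction for
#'   a predicted and a known pseudogene to be declared the same (default
#'   0.60; overlap of exactly 60% is not a match).
#' @param denominator length used as the denominator of the overlap fraction:
#'   the known element (default), the predicted element, or `reciprocal`
#'   (the smaller of the two fractions).
#' @return an object of class `overlap_params`.
#' @export
overlap_params <- function(min_overlap_fraction = 0.60,
                           denominator = c("known_length", "predicted_length",
                                           "reciprocal")) {
  if (min_overlap_fraction <= 0 || min_overlap_fraction >= 1)
    stop("'min_overlap_fraction' must be in (0, 1)", call. = FALSE)
  structure(list(min_overlap_fraction = min_overlap_fraction,
                 denominator = match.arg(denominator)),
            class = "overlap_params")
}
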