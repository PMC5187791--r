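#' Run configuration for the end-to-end prediction pipeline
#'
#' @param search a [search_params()].
#' @param chain a [chain_params()].
#' @param align an [align_params()].
#' @param classify a [classify_params()].
#' @param overlap an [overlap_params()].
#' @param min_call_score minimum realignment score for a locus to be emitted.
#' @return an object of class `run_config`.
#' @export
run_config <- function(search = search_params(), chain = chain_params(),
                       align = align_params(), classify = classify_params(),
                       overlap = overlap_params(), min_call_score = 0) {
  structure(list(search = search, chain = chain, align = align,
                 classify = classify, overlap = overlap,
                 min_call_score = min_call_score),
            class = "run_config")
}

empty_calls <- function() {
  data.frame(call_id = character(0), seq_id = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             parent_id = character(0), class = character(0),
             total_score = numeric(0), coverage = numeric(0),
             identity = numeric(0), n_stops = integer(0),
             n_frameshifts = integer(0), n_indels = integer(0),
             intron_status = character(0), polyA = logical(0),
             direct_repeats = logical(0), trunc5 = integer(0),
             trunc3 = integer(0), ka = numeric(0), ks = numeric(0),
             kaks = numeric(0), no_disablement = logical(0),
             stringsAsFactors = FALSE)
}

#' Predict pseudogenes genome-wide
#'
#' Executes the three-stage flow end to end: hard-mask gene (and repeat)
#' regions to derive the intergenic search space, run the translated
#' homology search, chain hits into single-parent candidate loci, re-align
#' each locus to its parent with the disablement-aware dynamic program,
#' classify (with poly-A and target-site-duplication evidence) and estimate
#' Ka/Ks per call.
#'
#' @param genome named character vector of sequences (see [read_fasta()]).
#' @param models named list of parent [gene_model()] objects.
#' @param config a [run_config()].
#' @param repeat_mask optional `GRanges` of repeat intervals.
#' @param verbose log record counts at stage boundaries.
#' @return list with `calls` (data frame), `alignments` (named by call id)
#'   and `report` (stage funnel, per-class counts and percentages, parents
#'   associated, Ka/Ks summary).
#' @export
predict_pseudogenes <- function(genome, models, config = run_config(),
                                repeat_mask = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  gene_mask <- gene_mask_from_models(models)
  intergenic <- build_intergenic(genome, gene_mask, repeat_mask)
  hits <- search_hits(models, intergenic, config$search)
  say("search: %d significant hits", nrow(hits))
  hits2 <- remove_gene_overlaps(hits, gene_mask)
  hits3 <- partition_disjoint(hits2)
  say("chaining: %d disjoint hits", nrow(hits3))
  loci <- assign_best_parent(merge_adjacent(hits3, config$chain))
  say("chaining: %d candidate loci", length(loci))

  calls <- list()
  alignments <- list()
  kaks_results <- list()
  for (locus in loci) {
    parent <- models[[locus$parent_id]]
    al <- global_align(parent, locus, genome, config$align)
    if (al$score <= config$min_call_score || al$q_end == 0) next
    pa <- detect_polyA(genome, al$seq_id, al$g_start, al$g_end, al$strand,
                       config$classify)
    dr <- detect_direct_repeats(genome, al$seq_id, al$g_start, al$g_end,
                                config$classify, polyA = pa)
    cls <- classify_call(al, parent, pa, dr, config$classify, config$align)
    tr <- detect_truncations(al, parent)
    kk <- ng86(codon_pairs_from_alignment(al, parent))
    id <- sprintf("psg%04d", length(calls) + 1)
    alignments[[id]] <- al
    kaks_results[[id]] <- kk
    calls[[id]] <- data.frame(
      call_id = id, seq_id = al$seq_id, strand = al$strand,
      start = al$g_start, end = al$g_end, parent_id = al$parent_id,
      class = cls$class, total_score = al$score,
      coverage = al$coverage, identity = al$identity,
      n_stops = al$n_premature_stops, n_frameshifts = al$n_frameshifts,
      n_indels = al$n_indel_events, intron_status = cls$intron_status,
      polyA = isTRUE(pa$polyA), direct_repeats = isTRUE(dr$tsd),
      trunc5 = tr$five_prime$aa, trunc3 = tr$three_prime$aa,
      ka = kk$ka, ks = kk$ks, kaks = kk$ratio,
      no_disablement = cls$no_disablement,
      stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, c(calls, make.row.names = FALSE))
           else empty_calls()
  say("calls: %d", nrow(calls))
  counts <- table(factor(calls$class,
                         levels = c("processed", "duplicated", "fragment")))
  report <- list(
    n_hits = nrow(hits), n_hits_after_gene_removal = nrow(hits2),
    n_disjoint_hits = nrow(hits3), n_loci = length(loci),
    n_calls = nrow(calls),
    class_counts = as.integer(counts),
    class_pct = if (nrow(calls) > 0)
      round_half_up(100 * as.integer(counts) / nrow(calls), 1)
      else rep(0, 3),
    classes = names(counts),
    parents_associated = length(unique(calls$parent_id)),
    kaks = kaks_summary(kaks_results))
  list(calls = calls, alignments = alignments, report = report)
}

#' Write the pseudogene call table as TSV
#'
#' @param calls call table from [predict_pseudogenes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Evaluate a call set against a known pseudogene annotation
#'
#' @param calls call table (`call_id` or `id`, `seq_id`, `start`, `end`).
#' @param known known-pseudogene table (`id`, `seq_id`, `start`, `end`).
#' @param unitary_ids known ids that are unitary pseudogenes.
#' @param params an [overlap_params()].
#' @return an `evaluation_report` (see [summarize_evaluation()]).
#' @export
evaluate_calls <- function(calls, known, unitary_ids = character(0),
                           params = overlap_params()) {
  pred <- calls
  if (is.null(pred$id)) pred$id <- pred$call_id %||% pred$element_id
  bad <- setdiff(unique(pred$seq_id), unique(known$seq_id))
  if (nrow(pred) > 0 && length(bad) == length(unique(pred$seq_id)))
    stop("no shared sequence ids between calls and known set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  m <- match_predictions(pred, known, params)
  summarize_evaluation(m, known, pred, unitary_ids)
}
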