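BASES <- c("T", "C", "A", "G")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# memoised codon bookkeeping for NG86: amino acid and per-codon synonymous
# site fraction (mutations to stop codons are excluded from site counting,
# so each sense codon still contributes exactly 3 sites)
codon_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE),
                    1, paste, collapse = "")
    aa <- vapply(codons, .translate_cpp, character(1))
    syn <- vapply(codons, function(cd) {
      if (cd %in% STOP_CODONS) return(0)
      total <- 0
      for (pos in 1:3) {
        alts <- vapply(setdiff(BASES, substr(cd, pos, pos)), function(b) {
          alt <- cd
          substr(alt, pos, pos) <- b
          alt
        }, character(1))
        valid <- alts[!alts %in% STOP_CODONS]
        if (length(valid) == 0) next
        total <- total + sum(aa[valid] == aa[[cd]]) / length(valid)
      }
      total
    }, numeric(1))
    cache <<- list(aa = aa, syn = syn)
    cache
  }
})

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# pathway-averaged synonymous/nonsynonymous difference counts between two
# codons; pathways through stop codons are excluded when any stop-free
# pathway exists
codon_diff_counts <- function(c1, c2) {
  tab <- codon_tables()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  paths <- perms_of(pos)
  tally <- function(path, allow_stops) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stops && nxt %in% STOP_CODONS && nxt != c2) return(NULL)
      if (tab$aa[[cur]] == tab$aa[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, tally, allow_stops = FALSE))
  if (length(res) == 0) res <- lapply(paths, tally, allow_stops = TRUE)
  colMeans(do.call(rbind, res))
}

#' Extract usable codon pairs from a realignment
#'
#' Only in-frame, gap-free, frameshift-free, stop-free aligned codon columns
#' are emitted; codons downstream of a frameshift re-enter in the restored
#' frame and are still usable. Columns whose genomic codon contains `N` are
#' skipped.
#'
#' @param alignment a `global_alignment`.
#' @param parent the parent [gene_model()] (its spliced CDS supplies the
#'   parent codons).
#' @return data frame with `parent_codon`, `pseudo_codon`, `q_pos`,
#'   `g_start`; attribute `reliable` is `FALSE` when fewer than 10 pairs
#'   remain.
#' @export
codon_pairs_from_alignment <- function(alignment, parent) {
  cols <- alignment$columns
  use <- cols$type == 1L & !cols$stop & cols$aa != "X"
  qp <- cols$q_pos[use]
  parent_codon <- substring(parent$cds, 3 * (qp - 1) + 1, 3 * qp)
  out <- data.frame(parent_codon = parent_codon,
                    pseudo_codon = cols$codon[use],
                    q_pos = qp, g_start = cols$g_start[use],
                    stringsAsFactors = FALSE)
  keep <- !out$parent_codon %in% STOP_CODONS &
    !grepl("[^ACGT]", out$parent_codon) & !grepl("[^ACGT]", out$pseudo_codon)
  out <- out[keep, , drop = FALSE]
  attr(out, "reliable") <- nrow(out) >= 10
  out
}

#' Nei-Gojobori (1986) Ka and Ks from aligned codon pairs
#'
#' Synonymous and nonsynonymous site counts are averaged over both
#' sequences; multi-nucleotide codon differences are counted by equal-weight
#' pathway averaging; the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - 4p/3)` is applied to both proportions. Stop-containing
#' codons never contribute sites.
#'
#' @param pairs data frame from [codon_pairs_from_alignment()], or any data
#'   frame with `parent_codon` and `pseudo_codon` columns.
#' @return an object of class `kaks_result`: `ka`, `ks`, `ratio` (`NA` when
#'   `ks` is 0 or undefined), `n_sites`, `s_sites`, `n_codons_used`, and
#'   flags `reliable` and `saturated`.
#' @export
ng86 <- function(pairs) {
  tab <- codon_tables()
  c1 <- pairs$parent_codon; c2 <- pairs$pseudo_codon
  keep <- !c1 %in% STOP_CODONS & !c2 %in% STOP_CODONS &
    !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2)
  c1 <- c1[keep]; c2 <- c2[keep]
  n_codons <- length(c1)
  if (n_codons == 0)
    return(structure(list(ka = NA_real_, ks = NA_real_, ratio = NA_real_,
                          n_sites = 0, s_sites = 0, n_codons_used = 0,
                          reliable = FALSE, saturated = FALSE),
                     class = "kaks_result"))
  s_sites <- (sum(tab$syn[c1]) + sum(tab$syn[c2])) / 2
  n_sites <- 3 * n_codons - s_sites
  d <- vapply(seq_len(n_codons),
              function(i) codon_diff_counts(c1[i], c2[i]), numeric(2))
  sd <- sum(d["sd", ]); nd <- sum(d["nd", ])
  pS <- if (s_sites > 0) sd / s_sites else 0
  pN <- if (n_sites > 0) nd / n_sites else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(pS); ka <- jc(pN)
  saturated <- is.na(ks) || is.na(ka)
  ratio <- if (!saturated && !is.na(ks) && ks > 0) ka / ks else NA_real_
  structure(list(ka = ka, ks = ks, ratio = ratio,
                 n_sites = n_sites, s_sites = s_sites,
                 n_codons_used = n_codons,
                 reliable = n_codons >= 10, saturated = saturated),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> Ka=%.4f Ks=%.4f Ka/Ks=%s (%d codons%s)\n",
              x$ka, x$ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio),
              x$n_codons_used,
              if (!x$reliable) ", unreliable" else ""))
  invisible(x)
}

#' Set-level Ka/Ks summary
#'
#' Pseudogenes evolve without selective constraint, so their Ka/Ks ratios
#' are expected near 1, in contrast with functional genes under purifying
#' selection. The geometric mean is taken over defined, nonzero ratios.
#'
#' @param results list of `kaks_result` objects.
#' @param near numeric range counted as "near 1".
#' @return list with `geometric_mean_ratio`, `count_defined`,
#'   `fraction_ratio_near_1`, `n_total`.
#' @export
kaks_summary <- function(results, near = c(0.5, 2)) {
  r <- vapply(results, function(x) x$ratio %||% NA_real_, numeric(1))
  r <- r[!is.na(r) & r > 0 & is.finite(r)]
  if (length(r) == 0)
    return(list(geometric_mean_ratio = NA_real_, count_defined = 0L,
                fraction_ratio_near_1 = NA_real_, n_total = length(results)))
  list(geometric_mean_ratio = exp(mean(log(r))),
       count_defined = length(r),
       fraction_ratio_near_1 = mean(r >= near[1] & r <= near[2]),
       n_total = length(results))
}
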