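# Independent oracles used to cross-check the package's own implementations.
# They deliberately take different computational routes: Biostrings for
# local alignment and translation, a naive R dynamic program for the
# protein-to-DNA alignment, and a from-scratch enumeration for NG86.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# local alignment score oracle (Biostrings); empty alignment floor at 0
oracle_sw_score <- function(q, t, params) {
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(t), type = "local",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
  max(0, sc)
}

# naive R dynamic program for the frameshift/stop/intron-aware alignment;
# same move set as the package's aligner, but with an O(L) per-cell intron
# scan instead of a running maximum, and no traceback
oracle_glocal_score <- function(prot, dna, params) {
  m <- nchar(prot); L <- nchar(dna)
  P <- strsplit(prot, "", fixed = TRUE)[[1]]
  mat <- params$substitution_matrix
  NEG <- -1e18
  go <- params$gap_open + params$gap_extend
  ge <- params$gap_extend
  sb <- params$splice_bonus / 2
  H <- matrix(0, m + 1, L + 1)
  E <- matrix(NEG, m + 1, L + 1)
  F <- matrix(NEG, m + 1, L + 1)
  donor <- function(jp) {
    if (jp + 2 <= L && substr(dna, jp + 1, jp + 2) == "GT") sb else 0
  }
  acceptor <- function(j) {
    if (j >= 2 && substr(dna, j - 1, j) == "AG") sb else 0
  }
  best <- 0
  for (i in 1:m) {
    for (j in 0:L) {
      if (j >= 3) {
        E[i + 1, j + 1] <- max(H[i + 1, j - 2] - go, E[i + 1, j - 2] - ge)
      }
      F[i + 1, j + 1] <- max(H[i, j + 1] - go, F[i, j + 1] - ge)
      cand <- 0
      if (j >= 3) {
        aa <- translate_frame(substr(dna, j - 2, j), "+", 0)
        sc <- if (aa == "*") params$stop_penalty else mat[P[i], aa]
        cand <- max(cand, H[i, j - 2] + sc)
      }
      for (st in c(1, 2, 4, 5)) {
        if (j >= st) cand <- max(cand, H[i, j - st + 1] +
                                   params$frameshift_penalty)
      }
      cand <- max(cand, E[i + 1, j + 1], F[i + 1, j + 1])
      if (j >= params$min_intron) {
        for (jp in 0:(j - params$min_intron)) {
          cand <- max(cand, H[i + 1, jp + 1] + donor(jp) +
                        params$intron_open + acceptor(j))
        }
      }
      H[i + 1, j + 1] <- cand
      if (cand > best) best <- cand
    }
  }
  best
}

# from-scratch NG86 counting oracle
oracle_ng86 <- function(codons1, codons2) {
  stops <- c("TAA", "TAG", "TGA")
  code <- Biostrings::GENETIC_CODE
  keep <- !(codons1 %in% stops) & !(codons2 %in% stops)
  codons1 <- codons1[keep]; codons2 <- codons2[keep]
  syn_sites <- function(cd) {
    total <- 0
    for (p in 1:3) {
      alts <- character(0)
      for (b in setdiff(c("A", "C", "G", "T"), substr(cd, p, p))) {
        alt <- cd; substr(alt, p, p) <- b
        alts <- c(alts, alt)
      }
      alts <- alts[!alts %in% stops]
      if (length(alts))
        total <- total + mean(code[alts] == code[[cd]])
    }
    total
  }
  all_orders <- function(pos) {
    if (length(pos) == 1) return(list(pos))
    out <- list()
    for (i in seq_along(pos))
      for (rest in all_orders(pos[-i]))
        out[[length(out) + 1]] <- c(pos[i], rest)
    out
  }
  path_counts <- function(a, b) {
    pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (length(pos) == 0) return(c(0, 0))
    counts <- list()
    for (ord in all_orders(pos)) {
      cur <- a; sd <- 0; nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(b, p, p)
        if (nxt %in% stops && nxt != b) { ok <- FALSE; break }
        if (code[[cur]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) counts[[length(counts) + 1]] <- c(sd, nd)
    }
    if (length(counts) == 0) {  # every pathway crosses a stop
      for (ord in all_orders(pos)) {
        cur <- a; sd <- 0; nd <- 0
        for (p in ord) {
          nxt <- cur; substr(nxt, p, p) <- substr(b, p, p)
          if (code[[cur]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        counts[[length(counts) + 1]] <- c(sd, nd)
      }
    }
    colMeans(do.call(rbind, counts))
  }
  S <- (sum(vapply(codons1, syn_sites, numeric(1))) +
          sum(vapply(codons2, syn_sites, numeric(1)))) / 2
  N <- 3 * length(codons1) - S
  d <- vapply(seq_along(codons1),
              function(i) path_counts(codons1[i], codons2[i]), numeric(2))
  sd <- sum(d[1, ]); nd <- sum(d[2, ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(s_sites = S, n_sites = N, sd = sd, nd = nd,
       ks = if (S > 0) jc(sd / S) else NA_real_,
       ka = if (N > 0) jc(nd / N) else NA_real_)
}

# brute-force maximum-weight disjoint interval subset (bitmask enumeration)
oracle_max_weight_disjoint <- function(start, end, weight) {
  n <- length(start)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) > 1) {
      o <- idx[order(start[idx])]
      if (any(start[o][-1] <= end[o][-length(o)])) next
    }
    w <- sum(weight[idx])
    if (w > best) best <- w
  }
  best
}
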