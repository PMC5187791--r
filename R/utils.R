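#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half away from zero
#'
#' The display convention for report percentages (so 85.15 prints as 85.2).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# 1-based inclusive interval intersection length (0 when disjoint)
intersect_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a number in [%s, %s]", name, lo, hi), call. = FALSE)
  invisible(x)
}
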