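# Internal numeric and allele helpers shared across modules.

#' @noRd
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows (including the exact a == b case).
#' @noRd
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' @noRd
reverse_complement <- function(alleles) {
  vapply(strsplit(chartr("ACGT", "TGCA", toupper(alleles)), ""),
         function(x) paste(rev(x), collapse = ""), character(1))
}

# A palindromic (ambiguous-strand) variant reads the same on both strands:
# effect allele equals the reverse complement of the other allele (A/T, C/G).
#' @noRd
is_palindromic <- function(ea, oa) {
  valid <- grepl("^[ACGT]+$", ea) & grepl("^[ACGT]+$", oa)
  out <- rep(FALSE, length(ea))
  out[valid] <- ea[valid] == reverse_complement(oa[valid])
  out
}

#' @noRd
is_indel <- function(ea, oa) {
  nchar(ea) != 1L | nchar(oa) != 1L
}

# Run an expression under a locally seeded RNG without disturbing the
# caller's RNG stream. seed = NULL uses (and advances) the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
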