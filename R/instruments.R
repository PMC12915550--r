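# Cis instrument selection and instrument-strength screening.

#' Instrument F statistic
#'
#' Single-variant strength statistic `(beta/se)^2`; values above 10 are the
#' conventional bar for ruling out weak-instrument bias.
#'
#' @param beta,se per-allele association estimate and its standard error
#'   (vectorized).
#' @return nonnegative numeric vector.
#' @export
f_statistic <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0)) stop("se must be positive", call. = FALSE)
  (beta / se)^2
}

#' Select cis instruments for one gene locus
#'
#' Keeps exposure variants lying within the gene body extended by
#' `window_bp` on each side (closed interval, 1-based), reaching the
#' association p-value threshold, and strong enough by F statistic. The
#' result is sorted by ascending p (ties by position, then variant id), so
#' selection is deterministic and independent of input row order.
#'
#' @param exp `trait_table` of exposure associations (needs `chrom`, `pos`).
#' @param locus one-row data.frame or list with `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param window_bp flank added to the gene body; default 1 Mb, the cis
#'   convention of the source pQTL studies.
#' @param p_threshold selection p-value; default genome-wide significance
#'   5e-8.
#' @param f_min minimum F statistic; default 10.
#' @return data.frame of instruments (exposure record columns plus
#'   `gene_id` and `f_stat`); zero rows when the locus has no eligible
#'   variant ("not available for analysis").
#' @export
select_cis_instruments <- function(exp, locus, window_bp = 1e6,
                                   p_threshold = 5e-8, f_min = 10) {
  locus <- as.list(locus)
  stopifnot(window_bp >= 0)
  lo <- as.numeric(locus$start) - window_bp
  hi <- as.numeric(locus$end) + window_bp
  ok <- !is.na(exp$chrom) & exp$chrom == as.character(locus$chrom) &
    !is.na(exp$pos) & exp$pos >= lo & exp$pos <= hi &
    !is.na(exp$pval) & exp$pval <= p_threshold &
    !is.na(exp$se) & exp$se > 0
  sel <- as.data.frame(exp)[ok, , drop = FALSE]
  if (nrow(sel) > 0L) {
    sel$f_stat <- f_statistic(sel$beta, sel$se)
    sel <- sel[sel$f_stat >= f_min, , drop = FALSE]
    sel <- sel[order(sel$pval, sel$pos, sel$variant_id), , drop = FALSE]
  } else {
    sel$f_stat <- numeric(0)
  }
  sel$gene_id <- rep(as.character(locus$gene_id), nrow(sel))
  rownames(sel) <- NULL
  sel
}

#' Greedy LD clumping of selected instruments
#'
#' Walks the instruments in ascending p order, keeping a candidate only if
#' its squared correlation with every already-kept variant is at most
#' `r2_max`. Without a regional LD matrix, independence cannot be verified
#' and only the single lowest-p instrument is returned (most cis instrument
#' sets in this pipeline end up as single variants).
#'
#' @param instruments output of [select_cis_instruments()].
#' @param ld square correlation (not r-squared) matrix with variant ids as
#'   dimnames, covering all instruments; or `NULL`.
#' @param r2_max maximum pairwise squared correlation, default 0.01.
#' @return subset of `instruments`, still sorted by ascending p.
#' @export
ld_clump <- function(instruments, ld = NULL, r2_max = 0.01) {
  if (nrow(instruments) == 0L) return(instruments)
  instruments <- instruments[order(instruments$pval, instruments$pos,
                                   instruments$variant_id), , drop = FALSE]
  if (is.null(ld)) return(instruments[1L, , drop = FALSE])
  if (!is.matrix(ld) || nrow(ld) != ncol(ld) ||
      is.null(rownames(ld)) || !all(instruments$variant_id %in% rownames(ld))) {
    stop("LD matrix must be square with dimnames covering all instruments",
         call. = FALSE)
  }
  ld <- ld[instruments$variant_id, instruments$variant_id, drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(instruments))) {
    if (all(ld[i, kept]^2 <= r2_max)) kept <- c(kept, i)
  }
  out <- instruments[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}
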