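# Aligning exposure and outcome association records to a common effect
# allele, with strand correction and palindromic-variant handling.

#' Align one exposure/outcome record pair to a common effect allele
#'
#' The outcome record is re-expressed per the exposure's effect allele.
#' Matching is attempted in this order: direct match (`kept_same`); swapped
#' alleles (`flipped`: outcome beta negated, eaf complemented); match after
#' reverse complement, with or without a swap (`strand_corrected`).
#' Palindromic variants (A/T or C/G) cannot be strand-resolved from allele
#' letters; under `policy = "drop"` they are always dropped, under
#' `"infer_by_eaf"` they are aligned by allele-frequency concordance unless
#' either trait's eaf is within `eaf_window` of 0.5 (or missing), in which
#' case they are dropped. Indels are matched by exact string equality or swap
#' only: reverse complement is ill-defined for length-mismatched alleles.
#'
#' @param exp,out single association records (one-row data.frames or lists
#'   with fields `variant_id`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`) for the same variant.
#' @param palindrome_policy `"infer_by_eaf"` (default) or `"drop"`.
#' @param eaf_window half-width of the ambiguity band around eaf 0.5 inside
#'   which a palindromic variant is dropped (default 0.08, i.e. drop when
#'   minor-allele frequency is above 0.42).
#'
#' @return one-row data.frame: `variant_id`, `effect_allele`, `other_allele`
#'   (the exposure orientation), `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`,
#'   `se_out`, `eaf_out`, `action` (one of `kept_same`, `flipped`,
#'   `strand_corrected`, `dropped_palindromic`, `dropped_mismatch`) and
#'   `reason` (detail for drops, e.g. `missing_eaf`). Dropped records carry
#'   `NA` outcome betas.
#' @export
align_pair <- function(exp, out,
                       palindrome_policy = c("infer_by_eaf", "drop"),
                       eaf_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  exp <- as.list(exp); out <- as.list(out)
  if (!identical(as.character(exp$variant_id), as.character(out$variant_id))) {
    stop("align_pair called on different variants: ",
         exp$variant_id, " vs ", out$variant_id, call. = FALSE)
  }
  ea_e <- toupper(exp$effect_allele); oa_e <- toupper(exp$other_allele)
  ea_o <- toupper(out$effect_allele); oa_o <- toupper(out$other_allele)
  eaf_e <- if (is.null(exp$eaf)) NA_real_ else as.numeric(exp$eaf)
  eaf_o <- if (is.null(out$eaf)) NA_real_ else as.numeric(out$eaf)
  b_o <- as.numeric(out$beta)

  result <- function(action, reason = NA_character_, beta_out = NA_real_,
                     se_out = NA_real_, eaf_out = NA_real_) {
    data.frame(variant_id = as.character(exp$variant_id),
               effect_allele = ea_e, other_allele = oa_e,
               beta_exp = as.numeric(exp$beta), se_exp = as.numeric(exp$se),
               eaf_exp = eaf_e,
               beta_out = beta_out, se_out = se_out, eaf_out = eaf_out,
               action = action, reason = reason,
               stringsAsFactors = FALSE)
  }
  keep <- function(action, flip) {
    result(action,
           beta_out = if (flip) -b_o else b_o,
           se_out = as.numeric(out$se),
           eaf_out = if (is.na(eaf_o)) NA_real_ else if (flip) 1 - eaf_o else eaf_o)
  }

  indel <- is_indel(ea_e, oa_e) || is_indel(ea_o, oa_o)
  if (ea_o == ea_e && oa_o == oa_e && !is_palindromic(ea_e, oa_e)) {
    return(keep("kept_same", flip = FALSE))
  }
  if (ea_o == oa_e && oa_o == ea_e && !is_palindromic(ea_e, oa_e)) {
    return(keep("flipped", flip = TRUE))
  }
  if (!indel && !is_palindromic(ea_e, oa_e)) {
    rc_ea <- reverse_complement(ea_o); rc_oa <- reverse_complement(oa_o)
    if (rc_ea == ea_e && rc_oa == oa_e) {
      return(keep("strand_corrected", flip = FALSE))
    }
    if (rc_ea == oa_e && rc_oa == ea_e) {
      return(keep("strand_corrected", flip = TRUE))
    }
    return(result("dropped_mismatch", reason = "irreconcilable_alleles"))
  }
  if (!indel && is_palindromic(ea_e, oa_e)) {
    # letters alone cannot distinguish strand flip from allele swap
    same_letters <- ea_o == ea_e && oa_o == oa_e
    swapped_letters <- ea_o == oa_e && oa_o == ea_e
    if (!same_letters && !swapped_letters) {
      return(result("dropped_mismatch", reason = "irreconcilable_alleles"))
    }
    if (palindrome_policy == "drop") {
      return(result("dropped_palindromic", reason = "policy_drop"))
    }
    if (is.na(eaf_e) || is.na(eaf_o)) {
      return(result("dropped_palindromic", reason = "missing_eaf"))
    }
    if (abs(eaf_e - 0.5) < eaf_window || abs(eaf_o - 0.5) < eaf_window) {
      return(result("dropped_palindromic", reason = "ambiguous_eaf"))
    }
    # eaf concordance: the outcome's effect allele is the exposure's effect
    # allele iff the reported frequencies fall on the same side of 0.5
    # (after undoing a letter swap).
    eaf_o_adj <- if (swapped_letters) 1 - eaf_o else eaf_o
    concordant <- (eaf_e < 0.5) == (eaf_o_adj < 0.5)
    if (same_letters) {
      if (concordant) return(keep("kept_same", flip = FALSE))
      return(keep("strand_corrected", flip = TRUE))
    }
    if (concordant) return(keep("flipped", flip = TRUE))
    return(keep("strand_corrected", flip = FALSE))
  }
  # indel path: exact or swapped string match only
  if (ea_o == ea_e && oa_o == oa_e) return(keep("kept_same", flip = FALSE))
  if (ea_o == oa_e && oa_o == ea_e) return(keep("flipped", flip = TRUE))
  result("dropped_mismatch", reason = "irreconcilable_alleles")
}

#' Harmonize an exposure table against the outcome table
#'
#' Variants present in both tables are aligned with [align_pair()]; exposure
#' variants absent from the outcome are tallied as unavailable (no proxy
#' search, deliberately: proxies would lower instrument stringency).
#'
#' @param exp,out `trait_table`s (or data.frames with the same columns).
#' @inheritParams align_pair
#' @return data.frame of harmonized pairs (all actions, including drops) with
#'   attribute `tally`: named counts per action/reason plus `unavailable`.
#' @export
harmonize_tables <- function(exp, out,
                             palindrome_policy = c("infer_by_eaf", "drop"),
                             eaf_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  shared <- intersect(exp$variant_id, out$variant_id)
  unavailable <- length(setdiff(exp$variant_id, out$variant_id))
  out_idx <- match(shared, out$variant_id)
  exp_idx <- match(shared, exp$variant_id)
  pairs <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    pairs[[i]] <- align_pair(exp[exp_idx[i], ], out[out_idx[i], ],
                             palindrome_policy = palindrome_policy,
                             eaf_window = eaf_window)
  }
  pairs <- if (length(pairs) > 0L) do.call(rbind, pairs) else empty_pairs()
  tally <- table(pairs$action)
  tally <- c(stats::setNames(as.integer(tally), names(tally)),
             unavailable = unavailable)
  attr(pairs, "tally") <- tally
  pairs
}

#' @noRd
empty_pairs <- function() {
  data.frame(variant_id = character(0), effect_allele = character(0),
             other_allele = character(0), beta_exp = numeric(0),
             se_exp = numeric(0), eaf_exp = numeric(0),
             beta_out = numeric(0), se_out = numeric(0), eaf_out = numeric(0),
             action = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' Keep only usable harmonized pairs
#'
#' @param pairs output of [harmonize_tables()].
#' @return the rows whose action is `kept_same`, `flipped` or
#'   `strand_corrected`.
#' @export
usable_pairs <- function(pairs) {
  pairs[pairs$action %in% c("kept_same", "flipped", "strand_corrected"), ,
        drop = FALSE]
}
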