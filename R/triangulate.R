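# Integrating MR and colocalization evidence across proteomic platforms and
# expression tissues into an evidence matrix and per-trait support tiers.

#' Directional consistency of estimates across datasets
#'
#' TRUE when all estimable point estimates share a strict sign; an estimate
#' of exactly zero counts as inconsistent. Consistency is assessed
#' separately from statistical significance (an association can be
#' directionally consistent across platforms while significant in only one).
#'
#' @param estimates numeric vector of point estimates for one trait across
#'   datasets/tissues (`NA` = not estimable).
#' @return logical, or `NA` when fewer than 2 estimates are estimable.
#' @export
directional_consistency <- function(estimates) {
  est <- estimates[!is.na(estimates)]
  if (length(est) < 2L) return(NA)
  all(est > 0) || all(est < 0)
}

#' @noRd
significance_stars <- function(p_adj) {
  ifelse(is.na(p_adj), NA_character_,
         ifelse(p_adj < 0.001, "***",
                ifelse(p_adj < 0.01, "**",
                       ifelse(p_adj < 0.05, "*", ""))))
}

#' Build the trait-by-dataset evidence matrix
#'
#' One cell per (trait, dataset) combination: populated with the MR estimate
#' sign, adjusted p and significance stars (thresholds 0.05 / 0.01 / 0.001
#' on the adjusted p) where a result exists, otherwise explicitly marked
#' unavailable (the "gray fields"). Colocalization posteriors are merged in
#' where available.
#'
#' @param mr_results data.frame of primary MR results with columns
#'   `trait_id`, `dataset`, `estimate`, `p_adj` (rows with `status !=
#'   "ok"` are treated as unavailable).
#' @param coloc_results optional data.frame with `trait_id`, `dataset`,
#'   `pp_h4`, `conditional_pp`.
#' @param traits,datasets optional universes; default to those observed.
#' @return long data.frame, exactly one row per (trait, dataset) cell, with
#'   `available`, `estimate`, `sign`, `p_adj`, `stars`, `pp_h4`,
#'   `conditional_pp`.
#' @export
build_evidence_matrix <- function(mr_results, coloc_results = NULL,
                                  traits = NULL, datasets = NULL) {
  ok <- mr_results[!is.na(mr_results$status) & mr_results$status == "ok", ,
                   drop = FALSE]
  if (anyDuplicated(paste(ok$trait_id, ok$dataset, sep = "\r"))) {
    stop("duplicate (trait, dataset) results", call. = FALSE)
  }
  if (is.null(traits)) traits <- unique(mr_results$trait_id)
  if (is.null(datasets)) datasets <- unique(mr_results$dataset)
  cells <- expand.grid(trait_id = traits, dataset = datasets,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(paste(cells$trait_id, cells$dataset, sep = "\r"),
               paste(ok$trait_id, ok$dataset, sep = "\r"))
  cells$available <- !is.na(idx)
  cells$estimate <- ok$estimate[idx]
  cells$sign <- ifelse(is.na(cells$estimate), NA_character_,
                       ifelse(cells$estimate > 0, "+",
                              ifelse(cells$estimate < 0, "-", "0")))
  cells$p_adj <- ok$p_adj[idx]
  cells$stars <- significance_stars(cells$p_adj)
  if (!is.null(coloc_results) && nrow(coloc_results) > 0L) {
    cidx <- match(paste(cells$trait_id, cells$dataset, sep = "\r"),
                  paste(coloc_results$trait_id, coloc_results$dataset, sep = "\r"))
    cells$pp_h4 <- coloc_results$pp_h4[cidx]
    cells$conditional_pp <- coloc_results$conditional_pp[cidx]
  } else {
    cells$pp_h4 <- rep(NA_real_, nrow(cells))
    cells$conditional_pp <- rep(NA_real_, nrow(cells))
  }
  cells[order(cells$trait_id, cells$dataset), , drop = FALSE]
}

#' Classify triangulated support for each trait
#'
#' An interpretive tiering of the evidence (the underlying analyses rank
#' candidates narratively; the tiers make that ranking a pure function of
#' the result tables):
#' * `T1` - MR-significant (adjusted p below `q_level`) in at least one
#'   protein platform, AND colocalization-supported (`pp_h4 >=
#'   coloc_threshold` in some dataset), AND corroborated by tissue eQTL
#'   evidence;
#' * `T2` - MR-significant plus exactly one of the two corroborations;
#' * `T3` - MR-significant only.
#' Traits significant nowhere receive no tier (excluded).
#'
#' "eQTL-corroborated" requires both FDR significance in that tissue and
#' sign consistency with the protein-level estimate.
#'
#' @param summary data.frame with one row per trait: `trait_id`,
#'   `mr_significant_datasets` (integer count), `coloc_supported` (logical),
#'   `eqtl_corroborated` (logical); optionally `directionally_consistent`.
#' @return the input with a `tier` column (`"T1"`, `"T2"`, `"T3"` or `NA`).
#' @export
classify_support <- function(summary) {
  sig <- summary$mr_significant_datasets >= 1L
  coloc <- !is.na(summary$coloc_supported) & summary$coloc_supported
  eqtl <- !is.na(summary$eqtl_corroborated) & summary$eqtl_corroborated
  summary$tier <- ifelse(!sig, NA_character_,
                         ifelse(coloc & eqtl, "T1",
                                ifelse(coloc | eqtl, "T2", "T3")))
  summary
}

#' Summarize per-trait evidence and assign tiers
#'
#' Aggregates the MR, colocalization and eQTL result tables into the
#' per-trait summary consumed by [classify_support()].
#'
#' @param mr_protein primary MR results for protein platforms (`trait_id`,
#'   `dataset`, `estimate`, `p_adj`, `status`).
#' @param coloc_protein colocalization results for protein platforms
#'   (`trait_id`, `dataset`, `pp_h4`).
#' @param mr_eqtl optional tissue MR results (same columns as `mr_protein`).
#' @param q_level FDR significance level (default 0.05).
#' @param coloc_threshold posterior support threshold on `pp_h4`
#'   (default 0.8).
#' @return tier table: one row per MR-significant trait universe member with
#'   counts, flags and tier.
#' @export
build_support_table <- function(mr_protein, coloc_protein = NULL,
                                mr_eqtl = NULL, q_level = 0.05,
                                coloc_threshold = 0.8) {
  ok <- mr_protein[mr_protein$status == "ok", , drop = FALSE]
  traits <- unique(mr_protein$trait_id)
  rows <- lapply(traits, function(tr) {
    mine <- ok[ok$trait_id == tr, , drop = FALSE]
    n_sig <- sum(!is.na(mine$p_adj) & mine$p_adj < q_level)
    dir_cons <- directional_consistency(mine$estimate)
    coloc_sup <- FALSE
    if (!is.null(coloc_protein) && nrow(coloc_protein) > 0L) {
      cp <- coloc_protein[coloc_protein$trait_id == tr, , drop = FALSE]
      coloc_sup <- any(!is.na(cp$pp_h4) & cp$pp_h4 >= coloc_threshold)
    }
    eqtl_cor <- FALSE
    tissues <- character(0)
    if (!is.null(mr_eqtl) && nrow(mr_eqtl) > 0L && nrow(mine) > 0L) {
      eq <- mr_eqtl[mr_eqtl$trait_id == tr & mr_eqtl$status == "ok", ,
                    drop = FALSE]
      eq <- eq[!is.na(eq$p_adj) & eq$p_adj < q_level, , drop = FALSE]
      # corroboration: FDR-significant in the tissue and sign-consistent
      # with the protein-level estimate on the outcome scale
      psign <- sign(mine$estimate[which.min(mine$p_adj)])
      cons <- sign(eq$estimate) == psign & sign(eq$estimate) != 0
      tissues <- eq$dataset[cons]
      eqtl_cor <- length(tissues) > 0L
    }
    data.frame(trait_id = tr,
               mr_significant_datasets = n_sig,
               directionally_consistent = dir_cons,
               coloc_supported = coloc_sup,
               eqtl_corroborated = eqtl_cor,
               eqtl_tissues = paste(tissues, collapse = ","),
               stringsAsFactors = FALSE)
  })
  classify_support(do.call(rbind, rows))
}
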