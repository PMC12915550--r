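# End-to-end orchestration: instrument selection -> harmonization -> MR ->
# FDR -> colocalization -> triangulation, plus the validation wrapper.
# Per-trait failures (no cis instruments, not-estimable sensitivity methods)
# are recorded in the manifest and never abort a scan.

#' Default scan configuration
#'
#' @return list of all tunable thresholds with their defaults: `cis_window`
#'   (1e6 bp), `p_threshold` (5e-8), `f_min` (10), `r2_max` (0.01),
#'   `palindrome_policy` (`"infer_by_eaf"`), `eaf_window` (0.08), coloc
#'   priors `p1`/`p2`/`p12` (1e-4/1e-4/1e-5), `coloc_threshold` (0.8),
#'   `q_level` (0.05), `n_boot` (2000).
#' @export
default_scan_config <- function() {
  list(cis_window = 1e6, p_threshold = 5e-8, f_min = 10, r2_max = 0.01,
       palindrome_policy = "infer_by_eaf", eaf_window = 0.08,
       p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, coloc_threshold = 0.8,
       q_level = 0.05, n_boot = 2000, genome_build = "synthetic")
}

#' @noRd
merge_config <- function(config) {
  cfg <- default_scan_config()
  for (k in names(config)) cfg[[k]] <- config[[k]]
  num_checks <- list(cis_window = c(0, Inf), p_threshold = c(0, 1),
                     f_min = c(0, Inf), r2_max = c(0, 1),
                     eaf_window = c(0, 0.5), coloc_threshold = c(0, 1),
                     q_level = c(0, 1))
  for (k in names(num_checks)) {
    v <- cfg[[k]]
    if (!is.numeric(v) || is.na(v) || v < num_checks[[k]][1] ||
        v > num_checks[[k]][2]) {
      stop("invalid config field: ", k, call. = FALSE)
    }
  }
  cfg
}

# Run one trait through instrument selection, harmonization, MR and coloc.
#' @noRd
scan_one_trait <- function(exp_tab, outcome, locus, ld, cfg, dataset, seed) {
  trait_id <- attr(exp_tab, "trait_id")
  trait_type <- attr(exp_tab, "trait_type")
  note <- function(status) {
    list(mr = NULL, coloc = NULL,
         log = data.frame(trait_id = trait_id, dataset = dataset,
                          status = status, n_instruments = 0L,
                          stringsAsFactors = FALSE))
  }
  instr <- select_cis_instruments(exp_tab, locus,
                                  window_bp = cfg$cis_window,
                                  p_threshold = cfg$p_threshold,
                                  f_min = cfg$f_min)
  if (nrow(instr) == 0L) return(note("no_cis_instruments"))
  instr <- ld_clump(instr, ld = ld, r2_max = cfg$r2_max)
  instr_tab <- trait_table(instr, trait_id = trait_id,
                           trait_type = trait_type, platform = dataset)
  pairs <- usable_pairs(harmonize_tables(instr_tab, outcome,
                                         palindrome_policy = cfg$palindrome_policy,
                                         eaf_window = cfg$eaf_window))
  if (nrow(pairs) == 0L || all(pairs$beta_exp == 0)) {
    return(note("unavailable_after_harmonization"))
  }
  pairs <- pairs[pairs$beta_exp != 0, , drop = FALSE]
  mr <- mr_all_methods(pairs, trait_id = trait_id,
                       n_boot = cfg$n_boot, seed = seed)
  mr$dataset <- dataset

  # colocalization uses the full cis region (no p filter), harmonized
  region_exp <- select_cis_instruments(exp_tab, locus,
                                       window_bp = cfg$cis_window,
                                       p_threshold = 1, f_min = 0)
  region_tab <- trait_table(region_exp, trait_id = trait_id,
                            trait_type = trait_type, platform = dataset)
  rpairs <- usable_pairs(harmonize_tables(region_tab, outcome,
                                          palindrome_policy = cfg$palindrome_policy,
                                          eaf_window = cfg$eaf_window))
  coloc <- NULL
  if (nrow(rpairs) > 0L) {
    r1 <- structure(data.frame(variant_id = rpairs$variant_id,
                               beta = rpairs$beta_exp, se = rpairs$se_exp,
                               stringsAsFactors = FALSE),
                    trait_type = "quantitative")
    r2 <- structure(data.frame(variant_id = rpairs$variant_id,
                               beta = rpairs$beta_out, se = rpairs$se_out,
                               stringsAsFactors = FALSE),
                    trait_type = "binary")
    coloc <- coloc_abf(r1, r2, p1 = cfg$p1, p2 = cfg$p2, p12 = cfg$p12)
    coloc <- cbind(data.frame(trait_id = trait_id, dataset = dataset,
                              stringsAsFactors = FALSE), coloc)
  }
  list(mr = mr, coloc = coloc,
       log = data.frame(trait_id = trait_id, dataset = dataset,
                        status = "analyzed", n_instruments = nrow(pairs),
                        stringsAsFactors = FALSE))
}

#' Run the proteome-/transcriptome-wide scan
#'
#' Executes, per dataset (proteomic platform or expression tissue) and per
#' trait: cis instrument selection, LD clumping, harmonization against the
#' outcome GWAS, MR estimation (Wald or IVW primary; Egger and weighted
#' median where at least 3 instruments exist), then Benjamini-Hochberg FDR
#' control within each dataset, regional Bayesian colocalization, and
#' cross-dataset triangulation.
#'
#' @param exposures named list: dataset label -> list of exposure
#'   `trait_table`s (one per trait).
#' @param outcome outcome `trait_table` (the disease GWAS).
#' @param loci locus annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`); trait ids must match locus `gene_id`s.
#' @param ld optional named list of per-locus LD correlation matrices
#'   (gene_id -> matrix). Loci without a matrix fall back to the single
#'   lowest-p instrument.
#' @param config list overriding [default_scan_config()] entries.
#' @param seed RNG seed (weighted-median bootstrap); recorded in the
#'   manifest.
#' @param out_dir optional directory; when given, all result tables plus a
#'   manifest are written via [write_results()].
#' @return list: `mr` (all methods, all traits; `p_adj` filled on primary
#'   rows within each dataset), `coloc`, `evidence` (trait x dataset cells),
#'   `tiers`, `log` (per-trait status), `manifest`.
#' @export
run_scan <- function(exposures, outcome, loci, ld = NULL, config = list(),
                     seed = 1L, out_dir = NULL) {
  cfg <- merge_config(config)
  stopifnot(is.list(exposures), !is.null(names(exposures)))
  mr_rows <- list(); coloc_rows <- list(); log_rows <- list()
  for (dataset in names(exposures)) {
    for (exp_tab in exposures[[dataset]]) {
      trait_id <- attr(exp_tab, "trait_id")
      locus <- loci[loci$gene_id == trait_id, , drop = FALSE]
      if (nrow(locus) == 0L) {
        log_rows[[paste(dataset, trait_id)]] <-
          data.frame(trait_id = trait_id, dataset = dataset,
                     status = "no_locus", n_instruments = 0L,
                     stringsAsFactors = FALSE)
        next
      }
      res <- scan_one_trait(exp_tab, outcome, locus[1L, ],
                            ld = if (is.null(ld)) NULL else ld[[trait_id]],
                            cfg = cfg, dataset = dataset, seed = seed)
      key <- paste(dataset, trait_id)
      mr_rows[[key]] <- res$mr
      coloc_rows[[key]] <- res$coloc
      log_rows[[key]] <- res$log
    }
  }
  mr <- do.call(rbind, mr_rows)
  coloc <- do.call(rbind, coloc_rows)
  log <- do.call(rbind, log_rows)
  if (!is.null(mr)) rownames(mr) <- NULL
  if (!is.null(coloc)) rownames(coloc) <- NULL
  if (!is.null(log)) rownames(log) <- NULL
  if (is.null(log)) {
    log <- data.frame(trait_id = character(0), dataset = character(0),
                      status = character(0), n_instruments = integer(0))
  }

  # FDR within each dataset over primary estimates (per-dataset testing
  # universes, matching per-platform reporting); configurable to pooled
  if (!is.null(mr)) {
    primary <- mr$method %in% c("wald", "ivw_fe", "ivw_mre") & mr$status == "ok"
    groups <- if (isTRUE(cfg$pooled_fdr)) rep("all", nrow(mr)) else mr$dataset
    for (g in unique(groups[primary])) {
      sel <- primary & groups == g
      mr$p_adj[sel] <- bh_adjust(mr$pval[sel])
    }
  }

  mr_primary <- if (is.null(mr)) NULL else
    mr[mr$method %in% c("wald", "ivw_fe", "ivw_mre"), , drop = FALSE]
  evidence <- if (is.null(mr_primary)) NULL else
    build_evidence_matrix(mr_primary, coloc)
  trait_types <- vapply(unlist(exposures, recursive = FALSE),
                        function(t) attr(t, "trait_type"), character(1))
  dataset_of <- rep(names(exposures),
                    vapply(exposures, length, integer(1)))
  protein_datasets <- unique(dataset_of[trait_types == "protein"])
  eqtl_datasets <- unique(dataset_of[trait_types == "transcript"])
  tiers <- NULL
  if (!is.null(mr_primary)) {
    mp <- mr_primary[mr_primary$dataset %in% protein_datasets, , drop = FALSE]
    me <- mr_primary[mr_primary$dataset %in% eqtl_datasets, , drop = FALSE]
    if (nrow(mp) > 0L) {
      tiers <- build_support_table(mp, coloc_protein = coloc,
                                   mr_eqtl = if (nrow(me) > 0L) me else NULL,
                                   q_level = cfg$q_level,
                                   coloc_threshold = cfg$coloc_threshold)
    }
  }
  manifest_cfg <- c(cfg, list(seed = seed,
                              n_datasets = length(exposures),
                              n_traits_input = length(unique(log$trait_id)),
                              n_analyzed = sum(log$status == "analyzed"),
                              n_unavailable = sum(log$status != "analyzed")))
  out <- list(mr = mr, coloc = coloc, evidence = evidence, tiers = tiers,
              log = log, manifest = manifest_cfg)
  if (!is.null(out_dir)) {
    tables <- Filter(Negate(is.null),
                     list(mr = mr, coloc = coloc, evidence = evidence,
                          tiers = tiers, scan_log = log))
    write_results(tables, out_dir, config = manifest_cfg)
  }
  out
}

#' Run the case-control validation analyses
#'
#' Wraps [de_test()] on the intensity matrix and [baseline_compare()] on the
#' clinical covariate table.
#'
#' @param intensities proteins x samples matrix.
#' @param groups per-sample `case`/`control` labels.
#' @param clinical optional clinical covariate data.frame with a `group`
#'   column.
#' @param types optional covariate type map for [baseline_compare()].
#' @param min_detect_frac detection threshold for [de_test()].
#' @param out_dir optional output directory.
#' @return list: `de`, `baseline` (NULL when no clinical table given).
#' @export
run_validate <- function(intensities, groups, clinical = NULL, types = NULL,
                         min_detect_frac = 0.5, out_dir = NULL) {
  de <- de_test(intensities, groups, min_detect_frac = min_detect_frac)
  baseline <- if (is.null(clinical)) NULL else baseline_compare(clinical, types)
  if (!is.null(out_dir)) {
    tables <- Filter(Negate(is.null), list(de = de, baseline = baseline))
    write_results(tables, out_dir,
                  config = list(min_detect_frac = min_detect_frac))
  }
  list(de = de, baseline = baseline)
}
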