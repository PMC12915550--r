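# Case-control statistics for the mass-spectrometry validation cohort:
# differential protein expression on extracellular-vesicle intensities and
# the baseline clinical comparison table.

#' Differential expression test on a protein intensity matrix
#'
#' Proteins detected (non-missing intensity) in at least `min_detect_frac`
#' of the samples of each group are log2-transformed and compared between
#' cases and controls with a two-sided t-test (Welch by default; the
#' unequal-variance form is the safer choice for MS intensities). The effect
#' size is `log2fc = mean(log2 case) - mean(log2 control)`. P-values are
#' Benjamini-Hochberg adjusted across tested proteins. Proteins below the
#' detection threshold are returned with `detected = FALSE` and no
#' statistics.
#'
#' @param m numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns; nonnegative intensities, `NA` = not detected.
#' @param groups factor/character per sample with levels `case`, `control`.
#' @param min_detect_frac minimum per-group detection fraction (default
#'   0.5).
#' @param zero_as_missing treat exact zeros as missing (MS intensity
#'   convention, default TRUE); otherwise `pseudo` is added before log2.
#' @param pseudo pseudo-intensity added when zeros are kept (default 1).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame: `protein_id`, `detected`, `n_case_detected`,
#'   `n_control_detected`, `log2fc`, `pval`, `p_adj`, `status`.
#' @export
de_test <- function(m, groups, min_detect_frac = 0.5, zero_as_missing = TRUE,
                    pseudo = 1, var_equal = FALSE) {
  stopifnot(is.matrix(m), nrow(m) > 0L, ncol(m) == length(groups))
  groups <- as.character(groups)
  if (!all(groups %in% c("case", "control"))) {
    stop("groups must be 'case' or 'control'", call. = FALSE)
  }
  is_case <- groups == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("protein_", seq_len(nrow(m)))

  one <- function(i) {
    x <- m[i, ]
    if (zero_as_missing) x[!is.na(x) & x == 0] <- NA
    else x <- x + pseudo
    det_case <- sum(!is.na(x[is_case]))
    det_ctrl <- sum(!is.na(x[!is_case]))
    detected <- det_case >= min_detect_frac * sum(is_case) &&
      det_ctrl >= min_detect_frac * sum(!is_case)
    base <- data.frame(protein_id = ids[i], detected = detected,
                       n_case_detected = det_case,
                       n_control_detected = det_ctrl,
                       log2fc = NA_real_, pval = NA_real_, p_adj = NA_real_,
                       status = NA_character_, stringsAsFactors = FALSE)
    if (!detected) {
      base$status <- "below_detection"
      return(base)
    }
    lx <- log2(x)
    ca <- lx[is_case & !is.na(lx)]
    co <- lx[!is_case & !is.na(lx)]
    if (length(ca) < 2L || length(co) < 2L) {
      base$status <- "not_testable"
      return(base)
    }
    base$log2fc <- mean(ca) - mean(co)
    tt <- tryCatch(stats::t.test(ca, co, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) {
      # zero within-group variance: identical intensities carry no evidence
      base$pval <- if (base$log2fc == 0) 1 else NA_real_
      base$status <- if (base$log2fc == 0) "ok" else "not_testable"
      return(base)
    }
    base$pval <- tt$p.value
    base$status <- "ok"
    base
  }
  res <- do.call(rbind, lapply(seq_len(nrow(m)), one))
  tested <- !is.na(res$pval)
  if (any(tested)) res$p_adj[tested] <- bh_adjust(res$pval[tested])
  rownames(res) <- NULL
  res
}

#' Baseline clinical characteristics comparison
#'
#' Compares each covariate between cases and controls: continuous covariates
#' by a two-sided two-sample t-test on means (Welch by default), categorical
#' covariates by Pearson's chi-square on the contingency table without
#' continuity correction (the uncorrected form is the conventional
#' large-sample test for baseline tables). Constant covariates get a missing
#' p-value.
#'
#' @param clinical data.frame with a `group` column (`case`/`control`) and
#'   one column per covariate.
#' @param types named character vector typing each covariate as
#'   `"continuous"` or `"categorical"`; covariates not named are typed by
#'   column class (numeric = continuous).
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return data.frame: `covariate`, `type`, `statistic`, `df`, `pval`,
#'   `case_summary`, `control_summary`.
#' @export
baseline_compare <- function(clinical, types = NULL, var_equal = FALSE) {
  stopifnot(is.data.frame(clinical), "group" %in% names(clinical))
  groups <- as.character(clinical$group)
  if (!all(groups %in% c("case", "control"))) {
    stop("group column must be 'case' or 'control'", call. = FALSE)
  }
  covars <- setdiff(names(clinical), "group")
  is_case <- groups == "case"

  one <- function(cv) {
    x <- clinical[[cv]]
    type <- if (!is.null(types) && cv %in% names(types)) types[[cv]]
    else if (is.numeric(x)) "continuous" else "categorical"
    row <- data.frame(covariate = cv, type = type, statistic = NA_real_,
                      df = NA_real_, pval = NA_real_,
                      case_summary = NA_character_,
                      control_summary = NA_character_,
                      stringsAsFactors = FALSE)
    if (type == "continuous") {
      ca <- x[is_case]; co <- x[!is_case]
      row$case_summary <- sprintf("%.3g +/- %.3g", mean(ca, na.rm = TRUE),
                                  stats::sd(ca, na.rm = TRUE))
      row$control_summary <- sprintf("%.3g +/- %.3g", mean(co, na.rm = TRUE),
                                     stats::sd(co, na.rm = TRUE))
      if (length(unique(stats::na.omit(x))) < 2L) return(row)
      tt <- stats::t.test(ca, co, var.equal = var_equal)
      row$statistic <- unname(tt$statistic)
      row$df <- unname(tt$parameter)
      row$pval <- tt$p.value
    } else {
      tab <- table(factor(x), factor(groups, levels = c("case", "control")))
      row$case_summary <- paste(sprintf("%s:%d", rownames(tab), tab[, "case"]),
                                collapse = ";")
      row$control_summary <- paste(sprintf("%s:%d", rownames(tab), tab[, "control"]),
                                   collapse = ";")
      if (nrow(tab) < 2L) return(row)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      row$statistic <- unname(ct$statistic)
      row$df <- unname(ct$parameter)
      row$pval <- ct$p.value
    }
    row
  }
  out <- do.call(rbind, lapply(covars, one))
  rownames(out) <- NULL
  out
}
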