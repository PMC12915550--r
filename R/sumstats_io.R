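# Reading, validating and writing GWAS summary-statistics tables and the
# pipeline's result tables.

#' Construct a per-trait summary-statistics table
#'
#' A trait table holds one association record per variant for a single trait
#' (a circulating protein, a tissue transcript, or the disease outcome).
#' Records failing validity rules are dropped with a per-reason tally;
#' duplicate variant keys are resolved by minimum p-value (ties by first
#' occurrence).
#'
#' @param x data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` and optionally `chrom`, `pos`, `eaf`,
#'   `pval`, `n`. Alleles are uppercased. When `pval` is absent it is filled
#'   from the two-sided normal test of `beta/se`.
#' @param trait_id trait name (protein, gene or outcome identifier).
#' @param trait_type one of `"protein"`, `"transcript"`, `"outcome"`.
#' @param platform data source label (e.g. `"deCODE-SOMAscan"`, `"aorta"`).
#'
#' @return data.frame of class `trait_table` with attributes `trait_id`,
#'   `trait_type`, `platform` and `drop_tally` (named integer vector; one
#'   reason per dropped row, so kept + dropped = input rows).
#' @export
trait_table <- function(x, trait_id, trait_type = c("protein", "transcript", "outcome"),
                        platform = NA_character_) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(x))
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols) > 0L) {
    stop("trait table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("chrom", "pos", "eaf", "pval", "n")) {
    if (!col %in% names(x)) x[[col]] <- NA
  }
  x <- x[, c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
             "eaf", "beta", "se", "pval", "n")]
  x$variant_id <- as.character(x$variant_id)
  x$chrom <- as.character(x$chrom)
  x$pos <- suppressWarnings(as.integer(x$pos))
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  x$n <- suppressWarnings(as.integer(x$n))

  n_in <- nrow(x)
  reason <- rep(NA_character_, n_in)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  flag(is.na(x$variant_id) | x$variant_id == "" |
         is.na(x$beta) | is.na(x$se) |
         is.na(x$effect_allele) | is.na(x$other_allele), "missing_field")
  flag(!grepl("^[ACGT]+$", x$effect_allele) | !grepl("^[ACGT]+$", x$other_allele) |
         x$effect_allele == x$other_allele, "invalid_alleles")
  flag(x$se <= 0, "nonpositive_se")
  flag(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1), "eaf_out_of_range")
  flag(!is.na(x$pval) & (x$pval <= 0 | x$pval > 1), "invalid_pval")
  flag(!is.na(x$pos) & x$pos < 1L, "invalid_pos")

  kept <- x[is.na(reason), , drop = FALSE]
  tally <- table(reason[!is.na(reason)])
  tally <- stats::setNames(as.integer(tally), names(tally))

  # fill missing p from the z statistic before duplicate resolution
  need_p <- is.na(kept$pval)
  kept$pval[need_p] <- 2 * stats::pnorm(-abs(kept$beta[need_p] / kept$se[need_p]))
  kept$pval[need_p & kept$pval == 0] <- .Machine$double.xmin

  if (anyDuplicated(kept$variant_id)) {
    ord <- order(kept$variant_id, kept$pval,
                 seq_len(nrow(kept)))            # min p, tie by first occurrence
    kept <- kept[ord, , drop = FALSE]
    dup <- duplicated(kept$variant_id)
    n_dup <- sum(dup)
    kept <- kept[!dup, , drop = FALSE]
    kept <- kept[order(match(kept$variant_id, x$variant_id)), , drop = FALSE]
    tally <- c(tally, duplicate = n_dup)
  }
  rownames(kept) <- NULL

  if (nrow(kept) == 0L) {
    stop("no valid rows remain for trait '", trait_id, "'", call. = FALSE)
  }
  structure(kept,
            class = c("trait_table", "data.frame"),
            trait_id = trait_id, trait_type = trait_type,
            platform = platform, drop_tally = tally)
}

#' Read a summary-statistics file into a trait table
#'
#' Reads a (optionally gzipped) delimited text file and maps its columns onto
#' the canonical association fields. Column mapping is explicit: the three
#' source ecosystems (deCODE, UKB-PPP, GTEx) use different headers and silent
#' guessing invites allele errors.
#'
#' @param path file path (TSV or whitespace-delimited; `.gz` accepted).
#' @param column_map named character vector mapping canonical field names to
#'   file column names. Mandatory keys: `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`. Optional: `chrom`, `pos`, `eaf`, `pval`,
#'   `n`.
#' @param trait_id,trait_type,platform passed to [trait_table()].
#'
#' @return a `trait_table`.
#' @export
read_sumstats <- function(path, column_map, trait_id,
                          trait_type = c("protein", "transcript", "outcome"),
                          platform = NA_character_) {
  if (!file.exists(path)) stop("cannot read summary statistics: ", path, call. = FALSE)
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  missing_keys <- setdiff(mandatory, names(column_map))
  if (length(missing_keys) > 0L) {
    stop("column_map lacks mandatory field(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE)
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent) > 0L) {
    stop("file ", path, " lacks mapped column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  df <- stats::setNames(raw[, unname(column_map), drop = FALSE], names(column_map))
  trait_table(df, trait_id = trait_id, trait_type = trait_type, platform = platform)
}

#' Read a gene-locus annotation table
#'
#' Four-column table (`gene_id`, `chrom`, `start`, `end`); coordinates are
#' 1-based and inclusive at both ends (unlike BED).
#'
#' @param path TSV path.
#' @return data.frame with the four columns, `start <= end` enforced.
#' @export
read_loci <- function(path) {
  if (!file.exists(path)) stop("cannot read locus table: ", path, call. = FALSE)
  loci <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                            stringsAsFactors = FALSE)
  needed <- c("gene_id", "chrom", "start", "end")
  if (!all(needed %in% names(loci))) {
    stop("locus table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  loci$chrom <- as.character(loci$chrom)
  loci$start <- as.integer(loci$start)
  loci$end <- as.integer(loci$end)
  bad <- loci$start > loci$end | loci$start < 1L
  if (any(bad)) {
    stop("invalid locus coordinates for: ",
         paste(loci$gene_id[bad], collapse = ", "), call. = FALSE)
  }
  loci[, needed]
}

# Format a data.frame for text output with round-trippable doubles
# (17 significant digits preserves IEEE-754 binary64 exactly).
#' @noRd
format_for_tsv <- function(df) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      v <- df[[col]]
      out <- sprintf("%.17g", v)
      out[is.na(v)] <- NA_character_
      df[[col]] <- out
    }
  }
  df
}

#' Write pipeline result tables and a run manifest
#'
#' Writes one TSV per result class and a JSON manifest recording the run
#' configuration, seed, package version and per-table row counts. Numeric
#' columns are written with 17 significant digits so a re-read reproduces
#' every value exactly.
#'
#' @param tables named list of data.frames (e.g. `mr`, `coloc`, `evidence`,
#'   `tiers`, `de`, `baseline`).
#' @param out_dir output directory, created if needed.
#' @param config list echoed into the manifest (thresholds, seed, ...).
#' @return (invisibly) the manifest list; files `<name>.tsv` and
#'   `manifest.json` under `out_dir`.
#' @export
write_results <- function(tables, out_dir, config = list()) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(names(tables) != ""))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  counts <- list()
  for (name in names(tables)) {
    tab <- format_for_tsv(tables[[name]])
    utils::write.table(tab, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    counts[[name]] <- nrow(tab)
  }
  manifest <- list(
    package = "scadmr",
    version = as.character(utils::packageVersion("scadmr")),
    config = config,
    row_counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Read back a result table written by [write_results()]
#'
#' @param path TSV path.
#' @return data.frame with numeric columns restored to full precision.
#' @export
read_results_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, na.strings = "NA")
}
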