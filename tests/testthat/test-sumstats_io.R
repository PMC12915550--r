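# Reading, validation and round-trip of summary-statistics tables.

write_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

base_rows <- function() {
  data.frame(rsid = c("rs1", "rs2", "rs3"), chr = "1",
             bp = c(100L, 200L, 300L),
             A1 = c("A", "C", "T"), A2 = c("G", "T", "C"),
             freq = c(0.2, 0.3, 0.4),
             b = c(0.1, -0.2, 0.05), se = c(0.01, 0.02, 0.03),
             p = c(1e-20, 1e-22, 0.1), N = 35000L,
             stringsAsFactors = FALSE)
}

cmap <- c(variant_id = "rsid", chrom = "chr", pos = "bp",
          effect_allele = "A1", other_allele = "A2", eaf = "freq",
          beta = "b", se = "se", pval = "p", n = "N")

test_that("a well-formed table reads with no drops and uppercased alleles", {
  df <- base_rows()
  df$A1[1] <- "a"
  tab <- read_sumstats(write_fixture(df), cmap, trait_id = "P1")
  expect_s3_class(tab, "trait_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(length(attr(tab, "drop_tally")), 0L)
  expect_equal(tab$effect_allele[1], "A")
  expect_equal(attr(tab, "trait_id"), "P1")
})

test_that("invalid rows are dropped with one named reason each", {
  df <- rbind(base_rows(),
              data.frame(rsid = c("rs4", "rs5", "rs6"), chr = "1",
                         bp = c(400L, 500L, 600L),
                         A1 = c("A", "A", "A"), A2 = c("G", "A", "G"),
                         freq = c(0.2, 0.2, 1.4),
                         b = 0.1, se = c(0, 0.01, 0.01),
                         p = 0.5, N = 35000L))
  tab <- read_sumstats(write_fixture(df), cmap, trait_id = "P1")
  tally <- attr(tab, "drop_tally")
  expect_equal(nrow(tab), 3L)
  expect_equal(unname(tally["nonpositive_se"]), 1L)
  expect_equal(unname(tally["invalid_alleles"]), 1L)
  expect_equal(unname(tally["eaf_out_of_range"]), 1L)
  expect_equal(sum(tally) + nrow(tab), nrow(df))  # validation is total
})

test_that("duplicate variant keys keep the lowest-p row (groupby-min oracle)", {
  set.seed(11)
  df <- base_rows()[rep(1:3, c(4, 3, 3)), ]
  df$p <- runif(10, 0.01, 0.9)
  df$b <- rnorm(10)
  # independent oracle: per key, the row attaining the minimum p
  oracle <- do.call(rbind, lapply(split(df, df$rsid), function(g) {
    g[which.min(g$p), ]
  }))
  tab <- read_sumstats(write_fixture(df), cmap, trait_id = "P1")
  expect_equal(nrow(tab), 3L)
  expect_equal(unname(attr(tab, "drop_tally")["duplicate"]), 7L)
  got <- tab[order(tab$variant_id), ]
  want <- oracle[order(oracle$rsid), ]
  expect_equal(got$pval, want$p)
  expect_equal(got$beta, want$b)
})

test_that("mandatory-column and empty-table failures are informative", {
  df <- base_rows()
  expect_error(read_sumstats(write_fixture(df), cmap[-1], "P1"),
               "variant_id")
  expect_error(read_sumstats(write_fixture(df),
                             replace(cmap, 1, "nope"), "P1"),
               "nope")
  expect_error(read_sumstats(tempfile(), cmap, "P1"), "cannot read")
  df$se <- 0
  expect_error(read_sumstats(write_fixture(df), cmap, "P1"), "no valid rows")
})

test_that("missing pval column is filled from the normal z test", {
  df <- base_rows()
  tab <- read_sumstats(write_fixture(df), cmap[names(cmap) != "pval"], "P1")
  expect_equal(tab$pval, 2 * pnorm(-abs(df$b / df$se)))
})

test_that("write_results round-trips numeric values to full precision", {
  mr <- data.frame(trait_id = c("a", "b", "c", "d"),
                   estimate = c(pi, exp(1), 1 / 3, 1e-300),
                   pval = c(0.1234567890123456, 1e-17, 0.5, 1))
  out_dir <- tempfile()
  manifest <- write_results(list(mr = mr), out_dir,
                            config = list(seed = 123L))
  back <- read_results_table(file.path(out_dir, "mr.tsv"))
  expect_identical(back$estimate, mr$estimate)
  expect_identical(back$pval, mr$pval)
  expect_equal(manifest$row_counts$mr, 4L)
  written <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  expect_equal(written$config$seed, 123L)

  empty <- write_results(list(mr = mr[0, ]), tempfile())
  expect_equal(empty$row_counts$mr, 0L)
})

test_that("locus tables enforce 1-based inclusive coordinates", {
  path <- tempfile()
  writeLines(c("gene_id\tchrom\tstart\tend", "G1\t1\t100\t200"), path)
  loci <- read_loci(path)
  expect_equal(loci$start, 100L)
  writeLines(c("gene_id\tchrom\tstart\tend", "G1\t1\t300\t200"), path)
  expect_error(read_loci(path), "G1")
})
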