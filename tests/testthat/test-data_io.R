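test_that("read_mirna_de parses the documented layout and preserves order", {
  f <- write_de_csv(c("miRNA,FC,pvalue",
                      "mmu-miR-25a-5p,0.8,0.03",
                      "mmu-miR-1a-3p,1.4,0.8"))
  de <- read_mirna_de(f, fc_scale = "linear")
  expect_equal(de$mirna, c("mmu-miR-25a-5p", "mmu-miR-1a-3p"))
  expect_equal(de$fc, c(0.8, 1.4))
  expect_equal(de$p, c(0.03, 0.8))
  expect_identical(attr(de, "fc_scale"), "linear")

  # header-only file gives an empty, well-typed table
  empty <- read_mirna_de(write_de_csv("miRNA,FC,pvalue"))
  expect_equal(nrow(empty), 0L)
  expect_type(empty$fc, "double")

  # custom column names
  f2 <- write_de_csv(c("name,logfc,padj", "miR-x,-1,0.5"))
  de2 <- read_mirna_de(f2, name_col = "name", fc_col = "logfc",
                       p_col = "padj")
  expect_equal(de2$fc, -1)
})

test_that("read_mirna_de validates columns, values and duplicates", {
  f <- write_de_csv(c("miRNA,FC,pvalue", "miR-x,1,0.5"))
  expect_error(read_mirna_de(f, fc_col = "logFC"), "logFC")
  bad_p <- write_de_csv(c("miRNA,FC,pvalue", "miR-x,1,1.5"))
  expect_error(read_mirna_de(bad_p), "outside \\[0, 1\\]")
  bad_fc <- write_de_csv(c("miRNA,FC,pvalue", "miR-x,abc,0.5"))
  expect_error(read_mirna_de(bad_fc), "non-numeric")
  neg_fc <- write_de_csv(c("miRNA,FC,pvalue", "miR-x,-2,0.5"))
  expect_error(read_mirna_de(neg_fc, fc_scale = "linear"), "linear")
  expect_silent(read_mirna_de(neg_fc, fc_scale = "log2"))
  dup <- write_de_csv(c("miRNA,FC,pvalue", "miR-x,1,0.5", "miR-X,2,0.1"))
  expect_error(read_mirna_de(dup), "duplicated")
  expect_warning(kept <- read_mirna_de(dup, dedup = "first"), "keeping first")
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$fc, 1)
})

test_that("GMT parsing collapses duplicate members and unions the universe", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("SETA\tna\tG1\tG2\tG2", "SETB\thttp://x\tG3"), f)
  gs <- read_gmt(f)
  expect_setequal(gs$sets$SETA, c("G1", "G2"))
  expect_setequal(gs$universe, c("G1", "G2", "G3"))
  expect_identical(gs$descriptions[["SETB"]], "http://x")

  writeLines("SETB\tna", f)
  expect_error(read_gmt(f), "line 1")
  writeLines(c("S\tna\tG1", "S\tna\tG2"), f)
  expect_error(read_gmt(f), "duplicate")
})

test_that("GMT round-trips reproduce names and member sets exactly", {
  sets <- list(ALPHA = c("G5", "G1", "G3"), BETA = c("G2"),
               GAMMA = paste0("G", 10:30))
  gs <- gene_set_collection(sets, c(ALPHA = "d1", BETA = "d2", GAMMA = "d3"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(gs, f)
  back <- read_gmt(f)
  expect_identical(back$sets, gs$sets)
  expect_identical(back$descriptions, gs$descriptions)
  expect_identical(back$universe, gs$universe)
})

test_that("interaction tables round-trip through the reader with extras", {
  f <- tempfile(fileext = ".csv")
  tab <- toy_interactions()
  tab$score <- c("0.9", "0.8", "0.7", "0.6")  # query-type-specific column
  utils::write.csv(tab[names(tab) != "query_type"], f, row.names = FALSE)
  got <- read_interactions(f, "validated")
  expect_equal(got$mirna_name, tab$mirna_name)
  expect_equal(got$score, tab$score)        # extra column preserved
  expect_true(all(got$query_type == "validated"))

  # header-only file -> empty
  utils::write.csv(tab[0, names(tab) != "query_type"], f, row.names = FALSE)
  expect_equal(nrow(read_interactions(f, "predicted")), 0L)

  # schema errors
  utils::write.csv(data.frame(database = "x", entrez_id = "1"), f,
                   row.names = FALSE)
  expect_error(read_interactions(f), "mirna_name")
  utils::write.csv(data.frame(mirna_name = "m", database = "x"), f,
                   row.names = FALSE)
  expect_error(read_interactions(f), "gene identifier")
})

test_that("enrichment results survive a CSV round-trip within 1e-10", {
  res <- data.frame(
    set_name = c("A", "B", "C"), n_universe = 100L, n_members = c(5L, 0L, 9L),
    theta0 = c(-2.123456789012, -1.5, NA), theta1 = c(0.987654321098, -3, NA),
    se_theta1 = c(0.1234567890123, 2, NA), statistic = c(8.0000000001, -1.5, NA),
    p_value = c(1.23456789e-15, 0.13, NA), adjusted_p = c(3.7e-15, 0.13, NA),
    converged = c(TRUE, TRUE, FALSE), iterations = c(5L, 7L, 0L),
    optimizer = "IWLS", stringsAsFactors = FALSE
  )
  f <- tempfile(fileext = ".csv")
  write_enrichment_csv(res, f)
  back <- read_enrichment_csv(f)
  expect_identical(back$set_name, res$set_name)
  expect_identical(back$converged, res$converged)
  for (col in c("theta0", "theta1", "se_theta1", "statistic", "p_value",
                "adjusted_p")) {
    expect_equal(back[[col]], res[[col]], tolerance = 1e-10)
  }
  # empty result set -> header-only file that reads back empty
  write_enrichment_csv(res[0, ], f)
  expect_equal(nrow(read_enrichment_csv(f)), 0L)
})

test_that("ortholog maps read as trimmed two-column tables", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("source_id,hsa_entrez", " 1001 ,2001", "1002,2002",
               "1002,2003"), f)
  om <- read_ortholog_map(f)
  expect_equal(om$source_id, c("1001", "1002", "1002"))
  writeLines(c("source_id,hsa_entrez", ",2001"), f)
  expect_error(read_ortholog_map(f), "empty")
})
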