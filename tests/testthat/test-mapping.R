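test_that("map_targets filters by database and query type, case-insensitively", {
  ints <- toy_interactions()
  got <- map_targets(c("MIR-A", "miR-z"), ints, species = "mmu",
                     query_type = "validated") |> suppressWarnings()
  expect_named(got, c("MIR-A", "miR-z"))
  expect_equal(nrow(got[["MIR-A"]]), 2L)   # miR-a validated records
  expect_equal(nrow(got[["miR-z"]]), 0L)   # absent name -> empty, warned
  expect_warning(map_targets("miR-z", ints, "mmu", "validated"),
                 "no interaction records")
  # predicted query picks up only the targetscan record
  gp <- map_targets("miR-b", ints, species = "mmu", query_type = "predicted")
  expect_equal(gp[["miR-b"]]$database, "targetscan")
  # restricting databases drops the others
  gv <- map_targets("miR-a", ints, "mmu", "validated",
                    databases = "mirTarBase")
  expect_equal(nrow(gv[["miR-a"]]), 1L)
  expect_error(map_targets("miR-a", ints, "mmu", "validated",
                           databases = "nosuchdb"), "valid:")
})

test_that("rat queries silently drop databases without rat coverage", {
  ints <- toy_interactions()
  expect_message(
    gr <- suppressWarnings(map_targets("miR-b", ints, species = "rno",
                                       query_type = "predicted")),
    "targetscan")
  expect_equal(nrow(gr[["miR-b"]]), 0L)  # only targetscan had the record
})

test_that("map_targets is order-independent and idempotent", {
  ints <- toy_interactions()
  shuffled <- ints[c(3, 1, 4, 2), ]
  a <- map_targets("miR-a", ints, "mmu", "validated")
  b <- map_targets("miR-a", shuffled, "mmu", "validated")
  expect_setequal(a[["miR-a"]]$entrez_id, b[["miR-a"]]$entrez_id)
})

test_that("per-miRNA export writes exactly one csv per queried miRNA", {
  ints <- toy_interactions()
  pm <- suppressWarnings(map_targets(c("miR-a", "miR-b", "miR-z"), ints,
                                     "mmu", "validated"))
  dir <- tempfile("maps")
  paths <- write_target_maps(pm, dir)
  expect_length(paths, 3L)
  expect_true(all(file.exists(paths)))
  expect_equal(length(list.files(dir, pattern = "\\.csv$")), 3L)
  # the empty one is header-only
  expect_equal(nrow(utils::read.csv(paths[["miR-z"]])), 0L)
})

test_that("interaction-map conversion deduplicates and weights edges", {
  ints <- toy_interactions()
  pm <- map_targets(c("miR-a", "miR-b"), ints, "mmu", "validated")
  imap <- to_interaction_map(pm, "entrez")
  # miR-a -> 101, 102; miR-b -> 103 (the predicted 102 record is filtered)
  expect_equal(nrow(imap$edges), 3L)
  expect_true(all(imap$edges$w == 1))
  # same edge from two databases collapses to one
  ints2 <- rbind(ints, ints[1, ])
  ints2$database[5] <- "tarbase"
  pm2 <- map_targets("miR-a", ints2, "mmu", "validated")
  expect_equal(nrow(to_interaction_map(pm2, "entrez")$edges), 2L)
  # weight table covers a subset; the rest default to 1
  wtab <- data.frame(mirna = "miR-a", gene = "101", w = 2.5)
  imw <- to_interaction_map(pm, "entrez", weights = wtab)
  expect_equal(imw$edges$w[imw$edges$gene == "101"], 2.5)
  expect_true(all(imw$edges$w[imw$edges$gene != "101"] == 1))
  # records lacking the chosen identifier are dropped and counted
  ints3 <- ints
  ints3$entrez_id[1] <- ""
  pm3 <- map_targets("miR-a", ints3, "mmu", "validated")
  expect_message(im3 <- to_interaction_map(pm3, "entrez"), "dropped")
  expect_equal(im3$edges$gene, "102")
  ints3$entrez_id <- ""
  pm4 <- map_targets("miR-a", ints3, "mmu", "validated")
  expect_error(to_interaction_map(pm4, "entrez"), "every record")
})

test_that("ortholog conversion relabels, fans out and drops unmapped genes", {
  imap <- interaction_map(c("m1", "m1", "m2"), c("A", "B", "C"),
                          w = c(1, 2, 1))
  orth <- data.frame(source_id = c("A", "B", "B"),
                     hsa_entrez = c("9001", "9002", "9003"),
                     stringsAsFactors = FALSE)
  out <- suppressMessages(convert_hsa_entrez(imap, orth))
  # A -> 9001; B fans out to 9002 and 9003 keeping w = 2; C dropped
  expect_setequal(out$edges$gene, c("9001", "9002", "9003"))
  expect_equal(sort(out$edges$w[out$edges$gene %in% c("9002", "9003")]),
               c(2, 2))
  expect_false(any(out$edges$gene == "C"))
  # conversion never invents genes outside the ortholog table
  expect_true(all(out$edges$gene %in% orth$hsa_entrez))
  expect_warning(suppressMessages(
    convert_hsa_entrez(interaction_map("m", "ZZZ"), orth)), "no target gene")
})

test_that("names -> targets -> scores reproduces hand-computed values", {
  ints <- data.frame(
    database = "mirtarbase",
    mirna_accession = "",
    mirna_name = c("miR-1", "miR-1", "miR-2", "miR-3"),
    gene_symbol = "",
    entrez_id = c("10", "20", "20", "30"),
    ensembl_id = "",
    query_type = "validated", stringsAsFactors = FALSE)
  de <- data.frame(mirna = c("miR-1", "miR-2", "miR-3"),
                   fc = c(1, -1, 2), p = c(0.1, 0.01, 1),
                   stringsAsFactors = FALSE)
  pm <- map_targets(de$mirna, ints, "hsa", "validated")
  imap <- to_interaction_map(pm, "entrez")
  s <- mrna_scores(mirna_score_table(de), imap)
  # S(miR-1)=1, S(miR-2)=-2, S(miR-3)=0
  expect_equal(s[["10"]], -1)
  expect_equal(s[["20"]], -(1 + (-2)))
  expect_equal(s[["30"]], 0)
})
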