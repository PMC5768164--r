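test_that("design vectors lay scores and labels over the universe", {
  scores <- c(g2 = -1.5, g9 = 3)   # g9 outside the universe is ignored
  d <- build_design(scores, members = "g2", universe = c("g1", "g2", "g3"))
  expect_equal(d$y, c(0, 1, 0))
  expect_equal(d$x, c(0, -1.5, 0))  # unscored genes default to 0
  expect_false(d$degenerate)
  expect_true(build_design(scores, "gX", c("g1", "g2"))$degenerate)
  expect_true(build_design(scores, c("g1", "g2"), c("g1", "g2"))$degenerate)
  expect_error(build_design(scores, "g1", character(0)), "non-empty")
})

test_that("enrich_all reports every set, flags degenerates, adjusts over the
           converged family only", {
  set.seed(31)
  genes <- paste0("g", 1:300)
  scores <- setNames(rnorm(300), genes)
  coll <- gene_set_collection(
    list(FIT1 = sample(genes, 30), FIT2 = sample(genes, 40),
         GONE = c("zz1", "zz2")),   # members absent from scored universe
    extra_universe = genes)
  # GONE's members enter the universe (union rule), so it is fittable too;
  # build a truly degenerate one via a collection whose universe covers it
  res <- suppressMessages(enrich_all(scores, coll))
  expect_equal(res$set_name, c("FIT1", "FIT2", "GONE"))
  expect_true(all(res$converged))
  expect_equal(res$n_universe, rep(302L, 3))

  # degenerate: set spanning the entire universe
  coll2 <- gene_set_collection(list(ALL = genes, SOME = genes[1:10]),
                               extra_universe = genes)
  res2 <- suppressMessages(enrich_all(scores, coll2))
  expect_false(res2$converged[1])
  expect_true(is.na(res2$p_value[1]))
  expect_true(is.na(res2$adjusted_p[1]))
  expect_true(res2$converged[2])
  # single-member BH family: adjusted = raw
  expect_equal(res2$adjusted_p[2], res2$p_value[2])
  expect_equal(attr(res2, "n_degenerate"), 1L)
})

test_that("the BH family excludes degenerate sets but keeps their rows", {
  set.seed(32)
  genes <- paste0("g", 1:200)
  scores <- setNames(rnorm(200), genes)
  sets <- c(lapply(1:4, function(i) sample(genes, 25)), list(genes))
  names(sets) <- c(paste0("S", 1:4), "ALL")
  res <- suppressMessages(
    enrich_all(scores, gene_set_collection(sets, extra_universe = genes)))
  expect_equal(nrow(res), 5L)
  conv <- res$converged
  expect_equal(res$adjusted_p[conv], adjust_fdr(res$p_value[conv]))
  expect_true(all(res$adjusted_p[conv] >= res$p_value[conv]))
})

test_that("mirgs fits end to end and its methods are coherent", {
  de <- toy_de()
  imap <- interaction_map(c("miR-a", "miR-a", "miR-b", "miR-c"),
                          c("g1", "g2", "g2", "g5"))
  gs <- toy_collection()
  fit <- suppressMessages(mirgs(de, imap, gs))
  expect_s3_class(fit, "mirgs")
  expect_equal(nrow(fit$results), 2L)
  expect_equal(rownames(coef(fit)), c("SETA", "SETB"))
  expect_output(print(fit), "gene sets: 2 tested")
  expect_output(print(summary(fit)), "Top sets")
  # hand-computed scores flow through: g2 gets -(S_a + S_b)
  s <- mirna_score_table(de)
  expect_equal(fit$mrna_scores[["g2"]], -(s[["miR-a"]] + s[["miR-b"]]))
  # predict returns the fitted sigmoid over the universe
  k <- which(fit$results$set_name == "SETA")
  if (fit$results$converged[k]) {
    pr <- predict(fit, "SETA")
    expect_length(pr, length(fit$universe))
    expect_true(all(pr > 0 & pr < 1))
    r <- residuals(fit, "SETA", type = "response")
    y <- as.numeric(fit$universe %in% gs$sets$SETA)
    expect_equal(unname(r), y - pr)
    sim <- simulate(fit, nsim = 3, seed = 1, set = "SETA")
    expect_equal(dim(sim), c(length(fit$universe), 3L))
    expect_true(all(sim %in% 0:1))
  }
  # a named per-gene score vector is an equally valid entry point
  fit2 <- suppressMessages(mirgs(fit$mrna_scores, NULL, gs))
  expect_equal(fit2$results$theta1, fit$results$theta1)
})

test_that("label swap and score negation mirror the fit exactly", {
  set.seed(41)
  for (rep in 1:20) {
    m <- sample(100:400, 1)
    x <- rnorm(m) * sample(c(0.5, 1, 3), 1)
    y <- rbinom(m, 1, plogis(-1.5 + 0.8 * x))
    if (all(y == 0) || all(y == 1)) next
    f <- fit_iwls(x, y)
    if (!f$converged) next
    # membership swap negates both coordinates, bitwise
    fswap <- fit_iwls(x, 1 - y)
    expect_identical(fswap$theta[["theta1"]], -f$theta[["theta1"]])
    expect_identical(fswap$theta[["theta0"]], -f$theta[["theta0"]])
    expect_identical(wald_test(fswap)$p, wald_test(f)$p)
    # score negation negates the slope only, bitwise
    fneg <- fit_iwls(-x, y)
    expect_identical(fneg$theta[["theta1"]], -f$theta[["theta1"]])
    expect_identical(fneg$theta[["theta0"]], f$theta[["theta0"]])
    expect_identical(wald_test(fneg)$p, wald_test(f)$p)
  }
})

test_that("empty universe and empty collection are configuration errors", {
  expect_error(gene_set_collection(list()), "named")
  gs <- toy_collection()
  gs$sets <- list()
  gs$universe <- character(0)
  expect_error(enrich_all(c(g1 = 1), gs), "no gene sets")
})
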