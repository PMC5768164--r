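#' Build the design vectors for one gene set
#'
#' Lays the per-gene impact scores and the 0/1 membership labels of one gene
#' set over a common gene universe: every universe gene contributes one
#' observation, with x = its score (0 when no upstream miRNA was measured,
#' i.e. no evidence of miRNA effect) and y = 1 iff it belongs to the set.
#' The same full universe is used for every set — the competitive framing:
#' the test asks whether members differ from the rest of the universe.
#'
#' @param scores Named numeric vector of per-gene scores ([mrna_scores()]).
#' @param members Character vector of the set's member gene IDs.
#' @param universe Character vector of universe gene IDs (non-empty).
#' @return List with `x`, `y`, `gene_ids` (parallel vectors) and `degenerate`
#'   (TRUE when y is all-0 or all-1, in which case no model can be fitted).
#' @export
build_design <- function(scores, members, universe) {
  universe <- as.character(universe)
  if (length(universe) == 0L) stop("universe must be non-empty")
  x <- unname(scores[universe])
  x[is.na(x)] <- 0
  y <- as.numeric(universe %in% members)
  list(x = x, y = y, gene_ids = universe,
       degenerate = all(y == 0) || all(y == 1))
}

#' Enrichment of every gene set in a collection
#'
#' Fits the univariate membership logistic regression for each gene set over
#' the collection's universe, tests the score coefficient by Wald test, and
#' adjusts p-values across the converged sets by Benjamini–Hochberg FDR.
#' Degenerate sets (no member in the universe, or spanning the whole
#' universe) and non-converged fits are reported with `converged = FALSE`
#' and NA p-values rather than dropped, and are excluded from the
#' FDR family.
#'
#' @param scores Named numeric vector of per-gene impact scores.
#' @param collection A `gene_set_collection`. Its universe is extended with
#'   the scored genes (genes outside every set still inform the competitive
#'   comparison).
#' @param optimizer `"IWLS"` (Fisher scoring), `"BFGS"` or `"L-BFGS-B"`.
#' @param df_mode Wald reference: `"normal_z"` (default) or `"t_df1"`.
#' @param p_adjust `"fdr"` (Benjamini–Hochberg) or `"none"`.
#' @param tol,max_iter Convergence control, passed to the fitter. `max_iter`
#'   defaults to 25 for IWLS and 200 for the quasi-Newton optimisers.
#' @return Data frame with one row per set, in collection order: `set_name`,
#'   `n_universe`, `n_members`, `theta0`, `theta1`, `se_theta1`, `statistic`,
#'   `p_value`, `adjusted_p`, `converged`, `iterations`, `optimizer`, plus
#'   attributes `n_fitted` / `n_degenerate` and `iteration_log`.
#' @export
enrich_all <- function(scores, collection,
                       optimizer = c("IWLS", "BFGS", "L-BFGS-B"),
                       df_mode = c("normal_z", "t_df1"),
                       p_adjust = c("fdr", "none"),
                       tol = 1e-8, max_iter = NULL) {
  optimizer <- match.arg(optimizer)
  df_mode <- match.arg(df_mode)
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0L) stop("collection has no gene sets")
  if (is.null(max_iter)) max_iter <- if (optimizer == "IWLS") 25L else 200L
  universe <- sort(unique(c(collection$universe, names(scores))))
  if (length(universe) == 0L) stop("empty universe: no sets and no scores")
  x <- unname(scores[universe])
  x[is.na(x)] <- 0

  nset <- length(collection$sets)
  res <- data.frame(
    set_name = names(collection$sets),
    n_universe = length(universe),
    n_members = NA_integer_, theta0 = NA_real_, theta1 = NA_real_,
    se_theta1 = NA_real_, statistic = NA_real_, p_value = NA_real_,
    adjusted_p = NA_real_, converged = FALSE, iterations = 0L,
    optimizer = optimizer, stringsAsFactors = FALSE
  )
  for (k in seq_len(nset)) {
    y <- as.numeric(universe %in% collection$sets[[k]])
    res$n_members[k] <- as.integer(sum(y))
    if (all(y == 0) || all(y == 1)) next   # degenerate: reported, not fitted
    fit <- if (optimizer == "IWLS") {
      fit_iwls(x, y, tol = tol, max_iter = max_iter)
    } else {
      fit_optim(x, y, method = optimizer, tol = tol, max_iter = max_iter)
    }
    res$theta0[k] <- fit$theta[["theta0"]]
    res$theta1[k] <- fit$theta[["theta1"]]
    res$se_theta1[k] <- fit$se[["theta1"]]
    res$converged[k] <- fit$converged
    res$iterations[k] <- fit$iterations
    if (fit$converged) {
      wt <- wald_test(fit, df_mode = df_mode)
      res$statistic[k] <- wt$statistic
      res$p_value[k] <- wt$p
    }
  }
  ok <- res$converged & !is.na(res$p_value)
  if (any(ok)) {
    res$adjusted_p[ok] <- if (p_adjust == "fdr") {
      adjust_fdr(res$p_value[ok])
    } else {
      res$p_value[ok]
    }
  }
  n_deg <- sum(res$n_members == 0L | res$n_members == res$n_universe)
  message("fitted ", sum(ok), "/", nset, " gene sets (",
          n_deg, " degenerate, ", nset - n_deg - sum(ok),
          " not converged)")
  attr(res, "n_fitted") <- sum(ok)
  attr(res, "n_degenerate") <- n_deg
  attr(res, "iteration_log") <- stats::setNames(res$iterations, res$set_name)
  attr(res, "universe") <- universe
  res
}

#' miRNA gene-set enrichment model
#'
#' The top-level fitter: takes a miRNA differential-expression table, a
#' miRNA:target interaction map and a gene-set collection; computes the
#' signed miRNA scores and per-gene impact scores; and fits the per-set
#' membership logistic regression with Wald tests and FDR adjustment.
#'
#' The fitted object answers, for every gene set, whether membership can be
#' predicted from the miRNA impact score alone — the operational definition
#' of the set being under miRNA-dependent regulation. A positive coefficient
#' reads as relief of miRNA inhibition of the set under the experimental
#' condition, a negative one as increased inhibition.
#'
#' @param de Data frame of miRNA DE results ([read_mirna_de()]), or a named
#'   numeric vector of precomputed miRNA scores.
#' @param interactions An `interaction_map`, or NULL if `de` already is a
#'   named vector of per-GENE scores (entry point after external scoring).
#' @param gene_sets A `gene_set_collection` ([read_gmt()]).
#' @param fc_scale Fold-change scale of `de` (default: its attribute, else
#'   `"log2"`).
#' @param ... Passed to [enrich_all()] (`optimizer`, `df_mode`, `p_adjust`,
#'   `tol`, `max_iter`).
#' @return An object of class `"mirgs"`: list with `results` (the per-set
#'   table of [enrich_all()]), `mrna_scores`, `mirna_scores`, `universe`,
#'   `n_unmapped_mirna` and `call`.
#' @examples
#' de <- data.frame(mirna = c("miR-1", "miR-2"), fc = c(1, -2),
#'                  p = c(0.01, 0.001))
#' imap <- interaction_map(c("miR-1", "miR-1", "miR-2"),
#'                         c("g1", "g2", "g2"))
#' gs <- gene_set_collection(list(SETA = c("g1", "g3"), SETB = c("g2")),
#'                           extra_universe = paste0("g", 1:10))
#' fit <- mirgs(de, imap, gs)
#' summary(fit)
#' @export
mirgs <- function(de, interactions, gene_sets, fc_scale = NULL, ...) {
  stopifnot(inherits(gene_sets, "gene_set_collection"))
  n_unmapped <- NA_integer_
  if (is.data.frame(de)) {
    ms <- mirna_score_table(de, fc_scale = fc_scale)
  } else if (is.numeric(de) && !is.null(names(de))) {
    ms <- de
  } else {
    stop("'de' must be a DE data frame or a named numeric score vector")
  }
  if (!is.null(interactions)) {
    stopifnot(inherits(interactions, "interaction_map"))
    n_unmapped <- length(setdiff(tolower(names(ms)),
                                 tolower(interactions$edges$mirna)))
    gs_scores <- mrna_scores(ms, interactions)
  } else {
    gs_scores <- ms   # 'de' already held per-gene scores
    ms <- NULL
  }
  results <- enrich_all(gs_scores, gene_sets, ...)
  structure(list(results = results,
                 mrna_scores = gs_scores,
                 mirna_scores = ms,
                 gene_sets = gene_sets,
                 universe = attr(results, "universe"),
                 n_unmapped_mirna = n_unmapped,
                 call = match.call()),
            class = "mirgs")
}

#' @export
#' @method print mirgs
print.mirgs <- function(x, ...) {
  r <- x$results
  cat("miRNA gene-set enrichment (", r$optimizer[1L], " / Wald)\n", sep = "")
  cat("  universe:", r$n_universe[1L], "genes;",
      length(x$mrna_scores), "with a computed impact score\n")
  cat("  gene sets:", nrow(r), "tested,", sum(r$converged), "converged,",
      sum(!is.na(r$adjusted_p) & r$adjusted_p < 0.05),
      "with adjusted p < 0.05\n")
  invisible(x)
}

#' @export
#' @method summary mirgs
summary.mirgs <- function(object, top_n = 10L, ...) {
  r <- object$results
  conv <- r[r$converged & !is.na(r$adjusted_p), , drop = FALSE]
  conv <- conv[order(conv$adjusted_p, -abs(conv$theta1), conv$set_name), ,
               drop = FALSE]
  out <- list(results = object$results,
              top = utils::head(conv, top_n),
              n_sets = nrow(r), n_converged = sum(r$converged),
              n_signif = sum(!is.na(r$adjusted_p) & r$adjusted_p < 0.05))
  class(out) <- "summary.mirgs"
  out
}

#' @export
#' @method print summary.mirgs
print.summary.mirgs <- function(x, ...) {
  cat("miRNA gene-set enrichment:", x$n_sets, "sets,", x$n_converged,
      "converged,", x$n_signif, "significant at adjusted p < 0.05\n\n")
  if (nrow(x$top)) {
    cat("Top sets by adjusted p:\n")
    show <- x$top[, c("set_name", "n_members", "theta1", "se_theta1",
                      "statistic", "p_value", "adjusted_p")]
    show$theta1 <- signif(show$theta1, 4)
    show$se_theta1 <- signif(show$se_theta1, 3)
    show$statistic <- signif(show$statistic, 4)
    show$p_value <- signif(show$p_value, 3)
    show$adjusted_p <- signif(show$adjusted_p, 3)
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' @export
#' @method coef mirgs
coef.mirgs <- function(object, ...) {
  r <- object$results
  m <- cbind(theta0 = r$theta0, theta1 = r$theta1)
  rownames(m) <- r$set_name
  m
}

#' Predicted membership probability for a gene set
#'
#' Evaluates the fitted sigmoid of one gene set at new impact-score values:
#' the modelled probability that a gene with that score belongs to the set.
#'
#' @param object A fitted `mirgs` model.
#' @param set Name of the gene set.
#' @param newdata Numeric vector of impact scores; defaults to the universe
#'   scores the model was fitted on.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.mirgs <- function(object, set, newdata = NULL, ...) {
  r <- object$results
  k <- match(set, r$set_name)
  if (is.na(k)) stop("unknown gene set: ", set)
  if (!r$converged[k]) stop("no converged fit for set ", set)
  if (is.null(newdata)) {
    newdata <- unname(object$mrna_scores[object$universe])
    newdata[is.na(newdata)] <- 0
  }
  stats::plogis(r$theta0[k] + r$theta1[k] * newdata)
}

#' Residuals of one gene set's membership fit
#'
#' @param object A fitted `mirgs` model.
#' @param set Name of the gene set.
#' @param type `"deviance"` (default) or `"response"`.
#' @param ... Unused.
#' @return Numeric vector over the universe (names = gene IDs).
#' @export
residuals.mirgs <- function(object, set, type = c("deviance", "response"),
                            ...) {
  type <- match.arg(type)
  r <- object$results
  k <- match(set, r$set_name)
  if (is.na(k)) stop("unknown gene set: ", set)
  if (!r$converged[k]) stop("no converged fit for set ", set)
  mu <- predict.mirgs(object, set)
  y <- as.numeric(object$universe %in% object$gene_sets$sets[[set]])
  res <- switch(type,
                response = y - mu,
                deviance = sign(y - mu) *
                  sqrt(-2 * (y * log(mu) + (1 - y) * log1p(-mu))))
  stats::setNames(res, object$universe)
}

#' Simulate membership labels from a fitted set model
#'
#' Draws Bernoulli membership indicators over the universe from the fitted
#' sigmoid of one gene set — a parametric-bootstrap building block.
#'
#' @param object A fitted `mirgs` model.
#' @param nsim Number of replicate label vectors.
#' @param seed Optional integer seed.
#' @param set Name of the gene set.
#' @param ... Unused.
#' @return A matrix (genes x nsim) of 0/1 labels.
#' @export
simulate.mirgs <- function(object, nsim = 1, seed = NULL, set, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict.mirgs(object, set)
  matrix(stats::rbinom(length(mu) * nsim, 1L, rep(mu, nsim)),
         ncol = nsim, dimnames = list(object$universe, NULL))
}

#' @export
#' @method plot mirgs
plot.mirgs <- function(x, type = c("volcano", "bar"), ...) {
  type <- match.arg(type)
  if (type == "volcano") plot_volcano(x$results, ...)
  else plot_bar(x$results, ...)
}
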