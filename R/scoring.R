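# smallest p-value admitted before the log transform; caps |S_mirna| at 300
.p_floor <- 1e-300

#' Signed miRNA expression score
#'
#' Combines the significance and the direction of a miRNA's differential
#' expression into one signed score,
#' \deqn{S_{mirna} = -\log_{10}(p)\,\mathrm{sign}(\log_2 FC),}
#' so a strongly significant up-regulated miRNA scores high positive, a
#' strongly significant down-regulated one high negative, and p = 1 (or a
#' fold change of exactly zero on the log scale) scores 0. p-values below
#' 1e-300 are clamped there (with a warning) so the score stays finite.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param fc Numeric vector of fold changes (recycled against `p`).
#' @param fc_scale `"log2"` if `fc` already is a log2 fold change, `"linear"`
#'   if it is a ratio (must then be > 0).
#' @return Numeric vector of scores.
#' @examples
#' mirna_score(0.01, 1.5)            # +2
#' mirna_score(0.05, 0.5, "linear")  # -1.30103
#' @export
mirna_score <- function(p, fc, fc_scale = c("log2", "linear")) {
  fc_scale <- match.arg(fc_scale)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (fc_scale == "linear") {
    if (any(is.na(fc)) || any(fc <= 0)) {
      stop("fold change must be > 0 on the linear scale")
    }
    log2fc <- log2(fc)
  } else {
    if (any(is.na(fc))) stop("fold change must not be NA")
    log2fc <- fc
  }
  if (any(p < .p_floor & p > 0) || any(p == 0)) {
    warning("p-value(s) below ", .p_floor, " clamped; |score| capped at ",
            -log10(.p_floor))
  }
  p <- pmax(p, .p_floor)
  -log10(p) * sign(log2fc)
}

#' Score a whole differential-expression table
#'
#' @param de Data frame from [read_mirna_de()] (columns `mirna`, `fc`, `p`).
#' @param fc_scale Fold-change scale; defaults to the table's `"fc_scale"`
#'   attribute when present.
#' @return Named numeric vector of scores, one per miRNA, in table order.
#' @export
mirna_score_table <- function(de, fc_scale = NULL) {
  stopifnot(is.data.frame(de), all(c("mirna", "fc", "p") %in% names(de)))
  if (is.null(fc_scale)) fc_scale <- attr(de, "fc_scale")
  if (is.null(fc_scale)) fc_scale <- "log2"
  stats::setNames(mirna_score(de$p, de$fc, fc_scale), de$mirna)
}

#' Construct a miRNA:target interaction map
#'
#' The weighted bipartite relation between miRNAs and their target genes.
#' Each edge (miRNA, gene) carries an affinity weight w, 1 by default (no
#' difference between interactions). Duplicate edges are collapsed, keeping
#' the first weight.
#'
#' @param mirna Character vector of miRNA names.
#' @param gene Character vector of target gene IDs (same length).
#' @param w Optional numeric vector of non-negative weights (recycled).
#' @return An `interaction_map`: a list with an `edges` data frame
#'   (`mirna`, `gene`, `w`).
#' @export
interaction_map <- function(mirna, gene, w = 1) {
  mirna <- trimws(as.character(mirna))
  gene <- trimws(as.character(gene))
  stopifnot(length(mirna) == length(gene))
  w <- rep_len(as.numeric(w), length(mirna))
  if (any(is.na(w) | w < 0)) stop("weights must be non-negative numbers")
  if (any(!nzchar(mirna)) || any(!nzchar(gene))) {
    stop("miRNA names and gene IDs must be non-empty")
  }
  edges <- data.frame(mirna = mirna, gene = gene, w = w,
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges[, c("mirna", "gene")]), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "interaction_map")
}

#' @export
#' @method print interaction_map
print.interaction_map <- function(x, ...) {
  cat("Interaction map:", nrow(x$edges), "edges,",
      length(unique(x$edges$mirna)), "miRNAs,",
      length(unique(x$edges$gene)), "target genes\n")
  invisible(x)
}

#' Weighted incidence matrix of scored miRNAs against their targets
#'
#' Builds the sparse matrix B with one row per miRNA of `mirnas` and one
#' column per target gene, B\[i, g\] = w(i, g) for edges present in the map
#' and 0 otherwise. The per-gene impact score is then the single product
#' -t(B) %*% s, which is how [mrna_scores()] computes it.
#'
#' @param mirnas Character vector of miRNA names indexing the rows (typically
#'   the names of a score table). Matching against the map is
#'   case-insensitive; miRNAs without targets give all-zero rows.
#' @param imap An `interaction_map`.
#' @return A `dgCMatrix` with dimnames (miRNA, gene). Columns span the union
#'   of targets of the listed miRNAs (zero columns if none).
#' @export
build_incidence <- function(mirnas, imap) {
  stopifnot(inherits(imap, "interaction_map"))
  mirnas <- as.character(mirnas)
  edges <- imap$edges
  ri <- match(tolower(edges$mirna), tolower(mirnas))
  keep <- !is.na(ri)
  edges <- edges[keep, , drop = FALSE]
  ri <- ri[keep]
  genes <- sort(unique(edges$gene))
  ci <- match(edges$gene, genes)
  Matrix::sparseMatrix(i = ri, j = ci, x = edges$w,
                       dims = c(length(mirnas), length(genes)),
                       dimnames = list(mirnas, genes))
}

#' Per-gene miRNA impact score
#'
#' For every gene with at least one scored upstream miRNA, the sign-reversed
#' weighted sum of its upstream miRNAs' scores,
#' \deqn{S_{mrna}(g) = -\sum_i w(i, g)\, S_{mirna}(i),}
#' computed as a negated incidence-matrix–vector product. Because miRNAs are
#' predominantly inhibitory, a positive value suggests relief of inhibition
#' under the experimental condition and a negative value increased
#' inhibition; opposite-signed upstream miRNAs accumulate and cancel.
#'
#' @param mirna_scores Named numeric vector (names = miRNA) from
#'   [mirna_score_table()].
#' @param imap An `interaction_map`. miRNAs present in the map but not in the
#'   score table contribute nothing (counted in a message); scored miRNAs with
#'   no targets affect no gene.
#' @return Named numeric vector of scores over the targeted genes.
#' @export
mrna_scores <- function(mirna_scores, imap) {
  stopifnot(inherits(imap, "interaction_map"))
  if (is.null(names(mirna_scores))) stop("mirna_scores must be named")
  unscored <- setdiff(unique(tolower(imap$edges$mirna)),
                      tolower(names(mirna_scores)))
  if (length(unscored)) {
    message(length(unscored),
            " mapped miRNA(s) have no expression score and contribute 0")
  }
  B <- build_incidence(names(mirna_scores), imap)
  if (ncol(B) == 0L) return(stats::setNames(numeric(0), character(0)))
  s <- as.numeric(Matrix::crossprod(B, mirna_scores))
  stats::setNames(-s, colnames(B))
}
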