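# derived substream seed: one global seed drives independent per-component
# streams, so adding a component does not perturb the others
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + k * 7919) %% 2147483629L
}

#' Specification of a synthetic benchmark fixture
#'
#' Describes a self-contained synthetic study: a miRNA differential
#' expression experiment, a miRNA:target interaction table, and a gene-set
#' collection in which `n_planted` sets are truly under miRNA-dependent
#' regulation. Regulated miRNAs receive small p-values (|score| ~ Gamma with
#' shape 2 and mean `effect`) and a coherent fold-change sign; their targets
#' are preferentially placed into the planted sets, shifting those sets'
#' member scores systematically — exactly the signal the membership logistic
#' regression is designed to detect. Null miRNAs draw p ~ Uniform(0, 1) with
#' random fold-change sign; null sets draw members uniformly.
#'
#' @param n_mirna Number of measured miRNAs.
#' @param n_genes Number of genes in the synthetic genome.
#' @param targets_per_mirna Mean targets per miRNA (Poisson).
#' @param n_sets Number of gene sets.
#' @param set_size Mean set size (Poisson, floored at 2).
#' @param n_planted Number of truly regulated sets (<= n_sets).
#' @param effect Mean |miRNA score| of regulated miRNAs (> 0 unless 0 for a
#'   pure null fixture).
#' @param frac_regulated_mirna Fraction of miRNAs that are regulated.
#' @param planted_frac Fraction of a planted set's members drawn from the
#'   targets of matching-direction regulated miRNAs (rest uniform).
#' @param direction `"suppressed"` (planted coefficient signs negative),
#'   `"derepressed"` (positive) or `"mixed"` (alternating).
#' @param seed Integer seed; fixes every file byte.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_mirna = 100L, n_genes = 2000L,
                         targets_per_mirna = 20, n_sets = 50L,
                         set_size = 50, n_planted = 5L, effect = 2,
                         frac_regulated_mirna = 0.3, planted_frac = 0.6,
                         direction = c("mixed", "suppressed", "derepressed"),
                         seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(n_mirna >= 1, n_genes >= 1, n_sets >= 1,
            n_planted >= 0, n_planted <= n_sets,
            targets_per_mirna > 0, set_size >= 1, effect >= 0,
            frac_regulated_mirna >= 0, frac_regulated_mirna <= 1,
            planted_frac >= 0, planted_frac <= 1)
  if (set_size > n_genes) stop("set_size cannot exceed n_genes")
  structure(list(n_mirna = as.integer(n_mirna), n_genes = as.integer(n_genes),
                 targets_per_mirna = targets_per_mirna,
                 n_sets = as.integer(n_sets), set_size = set_size,
                 n_planted = as.integer(n_planted), effect = effect,
                 frac_regulated_mirna = frac_regulated_mirna,
                 planted_frac = planted_frac, direction = direction,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic benchmark fixture
#'
#' Materialises a [fixture_spec()] into the four input artefacts of the
#' pipeline — miRNA DE table (log2 fold changes), interaction table in the
#' multi-database export schema, GMT gene-set file and ortholog map — plus
#' the ground truth (which sets were planted and with which expected
#' coefficient sign). Identical specs (including seed) produce byte-identical
#' files.
#'
#' @param spec A `fixture_spec`.
#' @param dir Optional output directory; when given, the files are written
#'   (`de.csv`, `interactions.csv`, `sets.gmt`, `orthologs.csv`,
#'   `truth_sets.csv`, `manifest.csv`) and their paths returned in `$files`.
#'   When NULL, only in-memory objects are returned.
#' @return A list with `de` (data frame, `fc_scale = "log2"` attribute),
#'   `interactions` (data frame in the [read_interactions()] schema), `imap`
#'   (`interaction_map`), `collection` (`gene_set_collection`), `orthologs`
#'   (data frame), `truth` (list: `planted_sets` data frame with
#'   `set_name`/`expected_sign`, `regulated_mirnas`, `edges`), and `files`
#'   (named paths, when `dir` was given).
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  mirnas <- sprintf("syn-miR-%04d-5p", seq_len(spec$n_mirna))
  genes <- as.character(100000L + seq_len(spec$n_genes))

  # --- miRNA stream: who is regulated, in which direction, DE values
  set.seed(.sub_seed(spec$seed, 1L))
  n_reg <- round(spec$frac_regulated_mirna * spec$n_mirna)
  if (spec$effect == 0) n_reg <- 0L
  reg_idx <- if (n_reg > 0) sort(sample.int(spec$n_mirna, n_reg)) else integer(0)
  # fc sign of each regulated miRNA; an up-regulated miRNA (+) pushes its
  # targets' impact scores negative (suppression)
  reg_sign <- if (n_reg > 0) {
    rep_len(c(1, -1), n_reg)[sample.int(n_reg)]
  } else {
    numeric(0)
  }
  p <- stats::runif(spec$n_mirna)
  log2fc <- stats::rnorm(spec$n_mirna, 0, 0.5)
  if (n_reg > 0) {
    g <- stats::rgamma(n_reg, shape = 2, scale = spec$effect / 2)
    p[reg_idx] <- 10^(-g)
    log2fc[reg_idx] <- reg_sign * stats::runif(n_reg, 0.5, 2)
  }
  de <- data.frame(mirna = mirnas, fc = log2fc, p = p,
                   stringsAsFactors = FALSE)
  attr(de, "fc_scale") <- "log2"

  # --- interaction stream
  set.seed(.sub_seed(spec$seed, 2L))
  k_targets <- pmin(stats::rpois(spec$n_mirna, spec$targets_per_mirna),
                    spec$n_genes)
  tgt <- lapply(k_targets, function(k) {
    if (k == 0L) character(0) else genes[sample.int(spec$n_genes, k)]
  })
  edges <- data.frame(
    mirna = rep(mirnas, vapply(tgt, length, 1L)),
    gene = unlist(tgt, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  dbs <- sample(c("targetscan", "miranda", "mirdb"), nrow(edges),
                replace = TRUE)
  interactions <- data.frame(
    database = dbs,
    mirna_accession = sprintf("MIMAT%07d", match(edges$mirna, mirnas)),
    mirna_name = edges$mirna,
    gene_symbol = paste0("SYM", edges$gene),
    entrez_id = edges$gene,
    ensembl_id = paste0("ENSSYNG", edges$gene),
    query_type = "predicted",
    score = round(stats::runif(nrow(edges)), 4),
    stringsAsFactors = FALSE
  )
  imap <- interaction_map(edges$mirna, edges$gene)

  # --- gene-set stream: planted sets draw from direction-matched targets
  set.seed(.sub_seed(spec$seed, 3L))
  planted_sign <- switch(spec$direction,
                         suppressed = rep(-1, spec$n_planted),
                         derepressed = rep(1, spec$n_planted),
                         mixed = rep_len(c(-1, 1), spec$n_planted))
  # pool of targets of up-regulated miRNAs (their scores shift negative) and
  # of down-regulated miRNAs (scores shift positive)
  pool_neg <- unique(edges$gene[edges$mirna %in% mirnas[reg_idx[reg_sign > 0]]])
  pool_pos <- unique(edges$gene[edges$mirna %in% mirnas[reg_idx[reg_sign < 0]]])
  set_names <- sprintf("GS%04d", seq_len(spec$n_sets))
  sizes <- pmax(2L, pmin(stats::rpois(spec$n_sets, spec$set_size),
                         spec$n_genes))
  sets <- vector("list", spec$n_sets)
  for (k in seq_len(spec$n_sets)) {
    if (k <= spec$n_planted) {
      pool <- if (planted_sign[k] < 0) pool_neg else pool_pos
      n_sig <- min(round(spec$planted_frac * sizes[k]), length(pool))
      sig <- if (n_sig > 0) pool[sample.int(length(pool), n_sig)] else character(0)
      rest <- setdiff(genes, sig)
      fill <- rest[sample.int(length(rest), sizes[k] - n_sig)]
      sets[[k]] <- c(sig, fill)
    } else {
      sets[[k]] <- genes[sample.int(spec$n_genes, sizes[k])]
    }
  }
  names(sets) <- set_names
  collection <- gene_set_collection(
    sets,
    stats::setNames(rep("synthetic", spec$n_sets), set_names),
    extra_universe = unique(edges$gene)
  )

  # --- ortholog stream: shifted IDs, ~5% one-to-many, ~5% unmapped
  set.seed(.sub_seed(spec$seed, 4L))
  u <- stats::runif(spec$n_genes)
  mapped <- u > 0.05
  orth <- data.frame(source_id = genes[mapped],
                     hsa_entrez = as.character(300000L +
                                                 seq_len(spec$n_genes)[mapped]),
                     stringsAsFactors = FALSE)
  twomap <- genes[u > 0.95]
  if (length(twomap)) {
    orth <- rbind(orth, data.frame(
      source_id = twomap,
      hsa_entrez = as.character(600000L + match(twomap, genes)),
      stringsAsFactors = FALSE))
  }

  truth <- list(
    planted_sets = data.frame(
      set_name = set_names[seq_len(spec$n_planted)],
      expected_sign = if (spec$n_planted) planted_sign else numeric(0),
      stringsAsFactors = FALSE),
    regulated_mirnas = mirnas[reg_idx],
    edges = edges
  )

  out <- list(de = de, interactions = interactions, imap = imap,
              collection = collection, orthologs = orth, truth = truth,
              spec = spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(de = file.path(dir, "de.csv"),
               interactions = file.path(dir, "interactions.csv"),
               gmt = file.path(dir, "sets.gmt"),
               orthologs = file.path(dir, "orthologs.csv"),
               truth = file.path(dir, "truth_sets.csv"),
               manifest = file.path(dir, "manifest.csv"))
    de_out <- data.frame(miRNA = de$mirna, FC = sprintf("%.15g", de$fc),
                         pvalue = sprintf("%.15g", de$p))
    utils::write.csv(de_out, files[["de"]], row.names = FALSE, quote = FALSE)
    utils::write.csv(interactions[names(interactions) != "query_type"],
                     files[["interactions"]], row.names = FALSE, quote = FALSE)
    write_gmt(collection, files[["gmt"]])
    utils::write.csv(orth, files[["orthologs"]], row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(truth$planted_sets, files[["truth"]],
                     row.names = FALSE, quote = FALSE)
    manifest <- data.frame(key = c("fc_scale", "query_type",
                                   names(unclass(spec))),
                           value = c("log2", "predicted",
                                     vapply(unclass(spec), as.character,
                                            character(1))))
    utils::write.csv(manifest, files[["manifest"]], row.names = FALSE,
                     quote = FALSE)
    out$files <- files
  }
  out
}

#' Recovery report for a fixture run
#'
#' Compares enrichment results against the fixture's ground truth: power
#' (planted sets discovered at `alpha` with the planted coefficient sign),
#' sign accuracy (planted sets whose fitted coefficient has the planted
#' sign, among converged planted fits), and empirical FDR (non-planted
#' discoveries over all discoveries).
#'
#' @param results Enrichment results data frame ([enrich_all()]).
#' @param truth Truth component of [generate_fixture()] output.
#' @param alpha Adjusted-p discovery threshold (default 0.05).
#' @return List: `power`, `sign_accuracy` (NA when nothing planted),
#'   `empirical_fdr`, `n_discoveries`, `n_planted`, `discovered_sets`.
#' @export
evaluate_recovery <- function(results, truth, alpha = 0.05) {
  planted <- truth$planted_sets
  if (!all(planted$set_name %in% results$set_name)) {
    stop("results and truth are inconsistent: planted set(s) missing ",
         "from results")
  }
  disc <- results$converged & !is.na(results$adjusted_p) &
    results$adjusted_p < alpha
  discovered <- results$set_name[disc]
  n_disc <- sum(disc)
  false_disc <- sum(!(discovered %in% planted$set_name))
  if (nrow(planted) > 0L) {
    k <- match(planted$set_name, results$set_name)
    conv <- results$converged[k]
    good_sign <- sign(results$theta1[k]) == planted$expected_sign
    power <- mean(disc[k] & good_sign)
    sign_accuracy <- if (any(conv)) mean(good_sign[conv]) else NA_real_
  } else {
    power <- NA_real_
    sign_accuracy <- NA_real_
  }
  list(power = power, sign_accuracy = sign_accuracy,
       empirical_fdr = false_disc / max(1L, n_disc),
       n_discoveries = n_disc, n_false = false_disc,
       n_planted = nrow(planted), discovered_sets = discovered)
}
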