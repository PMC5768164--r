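# canonical interaction-database names, by query type
.validated_dbs <- c("mirecords", "mirtarbase", "tarbase")
.predicted_dbs <- c("diana-microt-cds", "elmmo", "microcosm", "miranda",
                    "mirdb", "pictar", "pita", "targetscan")
# prediction databases without rat coverage; silently dropped for rno queries
.rno_skipped <- c("diana-microt-cds", "pictar", "pita", "targetscan")

.canonical_dbs <- function(databases, query_type, species) {
  known <- if (query_type == "validated") .validated_dbs else .predicted_dbs
  if (is.null(databases)) {
    dbs <- known
  } else {
    dbs <- tolower(trimws(databases))
    bad <- setdiff(dbs, known)
    if (length(bad)) {
      stop("unknown ", query_type, " database(s): ",
           paste(bad, collapse = ", "),
           " (valid: ", paste(known, collapse = ", "), ")")
    }
  }
  if (species == "rno") {
    dropped <- intersect(dbs, .rno_skipped)
    if (length(dropped)) {
      message("skipping database(s) without rat coverage: ",
              paste(dropped, collapse = ", "))
      dbs <- setdiff(dbs, dropped)
    }
  }
  dbs
}

#' Map miRNA names to their target-gene interaction records
#'
#' Resolves a list of miRNA names against locally loaded interaction tables,
#' keeping only records of the requested query type and databases. Name
#' matching is case-insensitive (miRBase names are conventionally lower-case
#' but exports are often capitalised); miRNAs with no hits map to empty
#' record sets and are reported. For rat queries, prediction databases
#' without rat coverage (DIANA-microT-CDS, PicTar, PITA, TargetScan) are
#' dropped from the effective database list.
#'
#' @param mirna_names Character vector of miRNA names (non-empty).
#' @param interactions Interaction data frame from [read_interactions()]
#'   (or several, rbind-ed).
#' @param species `"hsa"`, `"rno"` or `"mmu"`.
#' @param query_type `"validated"` or `"predicted"`.
#' @param databases Optional subset of database names (case-insensitive);
#'   defaults to all known databases of the query type.
#' @return Named list (one element per queried miRNA, in query order) of
#'   interaction data frames; empty data frames for miRNAs with no hits.
#' @export
map_targets <- function(mirna_names, interactions,
                        species = c("hsa", "rno", "mmu"),
                        query_type = c("validated", "predicted"),
                        databases = NULL) {
  species <- match.arg(species)
  query_type <- match.arg(query_type)
  mirna_names <- trimws(as.character(mirna_names))
  if (length(mirna_names) == 0L || any(!nzchar(mirna_names))) {
    stop("mirna_names must be a non-empty vector of non-empty names")
  }
  dbs <- .canonical_dbs(databases, query_type, species)
  keep <- tolower(trimws(interactions$database)) %in% dbs &
    interactions$query_type == query_type
  tab <- interactions[keep, , drop = FALSE]
  key <- tolower(tab$mirna_name)
  out <- lapply(mirna_names, function(nm) {
    hits <- tab[key == tolower(nm), , drop = FALSE]
    rownames(hits) <- NULL
    hits
  })
  names(out) <- mirna_names
  n0 <- sum(vapply(out, nrow, 1L) == 0L)
  if (n0) warning(n0, " queried miRNA(s) had no interaction records")
  out
}

#' Write one target CSV per queried miRNA
#'
#' Mirrors the per-miRNA export convention of interaction queries: exactly
#' one CSV per queried miRNA (header-only when it had no hits), named
#' `<prefix><miRNA>.csv` with path-hostile characters replaced by `_`.
#'
#' @param per_mirna Named list from [map_targets()].
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return Character vector of the written paths, named by miRNA.
#' @export
write_target_maps <- function(per_mirna, dir, prefix = "targets_") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(per_mirna), function(nm) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", nm)
    path <- file.path(dir, paste0(prefix, safe, ".csv"))
    utils::write.csv(per_mirna[[nm]], path, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' Collapse per-miRNA interaction records into an interaction map
#'
#' Bridges mapping output to score calculation: picks one gene identifier
#' column, deduplicates (miRNA, gene) edges across databases, and attaches
#' affinity weights (default 1 for every edge not covered by the supplied
#' weight table).
#'
#' @param per_mirna Named list from [map_targets()].
#' @param id_column `"entrez"`, `"symbol"` or `"ensembl"` — which identifier
#'   becomes the gene key.
#' @param weights Optional data frame with columns `mirna`, `gene`, `w`.
#' @return An `interaction_map`. Records lacking the chosen identifier are
#'   dropped and counted in a message.
#' @export
to_interaction_map <- function(per_mirna,
                               id_column = c("entrez", "symbol", "ensembl"),
                               weights = NULL) {
  id_column <- match.arg(id_column)
  col <- switch(id_column, entrez = "entrez_id", symbol = "gene_symbol",
                ensembl = "ensembl_id")
  recs <- do.call(rbind, c(per_mirna, list(make.row.names = FALSE)))
  if (is.null(recs) || nrow(recs) == 0L) {
    stop("no interaction records to convert")
  }
  gene <- trimws(recs[[col]])
  dropped <- sum(!nzchar(gene) | is.na(gene))
  if (dropped == nrow(recs)) {
    stop("every record lacks the '", id_column, "' identifier")
  }
  if (dropped) {
    message(dropped, " record(s) without a ", id_column, " identifier dropped")
  }
  keep <- nzchar(gene) & !is.na(gene)
  imap <- interaction_map(recs$mirna_name[keep], gene[keep], w = 1)
  if (!is.null(weights)) {
    stopifnot(all(c("mirna", "gene", "w") %in% names(weights)))
    key <- paste(tolower(imap$edges$mirna), imap$edges$gene, sep = "\r")
    wkey <- paste(tolower(trimws(weights$mirna)), trimws(weights$gene),
                  sep = "\r")
    hit <- match(key, wkey)
    imap$edges$w[!is.na(hit)] <- as.numeric(weights$w)[hit[!is.na(hit)]]
  }
  imap
}

#' Relabel an interaction map with human ortholog Entrez IDs
#'
#' Replaces every target gene by its human Entrez ortholog(s) from a local
#' ortholog table, so human-centric gene-set databases (MSigDB KEGG/GO) can
#' be used with rodent miRNA data. A source gene with several human
#' orthologs fans out into several edges, each inheriting the source edge's
#' weight; unmapped genes are dropped and counted.
#'
#' @param imap An `interaction_map`.
#' @param orthologs Data frame from [read_ortholog_map()] (columns
#'   `source_id`, `hsa_entrez`; one-to-many allowed).
#' @return A relabelled `interaction_map`.
#' @export
convert_hsa_entrez <- function(imap, orthologs) {
  stopifnot(inherits(imap, "interaction_map"))
  if (nrow(orthologs) == 0L) stop("ortholog map is empty")
  hit <- orthologs[orthologs$source_id %in% imap$edges$gene, , drop = FALSE]
  merged <- merge(imap$edges, hit, by.x = "gene", by.y = "source_id")
  n_unmapped <- length(setdiff(imap$edges$gene, orthologs$source_id))
  if (n_unmapped) {
    message(n_unmapped, " target gene(s) without a human ortholog dropped")
  }
  if (nrow(merged) == 0L) {
    warning("no target gene could be mapped to a human ortholog")
    return(interaction_map(character(0), character(0)))
  }
  interaction_map(merged$mirna, merged$hsa_entrez, merged$w)
}
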