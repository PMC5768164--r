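#' Read a miRNA differential-expression table
#'
#' Reads a CSV holding one row per measured miRNA with its name, fold change
#' and p-value — the standard export of a two-group miRNA differential
#' expression analysis. Column names are configurable so exports from any
#' DE tool can be consumed without editing the file.
#'
#' @param path Path to a CSV file (comma-separated, header row, UTF-8).
#' @param name_col,fc_col,p_col Names of the columns holding the miRNA name,
#'   fold change and p-value. Defaults `"miRNA"`, `"FC"`, `"pvalue"`.
#' @param fc_scale Scale of the fold-change column: `"log2"` (the column is a
#'   log2 fold change, may be negative) or `"linear"` (a ratio, must be > 0).
#' @param dedup How to treat duplicated miRNA names: `"error"` (default) or
#'   `"first"` (keep the first occurrence, with a warning). Silent duplicates
#'   would double-count a miRNA in every downstream target score.
#' @return A data frame with columns `mirna` (character), `fc` (numeric) and
#'   `p` (numeric), one row per data row of the file, in file order, plus a
#'   `"fc_scale"` attribute.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("miRNA,FC,pvalue", "mmu-miR-25a-5p,0.8,0.03"), f)
#' read_mirna_de(f, fc_scale = "linear")
#' @export
read_mirna_de <- function(path, name_col = "miRNA", fc_col = "FC",
                          p_col = "pvalue", fc_scale = c("log2", "linear"),
                          dedup = c("error", "first")) {
  fc_scale <- match.arg(fc_scale)
  dedup <- match.arg(dedup)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  for (col in c(name_col, fc_col, p_col)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path,
           " (columns present: ", paste(names(df), collapse = ", "), ")")
    }
  }
  if (nrow(df) == 0L) {
    out <- data.frame(mirna = character(0), fc = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "fc_scale") <- fc_scale
    return(out)
  }
  mirna <- trimws(df[[name_col]])
  fc <- suppressWarnings(as.numeric(df[[fc_col]]))
  p <- suppressWarnings(as.numeric(df[[p_col]]))
  bad_fc <- which(is.na(fc) & !is.na(df[[fc_col]]) & nzchar(df[[fc_col]]))
  if (length(bad_fc)) {
    stop("non-numeric fold change at data row ", bad_fc[1L],
         ": '", df[[fc_col]][bad_fc[1L]], "'")
  }
  bad_p <- which(is.na(p))
  if (length(bad_p)) {
    stop("non-numeric or missing p-value at data row ", bad_p[1L])
  }
  if (any(p < 0 | p > 1)) {
    i <- which(p < 0 | p > 1)[1L]
    stop("p-value outside [0, 1] at data row ", i, ": ", p[i])
  }
  if (any(!nzchar(mirna))) {
    stop("empty miRNA name at data row ", which(!nzchar(mirna))[1L])
  }
  if (fc_scale == "linear" && any(!is.na(fc) & fc <= 0)) {
    i <- which(fc <= 0)[1L]
    stop("fold change must be > 0 on the linear scale (data row ", i,
         ": ", fc[i], ")")
  }
  dup <- duplicated(tolower(mirna))
  if (any(dup)) {
    if (dedup == "error") {
      stop("duplicated miRNA name(s): ",
           paste(unique(mirna[dup]), collapse = ", "),
           " (use dedup = \"first\" to keep the first occurrence)")
    }
    warning("dropping ", sum(dup), " duplicated miRNA row(s), keeping first")
    keep <- !dup
    mirna <- mirna[keep]; fc <- fc[keep]; p <- p[keep]
  }
  out <- data.frame(mirna = mirna, fc = fc, p = p, stringsAsFactors = FALSE)
  attr(out, "fc_scale") <- fc_scale
  out
}

#' Read a GMT gene-set file
#'
#' Parses the tab-separated gene-set format used by MSigDB/GSEA: one set per
#' line, first field the set name, second a free-text description (often a
#' URL), remaining fields the member gene identifiers. Duplicate members
#' within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a list with elements `sets` (named list of
#'   character vectors of member IDs), `descriptions` (named character) and
#'   `universe` (character; the union of all members).
#' @seealso [write_gmt()], [gene_set_collection()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields) | seq_along(fields) <= 2L]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields ",
           "(name, description, >=1 member required)")
    }
    nms[i] <- fields[1L]
    descs[i] <- fields[2L]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name(s) in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  names(descs) <- nms
  gene_set_collection(sets, descs)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (member gene IDs per set).
#' @param descriptions Optional named character vector of descriptions.
#' @param extra_universe Additional gene IDs to include in the universe beyond
#'   the union of set members (typically the genes carrying a computed score).
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL,
                                extra_universe = character(0)) {
  stopifnot(is.list(sets))
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) stop("gene-set names must be unique")
  if (any(vapply(sets, length, 1L) == 0L)) {
    stop("gene sets must have at least one member")
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  universe <- sort(unique(c(unlist(sets, use.names = FALSE),
                            as.character(extra_universe))))
  structure(list(sets = sets, descriptions = descriptions,
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
#' @method print gene_set_collection
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x$sets), "sets,",
      length(x$universe), "genes in universe\n")
  sizes <- vapply(x$sets, length, 1L)
  cat("  set sizes: min", min(sizes), "/ median", stats::median(sizes),
      "/ max", max(sizes), "\n")
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# universal columns of the interaction-table export schema
.interaction_cols <- c("database", "mirna_accession", "mirna_name",
                       "gene_symbol", "entrez_id", "ensembl_id")

#' Read a miRNA:mRNA interaction table
#'
#' Reads a CSV in the export schema of multi-database interaction queries:
#' universal columns `database`, `mirna_accession`, `mirna_name`,
#' `gene_symbol`, `entrez_id`, `ensembl_id`, plus any number of query-type
#' specific columns (e.g. experiment/support type for validated interactions,
#' prediction scores for predicted ones), which are carried through untouched.
#'
#' @param path Path to a CSV file.
#' @param query_type `"validated"` or `"predicted"`; stamped on every record.
#' @return A data frame with the universal columns, any extra columns, and a
#'   `query_type` column.
#' @export
read_interactions <- function(path, query_type = c("validated", "predicted")) {
  query_type <- match.arg(query_type)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!"mirna_name" %in% names(df)) {
    stop("interaction table ", path, " lacks a 'mirna_name' column")
  }
  id_cols <- intersect(c("gene_symbol", "entrez_id", "ensembl_id"), names(df))
  if (length(id_cols) == 0L) {
    stop("interaction table ", path, " has none of the gene identifier ",
         "columns gene_symbol / entrez_id / ensembl_id")
  }
  for (col in setdiff(.interaction_cols, names(df))) df[[col]] <- ""
  for (col in .interaction_cols) df[[col]] <- trimws(df[[col]])
  if (nrow(df) > 0L) {
    no_id <- !nzchar(df$gene_symbol) & !nzchar(df$entrez_id) &
      !nzchar(df$ensembl_id)
    if (any(no_id)) {
      stop("interaction record(s) with no gene identifier at data row ",
           which(no_id)[1L])
    }
    if (any(!nzchar(df$mirna_name))) {
      stop("empty mirna_name at data row ", which(!nzchar(df$mirna_name))[1L])
    }
  }
  df$query_type <- rep(query_type, nrow(df))
  extra <- setdiff(names(df), c(.interaction_cols, "query_type"))
  df[, c(.interaction_cols, "query_type", extra), drop = FALSE]
}

#' Read an ortholog mapping table
#'
#' Two-column CSV mapping a source-species gene identifier to a human Entrez
#' ID. One-to-many mappings (one source gene, several human orthologs) are
#' allowed and kept as separate rows.
#'
#' @param path Path to a CSV with columns `source_id` and `hsa_entrez`
#'   (alternative headers: first column = source, second = human Entrez).
#' @return A data frame with columns `source_id` and `hsa_entrez`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("ortholog map must have two columns")
  out <- data.frame(source_id = trimws(df[[1L]]),
                    hsa_entrez = trimws(df[[2L]]),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$source_id) | !nzchar(out$hsa_entrez))) {
    stop("ortholog map contains empty identifiers")
  }
  out
}

# column order of the enrichment-results CSV; also the round-trip contract
.enrichment_cols <- c("set_name", "n_universe", "n_members", "theta0",
                      "theta1", "se_theta1", "statistic", "p_value",
                      "adjusted_p", "converged", "iterations", "optimizer")

#' Write enrichment results to CSV
#'
#' One row per gene set, in input order, with a fixed documented column order:
#' `set_name, n_universe, n_members, theta0, theta1, se_theta1, statistic,
#' p_value, adjusted_p, converged, iterations, optimizer`. Numeric fields are
#' written with 15 significant digits so a read-back reproduces them to well
#' below 1e-10.
#'
#' @param results Enrichment results data frame (see [enrich_all()]). An empty
#'   data frame yields a header-only file.
#' @param path Output path.
#' @seealso [read_enrichment_csv()]
#' @export
write_enrichment_csv <- function(results, path) {
  results <- as.data.frame(results)
  missing <- setdiff(.enrichment_cols, names(results))
  if (length(missing)) {
    stop("results lack column(s): ", paste(missing, collapse = ", "))
  }
  out <- results[, .enrichment_cols, drop = FALSE]
  for (col in c("theta0", "theta1", "se_theta1", "statistic", "p_value",
                "adjusted_p")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         sprintf("%.15g", out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read enrichment results from CSV
#'
#' Inverse of [write_enrichment_csv()].
#'
#' @param path Path to a results CSV.
#' @return Enrichment results data frame.
#' @export
read_enrichment_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.enrichment_cols, names(df))
  if (length(missing)) {
    stop("not an enrichment results file; missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("theta0", "theta1", "se_theta1", "statistic", "p_value",
                "adjusted_p")) df[[col]] <- as.numeric(df[[col]])
  df$n_universe <- as.integer(df$n_universe)
  df$n_members <- as.integer(df$n_members)
  df$iterations <- as.integer(df$iterations)
  df$converged <- as.logical(df$converged)
  df[, .enrichment_cols, drop = FALSE]
}
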