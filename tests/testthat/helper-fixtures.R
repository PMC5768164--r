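# shared builders for small in-code fixtures

write_de_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

toy_de <- function() {
  data.frame(mirna = c("miR-a", "miR-b", "miR-c"),
             fc = c(1, -1.5, 0.2), p = c(0.01, 0.001, 0.5),
             stringsAsFactors = FALSE)
}

toy_collection <- function() {
  gene_set_collection(list(SETA = c("g1", "g2"), SETB = c("g2", "g3", "g4")),
                      extra_universe = paste0("g", 1:6))
}

# random non-degenerate logistic design with known parameters
random_design <- function(m, theta0 = -2, theta1 = 1, sd_x = 1) {
  x <- stats::rnorm(m, 0, sd_x)
  y <- stats::rbinom(m, 1, stats::plogis(theta0 + theta1 * x))
  while (all(y == 0) || all(y == 1)) {
    y <- stats::rbinom(m, 1, stats::plogis(theta0 + theta1 * x))
  }
  list(x = x, y = y)
}

# small interaction data frame in the reader schema
toy_interactions <- function() {
  data.frame(
    database = c("mirtarbase", "tarbase", "targetscan", "mirtarbase"),
    mirna_accession = paste0("MIMAT000", 1:4),
    mirna_name = c("miR-a", "miR-a", "miR-b", "miR-b"),
    gene_symbol = c("S1", "S2", "S2", "S3"),
    entrez_id = c("101", "102", "102", "103"),
    ensembl_id = paste0("ENSG00", 1:4),
    query_type = c("validated", "validated", "predicted", "validated"),
    stringsAsFactors = FALSE
  )
}
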