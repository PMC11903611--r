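# In-code fixtures: tiny TSV writers for the four input dialects.

write_protein_fixture <- function(rows, path = withr::local_tempfile(
                                    fileext = ".tsv",
                                    .local_envir = parent.frame())) {
  header <- "Gene\tGene name\tTissue\tCell type\tLevel\tReliability"
  writeLines(c(header, rows), path)
  path
}

# one protein row; defaults give a clean kidney glomerular record
prow <- function(gene = "ENSG1", name = "A", tissue = "kidney",
                 cell_type = "cells in glomeruli", level = "High",
                 reliability = "Enhanced") {
  paste(gene, name, tissue, cell_type, level, reliability, sep = "\t")
}

write_rna_fixture <- function(rows, path = withr::local_tempfile(
                                fileext = ".tsv",
                                .local_envir = parent.frame())) {
  writeLines(c("Gene\tGene name\tTissue\tnTPM", rows), path)
  path
}

rrow <- function(gene = "ENSG1", name = "A", tissue = "kidney", ntpm = 1) {
  paste(gene, name, tissue, ntpm, sep = "\t")
}

write_ms_fixture <- function(rows, path = withr::local_tempfile(
                               fileext = ".tsv",
                               .local_envir = parent.frame())) {
  writeLines(c("gene_name\tcompartment\tmean_spectral_count", rows), path)
  path
}

write_ext_fixture <- function(rows, path = withr::local_tempfile(
                                fileext = ".tsv",
                                .local_envir = parent.frame())) {
  writeLines(c("gene_name\tcompartment\ttpm", rows), path)
  path
}

# a small paired-record tibble with explicit categories
make_pairs <- function(rna, protein, compartment = "glomeruli",
                       ntpm = NULL, gene_name = NULL) {
  n <- length(rna)
  rna <- as_expression_category(rna)
  if (is.null(ntpm)) {
    ntpm <- ifelse(rna == "Not detected", 0,
                   c(`Low` = 1, `Medium` = 5, `High` = 50)[as.character(rna)])
    ntpm[is.na(ntpm)] <- 0
  }
  tibble::tibble(
    gene_id = sprintf("G%03d", seq_len(n)),
    gene_name = gene_name %||% sprintf("GN%03d", seq_len(n)),
    compartment = compartment,
    ntpm = ntpm,
    rna_category = rna,
    protein_category = as_expression_category(protein),
    discordance_class = classify_pair(rna, protein)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random non-degenerate r x c contingency table
random_table <- function(r = 4, c = 4, lambda = 8) {
  repeat {
    m <- matrix(stats::rpois(r * c, lambda), r, c)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
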