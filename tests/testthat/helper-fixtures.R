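# Compact fixture builders shared across test files.

# quick exon-table constructor: tx("t1", "g1", "+", c(1, 100), c(201, 300))
mk_tx <- function(id, gene, strand, ..., chrom = "chr1",
                  provenance = "assembled", biotype = "other") {
  exons <- list(...)
  tibble::tibble(
    chrom = chrom,
    start = vapply(exons, `[`, numeric(1), 1),
    end = vapply(exons, `[`, numeric(1), 2),
    strand = strand,
    transcript_id = id, gene_id = gene,
    provenance = provenance, biotype = biotype
  )
}

mk_expr <- function(ids, ..., level = "gene") {
  vals <- list(...)
  m <- do.call(cbind, vals)
  rownames(m) <- ids
  expression_table(ids, m, level)
}

# one shared default-configuration bundle for the slower module tests
shared_bundle <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- simulate_bundle(sim_config(seed = 42))
    b
  }
})
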