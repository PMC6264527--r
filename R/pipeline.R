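# End-to-end orchestration over an input bundle.

#' Run the full analysis pipeline on a bundle
#'
#' Executes, in order: the discovery cascade with TSS refinement, coding-
#' potential classification of the HQ transcripts, genomic-context
#' classification, lncRNA-PCG pairing with correlation versus the random
#' background, iterative expression clustering, divergent-transcription
#' profiling, temporal conservation grouping, strain-specific expression,
#' and viability statistics. All stages are deterministic given `seed`.
#'
#' @param bundle An input bundle (see [simulate_bundle()] /
#'   [read_bundle()]).
#' @param seed Integer seed driving the random background and clustering
#'   restarts.
#' @param cascade A [cascade_config()].
#' @param n_random_sets Random background sets (default 1000).
#' @param out_dir Optional directory: writes the HQ GTF, cascade report,
#'   TSS refinement records, classification tables and a JSON summary.
#' @return List with every stage's result and a `summary` list of
#'   headline counts.
#' @export
run_pipeline <- function(bundle, seed = 1, cascade = cascade_config(),
                         n_random_sets = 1000, out_dir = NULL) {
  casc <- run_cascade(bundle, cascade)
  hq <- casc$hq
  hq_genes <- unique(hq$gene_id)

  coding <- NULL
  if (!is.null(bundle$sequences)) {
    seqs <- bundle$sequences[intersect(names(bundle$sequences),
                                       unique(hq$transcript_id))]
    scores <- NULL
    if (!is.null(bundle$coding_evidence)) {
      scores <- bundle$coding_evidence %>%
        filter(.data$transcript_id %in% names(seqs))
    }
    coding <- coding_potential(seqs, scores)
  }
  noncoding_genes <- hq_genes
  if (!is.null(coding)) {
    coding_tx <- coding$transcript_id[coding$label == "coding"]
    coding_genes <- unique(hq$gene_id[hq$transcript_id %in% coding_tx])
    noncoding_genes <- setdiff(hq_genes, coding_genes)
  }
  hq_nc <- hq %>% filter(.data$gene_id %in% noncoding_genes)

  # merged lncRNA set: HQ novel + annotated lncRNAs passing expression
  annot_lnc <- bundle$reference %>%
    filter(.data$biotype == "lncRNA_annotated")
  expr_gene <- bundle$expr_gene
  if (is.null(expr_gene)) {
    all_tx <- bind_rows(bundle$candidates, bundle$reference)
    expr_gene <- expr_to_gene_level(
      bundle$expr_tx, tx_info(all_tx)[, c("transcript_id", "gene_id")])
  }
  merged_lnc <- bind_rows(hq_nc, annot_lnc)

  pcg <- bundle$reference %>% filter(.data$biotype == "protein_coding")
  pcg_expr <- pcg %>%
    filter(.data$gene_id %in% expressed_genes(expr_gene, 1))

  context <- classify_context(merged_lnc, pcg_expr, bundle$enhancers)

  pairs <- build_pair_sets(merged_lnc, pcg_expr)
  rnd <- random_pairs(unique(merged_lnc$gene_id),
                      unique(pcg_expr$gene_id),
                      n_sets = n_random_sets, seed = seed)
  corr_conditions <- intersect(
    c("Meso_34", "Meso_46", "Meso_68", "Nuclear_34",
      "WE_34", "WE_46", "WE_68"),
    expr_conditions(expr_gene))
  pair_r <- pair_correlations(bind_rows(pairs,
                                        select(rnd, -"set")),
                              expr_gene, corr_conditions)
  bg <- pair_r$r[pair_r$category == "random"]
  corr_tests <- pair_r %>%
    filter(.data$category != "random") %>%
    group_by(.data$category) %>%
    summarise(n = n(), median_r = stats::median(.data$r),
              p_vs_random = compare_category_to_background(
                .data$r, bg)$p_value,
              .groups = "drop")

  lnc_expr <- expr_gene %>%
    filter(.data$feature_id %in% unique(merged_lnc$gene_id))
  attr(lnc_expr, "level") <- "gene"
  nn <- intersect(sim_conditions()$non_nuclear, expr_conditions(expr_gene))
  clusters <- tryCatch(
    iterative_kmeans(expr_matrix(lnc_expr, nn), seed = seed),
    error = function(e) NULL)

  divergent <- NULL
  if (!is.null(bundle$coverage)) {
    ptx <- tx_info(longest_isoforms(pcg_expr))
    divergent <- divergent_profiles(
      tibble(gene_id = ptx$gene_id, chrom = ptx$chrom, tss = ptx$tss,
             strand = ptx$strand),
      bundle$coverage)
    fpkm <- expr_matrix(expr_gene)[, "Meso_68"]
    divergent$tercile_test <- compare_terciles(divergent$ranking, fpkm)
  }

  nuc <- nuclear_enriched(bundle$de)
  nuc_lnc <- intersect(nuc, unique(merged_lnc$gene_id))

  cons <- NULL
  if (!is.null(bundle$conserved)) {
    scores <- conservation_scores(merged_lnc, bundle$conserved)
    grp <- temporal_groups(bundle$de, expr_gene,
                           genes = unique(merged_lnc$gene_id))
    cons <- compare_conservation(grp, scores)
    cons$groups <- grp
  }

  strain <- NULL
  if (!is.null(bundle$strain_expr)) {
    strain <- strain_specific(
      stats::setNames(bundle$strain_expr$fpkm_a,
                      bundle$strain_expr$feature_id),
      stats::setNames(bundle$strain_expr$fpkm_b,
                      bundle$strain_expr$feature_id))
    strain <- strain %>%
      filter(.data$feature_id %in% unique(hq_nc$gene_id))
  }

  viability <- NULL
  if (!is.null(bundle$viability)) {
    viability <- viability_table(bundle$viability)
  }

  summary <- list(
    n_candidate_transcripts = length(unique(bundle$candidates$transcript_id)),
    n_hq_transcripts = length(unique(hq$transcript_id)),
    n_hq_genes = length(hq_genes),
    n_main_genes = length(casc$main_genes),
    n_constitutive_genes = length(casc$constitutive_genes),
    n_coding_flagged = if (!is.null(coding))
      sum(coding$label == "coding") else NA_integer_,
    n_tss_refined = sum(casc$tss_records$direction != "unchanged"),
    mean_tss_shift = if (any(casc$tss_records$direction != "unchanged"))
      mean(casc$tss_records$nt_moved[
        casc$tss_records$direction != "unchanged"]) else 0,
    n_merged_lnc_genes = length(unique(merged_lnc$gene_id)),
    n_clustered = if (!is.null(clusters)) nrow(clusters$assignments)
    else NA_integer_,
    n_nuclear_enriched = length(nuc_lnc),
    n_strain_off = if (!is.null(strain))
      sum(strain$status == "off_in_b") else NA_integer_,
    context_counts = as.list(table(context$context))
  )

  res <- list(cascade = casc, coding = coding, context = context,
              pairs = pairs, correlations = pair_r,
              correlation_tests = corr_tests, clusters = clusters,
              divergent = divergent, nuclear_enriched = nuc_lnc,
              conservation = cons, strain = strain,
              viability = viability, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gtf(hq, file.path(out_dir, "hq_lncrna.gtf"))
    readr::write_tsv(casc$report, file.path(out_dir, "cascade_report.tsv"))
    readr::write_tsv(casc$removed, file.path(out_dir,
                                             "cascade_removed.tsv"))
    readr::write_tsv(casc$tss_records,
                     file.path(out_dir, "tss_refinement.tsv"))
    readr::write_tsv(context, file.path(out_dir, "context_labels.tsv"))
    readr::write_tsv(corr_tests, file.path(out_dir,
                                           "correlation_tests.tsv"))
    if (!is.null(coding)) {
      readr::write_tsv(coding, file.path(out_dir, "coding_potential.tsv"))
    }
    if (!is.null(viability)) {
      readr::write_tsv(viability, file.path(out_dir, "viability.tsv"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}
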