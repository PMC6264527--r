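# Per-transcript conservation scores from overlapping conserved elements
# and the early/constitutive/late temporal grouping.

#' Conservation score of transcripts from scored conserved elements
#'
#' For each transcript, s = sum_i (O_i * P_i) / L, where O_i is the exonic
#' overlap in nucleotides with conserved element i, P_i the element's
#' score, and L the transcript's exonic length. Elements contribute
#' independently (overlapping elements are allowed), so splitting an
#' element into abutting pieces of equal score leaves s unchanged.
#'
#' @param exons Exon table (any number of transcripts).
#' @param elements Tibble `chrom`, `start`, `end`, `score` (strandless).
#' @param use_span Use the genomic span instead of exonic bases for both
#'   overlap and length.
#' @return Tibble `transcript_id`, `gene_id`, `length`, `score`.
#' @export
conservation_scores <- function(exons, elements, use_span = FALSE) {
  if (use_span) {
    gi <- tx_info(exons)
    exons <- tibble(chrom = gi$chrom, start = gi$start, end = gi$end,
                    strand = gi$strand, transcript_id = gi$transcript_id,
                    gene_id = gi$gene_id)
  }
  ti <- tx_info(exons)
  tot <- stats::setNames(rep(0, nrow(ti)), ti$transcript_id)
  if (nrow(elements) > 0) {
    eg <- GenomicRanges::GRanges(
      elements$chrom, IRanges::IRanges(elements$start, elements$end))
    cg <- exons_granges(exons)
    h <- find_ov(cg, eg, ignore.strand = TRUE)
    if (length(h) > 0) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(cg)[S4Vectors::queryHits(h)],
        IRanges::ranges(eg)[S4Vectors::subjectHits(h)]))
      contrib <- ov * elements$score[S4Vectors::subjectHits(h)]
      agg <- tapply(contrib,
                    exons$transcript_id[S4Vectors::queryHits(h)], sum)
      tot[names(agg)] <- agg
    }
  }
  tibble(transcript_id = ti$transcript_id, gene_id = ti$gene_id,
         length = ti$length,
         score = unname(tot[ti$transcript_id]) / ti$length)
}

#' @rdname conservation_scores
#' @export
conservation_score <- function(exons, elements, use_span = FALSE) {
  conservation_scores(exons, elements, use_span)$score
}

#' Early / constitutive / late temporal grouping
#'
#' Genes that do not change significantly between the earliest and latest
#' time points (adjusted p at or above `alpha` in the `comparison` DE
#' contrast, or absent from it) are constitutive; significantly changing
#' genes are split by whole-embryo expression into early (higher at
#' 3-4 h) and late.
#'
#' @param de DE table containing `comparison`.
#' @param expr Gene-level expression table with the two whole-embryo
#'   conditions.
#' @param genes Genes to group (default: all in `expr`).
#' @param comparison DE contrast between the flanking time points.
#' @param alpha Significance threshold (strict below, default 0.01).
#' @param early_condition,late_condition Whole-embryo condition names.
#' @return Tibble `gene_id`, `group` in early/constitutive/late.
#' @export
temporal_groups <- function(de, expr, genes = NULL,
                            comparison = "Time34_VS_Time68",
                            alpha = 0.01,
                            early_condition = "WE_34",
                            late_condition = "WE_68") {
  missing <- setdiff(c(early_condition, late_condition),
                     expr_conditions(expr))
  if (length(missing) > 0) {
    stop("missing whole-embryo condition(s): ",
         paste(missing, collapse = ", "))
  }
  if (!comparison %in% de$comparison) {
    stop("DE table lacks comparison ", comparison)
  }
  genes <- genes %||% expr$feature_id
  dsub <- de %>% filter(.data$comparison == !!comparison)
  padj <- dsub$padj[match(genes, dsub$gene_id)]
  m <- expr_matrix(expr, c(early_condition, late_condition))
  early <- m[match(genes, rownames(m)), 1]
  late <- m[match(genes, rownames(m)), 2]
  tibble(
    gene_id = genes,
    group = dplyr::case_when(
      is.na(padj) | padj >= alpha ~ "constitutive",
      early > late ~ "early",
      TRUE ~ "late")
  )
}

#' Compare conservation scores between temporal groups
#'
#' One score per gene (longest isoform by default), then two-sided
#' Mann-Whitney tests of early versus constitutive and early versus late.
#'
#' @param groups Tibble `gene_id`, `group`.
#' @param scores Output of [conservation_scores()] (per transcript).
#' @param isoform_rule `"longest"` (default) or `"most_conserved"`.
#' @return List: `medians` (named by group), `tests` tibble
#'   (`contrast`, `p_value`); empty groups are skipped with a warning.
#' @export
compare_conservation <- function(groups, scores,
                                 isoform_rule = c("longest",
                                                  "most_conserved")) {
  isoform_rule <- match.arg(isoform_rule)
  per_gene <- scores %>%
    group_by(.data$gene_id) %>%
    arrange(if (isoform_rule == "longest") desc(.data$length) else
      desc(.data$score), .data$transcript_id, .by_group = TRUE) %>%
    slice(1) %>% ungroup() %>%
    inner_join(groups, by = "gene_id")
  split_scores <- split(per_gene$score, per_gene$group)
  medians <- vapply(split_scores, stats::median, numeric(1))
  tests <- list()
  for (other in c("constitutive", "late")) {
    if (is.null(split_scores$early) || is.null(split_scores[[other]]) ||
        length(split_scores$early) == 0 ||
        length(split_scores[[other]]) == 0) {
      warning("empty group in early-vs-", other, " comparison; skipped")
      next
    }
    wt <- stats::wilcox.test(split_scores$early, split_scores[[other]],
                             exact = FALSE)
    tests[[length(tests) + 1]] <- tibble(
      contrast = paste0("early_vs_", other), p_value = wt$p.value)
  }
  list(medians = medians, tests = bind_rows(tests), per_gene = per_gene)
}
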