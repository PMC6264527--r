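# The high-quality lncRNA filtering cascade and CAGE-based TSS refinement.
#
# Stages run in a fixed order; every stage returns the retained exon table
# plus a removal record (transcript, gene, reason), and run_cascade()
# assembles the per-stage audit report where retained + removed = input.

stage_result <- function(stage, candidates, removed_tx, reason) {
  ti <- tx_info(candidates)
  removed <- ti %>% filter(.data$transcript_id %in% removed_tx)
  reason <- unlist(reason)
  rs <- if (!is.null(names(reason))) {
    unname(reason[removed$transcript_id])
  } else if (length(reason) >= 1) {
    rep(reason[[1]], nrow(removed))
  } else {
    character(nrow(removed))
  }
  list(
    stage = stage,
    retained = candidates %>%
      filter(!.data$transcript_id %in% removed_tx),
    removed = tibble(stage = stage,
                     transcript_id = removed$transcript_id,
                     gene_id = removed$gene_id,
                     reason = rs)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# same-strand exonic overlap hits between two exon tables (by >= 1 nt)
same_strand_hits <- function(a, b) {
  ha <- exons_granges(a); hb <- exons_granges(b)
  h <- find_ov(ha, hb, ignore.strand = TRUE)
  keep <- a$strand[S4Vectors::queryHits(h)] ==
    b$strand[S4Vectors::subjectHits(h)]
  h[keep]
}

anti_strand_hits <- function(a, b) {
  ha <- exons_granges(a); hb <- exons_granges(b)
  h <- find_ov(ha, hb, ignore.strand = TRUE)
  sa <- a$strand[S4Vectors::queryHits(h)]
  sb <- b$strand[S4Vectors::subjectHits(h)]
  h[(sa == "+" & sb == "-") | (sa == "-" & sb == "+")]
}

# transcripts of `candidates` all of whose exons lie fully inside
# same-strand introns of `reference`
embedded_transcripts <- function(candidates, reference) {
  intr <- introns_tbl(reference)
  if (nrow(intr) == 0) return(character())
  cg <- exons_granges(candidates)
  ig <- GenomicRanges::GRanges(intr$chrom,
                               IRanges::IRanges(intr$start, intr$end))
  h <- find_ov(cg, ig, type = "within",
                                   ignore.strand = TRUE)
  same <- candidates$strand[S4Vectors::queryHits(h)] ==
    intr$strand[S4Vectors::subjectHits(h)]
  within_exon <- unique(S4Vectors::queryHits(h)[same])
  flag <- seq_len(nrow(candidates)) %in% within_exon
  ok <- tapply(flag, candidates$transcript_id, all)
  names(ok)[ok]
}

#' Remove candidates overlapping annotated exons on the same strand
#'
#' A candidate gene is discarded when any of its exons shares at least one
#' nucleotide with an annotated (protein-coding or non-coding) exon in the
#' same orientation; antisense-only overlap is retained.
#'
#' @param candidates,reference Exon tables.
#' @return A stage result list: `stage`, `retained` (exon table), `removed`
#'   (transcript/gene/reason tibble).
#' @export
filter_annotated_overlap <- function(candidates, reference) {
  h <- same_strand_hits(candidates, reference)
  bad_genes <- unique(candidates$gene_id[S4Vectors::queryHits(h)])
  bad_tx <- unique(candidates$transcript_id[candidates$gene_id %in%
                                              bad_genes])
  stage_result("annotated_overlap", candidates, bad_tx,
               list("annotated_same_strand_overlap"))
}

#' Remove pre-mRNA candidates fully contained in same-strand introns
#'
#' Genes whose every exon lies fully within annotated introns in the same
#' orientation are discarded, unless the gene also overlaps an annotated
#' exon antisense.
#'
#' @inheritParams filter_annotated_overlap
#' @return A stage result list.
#' @export
filter_intronic <- function(candidates, reference) {
  intr <- introns_tbl(reference)
  if (nrow(intr) == 0) {
    return(stage_result("intronic", candidates, character(), list()))
  }
  cg <- exons_granges(candidates)
  ig <- GenomicRanges::GRanges(intr$chrom,
                               IRanges::IRanges(intr$start, intr$end))
  h <- find_ov(cg, ig, type = "within",
                                   ignore.strand = TRUE)
  same <- candidates$strand[S4Vectors::queryHits(h)] ==
    intr$strand[S4Vectors::subjectHits(h)]
  exon_in <- seq_len(nrow(candidates)) %in%
    unique(S4Vectors::queryHits(h)[same])
  all_in <- tapply(exon_in, candidates$gene_id, all)
  anti <- anti_strand_hits(candidates, reference)
  anti_genes <- unique(candidates$gene_id[S4Vectors::queryHits(anti)])
  bad_genes <- setdiff(names(all_in)[all_in], anti_genes)
  bad_tx <- unique(candidates$transcript_id[candidates$gene_id %in%
                                              bad_genes])
  stage_result("intronic", candidates, bad_tx, list("intron_embedded"))
}

#' Monoexonic transcript rules
#'
#' In order: (1) unstranded monoexonic transcripts are removed as
#' ambiguous; (2) monoexonic transcripts are retained only with a
#' sense-strand read fraction of at least `min_ratio` in at least one
#' sample (DNA-contamination screen; transcripts with no strand counts in
#' any sample are removed); (3) monoexonic transcripts shorter than
#' `min_len` nt are removed. Multi-exonic transcripts pass untouched.
#'
#' @param candidates Exon table.
#' @param strand_counts Tibble `transcript_id`, `condition`, `sense_reads`,
#'   `antisense_reads`.
#' @param min_ratio Inclusive sense-fraction threshold (default 0.8).
#' @param min_len Monoexonic length threshold, exclusive of `min_len`
#'   itself (default 500: a 499-nt monoexonic transcript is removed, a
#'   500-nt one retained).
#' @param conditions Samples entering the ratio test (default: all present;
#'   the cascade passes the non-nuclear conditions).
#' @return A stage result list.
#' @export
filter_monoexonic <- function(candidates, strand_counts, min_ratio = 0.8,
                              min_len = 500, conditions = NULL) {
  ti <- tx_info(candidates)
  mono <- ti %>% filter(.data$n_exons == 1)
  reasons <- character()

  unstranded <- mono$transcript_id[mono$strand == "."]
  reasons[unstranded] <- "ambiguous_unstranded"
  left <- mono %>% filter(!.data$transcript_id %in% unstranded)

  sc <- strand_counts
  if (!is.null(conditions)) sc <- sc %>%
      filter(.data$condition %in% conditions)
  rt <- sc %>%
    filter(.data$sense_reads + .data$antisense_reads > 0) %>%
    mutate(ratio = .data$sense_reads /
             (.data$sense_reads + .data$antisense_reads)) %>%
    group_by(.data$transcript_id) %>%
    summarise(max_ratio = max(.data$ratio), .groups = "drop")
  left <- left %>% left_join(rt, by = "transcript_id")
  no_sup <- left$transcript_id[is.na(left$max_ratio)]
  low <- left$transcript_id[!is.na(left$max_ratio) &
                              left$max_ratio < min_ratio]
  reasons[no_sup] <- "no_strand_support"
  reasons[low] <- "strand_ratio"
  left <- left %>% filter(!.data$transcript_id %in% c(no_sup, low))

  short <- left$transcript_id[left$length < min_len]
  reasons[short] <- "short_monoexonic"

  stage_result("monoexonic", candidates, names(reasons),
               as.list(reasons))
}

#' Blacklisted chromosomes and minimum length
#'
#' Removes transcripts on unplaced/mitochondrial scaffolds and transcripts
#' with exonic length below 200 nt.
#'
#' @param candidates Exon table.
#' @param blacklist_chroms Chromosome names to drop.
#' @param min_len Minimum exonic length (inclusive; 200-nt retained).
#' @return A stage result list.
#' @export
filter_basic <- function(candidates, blacklist_chroms = c("U", "Uextra",
                                                          "M"),
                         min_len = 200) {
  ti <- tx_info(candidates)
  reasons <- character()
  bl <- ti$transcript_id[ti$chrom %in% blacklist_chroms]
  reasons[bl] <- "blacklist_chrom"
  short <- ti$transcript_id[!ti$transcript_id %in% bl &
                              ti$length < min_len]
  reasons[short] <- "too_short"
  stage_result("basic", candidates, names(reasons), as.list(reasons))
}

#' Minimum expression filter
#'
#' Retains genes reaching `min_fpkm` (inclusive) in at least one condition.
#'
#' @param candidates Exon table.
#' @param expr Gene-level (default) or transcript-level expression table.
#' @param min_fpkm FPKM threshold (default 2).
#' @param conditions Conditions considered (default all columns).
#' @param level `"gene"` or `"transcript"`.
#' @return A stage result list; features missing from `expr` are removed
#'   with reason `no_expression_record`.
#' @export
filter_expression <- function(candidates, expr, min_fpkm = 2,
                              conditions = NULL, level = "gene") {
  ti <- tx_info(candidates)
  conds <- conditions %||% expr_conditions(expr)
  m <- expr_matrix(expr, conds)
  mx <- apply(m, 1, max)
  if (level == "gene") {
    ids <- ti$gene_id
  } else {
    ids <- ti$transcript_id
  }
  mmax <- mx[ids]
  reasons <- character()
  missing <- ti$transcript_id[is.na(mmax)]
  lowex <- ti$transcript_id[!is.na(mmax) & mmax < min_fpkm]
  reasons[missing] <- "no_expression_record"
  reasons[lowex] <- "low_expression"
  stage_result("expression", candidates, names(reasons), as.list(reasons))
}

# exact masked exonic fraction per transcript
masked_fraction <- function(candidates, mask) {
  ti <- tx_info(candidates)
  if (nrow(mask) == 0) {
    return(stats::setNames(rep(0, nrow(ti)), ti$transcript_id))
  }
  mg <- GenomicRanges::reduce(GenomicRanges::GRanges(
    mask$chrom, IRanges::IRanges(mask$start, mask$end)))
  cg <- exons_granges(candidates)
  h <- find_ov(cg, mg, ignore.strand = TRUE)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(cg)[S4Vectors::queryHits(h)],
    IRanges::ranges(mg)[S4Vectors::subjectHits(h)]))
  cov <- tapply(ov, candidates$transcript_id[S4Vectors::queryHits(h)], sum)
  out <- stats::setNames(rep(0, nrow(ti)), ti$transcript_id)
  out[names(cov)] <- cov / ti$length[match(names(cov), ti$transcript_id)]
  out
}

#' Repeat/low-complexity content filter
#'
#' Removes transcripts whose exonic bases are repeat-masked for strictly
#' more than `max_frac` of their length (exactly 90% is retained).
#'
#' @param candidates Exon table.
#' @param mask Tibble of masked intervals (`chrom`, `start`, `end`).
#' @param max_frac Strict masked-fraction threshold (default 0.9).
#' @return A stage result list.
#' @export
filter_repeats <- function(candidates, mask, max_frac = 0.9) {
  frac <- masked_fraction(candidates, mask)
  bad <- names(frac)[frac > max_frac]
  stage_result("repeats", candidates, bad, list("repeat_content"))
}

#' Near-identical isoform de-duplication
#'
#' Within each gene, when a pair of isoforms has Jaccard similarity of
#' exonic bases strictly above `max_jaccard`, the smaller isoform is
#' removed (descending length, id tie-break; among three mutually
#' near-identical isoforms only the longest survives).
#'
#' @param candidates Exon table.
#' @param max_jaccard Strict similarity threshold (default 0.95; a pair at
#'   exactly 0.95 keeps both).
#' @return A stage result list.
#' @export
dedup_isoforms <- function(candidates, max_jaccard = 0.95) {
  ti <- tx_info(candidates)
  removed <- character()
  multi <- ti %>% group_by(.data$gene_id) %>% filter(n() > 1) %>% ungroup()
  for (g in unique(multi$gene_id)) {
    txs <- multi %>% filter(.data$gene_id == g) %>%
      arrange(desc(.data$length), .data$transcript_id)
    kept <- character()
    for (t in txs$transcript_id) {
      ex_t <- candidates %>% filter(.data$transcript_id == t)
      dup <- any(vapply(kept, function(k) {
        jaccard_similarity(ex_t, candidates %>%
                             filter(.data$transcript_id == k)) >
          max_jaccard
      }, logical(1)))
      if (dup) removed <- c(removed, t) else kept <- c(kept, t)
    }
  }
  stage_result("dedup", candidates, removed, list("redundant_isoform"))
}

#' Nuclear-enrichment ratio filter for intron-embedded monoexonic
#' transcripts
#'
#' For each monoexonic transcript fully embedded in annotated introns in
#' the same orientation (these survived the intronic filter through an
#' antisense exon overlap), the log2 ratio of nuclear over matched
#' non-nuclear FPKM (plus a 0.1 pseudo-FPKM) is computed at both time
#' points; transcripts with a ratio strictly above `log2_threshold` at
#' either time point are removed as pre-mRNA degradation leftovers.
#'
#' @param candidates,reference Exon tables.
#' @param expr_tx Transcript-level expression table containing the nuclear
#'   and matched non-nuclear conditions.
#' @param nuclear_pairs List of `c(nuclear, non_nuclear)` condition pairs.
#' @param pseudo_fpkm Pseudo-count added to both FPKM values (default 0.1).
#' @param log2_threshold Strict threshold (default 1; a ratio of exactly 2
#'   is retained).
#' @return A stage result list.
#' @export
filter_nuclear_ratio <- function(candidates, reference, expr_tx,
                                 nuclear_pairs =
                                   list(c("Nuclear_34", "Meso_34"),
                                        c("Nuclear_68", "Meso_68")),
                                 pseudo_fpkm = 0.1, log2_threshold = 1) {
  conds <- unlist(nuclear_pairs)
  missing <- setdiff(conds, expr_conditions(expr_tx))
  if (length(missing) > 0) {
    stop("nuclear-ratio filter: missing condition(s) in expression ",
         "table: ", paste(missing, collapse = ", "))
  }
  ti <- tx_info(candidates)
  emb <- embedded_transcripts(candidates, reference)
  qual <- intersect(emb, ti$transcript_id[ti$n_exons == 1])
  m <- expr_matrix(expr_tx, conds)
  bad <- character()
  for (t in qual) {
    if (!t %in% rownames(m)) next
    r <- vapply(nuclear_pairs, function(p) {
      log2((m[t, p[1]] + pseudo_fpkm) / (m[t, p[2]] + pseudo_fpkm))
    }, numeric(1))
    if (any(r > log2_threshold)) bad <- c(bad, t)
  }
  stage_result("nuclear_ratio", candidates, bad, list("nuclear_enriched"))
}

#' Flag putative read-through transcripts
#'
#' Flags candidates whose 5' end lies within `max_gap` nt downstream of
#' the 3' end of an expressed same-strand protein-coding gene. Flag-only
#' by default; set `drop = TRUE` to remove the flagged transcripts.
#'
#' @param candidates,reference Exon tables (`reference` biotype
#'   `protein_coding` rows define PCGs).
#' @param expr_gene Gene-level expression table; PCGs with maximum FPKM at
#'   or above `min_pcg_fpkm` count as expressed.
#' @param max_gap Maximum TES-to-TSS gap in nt (501 is not flagged).
#' @param min_pcg_fpkm Expression gate for the upstream PCG.
#' @param drop Remove flagged transcripts instead of only flagging.
#' @return A stage result list with an extra `flags` tibble
#'   (`transcript_id`, `upstream_pcg`, `gap`).
#' @export
flag_readthrough <- function(candidates, reference, expr_gene,
                             max_gap = 500, min_pcg_fpkm = 1,
                             drop = FALSE) {
  ti <- tx_info(candidates)
  pcg <- tx_info(reference %>% filter(.data$biotype == "protein_coding"))
  if (!is.null(expr_gene)) {
    mx <- apply(expr_matrix(expr_gene), 1, max)
    pcg <- pcg %>% filter(.data$gene_id %in%
                            names(mx)[mx >= min_pcg_fpkm])
  }
  flags <- tibble(transcript_id = character(), upstream_pcg = character(),
                  gap = integer())
  if (nrow(pcg) > 0) {
    win_start <- ifelse(pcg$strand == "+", pcg$tes, pcg$tes - max_gap)
    win_end <- ifelse(pcg$strand == "+", pcg$tes + max_gap, pcg$tes)
    wg <- GenomicRanges::GRanges(pcg$chrom,
                                 IRanges::IRanges(win_start, win_end))
    tg <- GenomicRanges::GRanges(ti$chrom,
                                 IRanges::IRanges(ti$tss, ti$tss))
    h <- find_ov(tg, wg, ignore.strand = TRUE)
    same <- ti$strand[S4Vectors::queryHits(h)] ==
      pcg$strand[S4Vectors::subjectHits(h)]
    h <- h[same]
    if (length(h) > 0) {
      flags <- tibble(
        transcript_id = ti$transcript_id[S4Vectors::queryHits(h)],
        upstream_pcg = pcg$gene_id[S4Vectors::subjectHits(h)],
        gap = abs(ti$tss[S4Vectors::queryHits(h)] -
                    pcg$tes[S4Vectors::subjectHits(h)])
      ) %>%
        group_by(.data$transcript_id) %>%
        arrange(.data$gap, .by_group = TRUE) %>% slice(1) %>% ungroup()
    }
  }
  res <- stage_result("readthrough", candidates,
                      if (drop) flags$transcript_id else character(),
                      list("readthrough"))
  res$flags <- flags
  res
}

#' Partition retained genes into main (DE) and constitutive sets
#'
#' A gene joins the main set when its BH-adjusted p-value is below `alpha`
#' in at least one comparison of the DE table; otherwise it becomes
#' constitutive when its maximum FPKM is at or above `min_fpkm_const` and,
#' for the constitutive set only, transcripts fully embedded in annotated
#' introns on the same strand are discarded. Everything else is dropped.
#'
#' @param candidates,reference Exon tables.
#' @param de DE table (`comparison`, `gene_id`, `log2fc`, `padj`).
#' @param expr_gene Gene-level expression table.
#' @param alpha Adjusted-p threshold (strict, default 0.01).
#' @param min_fpkm_const Inclusive constitutive FPKM floor (default 3).
#' @param conditions Conditions entering the FPKM maximum (default all).
#' @return List: `main_genes`, `constitutive_genes`, `retained` exon table,
#'   `removed` tibble, `stage`.
#' @export
partition_by_de <- function(candidates, reference, de, expr_gene,
                            alpha = 0.01, min_fpkm_const = 3,
                            conditions = NULL) {
  ti <- tx_info(candidates)
  genes <- unique(ti$gene_id)
  sig <- de %>% filter(.data$padj < alpha) %>% pull("gene_id") %>% unique()
  main <- intersect(genes, sig)
  rest <- setdiff(genes, main)
  conds <- conditions %||% expr_conditions(expr_gene)
  mx <- apply(expr_matrix(expr_gene, conds), 1, max)
  high <- rest[!is.na(mx[rest]) & mx[rest] >= min_fpkm_const]
  low <- setdiff(rest, high)
  emb <- embedded_transcripts(candidates, reference)

  reasons <- character()
  drop_tx <- ti$transcript_id[ti$gene_id %in% low]
  reasons[drop_tx] <- "not_de_low_fpkm"
  emb_tx <- intersect(emb, ti$transcript_id[ti$gene_id %in% high])
  reasons[emb_tx] <- "constitutive_intron_embedded"
  res <- stage_result("de_partition", candidates, names(reasons),
                      as.list(reasons))
  kept <- tx_info(res$retained)
  res$main_genes <- intersect(main, kept$gene_id)
  res$constitutive_genes <- intersect(high, kept$gene_id)
  res
}

#' Refine one transcript's TSS against CAGE evidence
#'
#' Searches same-strand CAGE positions with at least `min_tags` tags inside
#' the window from `max_upstream` nt upstream of the annotated TSS to
#' `max_inward_frac` of the transcript length inward (truncated at the
#' first exon's inner boundary so the refined first exon is never empty and
#' never crosses the first intron), and moves the TSS to the qualifying
#' peak closest to the original TSS (upstream wins ties). Unchanged when no
#' peak qualifies.
#'
#' @param tx_exons Exon table of a single transcript.
#' @param cage Tibble `chrom`, `pos`, `strand`, `count`.
#' @param min_tags Minimum tag count (inclusive; 49 tags never move a TSS).
#' @param max_upstream Maximum upstream extension in nt (default 800).
#' @param max_inward_frac Maximum inward clipping as a fraction of
#'   transcript length (default 0.3).
#' @return List: `exons` (adjusted exon table) and `record` (one-row
#'   tibble: `transcript_id`, `old_tss`, `new_tss`, `direction` in
#'   clipped/extended/unchanged, `nt_moved`).
#' @export
refine_tss <- function(tx_exons, cage, min_tags = 50, max_upstream = 800,
                       max_inward_frac = 0.3) {
  ex <- arrange(tx_exons, .data$start)
  plus <- ex$strand[1] == "+"
  L <- sum(ex$end - ex$start + 1)
  inward <- floor(max_inward_frac * L)
  if (plus) {
    tss <- ex$start[1]
    lo <- tss - max_upstream
    hi <- min(tss + inward, ex$end[1] - 1L)
  } else {
    tss <- ex$end[nrow(ex)]
    hi <- tss + max_upstream
    lo <- max(tss - inward, ex$start[nrow(ex)] + 1L)
  }
  peaks <- cage %>%
    filter(.data$chrom == ex$chrom[1], .data$strand == ex$strand[1],
           .data$count >= min_tags, .data$pos >= lo, .data$pos <= hi)
  rec <- tibble(transcript_id = ex$transcript_id[1], old_tss = tss,
                new_tss = tss, direction = "unchanged", nt_moved = 0L)
  if (nrow(peaks) == 0) return(list(exons = tx_exons, record = rec))
  peaks <- peaks %>%
    mutate(dist = abs(.data$pos - tss),
           upstream = if (plus) .data$pos < tss else .data$pos > tss) %>%
    arrange(.data$dist, desc(.data$upstream))
  new_tss <- peaks$pos[1]
  if (new_tss == tss) return(list(exons = tx_exons, record = rec))
  if (plus) ex$start[1] <- new_tss else ex$end[nrow(ex)] <- new_tss
  rec$new_tss <- new_tss
  rec$direction <- if (peaks$upstream[1]) "extended" else "clipped"
  rec$nt_moved <- abs(new_tss - tss)
  list(exons = ex, record = rec)
}

#' Cascade threshold configuration
#'
#' All cascade thresholds in one place, with the published defaults:
#' strand ratio 0.8 (inclusive), monoexonic length 500 (strict below),
#' overall length 200, expression 2 FPKM (inclusive), repeat fraction 0.90
#' (strict above), isoform Jaccard 0.95 (strict above), nuclear log2 ratio
#' 1 (strict above) with pseudo-FPKM 0.1, DE alpha 0.01 (strict below),
#' constitutive FPKM 3 (inclusive), read-through gap 500, CAGE support 50
#' tags within 800 nt upstream / 30% of length inward.
#'
#' @param ... Overrides for any default listed above.
#' @return A named list of thresholds.
#' @export
cascade_config <- function(...) {
  cfg <- list(
    blacklist_chroms = c("U", "Uextra", "M"),
    min_len = 200, min_mono_len = 500, min_strand_ratio = 0.8,
    min_fpkm = 2, max_repeat_frac = 0.9, max_jaccard = 0.95,
    nuclear_pairs = list(c("Nuclear_34", "Meso_34"),
                         c("Nuclear_68", "Meso_68")),
    pseudo_fpkm = 0.1, nuclear_log2 = 1,
    readthrough_gap = 500, readthrough_min_fpkm = 1,
    drop_readthrough = FALSE,
    de_alpha = 0.01, min_fpkm_const = 3,
    cage_min_tags = 50, tss_max_upstream = 800, tss_max_inward_frac = 0.3,
    refine_tss = TRUE,
    expression_conditions = sim_conditions()$non_nuclear,
    expression_level = "gene"
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown cascade config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  cfg
}

#' Run the full discovery cascade on an input bundle
#'
#' Applies the stages in the fixed published order (annotated overlap,
#' intronic, monoexonic rules, blacklist/length, expression, repeats,
#' isoform de-duplication, nuclear ratio, read-through flagging, DE
#' partition), merges the main and constitutive sets into the HQ
#' catalogue, and refines HQ TSSs against CAGE.
#'
#' @param bundle List with `candidates`, `reference`, `expr_tx` (and/or
#'   `expr_gene`), `strand_counts`, `repeats`, `de`, `cage` (see
#'   [simulate_bundle()]).
#' @param config A [cascade_config()].
#' @return List: `hq` exon table, `report` (stage/input/retained/removed
#'   counts), `removed` (per-transcript reasons), `main_genes`,
#'   `constitutive_genes`, `readthrough_flags`, `tss_records`.
#' @export
run_cascade <- function(bundle, config = cascade_config()) {
  needed <- c("candidates", "reference", "strand_counts", "repeats", "de")
  for (n in needed) {
    if (is.null(bundle[[n]])) stop("cascade input missing for stage ",
                                   "requiring '", n, "'")
  }
  if (is.null(bundle$expr_tx) && is.null(bundle$expr_gene)) {
    stop("cascade input missing for stage 'expression': no expression ",
         "table in bundle")
  }
  expr_tx <- bundle$expr_tx
  expr_gene <- bundle$expr_gene
  if (is.null(expr_gene)) {
    expr_gene <- expr_to_gene_level(
      expr_tx, tx_info(bundle$candidates)[, c("transcript_id", "gene_id")])
  }
  cfg <- config
  cur <- bundle$candidates
  report <- list(); removed <- list()
  note <- function(res) {
    report[[length(report) + 1]] <<- tibble(
      stage = res$stage,
      n_input = length(unique(cur$transcript_id)),
      n_retained = length(unique(res$retained$transcript_id)),
      n_removed = nrow(res$removed))
    removed[[length(removed) + 1]] <<- res$removed
    cur <<- res$retained
    res
  }

  note(filter_annotated_overlap(cur, bundle$reference))
  note(filter_intronic(cur, bundle$reference))
  note(filter_monoexonic(cur, bundle$strand_counts,
                         min_ratio = cfg$min_strand_ratio,
                         min_len = cfg$min_mono_len,
                         conditions = cfg$expression_conditions))
  note(filter_basic(cur, cfg$blacklist_chroms, cfg$min_len))
  expr_for_filter <- if (cfg$expression_level == "gene") expr_gene else
    expr_tx
  note(filter_expression(cur, expr_for_filter, cfg$min_fpkm,
                         conditions = intersect(
                           cfg$expression_conditions,
                           expr_conditions(expr_for_filter)),
                         level = cfg$expression_level))
  note(filter_repeats(cur, bundle$repeats, cfg$max_repeat_frac))
  note(dedup_isoforms(cur, cfg$max_jaccard))
  if (!is.null(expr_tx)) {
    note(filter_nuclear_ratio(cur, bundle$reference, expr_tx,
                              cfg$nuclear_pairs, cfg$pseudo_fpkm,
                              cfg$nuclear_log2))
  }
  rt <- note(flag_readthrough(cur, bundle$reference, expr_gene,
                              cfg$readthrough_gap,
                              cfg$readthrough_min_fpkm,
                              cfg$drop_readthrough))
  part <- note(partition_by_de(cur, bundle$reference, bundle$de, expr_gene,
                               cfg$de_alpha, cfg$min_fpkm_const,
                               conditions = intersect(
                                 cfg$expression_conditions,
                                 expr_conditions(expr_gene))))

  hq <- cur
  tss_records <- tibble(transcript_id = character(), old_tss = integer(),
                        new_tss = integer(), direction = character(),
                        nt_moved = integer())
  if (isTRUE(cfg$refine_tss) && !is.null(bundle$cage) && nrow(hq) > 0) {
    refined <- list(); recs <- list()
    for (t in unique(hq$transcript_id)) {
      r <- refine_tss(hq %>% filter(.data$transcript_id == t),
                      bundle$cage, cfg$cage_min_tags,
                      cfg$tss_max_upstream, cfg$tss_max_inward_frac)
      refined[[length(refined) + 1]] <- r$exons
      recs[[length(recs) + 1]] <- r$record
    }
    hq <- as_exon_tbl(bind_rows(refined))
    tss_records <- bind_rows(recs)
  }

  list(
    hq = hq,
    report = bind_rows(report),
    removed = bind_rows(removed),
    main_genes = part$main_genes,
    constitutive_genes = part$constitutive_genes,
    readthrough_flags = rt$flags,
    tss_records = tss_records
  )
}
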