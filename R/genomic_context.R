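# Genomic-context classification, TSS de-duplication, lncRNA-PCG pair
# sets and correlation-versus-random-background analysis.

context_levels <- c("TSS", "TES", "exon", "intron", "promoter",
                    "enhancer", "intergenic")

#' Filter genes by an expression gate
#'
#' @param expr Gene-level expression table.
#' @param min_fpkm Inclusive FPKM threshold (default 1, the gate used to
#'   call a reference PCG "expressed").
#' @return Character vector of gene ids reaching the threshold in at least
#'   one condition.
#' @export
expressed_genes <- function(expr, min_fpkm = 1) {
  mx <- apply(expr_matrix(expr), 1, max)
  names(mx)[mx >= min_fpkm]
}

#' Mutually exclusive genomic-context classification of lncRNA genes
#'
#' Assigns each lncRNA gene the first matching class in the fixed
#' hierarchy TSS > TES > exon > intron > promoter > enhancer > intergenic,
#' testing the gene's exonic bases (or its span when `use_span = TRUE`)
#' strand-blind against features of the reference protein-coding genes:
#' TSS and TES points, exons, introns, the 1-kb upstream promoter window,
#' and the enhancer track.
#'
#' @param lncs Exon table of lncRNA genes to classify.
#' @param reference Exon table of (expressed) protein-coding genes.
#' @param enhancers Optional tibble `chrom`, `start`, `end`.
#' @param promoter_len Promoter window upstream of each TSS (default 1000).
#' @param use_span Classify on gene spans instead of exonic bases.
#' @return Tibble `gene_id`, `context` (factor with the hierarchy levels).
#' @export
classify_context <- function(lncs, reference, enhancers = NULL,
                             promoter_len = 1000, use_span = FALSE) {
  ref_tx <- tx_info(reference)
  feat <- function(chrom, start, end) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pmax(1L, start), end))
  }
  intr <- introns_tbl(reference)
  prom_start <- ifelse(ref_tx$strand == "+", ref_tx$tss - promoter_len,
                       ref_tx$tss + 1L)
  prom_end <- ifelse(ref_tx$strand == "+", ref_tx$tss - 1L,
                     ref_tx$tss + promoter_len)
  features <- list(
    TSS = feat(ref_tx$chrom, ref_tx$tss, ref_tx$tss),
    TES = feat(ref_tx$chrom, ref_tx$tes, ref_tx$tes),
    exon = feat(reference$chrom, reference$start, reference$end),
    intron = if (nrow(intr) > 0) feat(intr$chrom, intr$start, intr$end)
    else GenomicRanges::GRanges(),
    promoter = feat(ref_tx$chrom, prom_start, prom_end),
    enhancer = if (!is.null(enhancers) && nrow(enhancers) > 0)
      feat(enhancers$chrom, enhancers$start, enhancers$end)
    else GenomicRanges::GRanges()
  )
  if (use_span) {
    gi <- gene_info(lncs)
    qg <- feat(gi$chrom, gi$start, gi$end)
    qid <- gi$gene_id
  } else {
    qg <- feat(lncs$chrom, lncs$start, lncs$end)
    qid <- lncs$gene_id
  }
  genes <- unique(lncs$gene_id)
  label <- stats::setNames(rep("intergenic", length(genes)), genes)
  assigned <- character()
  for (cls in names(features)) {
    if (length(features[[cls]]) == 0) next
    h <- find_ov(qg, features[[cls]],
                                     ignore.strand = TRUE)
    hit <- setdiff(unique(qid[S4Vectors::queryHits(h)]), assigned)
    label[hit] <- cls
    assigned <- c(assigned, hit)
  }
  tibble(gene_id = genes,
         context = factor(unname(label[genes]), levels = context_levels))
}

#' Collapse near-identical isoform TSSs to one representative per gene
#'
#' TSSs lying within `window` nt of an already kept TSS are collapsed to
#' the TSS of the highest-FPKM isoform (maximum FPKM over conditions).
#'
#' @param exons Exon table (possibly many genes).
#' @param expr_tx Transcript-level expression table.
#' @param window Collapse distance in nt (inclusive; TSSs 60 nt apart with
#'   a 50-nt window are both kept).
#' @return Tibble `gene_id`, `transcript_id`, `tss` of representatives.
#' @export
dedup_tss <- function(exons, expr_tx, window = 50) {
  ti <- tx_info(exons)
  mx <- apply(expr_matrix(expr_tx), 1, max)
  ti$fpkm <- unname(mx[ti$transcript_id])
  ti$fpkm[is.na(ti$fpkm)] <- 0
  out <- list()
  for (g in unique(ti$gene_id)) {
    txs <- ti %>% filter(.data$gene_id == g) %>%
      arrange(desc(.data$fpkm), .data$transcript_id)
    kept <- txs[0, ]
    for (i in seq_len(nrow(txs))) {
      if (nrow(kept) == 0 ||
          all(abs(kept$tss - txs$tss[i]) > window)) {
        kept <- bind_rows(kept, txs[i, ])
      }
    }
    out[[length(out) + 1]] <- kept
  }
  bind_rows(out) %>% select("gene_id", "transcript_id", "tss")
}

# per-chromosome span distance between two gene-info tables; returns for
# each query row the closest subject row (ties: lower start, then id)
closest_by_span <- function(q, s, overlap = c("allow", "exclude")) {
  overlap <- match.arg(overlap)
  out <- vector("list", nrow(q))
  for (i in seq_len(nrow(q))) {
    cand <- s %>% filter(.data$chrom == q$chrom[i],
                         .data$gene_id != q$gene_id[i])
    if (nrow(cand) == 0) next
    d <- pmax(0L, cand$start - q$end[i], q$start[i] - cand$end)
    cand$distance <- d
    if (overlap == "exclude") cand <- cand %>% filter(.data$distance > 0)
    if (nrow(cand) == 0) next
    best <- cand %>% arrange(.data$distance, .data$start, .data$gene_id) %>%
      slice(1)
    sign <- if (best$distance == 0) 0L else
      if (best$start > q$end[i]) 1L else -1L
    out[[i]] <- tibble(lnc_gene = q$gene_id[i], pcg_gene = best$gene_id,
                       distance = sign * best$distance)
  }
  bind_rows(out)
}

#' Build the five positional lncRNA-PCG pair sets
#'
#' Categories: closest PCG overlapping or not (`closest_any`), closest
#' non-overlapping PCG (`closest_nonoverlap`), lncRNA exons covering a PCG
#' TSS antisense (`antisense_TSS`), exon-exon antisense overlap
#' (`antisense_exon`), and lncRNA over a PCG promoter without touching the
#' coding gene itself (`promoter_overlap`). Longest isoforms represent each
#' gene; within the overlap categories redundancy is removed by keeping the
#' longest mRNA per lncRNA and the longest lncRNA per PCG, so every lncRNA
#' appears at most once per category.
#'
#' @param lncs,pcgs Exon tables.
#' @param promoter_len Promoter window (default 1000).
#' @return Tibble `lnc_gene`, `pcg_gene`, `category`, `distance` (signed;
#'   positive when the PCG lies downstream in genomic coordinates).
#' @export
build_pair_sets <- function(lncs, pcgs, promoter_len = 1000) {
  if (nrow(lncs) == 0 || nrow(pcgs) == 0) {
    stop("both lncRNA and PCG sets must be non-empty")
  }
  li <- longest_isoforms(lncs)
  pi <- longest_isoforms(pcgs)
  gl <- gene_info(li); gp <- gene_info(pi)
  ptx <- tx_info(pi)

  p1 <- closest_by_span(gl, gp, "allow") %>%
    mutate(category = "closest_any")
  p2 <- closest_by_span(gl, gp, "exclude") %>%
    mutate(category = "closest_nonoverlap")

  dedup_longest <- function(pairs) {
    pairs %>%
      left_join(select(gp, pcg_gene = "gene_id",
                       pcg_len = "longest_length"), by = "pcg_gene") %>%
      left_join(select(gl, lnc_gene = "gene_id",
                       lnc_len = "longest_length"), by = "lnc_gene") %>%
      group_by(.data$lnc_gene) %>%
      arrange(desc(.data$pcg_len), .data$pcg_gene, .by_group = TRUE) %>%
      slice(1) %>% ungroup() %>%
      group_by(.data$pcg_gene) %>%
      arrange(desc(.data$lnc_len), .data$lnc_gene, .by_group = TRUE) %>%
      slice(1) %>% ungroup() %>%
      select(-"pcg_len", -"lnc_len")
  }
  anti_pairs <- function(subject_gr, subject_gene) {
    lg <- exons_granges(li)
    h <- find_ov(lg, subject_gr, ignore.strand = TRUE)
    sa <- li$strand[S4Vectors::queryHits(h)]
    sb <- as.character(GenomicRanges::strand(subject_gr))[
      S4Vectors::subjectHits(h)]
    h <- h[(sa == "+" & sb == "-") | (sa == "-" & sb == "+")]
    tibble(lnc_gene = li$gene_id[S4Vectors::queryHits(h)],
           pcg_gene = subject_gene[S4Vectors::subjectHits(h)]) %>%
      distinct()
  }

  tss_gr <- GenomicRanges::GRanges(ptx$chrom,
                                   IRanges::IRanges(ptx$tss, ptx$tss),
                                   strand = ptx$strand)
  p3 <- anti_pairs(tss_gr, ptx$gene_id) %>% dedup_longest() %>%
    mutate(category = "antisense_TSS")

  ex_gr <- exons_granges(pi)
  p4 <- anti_pairs(ex_gr, pi$gene_id) %>% dedup_longest() %>%
    mutate(category = "antisense_exon")

  prom_start <- ifelse(ptx$strand == "+", ptx$tss - promoter_len,
                       ptx$tss + 1L)
  prom_end <- ifelse(ptx$strand == "+", ptx$tss - 1L,
                     ptx$tss + promoter_len)
  prom_gr <- GenomicRanges::GRanges(
    ptx$chrom, IRanges::IRanges(pmax(1L, prom_start), prom_end))
  lg <- exons_granges(li)
  hp <- find_ov(lg, prom_gr, ignore.strand = TRUE)
  # exclude lncRNAs overlapping the coding gene itself (strand-blind)
  hx <- find_ov(lg, ex_gr, ignore.strand = TRUE)
  ov_lnc <- unique(li$gene_id[S4Vectors::queryHits(hx)])
  p5 <- tibble(lnc_gene = li$gene_id[S4Vectors::queryHits(hp)],
               pcg_gene = ptx$gene_id[S4Vectors::subjectHits(hp)]) %>%
    filter(!.data$lnc_gene %in% ov_lnc) %>%
    distinct() %>% dedup_longest() %>%
    mutate(category = "promoter_overlap")

  sgn_dist <- function(pairs) {
    ql <- gl[match(pairs$lnc_gene, gl$gene_id), ]
    qp <- gp[match(pairs$pcg_gene, gp$gene_id), ]
    d <- pmax(0L, qp$start - ql$end, ql$start - qp$end)
    sgn <- ifelse(d == 0, 0L, ifelse(qp$start > ql$end, 1L, -1L))
    pairs$distance <- sgn * d
    pairs
  }
  bind_rows(p1, p2, sgn_dist(p3), sgn_dist(p4), sgn_dist(p5)) %>%
    select("lnc_gene", "pcg_gene", "category", "distance")
}

#' Random lncRNA-PCG background pairs
#'
#' `n_sets` uniform random assignments of every lncRNA to a PCG,
#' concatenated (349 lncRNAs and 1000 sets give 349,000 pairs).
#'
#' @param lnc_genes,pcg_genes Character vectors of gene ids.
#' @param n_sets Number of random sets (default 1000).
#' @param seed Integer seed.
#' @return Tibble `lnc_gene`, `pcg_gene`, `category = "random"`, `set`.
#' @export
random_pairs <- function(lnc_genes, pcg_genes, n_sets = 1000, seed = 1) {
  set.seed(seed)
  if (n_sets == 0) {
    return(tibble(lnc_gene = character(), pcg_gene = character(),
                  category = character(), set = integer()))
  }
  n <- length(lnc_genes)
  tibble(
    lnc_gene = rep(lnc_genes, n_sets),
    pcg_gene = sample(pcg_genes, n * n_sets, replace = TRUE),
    category = "random",
    set = rep(seq_len(n_sets), each = n)
  )
}

#' Pearson correlation of paired expression profiles
#'
#' Computes the per-pair Pearson correlation of gene FPKM over the named
#' experimental conditions. Pairs with a zero-variance member are excluded
#' and counted in the `n_excluded` attribute.
#'
#' @param pairs Tibble with `lnc_gene`, `pcg_gene` (and optionally
#'   `category`).
#' @param expr Gene-level expression table.
#' @param conditions Conditions forming the profile vector (>= 3).
#' @return `pairs` with an added `r` column (zero-variance pairs removed);
#'   attribute `n_excluded`.
#' @export
pair_correlations <- function(pairs, expr,
                              conditions = c("Meso_34", "Meso_46",
                                             "Meso_68", "Nuclear_34",
                                             "WE_34", "WE_46", "WE_68")) {
  if (length(conditions) < 3) stop("need at least 3 conditions")
  m <- expr_matrix(expr, conditions)
  keep <- pairs$lnc_gene %in% rownames(m) & pairs$pcg_gene %in% rownames(m)
  pairs <- pairs[keep, ]
  x <- m[pairs$lnc_gene, , drop = FALSE]
  y <- m[pairs$pcg_gene, , drop = FALSE]
  r <- row_pearson(x, y)
  ok <- !is.na(r)
  out <- pairs[ok, ]
  out$r <- r[ok]
  attr(out, "n_excluded") <- sum(!ok) + sum(!keep)
  out
}

# row-wise Pearson correlation of two matrices (NA when a row has zero
# variance)
row_pearson <- function(x, y) {
  cx <- x - rowMeans(x)
  cy <- y - rowMeans(y)
  sx <- sqrt(rowSums(cx^2))
  sy <- sqrt(rowSums(cy^2))
  r <- rowSums(cx * cy) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  unname(r)
}

#' Wilcoxon rank-sum comparison of a pair category against the random
#' background
#'
#' @param category_r Correlations of a real pair category.
#' @param random_r Correlations of the random background.
#' @param alternative Passed to [stats::wilcox.test()] (default
#'   two-sided).
#' @return List: `statistic`, `p_value`, medians of both samples.
#' @export
compare_category_to_background <- function(category_r, random_r,
                                           alternative = "two.sided") {
  if (length(category_r) < 5 || length(random_r) < 5) {
    stop("degenerate input: need at least 5 values per sample")
  }
  wt <- stats::wilcox.test(category_r, random_r,
                           alternative = alternative, exact = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_category = stats::median(category_r),
       median_random = stats::median(random_r))
}
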