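# Expression clustering, divergent promoter transcription, nuclear
# enrichment and strain-specific expression.

#' Iterative k-means clustering of expression profiles
#'
#' Two-round procedure: an initial k-means with `k1` centres, removal of
#' members farther than `outlier1` from their centroid (Euclidean distance
#' in the full rotation-only principal-component space, which preserves
#' distances) and of singleton clusters; a second k-means with `k2`
#' centres on the survivors, removal at `outlier2` and of clusters with
#' fewer than two members; and a final pruning of genes whose Pearson
#' correlation with their cluster's per-condition median profile is not
#' strictly above `min_corr`.
#'
#' @param expr Gene-level expression table or plain matrix
#'   (genes x conditions).
#' @param k1,outlier1 First-round centre count and distance cut-off
#'   (defaults 9 and 20).
#' @param k2,outlier2 Second-round centre count and distance cut-off
#'   (defaults 5 and 1.5).
#' @param min_corr Final profile-correlation threshold (default 0.905,
#'   strict: a gene at exactly 0.905 is removed).
#' @param seed Integer seed (k-means uses 50 restarts).
#' @param scale `"zscore"` (default) scales each gene's profile to mean 0,
#'   sd 1 before clustering; `"raw"` clusters FPKM directly.
#' @return List: `assignments` (tibble `gene_id`, `cluster`, `dist`,
#'   `corr`; pruned genes are absent), `centroids`, `medians`
#'   (per-cluster per-condition median profiles), `history` (per-step
#'   retained counts).
#' @export
iterative_kmeans <- function(expr, k1 = 9, outlier1 = 20, k2 = 5,
                             outlier2 = 1.5, min_corr = 0.905, seed = 1,
                             scale = c("zscore", "raw")) {
  scale <- match.arg(scale)
  m <- if (is.matrix(expr)) expr else expr_matrix(expr)
  if (nrow(m) < k1) stop("fewer genes (", nrow(m), ") than k1 = ", k1)
  keep <- apply(m, 1, stats::sd) > 0
  m <- m[keep, , drop = FALSE]
  z <- if (scale == "zscore") t(base::scale(t(m))) else m
  history <- list()
  note <- function(step) {
    history[[length(history) + 1]] <<- tibble(step = step,
                                              n_genes = nrow(z))
  }
  note("input")

  set.seed(seed)
  km1 <- stats::kmeans(z, centers = k1, nstart = 50, iter.max = 100)
  d1 <- sqrt(rowSums((z - km1$centers[km1$cluster, , drop = FALSE])^2))
  sizes <- table(km1$cluster)
  ok <- d1 <= outlier1 & km1$cluster %in%
    as.integer(names(sizes)[sizes > 1])
  z <- z[ok, , drop = FALSE]
  note("round1_pruned")
  if (nrow(z) < k2) stop("fewer genes than k2 after round-1 pruning")

  km2 <- stats::kmeans(z, centers = k2, nstart = 50, iter.max = 100)
  d2 <- sqrt(rowSums((z - km2$centers[km2$cluster, , drop = FALSE])^2))
  sizes <- table(km2$cluster)
  ok <- d2 <= outlier2 & km2$cluster %in%
    as.integer(names(sizes)[sizes >= 2])
  cl <- km2$cluster[ok]
  z2 <- z[ok, , drop = FALSE]
  d2 <- d2[ok]
  note2 <- tibble(step = "round2_pruned", n_genes = nrow(z2))
  history[[length(history) + 1]] <- note2

  med <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    apply(z2[cl == k, , drop = FALSE], 2, stats::median)
  }))
  rownames(med) <- sort(unique(cl))
  corr <- vapply(seq_len(nrow(z2)), function(i) {
    stats::cor(z2[i, ], med[as.character(cl[i]), ])
  }, numeric(1))
  ok <- corr > min_corr
  assignments <- tibble(gene_id = rownames(z2)[ok],
                        cluster = as.integer(cl[ok]),
                        dist = d2[ok], corr = corr[ok])
  # drop clusters reduced below two members by the correlation pruning
  sizes <- table(assignments$cluster)
  assignments <- assignments %>%
    filter(.data$cluster %in% as.integer(names(sizes)[sizes >= 2]))
  history[[length(history) + 1]] <- tibble(step = "correlation_pruned",
                                           n_genes = nrow(assignments))
  list(assignments = assignments, centroids = km2$centers, medians = med,
       history = bind_rows(history))
}

#' Divergent-transcription profiles around PCG promoters
#'
#' Bins stranded read counts in 10-nt windows across +/- 1 kb of each TSS,
#' orientation-normalised so that upstream-antisense signal is always on
#' the left (bins 1..100) regardless of the gene's genomic strand, ranks
#' promoters by summed upstream antisense signal and assigns terciles.
#'
#' @param tss Tibble `gene_id`, `chrom`, `tss`, `strand`.
#' @param coverage Tibble of per-base stranded read counts: `chrom`,
#'   `pos`, `strand`, `count`.
#' @param bin_size Bin width in nt (default 10).
#' @param half_window Half-window around the TSS (default 1000; 200 bins).
#' @param upstream_rank_window Upstream span (nt, from the TSS) whose
#'   antisense signal ranks the promoters (default 1000).
#' @return List: `sense` and `antisense` count matrices
#'   (genes x 2*half_window/bin_size bins), `ranking` tibble (`gene_id`,
#'   `upstream_antisense`, `rank`, `tercile` in top/middle/bottom,
#'   `edge_flag`).
#' @export
divergent_profiles <- function(tss, coverage, bin_size = 10,
                               half_window = 1000,
                               upstream_rank_window = 1000) {
  n_bins <- 2L * half_window / bin_size
  sense <- matrix(0L, nrow(tss), n_bins,
                  dimnames = list(tss$gene_id, NULL))
  anti <- matrix(0L, nrow(tss), n_bins,
                 dimnames = list(tss$gene_id, NULL))
  for (i in seq_len(nrow(tss))) {
    win <- coverage %>%
      filter(.data$chrom == tss$chrom[i],
             abs(.data$pos - tss$tss[i]) <= half_window)
    if (nrow(win) == 0) next
    plus <- tss$strand[i] == "+"
    off <- if (plus) win$pos - tss$tss[i] else tss$tss[i] - win$pos
    keep <- off >= -half_window & off < half_window
    win <- win[keep, ]; off <- off[keep]
    bin <- floor((off + half_window) / bin_size) + 1L
    is_sense <- win$strand == tss$strand[i]
    for (j in which(is_sense)) {
      sense[i, bin[j]] <- sense[i, bin[j]] + win$count[j]
    }
    for (j in which(!is_sense)) {
      anti[i, bin[j]] <- anti[i, bin[j]] + win$count[j]
    }
  }
  up_bins <- seq_len(upstream_rank_window / bin_size)
  up_anti <- rowSums(anti[, up_bins, drop = FALSE])
  ranking <- tibble(
    gene_id = tss$gene_id,
    upstream_antisense = up_anti,
    edge_flag = tss$tss <= half_window
  ) %>%
    mutate(rank = rank(-.data$upstream_antisense, ties.method = "first"),
           tercile = c("top", "middle", "bottom")[
             dplyr::ntile(.data$rank, 3)])
  list(sense = sense, antisense = anti, ranking = ranking)
}

#' Compare expression of top versus bottom divergence terciles
#'
#' @param ranking The `ranking` tibble from [divergent_profiles()].
#' @param fpkm Named numeric vector of gene expression.
#' @return List: two-sided Wilcoxon `p_value`, `median_top`,
#'   `median_bottom`.
#' @export
compare_terciles <- function(ranking, fpkm) {
  top <- fpkm[ranking$gene_id[ranking$tercile == "top"]]
  bot <- fpkm[ranking$gene_id[ranking$tercile == "bottom"]]
  top <- top[!is.na(top)]; bot <- bot[!is.na(bot)]
  if (length(top) < 3 || length(bot) < 3) {
    stop("terciles must contain at least 3 genes with expression values")
  }
  p <- if (stats::sd(c(top, bot)) == 0) 1 else
    stats::wilcox.test(top, bot, exact = FALSE)$p.value
  list(p_value = p, median_top = stats::median(top),
       median_bottom = stats::median(bot))
}

#' Genes significantly enriched in nuclear fractions
#'
#' @param de DE table (`comparison`, `gene_id`, `log2fc`, `padj`).
#' @param alpha Adjusted-p threshold (strict, default 0.01).
#' @param comparisons Nuclear-versus-whole comparison names (positive
#'   log2fc = higher in the nuclear fraction).
#' @return Character vector of gene ids.
#' @export
nuclear_enriched <- function(de, alpha = 0.01,
                             comparisons = c("Nuclear34S_VS_S34",
                                             "Nuclear68S_VS_S68")) {
  de %>%
    filter(.data$comparison %in% comparisons, .data$padj < alpha,
           .data$log2fc > 0) %>%
    pull("gene_id") %>%
    unique()
}

#' Strain-specific expression partition
#'
#' Selects features expressed in strain A at a relaxed threshold and
#' partitions them by their strain-B expression into shared, intermediate,
#' and virtually-off classes.
#'
#' @param fpkm_a,fpkm_b Named numeric vectors of FPKM (shared names).
#' @param thr_on Expression threshold (inclusive, default 1 FPKM).
#' @param thr_off "Virtually not expressed" threshold (strict below,
#'   default 0.1 FPKM).
#' @return Tibble `feature_id`, `fpkm_a`, `fpkm_b`, `status` in
#'   shared/intermediate/off_in_b, covering features with
#'   `fpkm_a >= thr_on` only.
#' @export
strain_specific <- function(fpkm_a, fpkm_b, thr_on = 1, thr_off = 0.1) {
  ids <- intersect(names(fpkm_a), names(fpkm_b))
  if (length(ids) == 0) stop("feature id sets are disjoint")
  a <- fpkm_a[ids]; b <- fpkm_b[ids]
  sel <- a >= thr_on
  tibble(
    feature_id = ids[sel],
    fpkm_a = unname(a[sel]),
    fpkm_b = unname(b[sel]),
    status = dplyr::case_when(
      b[sel] >= thr_on ~ "shared",
      b[sel] < thr_off ~ "off_in_b",
      TRUE ~ "intermediate")
  )
}
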