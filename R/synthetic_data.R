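# Synthetic embryo transcriptome with planted ground truth.
#
# The generator emulates the structure of a staged, sorted, nuclear-
# fractionated embryonic RNA-seq design at toy scale: two chromosomes,
# a few hundred protein-coding genes (PCGs), annotated lncRNAs, and a
# candidate set mixing clean novel lncRNAs (intergenic, antisense,
# promoter-proximal, divergent) with planted artifact classes that are each
# constructed to violate exactly one discovery filter:
#   dna_contamination  - monoexonic, sense-strand read fraction < 0.8 in
#                        every sample (caught by the strand-ratio rule)
#   pre_mrna_leftover  - monoexonic, embedded in a host PCG intron on the
#                        same strand while overlapping a nested antisense
#                        gene (so it survives the intronic filter), and
#                        nuclear-enriched (caught by the log2 nuclear ratio)
#   repeat_decoy       - 95% of exonic bases repeat-masked (caught by the
#                        repeat-content rule)
#   coding_orf         - carries a long ORF plus protein-similarity
#                        evidence (flagged by the coding-potential vote,
#                        not by the cascade)
#   readthrough        - starts just downstream of an expressed PCG's 3'
#                        end on the same strand (flagged, not dropped)

#' Configuration for the synthetic data generator
#'
#' Defaults define the study conditions every property test runs under:
#' 2 chromosomes x 2 Mb, 300 PCGs, 60 annotated lncRNAs and 80 candidate
#' transcripts split between clean planted lncRNAs and artifact classes,
#' expressed over 8 non-nuclear and 2 nuclear conditions with log-normal
#' FPKM noise (sigma = 0.3 on the log2 scale) and 4 replicates.
#'
#' @param seed Integer seed; mandatory, every generator output is a pure
#'   function of (config, seed).
#' @param n_chrom,chrom_len Genome shape.
#' @param n_pcg,n_lnc_annotated Reference annotation sizes (nested antisense
#'   genes hosting pre-mRNA leftovers are added on top of `n_pcg`).
#' @param n_clean_intergenic,n_clean_antisense,n_clean_promoter,n_clean_divergent
#'   Planted clean novel lncRNAs per genomic class.
#' @param n_dna_contamination,n_pre_mrna_leftover,n_repeat_decoy,n_coding_orf,n_readthrough
#'   Planted artifact candidates per class.
#' @param n_redundant_isoform Clean intergenic genes that receive a
#'   near-identical (Jaccard > 0.95) shorter isoform.
#' @param n_replicates,sigma_log2 Replicates per condition and log2-scale
#'   FPKM dispersion.
#' @param frac_nuclear_enriched Fraction of clean + annotated lncRNAs with
#'   a +2 log2 nuclear-fraction effect.
#' @param frac_divergent_pcg Fraction of PCGs with high divergent
#'   (upstream-antisense) promoter transcription and a 2x expression boost.
#' @param frac_strain_off Fraction of clean lncRNA genes silenced in the
#'   second wild-type strain.
#' @param tss_jitter_frac Fraction of clean lncRNA candidate models whose
#'   annotated TSS is displaced (within the legal refinement window) from
#'   the true TSS marked by the CAGE peak.
#' @param tss_unsupported_frac Fraction of clean lncRNAs whose CAGE peak is
#'   below the 50-tag support threshold (height 40).
#' @param cage_height_range Tag-count range for supported lncRNA TSS peaks.
#' @param repeat_density,repeat_len_range Background repeat-mask coverage.
#' @param conserved_density,conserved_len_range,conserved_score_range
#'   Conserved-element track shape.
#' @param n_enhancers Enhancer intervals.
#' @param n_noise_peaks Background CAGE positions (all below 50 tags).
#' @param coverage_reads_per_fpkm Read depth scale of the stranded
#'   promoter-coverage track.
#' @param n_lines,temperatures,progeny_range,p_hom_viable,p_hom_lethal,lethal_lines
#'   Knockout-cross viability design; `p_hom_viable = 1/3` is the Mendelian
#'   expectation when the balancer homozygote is lethal.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chrom = 2, chrom_len = 2e6,
                       n_pcg = 300, n_lnc_annotated = 60,
                       n_clean_intergenic = 20, n_clean_antisense = 8,
                       n_clean_promoter = 6, n_clean_divergent = 6,
                       n_dna_contamination = 8, n_pre_mrna_leftover = 8,
                       n_repeat_decoy = 8, n_coding_orf = 8,
                       n_readthrough = 8,
                       n_redundant_isoform = 10,
                       n_replicates = 4, sigma_log2 = 0.3,
                       frac_nuclear_enriched = 0.25,
                       frac_divergent_pcg = 0.2,
                       frac_strain_off = 0.3,
                       tss_jitter_frac = 0.6,
                       tss_unsupported_frac = 0.1,
                       cage_height_range = c(60, 500),
                       repeat_density = 0.02,
                       repeat_len_range = c(50, 200),
                       conserved_density = 0.3,
                       conserved_len_range = c(50, 300),
                       conserved_score_range = c(100, 600),
                       n_enhancers = 100,
                       n_noise_peaks = 200,
                       coverage_reads_per_fpkm = 3,
                       n_lines = 5, temperatures = c(25, 29),
                       progeny_range = c(60, 90),
                       p_hom_viable = 1 / 3, p_hom_lethal = 0.05,
                       lethal_lines = character()) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("sim_config requires an explicit integer seed")
  }
  cfg <- as.list(environment())
  counts <- cfg[grepl("^n_", names(cfg))]
  if (any(unlist(counts) < 0)) stop("all counts must be >= 0")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Experimental condition names used by the generator
#'
#' Eight non-nuclear conditions (sorted mesoderm and whole embryo at
#' 3-4 h, 4-6 h, 6-8 h, plus whole-embryo 6-8 h poly-A+ and ribo-depleted
#' libraries) and two nuclear fractions.
#'
#' @return A list with `non_nuclear` and `nuclear` character vectors.
#' @export
sim_conditions <- function() {
  list(
    non_nuclear = c("Meso_34", "Meso_46", "Meso_68",
                    "WE_34", "WE_46", "WE_68",
                    "WE_68_polyA", "WE_68_ribo"),
    nuclear = c("Nuclear_34", "Nuclear_68")
  )
}

#' Temporal/tissue expression archetypes planted by the generator
#'
#' Five profile shapes (early, late, mid-peak, mesoderm-specific,
#' whole-embryo-specific) as log2 offsets over the generator's conditions.
#'
#' @return A 5 x 10 numeric matrix, rows = archetypes, columns = conditions.
#' @export
cluster_archetypes <- function() {
  conds <- sim_conditions()
  base <- rbind(
    early = c(3, 1, -1, 3, 1, -1),
    late = c(-1, 1, 3, -1, 1, 3),
    mid = c(0, 3, 0, 0, 3, 0),
    meso = c(2.5, 2.5, 2.5, -2, -2, -2),
    we = c(-2, -2, -2, 2.5, 2.5, 2.5)
  )
  colnames(base) <- c("Meso_34", "Meso_46", "Meso_68",
                      "WE_34", "WE_46", "WE_68")
  m <- base[, c("Meso_34", "Meso_46", "Meso_68",
                "WE_34", "WE_46", "WE_68",
                "WE_68", "WE_68",      # polyA / ribo mirror WE_68
                "Meso_34", "Meso_68")] # nuclear fractions mirror Meso
  colnames(m) <- c(conds$non_nuclear, conds$nuclear)
  m
}

#' The differential-expression comparison registry
#'
#' The fourteen staged/sorted comparisons (S = FACS-sorted mesoderm,
#' U = unsorted whole embryo; 34/46/68 = hours of development) plus two
#' nuclear-versus-whole comparisons used for nuclear-enrichment calls.
#' Positive log2 fold change is toward the first-named group.
#'
#' @return Tibble with `comparison`, `group_a`, `group_b` (condition-name
#'   list columns).
#' @export
de_comparisons <- function() {
  g <- function(...) list(c(...))
  tibble::tribble(
    ~comparison, ~group_a, ~group_b,
    "S34_VS_S46", g("Meso_34"), g("Meso_46"),
    "S34_VS_S68", g("Meso_34"), g("Meso_68"),
    "S34_VS_U34", g("Meso_34"), g("WE_34"),
    "S46_VS_S68", g("Meso_46"), g("Meso_68"),
    "S46_VS_U46", g("Meso_46"), g("WE_46"),
    "S68_VS_U68", g("Meso_68"), g("WE_68"),
    "U34_VS_U46", g("WE_34"), g("WE_46"),
    "U34_VS_U68", g("WE_34"), g("WE_68"),
    "U46_VS_U68", g("WE_46"), g("WE_68"),
    "Nuclear34S_VS_Nuclear68S", g("Nuclear_34"), g("Nuclear_68"),
    "FacsSorted_VS_facsUnsorted", g("Meso_34", "Meso_46", "Meso_68"),
    g("WE_34", "WE_46", "WE_68"),
    "Time34_VS_Time46", g("Meso_34", "WE_34"), g("Meso_46", "WE_46"),
    "Time34_VS_Time68", g("Meso_34", "WE_34"), g("Meso_68", "WE_68"),
    "Time46_VS_Time68", g("Meso_46", "WE_46"), g("Meso_68", "WE_68"),
    "Nuclear34S_VS_S34", g("Nuclear_34"), g("Meso_34"),
    "Nuclear68S_VS_S68", g("Nuclear_68"), g("Meso_68")
  )
}

# -- internal transcript builders ---------------------------------------

# sample() that never treats a length-1 numeric vector as 1:n
rsample <- function(x, n = 1, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

# Build exon rows for one transcript from a genomic start, exon lengths and
# intron lengths (1-based inclusive coordinates).
build_tx <- function(chrom, strand, gstart, exon_lens, intron_lens,
                     transcript_id, gene_id, provenance, biotype) {
  n <- length(exon_lens)
  starts <- integer(n)
  ends <- integer(n)
  pos <- gstart
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + exon_lens[i] - 1L
    pos <- ends[i] + (if (i < n) intron_lens[i] else 0L) + 1L
  }
  tibble::tibble(chrom = chrom, start = starts, end = ends, strand = strand,
                 transcript_id = transcript_id, gene_id = gene_id,
                 provenance = provenance, biotype = biotype)
}

rand_pcg_shape <- function() {
  n_ex <- sample(2:4, 1)
  list(exon_lens = sample(150:500, n_ex, replace = TRUE),
       intron_lens = sample(200:800, max(n_ex - 1, 0), replace = TRUE))
}

rand_lnc_shape <- function(mono_ok = TRUE) {
  n_ex <- if (mono_ok) sample(1:3, 1) else sample(2:3, 1)
  if (n_ex == 1) {
    list(exon_lens = sample(600:1200, 1), intron_lens = integer())
  } else {
    list(exon_lens = sample(300:700, n_ex, replace = TRUE),
         intron_lens = sample(200:600, n_ex - 1, replace = TRUE))
  }
}

#' Generate the synthetic reference and candidate annotation
#'
#' Lays out reference PCGs (with introns, some hosting nested antisense
#' genes), annotated lncRNAs, and the candidate set with all planted clean
#' and artifact classes along the genome. Deterministic given the config
#' seed. Candidate TSSs of a configurable fraction of clean lncRNAs are
#' displaced from the planted true TSS within the legal CAGE-refinement
#' window; the truth table records the true TSS.
#'
#' @param config A [sim_config()].
#' @return List with exon tables `reference` and `candidates`, the `truth`
#'   tibble (one row per transcript: class, clean flag, true/candidate TSS,
#'   partner PCG, cluster, nuclear/divergent/strain labels), and
#'   `repeat_targets` (intervals that must mask the repeat decoys).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  plan <- c(
    rep("pcg_antisense", cfg$n_clean_antisense),
    rep("pcg_promoter", cfg$n_clean_promoter),
    rep("pcg_divergent", cfg$n_clean_divergent),
    rep("pcg_host_pre", cfg$n_pre_mrna_leftover),
    rep("pcg_readthrough", cfg$n_readthrough),
    rep("pcg_plain", max(0, cfg$n_pcg - cfg$n_clean_antisense -
                           cfg$n_clean_promoter - cfg$n_clean_divergent -
                           cfg$n_pre_mrna_leftover - cfg$n_readthrough)),
    rep("annot_lnc", cfg$n_lnc_annotated),
    rep("cand_intergenic", cfg$n_clean_intergenic),
    rep("cand_contamination", cfg$n_dna_contamination),
    rep("cand_repeat", cfg$n_repeat_decoy),
    rep("cand_coding", cfg$n_coding_orf)
  )
  plan <- sample(plan)
  # rough per-unit footprint (span + companion lead + gap); fail early when
  # the genome cannot hold the requested gene load
  if (length(plan) * 6500 > cfg$n_chrom * cfg$chrom_len) {
    stop("infeasible packing: too many genes for the configured genome size")
  }
  chrom_of <- rep(paste0("chr", seq_len(cfg$n_chrom)),
                  length.out = length(plan))
  chrom_of <- chrom_of[order(rep(seq_len(cfg$n_chrom),
                                 length.out = length(plan)))]

  ref <- list(); cand <- list(); truth <- list(); rpt <- list()
  counters <- new.env()
  nid <- function(prefix) {
    k <- (get0(prefix, counters, ifnotfound = 0L)) + 1L
    assign(prefix, k, counters)
    sprintf("%s_%04d", prefix, k)
  }
  truth_row <- function(gene_id, transcript_id, class, is_clean = FALSE,
                        true_tss = NA_integer_, partner = NA_character_) {
    tibble::tibble(gene_id = gene_id, transcript_id = transcript_id,
                   class = class, is_clean = is_clean,
                   true_tss = true_tss, partner_pcg = partner)
  }
  add_pcg <- function(chrom, strand, at, shape = rand_pcg_shape()) {
    g <- nid("PCG"); t <- paste0(g, ".t1")
    tx <- build_tx(chrom, strand, at, shape$exon_lens, shape$intron_lens,
                   t, g, "reference", "protein_coding")
    ref[[length(ref) + 1]] <<- tx
    truth[[length(truth) + 1]] <<- truth_row(g, t, "pcg")
    tx
  }

  cursor <- stats::setNames(rep(1L, cfg$n_chrom),
                            paste0("chr", seq_len(cfg$n_chrom)))
  lead <- 1500L

  for (i in seq_along(plan)) {
    unit <- plan[i]
    chrom <- chrom_of[i]
    at <- cursor[[chrom]] + lead
    strand <- sample(c("+", "-"), 1)
    anti <- if (strand == "+") "-" else "+"
    extent <- at

    if (unit %in% c("pcg_plain", "pcg_antisense", "pcg_promoter",
                    "pcg_divergent", "pcg_readthrough")) {
      tx <- add_pcg(chrom, strand, at)
      gspan <- c(min(tx$start), max(tx$end))
      gtss <- if (strand == "+") gspan[1] else gspan[2]
      gtes <- if (strand == "+") gspan[2] else gspan[1]
      extent <- gspan[2]
      pcg_id <- tx$gene_id[1]

      if (unit == "pcg_antisense") {
        # monoexonic lncRNA on the opposite strand overlapping the PCG:
        # half cover the TSS point, half only exon body
        len <- sample(600:900, 1)
        g <- nid("CAND"); t <- paste0(g, ".t1")
        lst <- if (stats::runif(1) < 0.5) {
          gtss - sample(100:(len - 100), 1)
        } else {
          tx$start[1] + 50L
        }
        ctx <- build_tx(chrom, anti, lst, len, integer(), t, g,
                        "assembled", "lncRNA_novel")
        cand[[length(cand) + 1]] <- ctx
        tt <- if (anti == "+") lst else lst + len - 1L
        truth[[length(truth) + 1]] <-
          truth_row(g, t, "clean_antisense", TRUE, tt, pcg_id)
        extent <- max(extent, lst + len - 1L)
      } else if (unit == "pcg_promoter") {
        # opposite-strand lncRNA inside the 1-kb upstream promoter window
        len <- sample(500:800, 1)
        g <- nid("CAND"); t <- paste0(g, ".t1")
        if (strand == "+") {
          lst <- gtss - 100L - len + 1L   # span [gtss-100-len+1, gtss-100]
        } else {
          lst <- gtss + 100L
        }
        ctx <- build_tx(chrom, anti, lst, len, integer(), t, g,
                        "assembled", "lncRNA_novel")
        cand[[length(cand) + 1]] <- ctx
        tt <- if (anti == "+") lst else lst + len - 1L
        truth[[length(truth) + 1]] <-
          truth_row(g, t, "clean_promoter", TRUE, tt, pcg_id)
        extent <- max(extent, lst + len - 1L)
      } else if (unit == "pcg_divergent") {
        # opposite-strand lncRNA whose TSS sits 100-250 nt upstream of the
        # PCG TSS, transcribed away from the gene
        d <- sample(100:250, 1)
        len <- sample(600:1000, 1)
        g <- nid("CAND"); t <- paste0(g, ".t1")
        if (strand == "+") {
          lend <- gtss - d
          lst <- lend - len + 1L
        } else {
          lst <- gtss + d
          lend <- lst + len - 1L
        }
        ctx <- build_tx(chrom, anti, lst, len, integer(), t, g,
                        "assembled", "lncRNA_novel")
        cand[[length(cand) + 1]] <- ctx
        tt <- if (anti == "+") lst else lend
        truth[[length(truth) + 1]] <-
          truth_row(g, t, "clean_divergent", TRUE, tt, pcg_id)
        extent <- max(extent, lend)
      } else if (unit == "pcg_readthrough") {
        # same-strand candidate starting 50-300 nt past the PCG 3' end
        gap <- sample(50:300, 1)
        len <- sample(600:1000, 1)
        g <- nid("CAND"); t <- paste0(g, ".t1")
        lst <- if (strand == "+") gtes + gap else gtes - gap - len + 1L
        ctx <- build_tx(chrom, strand, lst, len, integer(), t, g,
                        "assembled", "lncRNA_novel")
        cand[[length(cand) + 1]] <- ctx
        tt <- if (strand == "+") lst else lst + len - 1L
        truth[[length(truth) + 1]] <-
          truth_row(g, t, "readthrough", FALSE, tt, pcg_id)
        extent <- max(extent, lst + len - 1L)
      }
    } else if (unit == "pcg_host_pre") {
      # host PCG with a 3-kb intron carrying a nested antisense gene and a
      # same-strand monoexonic pre-mRNA leftover overlapping it
      host <- add_pcg(chrom, strand, at,
                      list(exon_lens = c(400L, 400L), intron_lens = 3000L))
      intron_lo <- host$end[1] + 1L
      nst <- intron_lo + 300L
      nshape <- list(exon_lens = sample(400:600, 1), intron_lens = integer())
      add_pcg(chrom, anti, nst, nshape)
      len <- sample(600:900, 1)
      g <- nid("CAND"); t <- paste0(g, ".t1")
      lst <- nst + 100L
      ctx <- build_tx(chrom, strand, lst, len, integer(), t, g,
                      "assembled", "lncRNA_novel")
      cand[[length(cand) + 1]] <- ctx
      tt <- if (strand == "+") lst else lst + len - 1L
      truth[[length(truth) + 1]] <-
        truth_row(g, t, "pre_mrna_leftover", FALSE, tt, host$gene_id[1])
      extent <- max(host$end)
    } else if (unit == "annot_lnc") {
      shape <- rand_lnc_shape()
      g <- nid("LNCA"); t <- paste0(g, ".t1")
      tx <- build_tx(chrom, strand, at, shape$exon_lens, shape$intron_lens,
                     t, g, "reference", "lncRNA_annotated")
      ref[[length(ref) + 1]] <- tx
      tt <- if (strand == "+") min(tx$start) else max(tx$end)
      truth[[length(truth) + 1]] <- truth_row(g, t, "lnc_annotated",
                                              TRUE, tt)
      extent <- max(tx$end)
    } else if (unit == "cand_intergenic") {
      shape <- rand_lnc_shape()
      g <- nid("CAND"); t <- paste0(g, ".t1")
      tx <- build_tx(chrom, strand, at, shape$exon_lens, shape$intron_lens,
                     t, g, "assembled", "lncRNA_novel")
      cand[[length(cand) + 1]] <- tx
      tt <- if (strand == "+") min(tx$start) else max(tx$end)
      truth[[length(truth) + 1]] <- truth_row(g, t, "clean_intergenic",
                                              TRUE, tt)
      extent <- max(tx$end)
    } else if (unit == "cand_contamination") {
      len <- sample(600:1200, 1)
      g <- nid("CAND"); t <- paste0(g, ".t1")
      tx <- build_tx(chrom, strand, at, len, integer(), t, g,
                     "assembled", "lncRNA_novel")
      cand[[length(cand) + 1]] <- tx
      truth[[length(truth) + 1]] <- truth_row(g, t, "dna_contamination")
      extent <- max(tx$end)
    } else if (unit == "cand_repeat") {
      g <- nid("CAND"); t <- paste0(g, ".t1")
      tx <- build_tx(chrom, strand, at, c(400L, 400L), 500L, t, g,
                     "assembled", "lncRNA_novel")
      cand[[length(cand) + 1]] <- tx
      truth[[length(truth) + 1]] <- truth_row(g, t, "repeat_decoy")
      # mask 95% of each exon
      rpt[[length(rpt) + 1]] <- tibble::tibble(
        chrom = chrom, start = tx$start,
        end = tx$start + floor(0.95 * (tx$end - tx$start + 1)) - 1L
      )
      extent <- max(tx$end)
    } else if (unit == "cand_coding") {
      len <- sample(900:1200, 1)
      half <- len %/% 2
      g <- nid("CAND"); t <- paste0(g, ".t1")
      tx <- build_tx(chrom, strand, at, c(half, len - half), 400L, t, g,
                     "assembled", "lncRNA_novel")
      cand[[length(cand) + 1]] <- tx
      tt <- if (strand == "+") min(tx$start) else max(tx$end)
      truth[[length(truth) + 1]] <- truth_row(g, t, "coding_orf", FALSE, tt)
      extent <- max(tx$end)
    }

    cursor[[chrom]] <- extent + sample(1200:2500, 1)
    if (cursor[[chrom]] > cfg$chrom_len - 5000L) {
      stop("infeasible packing: ran out of genome on ", chrom)
    }
  }

  reference <- as_exon_tbl(dplyr::bind_rows(ref))
  candidates <- as_exon_tbl(dplyr::bind_rows(cand))
  truth <- dplyr::bind_rows(truth)

  # near-identical redundant isoforms for the first clean intergenic genes
  clean_ig <- truth$transcript_id[truth$class == "clean_intergenic"]
  n_red <- min(config$n_redundant_isoform, length(clean_ig))
  if (n_red > 0) {
    red <- list()
    for (t0 in clean_ig[seq_len(n_red)]) {
      ex <- candidates %>% dplyr::filter(.data$transcript_id == t0) %>%
        dplyr::arrange(.data$start)
      L <- sum(ex$end - ex$start + 1)
      d <- max(1L, as.integer(floor(0.02 * L)))
      # trim d nt from the 3' end (genomic right for +, left for -)
      if (ex$strand[1] == "+") {
        ex$end[nrow(ex)] <- ex$end[nrow(ex)] - d
      } else {
        ex$start[1] <- ex$start[1] + d
      }
      t1 <- sub("\\.t1$", ".t2", t0)
      ex$transcript_id <- t1
      red[[length(red) + 1]] <- ex
      tr <- truth[truth$transcript_id == t0, ]
      truth <- dplyr::bind_rows(truth, dplyr::mutate(
        tr, transcript_id = t1, class = "redundant_isoform",
        is_clean = FALSE))
    }
    candidates <- as_exon_tbl(dplyr::bind_rows(candidates,
                                               dplyr::bind_rows(red)))
  }

  # candidate-model TSS jitter for clean lncRNAs (truth keeps the true TSS)
  ti <- tx_info(candidates)
  truth$candidate_tss <- truth$true_tss
  truth$tss_jitter <- 0L
  clean_tx <- truth$transcript_id[truth$is_clean &
                                    truth$transcript_id %in% ti$transcript_id]
  n_jit <- round(config$tss_jitter_frac * length(clean_tx))
  jit_tx <- if (n_jit > 0) sample(clean_tx, n_jit) else character()
  for (t0 in jit_tx) {
    idx <- which(candidates$transcript_id == t0)
    ex <- candidates[idx, ] %>% dplyr::arrange(.data$start)
    L <- sum(ex$end - ex$start + 1)
    plus <- ex$strand[1] == "+"
    first_len <- if (plus) ex$end[1] - ex$start[1] + 1 else
      ex$end[nrow(ex)] - ex$start[nrow(ex)] + 1
    # clip-jitter must keep the model above every length rule (500 nt
    # monoexonic, 200 nt overall) and leave a non-empty first exon
    clip_max <- min(700, first_len - 100,
                    if (nrow(ex) == 1) L - 550 else L - 250)
    if (stats::runif(1) < 0.5 || clip_max < 30) {
      # candidate extended 5' of the true TSS; refinement must clip inward
      d <- sample(30:max(31, floor(0.25 * L)), 1)
      if (plus) ex$start[1] <- ex$start[1] - d
      else ex$end[nrow(ex)] <- ex$end[nrow(ex)] + d
      jit <- -d
    } else {
      # candidate starts inside the true transcript; refinement must extend
      d <- rsample(30:clip_max, 1)
      if (plus) ex$start[1] <- ex$start[1] + d
      else ex$end[nrow(ex)] <- ex$end[nrow(ex)] - d
      jit <- d
    }
    candidates[idx, ] <- ex
    k <- truth$transcript_id == t0
    truth$tss_jitter[k] <- jit
    truth$candidate_tss[k] <- if (plus) min(ex$start) else max(ex$end)
  }
  candidates <- as_exon_tbl(candidates)

  # planted phenotype labels
  ti <- tx_info(candidates)
  truth <- truth %>%
    dplyr::left_join(dplyr::select(ti, "transcript_id", "n_exons",
                                   "length"),
                     by = "transcript_id") %>%
    dplyr::mutate(
      n_exons = dplyr::coalesce(.data$n_exons,
                                tx_info(reference)$n_exons[
                                  match(.data$transcript_id,
                                        tx_info(reference)$transcript_id)]),
      length = dplyr::coalesce(.data$length,
                               tx_info(reference)$length[
                                 match(.data$transcript_id,
                                       tx_info(reference)$transcript_id)])
    )
  lnc_genes <- unique(truth$gene_id[truth$is_clean |
                                      truth$class == "lnc_annotated"])
  truth$cluster <- NA_integer_
  cl <- sample(1:5, length(lnc_genes), replace = TRUE)
  truth$cluster <- cl[match(truth$gene_id, lnc_genes)]
  # partner PCGs of positional lncRNA classes co-express with them
  co <- truth %>%
    dplyr::filter(.data$class %in% c("clean_antisense", "clean_promoter",
                                     "clean_divergent"))
  pcl <- truth$cluster[match(co$gene_id, truth$gene_id)]
  truth$cluster[match(co$partner_pcg, truth$gene_id)] <- pcl
  # remaining PCGs: mostly flat (uncorrelated) so the random lncRNA-PCG
  # pairing background stays centred at zero; 40% carry an archetype
  pcg_rows <- which(truth$class == "pcg" & is.na(truth$cluster))
  pick <- stats::runif(length(pcg_rows)) < 0.4
  truth$cluster[pcg_rows[pick]] <- sample(1:5, sum(pick), replace = TRUE)

  lnc_ids <- unique(truth$gene_id[(truth$is_clean |
                                     truth$class == "lnc_annotated")])
  n_nuc <- round(config$frac_nuclear_enriched * length(lnc_ids))
  nuc <- if (n_nuc > 0) sample(lnc_ids, n_nuc) else character()
  truth$nuclear_enriched <- truth$gene_id %in% nuc

  pcg_ids <- unique(truth$gene_id[truth$class == "pcg"])
  div_partner <- truth$partner_pcg[truth$class == "clean_divergent"]
  n_div <- round(config$frac_divergent_pcg * length(pcg_ids))
  div <- unique(c(div_partner,
                  sample(setdiff(pcg_ids, div_partner), n_div)))
  truth$divergent_high <- truth$gene_id %in% div

  clean_ids <- unique(truth$gene_id[truth$is_clean &
                                      truth$class != "lnc_annotated"])
  n_off <- round(config$frac_strain_off * length(clean_ids))
  off <- if (n_off > 0) sample(clean_ids, n_off) else character()
  truth$strain_off <- truth$gene_id %in% off

  list(reference = reference, candidates = candidates, truth = truth,
       repeat_targets = if (length(rpt)) dplyr::bind_rows(rpt) else
         tibble::tibble(chrom = character(), start = integer(),
                        end = integer()))
}

# Vectorised Welch t-test across rows of two replicate matrices.
row_welch_p <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[is.na(p)] <- 1
  p
}

#' Generate expression tables, strand counts and DE results
#'
#' Log-normal FPKM with the planted condition effects: cluster archetype
#' offsets, +2 log2 nuclear enrichment for labelled genes, +2.5 log2
#' nuclear elevation for pre-mRNA leftovers (so the nuclear-ratio filter
#' removes them by construction), 2x expression for divergent-high PCGs,
#' and sense-strand read fractions below 0.8 in every sample for
#' DNA-contamination artifacts. DE p-values come from a Welch t-test on
#' log2 FPKM replicates, BH-adjusted within each comparison.
#'
#' @param annotation Output of [generate_annotation()].
#' @param config The same [sim_config()].
#' @return List: `expr_tx` (transcript-level FPKM), `expr_gene`,
#'   `strand_counts`, `de` (comparison/gene/log2fc/pvalue/padj),
#'   `strain_expr` (per-gene FPKM in strains A and B at WE 6-8 h).
#' @export
generate_expression <- function(annotation, config) {
  set.seed(config$seed + 1L)
  truth <- annotation$truth
  conds <- c(sim_conditions()$non_nuclear, sim_conditions()$nuclear)
  arch <- cluster_archetypes()
  genes <- truth %>% dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  G <- nrow(genes)

  mu <- numeric(G)
  mu[genes$class == "pcg"] <- stats::rnorm(sum(genes$class == "pcg"), 4.5, 1)
  is_lnc <- genes$class != "pcg"
  mu[is_lnc] <- stats::runif(sum(is_lnc), 2, 3.5)
  mu[genes$class == "pre_mrna_leftover"] <-
    stats::runif(sum(genes$class == "pre_mrna_leftover"), 1.7, 2.3)
  mu[genes$class == "dna_contamination"] <-
    stats::runif(sum(genes$class == "dna_contamination"), 1.5, 3)

  off <- matrix(0, G, length(conds), dimnames = list(genes$gene_id, conds))
  has_cl <- !is.na(genes$cluster)
  off[has_cl, ] <- arch[genes$cluster[has_cl], conds, drop = FALSE]
  nucc <- sim_conditions()$nuclear
  off[genes$nuclear_enriched, nucc] <- off[genes$nuclear_enriched, nucc] + 3
  off[genes$class == "pre_mrna_leftover", nucc] <-
    off[genes$class == "pre_mrna_leftover", nucc] + 2.5
  off[genes$divergent_high, ] <- off[genes$divergent_high, ] + 1

  R <- config$n_replicates
  reps <- array(
    stats::rnorm(G * length(conds) * R, 0, config$sigma_log2),
    dim = c(G, length(conds), R)
  )
  logmean <- sweep(off, 1, mu, "+")
  for (r in seq_len(R)) reps[, , r] <- reps[, , r] + logmean
  fpkm_gene <- apply(2^reps, c(1, 2), mean)
  dimnames(fpkm_gene) <- list(genes$gene_id, conds)

  # distribute gene FPKM over transcripts (redundant isoform takes 30%)
  share <- truth %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::mutate(share = dplyr::if_else(
      .data$class == "redundant_isoform", 0.3,
      dplyr::if_else(dplyr::n() > 1 & .data$class != "redundant_isoform",
                     0.7, 1.0))) %>%
    dplyr::ungroup()
  fpkm_tx <- fpkm_gene[share$gene_id, , drop = FALSE] * share$share
  expr_tx <- expression_table(share$transcript_id, fpkm_tx, "transcript")
  expr_gene <- expression_table(genes$gene_id, fpkm_gene, "gene")

  # strand counts for every monoexonic candidate transcript
  cand_tx <- tx_info(annotation$candidates)
  mono <- cand_tx %>% dplyr::filter(.data$n_exons == 1)
  nn <- sim_conditions()$non_nuclear
  sc <- tidyr::expand_grid(transcript_id = mono$transcript_id,
                           condition = nn) %>%
    dplyr::left_join(dplyr::select(truth, "transcript_id", "class"),
                     by = "transcript_id") %>%
    dplyr::mutate(
      total = stats::rpois(dplyr::n(), 40) + 20L,
      frac = dplyr::if_else(.data$class == "dna_contamination",
                            stats::runif(dplyr::n(), 0.40, 0.75),
                            stats::runif(dplyr::n(), 0.85, 0.99)),
      sense_reads = round(.data$total * .data$frac),
      antisense_reads = .data$total - .data$sense_reads
    ) %>%
    dplyr::select("transcript_id", "condition", "sense_reads",
                  "antisense_reads")

  # DE over all genes from the replicate-level log2 FPKM
  cmp <- de_comparisons()
  de <- purrr::pmap_dfr(cmp, function(comparison, group_a, group_b) {
    ia <- which(conds %in% unlist(group_a))
    ib <- which(conds %in% unlist(group_b))
    a <- matrix(reps[, ia, , drop = FALSE], nrow = G)
    b <- matrix(reps[, ib, , drop = FALSE], nrow = G)
    p <- row_welch_p(a, b)
    tibble::tibble(comparison = comparison, gene_id = genes$gene_id,
                   log2fc = rowMeans(a) - rowMeans(b),
                   pvalue = p, padj = bh_adjust(p))
  })

  # second wild-type strain: same WE 6-8 h means except silenced genes
  b_fpkm <- fpkm_gene[, "WE_68"] * 2^stats::rnorm(G, 0, config$sigma_log2)
  b_fpkm[genes$strain_off] <- stats::runif(sum(genes$strain_off), 0, 0.05)
  strain_expr <- tibble::tibble(
    feature_id = genes$gene_id,
    fpkm_a = fpkm_gene[, "WE_68"],
    fpkm_b = b_fpkm
  )

  list(expr_tx = expr_tx, expr_gene = expr_gene, strand_counts = sc,
       de = de, strain_expr = strain_expr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

orf_dna <- function(n, orf_frac = 0.88) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste0,
                  collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  n_cod <- max(20L, as.integer(floor((n * orf_frac - 6) / 3)))
  orf <- paste0("ATG", paste(sample(sense, n_cod, replace = TRUE),
                             collapse = ""), "TAA")
  pre_n <- max(0L, (n - nchar(orf)) %/% 2)
  post_n <- max(0L, n - nchar(orf) - pre_n)
  paste0(if (pre_n) random_dna(pre_n) else "", orf,
         if (post_n) random_dna(post_n) else "")
}

#' Generate CAGE, repeat, conservation, enhancer, sequence and coverage
#' tracks
#'
#' Every planted lncRNA receives a CAGE peak at its TRUE TSS (height below
#' 50 tags for the configured unsupported fraction); coding decoys receive
#' transcript sequences dominated by a long ORF; repeat decoys are masked
#' over 95% of their exons; a stranded promoter-proximal read-coverage
#' track is emitted for the divergent-transcription analysis when `expr`
#' is supplied.
#'
#' @param annotation Output of [generate_annotation()].
#' @param config The same [sim_config()].
#' @param expr Optional output of [generate_expression()] (enables the
#'   coverage track scaled to Meso 6-8 h FPKM).
#' @return List: `cage` (chrom/pos/strand/count), `repeats`, `conserved`
#'   (with `score`), `enhancers`, `sequences` (named character vector per
#'   candidate transcript), `coding_evidence` tibble, `coverage`
#'   (chrom/pos/strand/count) or NULL.
#' @export
generate_tracks <- function(annotation, config, expr = NULL) {
  set.seed(config$seed + 2L)
  truth <- annotation$truth
  ref_tx <- tx_info(annotation$reference)
  cand_tx <- tx_info(annotation$candidates)
  chroms <- paste0("chr", seq_len(config$n_chrom))

  # CAGE: true-TSS peaks for planted lncRNAs, plus reference gene peaks and
  # sub-threshold noise
  lnc <- truth %>%
    dplyr::filter(.data$is_clean, !is.na(.data$true_tss)) %>%
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  strand_of <- dplyr::coalesce(
    cand_tx$strand[match(lnc$transcript_id, cand_tx$transcript_id)],
    ref_tx$strand[match(lnc$transcript_id, ref_tx$transcript_id)])
  chrom_of <- dplyr::coalesce(
    cand_tx$chrom[match(lnc$transcript_id, cand_tx$transcript_id)],
    ref_tx$chrom[match(lnc$transcript_id, ref_tx$transcript_id)])
  n_unsup <- round(config$tss_unsupported_frac * nrow(lnc))
  unsup <- rep(FALSE, nrow(lnc))
  if (n_unsup > 0) unsup[sample(nrow(lnc), n_unsup)] <- TRUE
  h <- round(stats::runif(nrow(lnc), config$cage_height_range[1],
                          config$cage_height_range[2]))
  h[unsup] <- 40L
  cage_lnc <- tibble::tibble(chrom = chrom_of, pos = lnc$true_tss,
                             strand = strand_of, count = as.integer(h))
  truth$tss_supported <- TRUE
  truth$tss_supported[match(lnc$gene_id[unsup], truth$gene_id)] <- FALSE
  # propagate per gene (isoforms share the promoter)
  truth <- truth %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::mutate(tss_supported = all(.data$tss_supported)) %>%
    dplyr::ungroup()

  pcgs <- ref_tx
  cage_ref <- tibble::tibble(
    chrom = pcgs$chrom, pos = pcgs$tss, strand = pcgs$strand,
    count = as.integer(round(stats::runif(nrow(pcgs), 100, 800))))
  noise <- tibble::tibble(
    chrom = sample(chroms, config$n_noise_peaks, replace = TRUE),
    pos = sample.int(config$chrom_len, config$n_noise_peaks),
    strand = sample(c("+", "-"), config$n_noise_peaks, replace = TRUE),
    count = sample(1:45, config$n_noise_peaks, replace = TRUE))
  cage <- dplyr::bind_rows(cage_lnc, cage_ref, noise) %>%
    dplyr::distinct(.data$chrom, .data$strand, .data$pos, .keep_all = TRUE)

  # repeat mask: decoy-covering intervals plus background
  n_bg <- round(config$n_chrom * config$chrom_len * config$repeat_density /
                  mean(config$repeat_len_range))
  bg_len <- sample(config$repeat_len_range[1]:config$repeat_len_range[2],
                   n_bg, replace = TRUE)
  bg <- tibble::tibble(
    chrom = sample(chroms, n_bg, replace = TRUE),
    start = sample.int(config$chrom_len - max(bg_len), n_bg))
  bg$end <- bg$start + bg_len - 1L
  repeats <- dplyr::bind_rows(annotation$repeat_targets, bg) %>%
    dplyr::arrange(.data$chrom, .data$start)

  # conserved elements with phastCons-style scores
  n_ce <- round(config$n_chrom * config$chrom_len *
                  config$conserved_density /
                  mean(config$conserved_len_range))
  ce_len <- sample(config$conserved_len_range[1]:
                     config$conserved_len_range[2], n_ce, replace = TRUE)
  conserved <- tibble::tibble(
    chrom = sample(chroms, n_ce, replace = TRUE),
    start = sample.int(config$chrom_len - max(ce_len), n_ce))
  conserved$end <- conserved$start + ce_len - 1L
  conserved$score <- round(stats::runif(n_ce,
                                        config$conserved_score_range[1],
                                        config$conserved_score_range[2]))
  conserved <- dplyr::arrange(conserved, .data$chrom, .data$start)

  enh_len <- sample(200:800, config$n_enhancers, replace = TRUE)
  enhancers <- tibble::tibble(
    chrom = sample(chroms, config$n_enhancers, replace = TRUE),
    start = sample.int(config$chrom_len - 1000L, config$n_enhancers))
  enhancers$end <- enhancers$start + enh_len - 1L
  enhancers <- dplyr::arrange(enhancers, .data$chrom, .data$start)

  # candidate transcript sequences; coding decoys carry one long ORF
  seqs <- vapply(seq_len(nrow(cand_tx)), function(i) {
    cls <- truth$class[match(cand_tx$transcript_id[i],
                             truth$transcript_id)]
    if (identical(cls, "coding_orf")) orf_dna(cand_tx$length[i])
    else random_dna(cand_tx$length[i])
  }, character(1))
  names(seqs) <- cand_tx$transcript_id

  # protein-similarity evidence: strong hits for coding decoys only
  coding_tx <- truth$transcript_id[truth$class == "coding_orf"]
  coding_evidence <- tibble::tibble(
    transcript_id = coding_tx, method = "blastx",
    score = 10^(-stats::runif(length(coding_tx), 5, 50)))

  coverage <- NULL
  if (!is.null(expr)) {
    fpkm <- expr_matrix(expr$expr_gene)[, "Meso_68"]
    pcg <- truth %>% dplyr::filter(.data$class == "pcg") %>%
      dplyr::distinct(.data$gene_id, .keep_all = TRUE)
    info <- ref_tx[match(pcg$transcript_id, ref_tx$transcript_id), ]
    rows <- purrr::map_dfr(seq_len(nrow(pcg)), function(i) {
      tss <- info$tss[i]; chrom <- info$chrom[i]
      s <- info$strand[i]; anti <- if (s == "+") "-" else "+"
      dirn <- if (s == "+") 1L else -1L
      ns <- min(500L, max(5L, round(fpkm[pcg$gene_id[i]] *
                                      config$coverage_reads_per_fpkm)))
      d_s <- pmin(999L, as.integer(floor(stats::rexp(ns, 1 / 300))))
      sense_pos <- tss + dirn * d_s
      if (pcg$divergent_high[i]) {
        na <- max(20L, round(0.6 * ns))
        d_a <- 20L + pmin(979L, as.integer(floor(stats::rexp(na, 1 / 250))))
      } else {
        na <- stats::rpois(1, 2)
        d_a <- if (na > 0) sample.int(999L, na, replace = TRUE) else
          integer()
      }
      anti_pos <- tss - dirn * d_a
      tibble::tibble(
        chrom = chrom,
        pos = c(sense_pos, anti_pos),
        strand = c(rep(s, length(sense_pos)), rep(anti, length(anti_pos))))
    })
    coverage <- rows %>%
      dplyr::count(.data$chrom, .data$pos, .data$strand, name = "count") %>%
      dplyr::filter(.data$pos >= 1)
  }

  list(cage = cage, repeats = repeats, conserved = conserved,
       enhancers = enhancers, sequences = seqs,
       coding_evidence = coding_evidence, coverage = coverage,
       truth = truth)
}

#' Simulate knockout-cross progeny counts
#'
#' Balancer-stock sibling crosses: adult progeny counts are drawn
#' binomially with homozygote probability 1/3 under viability (the 2:1
#' Het/Hom Mendelian expectation) or a reduced probability for lines
#' configured as lethal.
#'
#' @param config A [sim_config()].
#' @return Tibble: `line`, `temperature`, `n_hom`, `n_het`.
#' @export
generate_viability <- function(config) {
  set.seed(config$seed + 3L)
  rows <- tidyr::expand_grid(
    line = sprintf("KO_line_%02d", seq_len(config$n_lines)),
    temperature = config$temperatures)
  n <- rsample(config$progeny_range[1]:config$progeny_range[2],
               nrow(rows), replace = TRUE)
  p <- ifelse(rows$line %in% config$lethal_lines, config$p_hom_lethal,
              config$p_hom_viable)
  hom <- stats::rbinom(nrow(rows), n, p)
  tibble::tibble(line = rows$line, temperature = rows$temperature,
                 n_hom = hom, n_het = n - hom)
}

#' Generate the complete synthetic input bundle
#'
#' Runs annotation, expression, track and viability generation and
#' optionally writes the full bundle (GTFs, TSVs, BEDs, FASTA, truth table,
#' config) to a directory readable by [read_bundle()].
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; created if needed.
#' @return The in-memory bundle list (reference, candidates, truth,
#'   expr_tx, expr_gene, strand_counts, de, strain_expr, cage, repeats,
#'   conserved, enhancers, sequences, coding_evidence, coverage,
#'   viability, config).
#' @export
simulate_bundle <- function(config, dir = NULL) {
  ann <- generate_annotation(config)
  expr <- generate_expression(ann, config)
  trk <- generate_tracks(ann, config, expr)
  via <- generate_viability(config)
  bundle <- list(
    reference = ann$reference, candidates = ann$candidates,
    truth = trk$truth,
    expr_tx = expr$expr_tx, expr_gene = expr$expr_gene,
    strand_counts = expr$strand_counts, de = expr$de,
    strain_expr = expr$strain_expr,
    cage = trk$cage, repeats = trk$repeats, conserved = trk$conserved,
    enhancers = trk$enhancers, sequences = trk$sequences,
    coding_evidence = trk$coding_evidence, coverage = trk$coverage,
    viability = via, config = config
  )
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' @rdname simulate_bundle
#' @param bundle A bundle list from [simulate_bundle()].
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gtf(bundle$reference, p("reference.gtf"))
  write_gtf(bundle$candidates, p("candidates.gtf"))
  readr::write_tsv(bundle$truth, p("truth.tsv"))
  write_expression(bundle$expr_tx, p("expression_tx.tsv"))
  write_expression(bundle$expr_gene, p("expression_gene.tsv"))
  readr::write_tsv(bundle$strand_counts, p("strand_counts.tsv"))
  readr::write_tsv(bundle$de, p("de_table.tsv"))
  readr::write_tsv(bundle$strain_expr, p("strain_expression.tsv"))
  readr::write_tsv(bundle$cage, p("cage_tags.tsv"))
  write_bed(bundle$repeats, p("repeats.bed"))
  write_bed(dplyr::mutate(bundle$conserved, name = "ce"),
            p("conserved.bed"))
  write_bed(bundle$enhancers, p("enhancers.bed"))
  writeLines(paste0(">", names(bundle$sequences), "\n", bundle$sequences),
             p("transcripts.fa"))
  readr::write_tsv(bundle$coding_evidence, p("coding_evidence.tsv"))
  if (!is.null(bundle$coverage)) {
    readr::write_tsv(bundle$coverage, p("coverage.tsv"))
  }
  readr::write_tsv(bundle$viability, p("viability.tsv"))
  cfg <- bundle$config
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.function, logical(1))],
                   p("config.yaml"))
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#' @param dir Bundle directory.
#' @return A bundle list (config restored from YAML).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  fa <- readLines(p("transcripts.fa"))
  hd <- grepl("^>", fa)
  seqs <- stats::setNames(fa[!hd], sub("^>", "", fa[hd]))
  cfgl <- yaml::read_yaml(p("config.yaml"))
  cfg <- do.call(sim_config, cfgl[names(cfgl) %in% names(formals(sim_config))])
  expr_tx <- read_expression(p("expression_tx.tsv"), "transcript")
  expr_gene <- read_expression(p("expression_gene.tsv"), "gene")
  list(
    reference = read_gtf(p("reference.gtf")),
    candidates = read_gtf(p("candidates.gtf")),
    truth = readr::read_tsv(p("truth.tsv"), show_col_types = FALSE),
    expr_tx = expr_tx, expr_gene = expr_gene,
    strand_counts = readr::read_tsv(p("strand_counts.tsv"),
                                    show_col_types = FALSE),
    de = readr::read_tsv(p("de_table.tsv"), show_col_types = FALSE),
    strain_expr = readr::read_tsv(p("strain_expression.tsv"),
                                  show_col_types = FALSE),
    cage = readr::read_tsv(p("cage_tags.tsv"), show_col_types = FALSE),
    repeats = read_bed(p("repeats.bed")),
    conserved = dplyr::select(read_bed(p("conserved.bed")),
                              "chrom", "start", "end", "score"),
    enhancers = dplyr::select(read_bed(p("enhancers.bed")),
                              "chrom", "start", "end"),
    sequences = seqs,
    coding_evidence = readr::read_tsv(p("coding_evidence.tsv"),
                                      show_col_types = FALSE),
    coverage = if (file.exists(p("coverage.tsv")))
      readr::read_tsv(p("coverage.tsv"), show_col_types = FALSE) else NULL,
    viability = readr::read_tsv(p("viability.tsv"), show_col_types = FALSE),
    config = cfg
  )
}
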