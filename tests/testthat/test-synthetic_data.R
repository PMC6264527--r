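test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 5, n_pcg = 40, n_lnc_annotated = 8,
                    n_clean_intergenic = 6, n_clean_antisense = 2,
                    n_clean_promoter = 2, n_clean_divergent = 2,
                    n_dna_contamination = 2, n_pre_mrna_leftover = 2,
                    n_repeat_decoy = 2, n_coding_orf = 2,
                    n_readthrough = 2, n_redundant_isoform = 2)
  a <- simulate_bundle(cfg)
  b <- simulate_bundle(cfg)
  expect_identical(a$candidates, b$candidates)
  expect_identical(a$expr_tx, b$expr_tx)
  expect_identical(a$cage, b$cage)
  expect_identical(a$viability, b$viability)
  # byte-identical GTF output under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_gtf(a$candidates, file.path(d1, "c.gtf"))
  write_gtf(b$candidates, file.path(d2, "c.gtf"))
  expect_identical(readLines(file.path(d1, "c.gtf")),
                   readLines(file.path(d2, "c.gtf")))
})

test_that("planted class counts match the configuration", {
  b <- shared_bundle()
  cfg <- b$config
  counts <- table(b$truth$class)
  expect_equal(unname(counts["clean_intergenic"]), cfg$n_clean_intergenic)
  expect_equal(unname(counts["clean_antisense"]), cfg$n_clean_antisense)
  expect_equal(unname(counts["clean_promoter"]), cfg$n_clean_promoter)
  expect_equal(unname(counts["clean_divergent"]), cfg$n_clean_divergent)
  expect_equal(unname(counts["dna_contamination"]),
               cfg$n_dna_contamination)
  expect_equal(unname(counts["pre_mrna_leftover"]),
               cfg$n_pre_mrna_leftover)
  expect_equal(unname(counts["repeat_decoy"]), cfg$n_repeat_decoy)
  expect_equal(unname(counts["coding_orf"]), cfg$n_coding_orf)
  expect_equal(unname(counts["readthrough"]), cfg$n_readthrough)
})

test_that("a zero-artifact config yields only clean candidates", {
  cfg <- sim_config(seed = 3, n_pcg = 40, n_lnc_annotated = 5,
                    n_clean_intergenic = 6, n_clean_antisense = 0,
                    n_clean_promoter = 0, n_clean_divergent = 0,
                    n_dna_contamination = 0, n_pre_mrna_leftover = 0,
                    n_repeat_decoy = 0, n_coding_orf = 0,
                    n_readthrough = 0, n_redundant_isoform = 0)
  ann <- generate_annotation(cfg)
  cand_classes <- b_classes <- ann$truth$class[
    ann$truth$transcript_id %in% ann$candidates$transcript_id]
  expect_true(all(cand_classes == "clean_intergenic"))
})

test_that("planted labels are mutually consistent", {
  b <- shared_bundle()
  tr <- b$truth
  ti <- tx_info(b$candidates)
  # DNA contamination only on monoexonic candidates
  contam <- tr$transcript_id[tr$class == "dna_contamination"]
  expect_true(all(ti$n_exons[match(contam, ti$transcript_id)] == 1))
  # every clean planted lncRNA carries a true TSS
  expect_false(any(is.na(tr$true_tss[tr$is_clean])))
  # pre-mRNA leftovers sit in same-strand introns and are monoexonic
  pre <- tr$transcript_id[tr$class == "pre_mrna_leftover"]
  expect_true(all(ti$n_exons[match(pre, ti$transcript_id)] == 1))
})

test_that("artifacts violate exactly their designated filter by construction", {
  b <- shared_bundle()
  tr <- b$truth
  # contamination: sense fraction below 0.8 in every sample
  contam <- tr$transcript_id[tr$class == "dna_contamination"]
  sc <- b$strand_counts %>%
    dplyr::filter(transcript_id %in% contam) %>%
    dplyr::mutate(ratio = sense_reads / (sense_reads + antisense_reads))
  expect_lt(max(sc$ratio), 0.8)
  # clean monoexonic candidates reach 0.8 somewhere
  clean_mono <- intersect(tr$transcript_id[tr$is_clean],
                          b$strand_counts$transcript_id)
  sc2 <- b$strand_counts %>%
    dplyr::filter(transcript_id %in% clean_mono) %>%
    dplyr::mutate(ratio = sense_reads / (sense_reads + antisense_reads)) %>%
    dplyr::group_by(transcript_id) %>%
    dplyr::summarise(mx = max(ratio))
  expect_gte(min(sc2$mx), 0.8)
  # pre-mRNA leftovers: nuclear/non-nuclear log2 ratio above 1
  pre <- tr$transcript_id[tr$class == "pre_mrna_leftover"]
  m <- expr_matrix(b$expr_tx)
  r <- log2((m[pre, "Nuclear_34"] + 0.1) / (m[pre, "Meso_34"] + 0.1))
  expect_gt(min(r), 1)
  # repeat decoys are masked above 90% of their exonic bases
  dec <- tr$transcript_id[tr$class == "repeat_decoy"]
  for (t in dec) {
    ex <- b$candidates %>% dplyr::filter(transcript_id == t)
    expect_gt(oracle_masked_fraction(ex, b$repeats), 0.9)
  }
})

test_that("null genes produce near-uniform DE p-values", {
  b <- shared_bundle()
  tr <- b$truth
  flat_pcg <- unique(tr$gene_id[tr$class == "pcg" & is.na(tr$cluster) &
                                  !tr$divergent_high])
  p <- b$de$pvalue[b$de$comparison == "S34_VS_S46" &
                     b$de$gene_id %in% flat_pcg]
  expect_gt(length(p), 50)
  frac <- mean(p < 0.05)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.15)
})

test_that("CAGE peaks mark the true TSS and jitter stays in the legal window", {
  b <- shared_bundle()
  tr <- b$truth %>% dplyr::filter(is_clean, !is.na(true_tss))
  ti <- tx_info(b$candidates)
  cand <- tr %>% dplyr::filter(transcript_id %in% ti$transcript_id)
  key <- paste(b$cage$chrom, b$cage$pos, b$cage$strand)
  info <- ti[match(cand$transcript_id, ti$transcript_id), ]
  expect_true(all(paste(info$chrom, cand$true_tss, info$strand) %in% key))
  # jittered models stay recoverable: upstream shift <= 800,
  # inward shift <= 0.3 x candidate length
  jit <- cand %>% dplyr::filter(tss_jitter != 0)
  L <- info$length[match(jit$transcript_id, info$transcript_id)]
  expect_true(all(jit$tss_jitter[jit$tss_jitter > 0] <= 800))
  neg <- jit$tss_jitter < 0
  expect_true(all(-jit$tss_jitter[neg] <= 0.3 * L[neg]))
  # unsupported genes only carry sub-threshold peaks at their TSS
  unsup <- b$truth %>% dplyr::filter(is_clean, !tss_supported)
  if (nrow(unsup) > 0) {
    hts <- b$cage$count[match(paste(info$chrom[match(unsup$transcript_id,
                                                     cand$transcript_id)],
                                    unsup$true_tss),
                              paste(b$cage$chrom, b$cage$pos))]
    expect_true(all(hts < 50, na.rm = TRUE))
  }
})

test_that("viability counts follow the configured binomial design", {
  cfg <- sim_config(seed = 9, n_lines = 1, temperatures = 25,
                    progeny_range = c(10000, 10000))
  v1 <- generate_viability(cfg)
  v2 <- generate_viability(cfg)
  expect_identical(v1, v2)
  # at n = 10,000 the het/hom ratio concentrates near 2
  ratios <- vapply(1:50, function(s) {
    v <- generate_viability(sim_config(seed = s, n_lines = 1,
                                       temperatures = 25,
                                       progeny_range = c(10000, 10000)))
    v$n_het / v$n_hom
  }, numeric(1))
  expect_gte(mean(abs(ratios - 2) <= 0.1), 0.95)
  # lethal configuration depresses homozygote counts
  lethal <- generate_viability(sim_config(
    seed = 9, n_lines = 2, temperatures = 25,
    progeny_range = c(500, 500), lethal_lines = "KO_line_02"))
  expect_gt(lethal$n_hom[lethal$line == "KO_line_01"],
            3 * lethal$n_hom[lethal$line == "KO_line_02"])
})

test_that("an infeasible gene load is rejected", {
  expect_error(generate_annotation(sim_config(seed = 1, n_pcg = 5000)),
               "infeasible")
})

test_that("the written bundle round-trips through the readers", {
  b <- shared_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back <- read_bundle(dir)
  cols <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  expect_equal(dplyr::arrange(back$candidates[cols], transcript_id, start),
               dplyr::arrange(b$candidates[cols], transcript_id, start))
  expect_equal(expr_matrix(back$expr_tx), expr_matrix(b$expr_tx),
               tolerance = 1e-9)
  expect_equal(back$viability, b$viability)
  expect_equal(back$conserved$score, b$conserved$score)
  expect_equal(sort(names(back$sequences)), sort(names(b$sequences)))
  # cascade accepts the re-read bundle
  res <- run_cascade(back)
  expect_gt(nrow(res$hq), 0)
})
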