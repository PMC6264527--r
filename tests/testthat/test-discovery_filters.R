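# Unit fixtures per cascade stage; the planted-truth recovery runs in the
# acceptance suite.

ref_pcg <- function() {
  # plus-strand PCG with two exons and a large intron
  mk_tx("PCG1.t1", "PCG1", "+", c(10000, 10400), c(13000, 13400),
        provenance = "reference", biotype = "protein_coding")
}

test_that("annotated-overlap filter uses same-strand single-nucleotide rule", {
  ref <- ref_pcg()
  cands <- dplyr::bind_rows(
    mk_tx("same.t1", "same", "+", c(10400, 11000)),    # 1-nt exon overlap
    mk_tx("anti.t1", "anti", "-", c(10000, 10400)),    # antisense only
    mk_tx("inter.t1", "inter", "+", c(20000, 20600))   # intergenic
  )
  res <- filter_annotated_overlap(cands, ref)
  expect_equal(sort(unique(res$retained$gene_id)), c("anti", "inter"))
  expect_equal(res$removed$reason, "annotated_same_strand_overlap")
})

test_that("intronic filter removes intron-contained genes unless antisense-supported", {
  ref <- dplyr::bind_rows(
    ref_pcg(),
    # nested antisense gene inside the PCG intron
    mk_tx("NEST.t1", "NEST", "-", c(11000, 11500),
          provenance = "reference", biotype = "protein_coding"))
  cands <- dplyr::bind_rows(
    mk_tx("in.t1", "in", "+", c(12000, 12600)),       # intron, same strand
    mk_tx("anti.t1", "anti", "+", c(11100, 11700)),   # overlaps NEST antisense
    mk_tx("half.t1", "half", "+", c(12500, 12800), c(15000, 15200)))
  res <- filter_intronic(cands, ref)
  expect_equal(res$removed$gene_id, "in")
  expect_true(all(c("anti", "half") %in% res$retained$gene_id))
})

test_that("monoexonic rules: unstranded, strand ratio 0.8, length 500", {
  cands <- dplyr::bind_rows(
    mk_tx("dot.t1", "dot", ".", c(1000, 1600)),
    mk_tx("ok.t1", "ok", "+", c(3000, 3600)),
    mk_tx("low.t1", "low", "+", c(5000, 5600)),
    mk_tx("none.t1", "none", "+", c(7000, 7600)),
    mk_tx("short.t1", "short", "+", c(9000, 9498)),    # 499 nt
    mk_tx("edge.t1", "edge", "+", c(11000, 11499)),    # exactly 500 nt
    mk_tx("multi.t1", "multi", "+", c(13000, 13100), c(13300, 13380)))
  sc <- tibble::tibble(
    transcript_id = c("ok.t1", "low.t1", "short.t1", "edge.t1"),
    condition = "Meso_34",
    sense_reads = c(8L, 7L, 9L, 9L),
    antisense_reads = c(2L, 3L, 1L, 1L))
  res <- filter_monoexonic(cands, sc)
  reasons <- setNames(res$removed$reason, res$removed$transcript_id)
  expect_equal(unname(reasons["dot.t1"]), "ambiguous_unstranded")
  expect_equal(unname(reasons["low.t1"]), "strand_ratio")   # 0.7 < 0.8
  expect_equal(unname(reasons["none.t1"]), "no_strand_support")
  expect_equal(unname(reasons["short.t1"]), "short_monoexonic")
  expect_true(all(c("ok.t1", "edge.t1", "multi.t1") %in%
                    res$retained$transcript_id))  # ratio 0.8 kept, 500 kept
})

test_that("basic filter removes blacklisted chromosomes and short models", {
  cands <- dplyr::bind_rows(
    mk_tx("u.t1", "u", "+", c(1000, 2000), chrom = "U"),
    mk_tx("s.t1", "s", "+", c(1000, 1198)),             # 199 nt
    mk_tx("k.t1", "k", "+", c(3000, 3199)))             # exactly 200 nt
  res <- filter_basic(cands)
  expect_setequal(res$removed$transcript_id, c("u.t1", "s.t1"))
  expect_equal(res$retained$transcript_id, "k.t1")
})

test_that("expression filter keeps FPKM >= 2 in any condition", {
  cands <- dplyr::bind_rows(
    mk_tx("a.t1", "a", "+", c(1000, 2000)),
    mk_tx("b.t1", "b", "+", c(3000, 4000)),
    mk_tx("c.t1", "c", "+", c(5000, 6000)),
    mk_tx("d.t1", "d", "+", c(7000, 8000)))
  expr <- mk_expr(c("a", "b", "c"),
                  c1 = c(2.0, 1.9, 0), c2 = c(0.5, 1.0, 0))
  res <- filter_expression(cands, expr)
  expect_equal(res$retained$gene_id, "a")
  reasons <- setNames(res$removed$reason, res$removed$gene_id)
  expect_equal(unname(reasons["b"]), "low_expression")
  expect_equal(unname(reasons["c"]), "low_expression")
  expect_equal(unname(reasons["d"]), "no_expression_record")
})

test_that("repeat filter is base-exact with a strict 90% boundary", {
  cands <- dplyr::bind_rows(
    mk_tx("x91.t1", "x91", "+", c(1, 1000)),
    mk_tx("x90.t1", "x90", "+", c(2001, 3000)),
    mk_tx("x0.t1", "x0", "+", c(5001, 6000)))
  mask <- tibble::tibble(chrom = "chr1",
                         start = c(1, 2001), end = c(910, 2900))
  res <- filter_repeats(cands, mask)
  expect_equal(res$removed$transcript_id, "x91.t1")       # 0.91 > 0.9
  expect_true(all(c("x90.t1", "x0.t1") %in%
                    res$retained$transcript_id))          # 0.90 kept

  set.seed(23)
  for (i in 1:100) {
    tx <- rand_tx("r", "gr", origin = sample(1:5000, 1))
    m <- tibble::tibble(
      chrom = "chr1",
      start = sample(1:6000, 5))
    m$end <- m$start + sample(50:400, 5, replace = TRUE)
    frac <- lncdiscover:::masked_fraction(tx, m)
    expect_equal(unname(frac), oracle_masked_fraction(tx, m),
                 tolerance = 1e-12)
  }
})

test_that("isoform de-duplication removes the smaller of near-identical pairs", {
  # identical pair: one survivor
  two <- dplyr::bind_rows(mk_tx("g.t1", "g", "+", c(1, 1000)),
                          mk_tx("g.t2", "g", "+", c(1, 1000)))
  res <- dedup_isoforms(two)
  expect_equal(nrow(res$removed), 1)
  # Jaccard exactly 0.95: both retained (strict threshold)
  pair95 <- dplyr::bind_rows(mk_tx("h.t1", "h", "+", c(1, 1000)),
                             mk_tx("h.t2", "h", "+", c(1, 950)))
  expect_equal(jaccard_similarity(pair95[1, ], pair95[2, ]), 0.95)
  res <- dedup_isoforms(pair95)
  expect_equal(nrow(res$removed), 0)
  # three mutually near-identical: only the longest survives
  three <- dplyr::bind_rows(mk_tx("k.t1", "k", "+", c(1, 1000)),
                            mk_tx("k.t2", "k", "+", c(1, 990)),
                            mk_tx("k.t3", "k", "+", c(1, 980)))
  res <- dedup_isoforms(three)
  expect_equal(res$retained$transcript_id, "k.t1")
})

test_that("nuclear-ratio filter removes intron-embedded nuclear transcripts", {
  ref <- dplyr::bind_rows(
    ref_pcg(),
    mk_tx("NEST.t1", "NEST", "-", c(11000, 11500),
          provenance = "reference", biotype = "protein_coding"))
  cands <- dplyr::bind_rows(
    mk_tx("hot.t1", "hot", "+", c(11100, 11800)),   # in intron, antisense ok
    mk_tx("cold.t1", "cold", "+", c(11900, 12600)),
    mk_tx("edge.t1", "edge", "+", c(11050, 11750)))
  expr <- mk_expr(c("hot.t1", "cold.t1", "edge.t1"),
                  Nuclear_34 = c(4.2, 1.0, 3.9),
                  Meso_34 = c(1.0, 1.0, 1.9),
                  Nuclear_68 = c(0.9, 2.0, 0.9),
                  Meso_68 = c(1.0, 2.0, 1.0),
                  level = "transcript")
  res <- filter_nuclear_ratio(cands, ref, expr)
  # log2(4.3/1.1) = 1.97 -> removed; equal -> kept;
  # (3.9+0.1)/(1.9+0.1) = 2 exactly (log2 = 1, strict) -> kept
  expect_equal(res$removed$transcript_id, "hot.t1")
  expect_true(all(c("cold.t1", "edge.t1") %in%
                    res$retained$transcript_id))
  expect_error(
    filter_nuclear_ratio(cands, ref, mk_expr("hot.t1", Meso_34 = 1,
                                             level = "transcript")),
    "missing condition")
})

test_that("read-through flagging is strand- and gap-aware", {
  ref <- ref_pcg()   # TES at 13400, strand +
  expr <- mk_expr("PCG1", c1 = 10)
  cands <- dplyr::bind_rows(
    mk_tx("rt.t1", "rt", "+", c(13500, 14200)),    # gap 100
    mk_tx("anti.t1", "anti", "-", c(13500, 14200)),
    mk_tx("far.t1", "far", "+", c(13901, 14600)))  # gap 501
  res <- flag_readthrough(cands, ref, expr)
  expect_equal(res$flags$transcript_id, "rt.t1")
  expect_equal(nrow(res$removed), 0)               # flag-only by default
  res2 <- flag_readthrough(cands, ref, expr, drop = TRUE)
  expect_equal(res2$removed$transcript_id, "rt.t1")
  # silent PCG never triggers the flag
  res3 <- flag_readthrough(cands, ref, mk_expr("PCG1", c1 = 0.5))
  expect_equal(nrow(res3$flags), 0)
})

test_that("DE partition separates main, constitutive and dropped genes", {
  ref <- ref_pcg()
  cands <- dplyr::bind_rows(
    mk_tx("de.t1", "de", "+", c(20000, 21000)),
    mk_tx("hi.t1", "hi", "+", c(23000, 24000)),
    mk_tx("lo.t1", "lo", "+", c(26000, 27000)))
  de <- tibble::tibble(
    comparison = "S34_VS_S46",
    gene_id = c("de", "hi", "lo"),
    log2fc = c(2, 0, 0),
    padj = c(0.005, 0.5, 0.5))
  expr <- mk_expr(c("de", "hi", "lo"), c1 = c(10, 3.0, 2.5))
  res <- partition_by_de(cands, ref, de, expr)
  expect_equal(res$main_genes, "de")
  expect_equal(res$constitutive_genes, "hi")     # FPKM exactly 3 kept
  expect_equal(res$removed$gene_id, "lo")
})

test_that("TSS refinement honours tag, distance and inward-fraction limits", {
  cage <- function(pos, count, strand = "+") {
    tibble::tibble(chrom = "chr1", pos = pos, strand = strand,
                   count = count)
  }
  tx <- mk_tx("t.t1", "t", "+", c(5000, 5999))       # L = 1000, TSS 5000
  # 50-tag peak 100 nt upstream: extended by 100
  r <- refine_tss(tx, cage(4900, 50))
  expect_equal(r$record$direction, "extended")
  expect_equal(r$record$new_tss, 4900)
  expect_equal(r$exons$start[1], 4900)
  # 49 tags never move a TSS
  r <- refine_tss(tx, cage(4900, 49))
  expect_equal(r$record$direction, "unchanged")
  # 900 nt upstream is outside the 800-nt window
  r <- refine_tss(tx, cage(4100, 500))
  expect_equal(r$record$direction, "unchanged")
  # 350 nt inward exceeds 0.3 x L = 300
  r <- refine_tss(tx, cage(5350, 500))
  expect_equal(r$record$direction, "unchanged")
  # 250 nt inward is clipped to
  r <- refine_tss(tx, cage(5250, 500))
  expect_equal(r$record$direction, "clipped")
  expect_equal(r$exons$start[1], 5250)
  # opposite-strand peaks are ignored
  r <- refine_tss(tx, cage(4900, 500, strand = "-"))
  expect_equal(r$record$direction, "unchanged")
  # upstream wins an exact distance tie
  r <- refine_tss(tx, cage(c(4900, 5100), c(60, 60)))
  expect_equal(r$record$new_tss, 4900)
  # minus-strand transcript mirrors the geometry
  txm <- mk_tx("m.t1", "m", "-", c(5000, 5999))      # TSS 5999
  r <- refine_tss(txm, cage(6100, 60, strand = "-"))
  expect_equal(r$record$direction, "extended")
  expect_equal(r$exons$end[1], 6100)
})

test_that("TSS refinement never exceeds its window and is idempotent", {
  set.seed(31)
  for (i in 1:50) {
    tx <- rand_tx("t", "g", n_exons = sample(1:3, 1), origin = 20000)
    L <- tx_info(tx)$length
    cage <- tibble::tibble(
      chrom = "chr1",
      pos = sample(18000:23000, 20),
      strand = sample(c("+", "-"), 20, replace = TRUE),
      count = sample(10:200, 20, replace = TRUE))
    r <- refine_tss(tx, cage)
    expect_lte(r$record$nt_moved, max(800, floor(0.3 * L)))
    # re-refining from the refined model with its peak present is stable
    r2 <- refine_tss(r$exons, cage)
    if (r$record$direction != "unchanged") {
      expect_equal(r2$record$new_tss, r$record$new_tss)
    }
    # the refined first exon is never empty
    expect_true(all(r$exons$end >= r$exons$start))
  }
})

test_that("cascade conserves counts at every stage and handles empties", {
  b <- shared_bundle()
  res <- run_cascade(b)
  expect_true(all(res$report$n_input ==
                    res$report$n_retained + res$report$n_removed))
  # stage chaining: each stage's input is the previous stage's output
  expect_true(all(res$report$n_input[-1] ==
                    res$report$n_retained[-nrow(res$report)]))
  expect_equal(res$report$stage[1], "annotated_overlap")
  expect_equal(res$report$stage[nrow(res$report)], "de_partition")

  empty <- b
  empty$candidates <- b$candidates[0, ]
  res0 <- run_cascade(empty)
  expect_equal(nrow(res0$hq), 0)
  expect_true(all(res0$report$n_input == 0))

  no_rep <- b
  no_rep$repeats <- NULL
  expect_error(run_cascade(no_rep), "repeats")
  expect_error(cascade_config(bogus_threshold = 1), "unknown cascade")
})
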