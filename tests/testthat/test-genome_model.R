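test_that("GTF coordinates are 1-based inclusive and round-trip", {
  path <- withr::local_tempfile(fileext = ".gtf")
  ex <- mk_tx("t1", "g1", "+", c(101, 200))
  write_gtf(ex, path)
  back <- read_gtf(path)
  expect_equal(back$start, 101)
  expect_equal(back$end, 200)
  expect_equal(tx_info(back)$length, 100)

  # two transcripts sharing a gene id collapse into one gene model
  ex2 <- dplyr::bind_rows(mk_tx("t1", "g1", "+", c(101, 200)),
                          mk_tx("t2", "g1", "+", c(101, 150), c(300, 400)))
  write_gtf(ex2, path)
  gi <- gene_info(read_gtf(path))
  expect_equal(nrow(gi), 1)
  expect_equal(gi$n_tx, 2)
})

test_that("GTF round-trip is the identity on random models", {
  set.seed(7)
  models <- dplyr::bind_rows(lapply(1:100, function(i) {
    rand_tx(sprintf("t%03d", i), sprintf("g%03d", i),
            chrom = sample(c("chr1", "chr2"), 1),
            origin = 1000 + 600 * i)
  }))
  models <- as_exon_tbl(models)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(models, path)
  back <- read_gtf(path)
  cols <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  expect_equal(dplyr::arrange(back[cols], transcript_id, start),
               dplyr::arrange(models[cols], transcript_id, start))
  # writing the re-read models gives byte-identical output
  path2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("exon table invariants are enforced", {
  expect_error(as_exon_tbl(mk_tx("t1", "g1", "+", c(100, 50))),
               "start <= end")
  mixed <- dplyr::bind_rows(mk_tx("t1", "g1", "+", c(1, 100)),
                            mk_tx("t1", "g1", "-", c(200, 300)))
  expect_error(as_exon_tbl(mixed), "mixed")
  multi_dot <- mk_tx("t1", "g1", ".", c(1, 100), c(200, 300))
  expect_error(as_exon_tbl(multi_dot), "monoexonic")
  overlapping <- mk_tx("t1", "g1", "+", c(1, 100), c(50, 150))
  expect_error(as_exon_tbl(overlapping), "overlapping")
})

test_that("tx_info computes strand-aware TSS/TES", {
  plus <- tx_info(mk_tx("t1", "g1", "+", c(100, 200), c(300, 400)))
  expect_equal(plus$tss, 100)
  expect_equal(plus$tes, 400)
  minus <- tx_info(mk_tx("t2", "g2", "-", c(100, 200), c(300, 400)))
  expect_equal(minus$tss, 400)
  expect_equal(minus$tes, 100)
})

test_that("exonic overlap matches spec examples and the per-base oracle", {
  a <- mk_tx("a", "ga", "+", c(1, 100))
  b <- mk_tx("b", "gb", "+", c(101, 200))
  expect_equal(exonic_overlap_length(a, b), 0)          # abutting, no touch
  expect_equal(exonic_overlap_length(a, a), 100)        # identical
  c <- mk_tx("c", "gc", "+", c(51, 150))
  expect_equal(exonic_overlap_length(a, c), 50)
  d <- mk_tx("d", "gd", "-", c(51, 150))
  expect_equal(exonic_overlap_length(a, d, stranded = TRUE), 0)

  set.seed(11)
  for (i in 1:100) {
    x <- rand_tx("x", "gx", origin = sample(1:3000, 1))
    y <- rand_tx("y", "gy", origin = sample(1:3000, 1))
    ov <- exonic_overlap_length(x, y)
    expect_equal(ov, oracle_overlap_len(x, y))
    expect_equal(ov, exonic_overlap_length(y, x))       # symmetric
    expect_lte(ov, min(tx_info(x)$length, tx_info(y)$length))
  }
})

test_that("Jaccard similarity matches examples and oracle", {
  a <- mk_tx("a", "ga", "+", c(1, 100))
  expect_equal(jaccard_similarity(a, a), 1)
  b <- mk_tx("b", "gb", "+", c(500, 600))
  expect_equal(jaccard_similarity(a, b), 0)
  c <- mk_tx("c", "gc", "+", c(51, 150))
  expect_equal(jaccard_similarity(a, c), 50 / 150, tolerance = 1e-12)

  set.seed(13)
  for (i in 1:100) {
    x <- rand_tx("x", "gx", strand = "+", origin = sample(1:2000, 1))
    y <- rand_tx("y", "gy", strand = "+", origin = sample(1:2000, 1))
    j <- jaccard_similarity(x, y)
    expect_equal(j, oracle_jaccard(x, y))
    expect_equal(j, jaccard_similarity(y, x))
    ident <- setequal(oracle_base_set(x), oracle_base_set(y))
    expect_equal(j == 1, ident)
  }
})

test_that("closest_gene picks minimal span gap with documented tie-break", {
  genes <- dplyr::bind_rows(
    mk_tx("q.t1", "q", "+", c(10000, 11000)),
    mk_tx("a.t1", "a", "+", c(10500, 10600)),   # overlapping
    mk_tx("b.t1", "b", "+", c(11501, 11600)),   # gap 500
    mk_tx("c.t1", "c", "-", c(13001, 13500))    # gap 2000
  )
  hit <- closest_gene("q", genes, c("a", "b", "c"))
  expect_equal(hit$gene_id, "a")
  expect_equal(hit$distance, 0)
  hit <- closest_gene("q", genes, c("b", "c"))
  expect_equal(hit$gene_id, "b")
  expect_equal(hit$distance, 501)
  hit <- closest_gene("q", genes, c("a", "b", "c"), allow_overlap = FALSE)
  expect_equal(hit$gene_id, "b")
  # symmetric tie resolves to the lower-coordinate candidate
  genes2 <- dplyr::bind_rows(
    mk_tx("q.t1", "q", "+", c(5000, 6000)),
    mk_tx("l.t1", "l", "+", c(3900, 4500)),
    mk_tx("r.t1", "r", "+", c(6500, 7100))
  )
  hit <- closest_gene("q", genes2, c("l", "r"))
  expect_equal(hit$gene_id, "l")
  # no candidate on the query chromosome -> empty sentinel
  none <- closest_gene("q", dplyr::bind_rows(
    mk_tx("q.t1", "q", "+", c(5000, 6000)),
    mk_tx("z.t1", "z", "+", c(100, 200), chrom = "chr9")), "z")
  expect_equal(nrow(none), 0)
})

test_that("BH adjustment validates input and matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.4, 5)), rep(0.4, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.1)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    sorted <- sort(p)
    expect_true(all(diff(bh_adjust(sorted)) >= -1e-12))
  }
})

test_that("FPKM computation follows the closed form and scaling", {
  expect_equal(compute_fpkm(1000, 1000, 1e6), 1000)
  expect_equal(compute_fpkm(0, 500, 1e6), 0)
  f1 <- compute_fpkm(c(10, 20), c(100, 200), 1e6)
  f2 <- compute_fpkm(c(10, 20), c(100, 200), 2e6)
  expect_equal(f1 / f2, c(2, 2))
  expect_error(compute_fpkm(10, 100, 0), "library")
  expect_error(compute_fpkm(10, 0, 1e6), "length")
  m <- matrix(c(100, 200, 300, 400), 2,
              dimnames = list(NULL, c("c1", "c2")))
  f <- compute_fpkm(m, c(1000, 2000), c(1e6, 2e6))
  expect_equal(unname(f[1, 1]), 100 * 1e9 / (1000 * 1e6))
  expect_equal(unname(f[2, 2]), 400 * 1e9 / (2000 * 2e6))
})

test_that("expression tables validate and aggregate to gene level", {
  expect_error(expression_table("a", matrix(-1, 1, 1,
                                            dimnames = list(NULL, "c"))),
               "non-negative")
  e <- mk_expr(c("t1", "t2", "t3"), c1 = c(1, 2, 4), c2 = c(0, 1, 1),
               level = "transcript")
  g <- expr_to_gene_level(e, tibble::tibble(
    transcript_id = c("t1", "t2", "t3"), gene_id = c("g1", "g1", "g2")))
  m <- expr_matrix(g)
  expect_equal(m["g1", "c1"], 3)
  expect_equal(m["g2", "c2"], 1)
  expect_error(expr_matrix(e, "nope"), "unknown condition")
})
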