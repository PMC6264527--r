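#' @importFrom dplyr %>% arrange bind_rows distinct filter group_by left_join
#'   mutate n rename select slice summarise ungroup across all_of first desc
#'   inner_join anti_join semi_join pull row_number if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom stats p.adjust
NULL

# Exon tables ------------------------------------------------------------
#
# The package's central container is the "exon table": one row per exon with
# columns chrom, start, end, strand, transcript_id, gene_id and optionally
# provenance ("reference" or "assembled") and biotype. Coordinates are
# 1-based inclusive (GTF/GRanges native); an exon [101, 200] has length 100.

exon_required_cols <- c("chrom", "start", "end", "strand",
                        "transcript_id", "gene_id")

#' Validate and normalise an exon table
#'
#' Checks the invariants every downstream operation relies on: positive
#' 1-based inclusive coordinates, strand in `+`/`-`/`.` (with `.` permitted
#' only for monoexonic transcripts), and per-transcript exons on a single
#' chromosome and strand, sorted and pairwise disjoint.
#'
#' @param exons A data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `transcript_id`, `gene_id` (optionally `provenance`, `biotype`).
#' @return A tibble with exons sorted by chromosome, transcript and start.
#' @export
as_exon_tbl <- function(exons) {
  exons <- as_tibble(exons)
  missing <- setdiff(exon_required_cols, names(exons))
  if (length(missing) > 0) {
    stop("exon table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"provenance" %in% names(exons)) exons$provenance <- "assembled"
  if (!"biotype" %in% names(exons)) exons$biotype <- "other"
  if (any(exons$start < 1) || any(exons$end < exons$start)) {
    stop("exon coordinates must satisfy 1 <= start <= end")
  }
  if (!all(exons$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  exons <- arrange(exons, .data$chrom, .data$transcript_id, .data$start)
  chk <- exons %>%
    group_by(.data$transcript_id) %>%
    summarise(
      n_chrom = dplyr::n_distinct(.data$chrom),
      n_strand = dplyr::n_distinct(.data$strand),
      n_exons = n(),
      unstranded = any(.data$strand == "."),
      disjoint = all(.data$start[-1] > .data$end[-n()]) || n() == 1,
      .groups = "drop"
    )
  bad <- chk$transcript_id[chk$n_chrom > 1 | chk$n_strand > 1]
  if (length(bad) > 0) {
    stop("transcripts with exons on mixed chromosomes or strands: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- chk$transcript_id[!chk$disjoint]
  if (length(bad) > 0) {
    stop("transcripts with overlapping exons: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- chk$transcript_id[chk$unstranded & chk$n_exons > 1]
  if (length(bad) > 0) {
    stop("strand '.' is only permitted for monoexonic transcripts: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  exons
}

#' Per-transcript summary of an exon table
#'
#' @param exons An exon table (see [as_exon_tbl()]).
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `n_exons`, `length` (sum of exon lengths), span
#'   `start`/`end`, and strand-aware `tss`/`tes`.
#' @export
tx_info <- function(exons) {
  if (nrow(exons) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  chrom = character(), strand = character(),
                  n_exons = integer(), length = integer(),
                  start = integer(), end = integer(),
                  tss = integer(), tes = integer()))
  }
  exons %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = first(.data$gene_id),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      n_exons = n(),
      length = sum(.data$end - .data$start + 1),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    ) %>%
    mutate(
      tss = if_else(.data$strand == "-", .data$end, .data$start),
      tes = if_else(.data$strand == "-", .data$start, .data$end)
    )
}

#' Per-gene summary (span over all isoforms, longest isoform id)
#'
#' @param exons An exon table.
#' @return One row per gene: chrom, strand, span `start`/`end`, number of
#'   transcripts, and `longest_tx` (longest isoform, ties broken by id).
#' @export
gene_info <- function(exons) {
  tx <- tx_info(exons)
  tx %>%
    group_by(.data$gene_id) %>%
    arrange(desc(.data$length), .data$transcript_id, .by_group = TRUE) %>%
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      start = min(.data$start),
      end = max(.data$end),
      n_tx = n(),
      longest_tx = first(.data$transcript_id),
      longest_length = first(.data$length),
      .groups = "drop"
    )
}

# Restrict an exon table to the longest isoform of each gene.
longest_isoforms <- function(exons) {
  gi <- gene_info(exons)
  exons %>% filter(.data$transcript_id %in% gi$longest_tx)
}

# findOverlaps with the benign disjoint-seqlevels warning silenced
find_ov <- function(...) {
  suppressWarnings(GenomicRanges::findOverlaps(...))
}

# GRanges conversion used by the bulk overlap machinery.
exons_granges <- function(exons) {
  GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = ifelse(exons$strand == ".", "*", exons$strand),
    transcript_id = exons$transcript_id,
    gene_id = exons$gene_id
  )
}

# Intron table: one row per intron (gap between consecutive exons of a
# transcript), 1-based inclusive.
introns_tbl <- function(exons) {
  exons %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    filter(n() > 1) %>%
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      gene_id = first(.data$gene_id),
      istart = list(.data$end[-n()] + 1),
      iend = list(.data$start[-1] - 1),
      .groups = "drop"
    ) %>%
    tidyr::unnest(c("istart", "iend")) %>%
    rename(start = "istart", end = "iend") %>%
    filter(.data$end >= .data$start)
}

# GTF I/O ----------------------------------------------------------------

#' Read transcript models from a GTF file
#'
#' Uses rtracklayer for parsing; only `exon` features are used to build
#' transcript models. Transcripts with exons on mixed strands, or malformed
#' GTF lines, raise an error.
#'
#' @param path Path to a GTF file with `gene_id`/`transcript_id` attributes.
#' @return A validated exon table.
#' @export
read_gtf <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", path, "': ",
                             conditionMessage(e))
  )
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("GTF '", path, "' contains no exon features")
  tbl <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    provenance = if (!is.null(gr$provenance)) gr$provenance else "assembled",
    biotype = if (!is.null(gr$biotype)) gr$biotype else "other"
  ) %>%
    mutate(strand = if_else(.data$strand == "*", ".", .data$strand))
  as_exon_tbl(tbl)
}

#' Write transcript models to a GTF file
#'
#' Emits one `exon` feature per exon row, with `gene_id`, `transcript_id`,
#' `provenance` and `biotype` attributes, in a deterministic order so that
#' identical models produce byte-identical files.
#'
#' @param exons An exon table.
#' @param path Output path.
#' @param source Value of the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path, source = "lncdiscover") {
  exons <- as_exon_tbl(exons)
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = ifelse(exons$strand == ".", "*", exons$strand),
    type = "exon",
    source = source,
    gene_id = exons$gene_id,
    transcript_id = exons$transcript_id,
    provenance = exons$provenance,
    biotype = exons$biotype
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# Interval operations ----------------------------------------------------

# Total number of bases shared by two sets of 1-based inclusive intervals
# on one chromosome.
ranges_intersect_len <- function(s1, e1, s2, e2) {
  ir1 <- IRanges::reduce(IRanges::IRanges(s1, e1))
  ir2 <- IRanges::reduce(IRanges::IRanges(s2, e2))
  sum(IRanges::width(IRanges::intersect(ir1, ir2)))
}

#' Exonic overlap between two transcripts, in nucleotides
#'
#' @param a,b Exon tables each containing a single transcript.
#' @param stranded If `TRUE`, transcripts on different strands overlap by 0.
#' @return Number of bases in the intersection of the exonic base sets.
#' @export
exonic_overlap_length <- function(a, b, stranded = FALSE) {
  if (a$chrom[1] != b$chrom[1]) return(0L)
  if (stranded && a$strand[1] != b$strand[1]) return(0L)
  as.integer(ranges_intersect_len(a$start, a$end, b$start, b$end))
}

#' Jaccard similarity of two transcripts' exonic base sets
#'
#' Intersection over union of exonic bases; 0 when the transcripts are on
#' different chromosomes or strands. This is the quantity thresholded (at
#' 0.95, strict) during isoform de-duplication.
#'
#' @param a,b Exon tables each containing a single transcript.
#' @return A fraction in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  if (a$chrom[1] != b$chrom[1] || a$strand[1] != b$strand[1]) return(0)
  inter <- ranges_intersect_len(a$start, a$end, b$start, b$end)
  ir <- IRanges::reduce(IRanges::IRanges(c(a$start, b$start),
                                         c(a$end, b$end)))
  uni <- sum(IRanges::width(ir))
  inter / uni
}

#' Closest gene to a query gene
#'
#' Distances are measured between gene spans of the longest isoform per
#' gene. Overlapping spans have distance 0. Ties are broken by lower start
#' coordinate, then lexicographic gene id.
#'
#' @param query_gene Gene id of the query.
#' @param genes Exon table containing the query and candidate genes.
#' @param candidates Character vector of candidate gene ids.
#' @param allow_overlap If `FALSE`, candidates whose spans overlap the query
#'   are excluded before choosing the closest.
#' @return A one-row tibble with `gene_id`, `distance` (gap in nt, 0 if
#'   overlapping) and `sign` (+1 candidate downstream in genomic
#'   coordinates, -1 upstream, 0 overlapping), or a zero-row tibble when no
#'   candidate is on the query's chromosome.
#' @export
closest_gene <- function(query_gene, genes, candidates,
                         allow_overlap = TRUE) {
  gi <- gene_info(longest_isoforms(genes))
  q <- gi %>% filter(.data$gene_id == query_gene)
  if (nrow(q) != 1) stop("query gene not found: ", query_gene)
  cand <- gi %>%
    filter(.data$gene_id %in% candidates,
           .data$gene_id != query_gene,
           .data$chrom == q$chrom)
  empty <- tibble(gene_id = character(), distance = integer(),
                  sign = integer())
  if (nrow(cand) == 0) return(empty)
  cand <- cand %>%
    mutate(
      distance = pmax(0L, .data$start - q$end, q$start - .data$end),
      sign = dplyr::case_when(
        .data$distance == 0L ~ 0L,
        .data$start > q$end ~ 1L,
        TRUE ~ -1L
      )
    )
  if (!allow_overlap) cand <- cand %>% filter(.data$distance > 0L)
  if (nrow(cand) == 0) return(empty)
  cand %>%
    arrange(.data$distance, .data$start, .data$gene_id) %>%
    slice(1) %>%
    select("gene_id", "distance", "sign")
}

# Shared statistics ------------------------------------------------------

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`; input order
#' is preserved.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must be in [0, 1] and non-missing")
  }
  p.adjust(pvalues, method = "BH")
}

#' FPKM from raw counts
#'
#' FPKM = count x 1e9 / (length x library size).
#'
#' @param counts Matrix (features x conditions) or vector of read counts.
#' @param lengths Feature lengths in nt (> 0).
#' @param library_sizes Mapped reads per condition (> 0); recycled for a
#'   vector `counts`.
#' @return FPKM values with the shape of `counts`.
#' @export
compute_fpkm <- function(counts, lengths, library_sizes) {
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (is.matrix(counts)) {
    if (length(lengths) != nrow(counts)) {
      stop("lengths must match rows of counts")
    }
    if (length(library_sizes) != ncol(counts)) {
      stop("library_sizes must match columns of counts")
    }
    sweep(counts * 1e9 / lengths, 2, library_sizes, "/")
  } else {
    counts * 1e9 / (lengths * library_sizes)
  }
}

# Expression tables ------------------------------------------------------
#
# An expression table is a tibble with a `feature_id` column and one numeric
# column per named condition, plus a "level" attribute ("transcript" or
# "gene").

#' Construct an expression table
#'
#' @param feature_id Character vector of feature ids.
#' @param fpkm Matrix of FPKM values (features x conditions), with condition
#'   names as column names.
#' @param level `"transcript"` or `"gene"`.
#' @return A tibble with attribute `level`.
#' @export
expression_table <- function(feature_id, fpkm, level = "transcript") {
  if (is.null(colnames(fpkm)) || anyDuplicated(colnames(fpkm))) {
    stop("fpkm must have unique condition column names")
  }
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  out <- dplyr::bind_cols(tibble(feature_id = feature_id),
                          as_tibble(fpkm))
  attr(out, "level") <- match.arg(level, c("transcript", "gene"))
  out
}

#' Condition columns of an expression table
#' @param expr An expression table.
#' @return Character vector of condition names.
#' @export
expr_conditions <- function(expr) setdiff(names(expr), "feature_id")

#' Expression table as a plain matrix (features x conditions)
#' @param expr An expression table.
#' @param conditions Conditions to keep (default all).
#' @return Numeric matrix with feature ids as rownames.
#' @export
expr_matrix <- function(expr, conditions = expr_conditions(expr)) {
  missing <- setdiff(conditions, names(expr))
  if (length(missing) > 0) {
    stop("unknown condition name(s): ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(expr[, conditions, drop = FALSE])
  rownames(m) <- expr$feature_id
  m
}

#' Aggregate a transcript-level expression table to gene level
#'
#' Gene FPKM is the sum of its transcripts' FPKM.
#'
#' @param expr Transcript-level expression table.
#' @param tx2gene Tibble with `transcript_id`, `gene_id`.
#' @return Gene-level expression table.
#' @export
expr_to_gene_level <- function(expr, tx2gene) {
  conds <- expr_conditions(expr)
  out <- expr %>%
    inner_join(tx2gene, by = c(feature_id = "transcript_id")) %>%
    group_by(.data$gene_id) %>%
    summarise(across(all_of(conds), sum), .groups = "drop") %>%
    rename(feature_id = "gene_id")
  attr(out, "level") <- "gene"
  out
}

#' @rdname expression_table
#' @param path TSV path (first column `feature_id`, one column per
#'   condition).
#' @export
read_expression <- function(path, level = "transcript") {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  names(out)[1] <- "feature_id"
  attr(out, "level") <- match.arg(level, c("transcript", "gene"))
  out
}

#' @rdname expression_table
#' @param expr An expression table to write.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

# BED-like I/O -----------------------------------------------------------

#' Read a BED file of scored intervals
#'
#' @param path BED3/BED5/BED6 path (0-based half-open, converted to the
#'   package's 1-based inclusive convention).
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  out <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  names(out) <- cols[seq_len(ncol(out))]
  out$start <- out$start + 1L
  as_tibble(out)
}

#' Write intervals as BED
#'
#' @param x Tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  out <- tibble(
    chrom = x$chrom,
    start = x$start - 1L,
    end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
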