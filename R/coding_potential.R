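# ORF detection and the two-of-three coding-evidence vote.
#
# Three method families vote: a coding-probability score (CPAT-like, with
# published cut-off 0.39), protein/domain sequence similarity (BLAST-type
# E-value, cut-off 0.01; protein and domain hits count as one family), and
# phylogenetic codon conservation (PhyloCSF-type score, cut-off 20
# decibans). A transcript is called coding when at least two families pass.

#' Find ATG-to-stop open reading frames in the three forward frames
#'
#' Reports every maximal ORF (first ATG after the previous stop, through
#' the next in-frame stop codon); nested ATGs inside a longer ORF start
#' their own record. `N` bases break ORFs.
#'
#' @param sequence A character string over A/C/G/T/N.
#' @return Tibble sorted by length descending: `frame` (0..2), `start`,
#'   `end` (1-based nt offsets of ATG and stop-codon end), `length` in nt
#'   (multiple of 3).
#' @export
find_orfs <- function(sequence) {
  empty <- tibble(frame = integer(), start = integer(), end = integer(),
                  length = integer())
  n <- nchar(sequence)
  if (n < 6) return(empty)
  s <- toupper(sequence)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (f in 0:2) {
    starts <- seq.int(1 + f, n - 2, by = 3)
    codons <- substring(s, starts, starts + 2)
    valid <- !grepl("N", codons, fixed = TRUE)
    is_atg <- codons == "ATG" & valid
    is_stop <- codons %in% stops & valid
    # next in-frame stop (with no intervening N codon) for each position
    open <- integer()  # ATG codon indices awaiting a stop
    for (i in seq_along(codons)) {
      if (!valid[i]) {
        open <- integer()
      } else if (is_stop[i]) {
        for (a in open) {
          out[[length(out) + 1]] <- tibble(
            frame = f, start = starts[a], end = starts[i] + 2L,
            length = starts[i] + 3L - starts[a])
        }
        open <- integer()
      } else if (is_atg[i]) {
        open <- c(open, i)
      }
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) %>% arrange(desc(.data$length), .data$frame, .data$start)
}

#' Two-of-three coding-potential vote
#'
#' One vote per method family whose score passes its threshold (all
#' comparisons strict: a CPAT score of exactly 0.39 does not vote).
#' Protein-similarity and domain hits form a single family (the better
#' E-value is used). Absent scores contribute no vote.
#'
#' @param evidence Tibble with `transcript_id` and any of `cpat_score`,
#'   `blast_evalue`, `domain_evalue`, `phylocsf_score` (NA = absent).
#' @param cpat_threshold Coding-probability cut-off (default 0.39).
#' @param evalue_threshold Similarity E-value cut-off (default 0.01).
#' @param phylocsf_threshold Codon-conservation cut-off in decibans
#'   (default 20).
#' @param inclusive Use >= / <= at the thresholds instead of strict
#'   comparisons.
#' @return `evidence` with added `votes` (0..3) and `label`
#'   (`"coding"` when votes >= 2, `"noncoding_flagged"` for a single
#'   vote, else `"noncoding"`).
#' @export
classify_coding <- function(evidence, cpat_threshold = 0.39,
                            evalue_threshold = 0.01,
                            phylocsf_threshold = 20,
                            inclusive = FALSE) {
  get <- function(col) {
    if (col %in% names(evidence)) evidence[[col]] else
      rep(NA_real_, nrow(evidence))
  }
  cpat <- get("cpat_score")
  blast <- pmin(get("blast_evalue"), get("domain_evalue"), na.rm = TRUE)
  phylo <- get("phylocsf_score")
  gt <- if (inclusive) `>=` else `>`
  lt <- if (inclusive) `<=` else `<`
  v_cpat <- !is.na(cpat) & gt(cpat, cpat_threshold)
  v_blast <- !is.na(blast) & lt(blast, evalue_threshold)
  v_phylo <- !is.na(phylo) & gt(phylo, phylocsf_threshold)
  votes <- v_cpat + v_blast + v_phylo
  evidence %>%
    mutate(votes = as.integer(votes),
           label = dplyr::case_when(
             votes >= 2 ~ "coding",
             votes == 1 ~ "noncoding_flagged",
             TRUE ~ "noncoding"))
}

#' Sequence-composition coding score
#'
#' A deterministic logistic score standing in the CPAT slot when no
#' external coding-probability scores are supplied: a logistic combination
#' of the longest-ORF coverage of the transcript and the log ORF length,
#' calibrated on the synthetic generator's coding and noncoding
#' transcripts so that full-length-ORF sequences score above 0.9 and
#' random noncoding sequences score below the 0.39 voting threshold in the
#' large majority of draws.
#'
#' @param sequence A character string over A/C/G/T/N, length >= 200.
#' @return A fraction in \[0, 1\], monotone in ORF coverage.
#' @export
surrogate_coding_score <- function(sequence) {
  if (nchar(sequence) < 200) {
    stop("surrogate_coding_score requires sequences of at least 200 nt")
  }
  orfs <- find_orfs(sequence)
  if (nrow(orfs) == 0) return(stats::plogis(-12))
  lmax <- orfs$length[1]
  cov <- lmax / nchar(sequence)
  # calibration: midpoint at 65% ORF coverage, mild absolute-length term
  stats::plogis(12 * (cov - 0.65) + 0.5 * log2(lmax / 600))
}

#' Score and classify a set of transcripts
#'
#' Builds the evidence table from external scores where given (TSV
#' ingestion format: `transcript_id`, `method`, `score`) and falls back on
#' [surrogate_coding_score()] for the coding-probability family when a
#' sequence is available but no external score is.
#'
#' @param sequences Named character vector of transcript sequences.
#' @param scores Optional long tibble of external scores with `method` in
#'   `cpat`, `blastx`, `rpstblastn`, `phylocsf`.
#' @param ... Passed to [classify_coding()].
#' @return The classified evidence tibble (one row per transcript).
#' @export
coding_potential <- function(sequences, scores = NULL, ...) {
  ev <- tibble(transcript_id = names(sequences),
               cpat_score = NA_real_, blast_evalue = NA_real_,
               domain_evalue = NA_real_, phylocsf_score = NA_real_)
  if (!is.null(scores) && nrow(scores) > 0) {
    wide <- scores %>%
      mutate(method = tolower(.data$method)) %>%
      group_by(.data$transcript_id, .data$method) %>%
      summarise(score = if (first(.data$method) %in%
                            c("blastx", "rpstblastn"))
        min(.data$score) else max(.data$score), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "method", values_from = "score")
    idx <- match(ev$transcript_id, wide$transcript_id)
    pickcol <- function(col) {
      if (col %in% names(wide)) wide[[col]][idx] else
        rep(NA_real_, nrow(ev))
    }
    ev$cpat_score <- pickcol("cpat")
    ev$blast_evalue <- pickcol("blastx")
    ev$domain_evalue <- pickcol("rpstblastn")
    ev$phylocsf_score <- pickcol("phylocsf")
  }
  need <- is.na(ev$cpat_score)
  ev$cpat_score[need] <- vapply(sequences[ev$transcript_id[need]],
                                surrogate_coding_score, numeric(1))
  classify_coding(ev, ...)
}
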