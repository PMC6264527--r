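# Brute-force reference implementations, deliberately written as plain
# per-base / per-codon enumerations, independent of the package's
# interval-algebra code paths.

# set of 1-based exonic positions of a single-transcript exon table
oracle_base_set <- function(ex) {
  unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:ex$end[i]))
}

oracle_overlap_len <- function(a, b, stranded = FALSE) {
  if (a$chrom[1] != b$chrom[1]) return(0L)
  if (stranded && a$strand[1] != b$strand[1]) return(0L)
  length(intersect(oracle_base_set(a), oracle_base_set(b)))
}

oracle_jaccard <- function(a, b) {
  if (a$chrom[1] != b$chrom[1] || a$strand[1] != b$strand[1]) return(0)
  sa <- oracle_base_set(a); sb <- oracle_base_set(b)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    v <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- v
    prev <- v
  }
  pmin(adj, 1)
}

oracle_masked_fraction <- function(ex, mask) {
  bases <- oracle_base_set(ex)
  mask <- mask[mask$chrom == ex$chrom[1], , drop = FALSE]
  mbases <- unique(unlist(lapply(seq_len(nrow(mask)),
                                 function(i) mask$start[i]:mask$end[i])))
  mean(bases %in% mbases)
}

oracle_conservation <- function(ex, elements) {
  bases <- oracle_base_set(ex)
  total <- 0
  for (i in seq_len(nrow(elements))) {
    if (elements$chrom[i] != ex$chrom[1]) next
    ov <- sum(bases >= elements$start[i] & bases <= elements$end[i])
    total <- total + ov * elements$score[i]
  }
  total / length(bases)
}

# codon-walk ORF scan: for every ATG, walk forward codon by codon to the
# first stop; report only ORFs that are closed by a stop
oracle_orfs <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (i in seq_len(max(0, n - 5))) {
    if (paste(s[i:(i + 2)], collapse = "") != "ATG") next
    j <- i
    while (j + 2 <= n) {
      codon <- paste(s[j:(j + 2)], collapse = "")
      if (grepl("N", codon)) break
      if (codon %in% stops) {
        if (j > i) {
          out[[length(out) + 1]] <- data.frame(
            frame = (i - 1) %% 3, start = i, end = j + 2,
            length = j + 3 - i)
        }
        break
      }
      j <- j + 3
    }
  }
  if (length(out) == 0) {
    return(data.frame(frame = integer(), start = integer(),
                      end = integer(), length = integer()))
  }
  do.call(rbind, out)
}

# two-sided exact binomial p by direct pmf summation (minimum-likelihood
# rule)
oracle_binom_two_sided <- function(k, n, p0) {
  pmf <- dbinom(0:n, n, p0)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_ranksum_exact <- function(x, y) {
  all <- c(x, y)
  n <- length(all); nx <- length(x)
  r <- rank(all)
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- nx * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# random single-transcript exon table
rand_tx <- function(id = "t1", gene = "g1", chrom = "chr1",
                    strand = sample(c("+", "-"), 1),
                    n_exons = sample(1:4, 1), origin = NULL) {
  start <- origin %||% sample(1000:50000, 1)
  exl <- sample(50:400, n_exons, replace = TRUE)
  inl <- if (n_exons > 1) sample(50:500, n_exons - 1, replace = TRUE)
  else integer()
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- start
  for (i in seq_len(n_exons)) {
    starts[i] <- pos; ends[i] <- pos + exl[i] - 1
    pos <- ends[i] + (if (i < n_exons) inl[i] else 0) + 1
  }
  tibble::tibble(chrom = chrom, start = starts, end = ends,
                 strand = strand, transcript_id = id, gene_id = gene)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
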