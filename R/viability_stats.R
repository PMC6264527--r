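# Knockout-cross progeny statistics: Het/Hom ratios against the 2:1
# Mendelian expectation from balancer-stock sibling crosses (homozygous
# balancer progeny die as embryos, so a viable knockout yields 2/3
# heterozygous and 1/3 homozygous adults).

#' Heterozygous/homozygous progeny ratio
#'
#' Rounded half-up to one decimal (2.174 prints as 2.2), matching how
#' such ratios are reported.
#'
#' @param n_het,n_hom Progeny counts.
#' @return Ratio(s); `Inf` when `n_hom` is 0.
#' @export
het_hom_ratio <- function(n_het, n_hom) {
  ifelse(n_hom == 0, Inf, floor(n_het / n_hom * 10 + 0.5) / 10)
}

#' Exact binomial test against Mendelian proportions
#'
#' Two-sided exact binomial p-value for observing `n_hom` homozygotes out
#' of `n_hom + n_het` progeny at homozygote probability `p0` (1/3 for a
#' viable knockout over a balancer). The two-sided p sums all outcomes
#' whose probability does not exceed that of the observation (the
#' minimum-likelihood rule, as implemented by [stats::binom.test()]).
#'
#' @param n_hom,n_het Progeny counts (vectorised).
#' @param p0 Expected homozygote proportion (default 1/3).
#' @return P-value(s) in \[0, 1\].
#' @export
mendelian_test <- function(n_hom, n_het, p0 = 1 / 3) {
  mapply(function(h, t) {
    if (h + t < 1) stop("need at least one scored progeny")
    stats::binom.test(h, h + t, p = p0)$p.value
  }, n_hom, n_het)
}

#' Annotate a viability table with ratios and Mendelian p-values
#'
#' @param records Tibble with `n_hom`, `n_het` (plus any id columns).
#' @param p0 Expected homozygote proportion.
#' @return `records` with `het_hom` and `p_mendelian` columns.
#' @export
viability_table <- function(records, p0 = 1 / 3) {
  records %>%
    mutate(het_hom = het_hom_ratio(.data$n_het, .data$n_hom),
           p_mendelian = mendelian_test(.data$n_hom, .data$n_het, p0))
}

#' Published knockout-line viability counts
#'
#' Adult progeny counts of sibling crosses for three lncRNA knockout
#' lines (two independent alleles each for two of them) at normal (25 C)
#' and restrictive (29 C) temperatures, as transcribed from the study's
#' viability table.
#'
#' @return Tibble `line`, `temperature`, `n_hom`, `n_het`.
#' @export
ko_viability <- function() {
  path <- system.file("extdata", "ko_viability.tsv",
                      package = "lncdiscover", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
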