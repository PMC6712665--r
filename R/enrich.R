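# Functional comparison of plasmid versus chromosome gene content:
# per-COG and per-category Fisher's exact tests with q-values, and an
# ARG-positive/negative plasmid abundance comparison.

#' Per-COG and per-category enrichment between plasmids and chromosomes
#'
#' For each COG family, a 2x2 table (genes with the COG versus without,
#' plasmid versus chromosome) is tested with a two-sided Fisher's exact
#' test; p-values are transformed to q-values. The same test is run at
#' the level of COG functional categories. COGs detected on plasmids but
#' absent from chromosomes are flagged plasmid-only.
#'
#' @param plasmid_genes,chrom_genes [gene_table()]s (must be non-empty).
#' @param q_method `"BH"` (Benjamini-Hochberg, default) or `"storey"`.
#' @return list with `per_cog` (data.frame: cog_id, n_plasmid, n_chrom,
#'   odds_ratio, direction, p, q, plasmid_only) and `per_category`
#'   (cog_category, n_plasmid, n_chrom, odds_ratio, p).
#' @export
cog_enrichment <- function(plasmid_genes, chrom_genes,
                           q_method = c("BH", "storey")) {
  q_method <- match.arg(q_method)
  if (nrow(plasmid_genes) == 0L || nrow(chrom_genes) == 0L) {
    stop("both gene tables must be non-empty")
  }
  n_p <- nrow(plasmid_genes)
  n_c <- nrow(chrom_genes)
  test_feature <- function(values_p, values_c, feature) {
    a <- sum(values_p == feature, na.rm = TRUE)
    b <- sum(values_c == feature, na.rm = TRUE)
    tab <- matrix(c(a, n_p - a, b, n_c - b), nrow = 2L)
    ft <- stats::fisher.test(tab)
    list(n_plasmid = a, n_chrom = b,
         odds_ratio = unname(ft$estimate), p = ft$p.value)
  }
  cogs <- sort(unique(c(plasmid_genes$cog_id, chrom_genes$cog_id)))
  cogs <- cogs[!is.na(cogs)]
  per_cog <- do.call(rbind, lapply(cogs, function(cg) {
    r <- test_feature(plasmid_genes$cog_id, chrom_genes$cog_id, cg)
    data.frame(cog_id = cg, n_plasmid = r$n_plasmid, n_chrom = r$n_chrom,
               odds_ratio = r$odds_ratio,
               direction = if (r$n_plasmid / n_p >= r$n_chrom / n_c)
                 "plasmid" else "chromosome",
               p = r$p,
               plasmid_only = r$n_plasmid > 0L && r$n_chrom == 0L,
               stringsAsFactors = FALSE)
  }))
  per_cog$q <- if (q_method == "BH") {
    stats::p.adjust(per_cog$p, method = "BH")
  } else {
    storey_qvalue(per_cog$p)
  }
  cats <- sort(unique(c(plasmid_genes$cog_category,
                        chrom_genes$cog_category)))
  cats <- cats[!is.na(cats)]
  per_category <- do.call(rbind, lapply(cats, function(cc) {
    r <- test_feature(plasmid_genes$cog_category, chrom_genes$cog_category,
                      cc)
    data.frame(cog_category = cc, n_plasmid = r$n_plasmid,
               n_chrom = r$n_chrom, odds_ratio = r$odds_ratio, p = r$p,
               stringsAsFactors = FALSE)
  }))
  list(per_cog = per_cog, per_category = per_category)
}

#' Storey-style q-values
#'
#' Estimates the null proportion `pi0` from the p-value distribution
#' above `lambda` and rescales Benjamini-Hochberg adjusted values.
#'
#' @param p numeric vector of p-values.
#' @param lambda tuning parameter in (0, 1) (default 0.5).
#' @return numeric vector of q-values.
#' @export
storey_qvalue <- function(p, lambda = 0.5) {
  stopifnot(all(p >= 0 & p <= 1), lambda > 0, lambda < 1)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' Compare abundance of ARG-positive and ARG-negative plasmids
#'
#' Two-sided Wilcoxon rank-sum test of per-plasmid abundance between
#' plasmids carrying at least one antibiotic resistance gene and those
#' carrying none.
#'
#' @param plasmid_arg data.frame with `plasmid_id` and logical `is_arg`
#'   (any ARG on the plasmid).
#' @param abundance named numeric vector of per-plasmid abundance.
#' @return list(p, n_arg, n_non_arg, median_arg, median_non_arg).
#' @export
arg_summary <- function(plasmid_arg, abundance) {
  stopifnot(all(plasmid_arg$plasmid_id %in% names(abundance)))
  x <- abundance[plasmid_arg$plasmid_id[plasmid_arg$is_arg]]
  y <- abundance[plasmid_arg$plasmid_id[!plasmid_arg$is_arg]]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both ARG-positive and ARG-negative groups must be non-empty")
  }
  wt <- stats::wilcox.test(x, y, exact = (length(x) + length(y)) <= 50)
  list(p = wt$p.value, n_arg = length(x), n_non_arg = length(y),
       median_arg = stats::median(x), median_non_arg = stats::median(y))
}
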