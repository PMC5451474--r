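## Audic-Claverie exact conditional test for two tag-count libraries.
##
## For a tag observed x times in a library of N1 total tags and y times in a
## library of N2 tags, the conditional distribution of y given x under equal
## relative abundance is
##
##   p(y | x) = (N2/N1)^y * (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) )
##
## which is a negative binomial with size x+1 and success probability
## N1/(N1+N2) (counting y as failures).  Tails:
##   C = P(Y <= y | x),  D = P(Y >= y | x),  so  C + D - p(y|x) = 1.
## The two-sided p-value doubles the smaller tail.

#' Conditional point mass of the Audic-Claverie test
#'
#' Probability of observing exactly `y` tags in library 2 given `x` tags in
#' library 1 and library totals `N1`, `N2`, under equal relative abundance.
#' Evaluated in log space via `lgamma`, so counts up to 1e7 do not overflow.
#'
#' @param x,y non-negative integer tag counts (vectorized).
#' @param N1,N2 positive library totals (total mapped tags).
#' @return probabilities in `[0, 1]`.
#' @export
ac_pointmass <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive")
  r <- N2 / N1
  exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

#' Lower and upper conditional tails
#'
#' `C = P(Y <= y | x)` and `D = P(Y >= y | x)` under the conditional
#' negative-binomial law of the test.  The lower tail is the regularized
#' incomplete beta function `I_{N1/(N1+N2)}(x+1, y+1)`, the exact closed form
#' of the negative-binomial CDF, and the upper tail is recovered from the
#' partition identity `C + D - p(y|x) = 1`.
#'
#' @inheritParams ac_pointmass
#' @return a list with numeric components `C` and `D`.
#' @export
ac_tails <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive")
  C <- stats::pbeta(N1 / (N1 + N2), x + 1, y + 1)
  D <- 1 - C + ac_pointmass(x, y, N1, N2)
  list(C = pmin(C, 1), D = pmin(D, 1))
}

#' Two-sided exact p-value for a tag-count comparison
#'
#' Doubles the smaller of the two conditional tails and caps at 1:
#' `p = min(1, 2 * min(C, D))`.
#'
#' @inheritParams ac_pointmass
#' @return two-sided p-values in `[0, 1]`.
#' @examples
#' ac_pvalue(0, 0, 1e6, 1e6)   # 1
#' ac_pvalue(5, 40, 1e6, 1e6)  # highly significant
#' @export
ac_pvalue <- function(x, y, N1, N2) {
  t <- ac_tails(x, y, N1, N2)
  pmin(1, 2 * pmin(t$C, t$D))
}

#' Log2 fold change on the normalized (TPM) scale
#'
#' `log2( ((y + pseudo)/N2) / ((x + pseudo)/N1) )`: the fold change of
#' library 2 relative to library 1 after per-million normalization, with a
#' pseudocount (default 0.5 tag-equivalents) guaranteeing finiteness at zero
#' counts.
#'
#' @inheritParams ac_pointmass
#' @param pseudo positive pseudocount in tag units.
#' @return log2 fold changes (library 2 relative to library 1).
#' @export
log2_fold_change <- function(x, y, N1, N2, pseudo = 0.5) {
  if (pseudo <= 0) stop("pseudo must be positive")
  log2(((y + pseudo) / N2) / ((x + pseudo) / N1))
}

#' Rank-based FDR adjustment
#'
#' Adjusts p-values by multiplying each by the total number of tests and
#' dividing by its ascending rank (ties take the maximal rank of their
#' group).  The default `"monotone"` mode additionally applies the step-up
#' running minimum from the largest rank, which makes the output
#' non-decreasing in p-rank; `"literal"` returns the raw ratio capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param mode `"monotone"` (step-up, default) or `"literal"`.
#' @return adjusted p-values in input order.
#' @export
adjust_fdr <- function(p, mode = c("monotone", "literal")) {
  mode <- match.arg(mode)
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  rk <- rank(p, ties.method = "max")
  raw <- pmin(1, p * m / rk)
  if (mode == "literal") return(raw)
  ord <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  adj[ord] <- cummin(raw[ord])
  adj
}

#' Significance rule sets for DE calling
#'
#' Two named rule sets: `"global"` flags miRNAs with p <= 0.005,
#' FDR <= 0.01 and |log2FC| >= 0.5 (the across-library catalogue rule);
#' `"pairwise"` flags miRNAs with fold change >= 2 and p < 0.05 (the
#' per-stage between-breed rule).  Custom thresholds may be supplied.
#'
#' @param rule `"global"` or `"pairwise"`.
#' @param p_max,fdr_max,min_abs_log2fc,min_fold_change override thresholds;
#'   `NA` disables a criterion.
#' @return an object of class `significance_criteria`.
#' @export
significance_criteria <- function(rule = c("global", "pairwise"),
                                  p_max = NULL, fdr_max = NULL,
                                  min_abs_log2fc = NULL,
                                  min_fold_change = NULL) {
  rule <- match.arg(rule)
  def <- if (rule == "global") {
    list(p_max = 0.005, p_strict = FALSE, fdr_max = 0.01,
         min_abs_log2fc = 0.5, min_fold_change = NA_real_)
  } else {
    list(p_max = 0.05, p_strict = TRUE, fdr_max = NA_real_,
         min_abs_log2fc = NA_real_, min_fold_change = 2)
  }
  if (!is.null(p_max)) def$p_max <- p_max
  if (!is.null(fdr_max)) def$fdr_max <- fdr_max
  if (!is.null(min_abs_log2fc)) def$min_abs_log2fc <- min_abs_log2fc
  if (!is.null(min_fold_change)) def$min_fold_change <- min_fold_change
  for (th in c("p_max", "fdr_max", "min_abs_log2fc", "min_fold_change"))
    if (!is.na(def[[th]]) && def[[th]] <= 0) stop(th, " must be positive")
  structure(c(list(rule = rule), def), class = "significance_criteria")
}

apply_criteria <- function(crit, p, fdr, log2_fc) {
  flag <- if (crit$p_strict) p < crit$p_max else p <= crit$p_max
  if (!is.na(crit$fdr_max)) flag <- flag & fdr <= crit$fdr_max
  if (!is.na(crit$min_abs_log2fc)) flag <- flag & abs(log2_fc) >= crit$min_abs_log2fc
  if (!is.na(crit$min_fold_change))
    flag <- flag & abs(log2_fc) >= log2(crit$min_fold_change)
  flag
}

#' Exact-test differential expression over a count matrix
#'
#' Runs the Audic-Claverie test for every miRNA in each requested pairwise
#' library comparison, with the FDR adjustment computed within each
#' comparison.  The fold change is reported for library 2 relative to library
#' 1; the direction column records `"up"` when expression is higher in the
#' first-listed library (the reference breed, e.g. LR in an LR-vs-LT
#' comparison) and `"down"` when lower.
#'
#' @param counts a [count_matrix()].
#' @param comparisons data.frame with columns `library1`, `library2` and
#'   optionally `stage` (a label carried through to the results; defaults to
#'   the stage parsed from `library1`).
#' @param criteria a [significance_criteria()] rule set (default pairwise).
#' @param fdr_mode passed to [adjust_fdr()].
#' @param pseudo pseudocount for [log2_fold_change()].
#' @return data.frame of class `de_results` with one row per miRNA per
#'   comparison: `mirna_id`, `comparison`, `stage`, `x`, `y`, `N1`, `N2`,
#'   `log2_fc`, `p`, `fdr`, `de` (logical flag), `direction`.
#' @export
de_test <- function(counts, comparisons,
                    criteria = significance_criteria("pairwise"),
                    fdr_mode = "monotone", pseudo = 0.5) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(criteria, "significance_criteria"))
  labs <- colnames(counts$counts)
  missing <- setdiff(unique(c(comparisons$library1, comparisons$library2)), labs)
  if (length(missing))
    stop("unknown library label(s): ", paste(missing, collapse = ", "))
  if (is.null(comparisons$stage)) {
    idx <- match(comparisons$library1, labs)
    comparisons$stage <- counts$stages[idx]
  }
  out <- vector("list", nrow(comparisons))
  for (i in seq_len(nrow(comparisons))) {
    l1 <- comparisons$library1[i]; l2 <- comparisons$library2[i]
    x <- counts$counts[, l1]; y <- counts$counts[, l2]
    N1 <- counts$library_sizes[[l1]]; N2 <- counts$library_sizes[[l2]]
    p <- ac_pvalue(x, y, N1, N2)
    fdr <- adjust_fdr(p, mode = fdr_mode)
    lfc <- log2_fold_change(x, y, N1, N2, pseudo = pseudo)
    de <- apply_criteria(criteria, p, fdr, lfc)
    out[[i]] <- data.frame(
      mirna_id = rownames(counts$counts),
      comparison = paste(l1, l2, sep = ":"),
      stage = comparisons$stage[i],
      x = x, y = y, N1 = N1, N2 = N2,
      log2_fc = lfc, p = p, fdr = fdr, de = de,
      direction = ifelse(lfc < 0, "up", ifelse(lfc > 0, "down", "none")),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "criteria") <- criteria
  class(res) <- c("de_results", class(res))
  res
}
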