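#' Normalize tag counts to tags per million (TPM)
#'
#' Scales each library's tag counts by its total mapped tags:
#' `tpm[i, j] = counts[i, j] / N_j * 1e6`.  When the library sizes equal the
#' column sums every column of the result sums to one million.
#'
#' @param counts a [count_matrix()].
#' @return a [tpm_matrix()] with the same axes.
#' @examples
#' cm <- count_matrix(matrix(c(1, 1, 2), 3, 1,
#'                           dimnames = list(paste0("mir-", 1:3), "LR_35E")))
#' tpm_normalize(cm)$tpm  # 250000, 250000, 500000
#' @export
tpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  tpm <- sweep(counts$counts, 2, counts$library_sizes, "/") * 1e6
  tpm_matrix(tpm, counts$library_sizes)
}

#' Log2-transform an FPKM matrix
#'
#' Applies `log2(fpkm + pseudocount)` elementwise and records the pseudocount
#' in the returned object.  A pseudocount of 1 (the default) maps FPKM 0 to 0.
#'
#' @param fpkm an [fpkm_matrix()] or non-negative numeric matrix.
#' @param pseudocount positive offset added before taking logs.
#' @return an [fpkm_matrix()] carrying both raw and log2 values.
#' @export
log2_transform <- function(fpkm, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  m <- if (inherits(fpkm, "fpkm_matrix")) fpkm$fpkm else as.matrix(fpkm)
  if (any(m < 0)) stop("FPKM values must be non-negative")
  if (pseudocount == 0 && any(m == 0))
    stop("pseudocount 0 with zero FPKM values gives -Inf; use a positive pseudocount")
  fpkm_matrix(m, log2(m + pseudocount), pseudocount = pseudocount)
}
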