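#' Tag-count matrix for pooled small-RNA libraries
#'
#' Lightweight container for miRNA tag counts across libraries, one pooled
#' library per breed x stage.  Library sizes are the total mapped tags per
#' library and may exceed the per-column miRNA count sums (miRNA tags are a
#' subset of mapped tags).
#'
#' @param counts integer matrix, rows = miRNAs, columns = libraries. Must have
#'   rownames (miRNA ids) and colnames (library labels such as `"LR_35E"`).
#' @param library_sizes numeric vector of total mapped tags per library, one
#'   per column. Defaults to the column sums of `counts`.
#' @param breeds,stages optional character vectors giving the breed and stage
#'   of each column; parsed from colnames of the form `"<breed>_<stage>"`
#'   when omitted.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `library_sizes`, `breeds`, `stages`.
#' @export
count_matrix <- function(counts, library_sizes = NULL,
                         breeds = NULL, stages = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have rownames (miRNA ids) and colnames (library labels)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate miRNA ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate library labels in count matrix")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  library_sizes <- as.numeric(library_sizes)
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes must have one entry per library")
  if (any(library_sizes <= 0)) {
    bad <- colnames(counts)[library_sizes <= 0][1]
    stop("library '", bad, "' has non-positive library size")
  }
  if (any(library_sizes + 1e-9 < colSums(counts)))
    stop("library_sizes must be >= column sums (counts are a subset of mapped tags)")
  names(library_sizes) <- colnames(counts)
  if (is.null(breeds) || is.null(stages)) {
    parts <- strsplit(colnames(counts), "_", fixed = TRUE)
    ok <- all(lengths(parts) == 2L)
    if (is.null(breeds)) breeds <- if (ok) vapply(parts, `[`, "", 1L) else rep(NA_character_, ncol(counts))
    if (is.null(stages)) stages <- if (ok) vapply(parts, `[`, "", 2L) else rep(NA_character_, ncol(counts))
  }
  structure(list(counts = counts, library_sizes = library_sizes,
                 breeds = breeds, stages = stages),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "miRNAs x", ncol(x$counts), "libraries\n")
  cat("library sizes:", paste(format(x$library_sizes, big.mark = ","), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Tags-per-million matrix
#'
#' Same axes as the parent [count_matrix()]; values are TPM.
#'
#' @param tpm numeric matrix of TPM values with dimnames.
#' @param library_sizes library totals used as the TPM denominator.
#' @return An object of class `tpm_matrix`.
#' @export
tpm_matrix <- function(tpm, library_sizes) {
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  structure(list(tpm = as.matrix(tpm), library_sizes = library_sizes),
            class = "tpm_matrix")
}

#' @export
print.tpm_matrix <- function(x, ...) {
  cat("tpm_matrix:", nrow(x$tpm), "miRNAs x", ncol(x$tpm), "libraries\n")
  invisible(x)
}

#' FPKM expression matrix with log2 values
#'
#' Holds gene-level FPKM across stage-labelled samples together with the
#' log2-transformed values and the pseudocount used.
#'
#' @param fpkm non-negative numeric matrix, rows = genes, columns = samples.
#' @param log2_values matrix of `log2(fpkm + pseudocount)`; computed when `NULL`.
#' @param pseudocount positive pseudocount recorded with the transform.
#' @return An object of class `fpkm_matrix`.
#' @export
fpkm_matrix <- function(fpkm, log2_values = NULL, pseudocount = 1) {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  if (is.null(log2_values)) log2_values <- log2(fpkm + pseudocount)
  structure(list(fpkm = fpkm, log2_values = as.matrix(log2_values),
                 pseudocount = pseudocount),
            class = "fpkm_matrix")
}

#' @export
print.fpkm_matrix <- function(x, ...) {
  cat("fpkm_matrix:", nrow(x$fpkm), "genes x", ncol(x$fpkm),
      "samples (pseudocount", x$pseudocount, ")\n")
  invisible(x)
}

## ---- TSV I/O -------------------------------------------------------------
## All tabular output is plain TSV with the feature id in the first column,
## written without quoting so reruns are byte-identical.

#' Write a feature-by-library matrix to TSV
#'
#' @param x a matrix, `count_matrix`, `tpm_matrix` or `fpkm_matrix`.
#' @param path output file path.
#' @param id_col header name of the first (feature id) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, id_col = "feature_id") {
  m <- if (inherits(x, "count_matrix")) x$counts
       else if (inherits(x, "tpm_matrix")) x$tpm
       else if (inherits(x, "fpkm_matrix")) x$fpkm
       else as.matrix(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-library matrix from TSV
#'
#' First column is taken as the feature id, remaining columns as libraries.
#'
#' @param path input TSV path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
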