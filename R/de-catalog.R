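#' Stage grouping into embryonic (G1) and postnatal (G2) sets
#'
#' @param G1 embryonic stage labels.
#' @param G2 postnatal stage labels.
#' @return an object of class `stage_grouping`.
#' @export
stage_grouping <- function(G1 = c("35E", "49E", "63E", "77E"),
                           G2 = c("2P", "28P", "90P", "180P")) {
  if (length(intersect(G1, G2)) > 0) stop("G1 and G2 must be disjoint")
  if (length(c(G1, G2)) != 8) stop("G1 and G2 must cover 8 stages")
  structure(list(G1 = G1, G2 = G2), class = "stage_grouping")
}

#' Classify DE miRNAs into group-wise up/down sets
#'
#' Builds the four catalogue sets G1_up, G1_down, G2_up, G2_down under the
#' at-least-one-stage rule: a miRNA belongs to a group's `up` set when it is
#' flagged DE with direction `up` (higher in the first-listed breed) at one
#' or more stages of that group.  A miRNA flagged in opposite directions at
#' different stages of one group is retained in both sets, with a warning.
#' Per-stage up/down/total counts are also tabulated.
#'
#' @param results a `de_results` data.frame from [de_test()] with `stage`,
#'   `de` and `direction` columns.
#' @param grouping a [stage_grouping()].
#' @return an object of class `de_catalog`: list with `sets` (named list of
#'   miRNA-id vectors), `stage_counts` (data.frame `stage`, `n_up`, `n_down`,
#'   `n_total`) and `group_counts`.
#' @export
classify_groups <- function(results, grouping) {
  stopifnot(inherits(grouping, "stage_grouping"))
  all_stages <- c(grouping$G1, grouping$G2)
  bad <- setdiff(unique(results$stage), all_stages)
  if (length(bad))
    stop("stage label(s) absent from grouping: ", paste(bad, collapse = ", "))
  for (g in c("G1", "G2"))
    if (!any(results$stage %in% grouping[[g]]))
      stop("results cover no stage of ", g)
  flagged <- results[results$de, , drop = FALSE]
  sets <- list()
  for (g in c("G1", "G2")) {
    in_g <- flagged[flagged$stage %in% grouping[[g]], , drop = FALSE]
    sets[[paste0(g, "_up")]] <-
      sort(unique(in_g$mirna_id[in_g$direction == "up"]))
    sets[[paste0(g, "_down")]] <-
      sort(unique(in_g$mirna_id[in_g$direction == "down"]))
    both <- intersect(sets[[paste0(g, "_up")]], sets[[paste0(g, "_down")]])
    if (length(both))
      warning(length(both), " miRNA(s) flagged in both directions within ",
              g, "; retained in both sets")
  }
  stage_counts <- do.call(rbind, lapply(all_stages, function(s) {
    fs <- flagged[flagged$stage == s, , drop = FALSE]
    data.frame(stage = s,
               n_up = sum(fs$direction == "up"),
               n_down = sum(fs$direction == "down"),
               n_total = nrow(fs), stringsAsFactors = FALSE)
  }))
  group_counts <- data.frame(
    group = c("G1", "G2"),
    n_up = c(length(sets$G1_up), length(sets$G2_up)),
    n_down = c(length(sets$G1_down), length(sets$G2_down)),
    stringsAsFactors = FALSE)
  structure(list(sets = sets, stage_counts = stage_counts,
                 group_counts = group_counts, grouping = grouping),
            class = "de_catalog")
}

#' @export
print.de_catalog <- function(x, ...) {
  cat("de_catalog: |G1_up| =", length(x$sets$G1_up),
      "|G1_down| =", length(x$sets$G1_down),
      "|G2_up| =", length(x$sets$G2_up),
      "|G2_down| =", length(x$sets$G2_down), "\n")
  invisible(x)
}

#' Venn overlap between two catalogue sets
#'
#' @param catalog a [classify_groups()] result (or plain list of sets under
#'   `$sets`).
#' @param set_a,set_b names of catalogue sets, e.g. `"G1_down"`, `"G2_up"`.
#' @return named integer vector `only_a`, `shared`, `only_b`.
#' @export
venn_overlap <- function(catalog, set_a, set_b) {
  sets <- if (inherits(catalog, "de_catalog")) catalog$sets else catalog
  for (nm in c(set_a, set_b))
    if (is.null(sets[[nm]])) stop("unknown set name: ", nm)
  a <- unique(sets[[set_a]]); b <- unique(sets[[set_b]])
  shared <- length(intersect(a, b))
  c(only_a = length(a) - shared, shared = shared,
    only_b = length(b) - shared)
}

#' Rank catalogue miRNAs by abundance within a stage group
#'
#' Ranks the miRNAs of a catalogue set by mean (or max) TPM over the group's
#' stages, descending, with a deterministic tie-break by id, and returns the
#' top `k`.
#'
#' @param tpm a [tpm_matrix()] whose column labels are `<breed>_<stage>`.
#' @param mirna_set character vector of miRNA ids.
#' @param stages stage labels of the group to average over; columns whose
#'   stage suffix is in this set are used.
#' @param k number of miRNAs to return (whole set if larger).
#' @param rank_stat `"mean"` or `"max"`.
#' @return data.frame `mirna_id`, `abundance`, ranked descending.
#' @export
top_abundant <- function(tpm, mirna_set, stages, k = 10,
                         rank_stat = c("mean", "max")) {
  rank_stat <- match.arg(rank_stat)
  if (k < 1) stop("k must be at least 1")
  if (length(mirna_set) == 0)
    return(data.frame(mirna_id = character(), abundance = numeric()))
  m <- tpm$tpm
  col_stage <- sub("^[^_]*_", "", colnames(m))
  cols <- col_stage %in% stages
  if (!any(cols)) stop("no library column matches the requested stages")
  sub <- m[rownames(m) %in% mirna_set, cols, drop = FALSE]
  stat <- apply(sub, 1, if (rank_stat == "mean") mean else max)
  ord <- order(-stat, names(stat))
  out <- data.frame(mirna_id = names(stat)[ord], abundance = unname(stat[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' PCA ordination of DE-miRNA expression across libraries
#'
#' Samples (libraries) are the observations and miRNAs the variables; TPM is
#' log2-transformed with a pseudocount, variables are mean-centred (no
#' unit-variance scaling) and the decomposition is via singular values.  The
#' sign convention fixes, per component, the loading of largest magnitude to
#' be positive.
#'
#' @param tpm a [tpm_matrix()] (or numeric matrix, miRNAs x libraries).
#' @param mirna_set optional restriction to a miRNA-id set (e.g. DE miRNAs).
#' @param pseudocount added before the log2 transform.
#' @return an object of class `ordination`: list with `scores` (samples x
#'   components), `loadings` (miRNAs x components), `variance_fraction`.
#' @export
pca_ordination <- function(tpm, mirna_set = NULL, pseudocount = 1) {
  m <- if (inherits(tpm, "tpm_matrix")) tpm$tpm else as.matrix(tpm)
  if (!is.null(mirna_set)) m <- m[rownames(m) %in% mirna_set, , drop = FALSE]
  if (ncol(m) < 2) stop("at least 2 samples required")
  if (nrow(m) < 2) stop("at least 2 miRNAs required")
  x <- t(log2(m + pseudocount))  # samples x miRNAs
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_fraction = vf), class = "ordination")
}

#' Hypergeometric term enrichment
#'
#' One-sided hypergeometric tail `P(X >= overlap)` per annotation term, with
#' the rank-based FDR adjustment ([adjust_fdr()], monotone mode) across
#' terms.  No ontology structure is used: terms are flat member lists.
#'
#' @param selection character vector of selected ids (must be a subset of
#'   `universe`).
#' @param universe character vector of all ids under consideration.
#' @param annotation data.frame with columns `term_id`, `member_id`; members
#'   outside the universe are ignored.
#' @return data.frame `term_id`, `term_size`, `overlap`, `p`, `fdr`.
#' @export
enrich_terms <- function(selection, universe, annotation) {
  selection <- unique(selection); universe <- unique(universe)
  if (!all(selection %in% universe))
    stop("selection contains ids outside the universe")
  annotation <- annotation[annotation$member_id %in% universe, , drop = FALSE]
  terms <- split(unique(annotation)$member_id, unique(annotation)$term_id)
  N <- length(universe); n <- length(selection)
  rows <- lapply(names(terms), function(tm) {
    K <- length(terms[[tm]])
    k <- length(intersect(terms[[tm]], selection))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm, term_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), term_size = integer(),
                      overlap = integer(), p = numeric(), fdr = numeric()))
  out$fdr <- adjust_fdr(out$p, mode = "monotone")
  out[order(out$p, out$term_id), , drop = FALSE]
}
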