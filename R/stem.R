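## STEM-style short time-series clustering.  Model profiles are integer
## templates of length T starting at 0 with successive changes bounded by c;
## genes are assigned to the selected profile their transformed series
## correlates best with, and per-profile significance compares observed
## assignment counts with the expectation under permutations of the time
## points.

#' Enumerate the model-profile universe
#'
#' All integer vectors of length `T` starting at 0 whose successive
#' differences lie in `[-c, c]`: exactly `(2c+1)^(T-1)` profiles, enumerated
#' in lexicographic order of their difference vectors and given dense ids
#' from 0.
#'
#' @param T number of time points (>= 2).
#' @param c maximum absolute unit change between consecutive points (>= 1).
#' @return list of profiles, each a list with integer `id` and integer
#'   `values` of length `T`.
#' @examples
#' length(generate_model_profiles(4, 2))  # 125
#' @export
generate_model_profiles <- function(T, c = 2) {
  if (T < 2) stop("T must be at least 2")
  if (c < 1) stop("c must be at least 1")
  steps <- seq.int(-c, c)
  diffs <- as.matrix(expand.grid(rep(list(steps), T - 1),
                                 KEEP.OUT.ATTRS = FALSE)[, (T - 1):1,
                                                          drop = FALSE])
  ## expand.grid varies the first factor fastest; reversing the columns
  ## yields lexicographic order of the difference vectors
  ord <- do.call(order, as.data.frame(diffs))
  diffs <- diffs[ord, , drop = FALSE]
  lapply(seq_len(nrow(diffs)), function(i) {
    list(id = i - 1L,
         values = as.integer(c(0L, cumsum(diffs[i, ]))))
  })
}

profile_value_matrix <- function(profiles) {
  t(vapply(profiles, function(p) as.numeric(p$values),
           numeric(length(profiles[[1]]$values))))
}

is_flat_profile <- function(profiles) {
  vapply(profiles, function(p) all(p$values == p$values[1]), TRUE)
}

#' Greedy max-min selection of representative profiles
#'
#' Selects `m` mutually dissimilar profiles under the distance
#' `1 - Pearson r`.  The flat (constant) profile has undefined correlation
#' and is excluded from the candidate pool.  The first pick is the candidate
#' with maximal summed distance to all other candidates; each further pick
#' maximizes the minimum distance to the already-selected set.  All ties
#' break to the lowest profile id.  When `m` is at least the number of
#' usable candidates, all of them are returned.
#'
#' @param candidates profile list from [generate_model_profiles()].
#' @param m number of representatives to select (>= 1).
#' @return list of selected profiles, ordered by id.
#' @export
select_representative_profiles <- function(candidates, m) {
  if (m < 1) stop("m must be at least 1")
  keep <- !is_flat_profile(candidates)
  pool <- candidates[keep]
  if (length(pool) == 0) stop("no non-flat candidate profiles")
  if (m >= length(pool)) return(pool)
  V <- profile_value_matrix(pool)
  D <- 1 - stats::cor(t(V))
  ids <- vapply(pool, function(p) p$id, integer(1))
  first <- which.max(rowSums(D))  # which.max takes the first (lowest-id) tie
  selected <- first
  while (length(selected) < m) {
    mind <- apply(D[, selected, drop = FALSE], 1, min)
    mind[selected] <- -Inf
    selected <- c(selected, which.max(mind))
  }
  pool[sort(selected)]
}

#' Normalize a log2 series to the profile convention
#'
#' Subtracts the first time point so the series starts at 0 (matching model
#' profiles).  Idempotent; a constant series maps to all zeros.
#'
#' @param series numeric vector or matrix (rows = genes).
#' @return transformed series with the same shape.
#' @export
transform_series <- function(series) {
  if (is.matrix(series)) series - series[, 1] else series - series[1]
}

#' Assign genes to their best-correlated model profile
#'
#' Computes the Pearson correlation of every gene's transformed series with
#' every selected profile and assigns each gene to the profile with maximal
#' correlation, ties to the lowest profile id.  Zero-variance (constant)
#' series have undefined correlation and are excluded with a recorded
#' reason.
#'
#' @param series numeric matrix of transformed log2 series (rows = genes,
#'   with rownames) or an untransformed matrix ([transform_series()] is
#'   applied; the transform is idempotent).
#' @param profiles list of selected (non-flat) profiles.
#' @return data.frame of class `profile_assignments`: `gene_id`,
#'   `profile_id` (NA when excluded), `r`, `excluded`, `reason`.
#' @export
assign_profiles <- function(series, profiles) {
  if (length(profiles) < 1) stop("at least one selected profile required")
  series <- as.matrix(series)
  P <- profile_value_matrix(profiles)
  if (ncol(series) != ncol(P))
    stop("series length does not match profile length")
  series <- transform_series(series)
  ids <- vapply(profiles, function(p) p$id, integer(1))
  if (is.unsorted(ids)) stop("profiles must be ordered by id")
  const <- apply(series, 1, function(z) stats::var(z) == 0)
  R <- matrix(NA_real_, nrow(series), nrow(P))
  if (any(!const))
    R[!const, ] <- stats::cor(t(series[!const, , drop = FALSE]), t(P))
  best <- rep(NA_integer_, nrow(series))
  bestr <- rep(NA_real_, nrow(series))
  if (any(!const)) {
    idx <- max.col(R[!const, , drop = FALSE], ties.method = "first")
    best[!const] <- ids[idx]
    bestr[!const] <- R[cbind(which(!const), idx)]
  }
  out <- data.frame(gene_id = rownames(series),
                    profile_id = best, r = bestr,
                    excluded = const,
                    reason = ifelse(const, "constant series", ""),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("profile_assignments", class(out))
  out
}

all_permutations <- function(T) {
  if (T == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(T - 1L)
  do.call(rbind, lapply(seq_len(T), function(k) {
    rest <- setdiff(seq_len(T), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Permutation significance of profile assignment counts
#'
#' Estimates, for each selected profile, the number of genes expected to be
#' assigned to it when the time points carry no order information: the time
#' points of every gene series are permuted, the series renormalized
#' (first point subtracted) and reassigned, and counts are averaged over
#' permutations — all `T!` orderings when `T <= max_exhaustive_T`, otherwise
#' `n_sampled` orderings drawn with the given seed.  The p-value is the
#' binomial tail `P(X >= observed)` with `X ~ Binomial(n_assigned,
#' expected / n_assigned)`, Bonferroni-corrected over the number of selected
#' profiles; a profile is significant when the corrected p is below `alpha`.
#'
#' @param series transformed (or raw log2) gene-series matrix with rownames.
#' @param profiles list of selected profiles, as used for the observed
#'   assignment.
#' @param assignments optional precomputed [assign_profiles()] result for
#'   `series`; recomputed when missing.
#' @param max_exhaustive_T largest `T` for which all `T!` permutations are
#'   enumerated.
#' @param n_sampled number of sampled permutations for larger `T`.
#' @param seed RNG seed used only when sampling permutations.
#' @param alpha significance level on the corrected p-value.
#' @return data.frame of class `profile_enrichment`: `profile_id`,
#'   `observed`, `expected`, `p`, `p_corrected`, `significant`.
#' @export
profile_significance <- function(series, profiles, assignments = NULL,
                                 max_exhaustive_T = 5, n_sampled = 500,
                                 seed = 1, alpha = 0.05) {
  series <- transform_series(as.matrix(series))
  if (is.null(assignments)) assignments <- assign_profiles(series, profiles)
  kept <- assignments[!assignments$excluded, , drop = FALSE]
  n <- nrow(kept)
  if (n == 0) stop("no assigned genes")
  T <- ncol(series)
  ids <- vapply(profiles, function(p) p$id, integer(1))
  observed <- as.integer(table(factor(kept$profile_id, levels = ids)))
  perms <- if (T <= max_exhaustive_T) all_permutations(T) else {
    set.seed(seed)
    t(replicate(n_sampled, sample.int(T)))
  }
  counts <- matrix(0, nrow(perms), length(ids))
  for (i in seq_len(nrow(perms))) {
    a <- assign_profiles(series[, perms[i, ], drop = FALSE], profiles)
    a <- a[!a$excluded, , drop = FALSE]
    counts[i, ] <- as.integer(table(factor(a$profile_id, levels = ids)))
  }
  expected <- colMeans(counts)
  p <- stats::pbinom(observed - 1L, n, pmin(1, expected / n),
                     lower.tail = FALSE)
  p_corr <- pmin(1, p * length(ids))
  out <- data.frame(profile_id = ids, observed = observed,
                    expected = expected, p = p, p_corrected = p_corr,
                    significant = p_corr < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("profile_enrichment", class(out))
  out
}
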