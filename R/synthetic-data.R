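## Synthetic-data generators.  Every downstream stage of the pipeline is
## exercised on data produced here, with recorded ground truth: planted
## breed x stage log2 effects in tag counts, planted model-profile templates
## in FPKM time courses, planted 7-mer seed-complement sites in 3'-UTRs and
## a symmetric gene-gene interaction-score table.

DEFAULT_STAGES <- c("35E", "49E", "63E", "77E", "2P", "28P", "90P", "180P")

#' Simulation configuration
#'
#' Describes the two-breed, eight-stage pooled-library design the generators
#' emulate: one library per breed per stage, four embryonic (suffix `E`) and
#' four postnatal (suffix `P`) stages.
#'
#' @param n_mirnas,n_genes numbers of miRNAs and genes to simulate.
#' @param breeds two breed labels (reference breed first).
#' @param stages ordered vector of exactly 8 stage labels, 4 ending in `E`
#'   and 4 in `P`.
#' @param library_size expected total mapped tags per library.
#' @param planted_de list of planted effects, each a list with elements
#'   `mirna` (id), `stages` (stage labels) and `log2fc` (finite log2 effect of
#'   the second breed relative to the first at those stages).
#' @param noise_model `"poisson"` or `"negative_binomial"`.
#' @param dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); ignored under Poisson noise.
#' @param profile_noise_sd standard deviation of Gaussian noise added to
#'   log2 FPKM time courses.
#' @param mirna_fraction fraction of mapped tags that are miRNA tags; keeps
#'   column sums below `library_size` so planted TPM ratios are unbiased.
#'   The default 0.25 guarantees headroom for planted effects up to 4-fold
#'   regardless of how much baseline mass the planted miRNAs carry;
#'   [gen_count_libraries()] errors if a configuration exceeds the headroom.
#' @param abundance_sdlog log-sd of the log-normal baseline abundances (the
#'   heavy tail mimics the dominance of a few miRNAs in real tag data).
#' @param seed RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_mirnas = 200, n_genes = 1000,
                       breeds = c("LR", "LT"), stages = DEFAULT_STAGES,
                       library_size = 1e6, planted_de = list(),
                       noise_model = c("poisson", "negative_binomial"),
                       dispersion = 0.1, profile_noise_sd = 0.25,
                       mirna_fraction = 0.25, abundance_sdlog = 1.5,
                       seed = 1) {
  noise_model <- match.arg(noise_model)
  if (n_mirnas < 1 || n_genes < 1) stop("n_mirnas and n_genes must be positive")
  if (length(breeds) != 2 || anyDuplicated(breeds))
    stop("exactly 2 distinct breed labels required")
  if (length(stages) != 8 || anyDuplicated(stages))
    stop("exactly 8 distinct stage labels required")
  emb <- grepl("E$", stages)
  if (sum(emb) != 4)
    stop("stages must split 4 embryonic (suffix E) + 4 postnatal (suffix P)")
  if (library_size <= 0) stop("library_size must be positive")
  if (profile_noise_sd < 0) stop("profile_noise_sd must be non-negative")
  if (mirna_fraction <= 0 || mirna_fraction > 1)
    stop("mirna_fraction must lie in (0, 1]")
  for (pd in planted_de) {
    if (!all(c("mirna", "stages", "log2fc") %in% names(pd)))
      stop("each planted_de entry needs mirna, stages, log2fc")
    if (!all(is.finite(pd$log2fc))) stop("planted effect sizes must be finite")
    if (!all(pd$stages %in% stages)) stop("planted stage not in stage list")
  }
  structure(list(n_mirnas = n_mirnas, n_genes = n_genes, breeds = breeds,
                 stages = stages, library_size = library_size,
                 planted_de = planted_de, noise_model = noise_model,
                 dispersion = dispersion, profile_noise_sd = profile_noise_sd,
                 mirna_fraction = mirna_fraction,
                 abundance_sdlog = abundance_sdlog, seed = seed),
            class = "sim_config")
}

#' Embryonic / postnatal stage grouping of a configuration
#'
#' @param config a [sim_config()] (or any object with a `stages` field).
#' @return a [stage_grouping()] with G1 = embryonic, G2 = postnatal stages.
#' @export
config_grouping <- function(config) {
  stage_grouping(G1 = config$stages[grepl("E$", config$stages)],
                 G2 = config$stages[grepl("P$", config$stages)])
}

#' Generate pooled tag-count libraries with planted DE effects
#'
#' Draws a heavy-tailed (log-normal) baseline abundance per miRNA, scales to
#' `mirna_fraction * library_size` expected miRNA tags per library, applies
#' the planted log2 effects to the second breed at the designated stages and
#' draws counts from the configured noise model.  Library sizes are the
#' nominal `library_size` (total mapped tags), so the expected log2 TPM ratio
#' of a planted miRNA equals its planted effect exactly and unplanted miRNAs
#' keep identical expected TPM in both breeds.  That requires headroom: the
#' expected miRNA mass of every library, planted effects included, must stay
#' below the nominal total with room for Poisson fluctuation; configurations
#' without that headroom are rejected with an error rather than silently
#' rescaled (rescaling either the rates or the library sizes would bias the
#' planted ratios or the null tests).
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (a [count_matrix()]) and `truth`
#'   (data.frame `mirna_id`, `stage`, `log2fc` of planted effects).
#' @export
gen_count_libraries <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_mirnas
  ids <- sprintf("mir-%03d", seq_len(n))
  labels <- as.vector(outer(config$breeds, config$stages, paste, sep = "_"))
  breeds <- rep(config$breeds, times = length(config$stages))
  stages <- rep(config$stages, each = 2)
  base <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  rel <- base / sum(base)
  lambda <- matrix(rel * config$mirna_fraction * config$library_size,
                   nrow = n, ncol = length(labels),
                   dimnames = list(ids, labels))
  truth <- list()
  for (pd in config$planted_de) {
    cols <- paste(config$breeds[2], pd$stages, sep = "_")
    lambda[pd$mirna, cols] <- lambda[pd$mirna, cols] * 2^pd$log2fc
    truth[[length(truth) + 1]] <- data.frame(
      mirna_id = pd$mirna, stage = pd$stages, log2fc = pd$log2fc,
      stringsAsFactors = FALSE)
  }
  ## headroom check: expected column mass (planted effects included) must
  ## leave room for Poisson fluctuation below the nominal library size
  mass <- colSums(lambda)
  col_var <- if (config$noise_model == "poisson") mass else
    colSums(lambda + config$dispersion * lambda^2)
  if (any(mass + 6 * sqrt(col_var) > config$library_size))
    stop("expected miRNA tag mass exceeds the library size headroom; ",
         "lower mirna_fraction or the planted effect sizes")
  cnt <- if (config$noise_model == "poisson") {
    matrix(stats::rpois(length(lambda), lambda), nrow = n,
           dimnames = dimnames(lambda))
  } else {
    matrix(stats::rnbinom(length(lambda), mu = lambda,
                          size = 1 / config$dispersion),
           nrow = n, dimnames = dimnames(lambda))
  }
  ## nominal mapped-tag totals: the non-miRNA fraction absorbs the planted
  ## mass shift, so both planted ratios and null comparisons are unbiased
  lib_sizes <- rep(config$library_size, length(labels))
  names(lib_sizes) <- labels
  cm <- count_matrix(cnt, library_sizes = lib_sizes,
                     breeds = breeds, stages = stages)
  list(counts = cm,
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(mirna_id = character(), stage = character(),
                               log2fc = numeric()))
}

#' Generate FPKM time courses from model-profile templates
#'
#' Each gene's log2 expression series over `T` time points is a baseline plus
#' a scaled integer template plus Gaussian noise; FPKM is `2^series`.  Genes
#' are dealt to the supplied templates in round-robin order and the template
#' of each gene is recorded as ground truth.
#'
#' @param config a [sim_config()] (supplies `n_genes`, `profile_noise_sd` and
#'   the seed).
#' @param profiles non-empty list of [model profiles][generate_model_profiles]
#'   (each with integer `values` starting at 0).
#' @param stage_labels column labels, one per time point; defaults to the
#'   embryonic stages of the configuration when lengths agree.
#' @param baseline_log2 mean log2 FPKM added to every series.
#' @param scale multiplier applied to template values (log2 units per
#'   template step).
#' @param template_index optional integer vector (length `n_genes`) giving
#'   the index into `profiles` of each gene's template; round-robin when
#'   omitted.
#' @return list with `fpkm` (an [fpkm_matrix()]) and `truth` (data.frame
#'   `gene_id`, `profile_id`).
#' @export
gen_expression_profiles <- function(config, profiles, stage_labels = NULL,
                                    baseline_log2 = 5, scale = 1,
                                    template_index = NULL) {
  stopifnot(inherits(config, "sim_config"), length(profiles) > 0)
  set.seed(config$seed + 1L)
  T <- length(profiles[[1]]$values)
  if (is.null(stage_labels)) {
    g1 <- config$stages[grepl("E$", config$stages)]
    stage_labels <- if (length(g1) == T) g1 else paste0("t", seq_len(T))
  }
  if (length(stage_labels) != T) stop("stage_labels length must match profiles")
  n <- config$n_genes
  ids <- sprintf("gene-%04d", seq_len(n))
  assigned <- if (is.null(template_index))
    rep(seq_along(profiles), length.out = n)
  else {
    if (length(template_index) != n || any(template_index < 1) ||
          any(template_index > length(profiles)))
      stop("template_index must index profiles, one entry per gene")
    as.integer(template_index)
  }
  templ <- t(vapply(profiles[assigned], function(p) as.numeric(p$values),
                    numeric(T)))
  series <- baseline_log2 + scale * templ +
    matrix(stats::rnorm(n * T, sd = config$profile_noise_sd), n, T)
  dimnames(series) <- list(ids, stage_labels)
  list(fpkm = fpkm_matrix(2^series, log2_values = series, pseudocount = 0),
       truth = data.frame(gene_id = ids,
                          profile_id = vapply(profiles[assigned],
                                              function(p) p$id, integer(1)),
                          stringsAsFactors = FALSE))
}

#' Generate random mature miRNA sequences
#'
#' Uniform-random RNA-alphabet sequences, used as scanning input for the
#' target-prediction stage.
#'
#' @param n number of miRNAs; ids are `mir-001` ...
#' @param length mature sequence length in nt.
#' @param seed RNG seed.
#' @return named character vector of RNA sequences.
#' @export
gen_mirna_sequences <- function(n, length = 22, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
          collapse = ""), "")
  names(seqs) <- sprintf("mir-%03d", seq_len(n))
  seqs
}

#' Generate 3'-UTR sequences with planted seed-complement sites
#'
#' Backgrounds are uniform-random DNA of the given length; for every planted
#' (miRNA, gene) pair the DNA reverse complement of the miRNA's seed
#' (positions 2-8) is written into the gene's UTR at a random, recorded,
#' non-overlapping position.  Motifs listed in `forbid` (plus, optionally,
#' all planted motifs outside their planted positions) are removed from
#' backgrounds by rejection sampling so that null inputs carry zero matches.
#'
#' @param config a [sim_config()] (supplies the seed and `n_genes`).
#' @param true_targets data.frame with columns `mirna_id`, `gene_id`; may be
#'   empty.
#' @param mirna_seqs named RNA sequences (e.g. from [gen_mirna_sequences()]).
#' @param utr_length UTR length in nt (>= 7).
#' @param gene_ids gene identifiers; defaults to `gene-0001` ...
#' @param forbid character vector of DNA 7-mers excluded from backgrounds by
#'   rejection sampling.
#' @return list with `utrs` (a [Biostrings::DNAStringSet]) and `truth`
#'   (data.frame `mirna_id`, `gene_id`, `start`, `end`, `motif`).
#' @export
gen_utr_sequences <- function(config, true_targets, mirna_seqs,
                              utr_length = 500, gene_ids = NULL,
                              forbid = character()) {
  stopifnot(inherits(config, "sim_config"))
  if (utr_length < 7) stop("UTR length must be at least 7 nt")
  set.seed(config$seed + 2L)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene-%04d", seq_len(config$n_genes))
  if (nrow(true_targets) > 0) {
    bad <- setdiff(true_targets$mirna_id, names(mirna_seqs))
    if (length(bad)) stop("planted miRNA without sequence: ", bad[1])
    if (!all(true_targets$gene_id %in% gene_ids))
      stop("planted gene outside the gene universe")
  }
  rand_utr <- function() paste(sample(c("A", "C", "G", "T"), utr_length,
                                      replace = TRUE), collapse = "")
  has_forbidden <- function(s) any(vapply(forbid, grepl, TRUE, x = s,
                                          fixed = TRUE))
  utrs <- vapply(gene_ids, function(g) {
    s <- rand_utr()
    while (length(forbid) && has_forbidden(s)) s <- rand_utr()
    s
  }, "")
  truth <- NULL
  if (nrow(true_targets) > 0) {
    motifs <- vapply(true_targets$mirna_id, function(m)
      seed_site_motif(extract_seed(mirna_seqs[[m]])), "")
    occupied <- lapply(gene_ids, function(g) integer(0))
    names(occupied) <- gene_ids
    starts <- integer(nrow(true_targets))
    for (i in seq_len(nrow(true_targets))) {
      g <- true_targets$gene_id[i]
      repeat {
        pos <- sample.int(utr_length - 6L, 1L)
        if (!any(abs(occupied[[g]] - pos) < 7L)) break
      }
      occupied[[g]] <- c(occupied[[g]], pos)
      substr(utrs[[g]], pos, pos + 6L) <- motifs[i]
      starts[i] <- pos
    }
    truth <- data.frame(mirna_id = true_targets$mirna_id,
                        gene_id = true_targets$gene_id,
                        start = starts, end = starts + 6L,
                        motif = motifs, row.names = NULL,
                        stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(mirna_id = character(), gene_id = character(),
                        start = integer(), end = integer(),
                        motif = character())
  }
  list(utrs = Biostrings::DNAStringSet(utrs), truth = truth)
}

#' Generate a symmetric gene-gene interaction-score table
#'
#' Emulates an offline STRING-style export: one row per unordered gene pair
#' with a combined score in `[0, 1]` and a validated/predicted evidence flag.
#' Self-pairs are rejected and duplicate unordered pairs are collapsed to a
#' single row (first occurrence kept).
#'
#' @param gene_pairs data.frame with columns `gene_a`, `gene_b`.
#' @param score_range length-2 numeric range the scores are drawn from.
#' @param validated_frac expected fraction of pairs flagged `validated`.
#' @param seed RNG seed.
#' @return data.frame `gene_a`, `gene_b`, `score`, `evidence`.
#' @export
gen_interaction_table <- function(gene_pairs, score_range = c(0.15, 0.999),
                                  validated_frac = 0.25, seed = 1) {
  if (nrow(gene_pairs) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), evidence = character()))
  if (any(gene_pairs$gene_a == gene_pairs$gene_b))
    stop("self-pairs are not allowed in the interaction table")
  key <- apply(cbind(gene_pairs$gene_a, gene_pairs$gene_b), 1,
               function(r) paste(sort(r), collapse = "|"))
  keep <- !duplicated(key)
  gene_pairs <- gene_pairs[keep, , drop = FALSE]
  set.seed(seed)
  n <- nrow(gene_pairs)
  data.frame(gene_a = gene_pairs$gene_a, gene_b = gene_pairs$gene_b,
             score = stats::runif(n, score_range[1], score_range[2]),
             evidence = ifelse(stats::runif(n) < validated_frac,
                               "validated", "predicted"),
             row.names = NULL, stringsAsFactors = FALSE)
}
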