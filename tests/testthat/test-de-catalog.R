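make_results <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(mirna_id = r[[1]], stage = r[[2]], de = r[[3]],
               direction = r[[4]], stringsAsFactors = FALSE)))
  df
}

test_that("group classification applies the at-least-one-stage rule", {
  res <- make_results(list(
    list("mirA", "35E", TRUE, "up"),
    list("mirA", "2P", FALSE, "none"),
    list("mirB", "49E", TRUE, "down"),
    list("mirB", "90P", TRUE, "down"),
    list("mirC", "180P", TRUE, "up"),
    list("mirD", "63E", FALSE, "none")))
  cat <- classify_groups(res, stage_grouping())
  expect_equal(cat$sets$G1_up, "mirA")
  expect_equal(cat$sets$G1_down, "mirB")
  expect_equal(cat$sets$G2_up, "mirC")
  expect_equal(cat$sets$G2_down, "mirB")
  sc <- cat$stage_counts
  expect_equal(sc$n_total[sc$stage == "35E"], 1)
  expect_true(all(sc$n_up + sc$n_down == sc$n_total))
})

test_that("dual-direction miRNAs are retained in both sets with a warning", {
  res <- make_results(list(
    list("mirX", "35E", TRUE, "up"),
    list("mirX", "49E", TRUE, "down"),
    list("mirY", "2P", TRUE, "up")))
  expect_warning(cat <- classify_groups(res, stage_grouping()),
                 "both directions")
  expect_true("mirX" %in% cat$sets$G1_up)
  expect_true("mirX" %in% cat$sets$G1_down)
})

test_that("classification matches a brute-force set builder on random flags", {
  set.seed(14)
  grouping <- stage_grouping()
  for (rep in 1:5) {
    ids <- sprintf("m%02d", 1:30)
    df <- expand.grid(mirna_id = ids, stage = DEFAULT_STAGES,
                      stringsAsFactors = FALSE)
    df$de <- runif(nrow(df)) < 0.2
    df$direction <- ifelse(df$de, sample(c("up", "down"), nrow(df), TRUE),
                           "none")
    cat <- suppressWarnings(classify_groups(df, grouping))
    for (g in c("G1", "G2")) for (d in c("up", "down")) {
      brute <- sort(unique(df$mirna_id[
        df$de & df$direction == d & df$stage %in% grouping[[g]]]))
      expect_equal(cat$sets[[paste0(g, "_", d)]], brute)
    }
  }
})

test_that("classification errors on unknown stages and uncovered groups", {
  res <- make_results(list(list("m1", "35E", TRUE, "up")))
  res$stage <- "77dpc"
  expect_error(classify_groups(res, stage_grouping()), "absent")
  res$stage <- "35E"
  expect_error(classify_groups(res, stage_grouping()), "G2")
})

test_that("Venn overlaps partition the sets exactly", {
  sets <- list(A = c("a", "b", "c"), B = c("c", "d"), C = c("x"),
               D = c("a", "b", "c"))
  expect_equal(venn_overlap(sets, "A", "B"),
               c(only_a = 2, shared = 1, only_b = 1))
  expect_equal(venn_overlap(sets, "A", "C"),
               c(only_a = 3, shared = 0, only_b = 1))
  expect_equal(unname(venn_overlap(sets, "A", "D")[c(1, 3)]), c(0, 0))
  expect_error(venn_overlap(sets, "A", "nope"), "unknown set")
  set.seed(5)
  for (i in 1:10) {
    a <- sample(letters, sample(1:20, 1))
    b <- sample(letters, sample(1:20, 1))
    v <- venn_overlap(list(a = a, b = b), "a", "b")
    expect_equal(unname(v["shared"]), length(intersect(a, b)))
    expect_equal(unname(v["only_a"] + v["shared"]), length(unique(a)))
  }
})

test_that("abundance ranking matches a naive sort oracle", {
  set.seed(8)
  m <- matrix(runif(20 * 4, 0, 1e5), 20, 4,
              dimnames = list(sprintf("m%02d", 1:20),
                              c("LR_35E", "LT_35E", "LR_2P", "LT_2P")))
  tpm <- tpm_matrix(m, colSums(m))
  sel <- sprintf("m%02d", 1:15)
  top <- top_abundant(tpm, sel, stages = "35E", k = 10)
  stat <- rowMeans(m[sel, 1:2])
  expect_equal(top$mirna_id, names(sort(stat, decreasing = TRUE))[1:10])
  # k larger than the set returns the whole set; singleton works
  expect_equal(nrow(top_abundant(tpm, "m01", stages = "35E", k = 5)), 1)
  expect_equal(nrow(top_abundant(tpm, sel, stages = "2P", k = 100)), 15)
  expect_equal(nrow(top_abundant(tpm, character(), stages = "35E")), 0)
})

test_that("PCA ordination is an exact decomposition with fixed signs", {
  set.seed(19)
  m <- matrix(rlnorm(30 * 6, 5, 1), 30, 6,
              dimnames = list(sprintf("m%02d", 1:30),
                              paste0("L", 1:6, "_s")))
  # duplicate a sample: identical scores expected
  m[, 6] <- m[, 5]
  ord <- pca_ordination(m)
  expect_equal(ord$scores[5, ], ord$scores[6, ])
  expect_true(all(ord$variance_fraction >= 0))
  expect_lte(sum(ord$variance_fraction), 1 + 1e-9)
  # reconstruction of the centred matrix from all components
  x <- t(log2(m + 1))
  centred <- sweep(x, 2, colMeans(x))
  expect_equal(unname(ord$scores %*% t(ord$loadings)), unname(centred),
               tolerance = 1e-8)
  # per-component dominant loading is positive
  for (j in seq_len(ncol(ord$loadings)))
    expect_gte(ord$loadings[which.max(abs(ord$loadings[, j])), j], 0)
  expect_error(pca_ordination(m[, 1, drop = FALSE]), "2 samples")
})

test_that("PCA scores match an independent eigendecomposition", {
  m <- matrix(c(2, 4, 8, 1, 9, 3, 5, 7, 6), 3, 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  ord <- pca_ordination(m, pseudocount = 1)
  x <- t(log2(m + 1))
  S <- cov(x) * (nrow(x) - 1) / nrow(x)  # scaling cancels in directions
  ev <- eigen(S, symmetric = TRUE)
  sc <- scale(x, center = TRUE, scale = FALSE) %*% ev$vectors
  for (j in 1:2) {
    r <- abs(cor(ord$scores[, j], sc[, j]))
    expect_equal(r, 1, tolerance = 1e-8)
  }
})

test_that("hypergeometric enrichment matches direct summation", {
  ann <- data.frame(term_id = rep("T1", 5),
                    member_id = paste0("g", 1:5), stringsAsFactors = FALSE)
  universe <- paste0("g", 1:20)
  sel <- paste0("g", c(1:4, 10, 11))  # overlap 4 with the term
  res <- enrich_terms(sel, universe, ann)
  expect_equal(res$p, 540 / 38760, tolerance = 1e-12)
  expect_equal(res$p, oracle_hyper(4, 5, 20, 6), tolerance = 1e-12)
  # selection = universe and zero-overlap terms: p = 1
  res_all <- enrich_terms(universe, universe, ann)
  expect_equal(res_all$p, 1)
  ann0 <- data.frame(term_id = "T2", member_id = "g20")
  expect_equal(enrich_terms(paste0("g", 1:3), universe, ann0)$p, 1)
  expect_error(enrich_terms("zz", universe, ann), "outside the universe")
})

test_that("enrichment p-values decrease in overlap for fixed margins", {
  ps <- vapply(0:5, oracle_hyper, numeric(1), term = 5, universe = 20,
               selection = 6)
  univ <- paste0("g", 1:20)
  got <- vapply(0:5, function(k) {
    sel <- c(if (k > 0) paste0("g", seq_len(k)),
             paste0("g", 6:20)[seq_len(6 - k)])
    ann <- data.frame(term_id = "T", member_id = paste0("g", 1:5))
    enrich_terms(sel, univ, ann)$p
  }, numeric(1))
  expect_equal(got, ps, tolerance = 1e-12)
  expect_true(all(diff(got) < 0))
})
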