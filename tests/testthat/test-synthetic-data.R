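test_that("configuration invariants are enforced", {
  expect_error(sim_config(stages = DEFAULT_STAGES[c(1:7, 7)]), "distinct")
  expect_error(sim_config(stages = c(DEFAULT_STAGES[1:6], "100E", "200P")),
               "split")
  expect_error(sim_config(library_size = 0), "library_size")
  expect_error(sim_config(planted_de = list(
    list(mirna = "mir-001", stages = "35E", log2fc = Inf))), "finite")
  expect_error(sim_config(planted_de = list(
    list(mirna = "mir-001", stages = "bogus", log2fc = 1))), "stage")
})

test_that("count generator is deterministic and structurally sound", {
  cfg <- sim_config(n_mirnas = 40, seed = 1)
  a <- gen_count_libraries(cfg)
  b <- gen_count_libraries(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_equal(ncol(a$counts$counts), 16)  # 2 breeds x 8 stages
  expect_true(all(a$counts$counts >= 0))
  expect_true(all(a$counts$counts == floor(a$counts$counts)))
  expect_true(all(colSums(a$counts$counts) <= a$counts$library_sizes))
  # expected column mass: mirna_fraction * library size, within 3 Poisson sds
  mu <- cfg$mirna_fraction * cfg$library_size
  expect_true(all(abs(colSums(a$counts$counts) - mu) < 3 * sqrt(mu)))
})

test_that("configurations without library-size headroom are rejected", {
  planted <- lapply(sprintf("mir-%03d", 1:20), function(m)
    list(mirna = m, stages = "49E", log2fc = 4))
  cfg <- sim_config(n_mirnas = 40, planted_de = planted,
                    mirna_fraction = 0.9, seed = 3)
  expect_error(gen_count_libraries(cfg), "headroom")
  # with headroom, all library sizes are the nominal total
  ok <- gen_count_libraries(sim_config(n_mirnas = 40, seed = 3))
  expect_true(all(ok$counts$library_sizes == 1e6))
})

test_that("null generator centres empirical log2 fold changes on zero", {
  cfg <- sim_config(n_mirnas = 150, seed = 9)
  sim <- gen_count_libraries(cfg)
  tpm <- tpm_normalize(sim$counts)
  lfc <- log2((tpm$tpm[, "LT_35E"] + 0.5) / (tpm$tpm[, "LR_35E"] + 0.5))
  expect_lt(abs(mean(lfc)), 0.05)
})

test_that("planted effects are recovered at the planted magnitude", {
  ids <- sprintf("mir-%03d", 1:20)
  planted <- lapply(ids, function(m)
    list(mirna = m, stages = "49E", log2fc = 2))
  reps <- vapply(1:50, function(s) {
    cfg <- sim_config(n_mirnas = 200, planted_de = planted, seed = s)
    sim <- gen_count_libraries(cfg)
    x <- sim$counts$counts[ids, "LR_49E"]
    y <- sim$counts$counts[ids, "LT_49E"]
    mean(log2_fold_change(x, y, sim$counts$library_sizes[["LR_49E"]],
                          sim$counts$library_sizes[["LT_49E"]]))
  }, numeric(1))
  expect_lt(abs(mean(reps) - 2), 0.2)
})

test_that("negative-binomial noise inflates variance beyond Poisson", {
  cfg_p <- sim_config(n_mirnas = 500, seed = 4, noise_model = "poisson")
  cfg_nb <- sim_config(n_mirnas = 500, seed = 4,
                       noise_model = "negative_binomial", dispersion = 0.5)
  vp <- apply(gen_count_libraries(cfg_p)$counts$counts, 1, var)
  vnb <- apply(gen_count_libraries(cfg_nb)$counts$counts, 1, var)
  expect_gt(median(vnb / (vp + 1)), 1)
})

test_that("expression generator reproduces templates in the noiseless limit", {
  profiles <- generate_model_profiles(4, 1)
  cfg <- sim_config(n_genes = 54, profile_noise_sd = 0, seed = 2)
  ex <- gen_expression_profiles(cfg, profiles)
  ex2 <- gen_expression_profiles(cfg, profiles)
  expect_identical(ex$fpkm$fpkm, ex2$fpkm$fpkm)
  vals <- t(vapply(profiles, function(p) as.numeric(p$values), numeric(4)))
  for (i in seq_len(54)) {
    tmpl <- vals[ex$truth$profile_id[i] + 1, ]
    if (var(tmpl) == 0) next  # flat template: correlation undefined
    expect_equal(cor(ex$fpkm$log2_values[i, ], tmpl), 1)
  }
})

test_that("UTR generator plants scannable sites at recorded positions", {
  mir <- gen_mirna_sequences(5, seed = 3)
  tt <- data.frame(mirna_id = names(mir)[c(1, 2, 2)],
                   gene_id = c("gene-0001", "gene-0001", "gene-0002"),
                   stringsAsFactors = FALSE)
  cfg <- sim_config(n_genes = 3, seed = 8)
  sim <- gen_utr_sequences(cfg, tt, mir)
  expect_equal(nrow(sim$truth), 3)
  for (i in seq_len(nrow(sim$truth))) {
    hit <- scan_utr(extract_seed(mir[[sim$truth$mirna_id[i]]]),
                    as.character(sim$utrs[[sim$truth$gene_id[i]]]))
    expect_true(sim$truth$start[i] %in% hit$start)
  }
  expect_error(gen_utr_sequences(cfg, tt, mir, utr_length = 6), "7 nt")
})

test_that("rejection sampling removes a motif from null backgrounds", {
  mir <- gen_mirna_sequences(1, seed = 6)
  motif <- seed_site_motif(extract_seed(mir[[1]]))
  cfg <- sim_config(n_genes = 30, seed = 10)
  sim <- gen_utr_sequences(cfg, data.frame(mirna_id = character(),
                                           gene_id = character()),
                           mir, forbid = motif)
  hits <- predict_targets(mir, sim$utrs)
  expect_equal(nrow(hits), 0)
})

test_that("interaction table is deduplicated, scored in range, no self-pairs", {
  expect_equal(nrow(gen_interaction_table(
    data.frame(gene_a = character(), gene_b = character()))), 0)
  pairs <- data.frame(gene_a = paste0("g", 1:48),
                      gene_b = paste0("g", 2:49))
  tab <- gen_interaction_table(pairs, seed = 2)
  expect_equal(nrow(tab), 48)
  expect_true(all(tab$score >= 0 & tab$score <= 1))
  dup <- data.frame(gene_a = c("g1", "g2"), gene_b = c("g2", "g1"))
  expect_equal(nrow(gen_interaction_table(dup)), 1)
  expect_error(gen_interaction_table(
    data.frame(gene_a = "g1", gene_b = "g1")), "self-pair")
})
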