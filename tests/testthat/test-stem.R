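test_that("profile universe enumeration follows the (2c+1)^(T-1) law", {
  p <- generate_model_profiles(2, 1)
  expect_equal(lapply(p, `[[`, "values"),
               list(c(0L, -1L), c(0L, 0L), c(0L, 1L)))
  expect_equal(length(generate_model_profiles(4, 2)), 125)
  for (c in 1:3) for (T in 2:4)
    expect_equal(length(generate_model_profiles(T, c)), (2 * c + 1)^(T - 1))
  p27 <- generate_model_profiles(4, 1)
  vals <- vapply(p27, function(x) paste(x$values, collapse = ","), "")
  expect_equal(length(unique(vals)), 27)
  expect_true(all(vapply(p27, function(x) x$values[1] == 0, TRUE)))
  expect_true(all(vapply(p27, function(x) max(abs(diff(x$values))) <= 1, TRUE)))
  expect_equal(vapply(p27, `[[`, integer(1), "id"), 0:26)
  expect_error(generate_model_profiles(1, 1), "T must")
  expect_error(generate_model_profiles(4, 0), "c must")
})

test_that("representative selection is greedy max-min with documented start", {
  cand <- generate_model_profiles(3, 1)
  # independent greedy trace: distances over non-flat candidates
  keep <- which(vapply(cand, function(p) var(p$values) > 0, TRUE))
  V <- t(vapply(cand[keep], function(p) as.numeric(p$values), numeric(3)))
  D <- 1 - cor(t(V))
  start <- keep[which.max(rowSums(D))]
  sel1 <- select_representative_profiles(cand, 1)
  expect_equal(sel1[[1]]$id, cand[[start]]$id)
  # m >= candidates returns all non-flat candidates
  all_sel <- select_representative_profiles(cand, 100)
  expect_equal(length(all_sel), length(keep))
  # full greedy trace for m = 3
  trace <- which.max(rowSums(D))
  while (length(trace) < 3) {
    mind <- apply(D[, trace, drop = FALSE], 1, min)
    mind[trace] <- -Inf
    trace <- c(trace, which.max(mind))
  }
  sel3 <- select_representative_profiles(cand, 3)
  expect_equal(sort(vapply(sel3, `[[`, integer(1), "id")),
               sort(vapply(cand[keep[trace]], `[[`, integer(1), "id")))
  expect_error(select_representative_profiles(cand, 0), "m must")
})

test_that("series transform starts at zero and is idempotent", {
  expect_equal(transform_series(c(3, 3, 3, 3)), c(0, 0, 0, 0))
  expect_equal(transform_series(c(0, 1, -1, 2)), c(0, 1, -1, 2))
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(transform_series(transform_series(x)), transform_series(x))
  expect_equal(unname(transform_series(x)[, 1]), c(0, 0, 0))
})

test_that("assignment picks the max-correlation profile, ties to lowest id", {
  profiles <- select_representative_profiles(generate_model_profiles(4, 2), 20)
  vals <- t(vapply(profiles, function(p) as.numeric(p$values), numeric(4)))
  ids <- vapply(profiles, `[[`, integer(1), "id")
  series <- rbind(exact = vals[7, ], const = c(2, 2, 2, 2))
  a <- assign_profiles(series, profiles)
  expect_equal(a$profile_id[1], ids[7])
  expect_equal(a$r[1], 1)
  expect_true(a$excluded[2])
  expect_equal(a$reason[2], "constant series")
  expect_true(is.na(a$profile_id[2]))
  # 200 random genes against a brute-force argmax oracle
  set.seed(23)
  g <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  got <- assign_profiles(g, profiles)
  ts <- transform_series(g)
  for (i in seq_len(200)) {
    rs <- apply(vals, 1, function(v) cor(ts[i, ], v))
    expect_equal(got$profile_id[i], ids[which.max(rs)])
    expect_equal(got$r[i], max(rs))
  }
  expect_error(assign_profiles(g[, 1:3], profiles), "length")
})

test_that("permutation significance uses all T! orderings and binomial tails", {
  profiles <- select_representative_profiles(generate_model_profiles(4, 1), 10)
  set.seed(41)
  g <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(sprintf("g%02d", 1:60), NULL))
  asg <- assign_profiles(g, profiles)
  enr <- profile_significance(g, profiles, assignments = asg)
  # 24 permutations enumerated for T = 4; expected counts sum to n assigned
  expect_equal(sum(enr$expected), sum(!asg$excluded), tolerance = 1e-9)
  expect_equal(sum(enr$observed), sum(!asg$excluded))
  expect_true(all(enr$p >= 0 & enr$p <= 1))
  # p-values match the direct binomial-tail oracle
  n <- sum(!asg$excluded)
  for (i in seq_len(nrow(enr))) {
    expect_equal(enr$p[i],
                 oracle_binom_tail(enr$observed[i], n,
                                   min(1, enr$expected[i] / n)),
                 tolerance = 1e-9)
  }
  expect_equal(enr$p_corrected, pmin(1, enr$p * length(profiles)))
  # observed = 0 gives p = 1
  expect_true(all(enr$p[enr$observed == 0] == 1))
  expect_equal(oracle_binom_tail(5, 10, 0.2),
               pbinom(4, 10, 0.2, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("planted-template genes are recovered and flagged significant", {
  sel <- select_representative_profiles(generate_model_profiles(4, 2), 50)
  vals <- t(vapply(sel, function(p) as.numeric(p$values), numeric(4)))
  ids <- vapply(sel, `[[`, integer(1), "id")
  a <- which.max(cor(t(vals), c(0, 1, 2, 3))[, 1])
  cfg <- sim_config(n_genes = 1000, profile_noise_sd = 0.25, seed = 6)
  ti <- c(rep(a, 100), rep(setdiff(seq_along(sel), a), length.out = 900))
  ex <- gen_expression_profiles(cfg, sel, template_index = ti)
  asg <- assign_profiles(ex$fpkm$log2_values, sel)
  # planted genes land on a profile within correlation distance 0.1
  d <- 1 - cor(t(vals), vals[a, ])[, 1]
  near <- d[match(asg$profile_id[1:100], ids)] <= 0.1
  expect_gte(mean(near), 0.95)
  enr <- profile_significance(ex$fpkm$log2_values, sel, assignments = asg)
  expect_true(enr$significant[enr$profile_id == ids[a]])
  expect_lt(enr$p_corrected[enr$profile_id == ids[a]], 0.05)
})
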