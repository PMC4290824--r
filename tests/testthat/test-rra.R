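test_that("beta order-statistic p-values match the closed-form CDF", {
  expect_equal(beta_order_pvalues(0.1), 0.1)          # Beta(1,1) uniform
  expect_equal(beta_order_pvalues(c(0.1, 0.5)),
               c(1 - 0.9^2, 0.5^2), tolerance = 1e-12)
  withr::with_seed(31, {
    for (n in 2:5) {
      for (rep in 1:20) {
        u <- sort(runif(n))
        got <- beta_order_pvalues(u)
        want <- vapply(seq_len(n),
                       function(k) oracle_order_stat_cdf(u[k], k, n),
                       numeric(1))
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  })
  expect_error(beta_order_pvalues(c(0.5, 0.1)), "sorted")
  expect_error(beta_order_pvalues(c(0, 0.5)), "0, 1")
})

test_that("beta order p-values agree with Monte-Carlo order statistics", {
  withr::with_seed(47, {
    n <- 5
    draws <- matrix(runif(2e5 * n), ncol = n)
    draws <- t(apply(draws, 1, sort))
    u <- sort(runif(n))
    for (k in 1:n) {
      mc <- mean(draws[, k] <= u[k])
      se <- sqrt(mc * (1 - mc) / nrow(draws))
      expect_lt(abs(beta_order_pvalues(u)[k] - mc), 3 * se + 1e-12)
    }
  })
})

test_that("alpha selection combines the p cut and the rank cut", {
  cfg <- alpha_config(p_threshold = 0.05)
  expect_identical(alpha_select(c(0.2, 0.4, 0.9), cfg),
                   c(FALSE, FALSE, FALSE))
  # degenerate classic-RRA limit: everything is good
  all_cfg <- alpha_config(p_threshold = 1, alpha_percent = 1)
  expect_identical(alpha_select(c(0.2, 0.4, 0.999), all_cfg),
                   c(TRUE, TRUE, TRUE))
  # default alpha: realized fraction below the threshold (prefix of 2)
  p_ranked <- c(0.01, 0.04, 0.2, 0.5, 0.9)
  expect_identical(alpha_select(p_ranked, cfg),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # explicit alpha tighter than the p cut wins
  tight <- alpha_config(p_threshold = 0.05, alpha_percent = 0.2)
  expect_identical(alpha_select(p_ranked, tight),
                   c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("rho is the min over the good prefix and ignores the rest", {
  u <- c(0.1, 0.5)
  expect_equal(rho_score(u, 2), 0.19)
  expect_equal(rho_score(u, 1), 0.19)
  expect_equal(rho_score(u, 0), 1)
  expect_error(rho_score(u, 3), "exceeds")

  # where the non-good sgRNAs sit never matters: for fixed n and a fixed
  # good prefix, moving the tail percentiles around leaves rho unchanged
  withr::with_seed(13, {
    for (rep in 1:20) {
      j <- sample(1:3, 1)
      u_good <- sort(runif(j, 0, 0.2))
      tail_a <- sort(runif(3, 0.5, 1))
      tail_b <- sort(runif(3, 0.5, 1))
      expect_equal(rho_score(c(u_good, tail_a), j),
                   rho_score(c(u_good, tail_b), j))
    }
  })

  # improving a good percentile never increases rho
  withr::with_seed(14, {
    for (rep in 1:20) {
      u <- sort(runif(4))
      j <- sample(1:4, 1)
      better <- u
      pick <- sample(seq_len(j), 1)
      better[pick] <- better[pick] * runif(1)
      expect_lte(rho_score(sort(better), j), rho_score(u, j))
    }
  })
})

test_that("the permutation null is uniform for single items and reproducible", {
  # n = 1, everything good: rho = u ~ Uniform(0, 1)
  null <- permutation_null(1, m = 10000, n_good = 10000,
                           num_permutations = 1e5, seed = 3)
  d <- suppressWarnings(ks.test(null[["1"]], "punif"))$statistic
  expect_lt(d, 0.01)

  again <- permutation_null(1, m = 10000, n_good = 10000,
                            num_permutations = 1e5, seed = 3)
  expect_identical(null, again)

  # degenerate: a single gene owning every sgRNA has a constant rho
  whole <- permutation_null(50, m = 50, n_good = 10,
                            num_permutations = 100, seed = 1)
  expect_length(unique(whole[["50"]]), 1L)
})

test_that("permutation p-values use the add-one estimator per size stratum", {
  null <- list("2" = c(0.1, 0.2, 0.3, 0.4), "3" = c(0.5, 0.6))
  expect_equal(gene_pvalues(0.05, 2, null), 1 / 5)   # beats all null
  expect_equal(gene_pvalues(1, 2, null), 1)          # rho = 1 never beats
  expect_equal(gene_pvalues(0.25, 2, null), 3 / 5)
  expect_equal(gene_pvalues(c(0.55, 0.05), c(3, 2), null),
               c(2 / 3, 1 / 5))
  expect_error(gene_pvalues(0.5, 4, null), "size")
})

test_that("BH q-values match the step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  withr::with_seed(53, {
    for (rep in 1:50) {
      p <- runif(sample(1:200, 1))
      q <- bh_fdr(p)
      expect_lt(max(abs(q - oracle_bh(p))), 1e-12)
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-15))
    }
  })
})

test_that("a gene owning the top ranks gets the best attainable p-value", {
  withr::with_seed(8, {
    m <- 400
    genes <- rep(sprintf("g%02d", 1:100), each = 4)
    p_ranked <- sort(c(runif(20, 0, 0.05), runif(m - 20, 0.05, 1)))
    # gene g01 owns ranks 1..4
    res <- data.frame(sgrna = sprintf("s%03d", 1:m), gene = genes,
                      control_mean = 100, treat_mean = 50,
                      p_low = p_ranked[order(seq_len(m))],
                      p_high = runif(m), all_zero = FALSE,
                      rank_neg = seq_len(m), rank_pos = sample(m))
    cfg <- alpha_config(num_permutations = 2000, seed = 4)
    gres <- gene_test(res, cfg, "neg")
    expect_identical(gres$gene[1], "g01")
    expect_equal(gres$perm_p[1], 1 / 2001)
    expect_identical(gres$rank, seq_len(100L))
  })
})

test_that("gene test output is deterministic for a fixed seed", {
  sim <- simulate_screen(sim_config(n_genes = 80, fraction_neg = 0.1,
                                    seed = 6))
  res <- run_screen(sim$table, sim_design(), alpha_config(seed = 99),
                    direction = "neg")
  res2 <- run_screen(sim$table, sim_design(), alpha_config(seed = 99),
                     direction = "neg")
  expect_identical(res$gene_neg, res2$gene_neg)
})

test_that("classic-RRA permutation p-values are null-uniform over genes", {
  sim <- simulate_screen(sim_config(seed = 11))
  res <- run_screen(sim$table, sim_design(),
                    alpha_config(p_threshold = 1, alpha_percent = 1,
                                 seed = 5),
                    direction = "neg")
  d <- suppressWarnings(ks.test(res$gene_neg$perm_p, "punif"))$statistic
  expect_lt(d, 0.05)
})

test_that("spiked depleted genes are recovered at the top of the ranking", {
  for (seed in 1:3) {
    sim <- simulate_screen(sim_config(fraction_neg = 0.04,
                                      effect_size = 4, seed = seed))
    res <- run_screen(sim$table, sim_design(), alpha_config(seed = seed),
                      direction = "neg")
    rec <- evaluate_recovery(res$gene_neg, sim$truth, top_k = 40)
    expect_gte(rec, 0.8)
  }
})

test_that("null screens produce no false gene discoveries", {
  sim <- simulate_screen(sim_config(seed = 11))
  res <- run_screen(sim$table, sim_design(), alpha_config(seed = 2),
                    direction = "neg")
  expect_lte(mean(res$gene_neg$fdr < 0.25), 0.05)
})
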