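# Validation harness plumbing (full-scale distributional checks live in
# the acceptance suite).

test_that("scenario i produces graphs without R-nodes", {
  p <- scenario_params("i", mode = "anc", seed = 2)
  # a reduced-size variant keeps this check cheap; r = 0 is what matters
  p2 <- sim_params(N_e = 40, L = 1e5, mu = 1e-7, r = 0, n_generations = 400,
                   sample_size = 10, mode = "anc", seed = 2)
  expect_equal(p$r, 0)
  res <- simulate_population(p2, store_graph = TRUE)
  expect_true(all(vapply(res$graphs, function(b) sum(b$kind == 2L),
                         integer(1)) == 0L))
})

test_that("run_scenario returns seeded per-replicate statistics", {
  df <- run_scenario("ii", mode = "anc", n_replicates = 3, seed = 100,
                     N_e = 40, L = 5e4, mu = 2e-7, r = 2e-7)
  expect_equal(nrow(df), 3L)
  expect_named(df, c("scenario", "mode", "replicate", "S", "pi", "K"))
  df2 <- run_scenario("ii", mode = "anc", n_replicates = 3, seed = 100,
                      N_e = 40, L = 5e4, mu = 2e-7, r = 2e-7)
  expect_identical(df, df2)
  # scenario v samples 75 haplotypes at full scale
  expect_equal(scenario_params("v")$sample_size, 75L)
})

test_that("mode_equivalence_test applies Bonferroni across the family", {
  set.seed(9)
  df <- rbind(tibble::tibble(mode = "anc", S = rpois(40, 50),
                             pi = rnorm(40, 20), K = rpois(40, 30)),
              tibble::tibble(mode = "for", S = rpois(40, 50),
                             pi = rnorm(40, 20), K = rpois(40, 30)),
              tibble::tibble(mode = "mix", S = rpois(40, 50),
                             pi = rnorm(40, 20), K = rpois(40, 30)))
  out <- mode_equivalence_test(df)
  expect_equal(nrow(out), 9L) # 3 pairs x 3 statistics
  expect_equal(unique(out$threshold), 0.01 / 9)
  expect_false(any(out$reject)) # identically distributed inputs
  # and a clearly shifted distribution is rejected
  df$S[df$mode == "mix"] <- df$S[df$mode == "mix"] + 40L
  out2 <- mode_equivalence_test(df)
  expect_true(any(out2$reject[out2$statistic == "S" &
                                (out2$mode_a == "mix" | out2$mode_b == "mix")]))
})

test_that("selection scenarios reduce diversity relative to a neutral control", {
  nrep <- 12
  sel <- run_selection_scenario(1, n_replicates = nrep, seed = 300)
  neu <- vapply(seq_len(nrep), function(k) {
    p <- selection_scenario_params(1, seed = 300 + k - 1L)
    p$neutral_fraction <- 1
    p$mode <- "anc"
    summary_stats(simulate_population(p)$matrices[[1]])$S
  }, numeric(1))
  expect_equal(nrow(sel), nrep)
  # one-sided: purifying selection lowers segregating sites
  expect_lt(mean(sel$S), mean(neu))
  expect_lt(t.test(sel$S, neu, alternative = "less")$p.value, 0.05)
  # scenario 2 (normal fitness effects) runs and reports the same battery
  sel2 <- run_selection_scenario(2, n_replicates = 3, seed = 900)
  expect_equal(nrow(sel2), 3L)
  expect_true(all(sel2$S >= 0))
})

test_that("the genome-scale runner reports per-locus and neutral totals", {
  g <- run_genome_scale(n_individuals = 20, scale = 0.003, seed = 5)
  expect_equal(nrow(g$per_locus), 23L)
  expect_equal(sum(g$per_locus$S), g$total_S)
  expect_lte(g$total_S_neutral, g$total_S)
  expect_equal(g$params$neutral_fraction, 0.9)
  expect_equal(sum(as.double(g$params$locus_lengths)),
               round(3.037e9 * 0.003), tolerance = 1e-3)
})
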