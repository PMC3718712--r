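# Forward engine: recombination draws, recombinants, mutation draws,
# fitness-proportional sampling, cleanup, determinism, engine agreement.

test_that("recombination breakpoint draws have Poisson moments and uniform positions", {
  expect_identical(draw_recombinations(1e6, 0), integer(0))
  set.seed(2)
  counts <- replicate(1e5, length(draw_recombinations(1e4, 1e-5))) # rate 0.1
  se <- sqrt(0.1 / 1e5)
  expect_lt(abs(mean(counts) - 0.1), 3 * se)
  expect_lt(abs(var(counts) - mean(counts)), 0.01) # variance ~ mean
  set.seed(3)
  pooled <- unlist(replicate(2000, draw_recombinations(1e6, 5e-6), simplify = FALSE))
  expect_gt(length(pooled), 5000)
  ks <- suppressWarnings(ks.test((pooled - 1) / (1e6 - 2), "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(pooled >= 1 & pooled <= 1e6 - 1))
})

test_that("make_recombinant splices alternating donor segments", {
  expect_equal(make_recombinant(c(10, 500), 300, breakpoints = integer(0)),
               c(10, 500))
  expect_equal(make_recombinant(c(10, 500), 300, breakpoints = 250),
               c(10, 300))
  expect_error(make_recombinant(1, 2, breakpoints = c(30, 10)), "sorted")
  set.seed(4)
  for (i in 1:1000) {
    a <- sort(sample.int(1000, rpois(1, 8)))
    b <- sort(sample.int(1000, rpois(1, 8)))
    bps <- sort(sample.int(999, rpois(1, 3)))
    expect_identical(make_recombinant(a, b, bps), brute_recombinant(a, b, bps))
  }
})

test_that("selected-mutation draws are thinned Poisson with model coefficients", {
  p <- tiny_params(N_e = 50, L = 1e5, mu = 2e-5, neutral_fraction = 0.9,
                   selection_model = selection_fixed(0.01, 0.2))
  expect_equal(nrow(draw_selected_mutations(tiny_params(neutral_fraction = 1),
                                            n_gametes = 50)), 0)
  set.seed(5)
  d <- draw_selected_mutations(p, n_gametes = 1e5) # per-gamete rate 0.2
  m <- nrow(d) / 1e5
  expect_lt(abs(m - 0.2), 3 * sqrt(0.2 / 1e5))
  expect_lt(abs(mean(d$s < 0) - 0.2), 4 * sqrt(0.2 * 0.8 / nrow(d)))
  expect_true(all(d$position >= 0 & d$position < 1e5))
})

test_that("offspring draw parents proportionally to fitness", {
  p <- sim_params(N_e = 2, L = 100, mu = 0, r = 0, neutral_fraction = 0.5,
                  n_generations = 1, sample_size = 2, seed = 8)
  st <- founder_population(p)
  # give individual 2 a deleterious mutation with s = 0.5 on one haplotype
  id <- begsim:::.reg_add(st$registry, 0L, 10L, 0L, 2L, 1L, 0.5, FALSE)
  st$haps[[1]][[3]] <- id
  st$hap_fitness[3] <- 0.5
  set.seed(8)
  st2 <- step_generation(st, p, N_next = 9000)
  freq1 <- mean(st2$log$parents[[2]] == 0) # fitness 1 vs 0.5 -> 2/3
  expect_lt(abs(freq1 - 2 / 3), 4 * sqrt((2 / 3) * (1 / 3) / 18000))
})

test_that("zero total fitness is a degenerate-population error", {
  p <- sim_params(N_e = 2, L = 100, mu = 0, r = 0, neutral_fraction = 0.5,
                  n_generations = 1, sample_size = 2, seed = 8)
  st <- founder_population(p)
  st$hap_fitness[] <- 0
  expect_error(step_generation(st, p, N_next = 2), "degenerate")
})

test_that("a single-individual population transmits verbatim copies", {
  p <- sim_params(N_e = 1, L = 1000, mu = 0, r = 0, n_generations = 3,
                  sample_size = 2, mode = "for", seed = 2)
  fr <- run_forward(p)
  expect_true(all(vapply(fr$final_haps[[1]], length, integer(1)) == 0))
  for (g in 1:3) expect_equal(fr$ancestry$parents[[g + 1]], c(0L, 0L))
  expect_equal(nrow(fr$ancestry$rec), 0L)
})

test_that("under neutrality parent choices are uniform", {
  p <- tiny_params(N_e = 40, L = 1000, mu = 1e-5, r = 0, n_generations = 100,
                   mode = "for", seed = 6)
  fr <- run_forward(p)
  draws <- unlist(fr$ancestry$parents[-1])
  tab <- tabulate(draws + 1L, nbins = 40)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("runs are deterministic given the seed", {
  p <- tiny_params(N_e = 15, L = 2000, mu = 1e-4, r = 1e-4,
                   n_generations = 60, mode = "for", seed = 11)
  a <- run_forward(p)
  b <- run_forward(p)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$final_haps, b$final_haps)
  expect_identical(a$ancestry$rec$breakpoints, b$ancestry$rec$breakpoints)
})

test_that("n_generations = 0 returns the founder population with empty ancestry", {
  p <- sim_params(N_e = 5, L = 100, mu = 1e-3, r = 0, n_generations = 0,
                  sample_size = 4, mode = "for", seed = 1)
  fr <- run_forward(p)
  expect_equal(nrow(fr$mutations), 0L)
  expect_length(fr$ancestry$parents, 1L)
  expect_true(all(vapply(fr$final_haps[[1]], length, integer(1)) == 0))
})

test_that("reference R engine and compiled engine are bit-identical", {
  p <- sim_params(N_e = 8, L = 500, mu = 5e-4, r = 5e-4, n_generations = 25,
                  neutral_fraction = 0.6,
                  selection_model = selection_fixed(0.05, 0.3),
                  sample_size = 6, mode = "mix", seed = 7)
  a <- run_forward(p, engine = "cpp")
  b <- run_forward(p, engine = "r")
  expect_identical(a$mutations, b$mutations)
  expect_identical(lapply(a$final_haps[[1]], as.integer),
                   lapply(b$final_haps[[1]], as.integer))
  expect_identical(lapply(a$ancestry$parents, as.integer),
                   lapply(b$ancestry$parents, as.integer))
  expect_equal(a$hap_fitness, b$hap_fitness)
  # and with the normal selection model over two loci
  p2 <- sim_params(N_e = 6, locus_lengths = c(400, 250), mu = 8e-4, r = 8e-4,
                   n_generations = 20, neutral_fraction = 0.5,
                   selection_model = selection_normal(-0.02, 0.01),
                   sample_size = 6, mode = "for", seed = 11)
  a2 <- run_forward(p2, engine = "cpp")
  b2 <- run_forward(p2, engine = "r")
  expect_identical(a2$mutations, b2$mutations)
  expect_identical(lapply(a2$ancestry$homolog_bits[[2]], as.integer),
                   lapply(b2$ancestry$homolog_bits[[2]], as.integer))
})

test_that("fixed-mutation cleanup is pure bookkeeping", {
  p1 <- tiny_params(N_e = 10, L = 2000, mu = 5e-4, r = 1e-4,
                    n_generations = 150, mode = "for", seed = 13,
                    cleanup_interval = 100)
  p2 <- p1
  p2$cleanup_interval <- 1000000L # never triggers
  a <- run_forward(p1)
  b <- run_forward(p2)
  seg_set <- function(fr) {
    ids <- unlist(fr$final_haps[[1]])
    cnt <- table(ids)
    nh <- 2 * fr$sizes[length(fr$sizes)]
    sort(unique(fr$registry_raw$position[as.integer(names(cnt)[cnt < nh]) + 1L]))
  }
  expect_gt(sum(!is.na(a$mutations$fixed_generation)), 0) # something was archived
  expect_identical(seg_set(a), seg_set(b))
  # archived mutations are gone from every haplotype
  fixed_ids <- which(!is.na(a$mutations$fixed_generation)) - 1L
  expect_false(any(fixed_ids %in% unlist(a$final_haps[[1]])))
})
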