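# Ancestry log: recording, parent lookup, homolog pairing, storage report,
# event-log export.

test_that("parent lookup follows the even/odd homolog pairing", {
  anc <- ancestry_log(sizes = c(4, 4))
  anc <- ancestry_record(anc, 1, 0, 6)
  anc <- ancestry_record(anc, 1, 1, 7)
  expect_equal(parent_of(anc, 1, 0), list(parent = 6L, homolog = 7L))
  expect_equal(parent_of(anc, 1, 1), list(parent = 7L, homolog = 6L))
  expect_error(parent_of(anc, 0, 0), "founders")
  expect_error(ancestry_record(anc, 1, 0, 99), "out of range")
  expect_error(ancestry_record(anc, 1, 42, 0), "out of range")
})

test_that("recorded events replay the engine's pedigree exactly", {
  for (seed in 1:5) {
    p <- tiny_params(N_e = 8, L = 1000, mu = 1e-4, r = 2e-4,
                     n_generations = 30, mode = "for", seed = seed)
    fr <- run_forward(p)
    pm <- begsim:::hap_parent_map(fr$ancestry)
    for (g in seq_len(p$n_generations)) {
      # total map: every child haplotype has exactly one in-range parent
      expect_length(pm[[g + 1]], 2L * fr$sizes[g + 1])
      expect_true(all(pm[[g + 1]] >= 0 & pm[[g + 1]] < 2L * fr$sizes[g]))
    }
    # point lookups agree with the bulk map
    g <- p$n_generations
    po <- parent_of(fr$ancestry, g, 3L)
    expect_equal(po$parent, pm[[g + 1]][4])
    expect_equal(po$homolog, bitwXor(po$parent, 1L))
    # recombination events reference existing haplotypes
    rec <- fr$ancestry$rec
    if (nrow(rec)) {
      expect_true(all(rec$hap_index < 2L * fr$sizes[rec$generation + 1]))
      expect_true(all(vapply(rec$breakpoints, length, integer(1)) >= 1))
    }
  }
})

test_that("ancestry storage uses the minimal integer width", {
  rep1 <- ancestry_storage_report(
    run_forward(tiny_params(N_e = 10, L = 100, mu = 0, r = 0,
                            n_generations = 5, sample_size = 4))$ancestry)
  expect_true(all(rep1$bytes_parents == rep1$entries)) # 10 <= 256 -> 1 byte
  anc2 <- ancestry_log(sizes = rep(500, 3))
  rep2 <- ancestry_storage_report(anc2)
  expect_true(all(rep2$bytes_parents == 2 * rep2$entries)) # 500 -> 2 bytes
  anc3 <- ancestry_log(sizes = rep(70000, 2))
  expect_equal(ancestry_storage_report(anc3)$bytes_parents,
               4 * 2 * 70000)
})

test_that("the event-log TSV round-trips", {
  p <- tiny_params(N_e = 6, L = 500, mu = 5e-4, r = 5e-4,
                   n_generations = 10, mode = "for", seed = 3)
  fr <- run_forward(p)
  path <- tempfile(fileext = ".tsv")
  write_ancestry_events(fr$ancestry, path, mutations = fr$mutations)
  ev <- read_ancestry_events(path)
  expect_setequal(unique(ev$type),
                  intersect(c("INHERIT", "REC", "MUT"), unique(ev$type)))
  inh <- ev[ev$type == "INHERIT", ]
  expect_equal(nrow(inh), sum(2L * fr$sizes[-1]))
  # spot-check one inherit row against parent_of
  row <- inh[inh$generation == 5 & inh$hap_index == 2, ]
  expect_equal(row$parent_index, parent_of(fr$ancestry, 5, 2)$parent)
  expect_equal(sum(ev$type == "REC"), nrow(fr$ancestry$rec))
  expect_equal(sum(ev$type == "MUT"), nrow(fr$mutations))
  unlink(path)
})
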