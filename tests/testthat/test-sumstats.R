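# Summary statistics against brute-force oracles and closed-form checks.

test_that("segregating sites counts positions with both alleles present", {
  expect_equal(segregating_sites(matrix(FALSE, 3, 4)), 0L)
  m <- matrix(c(0, 0, 0, 1, 1, 1), nrow = 3, byrow = TRUE) # rows 00 01 11
  expect_equal(segregating_sites(m), 2L)
  set.seed(1)
  for (i in 1:50) {
    b <- matrix(runif(60) < 0.4, nrow = 5)
    brute <- sum(apply(b, 2, function(col) any(col) && !all(col)))
    expect_equal(segregating_sites(b), brute)
  }
})

test_that("nucleotide diversity is the mean pairwise difference", {
  two <- matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE), nrow = 2)
  expect_equal(nucleotide_diversity(rbind(c(1, 0), c(0, 1))), 2)
  expect_equal(nucleotide_diversity(rbind(c(1, 1), c(1, 1))), 0)
  expect_error(nucleotide_diversity(matrix(TRUE, 1, 3)), "at least 2")
  set.seed(2)
  for (i in 1:30) {
    b <- matrix(runif(48) < 0.5, nrow = 6)
    prs <- utils::combn(6, 2)
    brute <- mean(apply(prs, 2, function(p) sum(b[p[1], ] != b[p[2], ])))
    expect_equal(nucleotide_diversity(b), brute)
  }
  # per-site variant divides by L
  hm <- hap_matrix(rbind(c(1, 0), c(0, 1)) == 1, c(3L, 9L), L = 100)
  expect_equal(nucleotide_diversity(hm, per_site = TRUE), 2 / 100)
})

test_that("haplotype count equals the number of distinct rows", {
  expect_equal(haplotype_count(matrix(TRUE, 4, 2)), 1L)
  expect_equal(haplotype_count(diag(4) == 1), 4L)
  set.seed(3)
  for (i in 1:30) {
    b <- matrix(runif(40) < 0.5, nrow = 8)
    expect_equal(haplotype_count(b),
                 length(unique(apply(b, 1, paste, collapse = ""))))
  }
})

test_that("the SFS counts sites by derived-allele class and sums to S", {
  m <- matrix(FALSE, 4, 1); m[1, 1] <- TRUE # one singleton in n = 4
  expect_equal(site_frequency_spectrum(m), c(1L, 0L, 0L))
  set.seed(4)
  for (i in 1:30) {
    b <- matrix(runif(70) < 0.3, nrow = 7)
    xi <- site_frequency_spectrum(b)
    expect_length(xi, 6L)
    expect_equal(sum(xi), segregating_sites(b))
  }
})

test_that("statistics are invariant under row and column permutation", {
  set.seed(5)
  b <- matrix(runif(80) < 0.4, nrow = 8)
  bp <- b[sample(8), sample(10)]
  expect_equal(segregating_sites(b), segregating_sites(bp))
  expect_equal(nucleotide_diversity(b), nucleotide_diversity(bp))
  expect_equal(haplotype_count(b), haplotype_count(bp))
  expect_equal(sort(site_frequency_spectrum(b)),
               sort(site_frequency_spectrum(bp)))
  expect_equal(site_frequency_spectrum(b), site_frequency_spectrum(b[sample(8), ]))
})

test_that("harmonic helpers match direct summation", {
  expect_equal(harmonic_number(49), sum(1 / (1:49)))
  expect_equal(watterson_expected_s(20, 50), 20 * sum(1 / (1:49)))
})
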