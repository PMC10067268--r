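test_that("generators are deterministic given a seed and record metadata", {
  for (gen in list(
    function(s) lk_landscape(4, 2, seed = s),
    function(s) lkp_landscape(3, 1, p = 0.3, seed = s),
    function(s) hoc_landscape(3, seed = s),
    function(s) rmf_landscape(4, seed = s),
    function(s) eggbox_landscape(3, seed = s),
    function(s) ising_landscape(3, seed = s)
  )) {
    expect_identical(gen(7)$fitness, gen(7)$fitness)
    expect_false(identical(gen(7)$fitness, gen(8)$fitness))
  }
  meta <- attr(lk_landscape(3, 1, seed = 5), "meta")
  expect_identical(meta$seed, 5)
  expect_identical(meta$model, "lk")
})

test_that("generated landscapes are strictly positive and complete", {
  for (ls in list(
    lk_landscape(4, 3, seed = 1),
    lkp_landscape(3, 1, p = 0.9, seed = 2), # near-certain zeros before shift
    rmf_landscape(4, additive_slope = 2, noise_sd = 1, seed = 3),
    eggbox_landscape(3, noise_sd = 0.5, seed = 4),
    ising_landscape(4, seed = 5)
  )) {
    expect_equal(nrow(ls), 2^landscape_L(ls))
    expect_false(anyDuplicated(ls$genotype) > 0)
    expect_true(all(ls$fitness > 0))
  }
})

test_that("additive (K = 0) landscapes have exactly one peak", {
  for (seed in 1:5) {
    expect_identical(nrow(find_peaks(lk_landscape(4, 0, seed = seed))), 1L)
  }
})

test_that("LK mean genotype fitness is L/2 (contributions are Uniform(0,1))", {
  withr::with_seed(42, {
    m <- mean(vapply(1:3000, function(i) {
      mean(lk_landscape(3, 1, seed = i)$fitness)
    }, numeric(1)))
  })
  expect_lt(abs(m - 1.5), 0.02)
})

test_that("neighbourhood schemes respect their partner structure", {
  expect_error(lk_landscape(6, 3, scheme = "block"), "divide")
  expect_s3_class(lk_landscape(6, 2, scheme = "block", seed = 1), "fitness_landscape")
  expect_s3_class(lk_landscape(5, 2, scheme = "adjacent", seed = 1), "fitness_landscape")
  # adjacent scheme, K = L - 1: every site interacts with every other
  expect_true(all(lk_landscape(3, 2, scheme = "adjacent", seed = 2)$fitness > 0))
})

test_that("LKp reduces to LK at p = 0 and to a flat landscape at p = 1", {
  expect_identical(
    lkp_landscape(3, 1, p = 0, seed = 9)$fitness,
    lk_landscape(3, 1, seed = 9)$fitness
  )
  flat <- lkp_landscape(3, 1, p = 1, seed = 9)$fitness
  expect_true(all(flat == flat[1]))
  # p = 0.5 creates neutral neighbour pairs (equal-fitness neighbours)
  n_neutral <- vapply(1:50, function(i) {
    f <- lkp_landscape(3, 1, p = 0.5, seed = i)$fitness
    nb <- peakwalk:::neighbour_matrix(3)
    sum(matrix(f[nb], 8) == f) / 2
  }, numeric(1))
  expect_gt(mean(n_neutral > 0), 0.3)
})

test_that("Rough Mount Fuji spans smooth to uncorrelated regimes", {
  smooth <- rmf_landscape(4, additive_slope = 1, noise_sd = 0, seed = 1)
  pk <- find_peaks(smooth)
  expect_identical(pk$genotype, "0000") # reference genotype is the only peak
  withr::with_seed(5, {
    dens_mixed <- mean(vapply(1:200, function(i) {
      nrow(find_peaks(rmf_landscape(4, 1, noise_sd = 0.5, seed = i))) / 16
    }, numeric(1)))
    dens_hoc <- mean(vapply(1:200, function(i) {
      nrow(find_peaks(rmf_landscape(4, 0, noise_sd = 1, seed = i + 500))) / 16
    }, numeric(1)))
  })
  expect_gt(dens_mixed, 1 / 16) # rougher than the single-peak limit
  expect_lt(dens_mixed, dens_hoc) # smoother than the pure-noise limit
})

test_that("noise-free Eggbox has the maximal peak number 2^(L-1)", {
  expect_identical(nrow(find_peaks(eggbox_landscape(3, noise_sd = 0, seed = 1))), 4L)
  expect_identical(nrow(find_peaks(eggbox_landscape(2, noise_sd = 0, seed = 1))), 2L)
  # peak count survives noise much smaller than the high-low gap
  for (seed in 1:5) {
    expect_identical(
      nrow(find_peaks(eggbox_landscape(3, noise_sd = 0.02, seed = seed))), 4L
    )
  }
})

test_that("Ising landscapes behave like their spin-glass energy", {
  J <- matrix(1, 3, 3) - diag(3)
  ferro <- ising_landscape(3, couplings = J)
  expect_setequal(find_peaks(ferro)$genotype, c("000", "111"))
  # zero field: symmetric under a global spin flip
  f <- ferro$fitness
  expect_equal(f, rev(f))
  # random couplings: peaks are exactly the one-flip-stable spin states
  ls <- ising_landscape(4, seed = 3)
  expect_identical(find_peaks(ls)$genotype, intersect(find_peaks(ls)$genotype, oracle_peaks(ls)))
  expect_setequal(find_peaks(ls)$genotype, oracle_peaks(ls))
})

test_that("find_peaks agrees with the string-based oracle on random fixtures", {
  for (seed in 1:8) {
    for (L in 2:4) {
      ls <- rand_landscape(L, seed * 10 + L)
      expect_setequal(find_peaks(ls)$genotype, oracle_peaks(ls))
    }
  }
})

test_that("House of Cards peak statistics match the rank-order enumeration", {
  # peak structure only depends on the rank order of the 8 fitness values:
  # enumerate all 8! orders for the exact multi-peak probability
  nb <- peakwalk:::neighbour_matrix(3)
  perms <- all_perms(8)
  n_pk <- apply(perms, 1, function(r) sum(peakwalk:::peak_mask(r, nb)))
  exact_multi <- mean(n_pk > 1)
  expect_equal(mean(n_pk), 8 / 4) # E[n_M] = 2^L / (L + 1)
  withr::with_seed(99, {
    sim <- vapply(1:4000, function(i) {
      nrow(find_peaks(hoc_landscape(3)))
    }, numeric(1))
  })
  se <- sqrt(exact_multi * (1 - exact_multi) / 4000)
  expect_lt(abs(mean(sim > 1) - exact_multi), 4 * se)
  expect_lt(abs(mean(sim) - 2), 0.05)
})

test_that("peak density behaves as expected across ensembles", {
  singles <- lapply(1:5, function(i) lk_landscape(4, 0, seed = i))
  expect_equal(peak_density(singles), 2^-4)
  hocs <- lapply(1:300, function(i) hoc_landscape(3, seed = i))
  expect_lt(abs(peak_density(hocs) - 1 / 4), 0.03)
})

test_that("landscape tables round-trip and malformed tables are rejected", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  ls <- lk_landscape(3, 1, seed = 123)
  write_landscape(ls, tf)
  back <- read_landscape(tf)
  expect_identical(back$genotype, ls$genotype)
  expect_equal(back$fitness, ls$fitness, tolerance = 1e-14)
  expect_identical(attr(back, "meta")$L, 3)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genotype\tfitness", "00\t1", "01\t2", "10\t3"), bad)
  expect_error(read_landscape(bad), "expected 4 rows")
  writeLines(c("genotype\tfitness", "00\t1", "00\t2", "10\t3", "11\t1"), bad)
  expect_error(read_landscape(bad), "duplicate")
  writeLines(c("genotype\tfitness", "00\t1", "01\t-2", "10\t3", "11\t1"), bad)
  expect_error(read_landscape(bad), "positive")
})

test_that("genotype indexing is a bijection with site 1 as the leading bit", {
  expect_identical(genotypes(2), c("00", "01", "10", "11"))
  expect_equal(genotype_index("101"), 5)
  expect_identical(index_to_genotype(genotype_index(genotypes(4)), 4), genotypes(4))
  expect_error(genotype_index("102"), "binary")
})

test_that("fittest_genotypes returns the top of the fitness order", {
  ls <- toy_l2()
  expect_identical(fittest_genotypes(ls, 1), "11")
  expect_identical(fittest_genotypes(ls, 2), c("11", "00"))
  expect_error(fittest_genotypes(ls, 5), "1..2")
})

test_that("the bundled synthetic two-peak table loads and analyses cleanly", {
  path <- system.file("extdata", "synthetic_twopeak_L4.tsv", package = "peakwalk")
  ls <- read_landscape(path)
  expect_identical(landscape_L(ls), 4L)
  expect_identical(nrow(find_peaks(ls)), 2L)
  expect_identical(attr(ls, "meta")$note, "synthetic")
  expect_s3_class(differential_accessibility(ls), "tbl_df")
})
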