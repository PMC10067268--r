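test_that("fixation probabilities reproduce known values", {
  # neutral branch: exactly 1/N
  expect_equal(moran_fixation(0, 50), 0.02)
  expect_equal(wf_fixation(0, 20), 0.05)
  # N = 1: every mutation fixes
  expect_equal(moran_fixation(c(-0.5, 0, 0.37, 10), 1), rep(1, 4))
  expect_equal(wf_fixation(c(-0.5, 0, 0.37, 10), 1), rep(1, 4))
  # frozen direct evaluations at (s = 0.1, N = 10)
  expect_equal(moran_fixation(0.1, 10), 0.14795035898410147, tolerance = 1e-12)
  expect_equal(wf_fixation(0.1, 10), 0.20964108215325952, tolerance = 1e-12)
  # large-N beneficial limits: s/(1+s) and 1 - exp(-2s)
  s <- c(0.05, 0.2, 0.8)
  expect_equal(moran_fixation(s, 1e7), s / (1 + s), tolerance = 1e-9)
  expect_equal(wf_fixation(s, 1e7), 1 - exp(-2 * s), tolerance = 1e-9)
  # deleterious mutations at large N: fixation vanishes
  expect_equal(moran_fixation(-0.2, 1e5), 0)
  expect_equal(wf_fixation(-0.2, 1e5), 0)
})

test_that("fixation probabilities are continuous near s = 0 and domain-checked", {
  expect_equal(moran_fixation(1e-14, 50), 0.02)
  expect_lt(abs(moran_fixation(1e-9, 50) - 0.02), 1e-6)
  expect_lt(abs(wf_fixation(-1e-9, 50) - 0.02), 1e-6)
  expect_error(moran_fixation(-1, 10), "s > -1")
  expect_error(wf_fixation(-1.2, 10), "s > -1")
  expect_error(moran_fixation(0.1, 0), "N")
})

test_that("probabilities lie in (0, 1] and WF beats Moran for beneficial s", {
  grid <- expand.grid(s = c(0.01, 0.05, 0.2, 0.5, 1), N = c(2, 5, 10, 100, 1e4))
  pm <- moran_fixation(grid$s, grid$N)
  pw <- wf_fixation(grid$s, grid$N)
  expect_true(all(pm > 0 & pm <= 1))
  expect_true(all(pw > 0 & pw <= 1))
  # ln(1+s) < 2s: the WF walk fixes beneficial mutations more readily
  expect_true(all(pw > pm))
})

test_that("embedded kernel rows sum to one for every walk and N", {
  ls <- rand_landscape(3, 77)
  for (walk in c("moran", "wright_fisher", "pure_random", "natural_aw",
                 "greedy_aw", "random_aw")) {
    for (N in c(1, 2, 17, 1e4)) {
      tk <- transition_kernel(ls, walk, N = N)
      sums <- as.vector(tapply(tk$prob, tk$from, sum))
      expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
    }
  }
})

test_that("the N = 1 kernel is the pure random walk", {
  ls <- rand_landscape(3, 5)
  for (walk in c("moran", "wright_fisher")) {
    tk <- transition_kernel(ls, walk, N = 1)
    expect_equal(tk$prob[!tk$from_is_peak], rep(1 / 3, sum(!tk$from_is_peak)))
  }
})

test_that("kernel limits match hand-computed values on the two-peak toy", {
  ls <- toy_l2()
  # large-N Moran from 01: s/(1+s) limits 1/2 (to 00) and 2/3 (to 11)
  tk <- transition_kernel(ls, "moran", N = 1e4)
  from01 <- tk[tk$from == "01", ]
  expect_equal(from01$prob[from01$to == "00"], 3 / 7, tolerance = 1e-6)
  expect_equal(from01$prob[from01$to == "11"], 4 / 7, tolerance = 1e-6)
  # greedy: all mass on the fittest neighbour
  tg <- transition_kernel(ls, "greedy_aw")
  expect_equal(tg$prob[tg$from == "01" & tg$to == "11"], 1)
  expect_equal(tg$prob[tg$from == "10" & tg$to == "11"], 1)
  # natural AW: weights proportional to the selection coefficients
  tn <- transition_kernel(ls, "natural_aw")
  from01 <- tn[tn$from == "01", ]
  expect_equal(
    from01$prob[from01$to == "11"] / from01$prob[from01$to == "00"],
    2 / 1 # s = 2 vs s = 1
  )
  # random AW: uniform over strictly fitter neighbours
  tr <- transition_kernel(ls, "random_aw")
  expect_equal(tr$prob[tr$from == "01", drop = TRUE], c(0.5, 0.5))
})

test_that("Moran and WF kernels converge to the natural AW for weak selection", {
  # all |s| <= ~0.02: N = 1e5 puts both walks deep in the adaptive-walk limit
  withr::with_seed(1, {
    ls <- as_landscape(data.frame(
      genotype = genotypes(3), fitness = 100 + runif(8)
    ))
  })
  ref <- oracle_kernel(ls, "natural_aw", NA)
  for (walk in c("moran", "wright_fisher")) {
    K <- oracle_kernel(ls, walk, 1e5)
    peaks <- oracle_peaks(ls)
    tv <- apply(abs(K[setdiff(rownames(K), peaks), ] -
      ref[setdiff(rownames(ref), peaks), ]), 1, sum) / 2
    expect_lt(max(tv), 1e-3)
  }
})

test_that("adaptive walks stall on plateaus with an explicit error", {
  flat <- as_landscape(data.frame(
    genotype = c("00", "01", "10", "11"), fitness = c(1, 1, 1, 2)
  ))
  expect_error(transition_kernel(flat, "natural_aw"), "plateau")
})

test_that("walk time rescaling divides by N", {
  expect_equal(walk_time_rescaled(100, 10), 10)
  expect_equal(walk_time_rescaled(7.5, 1), 7.5)
  expect_error(walk_time_rescaled(10, 0), "N")
})

test_that("walks started on a peak terminate immediately", {
  ls <- toy_l2()
  res <- simulate_walks(ls, "moran", N = 5, n_walks = 3, start = "11",
    record_time = TRUE, seed = 1)
  expect_equal(res$length, rep(0L, 3))
  expect_equal(res$time, rep(0, 3))
  expect_equal(res$height, rep(3, 3))
})

test_that("pure random walk from the toy saddle hits each peak half the time", {
  res <- simulate_walks(toy_l2(), "pure_random", n_walks = 10000,
    start = "01", seed = 42)
  expect_equal(res$length, rep(1L, 10000))
  p11 <- mean(res$first_peak == "11")
  expect_lt(abs(p11 - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("simulated first-peak frequencies match first-step analysis", {
  ls <- lk_landscape(3, 1, seed = 41)  # two peaks
  X <- oracle_hitting(ls, "moran", 10)
  res <- simulate_walks(ls, "moran", N = 10, n_walks = 30000,
    start = "000", seed = 7)
  for (pk in colnames(X)) {
    p <- X["000", pk]
    se <- sqrt(max(p * (1 - p), 1e-6) / 30000)
    expect_lt(abs(mean(res$first_peak == pk) - p), 4 * se)
  }
  # and the empirical mean height from uniform starts matches the FSA hbar
  res_u <- simulate_walks(ls, "moran", N = 10, n_walks = 30000, seed = 8)
  hs <- height_stats(ls, "moran", N = 10)
  expect_lt(
    abs(mean(res_u$height) - hs$hbar),
    4 * hs$sigma_h / sqrt(30000)
  )
})

test_that("simulated walk length and time match the first-step solution", {
  ls <- lk_landscape(3, 1, seed = 123)  # two peaks
  lt <- length_time_stats(ls, "moran", N = 100)
  res <- simulate_walks(ls, "moran", N = 100, n_walks = 12000,
    record_time = TRUE, seed = 9)
  expect_lt(
    abs(mean(res$length) - lt$lbar), 4 * sd(res$length) / sqrt(12000)
  )
  expect_lt(abs(mean(res$time) - lt$tbar), 4 * sd(res$time) / sqrt(12000))
  # at N = 1 every proposal is accepted: time equals length walk by walk
  res1 <- simulate_walks(ls, "moran", N = 1, n_walks = 500,
    record_time = TRUE, seed = 10)
  expect_equal(res1$time, as.double(res1$length))
})

test_that("single-walk trajectories are consistent and seeded runs reproduce", {
  ls <- lk_landscape(3, 1, seed = 2)
  w1 <- simulate_walk(ls, "moran", N = 20, start = "000", seed = 3)
  w2 <- simulate_walk(ls, "moran", N = 20, start = "000", seed = 3)
  expect_identical(w1, w2)
  traj <- w1$trajectory[[1]]
  expect_identical(traj[1], "000")
  expect_identical(traj[length(traj)], w1$first_peak)
  expect_identical(length(traj) - 1L, w1$length)
  expect_true(w1$first_peak %in% find_peaks(ls)$genotype)
})

test_that("large landscapes are simulated without materializing the kernel", {
  ls <- lk_landscape(17, 1, seed = 4)
  t0 <- Sys.time()
  res <- simulate_walks(ls, "moran", N = 100, n_walks = 40, seed = 5)
  expect_true(all(res$first_peak %in% find_peaks(ls)$genotype))
  expect_true(all(res$length > 0 | res$start %in% find_peaks(ls)$genotype))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
})
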