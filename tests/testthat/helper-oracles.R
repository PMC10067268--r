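# Fixtures and independent oracles used across the suite. The oracles work on
# genotype strings (not the package's integer indexing) so they exercise a
# genuinely different encoding of the hypercube.

# two-peak L = 2 workhorse: peaks at 00 (f = 2) and 11 (f = 3)
toy_l2 <- function() {
  as_landscape(data.frame(
    genotype = c("00", "01", "10", "11"),
    fitness = c(2, 1, 1.5, 3)
  ))
}

# uncorrelated random landscape fixture
rand_landscape <- function(L, seed) hoc_landscape(L, seed = seed)

flip_site <- function(g, k) {
  bits <- strsplit(g, "")[[1]]
  bits[k] <- if (bits[k] == "0") "1" else "0"
  paste(bits, collapse = "")
}

string_neighbours <- function(g) {
  vapply(seq_len(nchar(g)), flip_site, character(1), g = g)
}

# peaks by direct string-based neighbour comparison
oracle_peaks <- function(landscape) {
  f <- stats::setNames(landscape$fitness, landscape$genotype)
  keep <- vapply(names(f), function(g) {
    all(f[string_neighbours(g)] < f[g])
  }, logical(1))
  sort(names(f)[keep])
}

# embedded-chain transition matrix keyed by genotype strings
oracle_kernel <- function(landscape, walk, N) {
  f <- stats::setNames(landscape$fitness, landscape$genotype)
  gts <- names(f)
  P <- matrix(0, length(gts), length(gts), dimnames = list(gts, gts))
  for (g in gts) {
    nbs <- string_neighbours(g)
    s <- f[nbs] / f[g] - 1
    w <- switch(walk,
      moran = moran_fixation(s, N),
      wright_fisher = wf_fixation(s, N),
      pure_random = rep(1, length(s)),
      natural_aw = pmax(s, 0),
      stop("unsupported oracle walk")
    )
    if (sum(w) > 0) P[g, nbs] <- w / sum(w)
  }
  P
}

# first-hitting probabilities of each peak via the fundamental matrix of the
# absorbing chain: X = (I - Q)^{-1} R, assembled over genotype strings
oracle_hitting <- function(landscape, walk, N) {
  P <- oracle_kernel(landscape, walk, N)
  peaks <- oracle_peaks(landscape)
  trans <- setdiff(rownames(P), peaks)
  X <- matrix(0, nrow(P), length(peaks),
    dimnames = list(rownames(P), peaks)
  )
  X[cbind(peaks, peaks)] <- 1
  if (length(trans) > 0) {
    Q <- P[trans, trans, drop = FALSE]
    R <- P[trans, peaks, drop = FALSE]
    X[trans, ] <- solve(diag(length(trans)) - Q, R)
  }
  X
}

# accessible paths by enumerate-then-filter: list every strictly increasing
# path ending at the peak, then drop those extendable at their start
oracle_ap_count <- function(landscape, peak) {
  f <- stats::setNames(landscape$fitness, landscape$genotype)
  paths <- list()
  grow <- function(path) {
    head <- path[1]
    lower <- Filter(
      function(u) f[u] < f[head] && !(u %in% path),
      string_neighbours(head)
    )
    for (u in lower) grow(c(u, path))
    if (length(lower) == 0 && length(path) > 1) {
      paths[[length(paths) + 1]] <<- path
    }
  }
  grow(peak)
  length(paths)
}

# all permutations of seq_len(n), one per row
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# refine a geometric N grid by inserting midpoints (in log space)
refine_grid <- function(grid) {
  mids <- round(sqrt(grid[-length(grid)] * grid[-1]))
  sort(unique(c(grid, mids)))
}
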