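#' Random LK (NK) fitness landscapes
#'
#' In the LK model each site `i` contributes a fitness term that depends on the
#' states of site `i` and of its `K` epistatic partners; genotype fitness is the
#' sum of the `L` contributions, each drawn i.i.d. Uniform(0, 1) once per
#' (site, partner-state) combination. `K` tunes ruggedness: `K = 0` gives an
#' additive single-peak landscape, `K = L - 1` gives uncorrelated genotype
#' fitnesses (House of Cards).
#'
#' Partner sets contain site `i` plus `K` distinct other sites and are chosen
#' by one of three schemes: `"random"` (uniformly at random, the default),
#' `"adjacent"` (the `K` cyclically following sites) or `"block"` (sites split
#' into blocks of `K + 1` mutual partners; requires `K + 1` to divide `L`).
#'
#' @param L Genome length (binary sites). Capped at
#'   `getOption("peakwalk.max_L", 20)` since the full table has `2^L` rows.
#' @param K Number of epistatic partners per site, in `0:(L - 1)`.
#' @param scheme Partner-choice scheme, one of `"random"`, `"adjacent"`,
#'   `"block"`.
#' @param seed Optional integer seed; the landscape is reproducible bit-for-bit
#'   from `(L, K, scheme, seed)` and the seed is recorded in the metadata. With
#'   `seed = NULL` the current RNG stream is used.
#' @return A `fitness_landscape` tibble.
#' @examples
#' lk_landscape(L = 3, K = 1, seed = 42)
#' @export
lk_landscape <- function(L, K, scheme = c("random", "adjacent", "block"),
                         seed = NULL) {
  scheme <- match.arg(scheme)
  check_lk_params(L, K, scheme)
  f <- local_seed(seed, lk_fitness(L, K, scheme))
  new_landscape(f, L,
    meta = list(model = "lk", L = L, K = K, scheme = scheme, seed = seed)
  )
}

#' @rdname lk_landscape
#' @param p Probability that each fitness contribution is zero (neutral)
#'   instead of Uniform(0, 1); the LKp model. With `p = 0` the output is
#'   identical to [lk_landscape()] under the same seed. Landscapes whose
#'   minimum fitness is not strictly positive are shifted by the positivity
#'   policy (see [rmf_landscape()] Details).
#' @export
lkp_landscape <- function(L, K, p, scheme = c("random", "adjacent", "block"),
                          seed = NULL) {
  scheme <- match.arg(scheme)
  check_lk_params(L, K, scheme)
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]", call. = FALSE)
  }
  f <- local_seed(seed, lk_fitness(L, K, scheme, p_neutral = p))
  new_landscape(ensure_positive(f), L,
    meta = list(model = "lkp", L = L, K = K, p = p, scheme = scheme, seed = seed)
  )
}

#' House of Cards landscape: i.i.d. Uniform(0, 1) genotype fitnesses
#'
#' The maximally rugged null model: fitnesses of different genotypes are
#' completely uncorrelated, so each genotype is a peak with probability
#' `1 / (L + 1)` by symmetry.
#'
#' @inheritParams lk_landscape
#' @return A `fitness_landscape` tibble.
#' @export
hoc_landscape <- function(L, seed = NULL) {
  check_max_L(L)
  f <- local_seed(seed, stats::runif(2^L))
  new_landscape(f, L, meta = list(model = "hoc", L = L, seed = seed))
}

#' Rough Mount Fuji landscape
#'
#' An additive slope towards a reference genotype (all zeros) plus i.i.d.
#' Gaussian epistatic noise per genotype:
#' `f(g) = -additive_slope * hamming(g, ref) + noise_sd * N(0, 1)`.
#'
#' @details Models whose raw values can be non-positive (Rough Mount Fuji,
#' Ising, LKp) are made positive by an additive shift applied per landscape:
#' when the minimum raw fitness is not strictly positive, all values are
#' shifted so the minimum equals `0.01 * (max - min)`. The shift preserves rank
#' order, peaks and accessibility structure, but note it does rescale selection
#' coefficients `s = f_j / f_i - 1`.
#'
#' @inheritParams lk_landscape
#' @param additive_slope Fitness loss per mutation away from the reference.
#' @param noise_sd Standard deviation of the per-genotype epistatic noise;
#'   `noise_sd = 0` gives a smooth single-peak landscape, `additive_slope = 0`
#'   a Gaussian House of Cards.
#' @return A `fitness_landscape` tibble.
#' @export
rmf_landscape <- function(L, additive_slope = 1, noise_sd = 0.1, seed = NULL) {
  check_max_L(L)
  d <- hamming_weight(0:(2^L - 1))
  f <- local_seed(seed, {
    -additive_slope * d + noise_sd * stats::rnorm(2^L)
  })
  new_landscape(ensure_positive(f), L,
    meta = list(
      model = "rmf", L = L, additive_slope = additive_slope,
      noise_sd = noise_sd, seed = seed
    )
  )
}

#' Eggbox landscape
#'
#' Fitness alternates with the parity of the number of 1-bits: `high` for even
#' parity, `low` for odd parity, plus optional small Gaussian noise. Every
#' mutation flips parity, so without noise every even-parity genotype is a peak
#' and the landscape has the maximal peak number `2^(L-1)`.
#'
#' @inheritParams rmf_landscape
#' @param high,low Fitness of even- and odd-parity genotypes (`high > low`).
#' @return A `fitness_landscape` tibble.
#' @export
eggbox_landscape <- function(L, high = 2, low = 1, noise_sd = 0.1, seed = NULL) {
  check_max_L(L)
  if (high <= low) stop("`high` must exceed `low`", call. = FALSE)
  parity <- hamming_weight(0:(2^L - 1)) %% 2L
  f <- local_seed(seed, {
    ifelse(parity == 0L, high, low) + noise_sd * stats::rnorm(2^L)
  })
  new_landscape(ensure_positive(f), L,
    meta = list(
      model = "eggbox", L = L, high = high, low = low,
      noise_sd = noise_sd, seed = seed
    )
  )
}

#' Ising (spin-glass) landscape
#'
#' Sites are spins `s_i = 2 * sigma_i - 1`; fitness is minus the pairwise
#' mismatch energy, `f(g) = sum_{i<j} J_ij s_i s_j + sum_i field_i s_i`,
#' followed by the positivity shift (see [rmf_landscape()] Details). Peaks are
#' exactly the one-spin-flip-stable states of the spin glass. With uniform
#' ferromagnetic couplings and no field the only peaks are the two aligned
#' genotypes (all 0s and all 1s).
#'
#' @inheritParams rmf_landscape
#' @param couplings Either `NULL` (i.i.d. standard-normal couplings for each
#'   pair `i < j`) or a symmetric `L x L` numeric matrix (diagonal ignored).
#' @param field Per-site external field, scalar or length-`L` vector.
#' @return A `fitness_landscape` tibble.
#' @export
ising_landscape <- function(L, couplings = NULL, field = 0, seed = NULL) {
  check_max_L(L)
  J <- local_seed(seed, {
    if (is.null(couplings)) {
      J <- matrix(0, L, L)
      J[upper.tri(J)] <- stats::rnorm(L * (L - 1) / 2)
      J + t(J)
    } else {
      couplings <- as.matrix(couplings)
      if (!all(dim(couplings) == c(L, L)) || !isSymmetric(unname(couplings))) {
        stop("`couplings` must be a symmetric L x L matrix", call. = FALSE)
      }
      couplings - diag(diag(couplings))
    }
  })
  h <- rep_len(field, L)
  spins <- 2 * bit_matrix(L) - 1
  f <- rowSums((spins %*% J) * spins) / 2 + drop(spins %*% h)
  new_landscape(ensure_positive(f), L,
    meta = list(model = "ising", L = L, field = field, seed = seed)
  )
}

# ---- internals ------------------------------------------------------------

# LK fitness vector over all 2^L genotypes, drawn from the current RNG stream.
# Contribution tables are indexed by the joint state of the (K+1) partner
# sites; with p_neutral > 0 each table entry is zeroed with that probability
# (extra mask draws happen only when p_neutral > 0, so p_neutral = 0 consumes
# the same stream as the plain LK model).
lk_fitness <- function(L, K, scheme, p_neutral = 0) {
  partners <- partner_sets(L, K, scheme)
  g <- 0:(2^L - 1)
  f <- numeric(2^L)
  n_tab <- 2^(K + 1)
  for (i in seq_len(L)) {
    tab <- stats::runif(n_tab)
    if (p_neutral > 0) tab[stats::runif(n_tab) < p_neutral] <- 0
    nu <- sort(partners[[i]])
    idx <- integer(2^L)
    for (m in seq_along(nu)) {
      bit <- bitwAnd(g %/% 2^(L - nu[m]), 1L)
      idx <- idx * 2L + bit
    }
    f <- f + tab[idx + 1L]
  }
  f
}

# partner sets nu_i = {i} + K others, per scheme; drawn from current RNG
# (random scheme only)
partner_sets <- function(L, K, scheme) {
  switch(scheme,
    random = lapply(seq_len(L), function(i) {
      others <- setdiff(seq_len(L), i)
      c(i, if (K > 0) others[sample.int(L - 1, K)])
    }),
    adjacent = lapply(seq_len(L), function(i) {
      ((i - 1 + 0:K) %% L) + 1L
    }),
    block = {
      blocks <- split(seq_len(L), rep(seq_len(L / (K + 1)), each = K + 1))
      lapply(seq_len(L), function(i) {
        blocks[[ceiling(i / (K + 1))]]
      })
    }
  )
}

check_lk_params <- function(L, K, scheme) {
  check_max_L(L)
  if (!is.numeric(K) || length(K) != 1 || K != round(K) || K < 0 || K > L - 1) {
    stop("`K` must be an integer in 0:(L-1)", call. = FALSE)
  }
  if (scheme == "block" && (L %% (K + 1)) != 0) {
    stop("block scheme requires (K + 1) to divide L", call. = FALSE)
  }
  invisible(TRUE)
}

check_max_L <- function(L) {
  check_L(L)
  cap <- getOption("peakwalk.max_L", 20L)
  if (L > cap) {
    stop(
      "L = ", L, " exceeds the materialization cap (", cap,
      "); raise options(peakwalk.max_L = ...) at your own risk",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

# additive positivity shift: when the raw minimum is not strictly positive,
# shift all values so the minimum equals 1% of the fitness range
ensure_positive <- function(f, floor_frac = 0.01) {
  mn <- min(f)
  if (mn > 0) return(f)
  rng <- max(f) - mn
  if (rng == 0) return(rep(1, length(f)))
  f + (floor_frac * rng - mn)
}

hamming_weight <- function(g) {
  w <- integer(length(g))
  while (any(g > 0)) {
    w <- w + bitwAnd(g, 1L)
    g <- g %/% 2L
  }
  w
}

# 2^L x L matrix of genotype bits, site 1 in column 1 (most significant)
bit_matrix <- function(L) {
  g <- 0:(2^L - 1)
  vapply(seq_len(L), function(k) bitwAnd(g %/% 2^(L - k), 1L), integer(2^L))
}
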