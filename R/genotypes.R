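#' Enumerate all binary genotypes of a given genome length
#'
#' Genotypes are length-`L` binary strings \eqn{\sigma_1 \ldots \sigma_L}.
#' Site 1 is the most significant bit, so the string read left to right maps to
#' the integer index \eqn{\sum_k \sigma_k 2^{L-k}} in `0:(2^L - 1)`, and
#' genotypes are listed in increasing index order.
#'
#' @param L Genome length (number of binary sites), an integer >= 1.
#' @return A character vector of `2^L` binary strings in index order.
#' @examples
#' genotypes(2)
#' @export
genotypes <- function(L) {
  check_L(L)
  vapply(0:(2^L - 1), index_to_genotype, character(1), L = L)
}

#' Convert between genotype strings and integer indices
#'
#' @param genotype Character vector of binary strings (all the same length).
#' @param index Integer vector of genotype indices in `0:(2^L - 1)`.
#' @param L Genome length.
#' @return `genotype_index()` returns the 0-based integer index;
#'   `index_to_genotype()` returns the binary string.
#' @examples
#' genotype_index("101")
#' index_to_genotype(5, L = 3)
#' @export
genotype_index <- function(genotype) {
  if (!is.character(genotype) || any(!grepl("^[01]+$", genotype))) {
    stop("`genotype` must be binary strings of 0s and 1s", call. = FALSE)
  }
  L <- unique(nchar(genotype))
  if (length(L) != 1) stop("all genotype strings must have the same length", call. = FALSE)
  vapply(strsplit(genotype, ""), function(b) {
    sum(as.integer(b) * 2^((L - 1):0))
  }, numeric(1))
}

#' @rdname genotype_index
#' @export
index_to_genotype <- function(index, L) {
  check_L(L)
  vapply(index, function(i) {
    paste(as.integer(bitwAnd(i, 2^((L - 1):0)) > 0), collapse = "")
  }, character(1))
}

# 1-based matrix of single-mutation neighbours: row g+1, column k holds the
# 1-based index of the genotype obtained by flipping site k of genotype g.
neighbour_matrix <- function(L) {
  g <- 0:(2^L - 1)
  m <- vapply(seq_len(L), function(k) bitwXor(g, 2^(L - k)), integer(2^L))
  matrix(m, nrow = 2^L, ncol = L) + 1L
}

check_L <- function(L) {
  if (!is.numeric(L) || length(L) != 1 || L < 1 || L != round(L)) {
    stop("`L` must be a single integer >= 1", call. = FALSE)
  }
  invisible(as.integer(L))
}

# Evaluate `code` under a temporary seed, restoring the caller's RNG state.
# A NULL seed leaves the RNG stream untouched.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1) {
    stop("`seed` must be a single number or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Counter-based per-replicate seed derivation, kept below 2^31 so it is always
# a valid R integer seed. Lets ensembles be chunked without changing results.
derive_seed <- function(master, counter) {
  (as.double(master) * 48271 + as.double(counter) * 69621) %% 2147483563
}
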