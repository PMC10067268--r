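#' Fitness landscape tibbles
#'
#' A fitness landscape assigns a strictly positive fitness (a division rate) to
#' every one of the `2^L` binary genotypes of genome length `L`. Landscapes are
#' stored as tibbles with columns `genotype` (binary string) and `fitness`,
#' one row per genotype in index order, carrying `L` and generator metadata as
#' attributes. Single-mutation neighbours differ at exactly one site, so the
#' genotype graph is the `L`-dimensional hypercube.
#'
#' @param x A data frame with columns `genotype` and `fitness` covering all
#'   `2^L` genotypes exactly once, fitness strictly positive.
#' @param meta Optional named list of generator metadata (model, parameters,
#'   seed) recorded on the landscape.
#' @return A `fitness_landscape` tibble.
#' @examples
#' as_landscape(data.frame(
#'   genotype = c("00", "01", "10", "11"),
#'   fitness = c(2, 1, 1.5, 3)
#' ))
#' @export
as_landscape <- function(x, meta = list()) {
  if (!is.data.frame(x) || !all(c("genotype", "fitness") %in% names(x))) {
    stop("`x` must be a data frame with columns `genotype` and `fitness`", call. = FALSE)
  }
  gt <- as.character(x$genotype)
  if (any(!grepl("^[01]+$", gt))) {
    stop("genotype strings must contain only 0s and 1s", call. = FALSE)
  }
  L <- unique(nchar(gt))
  if (length(L) != 1) stop("all genotype strings must have the same length", call. = FALSE)
  if (nrow(x) != 2^L) {
    stop("expected ", 2^L, " rows for L = ", L, ", got ", nrow(x), call. = FALSE)
  }
  if (anyDuplicated(gt)) stop("duplicate genotypes in table", call. = FALSE)
  f <- as.double(x$fitness)
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("all fitness values must be finite and strictly positive", call. = FALSE)
  }
  ord <- order(genotype_index(gt))
  new_landscape(f[ord], L = L, meta = meta)
}

# fast internal constructor: f is the fitness vector in genotype-index order
new_landscape <- function(f, L, meta = list()) {
  out <- tibble::tibble(genotype = genotypes(L), fitness = as.double(f))
  attr(out, "L") <- as.integer(L)
  attr(out, "meta") <- meta
  class(out) <- c("fitness_landscape", class(out))
  out
}

#' @rdname as_landscape
#' @export
is_landscape <- function(x) inherits(x, "fitness_landscape")

#' Genome length of a landscape
#' @param landscape A `fitness_landscape`.
#' @return The integer number of binary sites `L`.
#' @export
landscape_L <- function(landscape) {
  L <- attr(landscape, "L")
  if (is.null(L)) L <- unique(nchar(as.character(landscape$genotype)))
  as.integer(L)
}

# fitness vector in index order; tolerates plain data frames in any row order
landscape_fitness <- function(landscape) {
  f <- as.double(landscape$fitness)
  f[order(genotype_index(as.character(landscape$genotype)))]
}

#' @export
print.fitness_landscape <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("# Fitness landscape: L = ", landscape_L(x), ", ", nrow(x), " genotypes",
    if (!is.null(meta$model)) paste0(" (", meta$model, ")"), "\n",
    sep = ""
  )
  NextMethod()
}

#' Locate the fitness peaks of a landscape
#'
#' A peak (local fitness maximum) is a genotype strictly fitter than all of its
#' `L` single-mutation neighbours; a genotype with an equal-fitness neighbour is
#' not a peak. Every landscape with strictly positive fitness has at least one
#' peak (the global maximum).
#'
#' @param landscape A `fitness_landscape` (or data frame coercible to one).
#' @return A tibble with columns `genotype`, `index` (0-based) and `fitness`,
#'   ordered by decreasing fitness.
#' @examples
#' find_peaks(lk_landscape(L = 3, K = 1, seed = 1))
#' @export
find_peaks <- function(landscape) {
  f <- landscape_fitness(landscape)
  L <- landscape_L(landscape)
  idx <- which(peak_mask(f, neighbour_matrix(L))) - 1L
  out <- tibble::tibble(
    genotype = index_to_genotype(idx, L),
    index = idx,
    fitness = f[idx + 1L]
  )
  dplyr::arrange(out, dplyr::desc(.data$fitness))
}

# logical peak indicator over the fitness vector, given the neighbour matrix
peak_mask <- function(f, nb) {
  nbf <- matrix(f[nb], nrow = length(f))
  f > apply(nbf, 1, max)
}

#' Mean density of peaks over an ensemble of landscapes
#'
#' @param landscapes A list of `fitness_landscape` objects (a single landscape
#'   is also accepted).
#' @return Mean of (number of peaks) / `2^L` over the ensemble.
#' @examples
#' peak_density(list(lk_landscape(3, 1, seed = 1), lk_landscape(3, 1, seed = 2)))
#' @export
peak_density <- function(landscapes) {
  if (is_landscape(landscapes)) landscapes <- list(landscapes)
  mean(vapply(landscapes, function(ls) {
    nrow(find_peaks(ls)) / 2^landscape_L(ls)
  }, numeric(1)))
}

#' The n fittest genotypes of a landscape
#'
#' Used to restrict the starting set of a walk to high-fitness genotypes,
#' emulating adaptation after a small environmental change.
#'
#' @param landscape A `fitness_landscape`.
#' @param n Number of genotypes to keep, `1 <= n <= 2^L`.
#' @return Character vector of the `n` fittest genotype strings.
#' @export
fittest_genotypes <- function(landscape, n) {
  f <- landscape_fitness(landscape)
  if (n < 1 || n > length(f)) stop("`n` must be in 1..2^L", call. = FALSE)
  L <- landscape_L(landscape)
  index_to_genotype(order(f, decreasing = TRUE)[seq_len(n)] - 1L, L)
}

#' Read and write genotype-fitness tables
#'
#' The on-disk format is tab-separated with header `genotype<TAB>fitness` and
#' optional leading comment lines starting with `#` that carry metadata
#' (`#L=3`, `#model=lk`, `#seed=7`). It is both the output of the generators
#' and the input accepted by every downstream analysis, so empirical
#' genotype-fitness measurements (for example combinatorially complete L=4
#' protein landscapes) can be analysed exactly like generated ones.
#'
#' @param path File path.
#' @param landscape A `fitness_landscape`.
#' @return `read_landscape()` returns a `fitness_landscape`;
#'   `write_landscape()` invisibly returns `path`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_landscape(lk_landscape(3, 1, seed = 1), tf)
#' read_landscape(tf)
#' @export
read_landscape <- function(path) {
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (cm in comments) {
    kv <- sub("^#\\s*", "", cm)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- sub("=.*$", "", kv)
      val <- sub("^[^=]*=", "", kv)
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("landscape table has no data rows", call. = FALSE)
  header <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:2], c("genotype", "fitness"))) {
    stop("expected header 'genotype<TAB>fitness'", call. = FALSE)
  }
  fields <- strsplit(body[-1], "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) stop("malformed landscape table row", call. = FALSE)
  df <- data.frame(
    genotype = vapply(fields, `[[`, character(1), 1),
    fitness = as.numeric(vapply(fields, `[[`, character(1), 2))
  )
  if (anyNA(df$fitness)) stop("non-numeric fitness value in table", call. = FALSE)
  as_landscape(df, meta = meta)
}

#' @rdname read_landscape
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(is_landscape(landscape))
  meta <- attr(landscape, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#L=%d", landscape_L(landscape)), con)
  for (key in setdiff(names(meta), "L")) {
    val <- meta[[key]]
    if (is.null(val) || length(val) != 1 || is.list(val)) next
    writeLines(sprintf("#%s=%s", key, format(val, digits = 17)), con)
  }
  writeLines("genotype\tfitness", con)
  writeLines(
    sprintf("%s\t%s", landscape$genotype, format(landscape$fitness, digits = 17)),
    con
  )
  invisible(path)
}
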