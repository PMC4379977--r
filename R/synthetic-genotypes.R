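#' Simulate a cluster-structured binary genotype matrix
#'
#' Emulates dominant (band presence/absence) marker data with a planted
#' population structure: loci are partitioned into K equal blocks and an
#' individual from cluster k carries a band at block-k loci with probability
#' \code{freq_in} and at all other loci with probability \code{freq_out}.
#' Entries are set missing at rate \code{missing_rate}.
#'
#' @param K number of clusters (>= 1).
#' @param n_per_cluster individuals per cluster.
#' @param L number of loci (>= K).
#' @param freq_in band frequency at a cluster's own loci.
#' @param freq_out band frequency elsewhere.
#' @param missing_rate fraction of entries set to NA.
#' @param seed integer seed.
#' @return a list with \code{genotypes} (a
#'   \code{\link{BinaryGenotypeMatrix}}) and \code{labels} (true cluster per
#'   individual).
#' @export
simulateGenotypeMatrix <- function(K = 3, n_per_cluster = 30, L = 100,
                                   freq_in = 0.9, freq_out = 0.1,
                                   missing_rate = 0, seed = 1) {
  if (K < 1) stop("K must be >= 1")
  if (L < K) stop("L must be >= K")
  stopifnot(freq_in >= 0, freq_in <= 1, freq_out >= 0, freq_out <= 1,
            missing_rate >= 0, missing_rate <= 1)
  set.seed(seed)
  n <- K * n_per_cluster
  labels <- rep(seq_len(K), each = n_per_cluster)
  block <- sort(rep_len(seq_len(K), L))     # locus -> block
  p <- matrix(freq_out, n, L)
  for (k in seq_len(K))
    p[labels == k, block == k] <- freq_in
  v <- matrix(rbinom(n * L, 1, as.vector(p)), n, L)
  if (missing_rate > 0)
    v[runif(n * L) < missing_rate] <- NA_integer_
  rownames(v) <- sprintf("ind%03d", seq_len(n))
  colnames(v) <- sprintf("locus%03d", seq_len(L))
  list(genotypes = BinaryGenotypeMatrix(v), labels = labels)
}

#' Write a binary genotype matrix as TSV
#' @param x a \code{\link{BinaryGenotypeMatrix}}.
#' @param path output path.
#' @export
writeGenotypeMatrix <- function(x, path) {
  df <- data.frame(individual = rownames(genotypeValues(x)),
                   genotypeValues(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary genotype matrix written by writeGenotypeMatrix
#' @param path path to a genotype TSV (first column \code{individual}).
#' @export
readGenotypeMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  BinaryGenotypeMatrix(m)
}
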