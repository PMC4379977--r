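#' Score electrophoretic bands into a binary genotype matrix
#'
#' Co-migrating bands are assumed to originate from the same locus: within
#' each marker, band sizes across individuals are clustered by
#' single-linkage with link distance \code{size_tolerance_bp} (a chain of
#' sizes each within tolerance of the next forms one locus).  Each cluster
#' becomes one locus column scored 1 (band present) / 0 (absent);
#' individuals with no data for a marker are missing at that marker's loci.
#'
#' @param bands data.frame with columns \code{individual}, \code{marker},
#'   \code{size} (one row per observed band); individuals with no band for
#'   a marker but data for others are scored 0 - list individuals with no
#'   data at all for a marker in \code{no_data} (data.frame
#'   \code{individual}, \code{marker}).
#' @param size_tolerance_bp single-linkage link distance (bp).
#' @param no_data optional data.frame of (individual, marker) pairs with
#'   missing data.
#' @return a \code{\link{BinaryGenotypeMatrix}} with loci named
#'   \code{<marker>_<median size>}.
#' @export
scoreBands <- function(bands, size_tolerance_bp = 10, no_data = NULL) {
  stopifnot(all(c("individual", "marker", "size") %in% colnames(bands)))
  individuals <- sort(unique(c(bands$individual, no_data$individual)))
  cols <- list()
  for (mk in sort(unique(bands$marker))) {
    sub <- bands[bands$marker == mk, , drop = FALSE]
    sizes <- sort(unique(sub$size))
    # single-linkage on 1-D sizes: break chains at gaps > tolerance
    grp <- cumsum(c(1, diff(sizes) > size_tolerance_bp))
    for (g in unique(grp)) {
      members <- sizes[grp == g]
      locus <- sprintf("%s_%g", mk, median(members))
      has <- unique(sub$individual[sub$size %in% members])
      v <- ifelse(individuals %in% has, 1L, 0L)
      if (!is.null(no_data))
        v[individuals %in% no_data$individual[no_data$marker == mk]] <-
          NA_integer_
      cols[[locus]] <- v
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- individuals
  BinaryGenotypeMatrix(m)
}

#' Jaccard similarity and distance matrices
#'
#' For individuals x and y over the loci where neither is missing:
#' J = a / (a + b + c) with a the shared presences and b, c the
#' mismatches; loci absent in both (0/0) are excluded.  Distance is 1 - J.
#'
#' @param x a \code{\link{BinaryGenotypeMatrix}} (or 0/1/NA matrix).
#' @return a list with \code{similarity} and \code{distance} matrices.
#' @export
jaccardMatrix <- function(x) {
  v <- if (is(x, "BinaryGenotypeMatrix")) genotypeValues(x) else x
  n <- nrow(v)
  sim <- matrix(1, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- !is.na(v[i, ]) & !is.na(v[j, ])
    a <- sum(v[i, ok] == 1 & v[j, ok] == 1)
    b <- sum(v[i, ok] == 1 & v[j, ok] == 0)
    cc <- sum(v[i, ok] == 0 & v[j, ok] == 1)
    if (a + b + cc == 0)
      stop("Jaccard similarity undefined for pair (", rownames(v)[i], ", ",
           rownames(v)[j], "): no scorable loci")
    sim[i, j] <- sim[j, i] <- a / (a + b + cc)
  }
  list(similarity = sim, distance = 1 - sim)
}

## --------------------------------------------------------------------------
## Neighbour joining (NJ via ape; UNJ, the equal-taxon-weight variant,
## in-package)
## --------------------------------------------------------------------------

# Gascuel's unweighted NJ: cluster sizes weight both the selection sums and
# the distance reduction, giving every taxon equal weight in the estimate
.unj <- function(d) {
  labels <- rownames(d)
  n <- nrow(d)
  sizes <- rep(1L, n)
  active <- seq_len(n)
  # edge bookkeeping in ape's phylo format
  n_tip <- n
  node_of <- as.list(seq_len(n_tip))  # active cluster -> phylo node id
  edges <- NULL; lens <- NULL
  cur_internal <- n_tip + 1L
  # we assign internal ids increasing as joins happen; root fixed later
  repeat {
    r <- length(active)
    if (r == 2) break
    # pair selection: cluster-level NJ criterion (consistent on additive
    # matrices); the taxon weights enter the branch-length estimates and
    # the reduction below, which is what gives every taxon equal weight
    S <- vapply(active, function(i)
      sum(d[i, setdiff(active, i)]), numeric(1))
    names(S) <- as.character(active)
    best <- NULL; bestQ <- Inf
    for (ii in seq_len(r - 1)) for (jj in seq(ii + 1, r)) {
      i <- active[ii]; j <- active[jj]
      Q <- (r - 2) * d[i, j] - S[[as.character(i)]] - S[[as.character(j)]]
      if (Q < bestQ - 1e-12) { bestQ <- Q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    others <- setdiff(active, c(i, j))
    W <- sum(sizes[others])
    diffsum <- sum(sizes[others] * (d[i, others] - d[j, others]))
    bi <- d[i, j] / 2 + diffsum / (2 * W)
    bj <- d[i, j] - bi
    u <- cur_internal; cur_internal <- cur_internal + 1L
    edges <- rbind(edges, c(u, node_of[[i]]), c(u, node_of[[j]]))
    lens <- c(lens, bi, bj)
    # weighted reduction
    dnew <- (sizes[i] * (d[i, others] - bi) +
             sizes[j] * (d[j, others] - bj)) / (sizes[i] + sizes[j])
    d[i, others] <- dnew; d[others, i] <- dnew
    sizes[i] <- sizes[i] + sizes[j]
    node_of[[i]] <- u
    active <- setdiff(active, j)
  }
  i <- active[1]; j <- active[2]
  # final edge between the last two clusters: collapse through the root
  u <- cur_internal
  edges <- rbind(edges, c(u, node_of[[i]]), c(u, node_of[[j]]))
  lens <- c(lens, d[i, j] / 2, d[i, j] / 2)
  # renumber internal nodes to ape convention (root = n_tip + 1)
  internal_ids <- sort(unique(edges[, 1]))
  remap <- setNames(seq_along(internal_ids) + n_tip, rev(internal_ids))
  e <- edges
  e[, 1] <- remap[as.character(edges[, 1])]
  sel <- edges[, 2] > n_tip
  e[sel, 2] <- remap[as.character(edges[sel, 2])]
  tr <- list(edge = e, edge.length = lens, tip.label = labels,
             Nnode = length(internal_ids))
  class(tr) <- "phylo"
  # the two root-adjacent branches were split arbitrarily; merge by
  # unrooting for a fair unrooted tree
  ape::unroot(ape::reorder.phylo(tr, "cladewise"))
}

#' Neighbour-joining tree from a distance matrix
#'
#' \code{variant = "NJ"} is Saitou-Nei neighbour joining (via
#' \code{ape::nj}); \code{variant = "UNJ"} is Gascuel's unweighted NJ,
#' which gives every taxon equal weight (the variant used by DARwin-style
#' dissimilarity analyses).  Negative branch lengths are clamped to zero
#' with a warning.
#'
#' @param d symmetric distance matrix (or \code{dist}).
#' @param variant \code{"NJ"} or \code{"UNJ"}.
#' @return an unrooted \code{phylo} tree.
#' @export
njTree <- function(d, variant = c("NJ", "UNJ")) {
  variant <- match.arg(variant)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("t", seq_len(nrow(d)))
  tr <- if (variant == "NJ") ape::nj(stats::as.dist(d)) else .unj(d)
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples loci with replacement, rebuilds the Jaccard-distance NJ tree
#' for each replicate, and reports for each internal bipartition of the
#' full-data tree the percentage of replicate trees containing it.
#'
#' @param x a \code{\link{BinaryGenotypeMatrix}}.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed.
#' @param variant tree variant passed to \code{\link{njTree}}.
#' @return the full-data \code{phylo} tree with support percentages in
#'   \code{node.label}.
#' @export
bootstrapSupport <- function(x, n_reps = 1000, seed = 1, variant = "NJ") {
  v <- genotypeValues(x)
  set.seed(seed)
  full <- njTree(jaccardMatrix(x)$distance, variant)
  boots <- vector("list", n_reps)
  n_ok <- 0L
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ncol(v), replace = TRUE)
    tr <- tryCatch(
      suppressWarnings(
        njTree(jaccardMatrix(BinaryGenotypeMatrix(v[, idx, drop = FALSE]))$distance,
               variant)),
      error = function(e) NULL)
    if (!is.null(tr)) { n_ok <- n_ok + 1L; boots[[n_ok]] <- tr }
  }
  if (n_ok == 0) stop("no bootstrap replicate produced a tree")
  boots <- boots[seq_len(n_ok)]
  cnt <- ape::prop.clades(full, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  full$node.label <- round(100 * cnt / n_ok, 1)
  full
}

## --------------------------------------------------------------------------
## No-admixture Bayesian clustering and Evanno delta-K
## --------------------------------------------------------------------------

#' No-admixture Bayesian clustering of dominant markers
#'
#' Gibbs sampler for the no-admixture model on binary band data: each
#' individual belongs to one of K clusters (uniform prior); cluster band
#' frequencies have independent Beta(lambda, lambda) priors.  Membership
#' probabilities q are posterior frequencies of cluster membership over
#' post-burn-in sweeps (label switching resolved by canonical
#' relabelling); Ln P(D) is estimated as mean(lnL) - var(lnL)/2.  Default
#' chain lengths are 200,000 burn-in plus 200,000 recorded sweeps; use
#' shorter chains for exploratory work.
#'
#' The correlated allele-frequency prior of STRUCTURE's F-model is not
#' implemented; \code{f_model_prior} is accepted for configuration
#' compatibility and ignored with a warning.
#'
#' @param x a \code{\link{BinaryGenotypeMatrix}}.
#' @param K number of clusters (1..n individuals).
#' @param burn_in,reps burn-in and recorded sweep counts.
#' @param lambda Beta prior parameter (default 1.0).
#' @param seed integer seed.
#' @param f_model_prior ignored (see above).
#' @return a \code{\link{StructureResult}}.
#' @export
structureNoAdmixture <- function(x, K, burn_in = 200000, reps = 200000,
                                 lambda = 1.0, seed = 1,
                                 f_model_prior = NULL) {
  v <- genotypeValues(x)
  if (K < 1 || K > nrow(v)) stop("K must lie in 1..number of individuals")
  if (!is.null(f_model_prior))
    warning("correlated allele-frequency (F-model) priors are not ",
            "implemented; ignoring f_model_prior")
  set.seed(seed)
  # initialise from a k-means partition of the band matrix: a cluster that
  # empties under this Gibbs scheme cannot refill, so a data-informed start
  # avoids chains stuck in merged-cluster modes
  z0 <- if (K == 1) rep(1L, nrow(v)) else {
    vi <- v
    cm <- colMeans(vi, na.rm = TRUE)
    for (l in seq_len(ncol(vi)))
      vi[is.na(vi[, l]), l] <- cm[l]
    tryCatch(suppressWarnings(
      as.integer(stats::kmeans(vi, centers = K, nstart = 5,
                               iter.max = 50)$cluster)),
      error = function(e) sample.int(K, nrow(v), replace = TRUE))
  }
  res <- structure_gibbs_cpp(v, as.integer(K), as.integer(burn_in),
                             as.integer(reps), lambda, z0)
  q <- res$q
  rownames(q) <- rownames(v)
  tr <- as.numeric(res$trace)
  lnPD <- mean(tr) - var(tr) / 2
  if (K == 1) lnPD <- mean(tr) - var(tr) / 2  # same estimator, single cluster
  new("StructureResult", K = as.integer(K), q = q,
      assignments = max.col(q, ties.method = "first"),
      lnPD = lnPD, lambda = lambda, trace = tr)
}

#' Evanno delta-K from replicate clustering runs
#'
#' L'(K) = mean L(K) - mean L(K-1); |L''(K)| = |L(K+1) - 2 L(K) + L(K-1)|
#' on the means; delta-K = |L''(K)| / sd(L(K)).  The selected K is the
#' argmax of delta-K over interior K (delta-K is undefined at the smallest
#' and largest K tested).
#'
#' @param runs data.frame with columns \code{K} and \code{lnPD} (one row
#'   per run).
#' @return a list with \code{table} (per K: \code{mean_lnPD},
#'   \code{sd_lnPD}, \code{L1}, \code{L2_abs}, \code{delta_K}) and
#'   \code{selected_K}.
#' @export
evannoDeltaK <- function(runs) {
  stopifnot(all(c("K", "lnPD") %in% colnames(runs)))
  Ks <- sort(unique(runs$K))
  if (length(Ks) < 3) stop("need at least three K values for delta-K")
  mean_l <- vapply(Ks, function(k) mean(runs$lnPD[runs$K == k]), numeric(1))
  sd_l <- vapply(Ks, function(k) sd(runs$lnPD[runs$K == k]), numeric(1))
  nrun <- vapply(Ks, function(k) sum(runs$K == k), integer(1))
  L1 <- c(NA, diff(mean_l))
  L2 <- rep(NA_real_, length(Ks))
  dK <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)) {
    if (i == 1 || i == length(Ks)) next
    if (nrun[i] < 2) stop("fewer than 2 runs at K = ", Ks[i],
                          ": sd undefined")
    if (sd_l[i] == 0) stop("sd of lnPD is 0 at K = ", Ks[i],
                           "; run more replicates")
    L2[i] <- abs(mean_l[i + 1] - 2 * mean_l[i] + mean_l[i - 1])
    dK[i] <- L2[i] / sd_l[i]
  }
  tab <- data.frame(K = Ks, n_runs = nrun, mean_lnPD = mean_l,
                    sd_lnPD = sd_l, L1 = L1, L2_abs = L2, delta_K = dK)
  sel <- tab$K[which.max(tab$delta_K)]
  list(table = tab, selected_K = sel)
}
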