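test_that("band scoring clusters co-migrating sizes by single linkage", {
  bands <- data.frame(individual = c("i1", "i2"), marker = "m1",
                      size = c(500, 505))
  m <- genotypeValues(scoreBands(bands))
  expect_equal(ncol(m), 1L)          # within tolerance: one locus
  expect_true(all(m == 1))

  bands2 <- data.frame(individual = c("i1", "i2"), marker = "m1",
                       size = c(500, 520))
  expect_equal(ncol(genotypeValues(scoreBands(bands2))), 2L)

  # chained sizes 500/508/516 collapse under single linkage
  bands3 <- data.frame(individual = c("i1", "i2", "i3"), marker = "m1",
                       size = c(500, 508, 516))
  expect_equal(ncol(genotypeValues(scoreBands(bands3))), 1L)

  # an individual with no data for a marker is missing there
  bands4 <- rbind(data.frame(individual = c("i1", "i2"), marker = "m1",
                             size = 300),
                  data.frame(individual = "i1", marker = "m2", size = 450))
  m4 <- genotypeValues(scoreBands(bands4,
                                  no_data = data.frame(individual = "i2",
                                                       marker = "m2")))
  expect_true(is.na(m4["i2", grep("m2", colnames(m4))]))
  expect_equal(unname(m4["i2", grep("m1", colnames(m4))]), 1L)
})

test_that("Jaccard similarity matches enumeration and vegan", {
  x <- BinaryGenotypeMatrix(rbind(a = c(1, 1, 0, 1, 0),
                                  b = c(1, 0, 0, 1, 1)))
  jm <- jaccardMatrix(x)
  expect_equal(jm$similarity["a", "b"], 0.5)   # a=2, b=1, c=1
  expect_equal(diag(jm$similarity), c(a = 1, b = 1))
  expect_equal(jm$similarity, t(jm$similarity))
  expect_equal(jm$distance, 1 - jm$similarity)

  # brute-force enumeration on random matrices, cross-checked with vegan
  set.seed(601)
  for (rep in 1:5) {
    v <- matrix(rbinom(8 * 20, 1, 0.5), 8, 20)
    rownames(v) <- paste0("i", 1:8)
    colnames(v) <- paste0("l", 1:20)
    v[1, ] <- pmax(v[1, ], 1L)  # guarantee scorable pairs
    jm <- jaccardMatrix(BinaryGenotypeMatrix(v))
    for (i in 1:7) for (j in (i + 1):8) {
      a <- sum(v[i, ] == 1 & v[j, ] == 1)
      b <- sum(v[i, ] == 1 & v[j, ] == 0)
      cc <- sum(v[i, ] == 0 & v[j, ] == 1)
      if (a + b + cc > 0)
        expect_equal(jm$similarity[i, j], a / (a + b + cc))
    }
    vd <- as.matrix(vegan::vegdist(v, method = "jaccard", binary = TRUE))
    expect_equal(unname(jm$distance), unname(vd), tolerance = 1e-9)
  }

  # an all-zero pair is undefined and names the culprits
  bad <- BinaryGenotypeMatrix(rbind(z1 = c(0, 0), z2 = c(0, 0)))
  expect_error(jaccardMatrix(bad), "z1.*z2")
})

test_that("three-taxon NJ solves the closed form", {
  d <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  for (variant in c("NJ", "UNJ")) {
    tr <- njTree(d, variant)
    bl <- setNames(tr$edge.length,
                   tr$tip.label[tr$edge[, 2]])
    expect_equal(bl[["A"]], 0.1)
    expect_equal(bl[["B"]], 0.2)
    expect_equal(bl[["C"]], 0.3)
  }
  expect_error(njTree(matrix(0, 2, 3)), "square")
  dm <- d; dm[1, 2] <- 0.9
  expect_error(njTree(dm), "symmetric")
})

test_that("additive distances are recovered exactly", {
  # the 4-taxon tree ((A:1,B:2):1,(C:3,D:4))
  d4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  for (variant in c("NJ", "UNJ")) {
    tr <- njTree(d4, variant)
    expect_equal(unname(as.matrix(stats::cophenetic(tr))[LETTERS[1:4],
                                                         LETTERS[1:4]]),
                 unname(d4), tolerance = 1e-9)
  }

  # random additive matrices up to 12 taxa: topology and branch lengths
  set.seed(602)
  for (rep in 1:6) {
    n <- sample(5:12, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    dm <- as.matrix(stats::cophenetic(ref))
    for (variant in c("NJ", "UNJ")) {
      tr <- njTree(dm, variant)
      expect_equal(unname(as.matrix(stats::cophenetic(tr))[rownames(dm),
                                                           colnames(dm)]),
                   unname(dm), tolerance = 1e-7,
                   info = paste(variant, "n =", n))
      expect_equal(phangorn::RF.dist(ape::unroot(ref), tr), 0)
    }
  }

  # identical rows form a zero-length cherry
  dz <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- njTree(dz)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["x"]], 0)
  expect_equal(bl[["y"]], 0)
})

test_that("bootstrap supports are percentages and reproducible", {
  # perfectly tree-like data: loci split the individuals into clean groups
  block <- function(members, n = 8) as.integer(seq_len(n) %in% members)
  loci <- cbind(replicate(30, block(1:2)), replicate(30, block(3:4)),
                replicate(30, block(1:4)), replicate(30, block(5:8)))
  rownames(loci) <- paste0("i", 1:8)
  colnames(loci) <- paste0("l", seq_len(ncol(loci)))
  x <- BinaryGenotypeMatrix(loci)
  tr <- suppressWarnings(bootstrapSupport(x, n_reps = 100, seed = 3))
  sup <- as.numeric(tr$node.label)
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_gte(mean(sup >= 95), 0.5)   # clean bipartitions are near-certain

  tr2 <- suppressWarnings(bootstrapSupport(x, n_reps = 100, seed = 3))
  expect_identical(tr$node.label, tr2$node.label)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("K = 1 clustering degenerates to the Beta-Bernoulli model", {
  x <- BinaryGenotypeMatrix(rbind(i1 = 1L, i2 = 0L))
  r <- structureNoAdmixture(x, K = 1, burn_in = 2000, reps = 20000,
                            seed = 7)
  expect_true(all(membershipMatrix(r) == 1))
  # closed form: marginal likelihood of (1, 0) at one Beta(1,1) locus is
  # 1/6; the mean - var/2 estimator approximates its log
  expect_lt(abs(lnProbData(r) - log(1 / 6)), 0.1)
})

test_that("clustering is deterministic and validates K", {
  sim <- simulateGenotypeMatrix(K = 2, n_per_cluster = 10, L = 40, seed = 8)
  r1 <- structureNoAdmixture(sim$genotypes, K = 2, burn_in = 500,
                             reps = 500, seed = 42)
  r2 <- structureNoAdmixture(sim$genotypes, K = 2, burn_in = 500,
                             reps = 500, seed = 42)
  expect_identical(r1@trace, r2@trace)
  expect_identical(membershipMatrix(r1), membershipMatrix(r2))
  expect_error(structureNoAdmixture(sim$genotypes, K = 0), "K must")
  expect_error(structureNoAdmixture(sim$genotypes, K = 50), "K must")
  expect_warning(structureNoAdmixture(sim$genotypes, K = 2, burn_in = 50,
                                      reps = 50, seed = 1,
                                      f_model_prior = list(mean = 0.01,
                                                           sd = 0.05)),
                 "F-model")
})

test_that("planted clusters are recovered at reduced chain lengths", {
  sim <- simulateGenotypeMatrix(K = 2, n_per_cluster = 30, L = 100,
                                freq_in = 0.9, freq_out = 0.1, seed = 9)
  r <- structureNoAdmixture(sim$genotypes, K = 2, burn_in = 2000,
                            reps = 2000, seed = 10)
  expect_gte(permAccuracy(clusterAssignments(r), sim$labels, 2), 0.95)
})

test_that("separation never hurts assignment accuracy", {
  accs <- vapply(c(0.6, 0.75, 0.9), function(f_in) {
    mean(vapply(1:3, function(s) {
      sim <- simulateGenotypeMatrix(K = 2, n_per_cluster = 20, L = 100,
                                    freq_in = f_in, freq_out = 0.1,
                                    seed = 700 + s)
      r <- structureNoAdmixture(sim$genotypes, K = 2, burn_in = 1500,
                                reps = 1500, seed = 800 + s)
      permAccuracy(clusterAssignments(r), sim$labels, 2)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.02))
})

test_that("Evanno delta-K arithmetic and boundaries are exact", {
  runs <- rbind(data.frame(K = 1, lnPD = c(-500, -500)),
                data.frame(K = 2, lnPD = -400 + c(-sqrt(2), sqrt(2))),
                data.frame(K = 3, lnPD = c(-391, -389)),
                data.frame(K = 4, lnPD = c(-389, -387)))
  res <- evannoDeltaK(runs)
  tab <- res$table
  expect_equal(tab$mean_lnPD, c(-500, -400, -390, -388))
  expect_equal(tab$sd_lnPD[2], 2)
  # delta-K(2) = |-390 + 800 - 500| / 2 = 45
  expect_equal(tab$delta_K[tab$K == 2], 45)
  expect_true(is.na(tab$delta_K[tab$K == 1]))
  expect_true(is.na(tab$delta_K[tab$K == 4]))

  expect_error(evannoDeltaK(data.frame(K = c(1, 2, 3),
                                       lnPD = c(-10, -5, -4))),
               "fewer than 2 runs")
  expect_error(evannoDeltaK(rbind(data.frame(K = 1, lnPD = c(-10, -10)),
                                  data.frame(K = 2, lnPD = c(-5, -5)),
                                  data.frame(K = 3, lnPD = c(-4, -4)))),
               "sd of lnPD is 0")
})

test_that("delta-K selects the planted cluster number", {
  sim <- simulateGenotypeMatrix(K = 3, n_per_cluster = 30, L = 100,
                                freq_in = 0.9, freq_out = 0.1, seed = 12)
  runs <- do.call(rbind, lapply(1:5, function(K) {
    data.frame(K = K, lnPD = vapply(1:3, function(r)
      lnProbData(structureNoAdmixture(sim$genotypes, K, burn_in = 2000,
                                      reps = 2000,
                                      seed = 50 * K + r)), numeric(1)))
  }))
  expect_equal(evannoDeltaK(runs)$selected_K, 3)
})
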