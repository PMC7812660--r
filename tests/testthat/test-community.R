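test_that("the three-class recode maps counts and censored bands", {
  expect_equal(three_class_recode(c(0, 1, 57)), c(0L, 1L, 2L))
  expect_equal(three_class_recode(c("0", "1", ">100")), c(0L, 1L, 2L))
  m <- matrix(c(0, 1, 3, 9), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  r <- three_class_recode(m)
  expect_equal(dim(r), dim(m))
  expect_equal(dimnames(r), dimnames(m))
  expect_lte(sum(r), 2 * length(r))
  expect_error(three_class_recode(-1), "non-negative")
})

test_that("species recorded in a single habitat are filtered out", {
  m <- rbind(one = c(3, 0, 0), two = c(0, 2, 1), three = c(4, 0, 2))
  f <- filter_single_habitat_species(m)
  expect_equal(rownames(f$matrix), c("two", "three"))
  expect_equal(f$removed, "one")
})

test_that("Bray-Curtis matches its formula and bounds", {
  X <- rbind(a = c(2, 1, 0), b = c(0, 1, 2), c = c(2, 1, 0))
  D <- as.matrix(bray_curtis(X))
  expect_equal(D["a", "b"], 4 / 6, tolerance = 1e-12)
  expect_equal(D["a", "c"], 0)
  expect_equal(as.vector(as.matrix(bray_curtis(rbind(c(1, 0), c(0, 2))))[1, 2]),
               1)
  expect_error(bray_curtis(rbind(a = c(1, 1), z = c(0, 0))), "z")
  expect_error(bray_curtis(rbind(c(-1, 1), c(0, 2))), "negative")
})

test_that("Bray-Curtis equals a naive double loop on random matrices", {
  set.seed(31)
  for (i in 1:5) {
    X <- matrix(rpois(8 * 6, 3) + (i == 1), 8, 6)
    X[rowSums(X) == 0, 1] <- 1
    expect_equal(unname(as.matrix(bray_curtis(X))), unname(naive_bray(X)),
                 tolerance = 1e-12)
  }
})

test_that("PAVA solves weighted monotone least squares", {
  expect_equal(pava_monotone(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(pava_monotone(c(3, 1)), c(2, 2))
  # weighted pooling: heavier element pulls the pooled level
  expect_equal(pava_monotone(c(3, 1), c(3, 1)), c(2.5, 2.5))
  # idempotent
  y <- c(4, 2, 6, 1, 8)
  expect_equal(pava_monotone(pava_monotone(y)), pava_monotone(y))
  expect_error(pava_monotone(c(1, 2), weights = c(1, -1)), "positive")
})

test_that("PAVA equals a brute-force oracle on short inputs", {
  set.seed(32)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    y <- round(rnorm(n, 0, 2), 2)
    w <- sample(1:4, n, replace = TRUE)
    expect_equal(pava_monotone(y, w), brute_force_isotonic(y, w),
                 tolerance = 1e-9)
  }
  # matches the unweighted stats::isoreg fit as well
  y <- c(5, 3, 4, 1, 6, 2)
  expect_equal(pava_monotone(y), stats::isoreg(y)$yf, tolerance = 1e-12)
})

test_that("NMDS embeds exactly embeddable configurations at zero stress", {
  # any 3 points embed exactly in 2-D
  D3 <- matrix(c(0, 1, 2, 1, 0, 1.5, 2, 1.5, 0), 3)
  f3 <- suppressWarnings(nmds(D3, n_starts = 3, seed = 1))
  expect_lt(f3$stress, 1e-6)
  # Euclidean 2-D distances recover at (near) zero stress
  set.seed(33)
  P <- matrix(rnorm(2 * 10), 10, 2)
  DE <- as.matrix(dist(P))
  fE <- suppressWarnings(nmds(DE, n_starts = 5, seed = 2))
  expect_lte(fE$stress, 1e-4)
})

test_that("NMDS is deterministic for a fixed seed and rotated to axes", {
  set.seed(34)
  X <- matrix(rpois(12 * 20, 2), 12, 20)
  X[rowSums(X) == 0, 1] <- 1
  D <- bray_curtis(X)
  f1 <- suppressWarnings(nmds(D, n_starts = 4, seed = 9))
  f2 <- suppressWarnings(nmds(D, n_starts = 4, seed = 9))
  expect_identical(f1, f2)
  v <- apply(f1$points, 2, var)
  expect_gte(v[1], v[2])  # axis 1 carries the largest variance
  expect_lt(max(abs(colMeans(f1$points))), 1e-8)  # centred
  expect_error(nmds(matrix(0, 2, 2)), "more than k")
})

test_that("NMDS stress is competitive with an independent implementation", {
  set.seed(35)
  X <- matrix(rpois(14 * 25, 2), 14, 25)
  X[rowSums(X) == 0, 1] <- 1
  D <- bray_curtis(X)
  mine <- suppressWarnings(nmds(D, n_starts = 8, seed = 3))
  ref <- vegan::monoMDS(D, k = 2)
  # at least as good a minimum as the reference optimiser finds
  expect_lte(mine$stress, ref$stress + 0.01)
})

test_that("MRPP switches to the exhaustive null for small designs", {
  set.seed(36)
  X <- matrix(runif(6 * 5), 6)
  D <- bray_curtis(X)
  g <- rep(c("a", "b"), each = 3)
  r <- mrpp(D, g)
  expect_true(r$exhaustive)
  expect_equal(r$B, 20L)
  expect_error(mrpp(D, c("a", "a", "a", "a", "a", "b")), "at least 2")
  expect_error(mrpp(D, rep("a", 6)), "two groups")
})

test_that("Monte-Carlo p reproduces the exhaustive p within binomial error", {
  set.seed(37)
  X <- matrix(runif(6 * 5), 6)
  D <- bray_curtis(X)
  g <- rep(c("a", "b"), each = 3)
  exact <- mrpp(D, g)
  mc <- mrpp(D, g, B = 9999, exhaustive_limit = 0, seed = 5)
  se <- sqrt(exact$p_raw * (1 - exact$p_raw) / 9999)
  expect_lt(abs(mc$p_raw - exact$p_raw), 3 * se + 2e-4)
})

test_that("well-separated groups force the minimal Monte-Carlo p", {
  set.seed(38)
  X <- rbind(matrix(rpois(8 * 10, 6), 8), matrix(0, 8, 10))
  X <- cbind(X, rbind(matrix(0, 8, 10), matrix(rpois(8 * 10, 6), 8)))
  X[rowSums(X) == 0, 1] <- 1
  D <- bray_curtis(X)
  g <- rep(c("a", "b"), each = 8)  # 12870 relabelings: Monte-Carlo path
  r <- mrpp(D, g, B = 999, seed = 6)
  expect_false(r$exhaustive)
  expect_equal(r$p_raw, 1 / 1000)
  expect_gt(r$A, 0.3)
})

test_that("MRPP agrees with an independent implementation", {
  set.seed(39)
  X <- matrix(rpois(10 * 12, 3), 10)
  X[rowSums(X) == 0, 1] <- 1
  D <- bray_curtis(X)
  g <- rep(c("a", "b"), each = 5)
  mine <- mrpp(D, g, B = 999, exhaustive_limit = 0, seed = 7)
  ref <- vegan::mrpp(D, g, permutations = 999, weight.type = 1)
  expect_equal(mine$delta_obs, ref$delta, tolerance = 1e-10)
  expect_lt(abs(mine$A - ref$A), 0.02)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(0.5, 3), 1.0)
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("UPGMA reproduces hand-traced merges", {
  # 3 leaves: (a,b) at 0.2, then c at mean(0.6, 0.8) = 0.7
  D3 <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  u <- upgma(D3)
  expect_equal(u$merges$height, c(0.2, 0.7))
  # 4 leaves, hand trace: (a,b) at 0.1; (c,d) at 0.3;
  # then between-pair mean (0.6+0.7+0.8+0.9)/4 = 0.75
  D4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D4["a", "b"] <- D4["b", "a"] <- 0.1
  D4["c", "d"] <- D4["d", "c"] <- 0.3
  D4["a", "c"] <- D4["c", "a"] <- 0.6
  D4["a", "d"] <- D4["d", "a"] <- 0.7
  D4["b", "c"] <- D4["c", "b"] <- 0.8
  D4["b", "d"] <- D4["d", "b"] <- 0.9
  u4 <- upgma(D4)
  expect_equal(u4$merges$height, c(0.1, 0.3, 0.75))
})

test_that("UPGMA cophenetic distances are ultrametric and a fixed point", {
  set.seed(40)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    M <- matrix(runif(n * n), n)
    M <- (M + t(M)) / 2; diag(M) <- 0
    coph <- as.matrix(cophenetic(upgma(M)))
    for (a in 1:(n - 1)) for (b in (a + 1):n) for (c_ in 1:n)
      if (c_ != a && c_ != b)
        expect_gte(max(coph[a, c_], coph[b, c_]) + 1e-12, coph[a, b])
    # feeding the ultrametric back returns it unchanged
    again <- as.matrix(cophenetic(upgma(coph)))
    expect_equal(unname(again[rownames(coph), rownames(coph)]),
                 unname(coph), tolerance = 1e-12)
  }
})

test_that("Newick export preserves tree distances", {
  D3 <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  u <- upgma(D3)
  phy <- ape::read.tree(text = write_newick(u))
  tree_d <- ape::cophenetic.phylo(phy)
  expect_equal(unname(tree_d[letters[1:3], letters[1:3]]),
               unname(as.matrix(cophenetic(u))), tolerance = 1e-12)
  # without halving, root-to-leaf depth equals the root merge height
  phy2 <- ape::read.tree(text = write_newick(u, halve = FALSE))
  expect_equal(max(ape::node.depth.edgelength(phy2)), max(u$merges$height))
})

test_that("overlap counts follow set algebra and a brute-force scan", {
  lists <- list(A = c("s1", "s2"), B = c("s2"), C = c("s2", "s3"))
  ov <- overlap_counts(lists, list(c("A", "B")))
  expect_equal(ov$n_in_all, 1L)   # s2 in both
  expect_equal(ov$n_unique, 0L)   # s2 is also in C
  ov2 <- overlap_counts(lists["A"], list("A"))
  expect_equal(ov2$n_in_all, 2L)
  expect_error(overlap_counts(lists, list(c("A", "zzz"))), "unknown")
  set.seed(41)
  pool <- paste0("s", 1:30)
  rl <- lapply(1:5, function(i) sample(pool, sample(5:15, 1)))
  names(rl) <- LETTERS[1:5]
  combo <- c("A", "C", "E")
  ov3 <- overlap_counts(rl, list(combo))
  in_all <- 0L; uniq <- 0L
  for (sp in pool) {
    inside <- all(vapply(combo, function(t) sp %in% rl[[t]], logical(1)))
    outside <- any(vapply(setdiff(names(rl), combo),
                          function(t) sp %in% rl[[t]], logical(1)))
    in_all <- in_all + inside
    uniq <- uniq + (inside && !outside)
  }
  expect_equal(ov3$n_in_all, in_all)
  expect_equal(ov3$n_unique, uniq)
})

test_that("NMDS never worsens its starting configuration", {
  set.seed(42)
  X <- matrix(rpois(10 * 15, 2), 10, 15)
  X[rowSums(X) == 0, 1] <- 1
  M <- as.matrix(bray_curtis(X))
  ij <- which(upper.tri(M), arr.ind = TRUE)
  diss <- M[upper.tri(M)]
  X0 <- stats::cmdscale(stats::as.dist(M), k = 2)
  s0 <- polyporeR:::nmds_stress(X0, diss, ij)$stress
  fit <- suppressWarnings(nmds(M, n_starts = 0, metric_start = TRUE,
                               seed = 1))
  expect_lte(fit$stress, s0 + 1e-12)
})
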