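# Numerical engine for assemblage analysis: the 0/1/2 recode and filters,
# Bray-Curtis dissimilarity, non-metric multidimensional scaling (Kruskal
# stress-1 minimised by steepest descent with monotone regression by
# pool-adjacent-violators), multi-response permutation procedures with an
# exhaustive or Monte-Carlo null, Bonferroni adjustment, UPGMA dendrograms
# and habitat set-overlap counts.

#' Recode record counts to the three-class assemblage scale
#'
#' No records -> 0, one record -> 1, more than one -> 2. The scale is a
#' compromise between observation bias in raw record numbers and the
#' presence/absence scale's over-emphasis of rare species. Censored banded
#' counts such as `">100"` imply more than one record and recode to 2.
#'
#' @param x non-negative numeric vector/matrix, or character counts
#'   possibly containing banded `">threshold"` entries.
#' @return integer vector/matrix in `{0, 1, 2}` (dimensions preserved).
#' @export
three_class_recode <- function(x) {
  d <- dim(x); dn <- dimnames(x)
  if (is.character(x)) {
    censored <- grepl("^>", x)
    val <- suppressWarnings(as.numeric(x))
    if (any(is.na(val) & !censored & !is.na(x)))
      stop("unparseable count: ",
           paste(unique(x[is.na(val) & !censored]), collapse = ", "))
    val[censored] <- 2  # censored above a threshold >= 1 means > 1 record
    x <- val
  }
  if (any(x < 0, na.rm = TRUE)) stop("counts must be non-negative")
  out <- as.integer(pmin(x, 2))
  dim(out) <- d; dimnames(out) <- dn
  out
}

#' Species x habitat count matrix from records
#'
#' @param records canonical record data frame.
#' @param exclude_early_successional drop early-successional (post
#'   clear-cut) habitat columns, restricting the matrix to older stands.
#' @return integer species x habitat-key matrix.
#' @export
build_habitat_matrix <- function(records, exclude_early_successional = TRUE) {
  keys <- habitat_keys(records)
  m <- table(records$species_id, keys)
  m <- unclass(m)
  storage.mode(m) <- "integer"
  if (exclude_early_successional)
    m <- m[, !is_early_successional(colnames(m)), drop = FALSE]
  m[rowSums(m) > 0, , drop = FALSE]
}

#' Drop species known from a single habitat type
#'
#' Species whose records all fall in one habitat carry no information on
#' assemblage differences and are omitted before ordination and MRPP.
#'
#' @param m species x habitat count (or 0/1/2) matrix.
#' @return list with `matrix` (filtered) and `removed` (species names).
#' @export
filter_single_habitat_species <- function(m) {
  nz <- rowSums(m > 0)
  list(matrix = m[nz >= 2, , drop = FALSE],
       removed = rownames(m)[nz < 2])
}

#' Bray-Curtis dissimilarity
#'
#' `D[i,j] = sum |x_i - x_j| / sum (x_i + x_j)` over variables, for rows
#' (samples) of a non-negative matrix; 0 for identical samples, 1 for
#' samples sharing nothing.
#'
#' @param X samples x variables non-negative matrix.
#' @return a `dist` object with sample labels.
#' @export
bray_curtis <- function(X) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("negative entries are not allowed")
  rs <- rowSums(X)
  if (any(rs == 0)) {
    who <- rownames(X)[rs == 0]
    if (is.null(who)) who <- which(rs == 0)
    stop("all-zero sample(s): ", paste(who, collapse = ", "))
  }
  vegan::vegdist(X, method = "bray")
}

#' Monotone (isotonic) least-squares regression
#'
#' Weighted least-squares fit of a non-decreasing sequence to `y` by the
#' pool-adjacent-violators algorithm; the monotone-regression step of
#' Kruskal's non-metric scaling. Idempotent: an already monotone input is
#' returned unchanged.
#'
#' @param y numeric vector.
#' @param weights positive weights (default equal).
#' @return fitted non-decreasing numeric vector.
#' @export
pava_monotone <- function(y, weights = rep(1, length(y))) {
  n <- length(y)
  if (length(weights) != n) stop("weights must match y in length")
  if (n == 0) return(numeric(0))
  if (!all(is.finite(y))) stop("y must be finite")
  if (!all(weights > 0)) stop("weights must be positive")
  val <- numeric(n); w <- numeric(n); sz <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- y[i]; w[nb] <- weights[i]; sz[nb] <- 1L
    while (nb > 1L && val[nb - 1L] > val[nb]) {
      val[nb - 1L] <- (w[nb - 1L] * val[nb - 1L] + w[nb] * val[nb]) /
        (w[nb - 1L] + w[nb])
      w[nb - 1L] <- w[nb - 1L] + w[nb]
      sz[nb - 1L] <- sz[nb - 1L] + sz[nb]
      nb <- nb - 1L
    }
  }
  rep(val[seq_len(nb)], sz[seq_len(nb)])
}

# stress-1 of a configuration against dissimilarities: monotone disparities
# by PAVA in dissimilarity order (ties resolved by current distances --
# Kruskal's primary approach, so tied dissimilarities may fit unequally)
nmds_stress <- function(X, diss, ij) {
  d <- sqrt(rowSums((X[ij[, 1], , drop = FALSE] -
                       X[ij[, 2], , drop = FALSE])^2))
  o <- order(diss, d)
  dhat <- numeric(length(d))
  dhat[o] <- pava_monotone(d[o])
  Tstar <- sum(d^2)
  Sstar <- sum((d - dhat)^2)
  list(stress = sqrt(Sstar / max(Tstar, .Machine$double.xmin)),
       d = d, dhat = dhat, Sstar = Sstar, Tstar = Tstar)
}

# Kruskal's analytic gradient of stress-1 (disparities held fixed)
nmds_gradient <- function(X, st, ij, n, k) {
  coef <- st$stress * ((st$d - st$dhat) / st$Sstar - st$d / st$Tstar) /
    pmax(st$d, 1e-12)
  diffs <- X[ij[, 1], , drop = FALSE] - X[ij[, 2], , drop = FALSE]
  W <- diffs * coef
  G <- rowsum(rbind(W, -W), c(ij[, 1], ij[, 2]))
  G[order(as.integer(rownames(G))), , drop = FALSE]
}

nmds_one_start <- function(X, diss, ij, max_iter, tol) {
  n <- nrow(X); k <- ncol(X)
  st <- nmds_stress(X, diss, ij)
  step <- 0.2
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    if (st$stress < 1e-9 || st$Sstar < 1e-18) { converged <- TRUE; break }
    G <- nmds_gradient(X, st, ij, n, k)
    gn <- sqrt(sum(G^2))
    if (gn < 1e-12) { converged <- TRUE; break }
    scale0 <- sqrt(sum(X^2)) / gn
    improved <- FALSE
    for (h in seq_len(12)) {
      X1 <- X - (step * scale0) * G
      st1 <- nmds_stress(X1, diss, ij)
      if (st1$stress < st$stress) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    rel <- (st$stress - st1$stress) / max(st$stress, 1e-12)
    X <- X1; st <- st1
    step <- min(step * 1.5, 1)
    if (rel < tol) { converged <- TRUE; break }
  }
  list(X = X, stress = st$stress, converged = converged)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Finds a `k`-dimensional configuration whose inter-point distances
#' minimise Kruskal's stress-1,
#' `sqrt( sum (d - dhat)^2 / sum d^2 )`, where `dhat` is the monotone
#' (PAVA) regression of configuration distances on the input
#' dissimilarities. Each start is optimised by steepest descent on the
#' analytic stress gradient with a backtracking line search, so the stress
#' sequence within a start is non-increasing. The best of `n_starts`
#' random starts (plus, by default, one metric start from classical
#' scaling) is retained, then centred and rotated to principal axes so
#' axis 1 carries the largest variance of site scores.
#'
#' @param D dissimilarity matrix or `dist`.
#' @param k number of dimensions (default 2).
#' @param n_starts number of random starting configurations.
#' @param max_iter,tol iteration cap and relative stress-improvement
#'   tolerance per start.
#' @param seed integer seed; fixed seed gives a deterministic result.
#' @param metric_start also try a classical-scaling (eigendecomposition)
#'   start; set `FALSE` for purely random starts.
#' @return list of class `nmds_fit`: `points` (n x k rotated coordinates),
#'   `stress`, `n_starts`, `best_start`, `converged`, `seed`.
#' @export
nmds <- function(D, k = 2, n_starts = 20, max_iter = 300, tol = 1e-7,
                 seed = 1, metric_start = TRUE) {
  M <- as.matrix(D)
  n <- nrow(M)
  if (n <= k) stop("need more than k objects (n = ", n, ", k = ", k, ")")
  labels <- rownames(M)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  set.seed(seed)
  ut <- upper.tri(M)
  ij <- which(ut, arr.ind = TRUE)
  diss <- M[ut]
  starts <- list()
  if (metric_start) {
    cmd <- suppressWarnings(stats::cmdscale(stats::as.dist(M), k = k))
    if (ncol(cmd) < k)  # degenerate input: pad with small noise
      cmd <- cbind(cmd, matrix(stats::rnorm(n * (k - ncol(cmd)), 0, 1e-4),
                               n, k - ncol(cmd)))
    starts[[1]] <- cmd
  }
  for (s in seq_len(n_starts))
    starts[[length(starts) + 1L]] <- matrix(stats::runif(n * k, -1, 1), n, k)
  best <- NULL; best_start <- NA_integer_
  for (s in seq_along(starts)) {
    fit <- nmds_one_start(starts[[s]], diss, ij, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit; best_start <- s
    }
  }
  if (!best$converged)
    warning("NMDS did not converge within max_iter for the best start")
  # centre and rotate to principal axes; fix signs deterministically
  X <- scale(best$X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  X <- X %*% sv$v
  for (a in seq_len(k))
    if (X[which.max(abs(X[, a])), a] < 0) X[, a] <- -X[, a]
  dimnames(X) <- list(labels, paste0("NMDS", seq_len(k)))
  structure(list(points = X, stress = best$stress,
                 n_starts = length(starts), best_start = best_start,
                 converged = best$converged, seed = seed),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat("Non-metric multidimensional scaling (Kruskal stress-1)\n")
  cat("  ", nrow(x$points), " sites in ", ncol(x$points),
      " dimensions; stress = ", format(x$stress, digits = 4),
      " (best of ", x$n_starts, " starts",
      if (!x$converged) ", not converged" else "", ")\n", sep = "")
  invisible(x)
}

#' @export
plot.nmds_fit <- function(x, ...) {
  graphics::plot(x$points[, 1], x$points[, 2],
                 xlab = "NMDS1", ylab = "NMDS2", asp = 1, ...)
  graphics::text(x$points[, 1], x$points[, 2], rownames(x$points),
                 pos = 3, cex = 0.7)
  invisible(x)
}

# all distinct assignments of group labels (1..k with given sizes) to
# positions 1..n, as an n x N integer matrix
multiset_permutations <- function(sizes) {
  n <- sum(sizes); k <- length(sizes)
  rec <- function(avail, gi) {
    if (gi == k) {
      m <- matrix(0L, n, 1L)
      m[avail, 1L] <- k
      return(m)
    }
    ch <- if (length(avail) == 1L) matrix(avail, 1L, 1L) else
      utils::combn(avail, sizes[gi])
    cols <- vector("list", ncol(ch))
    for (j in seq_len(ncol(ch))) {
      sub <- rec(setdiff(avail, ch[, j]), gi + 1L)
      sub[ch[, j], ] <- gi
      cols[[j]] <- sub
    }
    do.call(cbind, cols)
  }
  rec(seq_len(n), 1L)
}

# weighted mean within-group dissimilarity for each assignment column
mrpp_deltas <- function(M, A, sizes, w) {
  k <- length(sizes)
  delta <- numeric(ncol(A))
  for (g in seq_len(k)) {
    P <- A == g
    within <- colSums(P * (M %*% P)) / 2
    delta <- delta + w[g] * within / (sizes[g] * (sizes[g] - 1) / 2)
  }
  delta
}

#' Multi-response permutation procedure (MRPP)
#'
#' Tests whether within-group dissimilarities are smaller than expected
#' under random relabeling. The observed statistic is the weighted mean
#' within-group dissimilarity `delta = sum_g w_g * mean_g`; the null
#' distribution comes from all distinct relabelings when their number is
#' at most `exhaustive_limit`, otherwise from `B` random relabelings with
#' the add-one p estimator `(1 + #{delta_perm <= delta_obs}) / (B + 1)`.
#' The chance-corrected within-group agreement is
#' `A = 1 - delta_obs / expected_delta`.
#'
#' @param D dissimilarity matrix or `dist`.
#' @param groups grouping vector (>= 2 groups, each of size >= 2).
#' @param B number of Monte-Carlo relabelings.
#' @param weight group weights, proportional to group size `n_g`
#'   (default, i.e. `n_g / sum n_g`), to `n_g - 1`, or to the number of
#'   within-group pairs `n_g (n_g - 1) / 2`.
#' @param seed integer seed for the Monte-Carlo null.
#' @param exhaustive_limit enumerate the exact null when the number of
#'   distinct relabelings does not exceed this.
#' @param m Bonferroni multiplier for `p_adjusted` (number of tests in the
#'   family; default 1).
#' @return list of class `mrpp_result`: `delta_obs`, `expected_delta`,
#'   `A`, `p_raw`, `p_adjusted`, `B` (relabelings used), `exhaustive`,
#'   `seed`.
#' @export
mrpp <- function(D, groups, B = 999,
                 weight = c("group_size", "group_size_minus_1", "pairs"),
                 seed = 1, exhaustive_limit = 10000, m = 1) {
  weight <- match.arg(weight)
  M <- as.matrix(D)
  groups <- as.factor(groups)
  n <- nrow(M)
  if (length(groups) != n) stop("groups must match the matrix dimension")
  sizes <- as.integer(table(groups))
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group must have at least 2 members")
  w <- switch(weight,
              group_size = sizes,
              group_size_minus_1 = sizes - 1,
              pairs = sizes * (sizes - 1) / 2)
  w <- w / sum(w)
  gint <- as.integer(groups)
  obs <- mrpp_deltas(M, matrix(gint, n, 1), sizes, w)
  n_total <- round(exp(lfactorial(n) - sum(lfactorial(sizes))))
  eps <- 1e-12
  if (n_total <= exhaustive_limit) {
    A_all <- multiset_permutations(sizes)
    deltas <- mrpp_deltas(M, A_all, sizes, w)
    p_raw <- mean(deltas <= obs + eps)
    expected <- mean(deltas)
    B_used <- ncol(A_all)
    exhaustive <- TRUE
  } else {
    set.seed(seed)
    A_mc <- replicate(B, sample(gint))
    deltas <- mrpp_deltas(M, A_mc, sizes, w)
    p_raw <- (1 + sum(deltas <= obs + eps)) / (B + 1)
    expected <- mean(deltas)
    B_used <- B
    exhaustive <- FALSE
  }
  structure(list(delta_obs = obs, expected_delta = expected,
                 A = 1 - obs / expected, p_raw = p_raw,
                 p_adjusted = min(1, m * p_raw), B = B_used,
                 exhaustive = exhaustive, weight = weight, seed = seed),
            class = "mrpp_result")
}

#' @export
print.mrpp_result <- function(x, ...) {
  cat("MRPP: delta_obs = ", format(x$delta_obs, digits = 4),
      ", expected = ", format(x$expected_delta, digits = 4),
      ", A = ", format(x$A, digits = 3), "\n", sep = "")
  cat("  p = ", format(x$p_raw, digits = 4),
      if (x$p_adjusted != x$p_raw)
        paste0(" (Bonferroni-adjusted ", format(x$p_adjusted, digits = 4),
               ")") else "",
      " from ", x$B,
      if (x$exhaustive) " exhaustive relabelings\n" else
        " Monte-Carlo relabelings\n", sep = "")
  invisible(x)
}

#' Bonferroni adjustment
#'
#' @param p p-value(s) in \code{[0, 1]}.
#' @param m number of tests (default `length(p)`).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (m < 1) stop("m must be at least 1")
  pmin(1, m * p)
}

#' UPGMA (average-linkage) clustering
#'
#' Agglomerative clustering where the distance between clusters is the
#' size-weighted arithmetic mean over all cross pairs, producing an
#' ultrametric dendrogram whose merge heights are non-decreasing.
#'
#' @param D dissimilarity matrix or `dist` (n >= 2).
#' @return list of class `upgma_dendrogram`: `hclust` (the underlying
#'   merge tree), `labels`, `merges` (data frame of merge heights).
#' @seealso [write_newick()], [cut_dendrogram()],
#'   [stats::cophenetic()] (a method is provided).
#' @export
upgma <- function(D) {
  d <- stats::as.dist(D)
  if (attr(d, "Size") < 2) stop("need at least 2 objects")
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, labels = hc$labels,
                 merges = data.frame(left = hc$merge[, 1],
                                     right = hc$merge[, 2],
                                     height = hc$height)),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram over ", length(x$labels), " leaves; merge heights ",
      format(min(x$merges$height), digits = 3), " .. ",
      format(max(x$merges$height), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
plot.upgma_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, ...)
  invisible(x)
}

#' @export
cophenetic.upgma_dendrogram <- function(x) {
  stats::cophenetic(x$hclust)
}

#' Cut a dendrogram into k groups
#'
#' @param dend an [upgma()] result.
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cut_dendrogram <- function(dend, k) {
  stopifnot(inherits(dend, "upgma_dendrogram"))
  stats::cutree(dend$hclust, k = k)
}

#' Export a dendrogram to Newick
#'
#' @param dend an [upgma()] result.
#' @param file optional output path; omit to return the Newick string.
#' @param halve halve merge heights so leaf-to-leaf path lengths on the
#'   tree equal the merge heights (the usual ultrametric branch-length
#'   convention); `FALSE` doubles branch lengths so root-to-leaf depth
#'   equals the root merge height.
#' @return the Newick string, invisibly when written to `file`.
#' @export
write_newick <- function(dend, file = NULL, halve = TRUE) {
  stopifnot(inherits(dend, "upgma_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  if (!halve) phy$edge.length <- phy$edge.length * 2
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}

#' Habitat set-overlap counts
#'
#' For each requested combination of habitat types, counts the species
#' found in every member type (`n_in_all`) and, of those, the species
#' found in no type outside the combination (`n_unique`) -- the two
#' numbers an area-proportional overlap (Euler) diagram displays.
#'
#' @param species_lists named list of unique-species character vectors,
#'   one per habitat type.
#' @param combinations list of character vectors naming the types in each
#'   combination.
#' @return data frame: `combination` (types joined by `"+"`), `n_in_all`,
#'   `n_unique`.
#' @export
overlap_counts <- function(species_lists, combinations) {
  stopifnot(is.list(species_lists), !is.null(names(species_lists)))
  out <- data.frame(combination = character(), n_in_all = integer(),
                    n_unique = integer(), stringsAsFactors = FALSE)
  for (combo in combinations) {
    unknown <- setdiff(combo, names(species_lists))
    if (length(unknown))
      stop("unknown habitat type(s): ", paste(unknown, collapse = ", "))
    inter <- Reduce(intersect, species_lists[combo])
    elsewhere <- unique(unlist(species_lists[setdiff(names(species_lists),
                                                     combo)]))
    out[nrow(out) + 1L, ] <- list(paste(combo, collapse = "+"),
                                  length(inter),
                                  length(setdiff(inter, elsewhere)))
  }
  out
}
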