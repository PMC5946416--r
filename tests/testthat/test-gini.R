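test_that("gini index matches hand-derived values and conventions", {
  expect_equal(gini_index(c(5, 5, 5, 5)), 0)
  expect_equal(gini_index(c(4, 2, 2)), 1 / 6)
  expect_equal(gini_index(c(7, rep(0, 9))), 0.9) # (n-1)/n with one nonzero
  expect_equal(gini_index(numeric(5)), 0)        # all-zero convention
  expect_error(gini_index(3), "at least 2")
  expect_error(gini_index(c(1, -1)), "non-negative")
})

test_that("sorted-form gini equals the pairwise-difference oracle", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    x <- switch(sample(3, 1),
                rpois(n, 2),
                round(rexp(n, 0.1)),
                {v <- rpois(n, 1); v[sample(n, 1)] <- 50; v})
    expect_equal(gini_index(x), gini_pairwise(x), tolerance = 1e-12)
  }
})

test_that("gini index is scale invariant", {
  set.seed(11)
  x <- rpois(30, 3)
  for (c in c(0.01, 2, 1000)) {
    expect_equal(gini_index(c * x), gini_index(x), tolerance = 1e-12)
  }
})

test_that("score_gini reproduces vector-wise results on a sparse matrix", {
  set.seed(21)
  m <- matrix(rpois(300, 0.7), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:10)))
  sc <- score_gini(Matrix::Matrix(m, sparse = TRUE))
  expect_equal(sc$gini_raw, unname(apply(m, 1, gini_index)))
  expect_equal(sc$max_expr, unname(apply(m, 1, max)))
})

test_that("LOESS normalization removes a trend that is exactly linear in the covariate", {
  max_expr <- exp(seq(log(0.5), log(2000), length.out = 300))
  gini_raw <- 0.85 - 0.04 * log2(max_expr + 0.1)
  scores <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                           max_expr = max_expr, gini_raw = gini_raw)
  out <- normalize_gini(scores)
  expect_lt(max(abs(out$gini_norm)), 1e-6 * diff(range(gini_raw)))
})

test_that("a spiked gene gets the top normalized gini and the smallest p-value", {
  set.seed(3)
  max_expr <- exp(seq(log(0.5), log(2000), length.out = 300))
  gini_raw <- pmax(0, 0.85 - 0.04 * log2(max_expr + 0.1) + rnorm(300, 0, 0.005))
  gini_raw[120] <- gini_raw[120] + 0.4
  scores <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                           max_expr = max_expr, gini_raw = gini_raw)
  out <- normalize_gini(scores)
  expect_equal(which.max(out$gini_norm), 120)
  expect_equal(which.min(out$p_value), 120)
})

test_that("normal-tail p-values select the expected fraction of null genes", {
  set.seed(77)
  gnorm <- rnorm(1e6)
  p <- ginifano:::gini_pvalue(gnorm)
  frac <- mean(p < 1e-4)
  # binomial sampling error around 1e-4 at one million genes
  expect_lt(abs(frac - 1e-4), 5e-5)
})

test_that("high-gini selection is a strict threshold and is monotone", {
  scores <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                           p_value = c(5e-5, 2e-4, 0.5))
  expect_identical(select_high_gini(scores, 1e-4), "g1")
  expect_setequal(select_high_gini(scores, 1), c("g1", "g2", "g3"))
  expect_error(select_high_gini(tibble::tibble(gene_id = "g", p_value = 0.5)),
               "relax")
  # monotone: raising the threshold never drops a selected gene
  set.seed(9)
  sc <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                       p_value = runif(200, 0, 0.3))
  prev <- character(0)
  for (th in c(0.001, 0.01, 0.1, 0.3)) {
    cur <- tryCatch(select_high_gini(sc, th), error = function(e) character(0))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("jaccard distance follows the binary set definition", {
  m <- matrix(c(1, 1, 0,
                1, 0, 1), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  d <- jaccard_distance(m)
  expect_equal(d["a", "b"], 2 / 3) # |intersection| 1, |union| 3
  same <- matrix(c(2, 1, 0, 5, 9, 0), ncol = 2,
                 dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(jaccard_distance(same)["a", "b"], 0) # identical supports
  disj <- matrix(c(1, 0, 0, 1), ncol = 2,
                 dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(jaccard_distance(disj)["a", "b"], 1)
  zz <- matrix(0, 2, 3, dimnames = list(paste0("g", 1:2), c("a", "b", "c")))
  zz[1, 3] <- 1
  dz <- jaccard_distance(zz)
  expect_equal(dz["a", "b"], 0) # two empty profiles: distance 0 by convention
  expect_equal(dz["a", "c"], 1)
})

test_that("dbscan separates clean blocks and flags isolated cells as noise", {
  d <- matrix(1, 21, 21)
  d[1:10, 1:10] <- 0
  d[11:20, 11:20] <- 0
  diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("c%02d", 1:21)
  p <- dbscan_cluster(d, eps = 0.5, min_pts = 3)
  expect_equal(partition_k(p), 2)
  expect_equal(length(unique(p$cluster[1:10])), 1)
  expect_equal(length(unique(p$cluster[11:20])), 1)
  expect_equal(p$cluster[21], 0L) # isolated cell is noise
})

test_that("dbscan matches the reference implementation on a fixed instance", {
  # three gaussian blobs of differing tightness; expected labels computed
  # once with scikit-learn's DBSCAN (eps = 0.8, min_samples = 4,
  # metric = "precomputed") and frozen: -1 (noise) recoded as 0
  set.seed(42)
  x <- matrix(rnorm(60), ncol = 2)
  x[1:10, ] <- x[1:10, ] * 0.2
  x[11:20, ] <- x[11:20, ] * 0.2 + 3
  x[21:30, ] <- x[21:30, ] * 1.5 - 4
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- sprintf("c%02d", 1:30)
  p <- dbscan_cluster(d, eps = 0.8, min_pts = 4)
  expected <- c(rep(1L, 10), rep(2L, 10),
                3L, 0L, 0L, 0L, 0L, 3L, 3L, 0L, 0L, 3L)
  # canonicalize cluster ids by first appearance before comparing
  canon <- function(lab) {
    ids <- unique(lab[lab != 0L])
    ifelse(lab == 0L, 0L, match(lab, ids))
  }
  expect_identical(canon(p$cluster), expected)
})

test_that("dbscan labels are invariant under cell permutation", {
  set.seed(13)
  x <- rbind(matrix(rnorm(20, sd = 0.1), ncol = 2),
             matrix(rnorm(20, mean = 4, sd = 0.1), ncol = 2))
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- sprintf("c%02d", 1:20)
  p1 <- dbscan_cluster(d, eps = 0.7, min_pts = 3)
  perm <- sample(20)
  dp <- d[perm, perm]
  p2 <- dbscan_cluster(dp, eps = 0.7, min_pts = 3)
  expect_equal(ari(p1, p2), 1)
  expect_setequal(p1$cell_id[p1$cluster == 0], p2$cell_id[p2$cluster == 0])
})
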