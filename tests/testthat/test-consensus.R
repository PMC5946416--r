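test_that("connectivity encodes shared-cluster membership", {
  p <- as_partition(c(a = "A", b = "A", c = "B"))
  m <- connectivity(p)
  expect_equal(unname(m), rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))

  one <- new_partition(paste0("c", 1:5), rep(1, 5))
  expect_true(all(connectivity(one) == 1))

  singletons <- new_partition(paste0("c", 1:4), 1:4)
  expect_equal(unname(connectivity(singletons)), diag(4))

  # noise cells connect only to themselves
  noisy <- new_partition(paste0("c", 1:3), c(1, 0, 0))
  expect_equal(unname(connectivity(noisy)), diag(3))
})

test_that("parameter derivation inverts the logistic link and round-trips", {
  p <- derive_params(mu = 0.05, s = 0.0125, f = 0.25)
  expect_equal(p$f_prime, 1 / 3) # f' = f/(1-f)
  expect_equal(p$s_prime, p$s)

  set.seed(17)
  for (i in 1:100) {
    mu <- runif(1, 0.01, 0.9)
    s <- runif(1, 0.001, 0.2)
    f <- runif(1, 0.01, 0.49)
    pr <- derive_params(mu, s, f)
    back <- recover_params(pr$mu_prime, pr$s_prime, pr$f_prime)
    expect_equal(back$mu, mu, tolerance = 1e-12)
    expect_equal(back$s, s, tolerance = 1e-12)
    expect_equal(back$f, f, tolerance = 1e-12)
  }

  expect_error(derive_params(f = 1.2), "\\(0, 1\\)")
  expect_error(derive_params(f = 0.5), "below 0.5")
})

test_that("the cell weight curve is logistic with the documented landmarks", {
  p <- derive_params(mu = 0.05, s = 0.0125, f = 0.1)
  expect_equal(gini_cell_weight(p$mu_prime, p), 0.5)
  expect_equal(gini_cell_weight(p$mu_prime + p$s_prime, p),
               1 - 1 / (1 + exp(-1)), tolerance = 1e-12)
  # saturation for tiny proportions
  psat <- derive_params(mu = 0.5, s = 0.01, f = 0.4)
  expect_equal(gini_cell_weight(1e-6, psat), 1, tolerance = 1e-6)
  # strictly decreasing away from the saturated tails, non-increasing always
  xs <- seq(0.001, 1, length.out = 50)
  expect_true(all(diff(gini_cell_weight(xs, p)) <= 0))
  mid <- seq(max(1e-4, p$mu_prime - 3 * p$s_prime),
             p$mu_prime + 3 * p$s_prime, length.out = 20)
  expect_true(all(diff(gini_cell_weight(mid, p)) < 0))
  expect_error(gini_cell_weight(0, p), "proportions")
})

test_that("pair weights take the rarer member and normalize to one", {
  w <- pair_weights(1, 0, f_prime = 1)
  expect_equal(c(w$w_g, w$w_f), c(0.5, 0.5))
  w0 <- pair_weights(0, 0, f_prime = 0.2)
  expect_equal(c(w0$w_g, w0$w_f), c(0, 1)) # pure common-stage assignment
  expect_error(pair_weights(0, 0, f_prime = 0), "degenerate")

  set.seed(18)
  wi <- runif(1e4); wj <- runif(1e4); fp <- runif(1e4, 1e-6, 5)
  ww <- pair_weights(wi, wj, fp)
  expect_true(all(abs(ww$w_g + ww$w_f - 1) < 1e-12))
  expect_true(all(ww$w_g >= 0 & ww$w_f >= 0))
})

test_that("consensus matrix matches a per-pair scalar oracle and is convex", {
  set.seed(19)
  params <- derive_params(mu = 0.3, s = 0.05, f = 0.2)
  for (rep in 1:5) {
    pg <- random_partition(15, 3, noise_frac = 0.1)
    pf <- random_partition(15, 2)
    mbar <- consensus_matrix(pg, pf, params, block_size = 4)
    mg <- connectivity(pg); mf <- connectivity(pf)
    w <- cell_weights(pg, params)
    for (i in 1:15) {
      for (j in 1:15) {
        if (i == j) next
        wij <- max(w$w_tilde_g[i], w$w_tilde_g[j])
        wg <- wij / (wij + params$f_prime)
        expect_equal(mbar[i, j], wg * mg[i, j] + (1 - wg) * mf[i, j],
                     tolerance = 1e-12)
      }
    }
    expect_true(all(mbar >= pmin(mg, mf) - 1e-12 & mbar <= pmax(mg, mf) + 1e-12))
    expect_equal(mbar, t(mbar))
    expect_true(all(diag(mbar) == 1))
  }
  # identical partitions: consensus equals the shared connectivity
  p <- random_partition(12, 3)
  expect_equal(consensus_matrix(p, p, params), connectivity(p))
})

test_that("degenerate weights recover the pure rare or pure common partition", {
  set.seed(20)
  pg <- random_partition(20, 4)
  pf <- random_partition(20, 2)
  # f' -> 0 with saturated cell weights: consensus equals the rare-stage
  # connectivity and clustering it recovers the rare-stage partition
  p_lo <- derive_params(mu = 0.9, s = 0.0125, f = 1e-6)
  m_lo <- consensus_matrix(pg, pf, p_lo)
  expect_equal(m_lo, connectivity(pg), tolerance = 1e-4)
  rec <- final_cluster(m_lo, partition_k(pg), seed = 1)
  expect_equal(ari(rec, pg), 1)
  # f' enormous: consensus equals the common-stage connectivity
  p_hi <- structure(list(mu = NA, s = 0.0125, f = NA, mu_prime = 0.024,
                         s_prime = 0.0125, f_prime = 1e6),
                    class = "weight_params")
  m_hi <- consensus_matrix(pg, pf, p_hi)
  expect_equal(m_hi, connectivity(pf), tolerance = 1e-4)
  rec2 <- final_cluster(m_hi, partition_k(pf), seed = 1)
  expect_equal(ari(rec2, pf), 1)
})

test_that("final clustering solves the connectivity approximation problem", {
  # exact two-block consensus: blocks recovered with objective zero
  lab <- rep(1:2, c(5, 3))
  mb <- outer(lab, lab, "==") * 1
  dimnames(mb) <- list(paste0("c", 1:8), paste0("c", 1:8))
  p <- final_cluster(mb, 2, seed = 1)
  expect_equal(attr(p, "objective"), 0)
  expect_equal(ari(p, new_partition(paste0("c", 1:8), lab)), 1)

  # n = 8: ||Mbar - U||^2 of the returned bipartition equals the
  # exhaustive minimum over all 127 connectivity matrices. The partitions
  # carry the coherent structure the consensus operates on (the coarse
  # partition merges two blocks of the fine one); for such matrices the
  # k-means relaxation attains the exact optimizer.
  set.seed(22)
  labg <- rep(1:3, c(4, 2, 2))[sample(8)]
  labf <- ifelse(labg == 3, 2, 1)
  ids8 <- sprintf("c%02d", 1:8)
  pg <- new_partition(ids8, labg)
  pf <- new_partition(ids8, labf)
  params <- derive_params(mu = 0.4, s = 0.05, f = 0.2)
  mbar <- consensus_matrix(pg, pf, params)
  got <- final_cluster(mbar, 2, seed = 3)
  got_obj <- conn_objective(mbar, unname(partition_vector(got, ids8)))
  best <- min(vapply(all_bipartitions(8), function(l) conn_objective(mbar, l), 1))
  expect_equal(got_obj, best, tolerance = 1e-9)

  expect_error(final_cluster(mbar, 9, seed = 1), "exceeds")
})

test_that("k_final = n reduces the objective to the off-diagonal mass", {
  # choose partitions so no two cells agree in both stages: rows distinct
  pg <- new_partition(paste0("c", 1:4), c(1, 1, 2, 2))
  pf <- new_partition(paste0("c", 1:4), c(1, 2, 1, 2))
  params <- derive_params(mu = 0.6, s = 0.1, f = 0.3)
  mbar <- consensus_matrix(pg, pf, params)
  p <- final_cluster(mbar, 4, seed = 1)
  expect_equal(length(unique(p$cluster)), 4)
  obj <- conn_objective(mbar, partition_vector(p, paste0("c", 1:4)))
  expect_equal(obj, sum(mbar^2) - sum(diag(mbar)^2), tolerance = 1e-12)
})

test_that("the default k rule counts common clusters plus rare candidates", {
  params <- derive_params(mu = 0.05, s = 0.0125, f = 0.1)
  sizes <- c(9700, 30, 20, 13, 10)
  pg <- new_partition(sprintf("c%05d", seq_len(sum(sizes))),
                      rep(seq_along(sizes), sizes))
  pf <- new_partition(pg$cell_id, rep(1:2, c(6000, sum(sizes) - 6000)))
  k <- choose_k_final(pg, pf, params)
  expect_equal(as.integer(k), 6) # 2 common + 4 rare candidates

  # no rare candidate below mu
  pg2 <- new_partition(paste0("c", 1:100), rep(1:2, c(60, 40)))
  pf2 <- new_partition(pg2$cell_id, rep(1:2, c(50, 50)))
  expect_equal(as.integer(choose_k_final(pg2, pf2, params)), 2)
})
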