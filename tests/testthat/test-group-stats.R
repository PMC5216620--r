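test_that("one-sample t matches the textbook formula", {
  z <- c(2, -1, 0.5, 1.5, -0.5)
  st <- one_sample_t(cbind(z, z * 0 + 1e-9))
  s <- length(z)
  expect_equal(st$t[1], mean(z) / (sd(z) / sqrt(s)), tolerance = 1e-10)
  expect_equal(st$p[1], 2 * pt(-abs(st$t[1]), s - 1), tolerance = 1e-12)
  # degenerate columns
  st2 <- one_sample_t(cbind(rep(0, 4), rep(1, 4), rnorm(4)))
  expect_true(is.na(st2$t[1]))                # all zero: undefined
  expect_true(is.infinite(st2$t[2]) && st2$t[2] > 0)  # zero var, mean > 0
  expect_equal(st2$p[2], 0)
})

test_that("covariate residualization matches a normal-equations oracle", {
  set.seed(10)
  s <- 8; z <- matrix(rnorm(s * 2), s, 2)
  covs <- matrix(rnorm(s * 2), s, 2)
  out <- residualize_covariates(z, covs)
  x <- cbind(1, covs)
  beta <- solve(t(x) %*% x, t(x) %*% z)        # explicit normal equations
  oracle <- z - x %*% beta + rep(1, s) %*% t(colMeans(z))
  expect_equal(out, oracle, tolerance = 1e-10)
  # group means preserved
  expect_equal(colMeans(out), colMeans(z), tolerance = 1e-12)
  # orthogonal covariate leaves data unchanged
  zc <- scale(z, scale = FALSE)
  qz <- qr.Q(qr(cbind(1, zc)))
  ortho <- rnorm(s); ortho <- ortho - qz %*% (t(qz) %*% ortho)
  out2 <- residualize_covariates(z, cbind(ortho))
  expect_equal(out2, z, tolerance = 1e-8)
  # z exactly linear in a covariate -> residual variance ~ 0
  zl <- cbind(3 * covs[, 1] - 1)
  out3 <- residualize_covariates(zl, covs)
  expect_lt(var(as.numeric(out3)) / var(as.numeric(zl)), 1e-20)
})

test_that("two-sample t matches the pooled-variance oracle", {
  zA <- matrix(c(1.2, 0.8, 1.5, 1.1, 0.9), 5, 1)
  zB <- matrix(c(0.3, 0.6, 0.2, 0.5, 0.4), 5, 1)
  st <- two_sample_t(zA, zB)
  n1 <- 5; n2 <- 5
  sp2 <- ((n1 - 1) * var(zA[, 1]) + (n2 - 1) * var(zB[, 1])) / (n1 + n2 - 2)
  t_or <- (mean(zA) - mean(zB)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(st$t[1], t_or, tolerance = 1e-10)
  expect_equal(st$direction[1], "increase")
  expect_equal(st$t[1], unname(t.test(zA, zB, var.equal = TRUE)$statistic))
  # identical groups -> t = 0, p = 1
  st0 <- two_sample_t(zA, zA)
  expect_equal(st0$t[1], 0)
  expect_equal(st0$p[1], 1)
  # separated groups with zero within-group variance -> p -> 0 sentinel
  stS <- two_sample_t(matrix(1, 4, 1), matrix(-1, 4, 1))
  expect_true(is.infinite(stS$t[1]))
  expect_equal(stS$p[1], 0)
  # mask restricts testing
  stM <- two_sample_t(cbind(zA, zA), cbind(zB, zB), mask = c(TRUE, FALSE))
  expect_true(is.na(stM$t[2]) && !is.na(stM$t[1]))
  expect_warning(two_sample_t(zA, zB, mask = FALSE), "empty mask")
})

test_that("BH mask matches the hand example and brute-force enumeration", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.2, 0.9), q = 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fdr_bh(rep(1, 5)), rep(FALSE, 5))
  expect_equal(fdr_bh(rep(0, 5)), rep(TRUE, 5))
  # brute force: largest k with p_(k) <= q k / m, computed independently
  bh_oracle <- function(p, q) {
    m <- length(p); o <- order(p); ps <- p[o]
    k <- 0
    for (i in seq_len(m)) if (ps[i] <= q * i / m) k <- i
    mask <- rep(FALSE, m)
    if (k > 0) mask[o[seq_len(k)]] <- TRUE
    mask
  }
  set.seed(11)
  for (rep in 1:50) {
    p <- round(runif(sample(3:8, 1)), 3)
    expect_identical(fdr_bh(p, 0.1), bh_oracle(p, 0.1))
  }
  # p.adjust cross-check (dual route)
  p <- runif(40)
  expect_identical(fdr_bh(p, 0.05),
                   p.adjust(p, "BH") <= 0.05)
})

test_that("cluster filtering applies a strict size threshold", {
  # line graph of 40 nodes; mask has components of sizes 5 and 30
  n <- 40
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  mask <- rep(FALSE, n)
  mask[1:5] <- TRUE; mask[10:39] <- TRUE
  out <- cluster_filter(mask, adj, k = 23)
  expect_equal(which(out), 10:39)
  # component of exactly 23 removed (strict > 23)
  m23 <- rep(FALSE, n); m23[1:23] <- TRUE
  expect_false(any(cluster_filter(m23, adj, k = 23)))
  m24 <- rep(FALSE, n); m24[1:24] <- TRUE
  expect_equal(sum(cluster_filter(m24, adj, k = 23)), 24)
  # empty mask -> empty mask
  expect_false(any(cluster_filter(rep(FALSE, n), adj, k = 23)))
  # ROI mode: singletons survive only with k = 0
  expect_equal(cluster_filter(c(TRUE, FALSE, TRUE), k = 0),
               c(TRUE, FALSE, TRUE))
  expect_false(any(cluster_filter(c(TRUE, FALSE, TRUE), k = 1)))
})

test_that("cluster filtering is monotone in the input mask", {
  set.seed(12)
  n <- 30
  adj <- matrix(runif(n * n) < 0.1, n, n)
  adj <- adj | t(adj); diag(adj) <- FALSE
  for (rep in 1:20) {
    big <- runif(n) < 0.6
    small <- big & (runif(n) < 0.7)
    out_big <- cluster_filter(big, adj, k = 2)
    out_small <- cluster_filter(small, adj, k = 2)
    # a node surviving from the smaller mask must survive from the larger one
    expect_true(all(out_big[out_small]))
  }
})

test_that("FDR controls the false discovery proportion under the null", {
  # two-sample pipeline on fully null z-maps: mean FDP <= q + 0.02
  set.seed(13)
  q <- 0.05
  fdp <- replicate(200, {
    zA <- matrix(rnorm(50 * 100, 0, 0.1), 50, 100)
    zB <- matrix(rnorm(50 * 100, 0, 0.1), 50, 100)
    st <- two_sample_t(zA, zB)
    mask <- fdr_bh(st$p, q)
    if (!any(mask)) 0 else 1   # all discoveries are false under the null
  })
  expect_lte(mean(fdp), q + 0.02)
})

test_that("feature definition and extraction follow the contrast", {
  node_labels <- c("n1", "n2", "n3")
  stat <- structure(list(t = c(3, -4, 0.1), p = c(0.001, 0.0001, 0.9),
                         df = rep(20, 3),
                         direction = c("increase", "decrease", "increase")),
                    class = "group_stat")
  defs <- define_features(stat, "M1.L", node_labels, q = 0.05, k = 0)
  expect_length(defs, 2)
  expect_equal(vapply(defs, `[[`, "", "label"),
               c("n1 and M1.L", "n2 and M1.L"))
  expect_equal(vapply(defs, `[[`, "", "direction"),
               c("increase", "decrease"))
  # no significant nodes -> empty list; extraction then errors
  stat0 <- structure(list(t = c(1, 1, 1), p = rep(0.5, 3), df = rep(20, 3),
                          direction = rep("increase", 3)),
                     class = "group_stat")
  expect_length(define_features(stat0, "M1.L", node_labels), 0)
  expect_error(extract_feature_table(list(), list()), "empty feature")
  # single-node feature value equals that node's z
  map <- structure(list(subject_id = "s1", seed_label = "M1.L",
                        node_labels = node_labels, r = c(0.1, 0.2, 0.3),
                        z = atanh(c(0.1, 0.2, 0.3)), seed_nodes = integer()),
                   class = "rsfc_map")
  ft <- extract_feature_table(list(s1 = list(M1.L = map)), defs)
  expect_equal(unname(ft$values[1, ]), atanh(c(0.1, 0.2)))
  expect_equal(ft$feature_labels, c("n1 and M1.L", "n2 and M1.L"))
})

test_that("the stats pipeline recovers planted group differences", {
  # full generator path: insula edges decreased, parietal edges increased
  cfg <- sim_config(n_older = 40, n_younger = 40, rng_seed = 77)
  sim <- simulate_cohort(cfg)
  seeds <- default_seeds()
  kept <- sim$cohort
  maps <- lapply(kept$subject_id, function(id) {
    m <- lapply(seeds, function(sd) rsfc_map(sim$series[[id]], sd, id))
    names(m) <- vapply(seeds, `[[`, "", "label")
    m
  })
  names(maps) <- kept$subject_id
  grp <- kept$group
  hits <- 0; total <- 0
  for (sl in names(maps[[1]])) {
    z <- t(vapply(kept$subject_id, function(id) maps[[id]][[sl]]$z,
                  numeric(length(cfg$node_labels))))
    st <- two_sample_t(z[grp == "older", ], z[grp == "younger", ])
    mask <- fdr_bh(st$p, 0.05)
    for (tgt in c("Ins.L", "Ins.R")) {
      j <- match(tgt, cfg$node_labels); total <- total + 1
      if (mask[j] && st$direction[j] == "decrease") hits <- hits + 1
    }
    for (tgt in c("SPL.L", "SPL.R")) {
      j <- match(tgt, cfg$node_labels); total <- total + 1
      if (mask[j] && st$direction[j] == "increase") hits <- hits + 1
    }
    # null nodes stay quiet
    expect_lte(sum(mask[grepl("^Null", cfg$node_labels)]), 1)
  }
  expect_gte(hits / total, 0.95)
})
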