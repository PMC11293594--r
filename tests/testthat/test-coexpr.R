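as_expr <- function(vals) {
  structure(list(values = vals,
                 gene_meta = data.frame(id = rownames(vals), chrom = "1",
                                        tss = seq_len(nrow(vals)))),
            class = "expression_matrix")
}

test_that("preprocessing removes PCs and averages serial samples", {
  set.seed(80)
  G <- 20
  ind <- rep(c("a", "b", "c"), each = 2)
  smp <- data.frame(sample_id = paste0("s", 1:6), individual_id = ind)
  # duplicated samples within individuals: columns equal the shared value
  base <- matrix(rnorm(G * 3), G, 3)
  vals <- base[, rep(1:3, each = 2)]
  colnames(vals) <- smp$sample_id; rownames(vals) <- paste0("g", 1:G)
  out <- preprocess_expression(as_expr(vals), smp, n_pcs_remove = 0)
  expect_equal(unname(out), unname(base[, order(c("a", "b", "c"))]),
               tolerance = 1e-12)

  # rank-1 expression dies under removal of its single PC
  u <- rnorm(G); v <- rnorm(6)
  r1 <- u %o% v
  dimnames(r1) <- dimnames(vals)
  res <- preprocess_expression(as_expr(r1), smp, n_pcs_remove = 1)
  expect_lt(max(abs(res)), 1e-8)
  expect_error(preprocess_expression(as_expr(vals), smp, n_pcs_remove = 6),
               "n_pcs_remove")
})

test_that("biweight midcorrelation matches the direct formula and resists
           outliers", {
  bicor_direct <- function(x, y) {
    w_of <- function(v) {
      u <- (v - median(v)) / (9 * median(abs(v - median(v))))
      (v - median(v)) * (1 - u^2)^2 * (abs(u) < 1)
    }
    xt <- w_of(x); yt <- w_of(y)
    sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
  }
  x <- c(1.2, -0.4, 0.8, 2.1, -1.3)
  y <- c(0.9, -0.2, 1.4, 1.8, -0.7)
  M <- bicor_matrix(rbind(a = x, b = y, c = -x))
  expect_equal(M["a", "b"], bicor_direct(x, y), tolerance = 1e-12)
  expect_equal(M["a", "a"], 1)
  expect_equal(M["a", "c"], -1, tolerance = 1e-12)
  expect_true(isSymmetric(M, tol = 1e-12))

  # one gross outlier distorts Pearson far more than bicor
  set.seed(81)
  n <- 60
  f <- rnorm(n)
  x2 <- f + rnorm(n, 0, 0.4)
  y2 <- f + rnorm(n, 0, 0.4)
  clean <- cor(x2, y2)
  x2o <- x2; x2o[1] <- 30
  pears <- cor(x2o, y2)
  bic <- bicor_matrix(rbind(a = x2o, b = y2))["a", "b"]
  expect_lt(abs(bic - clean), abs(pears - clean))

  expect_error(bicor_matrix(rbind(a = rep(1, 5), b = rnorm(5))), "constant")
})

test_that("spatial quantile normalization equalizes block-pair distributions", {
  set.seed(82)
  G <- 210; n <- 120
  X <- make_block_data(bsize = 30, n_noise = G - 60, n = n, r = 0.5,
                       seed = 82)
  C <- bicor_matrix(X)
  mean_expr <- seq_len(G)  # deterministic ranking
  # inject a mean-correlation bias: shrink low-expression block correlations
  low <- 1:70
  Cb <- C
  Cb[low, low] <- C[low, low] * 0.5
  diag(Cb) <- 1
  Cn <- spqn_normalize(Cb, mean_expr, n_blocks = 7, ref_block = 6)

  expect_true(all(abs(Cn) <= 1 + 1e-12))
  expect_true(all(diag(Cn) == 1))
  expect_true(isSymmetric(Cn, tol = 1e-10))

  blk <- function(M, i, j) {
    idx <- split(seq_len(G), rep(1:7, each = 30))
    v <- M[idx[[i]], idx[[j]]]
    if (i == j) v[upper.tri(v)] else as.vector(v)
  }
  ref <- blk(Cn, 6, 6)
  ks <- suppressWarnings(ks.test(blk(Cn, 1, 1), ref))
  expect_gt(ks$p.value, 0.01)
  # rank order within a block pair is preserved
  expect_equal(order(blk(Cb, 1, 2)), order(blk(Cn, 1, 2)))

  # homogeneous input (noise, identical block-pair distributions) is
  # nearly unchanged
  Xh <- matrix(rnorm(G * n), G, n, dimnames = list(paste0("h", 1:G), NULL))
  Cu <- bicor_matrix(Xh)
  Ch <- spqn_normalize(Cu, seq_len(G), n_blocks = 7, ref_block = 4)
  expect_lt(max(abs(Ch - Cu)), 0.15)   # far-tail quantile interpolation
  expect_lt(mean(abs(Ch - Cu)), 0.01)
  expect_error(spqn_normalize(C, mean_expr, n_blocks = 7, ref_block = 9),
               "ref_block")
})

test_that("topological overlap matches brute-force evaluation", {
  # formula limits
  C2 <- diag(2) * 0 + 1
  net2 <- build_network(C2, power = 1)
  expect_equal(net2$tom[1, 2], 1)
  C0 <- diag(2)
  expect_equal(build_network(C0, power = 1)$tom[1, 2], 0)

  # 6-node toy vs direct summation
  set.seed(83)
  A <- matrix(runif(36, 0, 0.9), 6, 6)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  net <- build_network(A, power = 1)  # adjacency = |A|, diag zeroed
  Az <- abs(A); diag(Az) <- 0
  brute <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    l <- sum(vapply(setdiff(1:6, c(i, j)), function(u) Az[i, u] * Az[u, j],
                    numeric(1)))
    k_i <- sum(Az[i, -i]); k_j <- sum(Az[j, -j])
    brute[i, j] <- (l + Az[i, j]) / (min(k_i, k_j) + 1 - Az[i, j])
  }
  diag(brute) <- 1
  expect_equal(unname(net$tom), brute, tolerance = 1e-12)
  expect_true(all(net$tom >= 0 & net$tom <= 1))
})

test_that("automatic soft threshold targets a scale-free fit", {
  X <- make_block_data(bsize = 40, n_noise = 120, n = 150, r = 0.7,
                       seed = 84)
  C <- bicor_matrix(X)
  net <- suppressWarnings(build_network(C, power = "auto", rsq_target = 0.8))
  expect_true(net$power >= 1 && net$power <= 20)
  expect_equal(nrow(net$fit_table), 20)
})

test_that("planted modules are recovered and noise stays unassigned", {
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  X <- make_block_data(bsize = 50, n_noise = 100, n = 150, r = 0.8,
                       seed = 85)
  ms <- detect_modules(build_network(bicor_matrix(X), power = 4)$tom, X)
  lab <- ms$labels
  expect_equal(length(unique(lab[lab > 0])), 2L)
  t1 <- paste0("g", 1:50); t2 <- paste0("g", 51:100)
  j1 <- max(vapply(unique(lab[lab > 0]), function(m)
    jacc(names(lab)[lab == m], t1), numeric(1)))
  j2 <- max(vapply(unique(lab[lab > 0]), function(m)
    jacc(names(lab)[lab == m], t2), numeric(1)))
  expect_gte(j1, 0.9); expect_gte(j2, 0.9)
  # sizes respect the floor; labels ordered by decreasing size
  expect_true(all(table(lab[lab > 0]) >= 10))

  for (s in 1:3) {
    Xn <- matrix(rnorm(200 * 150), 200, 150,
                 dimnames = list(paste0("g", 1:200), NULL))
    msn <- detect_modules(build_network(bicor_matrix(Xn), power = 4)$tom, Xn)
    expect_gte(mean(msn$labels == 0), 0.95)
  }
})

test_that("modules with identical eigengenes are merged", {
  # two 20-gene groups driven by the same factor
  set.seed(86)
  n <- 120
  f <- rnorm(n)
  X <- rbind(
    t(vapply(1:20, function(i) 0.9 * f + 0.3 * rnorm(n), numeric(n))),
    t(vapply(1:20, function(i) 0.9 * f + 0.3 * rnorm(n), numeric(n))),
    matrix(rnorm(60 * n), 60, n))
  rownames(X) <- paste0("g", seq_len(nrow(X)))
  ms <- detect_modules(build_network(bicor_matrix(X), power = 4)$tom, X)
  lab <- ms$labels[paste0("g", 1:40)]
  expect_equal(length(unique(lab[lab > 0])), 1L)
})

test_that("eigengenes are first-PC scores with aligned sign", {
  set.seed(87)
  n <- 50
  f <- rnorm(n)
  X <- t(vapply(1:5, function(i) 2 * f + 0.01 * rnorm(n), numeric(n)))
  rownames(X) <- paste0("g", 1:5)
  labels <- setNames(rep(1L, 5), rownames(X))
  eg <- module_eigengenes(X, labels)
  # identical genes: eigengene is the standardized profile, full variance
  expect_gt(eg$var_explained[["M1"]], 0.99)
  expect_gt(cor(eg$eigengenes["M1", ], f), 0.999)
  expect_equal(sum(eg$eigengenes["M1", ]^2), 1)    # unit-norm scores
  # flipping all member genes flips the mean profile, hence the aligned
  # eigengene: sign equivariance, identical up to orientation
  eg2 <- module_eigengenes(-X, labels)
  expect_equal(abs(cor(eg2$eigengenes["M1", ], eg$eigengenes["M1", ])), 1,
               tolerance = 1e-10)
  expect_gte(cor(eg2$eigengenes["M1", ], colMeans(t(scale(t(-X))))), 0)
  # direct SVD oracle on a 3-gene module
  X3 <- matrix(rnorm(3 * 20), 3, 20, dimnames = list(paste0("g", 1:3), NULL))
  sv <- svd(t(scale(t(X3))))
  eg3 <- module_eigengenes(X3, setNames(rep(1L, 3), rownames(X3)))
  expect_equal(abs(eg3$eigengenes["M1", ]), abs(sv$v[, 1]), tolerance = 1e-10)
})

test_that("module associations pick up planted phenotype, survival and
           marker signals", {
  set.seed(88)
  n_ind <- 200
  ind <- rep(sprintf("i%03d", 1:n_ind), each = 2)
  S <- length(ind)
  srs <- rbinom(S, 1, 0.4)
  eig <- matrix(rnorm(2 * S), 2, S, dimnames = list(c("M1", "M2"), NULL))
  eig[1, ] <- eig[1, ] * 0.1 + ifelse(srs == 1, 1, -1)
  # exponential survival tied to M2 at the last time point
  last <- seq(2, S, by = 2)
  lp <- eig[2, last] * 1.0
  t_raw <- rexp(n_ind, rate = 0.02 * exp(lp))
  smp <- data.frame(sample_id = paste0("s", 1:S), individual_id = ind,
                    time_point = rep(c(1, 3), n_ind), srs1 = srs,
                    diagnosis = sample(c("CAP", "FP"), S, TRUE),
                    surv_time = pmin(t_raw, 28)[rep(1:n_ind, each = 2)],
                    surv_event = as.integer(t_raw <= 28)[rep(1:n_ind,
                                                             each = 2)])
  labels <- setNames(c(rep(1L, 12), rep(2L, 12), rep(0L, 26)),
                     paste0("g", 1:50))
  markers <- list(hit = paste0("g", 1:12), other = paste0("g", 40:50))
  res <- module_associations(eig, smp, labels = labels,
                             marker_sets = markers)
  ph <- res$phenotype
  srs_row <- ph[ph$module == "M1" & ph$phenotype == "srs1", ]
  expect_gt(srs_row$effect, 1.5)
  expect_lt(srs_row$p, 1e-10)
  # Cox log-hazard recovered within a simulation band of +/- 0.3
  expect_true(!is.null(res$survival))
  expect_lt(abs(res$survival$loghr[res$survival$module == "M2"] - 1), 0.3)
  # the marker set equal to the module membership is the top enrichment
  mk <- res$markers[res$markers$module == "M1", ]
  expect_equal(mk$set[which.min(mk$p)], "hit")
  expect_lt(min(mk$q), 0.05)
})
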