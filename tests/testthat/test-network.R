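test_that("pair_count is the binomial pair formula", {
  expect_equal(pair_count(2), 1)
  expect_equal(pair_count(5), 10)
  expect_equal(pair_count(0), 0)
  expect_error(pair_count(-1), "non-negative")
  expect_error(pair_count(2.5), "integer")
})

test_that("fit_edge reproduces exact affine relations in both orientations", {
  x <- c(1, 2, 3, 4, 5)
  ident <- fit_edge(x, x, "a", "b")
  expect_equal(ident$r, 1)
  expect_equal(ident$b1_ab, 1)
  expect_equal(ident$b0_ab, 0)
  expect_equal(ident$b1_ba, 1)

  aff <- fit_edge(x, 2 * x + 3, "a", "b")
  expect_equal(aff$r, 1)
  expect_equal(aff$b1_ba, 2)    # predict b from a
  expect_equal(aff$b0_ba, 3)
  expect_equal(aff$b1_ab, 0.5)  # predict a from b
  expect_equal(aff$b0_ab, -1.5)
})

test_that("fit_edge matches the closed-form normal-equation oracle", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(5); y <- rnorm(5) + 0.5 * x
    e <- fit_edge(x, y)
    # oracle: beta = (X'X)^-1 X'y with X = [1, x]
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(e$b0_ba, beta[1L], tolerance = 1e-10)
    expect_equal(e$b1_ba, beta[2L], tolerance = 1e-10)
    Xy <- cbind(1, y)
    beta2 <- solve(t(Xy) %*% Xy, t(Xy) %*% x)
    expect_equal(e$b0_ab, beta2[1L], tolerance = 1e-10)
    expect_equal(e$b1_ab, beta2[2L], tolerance = 1e-10)
    expect_equal(e$r, sum(scale(x) * scale(y)) / 4, tolerance = 1e-10)
  }
  expect_error(fit_edge(c(1, 1, 1), c(1, 2, 3), "gz", "gy"), "gz")
  expect_error(fit_edge(1:2, 1:2), "length")
})

test_that("corr_pvalue_bonferroni matches the incomplete-beta tail oracle", {
  expect_equal(corr_pvalue_bonferroni(0, 10, 1), 1)
  expect_equal(corr_pvalue_bonferroni(1, 10, 5), 0)
  # oracle: two-sided p = I_{1-r^2}((n-2)/2, 1/2)
  for (r in c(0.3, 0.6, 0.9)) for (n in c(10, 50)) {
    expect_equal(corr_pvalue_bonferroni(r, n, 1),
                 pbeta(1 - r^2, (n - 2) / 2, 0.5), tolerance = 1e-12)
  }
  expect_equal(corr_pvalue_bonferroni(0.8, 20, 4),
               4 * corr_pvalue_bonferroni(0.8, 20, 1), tolerance = 1e-12)
  expect_equal(corr_pvalue_bonferroni(0.1, 5, 1e9), 1)  # capped
  expect_error(corr_pvalue_bonferroni(1.2, 10), "r")
  expect_error(corr_pvalue_bonferroni(0.5, 2), "n")
})

test_that("corr_pvalue_bonferroni is monotone in |r|, n and m", {
  rs <- seq(0.1, 0.9, by = 0.2)
  ps <- vapply(rs, corr_pvalue_bonferroni, numeric(1), n = 30, m = 1)
  expect_true(all(diff(ps) < 0))
  ns <- c(10, 30, 100, 300)
  pn <- vapply(ns, function(n) corr_pvalue_bonferroni(0.5, n, 1), numeric(1))
  expect_true(all(diff(pn) < 0))
  # increasing in m before the cap at 1
  pm <- vapply(c(1, 10, 100), function(m) corr_pvalue_bonferroni(0.8, 30, m),
               numeric(1))
  expect_true(all(diff(pm) > 0))
})

test_that("build_network retains exactly the above-threshold pairs", {
  # 3 genes, one exactly affine pair, third near-independent
  set.seed(4)
  n <- 50
  g1 <- rnorm(n, 8)
  vals <- rbind(g1 = g1, g2 = 2 * g1 - 3, g3 = rnorm(n, 8))
  colnames(vals) <- sprintf("s%02d", 1:n)
  net <- build_network(expression_matrix(vals), 0.75)
  expect_equal(nrow(net$edges), 1L)
  expect_identical(c(net$edges$gene_a, net$edges$gene_b), c("g1", "g2"))
  expect_identical(net$isolated, "g3")

  # 4 exact affine transforms of one latent -> complete graph K4
  lat <- rnorm(n)
  vals4 <- rbind(a = lat, b = 2 * lat + 1, c = -lat + 4, d = 0.5 * lat)
  colnames(vals4) <- sprintf("s%02d", 1:n)
  net4 <- build_network(expression_matrix(vals4), 0.75)
  expect_equal(nrow(net4$edges), 6L)

  small <- expression_matrix(vals[, 1:2])
  expect_error(build_network(small), "3 samples")
})

test_that("build_network equals the dense correlation-matrix oracle", {
  sim <- simulate_transcriptomes(c(6, 6, 6), n_samples = 80,
                                 target_r = 0.85, seed = 21)
  net <- build_network(sim$matrix, 0.75)
  cc <- cor(t(unclass(sim$matrix)))
  idx <- which(abs(cc) > 0.75 & upper.tri(cc), arr.ind = TRUE)
  oracle <- sort(paste(rownames(cc)[idx[, 1L]], rownames(cc)[idx[, 2L]]))
  got <- sort(paste(net$edges$gene_a, net$edges$gene_b))
  expect_identical(got, oracle)
  # edge r values equal the dense matrix entries
  expect_equal(net$edges$r,
               cc[cbind(net$edges$gene_a, net$edges$gene_b)],
               tolerance = 1e-12)
})

test_that("blockwise correlation is independent of block size", {
  sim <- simulate_transcriptomes(c(7, 6), n_samples = 40, target_r = 0.8,
                                 seed = 13)
  full <- build_network(sim$matrix, 0.75)
  for (bs in c(3, 5, 20)) {
    blk <- build_network(sim$matrix, 0.75, block_size = bs)
    expect_identical(blk$edges[, c("gene_a", "gene_b")],
                     full$edges[, c("gene_a", "gene_b")])
    expect_equal(blk$edges$r, full$edges$r, tolerance = 1e-12)
  }
})

test_that("zero-variance genes are dropped with a warning, not an error", {
  set.seed(2)
  vals <- rbind(a = rnorm(20), b = rnorm(20), flat = rep(5, 20))
  vals["b", ] <- vals["a", ] * 1.5 + rnorm(20, sd = 0.05)
  colnames(vals) <- sprintf("s%02d", 1:20)
  expect_warning(net <- build_network(expression_matrix(vals), 0.75), "flat")
  expect_identical(net$dropped, "flat")
  expect_false("flat" %in% network_nodes(net))
})

test_that("every fitted edge satisfies the least-squares identity", {
  sim <- simulate_transcriptomes(c(8, 8), n_samples = 60, target_r = 0.85,
                                 seed = 31)
  net <- build_network(sim$matrix, 0.75)
  expect_gt(nrow(net$edges), 10)
  with(net$edges, {
    expect_equal(b1_ab * b1_ba, r^2, tolerance = 1e-9)
    expect_true(all(sign(b1_ab) == sign(r)))
    expect_true(all(abs(r) > 0.75))
    expect_true(all(n >= 3))
  })
})

test_that("raising the threshold is a monotone filtration", {
  sim <- simulate_transcriptomes(c(10), n_samples = 40, target_r = 0.8,
                                 seed = 17)
  keys <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  nets <- lapply(c(0.5, 0.75, 0.9), function(th)
    build_network(sim$matrix, th))
  expect_true(all(keys(nets[[2]]) %in% keys(nets[[1]])))
  expect_true(all(keys(nets[[3]]) %in% keys(nets[[2]])))
})

test_that("edge lookup is orientation-independent and degree counts edges", {
  net <- toy_network(rbind(c("h", "l1"), c("h", "l2"), c("h", "l3"),
                           c("h", "l4"), c("h", "l5")))
  expect_equal(gene_degree(net, "h"), 5L)
  expect_equal(gene_degree(net, "l1"), 1L)
  expect_error(gene_degree(net, "nope"), "nope")
  e1 <- edge_model(net, "h", "l3")
  e2 <- edge_model(net, "l3", "h")
  expect_identical(e1, e2)
  expect_null(edge_model(net, "l1", "l2"))

  # random graph: degree equals adjacency-list count oracle
  rnet <- random_toy_network(12, 0.3, seed = 8)
  adj <- adjacency_of(rnet)
  for (g in network_nodes(rnet))
    expect_equal(gene_degree(rnet, g), length(adj[[g]]))
})

test_that("GraphML and JSON-lines serializations round-trip", {
  sim <- simulate_transcriptomes(c(5, 5), n_samples = 30, target_r = 0.9,
                                 seed = 19)
  net <- build_network(sim$matrix, 0.75)
  cols <- c("r", "n", "b1_ab", "b0_ab", "b1_ba", "b0_ba")

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  back <- read_network_graphml(gml)
  expect_identical(back$edges[, c("gene_a", "gene_b")],
                   net$edges[, c("gene_a", "gene_b")])
  for (cl in cols) expect_equal(back$edges[[cl]], net$edges[[cl]],
                                tolerance = 1e-12)
  expect_equal(back$threshold, net$threshold)

  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_network_jsonl(net, jl)
  back2 <- read_network_jsonl(jl)
  expect_identical(back2$edges[, c("gene_a", "gene_b")],
                   net$edges[, c("gene_a", "gene_b")])
  for (cl in cols) expect_equal(back2$edges[[cl]], net$edges[[cl]],
                                tolerance = 1e-12)
})
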