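# --- gene-set median ranking ------------------------------------------------

test_that("a set of identical rows behaves like that single gene", {
  toy <- make_toy_expr(10, 5, 5, seed = 21)
  toy$expr[2L, ] <- toy$expr[1L, ]
  toy$expr[3L, ] <- toy$expr[1L, ]
  sets <- list(structure(list(set_id = "S", members = c("g001", "g002", "g003")),
                         class = "gene_set"))
  prof <- set_median_features(toy$expr, sets)
  expect_equal(unname(prof["S", ]), unname(toy$expr[1L, ]))
  rk <- median_set_scores(toy$expr, toy$labels, sets)
  expect_identical(rk$feature_ids, "S")
})

test_that("per-sample median uses the middle value / midpoint convention", {
  expr <- matrix(c(1, 2, 9, 1, 2, 9), nrow = 3,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  sets <- list(structure(list(set_id = "S", members = c("a", "b", "c")),
                         class = "gene_set"))
  expect_equal(unname(set_median_features(expr, sets)["S", ]), c(2, 2))
  expr4 <- rbind(expr, d = c(4, 4))
  sets4 <- list(structure(list(set_id = "S", members = letters[1:4]),
                          class = "gene_set"))
  expect_equal(unname(set_median_features(expr4, sets4)["S", "s1"]), 3) # (2+4)/2
})

test_that("a planted shifted set ranks first among null sets", {
  set.seed(22)
  n_sets <- 50
  toy <- make_toy_expr(n_sets * 3, 10, 10, seed = 22)
  sets <- lapply(seq_len(n_sets), function(i) {
    structure(list(set_id = sprintf("set%02d", i),
                   members = rownames(toy$expr)[(3 * i - 2):(3 * i)]),
              class = "gene_set")
  })
  toy$expr[1:3, toy$labels == "PP"] <- toy$expr[1:3, toy$labels == "PP"] + 2
  rk <- median_set_scores(toy$expr, toy$labels, sets)
  expect_identical(rk$feature_ids[1L], "set01")
  # brute force: smallest p over per-set median profiles
  profs <- set_median_features(toy$expr, sets)
  ps <- vapply(seq_len(n_sets), function(i) {
    oracle_moderated_t(profs, toy$labels)$table$p_value[
      oracle_moderated_t(profs, toy$labels)$table$feature_id == sprintf("set%02d", i)]
  }, numeric(1L))
  expect_identical(sprintf("set%02d", which.min(ps)), "set01")
})

test_that("sets with no measured member are dropped with a warning", {
  toy <- make_toy_expr(4, 5, 5, seed = 23)
  sets <- list(structure(list(set_id = "ok", members = c("g001", "g002")),
                         class = "gene_set"),
               structure(list(set_id = "gone", members = c("zz1", "zz2")),
                         class = "gene_set"))
  expect_warning(rk <- median_set_scores(toy$expr, toy$labels, sets), "gone")
  expect_identical(rk$feature_ids, "ok")
})

# --- netrank ----------------------------------------------------------------

test_that("a = 0 ranks by absolute survival correlation alone", {
  toy <- make_toy_expr(30, 6, 6, seed = 24)
  surv <- c(runif(6, 4, 10), runif(6, 0.1, 1))
  net <- suppressWarnings(ppi_network(cbind(rownames(toy$expr)[1:10],
                                            rownames(toy$expr)[11:20])))
  rk <- netrank(toy$expr, surv, net, a = 0)
  cvec <- abs(apply(toy$expr, 1L, cor, surv))
  in_net <- rownames(toy$expr) %in% net$nodes
  exp_net <- names(sort(-cvec[in_net]))
  expect_identical(rk$feature_ids[seq_along(exp_net)], exp_net)
  exp_out <- names(sort(-cvec[!in_net]))
  expect_identical(rk$feature_ids[-seq_along(exp_net)], exp_out)
})

test_that("identical expression profiles on a regular graph get equal ranks", {
  base <- rnorm(8)
  expr <- matrix(rep(base, each = 4), nrow = 4,
                 dimnames = list(c("a", "b", "c", "d"), sprintf("s%d", 1:8)))
  ring <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
  rk <- netrank(expr, seq_len(8), ring, a = 0.5)
  expect_equal(diff(range(rk$scores)), 0, tolerance = 1e-12)
})

test_that("the iterative fixed point matches the dense linear solve", {
  toy <- make_toy_expr(12, 8, 7, seed = 25)
  surv <- c(runif(8, 4, 10), runif(7, 0.1, 1))
  net <- ppi_network(rbind(c("g001", "g002"), c("g002", "g003"),
                           c("g003", "g004"), c("g004", "g007"),
                           c("g002", "g007")))
  for (a in c(0, 0.3, 0.85)) {
    rk <- netrank(toy$expr, surv, net, a = a, tol = 1e-14, max_iter = 5000)
    ora <- oracle_netrank_solve(toy$expr, surv, net, a)
    got <- rk$table[rk$table$in_network, ]
    expect_equal(got$score, unname(ora[got$feature_id]), tolerance = 1e-8)
  }
})

test_that("netrank validates a, warns on non-convergence, and scores are non-negative", {
  toy <- make_toy_expr(6, 4, 4, seed = 26)
  surv <- runif(8)
  net <- ppi_network(rbind(c("g001", "g002"), c("g002", "g003")))
  expect_error(netrank(toy$expr, surv, net, a = 1), "\\[0, 1\\)")
  expect_error(netrank(toy$expr, surv, net, a = -0.1), "\\[0, 1\\)")
  expect_warning(netrank(toy$expr, surv, net, a = 0.9, tol = 1e-16, max_iter = 2L),
                 "converge")
  rk <- netrank(toy$expr, surv, net, a = 0.3)
  expect_true(all(rk$scores >= 0))
})

test_that("netrank converges geometrically (L1 ratio <= a)", {
  toy <- make_toy_expr(10, 5, 5, seed = 27)
  surv <- runif(10)
  edges <- t(combn(rownames(toy$expr)[1:6], 2))
  net <- ppi_network(edges)
  a <- 0.6
  rk1 <- netrank(toy$expr, surv, net, a = a, tol = 1e-15, max_iter = 10000)
  expect_lte(rk1$iterations, ceiling(log(1e-15) / log(a)) + 5)
})

# --- edge correlations / taylor / bss-wss -----------------------------------

test_that("edge correlations recover exact and sampled relationships", {
  set.seed(28)
  n <- 60
  h <- rnorm(n)
  expr <- rbind(H = h, A = h, B = c(h[1:30], -h[31:60]))
  colnames(expr) <- sprintf("s%02d", 1:n)
  labels <- rep(c("GP", "PP"), each = 30)
  sn <- hub_subnetworks(make_star("H", c("A", "B")), "H")[[1L]]
  ec <- edge_correlations(expr, labels, sn)
  expect_equal(ec$r_gp[ec$interactor == "A"], 1, tolerance = 1e-12)
  expect_equal(ec$r_pp[ec$interactor == "A"], 1, tolerance = 1e-12)
  expect_equal(ec$r_gp[ec$interactor == "B"], 1, tolerance = 1e-12)
  expect_equal(ec$r_pp[ec$interactor == "B"], -1, tolerance = 1e-12)
})

test_that("sampled correlation is close to the generating rho", {
  set.seed(29)
  n <- 30
  h <- rnorm(2 * n)
  i1 <- 0.8 * h + sqrt(1 - 0.64) * rnorm(2 * n)
  expr <- rbind(H = h, A = i1)
  colnames(expr) <- sprintf("s%02d", seq_len(2 * n))
  labels <- rep(c("GP", "PP"), each = n)
  ec <- edge_correlations(expr, labels, hub_subnetworks(make_star("H", "A"), "H")[[1L]])
  expect_lt(abs(ec$r_gp - 0.8), 0.15)
  expect_lt(abs(ec$r_pp - 0.8), 0.15)
})

test_that("edge_correlations enforces 3 samples per class and zero-variance policy", {
  toy <- make_toy_expr(3, 2, 5, seed = 30)
  sn <- hub_subnetworks(make_star("g001", "g002"), "g001")[[1L]]
  expect_error(edge_correlations(toy$expr, toy$labels, sn), "3 samples")
  toy2 <- make_toy_expr(3, 4, 4, seed = 31)
  toy2$expr["g002", ] <- 5    # constant interactor
  sn2 <- hub_subnetworks(make_star("g001", "g002"), "g001")[[1L]]
  expect_warning(ec <- edge_correlations(toy2$expr, toy2$labels, sn2), "undefined")
  expect_identical(ec$r_gp, 0)
})

test_that("taylor score hits its bounds and ranks a planted flip first", {
  # perfect flip: every edge r_GP = 1, r_PP = -1 -> score 2
  n <- 20
  h <- rnorm(2 * n)
  expr <- rbind(H = h, A = c(h[1:n], -h[(n + 1):(2 * n)]),
                B = c(h[1:n], -h[(n + 1):(2 * n)]))
  colnames(expr) <- sprintf("s%02d", seq_len(2 * n))
  labels <- rep(c("GP", "PP"), each = n)
  sn <- hub_subnetworks(make_star("H", c("A", "B")), "H")
  rk <- taylor_score(expr, labels, sn)
  expect_equal(rk$scores, 2, tolerance = 1e-12)

  # null hubs score near 0, planted flip ranks first among 21 hubs
  set.seed(32)
  nets <- lapply(1:21, function(i) make_star(sprintf("h%02d", i),
                                             sprintf("h%02d_i%d", i, 1:4)))
  genes <- unique(unlist(lapply(nets, function(n) n$nodes)))
  expr2 <- matrix(rnorm(length(genes) * 40), nrow = length(genes),
                  dimnames = list(genes, sprintf("s%02d", 1:40)))
  labels2 <- rep(c("GP", "PP"), each = 20)
  hub1 <- "h01"
  for (ii in sprintf("h01_i%d", 1:4)) {
    expr2[ii, 1:20] <- 0.9 * expr2[hub1, 1:20] + sqrt(1 - 0.81) * rnorm(20)
    expr2[ii, 21:40] <- -0.9 * expr2[hub1, 21:40] + sqrt(1 - 0.81) * rnorm(20)
  }
  net_all <- ppi_network(do.call(rbind, lapply(nets, `[[`, "edges")))
  sns <- hub_subnetworks(net_all, sprintf("h%02d", 1:21))
  rk2 <- taylor_score(expr2, labels2, sns)
  expect_identical(rk2$feature_ids[1L], "h01")
  expect_true(all(rk2$scores >= 0 & rk2$scores <= 2))
  # brute force over hubs agrees on the winner
  brute <- vapply(sns, function(s) {
    ec <- edge_correlations(expr2, labels2, s)
    mean(abs(ec$r_gp - ec$r_pp))
  }, numeric(1L))
  expect_identical(sprintf("h%02d", which.max(brute)), "h01")
})

test_that("identical class distributions give near-zero taylor scores", {
  set.seed(33)
  toy <- make_toy_expr(12, 25, 25, seed = 33)
  net <- make_star("g001", sprintf("g%03d", 2:7))
  rk <- taylor_score(toy$expr, toy$labels, hub_subnetworks(net, "g001"))
  expect_lt(rk$scores, 0.6)   # pure sampling noise at n = 25/class
})

test_that("bss/wss matches hand arithmetic on exact correlations", {
  # construct data whose within-class edge correlations are exactly
  # (0.9, 0.7) in GP and (-0.8, -0.6) in PP
  n <- 25
  set.seed(34)
  h <- rnorm(2 * n)
  mk <- function(cols, rho, seed) {
    v <- numeric(2 * n); v[cols] <- make_cor_pair(h[cols], rho, seed); v
  }
  gp <- 1:n; pp <- (n + 1):(2 * n)
  A <- mk(gp, 0.9, 1) + mk(pp, -0.8, 2)
  B <- mk(gp, 0.7, 3) + mk(pp, -0.6, 4)
  expr <- rbind(H = h, A = A, B = B)
  colnames(expr) <- sprintf("s%02d", seq_len(2 * n))
  labels <- rep(c("GP", "PP"), each = n)
  sn <- hub_subnetworks(make_star("H", c("A", "B")), "H")
  ec <- edge_correlations(expr, labels, sn[[1L]])
  expect_equal(sort(ec$r_gp), c(0.7, 0.9), tolerance = 1e-10)
  expect_equal(sort(ec$r_pp), c(-0.8, -0.6), tolerance = 1e-10)
  rk <- bss_wss_score(expr, labels, sn)
  expect_equal(rk$scores, 2.25 / (0.04 + 1e-9), tolerance = 1e-6)
})

test_that("bss/wss is zero for equal class correlations and symmetric in labels", {
  n <- 20
  h <- rnorm(2 * n)
  expr <- rbind(H = h, A = h, B = -h)   # r identical in both classes
  colnames(expr) <- sprintf("s%02d", seq_len(2 * n))
  labels <- rep(c("GP", "PP"), each = n)
  sn <- hub_subnetworks(make_star("H", c("A", "B")), "H")
  expect_equal(bss_wss_score(expr, labels, sn)$scores, 0, tolerance = 1e-9)

  toy <- make_toy_expr(8, 10, 10, seed = 35)
  net <- make_star("g001", sprintf("g%03d", 2:6))
  sns <- hub_subnetworks(net, "g001")
  s1 <- bss_wss_score(toy$expr, toy$labels, sns)
  flipped <- factor(ifelse(toy$labels == "GP", "PP", "GP"), levels = c("GP", "PP"))
  s2 <- bss_wss_score(toy$expr, flipped, sns)
  expect_equal(s1$scores, s2$scores, tolerance = 1e-12)
})

test_that("hubs with fewer than 2 measured edges are dropped by bss/wss", {
  toy <- make_toy_expr(6, 5, 5, seed = 36)
  sns <- list(hub_subnetworks(make_star("g001", "g002"), "g001")[[1L]],
              hub_subnetworks(make_star("g003", c("g004", "g005")), "g003")[[1L]])
  expect_warning(rk <- bss_wss_score(toy$expr, toy$labels, sns), "fewer than 2")
  expect_identical(rk$feature_ids, "g003")
})

# --- select_top -------------------------------------------------------------

test_that("select_top truncates, warns on short lists, preserves order", {
  toy <- make_toy_expr(100, 5, 5, seed = 37)
  rk <- moderated_t(toy$expr, toy$labels)
  expect_identical(length(select_top(rk, 50L)), 50L)
  expect_identical(select_top(rk, 1L)$feature_ids, rk$feature_ids[1L])
  short <- select_top(rk, 30L)
  expect_warning(res <- select_top(short, 50L), "only 30")
  expect_identical(length(res), 30L)
  expect_identical(res$feature_ids, rk$feature_ids[1:30])
})
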