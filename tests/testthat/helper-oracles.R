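# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (per-gene loops, root-finding instead of Newton,
# dense linear algebra) so they share no code path with the package.

# --- moderated t oracle -----------------------------------------------------

# Trigamma inverse by bisection/uniroot (the package uses Newton).
oracle_trigamma_inverse <- function(y) {
  stats::uniroot(function(x) trigamma(x) - y, lower = 1e-6, upper = 1e8,
                 tol = 1e-14, maxiter = 2000L)$root
}

# Full per-gene recomputation of the empirical-Bayes moderated t: pooled
# variances by explicit sums, hyperparameters by moment matching on log s^2,
# ordering by p then id.
oracle_moderated_t <- function(expr, labels, d0 = NULL, s0_sq = NULL) {
  labels <- factor(toupper(as.character(labels)), levels = c("GP", "PP"))
  idx1 <- which(labels == "GP"); idx2 <- which(labels == "PP")
  n1 <- length(idx1); n2 <- length(idx2)
  dgf <- n1 + n2 - 2
  G <- nrow(expr)
  s2 <- diffs <- numeric(G)
  for (g in seq_len(G)) {
    x1 <- expr[g, idx1]; x2 <- expr[g, idx2]
    diffs[g] <- mean(x2) - mean(x1)
    s2[g] <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / dgf
  }
  if (is.null(d0)) {
    ok <- s2 > 0
    e <- log(s2[ok]) - digamma(dgf / 2) + log(dgf / 2)
    m <- length(e)
    ev <- mean((e - mean(e))^2 * m / (m - 1) - trigamma(dgf / 2))
    if (ev > 0) {
      d0 <- 2 * oracle_trigamma_inverse(ev)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(mean(e))
    }
  }
  s2_mod <- if (is.finite(d0)) (d0 * s0_sq + dgf * s2) / (d0 + dgf)
            else rep(s0_sq, G)
  tt <- diffs / sqrt(s2_mod * (1 / n1 + 1 / n2))
  pv <- 2 * stats::pt(-abs(tt), df = d0 + dgf)
  ids <- rownames(expr)
  ord <- order(pv, ids, method = "radix")
  list(d0 = d0, s0_sq = s0_sq,
       table = data.frame(feature_id = ids[ord], statistic = tt[ord],
                          p_value = pv[ord], stringsAsFactors = FALSE))
}

# --- netrank oracle ---------------------------------------------------------

# Dense direct solve of the fixed point (I - a M') r = (1 - a) c, with c the
# normalised absolute survival correlations, recomputed independently.
oracle_netrank_solve <- function(expr, survival, net, a) {
  nodes <- net$nodes
  cvec <- vapply(rownames(expr), function(g) {
    r <- suppressWarnings(stats::cor(expr[g, ], survival))
    if (!is.finite(r)) 0 else abs(r)
  }, numeric(1L))
  cvec <- cvec / sum(cvec)
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(net$edges))) {
    W[net$edges[i, 1L], net$edges[i, 2L]] <- 1
    W[net$edges[i, 2L], net$edges[i, 1L]] <- 1
  }
  deg <- rowSums(W)
  M <- W / ifelse(deg > 0, deg, 1)
  M[deg == 0, ] <- 0
  r <- solve(diag(length(nodes)) - a * t(M), (1 - a) * cvec[nodes])
  stats::setNames(as.vector(r), nodes)
}

# --- data builders ----------------------------------------------------------

# Small labelled expression matrix with iid Gaussian noise.
make_toy_expr <- function(n_genes, n_gp, n_pp, sd = 1, seed = 1) {
  set.seed(seed)
  n <- n_gp + n_pp
  expr <- matrix(rnorm(n_genes * n, sd = sd), nrow = n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("s%03d", seq_len(n))))
  labels <- factor(rep(c("GP", "PP"), c(n_gp, n_pp)), levels = c("GP", "PP"))
  list(expr = expr, labels = labels)
}

# A vector whose sample Pearson correlation with h is exactly rho: mix h with
# a vector orthogonalised against it.
make_cor_pair <- function(h, rho, seed = 1) {
  set.seed(seed)
  z <- rnorm(length(h))
  z <- residuals(lm(z ~ h))              # exactly orthogonal to h in sample
  z <- z / sd(z)
  hs <- (h - mean(h)) / sd(h)
  rho * hs + sqrt(1 - rho^2) * z
}

# Star network: hub 'H' with the given interactors.
make_star <- function(hub, interactors) {
  ppi_network(cbind(rep(hub, length(interactors)), interactors))
}
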