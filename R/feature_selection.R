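# The gene-set and network-based feature selection methods. All methods are
# deterministic and must be run on training samples only inside
# cross-validation (the CV engine enforces this).

#' Rank gene-sets by moderated t on their median expression
#'
#' Each gene-set is summarised per sample by the median expression of its
#' measured members, giving a set x sample matrix to which the moderated t
#' ranking ([moderated_t()]) is applied. Sets with no measured member are
#' dropped with a warning.
#'
#' @param expr Numeric genes x samples matrix.
#' @param labels GP/PP labels per sample.
#' @param genesets List of `gene_set` objects (see
#'   [subnetworks_to_genesets()]).
#' @return A `ranked_features` object (`method = "median_set"`) over set
#'   identifiers (hub genes).
#' @export
median_set_scores <- function(expr, labels, genesets) {
  if (length(genesets) == 0L) abort("no gene-sets supplied")
  prof <- set_median_features(expr, genesets, allow_drop = TRUE)
  out <- moderated_t(prof, labels)
  out$method <- "median_set"
  out
}

#' NetRank: network-damped survival-correlation gene ranking
#'
#' A PageRank-style iteration in which a gene's score mixes the absolute
#' Pearson correlation of its expression profile with survival time (the
#' "prior" c, normalised to sum 1) and the scores of its network neighbours:
#' \code{r = (1 - a) c + a t(M) r}, with `M` the degree-row-normalised
#' adjacency matrix (degree-0 rows are zero, so dangling genes distribute
#' nothing and their score stays driven by c). Iteration starts at \code{r = c}
#' and is an L1 contraction with factor `a`, so it converges geometrically
#' for `a < 1`. Genes measured on the platform but absent from the network
#' are appended after all network genes, ordered by c descending.
#'
#' @param expr Numeric genes x samples matrix (training samples).
#' @param survival Numeric survival times, one per column of `expr`.
#' @param net A [ppi_network()] whose nodes all appear in `expr`.
#' @param a Damping factor in `[0, 1)`; 0 ranks by correlation alone.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; non-convergence returns the current
#'   iterate with a warning.
#' @return A `ranked_features` object (`method = "netrank"`); its `table`
#'   has columns `feature_id`, `score`, `surv_cor`, `in_network`.
#' @export
netrank <- function(expr, survival, net, a = 0.3, tol = 1e-10,
                    max_iter = 1000L) {
  if (length(a) != 1L || !is.finite(a) || a < 0 || a >= 1) {
    abort("netrank damping 'a' must be in [0, 1)")
  }
  if (length(survival) != ncol(expr)) abort("survival must match samples")
  if (any(!is.finite(survival))) abort("survival times must be finite")
  missing_nodes <- setdiff(net$nodes, rownames(expr))
  if (length(missing_nodes) > 0L) {
    abort("network node(s) missing from expression: ",
          paste(utils::head(missing_nodes, 5L), collapse = ", "))
  }
  genes <- rownames(expr)
  cvec <- suppressWarnings(as.vector(stats::cor(t(expr), survival)))
  cvec[!is.finite(cvec)] <- 0       # zero-variance profiles carry no signal
  cvec <- abs(cvec)
  names(cvec) <- genes
  tot <- sum(cvec)
  if (tot > 0) cvec <- cvec / tot else
    warning("all survival correlations are zero", call. = FALSE)

  nodes <- net$nodes
  in_net <- genes %in% nodes
  r_full <- cvec
  iters <- 0L
  if (length(nodes) > 0L) {
    W <- adjacency_matrix(net)
    deg <- Matrix::rowSums(W)
    inv_deg <- ifelse(deg > 0, 1 / deg, 0)
    Mt <- Matrix::t(W * inv_deg)    # column j of M row-normalised -> t(M)
    cn <- cvec[nodes]
    r <- cn
    repeat {
      iters <- iters + 1L
      r_new <- (1 - a) * cn + a * as.vector(Mt %*% r)
      delta <- sum(abs(r_new - r))
      r <- r_new
      if (delta < tol) break
      if (iters >= max_iter) {
        warning(sprintf("netrank did not converge in %d iterations (L1 delta %.3g)",
                        max_iter, delta), call. = FALSE)
        break
      }
    }
    names(r) <- nodes
    r_full[nodes] <- r
  }
  ord_net <- order_features(r_full[genes[in_net]], genes[in_net], decreasing = TRUE)
  ord_out <- order_features(cvec[genes[!in_net]], genes[!in_net], decreasing = TRUE)
  ids <- c(genes[in_net][ord_net], genes[!in_net][ord_out])
  scores <- c(r_full[genes[in_net]][ord_net], cvec[genes[!in_net]][ord_out])
  tab <- data.frame(feature_id = ids, score = unname(scores),
                    surv_cor = unname(cvec[ids]),
                    in_network = ids %in% nodes, stringsAsFactors = FALSE)
  out <- new_ranked_features("netrank", ids, unname(scores), "score", table = tab)
  out$iterations <- iters
  out
}

#' Within-class hub-interactor edge correlations
#'
#' For every hub-interactor edge of a hub sub-network, computes the Pearson
#' correlation between the hub's and the interactor's expression profiles
#' separately within each prognosis class. Undefined correlations (a
#' zero-variance profile) are set to 0 with a warning. Edges whose
#' interactor is not measured are dropped.
#'
#' @param expr Numeric genes x samples matrix.
#' @param labels GP/PP labels per sample (at least 3 per class).
#' @param subnet A `hub_subnetwork` object whose hub is measured.
#' @return Data frame with columns `hub`, `interactor`, `r_gp`, `r_pp`, one
#'   row per retained edge (possibly zero rows).
#' @export
edge_correlations <- function(expr, labels, subnet) {
  labels <- as_prognosis(labels)
  if (min(table(labels)) < 3L) abort("need at least 3 samples per class")
  if (!(subnet$hub %in% rownames(expr))) abort("hub not measured: ", subnet$hub)
  ints <- subnet$interactors[subnet$interactors %in% rownames(expr)]
  if (length(ints) == 0L) {
    return(data.frame(hub = character(), interactor = character(),
                      r_gp = numeric(), r_pp = numeric()))
  }
  class_cor <- function(cl) {
    cols <- labels == cl
    h <- expr[subnet$hub, cols]
    r <- suppressWarnings(as.vector(stats::cor(h, t(expr[ints, cols, drop = FALSE]))))
    if (any(!is.finite(r))) {
      warning("undefined correlation set to 0 for hub ", subnet$hub,
              call. = FALSE)
      r[!is.finite(r)] <- 0
    }
    r
  }
  data.frame(hub = rep(subnet$hub, length(ints)), interactor = ints,
             r_gp = class_cor("GP"), r_pp = class_cor("PP"),
             stringsAsFactors = FALSE)
}

#' Rank hub sub-networks by mean absolute correlation difference
#'
#' The differential correlation score of a hub sub-network is the mean over
#' its edges of `|r_GP - r_PP|` (range `[0, 2]`). Absolute differences are
#' used so that flips of opposite sign on different edges cannot cancel;
#' `signed = TRUE` gives the plain mean difference instead. Sub-networks
#' whose every edge was dropped (unmeasured interactors) are dropped with a
#' warning.
#'
#' @param expr Numeric genes x samples matrix.
#' @param labels GP/PP labels per sample.
#' @param subnets List of `hub_subnetwork` objects.
#' @param signed Use the signed mean difference instead of absolute values.
#' @return A `ranked_features` object (`method = "taylor"`, score
#'   descending) over hub identifiers.
#' @export
taylor_score <- function(expr, labels, subnets, signed = FALSE) {
  if (length(subnets) == 0L) abort("no hub sub-networks supplied")
  hubs <- vapply(subnets, `[[`, character(1L), "hub")
  scores <- vapply(subnets, function(s) {
    ec <- edge_correlations(expr, labels, s)
    if (nrow(ec) == 0L) return(NA_real_)
    d <- ec$r_gp - ec$r_pp
    if (signed) mean(d) else mean(abs(d))
  }, numeric(1L))
  if (anyNA(scores)) {
    warning("dropping hub sub-network(s) with no measured edges: ",
            paste(hubs[is.na(scores)], collapse = ", "), call. = FALSE)
    hubs <- hubs[!is.na(scores)]; scores <- scores[!is.na(scores)]
  }
  ord <- order_features(scores, hubs, decreasing = TRUE)
  new_ranked_features("taylor", hubs[ord], scores[ord], "score",
                      table = data.frame(feature_id = hubs[ord],
                                         score = scores[ord],
                                         stringsAsFactors = FALSE))
}

#' Rank hub sub-networks by the BSS/WSS ratio of edge correlations
#'
#' Treats the per-edge within-class correlations of a hub sub-network as
#' observations grouped by class: with m edges and class means `rbar_k`
#' around the grand mean `rbar`, `BSS = sum_k m * (rbar_k - rbar)^2` and
#' `WSS = sum_k sum_e (r_ek - rbar_k)^2`. The score is
#' `BSS / (WSS + eps)`; the epsilon keeps hubs whose within-class
#' correlations are exactly constant finite. Hubs with fewer than 2 measured
#' edges are dropped with a warning (their WSS is degenerate).
#'
#' @inheritParams taylor_score
#' @param eps Regularisation added to WSS (default 1e-9).
#' @return A `ranked_features` object (`method = "bss_wss"`, score
#'   descending) over hub identifiers.
#' @export
bss_wss_score <- function(expr, labels, subnets, eps = 1e-9) {
  if (length(subnets) == 0L) abort("no hub sub-networks supplied")
  hubs <- vapply(subnets, `[[`, character(1L), "hub")
  scores <- vapply(subnets, function(s) {
    ec <- edge_correlations(expr, labels, s)
    m <- nrow(ec)
    if (m < 2L) return(NA_real_)
    rk <- c(mean(ec$r_gp), mean(ec$r_pp))
    rb <- mean(c(ec$r_gp, ec$r_pp))
    bss <- m * sum((rk - rb)^2)
    wss <- sum((ec$r_gp - rk[1L])^2) + sum((ec$r_pp - rk[2L])^2)
    bss / (wss + eps)
  }, numeric(1L))
  if (anyNA(scores)) {
    warning("dropping hub sub-network(s) with fewer than 2 measured edges: ",
            paste(hubs[is.na(scores)], collapse = ", "), call. = FALSE)
    hubs <- hubs[!is.na(scores)]; scores <- scores[!is.na(scores)]
  }
  ord <- order_features(scores, hubs, decreasing = TRUE)
  new_ranked_features("bss_wss", hubs[ord], scores[ord], "score",
                      table = data.frame(feature_id = hubs[ord],
                                         score = scores[ord],
                                         stringsAsFactors = FALSE))
}
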