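# Synthetic cohorts with planted, ground-truth-labelled signal of the three
# informative-feature archetypes: differentially expressed single genes,
# differentially (median-) expressed hub gene-sets, and differentially
# correlated hub sub-networks. Defaults mirror a small two-class prognosis
# cohort (25 good / 22 poor prognosis samples) measured on a few thousand
# genes against a sparse scale-free-like interaction network with hubs of
# degree >= 5.

#' Simulation configuration
#'
#' @param n_genes Number of measured genes.
#' @param n_gp,n_pp Samples per class (defaults 25 good / 22 poor prognosis,
#'   a realistic small prognosis cohort).
#' @param n_hubs Number of hub genes (each a star core of degree >= 5).
#' @param hub_degree Integer range of hub degrees, inclusive.
#' @param n_background_edges Random edges among non-hub genes (capped so no
#'   non-hub node reaches degree 5).
#' @param n_de_genes Planted differentially expressed genes.
#' @param delta Mean shift of planted DE genes/sets in the PP class, in
#'   units of the within-class SD.
#' @param n_de_sets Hub gene-sets whose every member is shifted by
#'   `delta * sigma` in PP.
#' @param n_flip_hubs Hub sub-networks whose hub-interactor correlation is
#'   `rho_gp` in GP and `rho_pp` in PP.
#' @param rho_gp,rho_pp Within-class hub-interactor correlations of flip
#'   hubs (|rho| < 1).
#' @param sigma Within-class expression SD (log scale).
#' @param surv_gp,surv_pp Uniform survival-time ranges (years) per class;
#'   the defaults (4-10 vs 0.1-1) emulate a "> 4 years" versus "< 1 year"
#'   prognosis split, so GP and PP survival times never overlap.
#' @param de_in_network Plant DE genes among network (background-edge)
#'   genes, so network-aware rankings can recover them (default `TRUE`).
#' @param subspace_split When `TRUE`, the PP class is split in half: the DE
#'   mean shift is applied only to the first half and the correlation flip
#'   only to the second, planting each archetype in a different patient
#'   subspace.
#' @param noise `"gaussian"` (default) or `"t"` for heavier-tailed noise.
#' @param t_df Degrees of freedom when `noise = "t"`.
#' @param seed Integer seed (network generation consumes `seed`, expression
#'   `seed + 1`).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 2000L, n_gp = 25L, n_pp = 22L,
                       n_hubs = 50L, hub_degree = c(5L, 8L),
                       n_background_edges = 1000L,
                       n_de_genes = 20L, delta = 2,
                       n_de_sets = 5L, n_flip_hubs = 5L,
                       rho_gp = 0.8, rho_pp = -0.8, sigma = 1,
                       surv_gp = c(4, 10), surv_pp = c(0.1, 1),
                       de_in_network = TRUE, subspace_split = FALSE,
                       noise = c("gaussian", "t"), t_df = 5,
                       seed = 1L) {
  noise <- match.arg(noise)
  cfg <- list(n_genes = as.integer(n_genes), n_gp = as.integer(n_gp),
              n_pp = as.integer(n_pp), n_hubs = as.integer(n_hubs),
              hub_degree = as.integer(hub_degree),
              n_background_edges = as.integer(n_background_edges),
              n_de_genes = as.integer(n_de_genes), delta = delta,
              n_de_sets = as.integer(n_de_sets),
              n_flip_hubs = as.integer(n_flip_hubs),
              rho_gp = rho_gp, rho_pp = rho_pp, sigma = sigma,
              surv_gp = surv_gp, surv_pp = surv_pp,
              de_in_network = isTRUE(de_in_network),
              subspace_split = isTRUE(subspace_split),
              noise = noise, t_df = t_df, seed = as.integer(seed))
  if (cfg$delta < 0) abort("delta must be non-negative")
  if (abs(cfg$rho_gp) >= 1 || abs(cfg$rho_pp) >= 1) abort("|rho| must be < 1")
  if (cfg$n_flip_hubs + cfg$n_de_sets > cfg$n_hubs) {
    abort("n_flip_hubs + n_de_sets exceeds n_hubs")
  }
  if (length(cfg$hub_degree) != 2L || cfg$hub_degree[1L] < 5L ||
      cfg$hub_degree[2L] < cfg$hub_degree[1L]) {
    abort("hub_degree must be an increasing range with minimum >= 5")
  }
  # every hub star needs its own interactors (stars are disjoint)
  if (cfg$n_hubs * cfg$hub_degree[2L] > cfg$n_genes - cfg$n_hubs) {
    abort("infeasible: hubs require more interactors than available genes")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a scale-free-like interaction network with guaranteed hubs
#'
#' Builds `n_hubs` disjoint star cores whose hubs have degree drawn from
#' `hub_degree`, then adds random background edges among non-hub genes,
#' rejecting any edge that would raise a non-hub node to degree 5, so the
#' generated network has exactly `n_hubs` hubs at the conventional
#' degree->=5 threshold. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A [ppi_network()].
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  hubs <- sort(sample(genes, cfg$n_hubs))
  degs <- sample(seq(cfg$hub_degree[1L], cfg$hub_degree[2L]),
                 cfg$n_hubs, replace = TRUE)
  pool <- sample(setdiff(genes, hubs))
  stopifnot(sum(degs) <= length(pool))
  stops <- cumsum(degs)
  starts <- c(1L, stops[-length(stops)] + 1L)
  star_edges <- do.call(rbind, lapply(seq_len(cfg$n_hubs), function(i) {
    cbind(hubs[i], pool[starts[i]:stops[i]])
  }))
  deg_count <- stats::setNames(integer(cfg$n_genes), genes)
  deg_count[star_edges[, 2L]] <- 1L
  nonhub <- setdiff(genes, hubs)
  bg <- matrix(character(), ncol = 2L)
  if (cfg$n_background_edges > 0L) {
    cand_a <- sample(nonhub, 4L * cfg$n_background_edges, replace = TRUE)
    cand_b <- sample(nonhub, 4L * cfg$n_background_edges, replace = TRUE)
    ok <- cand_a != cand_b
    cand_a <- cand_a[ok]; cand_b <- cand_b[ok]
    key <- paste(pmin(cand_a, cand_b), pmax(cand_a, cand_b))
    first <- !duplicated(key)
    cand_a <- cand_a[first]; cand_b <- cand_b[first]
    keep_a <- character(cfg$n_background_edges)
    keep_b <- character(cfg$n_background_edges)
    got <- 0L
    for (i in seq_along(cand_a)) {
      if (got >= cfg$n_background_edges) break
      # cap at degree 4 so background never manufactures a hub
      if (deg_count[cand_a[i]] < 4L && deg_count[cand_b[i]] < 4L) {
        got <- got + 1L
        keep_a[got] <- cand_a[i]; keep_b[got] <- cand_b[i]
        deg_count[cand_a[i]] <- deg_count[cand_a[i]] + 1L
        deg_count[cand_b[i]] <- deg_count[cand_b[i]] + 1L
      }
    }
    bg <- cbind(keep_a[seq_len(got)], keep_b[seq_len(got)])
  }
  ppi_network(rbind(star_edges, bg))
}

#' Simulate expression, phenotype and survival over a network
#'
#' Baseline log-expression is i.i.d. Gaussian(0, sigma^2) (optionally
#' t-distributed, rescaled to SD sigma). Planted signal: (i) DE genes get a
#' `+delta*sigma` mean shift in PP; (ii) DE gene-sets apply the same shift
#' to every member (hub + interactors) of chosen hub sub-networks; (iii)
#' correlation-flip hubs regenerate each interactor as
#' `rho_k * hub + sqrt(1 - rho_k^2) * noise` with class-specific `rho_k`, so
#' the hub-interactor correlation is `rho_gp` in GP and `rho_pp` in PP while
#' marginals stay N(0, sigma^2). Survival times are uniform within
#' class-specific ranges. The three planted truth groups are disjoint: flip
#' hubs and DE-set hubs are distinct hubs, and DE genes avoid all hub
#' sub-networks.
#'
#' @param net The [simulate_network()] output for `cfg`.
#' @param cfg A [sim_config()].
#' @return List with `expression` (matrix), `phenotype` (data frame),
#'   `truth` (list `de_genes`, `de_sets`, `flip_hubs`).
#' @export
simulate_expression <- function(net, cfg) {
  stopifnot(inherits(net, "ppi_network"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  n <- cfg$n_gp + cfg$n_pp
  samples <- sprintf("S%03d", seq_len(n))
  labels <- factor(rep(prognosis_levels(), c(cfg$n_gp, cfg$n_pp)),
                   levels = prognosis_levels())
  draw <- function(m) {
    if (cfg$noise == "gaussian") {
      matrix(stats::rnorm(m * n, 0, cfg$sigma), nrow = m)
    } else {
      sc <- cfg$sigma / sqrt(cfg$t_df / (cfg$t_df - 2))
      matrix(stats::rt(m * n, df = cfg$t_df) * sc, nrow = m)
    }
  }
  expr <- draw(cfg$n_genes)
  dimnames(expr) <- list(genes, samples)

  hubs <- find_hubs(net, 5L)
  if (cfg$n_flip_hubs + cfg$n_de_sets > length(hubs)) {
    abort("network has too few hubs for the requested planted signal")
  }
  special <- sample(hubs, cfg$n_flip_hubs + cfg$n_de_sets)
  flip_hubs <- sort(special[seq_len(cfg$n_flip_hubs)])
  de_set_hubs <- sort(special[-seq_len(cfg$n_flip_hubs)])
  subnets <- hub_subnetworks(net, hubs)
  names(subnets) <- hubs
  hub_members <- unique(c(hubs, unlist(lapply(subnets, `[[`, "interactors"))))

  deg <- network_degree(net)
  eligible <- if (cfg$de_in_network) {
    setdiff(names(deg)[deg >= 1L], hub_members)
  } else {
    setdiff(genes, hub_members)
  }
  if (length(eligible) < cfg$n_de_genes) {
    abort("not enough eligible genes for the requested DE planting")
  }
  de_genes <- sort(sample(eligible, cfg$n_de_genes))

  pp_cols <- which(labels == "PP")
  gp_cols <- which(labels == "GP")
  if (cfg$subspace_split) {
    half <- length(pp_cols) %/% 2L
    pp_shift_cols <- pp_cols[seq_len(half)]          # DE archetype carriers
    pp_flip_cols <- pp_cols[-seq_len(half)]          # flip archetype carriers
  } else {
    pp_shift_cols <- pp_cols
    pp_flip_cols <- pp_cols
  }

  shift <- cfg$delta * cfg$sigma
  expr[de_genes, pp_shift_cols] <- expr[de_genes, pp_shift_cols] + shift
  for (h in de_set_hubs) {
    members <- c(h, subnets[[h]]$interactors)
    expr[members, pp_shift_cols] <- expr[members, pp_shift_cols] + shift
  }
  plant_cor <- function(h, cols, rho) {
    ints <- subnets[[h]]$interactors
    hv <- expr[h, cols]
    noise <- matrix(stats::rnorm(length(ints) * length(cols), 0, cfg$sigma),
                    nrow = length(ints))
    expr[ints, cols] <<- rho * rep(hv, each = length(ints)) +
      sqrt(1 - rho^2) * noise
  }
  for (h in flip_hubs) {
    plant_cor(h, gp_cols, cfg$rho_gp)
    if (cfg$subspace_split) {
      # non-flip PP samples keep the GP-like correlation structure
      plant_cor(h, pp_shift_cols, cfg$rho_gp)
      plant_cor(h, pp_flip_cols, cfg$rho_pp)
    } else {
      plant_cor(h, pp_cols, cfg$rho_pp)
    }
  }
  survival <- numeric(n)
  survival[gp_cols] <- stats::runif(length(gp_cols), cfg$surv_gp[1L], cfg$surv_gp[2L])
  survival[pp_cols] <- stats::runif(length(pp_cols), cfg$surv_pp[1L], cfg$surv_pp[2L])
  pheno <- data.frame(sample_id = samples, class = labels,
                      survival_time = survival, stringsAsFactors = FALSE)
  list(expression = expr, phenotype = pheno,
       truth = list(de_genes = de_genes, de_sets = de_set_hubs,
                    flip_hubs = flip_hubs))
}

#' Simulate a full dataset
#'
#' Convenience wrapper: [simulate_network()] then [simulate_expression()],
#' returning the aligned dataset plus ground truth.
#'
#' @param cfg A [sim_config()].
#' @return List with `data` (an `aligned_dataset`), `truth`, `network`,
#'   `expression`, `phenotype`.
#' @export
simulate_dataset <- function(cfg) {
  net <- simulate_network(cfg)
  sim <- simulate_expression(net, cfg)
  data <- suppressMessages(align_dataset(sim$expression, sim$phenotype, net))
  list(data = data, truth = sim$truth, network = net,
       expression = sim$expression, phenotype = sim$phenotype)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `expression.tsv`, `phenotype.tsv`, `network.tsv` and `truth.json`
#' in the package's documented formats; the files round-trip exactly through
#' [read_expression()], [read_phenotype()] and [read_edge_list()].
#'
#' @param expr,pheno,net,truth Components as produced by
#'   [simulate_expression()] / [simulate_network()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(expr, pheno, net, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(expr, file.path(dir, "expression.tsv"))
  write_phenotype(pheno, file.path(dir, "phenotype.tsv"))
  write_edge_list(net, file.path(dir, "network.tsv"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}
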