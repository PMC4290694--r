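#' Construct an undirected protein-protein interaction network
#'
#' The network is stored as a deduplicated undirected edge list plus the node
#' set. Self-loops are dropped (with a warning) and each unordered pair is
#' kept once. The adjacency matrix W = (w_ij) is 0/1, symmetric, with zero
#' diagonal, so a node's degree is its row sum.
#'
#' @param edges Two-column character matrix (or data frame) of gene pairs;
#'   may have zero rows.
#' @param nodes Optional extra isolated nodes to include.
#' @return An object of class `ppi_network` with elements `nodes` (character)
#'   and `edges` (two-column character matrix, columns `from`/`to`).
#' @export
ppi_network <- function(edges, nodes = character()) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) abort("edges must have exactly two columns")
  storage.mode(edges) <- "character"
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  # undirected dedup: order endpoints within each edge, then unique rows
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  edges <- matrix(c(a[keep], b[keep]), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  ord <- order(edges[, 1L], edges[, 2L], method = "radix")
  edges <- edges[ord, , drop = FALSE]
  nodes <- sort(unique(c(as.character(nodes), edges)))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d undirected edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a network edge list (TSV or SIF)
#'
#' Accepts a two-column tab-separated edge list, or three-column SIF lines
#' (`geneA<TAB>interaction<TAB>geneB`) whose middle column is ignored. Blank
#' lines are skipped; any other field count is a parse error naming the line.
#'
#' @param path Path to the file.
#' @return A [ppi_network()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort("network file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty network file: ", path, call. = FALSE)
    return(ppi_network(matrix(character(), ncol = 2L)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (!all(nf %in% c(2L, 3L))) {
    bad <- which(!(nf %in% c(2L, 3L)))[1L]
    abort(sprintf("line %d of '%s' has %d field(s); expected 2 (edge list) or 3 (SIF)",
                  bad, path, nf[bad]))
  }
  from <- vapply(parts, `[[`, character(1L), 1L)
  to <- vapply(parts, function(p) p[[length(p)]], character(1L))
  ppi_network(cbind(from, to))
}

#' Write a network as a two-column TSV edge list
#' @param net A [ppi_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  writeLines(paste(net$edges[, 1L], net$edges[, 2L], sep = "\t"), path)
  invisible(path)
}

# Restrict a network to the given gene universe (nodes and incident edges
# outside it are dropped). Isolated retained nodes are kept.
restrict_network <- function(net, genes) {
  keep <- net$edges[, 1L] %in% genes & net$edges[, 2L] %in% genes
  ppi_network(net$edges[keep, , drop = FALSE],
              nodes = intersect(net$nodes, genes))
}

#' Node degrees
#' @param net A [ppi_network()].
#' @return Named integer vector over all nodes.
#' @export
network_degree <- function(net) {
  deg <- integer(length(net$nodes))
  names(deg) <- net$nodes
  tab <- table(factor(c(net$edges[, 1L], net$edges[, 2L]), levels = net$nodes))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Sparse symmetric adjacency matrix
#' @param net A [ppi_network()].
#' @return A `dgCMatrix` with 0/1 entries, rows/columns named by node.
#' @export
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  i <- match(net$edges[, 1L], net$nodes)
  j <- match(net$edges[, 2L], net$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                       dims = c(n, n), dimnames = list(net$nodes, net$nodes))
}

#' Find hub genes
#'
#' A hub is a node whose degree is at least `min_degree` (default 5, the
#' conventional threshold for highly connected nodes in interaction
#' networks). Hubs are returned sorted by degree descending, ties broken by
#' gene identifier ascending, so downstream selection is reproducible.
#'
#' @param net A [ppi_network()].
#' @param min_degree Positive integer threshold.
#' @return Character vector of hub gene identifiers (possibly empty).
#' @export
find_hubs <- function(net, min_degree = 5L) {
  stopifnot(inherits(net, "ppi_network"), min_degree >= 1L)
  deg <- network_degree(net)
  hubs <- names(deg)[deg >= min_degree]
  hubs[order(-deg[hubs], hubs, method = "radix")]
}

#' Extract hub sub-networks
#'
#' A hub sub-network is the hub together with its immediate interactors and
#' only the hub-interactor edges; interactor-interactor edges present in the
#' full network are excluded by definition.
#'
#' @param net A [ppi_network()].
#' @param hubs Character vector of hub gene identifiers (must be nodes).
#' @return A list of `hub_subnetwork` objects, one per hub, each with
#'   elements `hub`, `interactors` (sorted) and `edges` (hub-interactor
#'   pairs).
#' @export
hub_subnetworks <- function(net, hubs) {
  stopifnot(inherits(net, "ppi_network"))
  unknown <- setdiff(hubs, net$nodes)
  if (length(unknown) > 0L) {
    abort("hub(s) not in network: ", paste(unknown, collapse = ", "))
  }
  lapply(hubs, function(h) {
    nb <- sort(unique(c(net$edges[net$edges[, 1L] == h, 2L],
                        net$edges[net$edges[, 2L] == h, 1L])))
    structure(list(hub = h, interactors = nb,
                   edges = cbind(hub = rep(h, length(nb)), interactor = nb)),
              class = "hub_subnetwork")
  })
}

#' Convert hub sub-networks to gene-sets
#'
#' The edge structure is discarded: each gene-set is the hub plus its
#' interactors, identified by the hub gene.
#'
#' @param subnets List of `hub_subnetwork` objects.
#' @return A list of `gene_set` objects with elements `set_id` and `members`.
#' @export
subnetworks_to_genesets <- function(subnets) {
  lapply(subnets, function(s) {
    structure(list(set_id = s$hub, members = unique(c(s$hub, s$interactors))),
              class = "gene_set")
  })
}
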