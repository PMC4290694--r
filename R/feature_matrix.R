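# Classification feature values. Every builder computes a sample's column
# from that sample's expression values and fixed feature definitions only,
# so definitions frozen on a training fold transfer unchanged to test
# samples.

#' Expression features for individual genes
#'
#' @param expr Numeric genes x samples matrix.
#' @param genes Gene identifiers, in selected order.
#' @return Numeric features x samples matrix (rows = genes).
#' @export
gene_features <- function(expr, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) abort("no genes selected; classifier needs >= 1 feature")
  unknown <- setdiff(genes, rownames(expr))
  if (length(unknown) > 0L) {
    abort("unknown gene(s): ", paste(unknown, collapse = ", "))
  }
  expr[genes, , drop = FALSE]
}

#' Median-expression features for gene-sets
#'
#' The value of a set for a sample is the median expression of the set's
#' measured members in that sample (mean of the two central values for even
#' member counts).
#'
#' @param expr Numeric genes x samples matrix.
#' @param sets List of `gene_set` objects.
#' @param allow_drop Drop sets with no measured member (with a warning)
#'   instead of erroring; used by the selection step.
#' @return Numeric features x samples matrix, rows named by set identifier.
#' @export
set_median_features <- function(expr, sets, allow_drop = FALSE) {
  if (length(sets) == 0L) abort("no gene-sets supplied")
  ids <- vapply(sets, `[[`, character(1L), "set_id")
  members <- lapply(sets, function(s) intersect(s$members, rownames(expr)))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    if (!allow_drop) abort("gene-set(s) with no measured member: ",
                           paste(ids[empty], collapse = ", "))
    warning("dropping gene-set(s) with no measured member: ",
            paste(ids[empty], collapse = ", "), call. = FALSE)
    ids <- ids[!empty]; members <- members[!empty]
    if (length(ids) == 0L) abort("all gene-sets were dropped")
  }
  vals <- t(vapply(members, function(m) {
    apply(expr[m, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(expr))))
  dimnames(vals) <- list(ids, colnames(expr))
  vals
}

#' Hub-interactor expression-difference features
#'
#' One feature per hub-interactor edge across the selected sub-networks; the
#' value for a sample is `expr[hub, ] - expr[interactor, ]` (orientation
#' fixed as hub minus interactor). Edges with unmeasured interactors are
#' dropped; identical `hub|interactor` rows arising from overlapping
#' sub-networks are deduplicated, keeping first occurrence.
#'
#' @param expr Numeric genes x samples matrix.
#' @param subnets List of `hub_subnetwork` objects (typically the top-ranked
#'   sub-networks from [taylor_score()]).
#' @return Numeric features x samples matrix with rownames
#'   `"hub|interactor"`.
#' @export
edge_difference_features <- function(expr, subnets) {
  if (length(subnets) == 0L) abort("no hub sub-networks supplied")
  hub <- unlist(lapply(subnets, function(s)
    rep(s$hub, length(s$interactors))), use.names = FALSE)
  int <- unlist(lapply(subnets, `[[`, "interactors"), use.names = FALSE)
  keep <- hub %in% rownames(expr) & int %in% rownames(expr)
  hub <- hub[keep]; int <- int[keep]
  ids <- paste(hub, int, sep = "|")
  first <- !duplicated(ids)
  hub <- hub[first]; int <- int[first]; ids <- ids[first]
  if (length(ids) == 0L) abort("all edges dropped (unmeasured genes)")
  vals <- expr[hub, , drop = FALSE] - expr[int, , drop = FALSE]
  rownames(vals) <- ids
  vals
}

#' Hub-gene expression features
#'
#' The feature for each selected sub-network is the expression of its hub
#' gene. Duplicate hubs are deduplicated keeping first occurrence.
#'
#' @param expr Numeric genes x samples matrix.
#' @param subnets List of `hub_subnetwork` objects (typically the top-ranked
#'   sub-networks from [bss_wss_score()]).
#' @return Numeric features x samples matrix (rows = hub genes).
#' @export
hub_gene_features <- function(expr, subnets) {
  if (length(subnets) == 0L) abort("no hub sub-networks supplied")
  hubs <- unique(vapply(subnets, `[[`, character(1L), "hub"))
  unknown <- setdiff(hubs, rownames(expr))
  if (length(unknown) > 0L) {
    abort("hub(s) not measured: ", paste(unknown, collapse = ", "))
  }
  expr[hubs, , drop = FALSE]
}

#' Write a feature value matrix as TSV
#' @param fvm Numeric features x samples matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fvm, path) {
  txt <- matrix(sprintf("%.17g", fvm), nrow = nrow(fvm))
  lines <- c(paste(c("feature_id", colnames(fvm)), collapse = "\t"),
             paste(rownames(fvm), apply(txt, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
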