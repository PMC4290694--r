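#' Read a gene expression matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample identifiers,
#' whose first column holds gene identifiers, and whose body is numeric
#' log-scale expression. Duplicate gene rows are collapsed by keeping the row
#' with the highest variance (a warning names the genes); missing or
#' non-numeric cells are rejected, naming the offending gene and sample,
#' because inputs are expected to be fully pre-processed upstream.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix (genes x samples) with gene rownames and sample
#'   colnames.
#' @seealso [write_expression()], [read_phenotype()], [align_dataset()]
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort("expression file not found: ", path)
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE,
                      quote = "", comment.char = ""),
    error = function(e) abort("empty or malformed expression file '", path,
                              "': ", conditionMessage(e)))
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort("expression file is empty or has no sample columns: ", path)
  }
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) abort("duplicate sample identifiers in header")
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "non-numeric or missing expression value at gene '%s', sample '%s' (%s)",
      genes[bad[1L]], samples[bad[2L]], body[bad[1L], bad[2L]]))
  }
  dimnames(vals) <- list(genes, samples)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing duplicate gene rows (keeping highest variance): ",
            paste(dup, collapse = ", "), call. = FALSE)
    v <- apply(vals, 1L, stats::var)
    keep <- !logical(nrow(vals))
    for (g in dup) {
      rows <- which(genes == g)
      keep[rows] <- FALSE
      keep[rows[which.max(v[rows])]] <- TRUE
    }
    vals <- vals[keep, , drop = FALSE]
  }
  check_expression_matrix(vals)
  vals
}

#' Write an expression matrix to TSV
#'
#' Values are rendered with `%.17g` so that a write/read round trip through
#' [read_expression()] reproduces every double exactly.
#'
#' @param expr Numeric matrix (genes x samples) with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  check_expression_matrix(expr)
  txt <- matrix(sprintf("%.17g", expr), nrow = nrow(expr))
  lines <- c(
    paste(c("gene_id", colnames(expr)), collapse = "\t"),
    paste(rownames(expr), apply(txt, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' Expects columns `sample_id`, `class` and `survival_time`. Class tokens must
#' be `GP`/`PP` (case-insensitive); survival times must be finite non-negative
#' numbers (years) and are mandatory because the network-based survival
#' correlation ranking needs them.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `sample_id` (character), `class` (factor
#'   with levels GP, PP) and `survival_time` (numeric), input order preserved.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) abort("phenotype file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "class", "survival_time")
  miss <- setdiff(need, colnames(raw))
  if (length(miss) > 0L) {
    abort("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(raw$sample_id)) abort("duplicate sample_id in phenotype")
  surv <- suppressWarnings(as.numeric(raw$survival_time))
  if (anyNA(surv)) {
    abort("missing or non-numeric survival_time for sample(s): ",
          paste(raw$sample_id[is.na(surv)], collapse = ", "))
  }
  if (any(!is.finite(surv)) || any(surv < 0)) {
    abort("survival_time must be finite and non-negative")
  }
  pheno <- data.frame(sample_id = raw$sample_id,
                      class = as_prognosis(raw$class),
                      survival_time = surv,
                      stringsAsFactors = FALSE)
  pheno
}

#' Write a phenotype table to TSV
#' @param pheno Data frame as returned by [read_phenotype()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(pheno, path) {
  out <- data.frame(sample_id = pheno$sample_id,
                    class = as.character(pheno$class),
                    survival_time = sprintf("%.17g", pheno$survival_time))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align expression, phenotype and network to a shared universe
#'
#' Restricts samples to those present in both the expression matrix and the
#' phenotype table (expression column order is canonical; the phenotype is
#' reordered to it) and restricts the interaction network to genes measured on
#' the expression platform, mirroring the usual intersection of a prior
#' knowledge network with a microarray platform. Drop counts are reported via
#' `message()`.
#'
#' @param expr Numeric genes x samples matrix.
#' @param pheno Phenotype data frame (see [read_phenotype()]).
#' @param net A [ppi_network()] object.
#' @return An object of class `aligned_dataset`: a list with elements
#'   `expression`, `phenotype`, `network`.
#' @export
align_dataset <- function(expr, pheno, net) {
  check_expression_matrix(expr)
  stopifnot(inherits(net, "ppi_network"))
  shared <- intersect(colnames(expr), pheno$sample_id)
  if (length(shared) == 0L) abort("expression and phenotype share no samples")
  dropped_expr <- setdiff(colnames(expr), shared)
  dropped_pheno <- setdiff(pheno$sample_id, shared)
  if (length(dropped_expr) || length(dropped_pheno)) {
    message(sprintf("align: dropped %d expression sample(s), %d phenotype sample(s)",
                    length(dropped_expr), length(dropped_pheno)))
  }
  expr <- expr[, shared, drop = FALSE]
  pheno <- pheno[match(shared, pheno$sample_id), , drop = FALSE]
  rownames(pheno) <- NULL
  pheno$class <- as_prognosis(pheno$class)
  tab <- table(pheno$class)
  if (any(tab == 0L)) {
    abort("class emptied by sample intersection: ",
          paste(names(tab)[tab == 0L], collapse = ", "))
  }
  if (any(tab < 2L)) abort("need at least 2 samples per class after alignment")
  net2 <- restrict_network(net, rownames(expr))
  dn <- length(net$nodes) - length(net2$nodes)
  de <- nrow(net$edges) - nrow(net2$edges)
  if (dn > 0L || de > 0L) {
    message(sprintf("align: dropped %d network node(s) and %d edge(s) not measured",
                    dn, de))
  }
  structure(list(expression = expr, phenotype = pheno, network = net2),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  tab <- table(x$phenotype$class)
  cat(sprintf("aligned_dataset: %d genes x %d samples (GP=%d, PP=%d); network %d nodes / %d edges\n",
              nrow(x$expression), ncol(x$expression), tab[["GP"]], tab[["PP"]],
              length(x$network$nodes), nrow(x$network$edges)))
  invisible(x)
}
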