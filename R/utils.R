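# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort <- function(..., call. = FALSE) stop(..., call. = call.)

#' Class labels used throughout the package
#'
#' Cohorts are binary: good prognosis (`GP`, longer survival) versus poor
#' prognosis (`PP`, shorter survival).
#' @return Character vector `c("GP", "PP")`.
#' @export
prognosis_levels <- function() c("GP", "PP")

# Coerce a label vector to the canonical GP/PP factor, failing loudly on
# unknown tokens (matching is case-insensitive).
as_prognosis <- function(x) {
  up <- toupper(as.character(x))
  bad <- setdiff(unique(up), prognosis_levels())
  if (length(bad) > 0L) {
    abort("unknown class token(s): ", paste(bad, collapse = ", "),
          "; allowed tokens are GP, PP (case-insensitive)")
  }
  factor(up, levels = prognosis_levels())
}

# Deterministic ordering: primary key ascending/descending, ties broken by
# feature identifier ascending. `decreasing` applies to `score` only.
order_features <- function(score, ids, decreasing = FALSE) {
  ids <- as.character(ids)
  if (decreasing) {
    order(-xtfrm(score), ids, method = "radix")
  } else {
    order(xtfrm(score), ids, method = "radix")
  }
}

# Derive a child RNG seed from a base seed and stream indices; stays within
# the 32-bit signed integer range R requires.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k)) %% 2147483647
  as.integer(s)
}

# Validate a genes x samples numeric matrix with dimnames.
check_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr))) abort("duplicate gene identifiers")
  if (anyDuplicated(colnames(expr))) abort("duplicate sample identifiers")
  if (anyNA(expr)) abort("expression matrix contains missing values")
  invisible(expr)
}
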