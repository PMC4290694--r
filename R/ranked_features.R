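# Ranked feature lists produced by the selection methods.

#' Methods in the comparison roster
#' @return Character vector of method identifiers.
#' @export
method_roster <- function() c("mod_t", "median_set", "netrank", "taylor", "bss_wss")

# Internal constructor. `scores` must already be ordered consistently with
# `feature_ids`: p-ascending for p-value methods, score-descending otherwise,
# ties broken by identifier ascending before construction.
new_ranked_features <- function(method, feature_ids, scores,
                                score_type = c("score", "p_value"),
                                table = NULL) {
  score_type <- match.arg(score_type)
  if (anyDuplicated(feature_ids)) abort("duplicate feature identifiers")
  structure(list(method = method, feature_ids = as.character(feature_ids),
                 scores = as.numeric(scores), score_type = score_type,
                 table = table),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, n = 10L, ...) {
  cat(sprintf("ranked_features [%s]: %d feature(s), ordered by %s\n",
              x$method, length(x$feature_ids),
              if (x$score_type == "p_value") "p-value ascending" else "score descending"))
  k <- min(n, length(x$feature_ids))
  if (k > 0L) {
    print(data.frame(rank = seq_len(k), feature_id = x$feature_ids[seq_len(k)],
                     score = x$scores[seq_len(k)]), row.names = FALSE)
  }
  invisible(x)
}

#' @export
length.ranked_features <- function(x) length(x$feature_ids)

#' Keep the top-ranked features
#'
#' @param ranked A `ranked_features` object.
#' @param n Positive integer; if the list is shorter, the whole list is
#'   returned with a warning.
#' @return A `ranked_features` object with at most `n` features, order
#'   preserved.
#' @export
select_top <- function(ranked, n) {
  stopifnot(inherits(ranked, "ranked_features"), length(n) == 1L, n >= 1L)
  m <- length(ranked$feature_ids)
  if (n > m) {
    warning(sprintf("requested top %d but only %d feature(s) are ranked", n, m),
            call. = FALSE)
    n <- m
  }
  idx <- seq_len(n)
  new_ranked_features(ranked$method, ranked$feature_ids[idx], ranked$scores[idx],
                      ranked$score_type,
                      table = if (!is.null(ranked$table)) ranked$table[idx, , drop = FALSE])
}

#' Export a ranked list as a data frame
#' @param x A `ranked_features` object.
#' @param ... Unused.
#' @return Data frame with columns `method`, `rank`, `feature_id`, `score`.
#' @export
as.data.frame.ranked_features <- function(x, ...) {
  data.frame(method = rep(x$method, length(x$feature_ids)),
             rank = seq_along(x$feature_ids),
             feature_id = x$feature_ids, score = x$scores,
             stringsAsFactors = FALSE)
}
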