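# Repeated stratified K-fold cross-validation with strictly in-fold feature
# selection, and the three evaluation layers: overall/class-specific error,
# feature selection stability and patient-level accuracy.

#' Build a repeated K-fold plan
#'
#' For each of `R` rounds the samples are partitioned into `K` folds "as
#' equal as possible" (sizes differ by at most one) with stratification:
#' each fold's class mix approximates the cohort's, which protects small
#' cohorts from single-class training folds. If a class has fewer samples
#' than `K`, the plan falls back to unstratified folds with a warning.
#'
#' @param labels GP/PP labels for the cohort (order defines sample indices).
#' @param K Folds per round (default 5).
#' @param R Number of rounds (default 100).
#' @param seed Integer seed; the same seed reproduces the plan exactly.
#' @return An object of class `fold_plan`: list with `K`, `R`, `seed`, `n`
#'   and `assignment`, a list of `R` integer vectors giving each sample's
#'   test fold in that round.
#' @export
make_fold_plan <- function(labels, K = 5L, R = 100L, seed = 1L) {
  labels <- as_prognosis(labels)
  n <- length(labels)
  if (n < K) abort("fewer samples than folds")
  stratified <- min(table(labels)) >= K
  if (!stratified) {
    warning("a class has fewer samples than K; using unstratified folds",
            call. = FALSE)
  }
  groups <- if (stratified) split(seq_len(n), labels) else list(seq_len(n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  assignment <- vector("list", R)
  for (r in seq_len(R)) {
    fold_of <- integer(n)
    totals <- integer(K)
    for (idx in groups) {
      idx <- idx[sample.int(length(idx))]
      base <- length(idx) %/% K
      rem <- length(idx) %% K
      cnt <- rep.int(base, K)
      if (rem > 0L) {
        # give the extras to the currently least-filled folds, random ties
        perm <- sample.int(K)
        cnt[perm[order(totals[perm])][seq_len(rem)]] <- base + 1L
      }
      fold_of[idx] <- rep.int(seq_len(K), cnt)
      totals <- totals + cnt
    }
    assignment[[r]] <- fold_of
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(K = as.integer(K), R = as.integer(R), seed = as.integer(seed),
                 n = n, stratified = stratified, assignment = assignment),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %d round(s) of %d-fold CV over %d samples (seed %d, %s)\n",
              x$R, x$K, x$n, x$seed,
              if (x$stratified) "stratified" else "unstratified"))
  invisible(x)
}

# In-fold feature selection + feature construction for one method.
# Returns list(selected = ranked_features (top n), build = function(expr_cols))
# where build() maps any sample subset of the aligned expression matrix to
# the feature value matrix, using definitions frozen on the training fold.
select_and_define <- function(method, data, train_idx, n_features,
                              context) {
  expr_tr <- data$expression[, train_idx, drop = FALSE]
  labels_tr <- data$phenotype$class[train_idx]
  sel <- switch(method,
    mod_t = moderated_t(expr_tr, labels_tr),
    median_set = median_set_scores(expr_tr, labels_tr, context$genesets),
    netrank = netrank(expr_tr, data$phenotype$survival_time[train_idx],
                      data$network, a = context$netrank_a,
                      tol = context$netrank_tol,
                      max_iter = context$netrank_max_iter),
    taylor = taylor_score(expr_tr, labels_tr, context$subnets),
    bss_wss = bss_wss_score(expr_tr, labels_tr, context$subnets),
    abort("unknown method '", method, "'; roster: ",
          paste(method_roster(), collapse = ", ")))
  top <- suppressWarnings(select_top(sel, n_features))
  build <- switch(method,
    mod_t = , netrank = function(e) gene_features(e, top$feature_ids),
    median_set = {
      sets <- context$genesets[match(top$feature_ids,
                                     vapply(context$genesets, `[[`, "", "set_id"))]
      function(e) set_median_features(e, sets)
    },
    taylor = {
      sn <- context$subnets[match(top$feature_ids,
                                  vapply(context$subnets, `[[`, "", "hub"))]
      function(e) edge_difference_features(e, sn)
    },
    bss_wss = {
      sn <- context$subnets[match(top$feature_ids,
                                  vapply(context$subnets, `[[`, "", "hub"))]
      function(e) hub_gene_features(e, sn)
    })
  list(selected = top, build = build)
}

#' Run repeated cross-validation for one method/classifier pair
#'
#' For every round and fold, feature selection runs on the training samples
#' only (including the survival correlations of the network ranking and all
#' within-class edge correlations), the top `n_features` are kept, feature
#' values are built for training and test samples from the frozen
#' definitions, the classifier is trained and the withheld fold predicted.
#' Every sample is predicted exactly once per round.
#'
#' @param data An [align_dataset()] result.
#' @param method One of [method_roster()].
#' @param classifier A [classifier_adapter()] spec or a kind string.
#' @param plan A [make_fold_plan()] plan for this cohort.
#' @param n_features Features selected per fold (default 50).
#' @param min_degree Hub degree threshold used to derive gene-sets and hub
#'   sub-networks from the aligned network (default 5).
#' @param netrank_a,netrank_tol,netrank_max_iter Network ranking
#'   parameters.
#' @return An object of class `cv_result`: predictions (R x n character
#'   matrix), per-round/fold selected feature lists, labels, and the plan.
#' @export
run_cv <- function(data, method, classifier, plan, n_features = 50L,
                   min_degree = 5L, netrank_a = 0.3, netrank_tol = 1e-10,
                   netrank_max_iter = 1000L) {
  stopifnot(inherits(data, "aligned_dataset"), inherits(plan, "fold_plan"))
  if (is.character(classifier)) classifier <- classifier_adapter(classifier)
  n <- ncol(data$expression)
  if (plan$n != n) abort("fold plan was built for a different cohort size")
  method <- match.arg(method, method_roster())
  context <- list(netrank_a = netrank_a, netrank_tol = netrank_tol,
                  netrank_max_iter = netrank_max_iter)
  if (method %in% c("median_set", "taylor", "bss_wss")) {
    hubs <- find_hubs(data$network, min_degree)
    if (length(hubs) == 0L) abort("no hubs of degree >= ", min_degree,
                                  " in the aligned network")
    context$subnets <- hub_subnetworks(data$network, hubs)
    context$genesets <- subnetworks_to_genesets(context$subnets)
  }
  labels <- data$phenotype$class
  preds <- matrix(NA_character_, nrow = plan$R, ncol = n,
                  dimnames = list(NULL, colnames(data$expression)))
  selected <- vector("list", plan$R)
  base_seed <- classifier$seed %||% plan$seed
  for (r in seq_len(plan$R)) {
    fold_of <- plan$assignment[[r]]
    sel_r <- vector("list", plan$K)
    for (k in seq_len(plan$K)) {
      test_idx <- which(fold_of == k)
      train_idx <- which(fold_of != k)
      sd <- select_and_define(method, data, train_idx, n_features, context)
      sel_r[[k]] <- sd$selected$feature_ids
      X_tr <- sd$build(data$expression[, train_idx, drop = FALSE])
      X_te <- sd$build(data$expression[, test_idx, drop = FALSE])
      spec <- classifier
      spec$seed <- derive_seed(base_seed, r, k)
      fit <- train_classifier(spec, X_tr, labels[train_idx])
      preds[r, test_idx] <- as.character(predict(fit, X_te))
    }
    selected[[r]] <- sel_r
  }
  stopifnot(!anyNA(preds))   # fold coverage: every sample predicted per round
  structure(list(method = method, classifier = classifier$kind,
                 predictions = preds, selected = selected,
                 labels = labels, sample_ids = colnames(data$expression),
                 n_features = n_features, plan = plan),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %s + %s, %d round(s) x %d samples, error %.3f\n",
              x$method, x$classifier, nrow(x$predictions),
              ncol(x$predictions), overall_error(x)))
  invisible(x)
}

#' Overall cross-validation error
#'
#' The fraction of misclassified predictions over all rounds and samples.
#' Because every round's folds partition the cohort, this equals the mean
#' over rounds of the per-round error and satisfies the exact conservation
#' identities with the class-specific and patient-level summaries.
#'
#' @param res A `cv_result`.
#' @return Error fraction in `[0, 1]`.
#' @export
overall_error <- function(res) {
  truth <- matrix(as.character(res$labels), nrow = nrow(res$predictions),
                  ncol = ncol(res$predictions), byrow = TRUE)
  mean(res$predictions != truth)
}

#' Class-specific cross-validation error
#'
#' @param res A `cv_result`.
#' @return Named numeric vector with the GP and PP error fractions; the
#'   sample-weighted mean reconstructs [overall_error()] exactly.
#' @export
class_specific_error <- function(res) {
  truth <- as.character(res$labels)
  vapply(prognosis_levels(), function(cl) {
    cols <- truth == cl
    mean(res$predictions[, cols, drop = FALSE] != cl)
  }, numeric(1L))
}

#' Patient-level accuracy counts
#'
#' @param res A `cv_result`.
#' @return Data frame with `sample_id`, `class`, `correct` (rounds correctly
#'   classified, in `[0, R]`) and `fraction` (`correct / R`).
#' @export
patient_accuracy <- function(res) {
  truth <- matrix(as.character(res$labels), nrow = nrow(res$predictions),
                  ncol = ncol(res$predictions), byrow = TRUE)
  correct <- colSums(res$predictions == truth)
  data.frame(sample_id = res$sample_ids, class = as.character(res$labels),
             correct = as.integer(correct),
             fraction = correct / nrow(res$predictions),
             stringsAsFactors = FALSE)
}

#' Feature selection stability across CV folds
#'
#' For each truncation depth `n`, every selected list is cut to its top `n`
#' and the mean size of the pairwise intersection over all unordered pairs
#' of lists is reported, together with the same as a fraction of `n`. The
#' mean over all C(L, 2) pairs is computed exactly via per-feature
#' occurrence counts (`sum_f m_f (m_f - 1) / 2` intersecting pairs), so 500
#' lists cost no more than a table.
#'
#' @param lists A `cv_result`, or a list of character vectors of selected
#'   feature identifiers (rank order, top first).
#' @param top_ns Truncation depths (default 20, 30, 40, 50).
#' @return Data frame with `top_n`, `mean_overlap`, `fraction`.
#' @export
stability <- function(lists, top_ns = c(20L, 30L, 40L, 50L)) {
  if (inherits(lists, "cv_result")) {
    lists <- unlist(lists$selected, recursive = FALSE)
  }
  L <- length(lists)
  if (L < 2L) abort("stability needs at least 2 selected lists")
  out <- lapply(top_ns, function(n) {
    short <- vapply(lists, length, integer(1L)) < n
    if (any(short)) {
      warning(sum(short), " list(s) shorter than ", n, "; truncated at length",
              call. = FALSE)
    }
    counts <- table(unlist(lapply(lists, utils::head, n), use.names = FALSE))
    pairs_total <- L * (L - 1) / 2
    mean_ov <- sum(counts * (counts - 1) / 2) / pairs_total
    data.frame(top_n = n, mean_overlap = mean_ov, fraction = mean_ov / n)
  })
  do.call(rbind, out)
}

#' Categorise patients as easy, hard or differential
#'
#' A patient is `easy` when correctly classified in at least
#' `easy_threshold` of rounds under every supplied result, `hard` when at
#' most `hard_threshold` under every result, and `differential` otherwise
#' (captured by some methods but not others).
#'
#' @param results List of `cv_result` objects on a shared fold plan.
#' @param easy_threshold,hard_threshold Round fractions (defaults 0.95 and
#'   0.05).
#' @return Data frame with `sample_id`, `class`, `category` and one
#'   `frac_<method>_<classifier>` column per result.
#' @export
categorize_patients <- function(results, easy_threshold = 0.95,
                                hard_threshold = 0.05) {
  fracs <- vapply(results, function(r) patient_accuracy(r)$fraction,
                  numeric(length(results[[1L]]$sample_ids)))
  fracs <- matrix(fracs, ncol = length(results))
  category <- ifelse(apply(fracs, 1L, min) >= easy_threshold, "easy",
              ifelse(apply(fracs, 1L, max) <= hard_threshold, "hard",
                     "differential"))
  out <- data.frame(sample_id = results[[1L]]$sample_ids,
                    class = as.character(results[[1L]]$labels),
                    category = category, stringsAsFactors = FALSE)
  cn <- vapply(results, function(r) paste0("frac_", r$method, "_", r$classifier),
               character(1L))
  colnames(fracs) <- make.unique(cn)
  cbind(out, as.data.frame(fracs))
}

#' Cross-method comparison report
#'
#' Collates results from several method/classifier combinations run on the
#' same fold plan into the evaluation tables: overall errors, class-specific
#' errors, selection stability, the patient accuracy matrix (rows =
#' method/classifier, cells = fraction of rounds correct) and the
#' easy/hard/differential patient categorisation.
#'
#' @param results List of `cv_result` objects sharing one fold plan.
#' @param top_ns Stability truncation depths.
#' @param easy_threshold,hard_threshold See [categorize_patients()].
#' @return An object of class `method_comparison`: list of data frames
#'   `errors`, `class_errors`, `stability`, `patient_matrix`, `patients`.
#' @export
method_comparison_report <- function(results, top_ns = c(20L, 30L, 40L, 50L),
                                     easy_threshold = 0.95,
                                     hard_threshold = 0.05) {
  if (length(results) < 2L) abort("comparison needs at least 2 results")
  ref <- results[[1L]]$plan
  same <- vapply(results, function(r) identical(r$plan$assignment, ref$assignment),
                 logical(1L))
  if (!all(same)) {
    abort("results use different fold plans; patient-level comparison requires shared folds")
  }
  errors <- do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, classifier = r$classifier,
               error = overall_error(r), stringsAsFactors = FALSE)
  }))
  class_errors <- do.call(rbind, lapply(results, function(r) {
    ce <- class_specific_error(r)
    data.frame(method = r$method, classifier = r$classifier,
               error_GP = ce[["GP"]], error_PP = ce[["PP"]],
               stringsAsFactors = FALSE)
  }))
  stab <- do.call(rbind, lapply(results, function(r) {
    cbind(data.frame(method = r$method, classifier = r$classifier,
                     stringsAsFactors = FALSE),
          stability(r, top_ns))
  }))
  pm <- t(vapply(results, function(r) patient_accuracy(r)$fraction,
                 numeric(length(ref$assignment[[1L]]))))
  rownames(pm) <- make.unique(vapply(results, function(r)
    paste(r$method, r$classifier, sep = "_"), character(1L)))
  colnames(pm) <- results[[1L]]$sample_ids
  patients <- categorize_patients(results, easy_threshold, hard_threshold)
  structure(list(errors = errors, class_errors = class_errors,
                 stability = stab, patient_matrix = pm, patients = patients),
            class = "method_comparison")
}

#' Write a comparison report to CSV files
#'
#' Writes `errors.csv`, `class_errors.csv`, `stability.csv`,
#' `patient_matrix.csv` and `patients_categorized.csv`, plus (optionally) a
#' grayscale patient-accuracy heatmap (`patient_matrix.png`; black = correct
#' in all rounds).
#'
#' @param report A `method_comparison` object.
#' @param dir Output directory (created if needed).
#' @param heatmap Also write the PNG heatmap.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, heatmap = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$errors, file.path(dir, "errors.csv"), row.names = FALSE)
  utils::write.csv(report$class_errors, file.path(dir, "class_errors.csv"),
                   row.names = FALSE)
  utils::write.csv(report$stability, file.path(dir, "stability.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(combination = rownames(report$patient_matrix),
                              report$patient_matrix, check.names = FALSE),
                   file.path(dir, "patient_matrix.csv"), row.names = FALSE)
  utils::write.csv(report$patients, file.path(dir, "patients_categorized.csv"),
                   row.names = FALSE)
  if (heatmap) {
    grDevices::png(file.path(dir, "patient_matrix.png"), width = 900,
                   height = 120 + 40 * nrow(report$patient_matrix))
    op <- graphics::par(mar = c(6, 10, 2, 1))
    m <- report$patient_matrix
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                    col = grDevices::gray(seq(1, 0, length.out = 64)),
                    zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "")
    graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.6)
    graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2, cex.axis = 0.8)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(dir)
}
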