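# Helper: small aligned simulated dataset reused across CV tests.
small_sim <- function(seed = 61, delta = 2, ...) {
  cfg <- sim_config(n_genes = 300L, n_gp = 12L, n_pp = 10L, n_hubs = 8L,
                    n_background_edges = 150L, n_de_genes = 8L, delta = delta,
                    n_de_sets = 2L, n_flip_hubs = 2L, seed = seed, ...)
  simulate_dataset(cfg)
}

test_that("fold plans are balanced, stratified and deterministic", {
  labels <- rep(c("GP", "PP"), c(5, 5))
  plan <- make_fold_plan(labels, K = 5, R = 3, seed = 1)
  for (r in 1:3) {
    expect_identical(as.integer(table(plan$assignment[[r]])), rep(2L, 5))
  }
  plan2 <- make_fold_plan(labels, K = 5, R = 3, seed = 1)
  expect_identical(plan, plan2)

  # melanoma-sized cohort: folds as equal as possible
  lab47 <- rep(c("GP", "PP"), c(25, 22))
  p47 <- make_fold_plan(lab47, K = 5, R = 10, seed = 2)
  for (r in 1:10) {
    sizes <- sort(as.integer(table(p47$assignment[[r]])), decreasing = TRUE)
    expect_identical(sizes, c(10L, 10L, 9L, 9L, 9L))
    # stratification: every fold has both classes
    expect_true(all(table(p47$assignment[[r]], lab47) > 0))
  }
})

test_that("tiny classes fall back to unstratified folds with a warning", {
  labels <- rep(c("GP", "PP"), c(12, 3))
  expect_warning(plan <- make_fold_plan(labels, K = 5, R = 2, seed = 3),
                 "unstratified")
  expect_false(plan$stratified)
  expect_error(make_fold_plan(rep("GP", 3), K = 5, R = 1, seed = 1),
               "fewer samples than folds")
})

test_that("every sample is tested exactly once per round", {
  sim <- small_sim()
  plan <- make_fold_plan(sim$data$phenotype$class, K = 5, R = 4, seed = 4)
  res <- run_cv(sim$data, "mod_t", "dlda", plan, n_features = 10)
  expect_false(anyNA(res$predictions))
  expect_identical(dim(res$predictions), c(4L, 22L))
  for (r in 1:4) {
    expect_identical(sort(unique(plan$assignment[[r]])), 1:5)
  }
})

test_that("conservation identities hold exactly", {
  sim <- small_sim(delta = 0.5)
  plan <- make_fold_plan(sim$data$phenotype$class, K = 5, R = 5, seed = 5)
  res <- run_cv(sim$data, "mod_t", "dlda", plan, n_features = 10)
  err <- overall_error(res)
  ce <- class_specific_error(res)
  tab <- table(sim$data$phenotype$class)
  expect_equal(unname(ce[["GP"]] * tab[["GP"]] + ce[["PP"]] * tab[["PP"]]) / sum(tab),
               err, tolerance = 1e-12)
  pa <- patient_accuracy(res)
  expect_equal(1 - mean(pa$correct) / nrow(res$predictions), err, tolerance = 1e-12)
  expect_true(all(pa$correct >= 0 & pa$correct <= nrow(res$predictions)))
})

test_that("degenerate accuracy cases behave", {
  sim <- small_sim(seed = 62, delta = 6)
  plan <- make_fold_plan(sim$data$phenotype$class, K = 5, R = 3, seed = 6)
  res <- run_cv(sim$data, "mod_t", "dlda", plan, n_features = 8)
  expect_lt(overall_error(res), 0.1)
  pa <- patient_accuracy(res)
  expect_true(any(pa$correct == 3L))       # easy samples at full count
})

test_that("CV is deterministic for dlda given plan and seed", {
  sim <- small_sim(seed = 63)
  plan <- make_fold_plan(sim$data$phenotype$class, K = 5, R = 2, seed = 7)
  r1 <- run_cv(sim$data, "netrank", "dlda", plan, n_features = 10)
  r2 <- run_cv(sim$data, "netrank", "dlda", plan, n_features = 10)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$selected, r2$selected)
})

test_that("no leakage: corrupting the test fold leaves selection and model unchanged", {
  sim <- small_sim(seed = 64)
  d <- sim$data
  plan <- make_fold_plan(d$phenotype$class, K = 5, R = 1, seed = 8)
  res_a <- run_cv(d, "mod_t", "dlda", plan, n_features = 10)
  test1 <- which(plan$assignment[[1L]] == 1L)
  # corrupt the labels of fold 1's test samples: they are never used when
  # fold 1 is the test fold, so its selection and predictions must not move
  # (other folds legitimately change, since these samples train them)
  d_bad <- d
  lv <- levels(d_bad$phenotype$class)
  d_bad$phenotype$class[test1] <- factor(
    ifelse(d$phenotype$class[test1] == "GP", "PP", "GP"), levels = lv)
  res_b <- run_cv(d_bad, "mod_t", "dlda", plan, n_features = 10)
  expect_identical(res_a$selected[[1L]][[1L]], res_b$selected[[1L]][[1L]])
  expect_identical(res_a$predictions[1L, test1], res_b$predictions[1L, test1])
  # corrupting test-fold expression likewise leaves the selection alone
  d_bad2 <- d
  set.seed(999)
  d_bad2$expression[, test1] <- matrix(rnorm(nrow(d$expression) * length(test1), 0, 50),
                                       ncol = length(test1))
  res_c <- run_cv(d_bad2, "mod_t", "dlda", plan, n_features = 10)
  expect_identical(res_a$selected[[1L]][[1L]], res_c$selected[[1L]][[1L]])
})

test_that("run_cv validates its inputs", {
  sim <- small_sim(seed = 65)
  plan <- make_fold_plan(sim$data$phenotype$class, K = 5, R = 1, seed = 9)
  expect_error(run_cv(sim$data, "gsea", "dlda", plan), "arg")
  bad_plan <- make_fold_plan(rep(c("GP", "PP"), 5), K = 5, R = 1, seed = 9)
  expect_error(run_cv(sim$data, "mod_t", "dlda", bad_plan), "different cohort")
})

# --- stability --------------------------------------------------------------

test_that("stability hits its extremes and matches pair enumeration", {
  same <- replicate(6, sprintf("f%02d", 1:50), simplify = FALSE)
  st <- stability(same)
  expect_equal(st$mean_overlap, c(20, 30, 40, 50))
  expect_equal(st$fraction, rep(1, 4))

  disjoint <- list(sprintf("a%d", 1:20), sprintf("b%d", 1:20), sprintf("c%d", 1:20))
  st0 <- stability(disjoint, top_ns = 20)
  expect_equal(st0$mean_overlap, 0)

  lists <- list(sprintf("f%d", 1:5), sprintf("f%d", 1:5), sprintf("f%d", 4:8))
  st3 <- suppressWarnings(stability(lists, top_ns = 5))
  expect_equal(st3$mean_overlap, 3)            # pairs: 5, 2, 2
  expect_equal(st3$fraction, 3 / 5)

  # brute-force enumeration over random lists
  set.seed(66)
  rnd <- replicate(7, sample(sprintf("f%02d", 1:30), 10), simplify = FALSE)
  st_r <- suppressWarnings(stability(rnd, top_ns = 10))
  pairs <- combn(7, 2)
  brute <- mean(apply(pairs, 2L, function(p)
    length(intersect(rnd[[p[1L]]], rnd[[p[2L]]]))))
  expect_equal(st_r$mean_overlap, brute)

  expect_warning(stability(list(sprintf("f%d", 1:5), sprintf("f%d", 1:5)),
                           top_ns = 10), "shorter")
  expect_error(stability(list(letters)), "at least 2")
})

# --- comparison report ------------------------------------------------------

# Construct a toy cv_result without running CV.
toy_cv_result <- function(preds, labels, method = "mod_t", classifier = "dlda",
                          plan = NULL) {
  structure(list(method = method, classifier = classifier,
                 predictions = preds,
                 selected = list(list(colnames(preds)[1:2], colnames(preds)[1:2])),
                 labels = factor(labels, levels = c("GP", "PP")),
                 sample_ids = colnames(preds), n_features = 2L,
                 plan = if (is.null(plan)) list(assignment = list(seq_len(ncol(preds)))) else plan),
            class = "cv_result")
}

test_that("identical methods give identical report rows and no differential patients", {
  labels <- rep(c("GP", "PP"), each = 3)
  preds <- matrix(rep(c("GP", "GP", "PP", "PP", "PP", "GP"), 4), nrow = 4,
                  byrow = TRUE, dimnames = list(NULL, sprintf("s%d", 1:6)))
  a <- toy_cv_result(preds, labels, method = "mod_t")
  b <- toy_cv_result(preds, labels, method = "netrank")
  rep_ <- method_comparison_report(list(a, b), top_ns = 2)
  expect_equal(rep_$errors$error[1L], rep_$errors$error[2L])
  expect_identical(unname(rep_$patient_matrix[1L, ]), unname(rep_$patient_matrix[2L, ]))
  expect_false(any(rep_$patients$category == "differential"))
})

test_that("complementary methods make all non-degenerate patients differential", {
  labels <- rep(c("GP", "PP"), each = 3)
  right <- matrix(rep(labels, 5), nrow = 5, byrow = TRUE,
                  dimnames = list(NULL, sprintf("s%d", 1:6)))
  wrong <- ifelse(right == "GP", "PP", "GP")
  a <- toy_cv_result(right, labels, method = "mod_t")
  b <- toy_cv_result(wrong, labels, method = "taylor")
  rep_ <- method_comparison_report(list(a, b), top_ns = 2)
  expect_true(all(rep_$patients$category == "differential"))
})

test_that("reports refuse differing fold plans and write all tables", {
  labels <- rep(c("GP", "PP"), each = 3)
  preds <- matrix(rep(labels, 2), nrow = 2, byrow = TRUE,
                  dimnames = list(NULL, sprintf("s%d", 1:6)))
  a <- toy_cv_result(preds, labels, plan = list(assignment = list(1:6)))
  b <- toy_cv_result(preds, labels, plan = list(assignment = list(6:1)))
  expect_error(method_comparison_report(list(a, b)), "shared folds")

  b2 <- toy_cv_result(preds, labels, method = "netrank",
                      plan = list(assignment = list(1:6)))
  rep_ <- method_comparison_report(list(a, b2), top_ns = 2)
  dir <- withr::local_tempdir()
  write_report(rep_, dir)
  for (f in c("errors.csv", "class_errors.csv", "stability.csv",
              "patient_matrix.csv", "patients_categorized.csv")) {
    expect_true(file.exists(file.path(dir, f)))
  }
})
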