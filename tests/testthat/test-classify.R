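test_that("null genes score F ~ 0 and p ~ 1; zero-variance genes are flagged last", {
  groups <- factor(rep(c("S", "MS", "MR", "R"), each = 5),
                   levels = sensitivity_levels())
  within <- withr::with_seed(41, stats::rnorm(20))
  expr <- rbind(
    flat = rep(c(1, 2, 3, 4), each = 5) * 0 + within, # identical group means
    const = rep(1, 20),                               # no variance at all
    strong = rep(c(0, 2, 4, 6), each = 5) + 0.01 * within)
  ranking <- rank_genes(expr, groups)
  expect_equal(ranking$gene[1], "strong")
  flat <- ranking[ranking$gene == "flat", ]
  expect_lt(flat$f_statistic, 3)
  expect_gt(flat$p_value, 0.05)
  const <- ranking[ranking$gene == "const", ]
  expect_true(const$degenerate)
  expect_equal(const$rank, 3L)
})

test_that("with two groups the F statistic is the squared t statistic", {
  groups <- factor(rep(c("other", "resistant"), times = c(12, 8)))
  expr <- withr::with_seed(42, matrix(stats::rnorm(50 * 20), nrow = 50,
                                      dimnames = list(sprintf("g%02d", 1:50),
                                                      NULL)))
  ranking <- rank_genes(expr, groups)
  t2 <- apply(expr, 1, function(y) {
    unname(stats::t.test(y ~ groups, var.equal = TRUE)$statistic^2)
  })
  expect_equal(unname(ranking$f_statistic[match(names(t2), ranking$gene)]),
               unname(t2), tolerance = 1e-10)
})

test_that("ranking is invariant to gene order and validates inputs", {
  sim <- simulate_expression(expression_design(n_genes = 60, seed = 43))
  base <- rank_genes(sim$expr, sim$labels$group)
  perm <- withr::with_seed(44, sample(nrow(sim$expr)))
  shuffled <- rank_genes(sim$expr[perm, ], sim$labels$group)
  expect_identical(base$gene, shuffled$gene)
  expect_error(rank_genes(sim$expr, sim$labels$group[-1]), "one label per")
  tiny <- factor(c(rep("A", ncol(sim$expr) - 1), "B"))
  expect_error(rank_genes(sim$expr, tiny), ">= 2 samples")
  bad <- sim$expr; bad[1, 1] <- NA
  expect_error(rank_genes(bad, sim$labels$group), "missing")
})

test_that("moderated ranking shrinks small-variance artefacts but keeps signal", {
  sim <- simulate_expression(expression_design(n_genes = 300, seed = 45))
  plain <- rank_genes(sim$expr, sim$labels$group)
  mod <- rank_genes(sim$expr, sim$labels$group, moderated = TRUE)
  expect_gte(mean(mod$gene[1:40] %in% sim$informative), 0.8)
  # shrinkage reorders mildly: strongly correlated but not identical ranks
  j <- match(plain$gene, mod$gene) # plain-rank position -> moderated rank
  expect_gt(stats::cor(seq_along(j), j, method = "spearman"), 0.9)
  expect_false(identical(plain$f_statistic, mod$f_statistic[j]))
})

test_that("separable data classify perfectly at any sufficient panel size", {
  design <- expression_design(n_genes = 60, n_informative = 10,
                              samples_per_group = c(5, 5, 5, 5),
                              group_shift = c(0, 3, 6, 9),
                              noise_sd = 0.05, seed = 46)
  sim <- simulate_expression(design)
  ev <- suppressWarnings( # 5-member classes span only half the test folds
    evaluate_panels(sim$expr, sim$labels$group, sizes = c(10, 20),
                    folds = 10, repeats = 2, seed = 47))
  expect_true(all(ev$mean_accuracy == 1))
  expect_true(all(ev$balanced_accuracy == 1))
})

test_that("label-permuted data score at chance with selection inside the CV loop", {
  design <- expression_design(n_genes = 200, n_informative = 40,
                              samples_per_group = c(10, 10, 10, 10),
                              group_shift = c(0, 2, 4, 6), seed = 48)
  sim <- simulate_expression(design)
  accs <- vapply(1:20, function(i) {
    permuted <- withr::with_seed(100 + i, sample(sim$labels$group))
    ev <- evaluate_panels(sim$expr, permuted, sizes = 10, folds = 10,
                          repeats = 1, selection = "inside_cv",
                          seed = 200 + i)
    ev$mean_accuracy
  }, numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.25), 3 * se + 1e-12)
})

test_that("a panel-sized informative design is classified with high accuracy", {
  sim <- simulate_expression(expression_design(seed = 49)) # 38 samples, 3-13/group
  ev <- suppressWarnings( # 3-member R cohort cannot reach every test fold
    evaluate_panels(sim$expr, sim$labels$group, sizes = c(10, 20, 40),
                    folds = 10, repeats = 3, seed = 50))
  expect_gte(max(ev$mean_accuracy), 0.8)
})

test_that("signature selection maximises accuracy with parsimony tie-break", {
  evals <- tibble::tibble(panel_size = c(10L, 37L, 100L),
                          mean_accuracy = c(0.7, 0.86, 0.86),
                          balanced_accuracy = c(0.7, 0.86, 0.86))
  expect_equal(select_signature(evals)$panel_size, 37L)
  expect_equal(select_signature(evals[2, ])$panel_size, 37L)
  monotone <- tibble::tibble(panel_size = c(4L, 8L, 16L),
                             mean_accuracy = c(0.5, 0.6, 0.7))
  expect_equal(select_signature(monotone)$panel_size, 16L)
  expect_error(select_signature(evals[0, ]), "non-empty")
})

test_that("binary resistant-vs-rest mode reports majority-rate nulls honestly", {
  design <- expression_design(n_genes = 150, n_informative = 30,
                              group_shift = c(0, 0, 0, 4), seed = 51)
  sim <- simulate_expression(design) # 38 samples, 3 in R
  binary <- resistant_labels(sim$labels$group)
  expect_equal(sum(binary == "resistant"), 3)
  # separable resistant group: balanced accuracy reaches 1
  ev <- suppressWarnings(evaluate_panels(sim$expr, binary, sizes = 10,
                                         folds = 10, repeats = 2, seed = 52))
  expect_gte(ev$balanced_accuracy, 0.99)
  # permuted-label null: plain accuracy hugs the majority rate (35/38),
  # balanced accuracy collapses toward 0.5 or below
  null_accs <- vapply(1:10, function(i) {
    permuted <- withr::with_seed(300 + i, sample(binary))
    ev <- suppressWarnings(
      evaluate_panels(sim$expr, permuted, sizes = 10, folds = 10,
                      repeats = 1, selection = "inside_cv", seed = 400 + i))
    c(ev$mean_accuracy, ev$balanced_accuracy)
  }, numeric(2))
  expect_equal(mean(null_accs[1, ]), 35 / 38, tolerance = 0.05)
  expect_lt(mean(null_accs[2, ]), 0.7)
})

test_that("fold assignment is stratified and seed-reproducible", {
  sim <- simulate_expression(expression_design(n_genes = 80, seed = 53))
  a <- suppressWarnings(evaluate_panels(sim$expr, sim$labels$group, sizes = 10,
                                        folds = 10, repeats = 2, seed = 54))
  b <- suppressWarnings(evaluate_panels(sim$expr, sim$labels$group, sizes = 10,
                                        folds = 10, repeats = 2, seed = 54))
  expect_identical(a$mean_accuracy, b$mean_accuracy)
  expect_identical(a$repeat_accuracies, b$repeat_accuracies)
})
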