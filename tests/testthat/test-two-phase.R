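# Feature assembly, model training, attributions, directionality and the
# correlation shift.

test_that("build_features doubles columns with rank transforms", {
  set.seed(1)
  raw <- data.frame(matrix(rnorm(50 * 10), 50, 10))
  names(raw) <- sprintf("f%02d", 1:10)
  ft <- build_features("initial", raw)
  expect_equal(ncol(ft$x), 20L)
  expect_true(all(paste0("rank.", names(raw)) %in% colnames(ft$x)))
  # rank columns are invariant under monotone rescaling of the raw values
  raw2 <- as.data.frame(lapply(raw, function(v) exp(2 * v)))
  ft2 <- build_features("initial", raw2)
  expect_equal(ft$x[, 11:20], ft2$x[, 11:20], ignore_attr = TRUE)
  # permuting gene order leaves each gene's row unchanged
  rownames(raw) <- sprintf("g%02d", 1:50)
  fta <- build_features("initial", raw)
  ftb <- build_features("initial", raw[sample(50), ])
  expect_equal(fta$x[rownames(ftb$x), ], ftb$x)
})

test_that("differential features use pseudo-counted fold changes", {
  mu <- data.frame(connectivity = c(0, 3), promoter_methylation = c(10, 20),
                   accessibility = c(2, 4))
  st <- data.frame(connectivity = c(0, 1), promoter_methylation = c(30, 20),
                   accessibility = c(2, 8))
  ft <- build_features("differential", mu, stage = st)
  # connectivity 0 -> 0 with pseudo-count: log2(1/1) = 0
  expect_equal(unname(ft$x[1, "connectivity"]), 0)
  expect_equal(unname(ft$x[2, "connectivity"]), log2(2 / 4))
  expect_equal(unname(ft$x[1, "promoter_methylation"]), log2(31 / 11))
  expect_equal(unname(ft$x[2, "accessibility"]), 1)
  expect_error(build_features("differential", mu), "stage")
})

test_that("training is seed-deterministic and selects the best epoch", {
  coh <- simulate_feature_cohort(n_genes = 1500, n_tf = 6, n_types = 2,
                                 seed = 3)
  ft <- build_features("initial", coh$features, target = coh$target)
  m1 <- two_phase_fit(ft, test_n = 400, epochs = 8, hidden = c(16, 8),
                      seed = 21)
  m2 <- two_phase_fit(ft, test_n = 400, epochs = 8, hidden = c(16, 8),
                      seed = 21)
  expect_identical(m1$test_idx, m2$test_idx)
  expect_identical(m1$selected_epoch, m2$selected_epoch)
  expect_identical(m1$predictions, m2$predictions)
  expect_equal(m1$mlp$history[m1$selected_epoch], min(m1$mlp$history))
  # a different seed changes the split
  m3 <- two_phase_fit(ft, test_n = 400, epochs = 8, hidden = c(16, 8),
                      seed = 22)
  expect_false(identical(m1$test_idx, m3$test_idx))
  # print / predict / residuals surface
  expect_output(print(m1), "held-out r")
  expect_equal(length(predict(m1)), nrow(ft$x))
  expect_equal(length(residuals(m1)), nrow(ft$x))
})

test_that("the model learns a planted signal but not pure noise", {
  coh <- simulate_feature_cohort(n_genes = 4000, n_tf = 8, n_types = 2,
                                 seed = 5)
  ft <- build_features("initial", coh$features, target = coh$target)
  m <- two_phase_fit(ft, test_n = 1000, epochs = 20, hidden = c(32, 16, 8),
                     seed = 7)
  expect_gt(m$r, 0.6)
  set.seed(99)
  noise <- rnorm(4000)
  mnull <- two_phase_fit(ft, target = noise, test_n = 1000, epochs = 20,
                         hidden = c(32, 16, 8), seed = 7)
  expect_lt(abs(mnull$r), 0.12)
})

test_that("attributions find planted effects and agree with exact Shapley", {
  set.seed(11)
  n <- 2000
  x <- data.frame(x1 = rlnorm(n, 0, 0.5), x2 = rnorm(n), x3 = rnorm(n))
  y <- 2 * x$x1 - 1.5 * x$x2 + rnorm(n, 0, 0.3)   # x3 unused
  ft <- build_features("initial", x)
  m <- two_phase_fit(ft, target = y, test_n = 500, epochs = 40,
                     hidden = c(8, 4), dropout = 0, seed = 13)
  fi <- feature_importance(m, n_perm = 5, seed = 1)
  imp <- setNames(fi$importance, fi$feature)
  # combined (raw + rank) importance: the unused feature sits at the noise
  # floor, well below each informative feature
  comb <- sapply(c("x1", "x2", "x3"),
                 function(f) imp[[f]] + imp[[paste0("rank.", f)]])
  expect_gt(min(comb[c("x1", "x2")]), 3 * comb[["x3"]])
  # attribution-value association carries the planted effect signs
  expect_gt(fi$association[fi$feature == "x1"], 0.5)
  expect_lt(fi$association[fi$feature == "x2"], -0.5)
  # sign agreement with the exact Shapley oracle on held-out rows
  take <- seq_len(60)
  rows <- m$x[m$test_idx[take], , drop = FALSE]
  phi_shap <- shapley_exact(function(z) predict(m, z), rows)
  phi_perm <- attr(feature_importance(m, n_perm = 10, seed = 2),
                   "attributions")
  for (f in c("x1", "x2")) {
    j <- match(f, colnames(m$x))
    expect_gt(cor(phi_shap[, j], phi_perm[take, j]), 0.7)
  }
})

test_that("exact Shapley matches the closed form for a linear model", {
  f <- function(z) 2 * z[, 1] - 3 * z[, 2] + 0.5 * z[, 3]
  set.seed(2)
  x <- matrix(rnorm(30), 10, 3)
  phi <- shapley_exact(f, x)
  expected <- sweep(x, 2, colMeans(x)) %*% diag(c(2, -3, 0.5))
  expect_equal(phi, expected, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(shapley_exact(f, matrix(0, 2, 13)), "12 features")
})

test_that("directionality scores average coded calls", {
  expect_equal(directionality_score(matrix(c(1, 1, 1, -1), 1)), 0.5)
  expect_equal(directionality_score(matrix(0, 2, 4)), c(0, 0))
  expect_equal(directionality_score(matrix(1, 1, 5)), 1)
})

test_that("de_calls applies both the FDR and fold gates", {
  set.seed(8)
  mk <- function(mu_ref, mu_cond) {
    t(replicate(60, c(rnorm(4, mu_ref, 0.05), rnorm(4, mu_cond, 0.05))))
  }
  tpm <- rbind(mk(10, 30), mk(10, 10), mk(30, 10), mk(10, 12))
  group <- rep(c("ref", "cond"), each = 4)
  calls <- de_calls(tpm, group)
  expect_true(all(calls[1:60] == 1))
  expect_true(all(calls[61:120] == 0))
  expect_true(all(calls[121:180] == -1))
  # 1.2-fold change fails the 1.3-fold gate even when significant
  expect_true(all(calls[181:240] == 0))
})

test_that("direction prediction: AUC extremes and accuracy bins", {
  calls <- matrix(c(1, 1, -1, -1, 1, 1, -1, -1), 4, 2)
  perfect <- c(2, 1, -1, -2)
  ev <- direction_prediction_eval(perfect, calls)
  expect_equal(ev$auc, 1)
  set.seed(3)
  calls_big <- matrix(sample(c(-1, 1), 4000, replace = TRUE), 1000, 4)
  ev2 <- direction_prediction_eval(rnorm(1000), calls_big)
  expect_lt(abs(ev2$auc - 0.5), 0.05)
  expect_error(direction_prediction_eval(1:3, matrix(0, 3, 2)),
               "nonzero")
})

test_that("correlation shift behaves at the extremes", {
  set.seed(4)
  conn <- cbind(mucosa = runif(300, 1, 5), polyp = runif(300, 1, 5))
  expr_m <- conn[, 1]^2   # exact monotone map
  expr_p <- runif(300, 1, 5)
  out <- correlation_shift(conn, cbind(mucosa = expr_m, polyp = expr_p))
  expect_equal(unname(out$rho["mucosa"]), 1)
  expect_lt(abs(out$rho["polyp"]), 0.15)
  expect_equal(unname(out$delta["mucosa"]), 0)
})

test_that("the saturating cohort shifts correlation toward attenuated
           stages", {
  coh <- simulate_feature_cohort(n_genes = 3000, seed = 6)
  out <- correlation_shift(coh$conn_by_stage, coh$expr_by_stage)
  expect_gt(out$rho["polyp"], out$rho["mucosa"])
  expect_gt(out$rho["adenocarcinoma"], out$rho["mucosa"])
})
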