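test_that("the FIR band-pass meets its frequency-response contract", {
  t <- seq_len(2000) / 500
  pass <- matrix(sin(2 * pi * 10 * t), 1)
  stop_ <- matrix(sin(2 * pi * 2 * t), 1)
  fp <- fir_bandpass(pass, sfreq = 500)
  fs <- fir_bandpass(stop_, sfreq = 500)
  mid <- 500:1500
  expect_equal(stats::sd(fp[mid]) / stats::sd(pass[mid]), 1,
               tolerance = 0.05)
  expect_lt(20 * log10(stats::sd(fs[mid]) / stats::sd(stop_[mid])), -40)
  # zero net phase: impulse response symmetric about the impulse
  imp <- matrix(0, 1, 4001); imp[2001] <- 1
  fi <- fir_bandpass(imp, sfreq = 500)
  expect_lt(max(abs(fi[1, ] - rev(fi[1, ]))), 1e-12)
  expect_error(fir_bandpass(pass, hi = 300, sfreq = 500), "Nyquist")
})

test_that("epoching returns the labelled trials in event order", {
  rec <- mi_fixture()
  tr <- epoch_trials(rec, 0, 4)
  expect_equal(dim(tr$epochs), c(36, 58, 2000))
  expect_identical(tr$labels, rec$events$label)
  tr2 <- epoch_trials(rec, -3, 4)
  expect_equal(dim(tr2$epochs)[3], 3500)
  empty <- raw_recording(matrix(0, 1, 1000), 500, "CZ")
  expect_equal(dim(epoch_trials(empty)$epochs)[1], 0)
  bad <- raw_recording(matrix(0, 1, 1000), 500, "CZ",
                       events = data.frame(onset = 900, duration = 0,
                                           label = "left"))
  expect_error(epoch_trials(bad, 0, 4), "trial 1")
})

test_that("CSP filters match the closed-form eigen oracle on 2-channel toys", {
  # class covariances diag(1, eps) vs diag(eps, 1): whitened composite is
  # a multiple of the identity, so the discriminative filters are exactly
  # the coordinate axes regardless of shrinkage
  eps <- 1e-3
  mk_trials <- function(sds, n = 6) {
    lapply(seq_len(n), function(i) diag(sds) / sum(sds))
  }
  covs <- c(mk_trials(c(1, eps)), mk_trials(c(eps, 1)))
  labels <- rep(c("a", "b"), each = 6)
  model <- alphanft:::csp_fit_from_covs(covs, labels, n_per_problem = 2)
  F <- model$filters[["a"]]
  F <- F / sqrt(rowSums(F^2))
  # each filter aligns with a coordinate axis up to sign
  align <- abs(F)
  expect_lt(min(apply(align, 1, max)) - 1, 1e-6)
  expect_lt(max(apply(align, 1, min)), 1e-6)
  # identical covariances: whitened eigenvalues all 1/2, nothing to find
  same <- c(mk_trials(c(1, 1)), mk_trials(c(1, 1)))
  m2 <- alphanft:::csp_fit_from_covs(same, labels, n_per_problem = 2)
  ev <- eigen(diag(2) / 2, symmetric = TRUE)$values
  expect_equal(ev, c(0.5, 0.5))
  # one trial in a class errors
  arr <- array(stats::rnorm(3 * 2 * 100), c(3, 2, 100))
  expect_error(csp_fit(arr, c("a", "a", "b")), "2 trials")
})

test_that("log-variance features scale additively and floor zero epochs", {
  set.seed(9)
  arr <- array(stats::rnorm(8 * 4 * 200), c(8, 4, 200))
  labels <- rep(c("a", "b"), each = 4)
  arr[labels == "b", 2, ] <- arr[labels == "b", 2, ] * 4
  model <- csp_fit(arr, labels, n_per_problem = 2)
  f1 <- csp_features(model, arr)
  expect_equal(csp_features(model, arr * 2) - f1,
               matrix(log(4), nrow(f1), ncol(f1)), tolerance = 1e-12)
  expect_error(csp_features(model, array(0, c(1, 4, 200))), "zero variance")
  expect_error(csp_features(model, arr[, 1:3, , drop = FALSE]), "mismatch")
})

test_that("cross-validation decodes a separable subject and is honest at chance", {
  tr <- mi_trials_filtered()
  acc <- evaluate_cv(tr, "three_class", seed = 1)
  expect_gte(acc, 0.85)                    # strong-ERD low-noise subject
  expect_gte(evaluate_cv(tr, "L_vs_R", seed = 1), 0.85)
  # label permutation: mean accuracy near chance
  perm <- tr
  accs <- vapply(1:6, function(s) {
    set.seed(s)
    perm$labels <<- sample(tr$labels)
    evaluate_cv(perm, "three_class", seed = s)
  }, 0)
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / 3), max(3 * se, 0.08))
  expect_error(evaluate_cv(trial_set(tr$epochs[1:12, , ],
                                     tr$labels[1:12], 500)),
               "at least")
})

test_that("held-out trials cannot leak into training-fold CSP filters", {
  tr <- mi_trials_filtered()
  train_idx <- which(tr$labels != "idle")[1:20]
  fit1 <- csp_fit(tr$epochs[train_idx, , , drop = FALSE],
                  tr$labels[train_idx])
  # inflate a trial outside the training fold; filters must be unchanged
  inflated <- tr$epochs
  inflated[36, , ] <- inflated[36, , ] * 100
  fit2 <- csp_fit(inflated[train_idx, , , drop = FALSE],
                  tr$labels[train_idx])
  expect_identical(fit1$filters, fit2$filters)
})

test_that("the SVM reproduces the reference implementation on a fixture", {
  # frozen from scikit-learn SVC(C = 1, rbf, median-heuristic gamma)
  set.seed(42)
  X <- rbind(matrix(stats::rnorm(40, -1, 0.7), 20, 2),
             matrix(stats::rnorm(40, 1, 0.7), 20, 2))
  y <- rep(c("0", "1"), each = 20)
  Xte <- as.matrix(expand.grid(seq(-2, 2, by = 1), seq(-2, 2, by = 1)))
  expect_equal(median_heuristic_gamma(X), 0.1244932, tolerance = 1e-6)
  fit <- svm_fit(X, y, seed = 1)
  expect_identical(paste(predict(fit, Xte), collapse = ""),
                   "0000000001000110111111111")
  # three-class OVR: separable gaussian blobs
  X3 <- rbind(matrix(stats::rnorm(40, -3, 0.5), 20, 2),
              matrix(stats::rnorm(40, 0, 0.5), 20, 2),
              matrix(stats::rnorm(40, 3, 0.5), 20, 2))
  y3 <- rep(c("a", "b", "c"), each = 20)
  fit3 <- svm_fit(X3, y3, seed = 1)
  expect_gte(mean(predict(fit3, X3) == y3), 0.95)
})
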