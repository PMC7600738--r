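# Small shared training fixture: clean substructure separation.
make_sep_data <- function(n_per_class = 40, seed = 11) {
  ds <- generate_dataset(n_per_class, seed = seed, signal = "substructure",
                         size_range = c(150, 900))
  ds <- deduplicate(prepare_dataset(ds), seed = 2)
  sp <- split_train_test(ds, 0.5, seed = 3)
  sig <- map4_fingerprint(dplyr::bind_rows(sp$train, sp$test))
  list(train = sp$train, test = sp$test, sig = sig)
}

small_cv <- function(seed = 5) {
  cv_config(C_grid = c(1, 10), k_grid = c(3L, 5L), gamma_grid = c(0.1, 1),
            seed = seed)
}

test_that("kernel matrix is the pairwise similarity with unit diagonal", {
  f <- map4_fingerprint(c(a = "CCO", b = "CCCO", c = "c1ccccc1"))
  K <- kernel_matrix(f)
  expect_equal(dim(K), c(3, 3))
  expect_equal(diag(K), c(a = 1, b = 1, c = 1))
  expect_identical(K, t(K))
  expect_equal(K["a", "b"], estimate_similarity(f["a", ], f["b", ]))
  # 1x1 case
  expect_equal(unname(kernel_matrix(f[1, , drop = FALSE])), matrix(1))
  expect_error(kernel_matrix(f, f[, 1:10]), "length mismatch")
})

test_that("MAP4 SVM separates constructed classes and refuses degenerate input", {
  dat <- make_sep_data()
  m <- train_map4_svm(dat$train, dat$sig, cv = small_cv())
  # training-set fit is essentially perfect on separable classes
  pr_tr <- predict_origin(m, dat$train)
  expect_gte(metric_suite(dat$train$origin, pr_tr$p_bacterial)$roc_auc, 0.99)
  # held-out performance remains high
  pr_te <- predict_origin(m, dat$test)
  expect_gte(metric_suite(dat$test$origin, pr_te$p_bacterial)$roc_auc, 0.95)
  # probabilities are complementary and labels follow the 0.5 rule
  expect_equal(pr_te$p_fungal + pr_te$p_bacterial, rep(1, nrow(pr_te)))
  expect_equal(pr_te$label, ifelse(pr_te$p_bacterial >= 0.5, "bacterium", "fungus"))

  single <- dat$train[dat$train$origin == "bacterium", ]
  expect_error(train_map4_svm(single, dat$sig, cv = small_cv()), "single-class")
  bad <- dat$train
  bad$origin[1] <- "plant"
  expect_error(train_map4_svm(bad, dat$sig, cv = small_cv()), "bacterium")
})

test_that("k-NN trivial geometries give the forced probabilities", {
  dat <- make_sep_data()
  m <- train_map4_knn(dat$train, dat$sig, cv = cv_config(k_grid = 3L,
                                                         C_grid = 1, seed = 5))
  # a query identical to a training molecule reports it as NN at distance 0
  q <- dat$train[1, ]
  pr <- predict_origin(m, q)
  expect_equal(pr$nn_id, q$compound_id)
  expect_equal(pr$nn_jaccard_distance, 0)

  # equidistant two-point training set, k = 2: probability exactly 0.5
  two <- tibble::tibble(compound_id = c("tb", "tf"),
                        smiles_canonical = canonicalize_strip_stereo(c("CCO", "CCO")),
                        origin = c("bacterium", "fungus"))
  sig2 <- map4_fingerprint(two)
  m2 <- train_map4_knn(two, sig2, cv = cv_config(k_grid = 1L, C_grid = 1,
                                                 folds = 2, seed = 1))
  m2$k <- 2L
  pr2 <- predict_origin(m2, tibble::tibble(compound_id = "q",
                                           smiles_raw = "CCO"))
  expect_equal(pr2$p_bacterial, 0.5)

  expect_error(train_map4_knn(two, sig2, cv = cv_config(k_grid = 50L, C_grid = 1,
                                                        seed = 1)),
               "exceeds")
})

test_that("physchem SVM scales features on the training set and learns property signal", {
  # classes differing only in MW distribution (means 300 vs 900, sd 50)
  ds <- generate_dataset(40, seed = 19, signal = "property",
                         property_means = c(300, 900), property_sd = 50)
  ds <- deduplicate(prepare_dataset(ds), seed = 2)
  sp <- split_train_test(ds, 0.5, seed = 3)
  suppressWarnings({
    tr <- joback_boiling_point(compute_descriptors(sp$train))
    te <- joback_boiling_point(compute_descriptors(sp$test))
  })
  m <- train_physchem_svm(tr, cv = small_cv())
  # stored training features have mean ~0, sd ~1 per column
  expect_true(all(abs(colMeans(m$train_features)) < 1e-8))
  expect_true(all(abs(apply(m$train_features, 2, stats::sd) - 1) < 1e-8))
  pr <- suppressWarnings(predict_origin(m, te))
  expect_gte(metric_suite(sp$test$origin, pr$p_bacterial)$roc_auc, 0.95)

  # constant features are dropped with a warning
  tr2 <- tr
  tr2$tpsa <- 5
  expect_warning(train_physchem_svm(tr2, cv = small_cv()), "constant")
})

test_that("training is deterministic under a fixed seed", {
  dat <- make_sep_data(n_per_class = 25)
  m1 <- train_map4_svm(dat$train, dat$sig, cv = small_cv(seed = 7))
  m2 <- train_map4_svm(dat$train, dat$sig, cv = small_cv(seed = 7))
  expect_identical(m1$C, m2$C)
  expect_identical(m1$platt, m2$platt)
  p1 <- predict_origin(m1, dat$test)
  p2 <- predict_origin(m2, dat$test)
  expect_identical(p1$p_bacterial, p2$p_bacterial)
})

test_that("inverse-frequency class weights raise minority recall under 9:1 imbalance", {
  ds <- generate_dataset(60, seed = 23, signal = "substructure",
                         size_range = c(150, 900))
  ds <- deduplicate(prepare_dataset(ds), seed = 2)
  # keep all fungus, a ninth as many bacterium -> bacterium is the minority
  bact <- ds[ds$origin == "bacterium", ][1:6, ]
  fung <- ds[ds$origin == "fungus", ]
  imb <- dplyr::bind_rows(bact, fung)
  sp <- split_train_test(imb, 0.5, seed = 3)
  sig <- map4_fingerprint(dplyr::bind_rows(sp$train, sp$test))
  if (length(unique(sp$train$origin)) < 2 ||
      sum(sp$train$origin == "bacterium") < 2) {
    skip("split left too few minority molecules to train on")
  }
  m_w <- train_map4_svm(sp$train, sig, cv = cv_config(C_grid = 10, seed = 5))
  # same model with flat weights
  m_u <- m_w
  y <- factor(sp$train$origin, levels = c("fungus", "bacterium"))
  K <- kernel_matrix(sig[sp$train$compound_id, , drop = FALSE])
  m_u$fit <- map4np:::fit_kernel_svc(K, y, C = 10,
                                     weights = c(fungus = 1, bacterium = 1))
  pr_w <- predict_origin(m_w, sp$test)
  pr_u <- predict_origin(m_u, sp$test)
  rec <- function(pr) {
    truth <- sp$test$origin == "bacterium"
    if (!any(truth)) return(NA_real_)
    sum(pr$label == "bacterium" & truth) / sum(truth)
  }
  expect_gte(rec(pr_w), rec(pr_u))
})

test_that("prediction handles unparseable SMILES as per-row errors", {
  dat <- make_sep_data(n_per_class = 15)
  m <- train_map4_svm(dat$train, dat$sig, cv = small_cv())
  mixed <- tibble::tibble(compound_id = c("ok", "bad"),
                          smiles_raw = c("CCO", "C1CC"))
  pr <- predict_origin(m, mixed)
  expect_true(is.na(pr$p_bacterial[2]))
  expect_match(pr$error[2], "parse")
  expect_false(is.na(pr$p_bacterial[1]))
})

test_that("model bundles round-trip and refuse incompatible versions", {
  dat <- make_sep_data(n_per_class = 15)
  m <- train_map4_svm(dat$train, dat$sig, cv = small_cv())
  tf <- withr::local_tempfile(fileext = ".rds")
  save_origin_model(m, tf)
  back <- load_origin_model(tf)
  expect_identical(back$C, m$C)
  expect_identical(predict_origin(back, dat$test)$p_bacterial,
                   predict_origin(m, dat$test)$p_bacterial)
  stale <- m
  stale$version <- "map4np-enc-0"
  saveRDS(stale, tf)
  expect_error(load_origin_model(tf), "version")
})

test_that("tidy and glance summarize the cross-validation trace", {
  dat <- make_sep_data(n_per_class = 15)
  m <- train_map4_svm(dat$train, dat$sig, cv = small_cv())
  td <- tidy(m)
  expect_equal(nrow(td), 2)  # C grid size
  expect_equal(sum(td$selected), 1)
  gl <- glance(m)
  expect_equal(gl$kind, "map4_svm")
  expect_equal(gl$n_train, nrow(dat$train))
  expect_true(gl$cv_roc_auc >= 0 && gl$cv_roc_auc <= 1)
})
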