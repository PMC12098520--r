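# Training: fold construction, losses, the adversarial update direction,
# learning progress, determinism, ablation and fine-tuning contracts.

test_that("LOSO folds cover every subject exactly once", {
  folds <- loso_folds(0:9, seed = 3)
  expect_length(folds, 10)
  expect_equal(sort(vapply(folds, `[[`, integer(1), "test_subject")), 0:9)
  for (f in folds) {
    expect_length(f$train_subjects, 9)
    expect_length(intersect(f$train_subjects, f$test_subject), 0)
    expect_setequal(c(f$train_subjects, f$test_subject), 0:9)
  }
  f2 <- loso_folds(c(5, 9), seed = 1)
  expect_length(f2, 2)
  expect_equal(f2[[1]]$train_subjects, 9)
  expect_error(loso_folds(3L), "at least 2")
})

test_that("cross-entropy matches closed forms and hand-worked cases", {
  perfect <- diag(5)[c(1, 3, 5), ]
  expect_equal(cross_entropy(perfect, perfect), 0)
  unif <- matrix(0.2, 4, 5)
  y <- diag(5)[c(1, 2, 3, 4), ]
  expect_equal(cross_entropy(unif, y), log(5), tolerance = 1e-6)
  expect_equal(log(5), 1.6094379, tolerance = 1e-7)
  probs <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  oh <- rbind(c(1, 0), c(0, 1))
  expect_equal(cross_entropy(probs, oh), 0.4337503, tolerance = 1e-7)
  # zero probability on a true class is clamped, not infinite
  expect_warning(v <- cross_entropy(rbind(c(0, 1)), rbind(c(1, 0))),
                 "clamped")
  expect_true(is.finite(v) && v > 20)
})

test_that("the overall loss is exactly L_cla - lambda * L_d", {
  expect_equal(total_loss(1.0, 0.5, 1), 0.5)
  expect_equal(total_loss(1.2, 99, 0), 1.2)     # discriminator-free limit
  expect_equal(total_loss(1.6094, log(9), 0.5), 0.5108, tolerance = 1e-4)
  set.seed(10)
  for (i in 1:50) {
    lc <- runif(1, 0, 3); ld <- runif(1, 0, 3); lam <- runif(1, 0, 2)
    expect_lt(abs(total_loss(lc, ld, lam) - (lc - lam * ld)), 1e-6)
  }
  expect_error(total_loss(1, 1, -0.1), "lambda")
})

test_that("domain datasets re-base labels contiguously without leakage", {
  sm <- small_prepared_cohort()
  fold <- loso_folds(0:2, seed = 1)[[2]]   # subject 1 held out
  ds <- build_domain_dataset(sm$epochs, fold)
  expect_equal(ds$n_domains, 2)
  dl <- vapply(ds$train, `[[`, integer(1), "domain_label")
  expect_setequal(unique(dl), c(0L, 1L))
  expect_false(1L %in% vapply(ds$train, `[[`, integer(1), "subject_id"))
  expect_true(all(vapply(ds$test, `[[`, integer(1), "subject_id") == 1L))
})

test_that("one optimizer step moves the two players in opposite directions", {
  cfg <- tiny_model_config()
  params <- init_model_params(cfg)
  sm <- small_prepared_cohort()
  ds <- build_domain_dataset(sm$epochs, loso_folds(0:2, seed = 1)[[1]])
  batch <- lapply(ds$train[1:6], function(s) {
    s$tensor <- adgsleep:::pool_input(s$tensor, cfg$input_size); s
  })
  l_d_of <- function(p) {
    ld <- 0
    for (s in batch) {
      fe <- feature_extract(s$tensor, p, cfg)
      pd <- domain_predict(fe$feat, p)
      ld <- ld - log(pd[s$domain_label + 1])
    }
    ld / length(batch)
  }
  st <- adgsleep:::batch_step(batch, params, cfg, lambda = 1)
  eta <- 1e-3
  # extractor follows the reversed gradient -> domain loss goes UP
  p_ext <- params
  for (part in c("enc", "dec", "gru"))
    p_ext[[part]] <- adgsleep:::tree_map2(p_ext[[part]], st$grads[[part]],
                                          function(a, g) a - eta * g)
  expect_gt(l_d_of(p_ext), st$l_d)
  # discriminator descends its own gradient -> domain loss goes DOWN
  p_dis <- params
  p_dis$domain <- adgsleep:::tree_map2(p_dis$domain, st$grads$domain,
                                       function(a, g) a - eta * g)
  expect_lt(l_d_of(p_dis), st$l_d)
})

test_that("desk-scale training learns, is deterministic, and logs Eq-14-consistent losses", {
  sm <- small_prepared_cohort()
  ds <- build_domain_dataset(sm$epochs, loso_folds(0:2, seed = 1)[[1]])
  cfg <- model_config_desk(seed = 1L)
  tcfg <- train_config(epochs = 5, batch_size = 16, lr = 1e-3)
  fit1 <- train_fold(ds, cfg, tcfg, seed = 4)
  expect_lt(fit1$history$l_cla[5], fit1$history$l_cla[1])
  expect_true(all(abs(fit1$history$l_all -
                      (fit1$history$l_cla -
                       fit1$history$lambda * fit1$history$l_d)) < 1e-6))
  fit2 <- train_fold(ds, cfg, tcfg, seed = 4)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
})

test_that("removing the discriminator removes the domain loss entirely", {
  sm <- small_prepared_cohort()
  ds <- build_domain_dataset(sm$epochs, loso_folds(0:2, seed = 1)[[1]])
  cfg <- model_config_desk(use_discriminator = FALSE, seed = 1L)
  fit <- train_fold(ds, cfg, train_config(epochs = 2, lr = 1e-3), seed = 4)
  expect_true(all(is.na(fit$history$l_d)))
  expect_equal(fit$history$l_all, fit$history$l_cla)
  expect_false(any(startsWith(param_paths(fit$params), "domain")))
})

test_that("fine-tuning freezes convolutions bit-exactly and retrains heads", {
  sm <- small_prepared_cohort()
  ds <- build_domain_dataset(sm$epochs, loso_folds(0:2, seed = 1)[[1]])
  cfg <- model_config_desk(seed = 2L)
  pre <- train_fold(ds, cfg, train_config(epochs = 1, lr = 1e-3), seed = 2)
  # new fold plays the role of a new cohort
  ds2 <- build_domain_dataset(sm$epochs, loso_folds(0:2, seed = 1)[[3]])
  ft <- fine_tune(list(params = pre$params, config = pre$config), ds2,
                  train_config(epochs = 2, lr = 1e-3), seed = 5)
  expect_identical(ft$params$enc, pre$params$enc)
  expect_identical(ft$params$dec, pre$params$dec)
  expect_false(identical(ft$params$label, pre$params$label))
  expect_false(identical(ft$params$gru, pre$params$gru))
  expect_error(fine_tune(list(params = pre$params, config = pre$config),
                         ds2, freeze_spec = "nonexistent.layer"),
               "matches no parameter")
})

test_that("freezing every layer leaves the model function unchanged", {
  sm <- small_prepared_cohort()
  ds <- build_domain_dataset(sm$epochs, loso_folds(0:2, seed = 1)[[1]])
  cfg <- model_config_desk(seed = 3L)
  pre <- train_fold(ds, cfg, train_config(epochs = 1, lr = 1e-3), seed = 3)
  ft <- fine_tune(list(params = pre$params, config = pre$config), ds,
                  train_config(epochs = 1, lr = 1e-3),
                  freeze_spec = c("enc", "dec", "gru", "label", "domain"),
                  seed = 6)
  expect_identical(ft$params, pre$params)
  x <- ds$test[[1]]$tensor
  fe1 <- feature_extract(x, pre$params, pre$config)
  fe2 <- feature_extract(x, ft$params, ft$config)
  expect_identical(label_predict(fe1$feat, pre$params),
                   label_predict(fe2$feat, ft$params))
})
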