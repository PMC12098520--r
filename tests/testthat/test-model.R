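# Network components: SE attention, residual blocks, extractor shape chain,
# GRL, probability heads, and finite-difference validation of the full
# backward pass.

test_that("SE block follows its squeeze/excite/scale definition", {
  # zero input, zero biases: z = 0, s = sigmoid(0) = 0.5, output = 0
  p0 <- list(W1 = matrix(0, 1, 2), b1 = 0, W2 = matrix(0, 2, 1), b2 = c(0, 0))
  o0 <- array(0, dim = c(3, 3, 2))
  se0 <- se_forward(o0, p0)
  expect_equal(se0$s, c(0.5, 0.5))
  expect_equal(se0$out, o0)
  # 1x1 spatial, identity weights: hand-evaluated excitation
  pid <- list(W1 = diag(2), b1 = c(0, 0), W2 = diag(2), b2 = c(0, 0))
  o <- array(c(2, 4), dim = c(1, 1, 2))
  se <- se_forward(o, pid)
  expect_equal(se$z, c(2, 4))
  expect_equal(se$s, c(0.880797, 0.982014), tolerance = 1e-6)
  expect_equal(as.vector(se$out), c(1.761594, 3.928055), tolerance = 1e-6)
  # squeeze of a constant channel is that constant
  oc <- array(rep(c(3.25, -1.5), each = 16), dim = c(4, 4, 2))
  pr <- list(W1 = matrix(rnorm(2), 1, 2), b1 = 0,
             W2 = matrix(rnorm(2), 2, 1), b2 = c(0, 0))
  expect_equal(se_forward(oc, pr)$z, c(3.25, -1.5))
  expect_error(se_forward(oc, p0[c("W1", "b1")]), NULL)
})

test_that("saturating the excitation bias makes the SE block the identity", {
  set.seed(2)
  o <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3))
  p <- list(W1 = matrix(0, 1, 3), b1 = 0, W2 = matrix(0, 3, 1), b2 = rep(50, 3))
  expect_equal(se_forward(o, p)$out, o, tolerance = 1e-12)
})

test_that("residual blocks reduce to relu(x) under zero weights", {
  z2 <- function(...) array(0, dim = c(...))
  p <- list(conv = list(W = z2(3, 3, 2, 2), b = c(0, 0)),
            se = list(W1 = matrix(0, 1, 2), b1 = 0,
                      W2 = matrix(0, 2, 1), b2 = c(-50, -50)))
  set.seed(3)
  x <- array(rnorm(5 * 5 * 2), dim = c(5, 5, 2))
  out <- res_cab_forward(x, p, "standard", use_se = TRUE)$out
  expect_equal(out, pmax(x, 0))           # negatives clipped by the ReLU
  xp <- abs(x)
  expect_equal(res_cab_forward(xp, p, "standard")$out, xp)
  # channel mismatch points at the projection variant
  pbad <- list(conv = list(W = z2(3, 3, 2, 4), b = numeric(4)),
               se = list(W1 = matrix(0, 1, 4), b1 = 0,
                         W2 = matrix(0, 4, 1), b2 = numeric(4)))
  expect_error(res_cab_forward(x, pbad, "standard"), "projection")
})

test_that("residual block matches the literal loop oracle on pinned input", {
  set.seed(17)
  x <- array(rnorm(4 * 4 * 2) * 0.7, dim = c(4, 4, 2))
  p <- list(conv = list(W = array(rnorm(3 * 3 * 2 * 2) * 0.3,
                                  dim = c(3, 3, 2, 2)),
                        b = rnorm(2) * 0.1),
            se = list(W1 = matrix(rnorm(2) * 0.5, 1, 2), b1 = rnorm(1),
                      W2 = matrix(rnorm(2) * 0.5, 2, 1), b2 = rnorm(2)))
  got <- res_cab_forward(x, p, "standard", use_se = TRUE)$out
  conv_ref <- conv2d_oracle(x, p$conv$W, p$conv$b, stride = 1, pad = 1)
  se_ref <- se_oracle(conv_ref, p$se)
  expect_equal(got, pmax(se_ref$out + x, 0), tolerance = 1e-6)
  # projection variant with 1x1 shortcut, stride 2
  pp <- c(p, list(short = list(W = array(rnorm(1 * 1 * 2 * 2),
                                         dim = c(1, 1, 2, 2)),
                               b = rnorm(2))))
  gotp <- res_cab_forward(x, pp, "projection", stride = 2)$out
  conv_s2 <- conv2d_oracle(x, p$conv$W, p$conv$b, stride = 2, pad = 1)
  short_ref <- conv2d_oracle(x, pp$short$W, pp$short$b, stride = 2, pad = 0)
  expect_equal(gotp, pmax(se_oracle(conv_s2, p$se)$out + short_ref, 0),
               tolerance = 1e-6)
})

test_that("the reference configuration obeys the published shape chain", {
  cfg <- model_config(n_domains = 9L, seed = 1L)
  params <- init_model_params(cfg)
  set.seed(1)
  x <- array(rnorm(128 * 128 * 10), dim = c(128, 128, 10))
  fe <- feature_extract(x, params, cfg)
  expect_equal(fe$encoder_shape, c(8L, 8L, 256L))
  expect_equal(dim(fe$feat), c(32L, 256L))
  expect_length(label_predict(fe$feat, params), 5L)
  expect_length(domain_predict(fe$feat, params), 9L)
  # pure function: repeated call gives the identical sequence
  expect_identical(fe$feat, feature_extract(x, params, cfg)$feat)
})

test_that("gradient reversal is the identity forward and -lambda backward", {
  x <- matrix(rnorm(6), 2, 3)
  expect_equal(as.vector(grl_forward(x, 2)), as.vector(x))
  # toy objective f(x) = w * grl(x, 2): df/dx must equal -2w, i.e. the
  # finite-difference slope of the sign-flipped objective
  w <- 1.7; lam <- 2; x0 <- 0.4
  analytic <- grl_backward(w, lam)
  eps <- 1e-6
  fd <- (-lam * w * (x0 + eps) - (-lam * w * (x0 - eps))) / (2 * eps)
  expect_equal(analytic, fd, tolerance = 1e-4)
  expect_equal(grl_backward(matrix(5, 2, 2), 0), matrix(0, 2, 2))
})

test_that("probability heads emit valid distributions", {
  cfg <- tiny_model_config()
  params <- init_model_params(cfg)
  set.seed(77)
  for (i in 1:100) {
    feat <- matrix(rnorm(8 * 10, sd = 3), 8, 10)
    pl <- label_predict(feat, params)
    pd <- domain_predict(feat, params)
    expect_true(all(pl > 0 & pl < 1) && abs(sum(pl) - 1) < 1e-6)
    expect_true(all(pd > 0 & pd < 1) && abs(sum(pd) - 1) < 1e-6)
  }
})

test_that("softmax matches hand-computed values and is shift invariant", {
  sm <- adgsleep:::softmax
  expect_equal(sm(rep(0, 5)), rep(0.2, 5))
  expect_equal(sm(c(1, 0, 0, 0, 0)),
               c(0.40461, 0.14885, 0.14885, 0.14885, 0.14885),
               tolerance = 1e-5)
  l <- c(0.3, -1, 2, 0.5, 0)
  expect_equal(sm(l), sm(l + 17.3), tolerance = 1e-12)
  expect_error(sm(c(1, NaN)), "non-finite")
})

test_that("disabling the discriminator removes its parameters entirely", {
  cfg <- tiny_model_config(use_discriminator = FALSE)
  params <- init_model_params(cfg)
  expect_false(any(startsWith(param_paths(params), "domain")))
  expect_error(domain_predict(matrix(0, 8, 10), params), "discriminator")
})

test_that("analytic gradients match finite differences through the model", {
  cfg <- tiny_model_config()
  params <- init_model_params(cfg)
  set.seed(42)
  x <- array(rnorm(32 * 32 * 10) * 0.5, dim = c(32, 32, 10))
  y <- 2L; d <- 1L; lam <- 0.7
  s <- list(tensor = x, stage_label = y, domain_label = d)
  st <- adgsleep:::batch_step(list(s), params, cfg, lam)
  loss_parts <- function(p) {
    fe <- feature_extract(x, p, cfg)
    fv <- adgsleep:::flatten_feat(fe$feat)
    lp <- adgsleep:::head_forward(fv, p$label)$probs
    dp <- adgsleep:::head_forward(fv, p$domain)$probs
    c(l_cla = -log(lp[y + 1]), l_d = -log(dp[d + 1]))
  }
  check_path <- function(path, n_idx = 3) {
    g <- st$grads; for (k in path) g <- g[[k]]
    p_at <- function(p) { for (k in path) p <- p[[k]]; p }
    set.seed(sum(utf8ToInt(paste(path, collapse = ""))))
    for (idx in sample(length(g), min(n_idx, length(g)))) {
      eps <- 1e-5
      bump <- function(delta) {
        p2 <- params
        leaf <- p_at(p2); leaf[idx] <- leaf[idx] + delta
        expr <- paste0("p2[[", paste0('"', path, '"', collapse = "]][["),
                       "]] <- leaf")
        eval(parse(text = expr))
        loss_parts(p2)
      }
      l1 <- bump(eps); l2 <- bump(-eps)
      # heads see their own losses; the extractor sees l_cla - lam * l_d
      num <- switch(path[1],
        label = (l1["l_cla"] - l2["l_cla"]) / (2 * eps),
        domain = (l1["l_d"] - l2["l_d"]) / (2 * eps),
        ((l1["l_cla"] - lam * l1["l_d"]) -
         (l2["l_cla"] - lam * l2["l_d"])) / (2 * eps))
      expect_equal(unname(g[idx]), unname(num), tolerance = 2e-4)
    }
  }
  for (path in list(c("enc", "stage1", "proj", "conv", "W"),
                    c("enc", "stage2", "std", "se", "W1"),
                    c("enc", "stage4", "std", "conv", "W"),
                    c("dec", "fuse1", "W"),
                    c("gru", "fwd", "Wz"), c("gru", "bwd", "Un"),
                    c("label", "fc1", "W"), c("domain", "fc3", "b")))
    check_path(path)
})

test_that("checkpoints round-trip parameters and configuration", {
  cfg <- tiny_model_config()
  params <- init_model_params(cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(params, cfg, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, params)
  expect_equal(back$config$widths, cfg$widths)
  manifest <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(manifest$n_parameters, count_params(params))
})
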