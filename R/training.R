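# Multi-source-domain adversarial training: leave-one-subject-out folds,
# cross-entropy losses, the overall objective L_all = L_cla - lambda * L_d,
# Adam, the per-batch adversarial update, and fine-tuning with layer
# freezing.

#' Leave-one-subject-out folds
#'
#' One fold per subject; the fold's subject is the entire test set, every
#' other subject is a training (source) domain. Domain labels are the 0-based
#' positions of the training subjects, so a 10-subject cohort yields 9
#' domains per fold.
#'
#' @param subject_ids Integer vector of distinct subject ids.
#' @param seed Recorded per fold for downstream reproducibility.
#' @return List of fold specs: `fold`, `test_subject`, `train_subjects`,
#'   `seed`.
#' @export
loso_folds <- function(subject_ids, seed = 1L) {
  subject_ids <- sort(unique(as.integer(subject_ids)))
  if (length(subject_ids) < 2)
    stop("leave-one-subject-out needs at least 2 subjects")
  lapply(seq_along(subject_ids), function(i) {
    list(fold = i, test_subject = subject_ids[i],
         train_subjects = subject_ids[-i],
         seed = derive_seed(seed, 3L, i))
  })
}

#' Build the multi-source / target split for one fold
#'
#' Assigns contiguous 0-based domain labels to the training subjects and
#' normalizes all tensors with training-set statistics only.
#'
#' @param epochs List of `spectrogram_epoch` across all subjects.
#' @param fold One element of [loso_folds()].
#' @return List with `train`, `test`, `stats`, `n_domains`.
#' @export
build_domain_dataset <- function(epochs, fold) {
  sid <- vapply(epochs, `[[`, integer(1), "subject_id")
  train <- epochs[sid %in% fold$train_subjects]
  test <- epochs[sid == fold$test_subject]
  if (length(train) == 0 || length(test) == 0)
    stop("fold yields an empty train or test set")
  dom_of <- match(vapply(train, `[[`, integer(1), "subject_id"),
                  sort(fold$train_subjects)) - 1L
  for (i in seq_along(train)) train[[i]]$domain_label <- dom_of[i]
  nd <- normalize_dataset(train, test)
  list(train = nd$train, test = nd$other, stats = nd$stats,
       n_domains = length(fold$train_subjects))
}

#' Multi-class cross-entropy
#'
#' `-(1/M) * sum_i sum_j y_ij log p_ij` over one-hot targets. Probabilities
#' are clamped below at 1e-12 (with a warning) so a zero probability on a
#' true class yields a large finite loss.
#'
#' @param probs M x K matrix of predicted probabilities (rows sum to 1).
#' @param onehot M x K one-hot target matrix.
#' @return Non-negative scalar; 0 iff every prediction puts mass 1 on the
#'   true class.
#' @export
cross_entropy <- function(probs, onehot) {
  stopifnot(is.matrix(probs), all(dim(probs) == dim(onehot)))
  p_true <- rowSums(probs * onehot)
  if (any(p_true < 1e-12)) {
    warning("probabilities clamped at 1e-12 in cross-entropy")
    p_true <- pmax(p_true, 1e-12)
  }
  -mean(log(p_true))
}

#' Overall adversarial objective
#'
#' `L_all = L_cla - lambda * L_d`: the feature extractor minimizes the stage
#' loss while maximizing the domain loss the discriminator minimizes.
#'
#' @param l_cla Stage-classification loss.
#' @param l_d Domain-discrimination loss.
#' @param lambda Non-negative adversarial weight.
#' @return `l_cla - lambda * l_d`.
#' @export
total_loss <- function(l_cla, l_d, lambda) {
  stopifnot(lambda >= 0)
  l_cla - lambda * l_d
}

one_hot <- function(labels, K) {
  m <- matrix(0, length(labels), K)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

# ---- parameter-tree utilities -------------------------------------------

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a))
      out[[nm]] <- if (is.null(a[[nm]])) NULL
                   else tree_map2(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, function(e) if (is.null(e)) NULL else tree_zero(e))
  else a * 0
}

tree_add <- function(a, b) tree_map2(a, b, `+`)
tree_scale <- function(a, s) {
  if (is.list(a)) lapply(a, function(e) if (is.null(e)) NULL
                         else tree_scale(e, s))
  else a * s
}

# Adam over the parameter tree; `frozen` is a character vector of dotted
# path prefixes (e.g. "enc", "dec.fuse1") whose leaves are not updated.
adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8, frozen = character(0)) {
  state$t <- state$t + 1
  tt <- state$t
  walk <- function(p, g, m, v, path) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.null(p[[nm]])) next
        sub <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]],
                    if (nzchar(path)) paste(path, nm, sep = ".") else nm)
        p[[nm]] <- sub$p; m[[nm]] <- sub$m; v[[nm]] <- sub$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (length(frozen) && any(startsWith(path, frozen)))
      return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^tt)
    vh <- v / (1 - beta2^tt)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v, "")
  list(params = res$p, state = list(m = res$m, v = res$v, t = tt))
}

adam_init <- function(params) list(m = tree_zero(params),
                                   v = tree_zero(params), t = 0)

#' Training hyperparameters
#'
#' Defaults follow the published protocol: Adam, learning rate 2e-5, batch
#' size 16, 150 training epochs. Desk-scale runs override `epochs` (and use
#' the reduced [model_config_desk()]).
#'
#' @param epochs Training epochs (full passes over the pooled source set).
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param shuffle Reshuffle the pooled multi-source set every epoch.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 150L, batch_size = 16L, lr = 2e-5,
                         shuffle = TRUE) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 shuffle = isTRUE(shuffle)),
            class = "train_config")
}

lambda_at <- function(config, progress) {
  if (config$lambda_schedule == "dann_ramp")
    config$lambda * (2 / (1 + exp(-10 * progress)) - 1)
  else config$lambda
}

# one forward+backward over a batch; returns grads, losses, accuracy
batch_step <- function(batch, params, config, lambda) {
  M <- length(batch)
  grads <- NULL
  l_cla_sum <- 0; l_d_sum <- 0; correct <- 0
  use_d <- config$use_discriminator && lambda >= 0 && !is.null(params$domain)
  for (s in batch) {
    fe <- feature_extract(s$tensor, params, config, keep_cache = TRUE)
    fv <- flatten_feat(fe$feat)
    lh <- head_forward(fv, params$label)
    y1 <- one_hot(s$stage_label, config$n_classes)[1, ]
    l_cla_sum <- l_cla_sum - log(max(lh$probs[s$stage_label + 1L], 1e-12))
    if (which.max(lh$probs) - 1L == s$stage_label) correct <- correct + 1
    dlog_l <- (lh$probs - y1) / M
    hb_l <- head_backward(dlog_l, lh$cache)
    dfv <- hb_l$dx
    g <- list(label = hb_l$grads)
    if (use_d) {
      dh <- head_forward(grl_forward(fv, lambda), params$domain)
      d1 <- one_hot(s$domain_label, config$n_domains)[1, ]
      l_d_sum <- l_d_sum - log(max(dh$probs[s$domain_label + 1L], 1e-12))
      dlog_d <- (dh$probs - d1) / M
      hb_d <- head_backward(dlog_d, dh$cache)
      g$domain <- hb_d$grads
      # GRL: reversed, lambda-scaled domain gradient into the extractor
      dfv <- dfv + grl_backward(hb_d$dx, lambda)
    }
    dfeat <- matrix(dfv, nrow = nrow(fe$feat))
    g_ext <- feature_extract_backward(dfeat, fe$cache, config)
    g <- c(g_ext, g)
    grads <- if (is.null(grads)) g else tree_add(grads, g)
  }
  list(grads = grads, l_cla = l_cla_sum / M,
       l_d = if (use_d) l_d_sum / M else NA_real_,
       acc = correct / M)
}

#' Train one leave-one-subject-out fold
#'
#' Per batch: forward through the feature extractor; the stage head descends
#' the classification loss; the domain head descends the domain loss on its
#' own parameters while the extractor receives the gradient-reversed domain
#' term, implementing `L_all = L_cla - lambda * L_d`. With
#' `use_discriminator = FALSE` only the classification loss is optimized.
#'
#' @param dataset Output of [build_domain_dataset()].
#' @param config A [model_config()] (`n_domains` is overridden by the fold's
#'   training-subject count).
#' @param tcfg A [train_config()].
#' @param seed Seed controlling initialization and batch shuffling.
#' @param params Optional warm-start parameters (used by [fine_tune()]).
#' @param frozen Character vector of frozen parameter-path prefixes.
#' @param verbose Print per-epoch losses.
#' @return List with trained `params`, `history` (per-epoch `l_cla`, `l_d`,
#'   `l_all`, `acc`), and `config`.
#' @export
train_fold <- function(dataset, config, tcfg = train_config(), seed = 1L,
                       params = NULL, frozen = character(0),
                       verbose = FALSE) {
  stopifnot(inherits(config, "model_config"), inherits(tcfg, "train_config"))
  config$n_domains <- dataset$n_domains
  config$seed <- as.integer(seed)
  # pool tensors to the model input size once, not on every forward pass
  dataset$train <- lapply(dataset$train, function(s) {
    s$tensor <- pool_input(s$tensor, config$input_size); s
  })
  if (is.null(params)) params <- init_model_params(config)
  state <- adam_init(params)
  set.seed(derive_seed(seed, 11L))
  n <- length(dataset$train)
  history <- data.frame(epoch = integer(0), l_cla = numeric(0),
                        l_d = numeric(0), l_all = numeric(0),
                        acc = numeric(0), lambda = numeric(0))
  n_batches <- ceiling(n / tcfg$batch_size)
  for (ep in seq_len(tcfg$epochs)) {
    idx <- if (tcfg$shuffle) sample.int(n) else seq_len(n)
    lam <- lambda_at(config, (ep - 1) / max(tcfg$epochs - 1, 1))
    ep_cla <- 0; ep_d <- 0; ep_acc <- 0; nb_d <- 0
    for (b in seq_len(n_batches)) {
      take <- idx[((b - 1) * tcfg$batch_size + 1):min(b * tcfg$batch_size, n)]
      st <- batch_step(dataset$train[take], params, config, lam)
      if (!all(is.finite(c(st$l_cla, st$l_d)) | is.na(st$l_d)))
        stop("non-finite loss at epoch ", ep, ", batch ", b)
      up <- adam_update(params, st$grads, state, tcfg$lr, frozen = frozen)
      params <- up$params; state <- up$state
      ep_cla <- ep_cla + st$l_cla * length(take)
      ep_acc <- ep_acc + st$acc * length(take)
      if (!is.na(st$l_d)) { ep_d <- ep_d + st$l_d * length(take); nb_d <- nb_d + length(take) }
    }
    l_cla <- ep_cla / n
    l_d <- if (nb_d > 0) ep_d / nb_d else NA_real_
    l_all <- if (is.na(l_d)) l_cla else total_loss(l_cla, l_d, lam)
    history <- rbind(history,
                     data.frame(epoch = ep, l_cla = l_cla, l_d = l_d,
                                l_all = l_all, acc = ep_acc / n,
                                lambda = lam))
    if (verbose)
      message(sprintf("epoch %3d  L_cla %.4f  L_d %s  acc %.3f", ep, l_cla,
                      ifelse(is.na(l_d), "--", sprintf("%.4f", l_d)),
                      ep_acc / n))
  }
  list(params = params, history = history, config = config)
}

#' Default freeze set for fine-tuning
#'
#' All encoder and decoder convolutional parameters (including their SE
#' modules); the Bi-GRU and both heads stay trainable.
#'
#' @return Character vector of parameter-path prefixes.
#' @export
default_freeze_spec <- function() c("enc", "dec")

#' Fine-tune a pretrained model on a new cohort
#'
#' Parameters matching the freeze spec stay bit-identical; the domain head is
#' rebuilt to the new fold's training-subject count (its width depends on the
#' domain count, so pretrained weights cannot carry over).
#'
#' @param pretrained List with `params` and `config`
#'   (e.g. [load_checkpoint()]).
#' @param dataset New-fold dataset from [build_domain_dataset()].
#' @param tcfg A [train_config()].
#' @param freeze_spec Path prefixes to freeze; default
#'   [default_freeze_spec()].
#' @param seed Seed for the fine-tuning run.
#' @return Same structure as [train_fold()].
#' @export
fine_tune <- function(pretrained, dataset, tcfg = train_config(),
                      freeze_spec = default_freeze_spec(), seed = 1L) {
  params <- pretrained$params
  config <- pretrained$config
  known <- param_paths(params)
  for (fz in freeze_spec)
    if (!any(startsWith(known, fz)))
      stop("freeze_spec entry '", fz, "' matches no parameter path")
  if (config$use_discriminator && dataset$n_domains != config$n_domains) {
    config$n_domains <- dataset$n_domains
    set.seed(derive_seed(seed, 17L))
    w <- config$widths
    d_feat <- (config$input_size %/% 4L) * 2L * config$gru_hidden
    params$domain <- init_head(d_feat, config$head_hidden, config$n_domains)
  }
  train_fold(dataset, config, tcfg, seed = seed, params = params,
             frozen = freeze_spec)
}

#' Dotted paths of all parameter leaves
#' @param params Nested parameter list.
#' @return Character vector like `"enc.stage1.proj.conv.W"`.
#' @export
param_paths <- function(params) {
  out <- character(0)
  walk <- function(p, path) {
    if (is.list(p)) {
      for (nm in names(p))
        if (!is.null(p[[nm]]))
          walk(p[[nm]], if (nzchar(path)) paste(path, nm, sep = ".") else nm)
    } else out <<- c(out, path)
  }
  walk(params, "")
  out
}
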