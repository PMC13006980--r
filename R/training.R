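#' Training configuration
#'
#' @param epochs number of passes over the training split.
#' @param batch_size minibatch size.
#' @param lr learning rate.
#' @param optimizer `"sgd"` (momentum SGD, the default) or `"adam"`.
#'   Momentum SGD with L2 is the default because, on high-dimensional
#'   inputs with few training samples, Adam's per-coordinate step sizes
#'   let the first projection layer memorize feature noise within a few
#'   epochs, while the L2-regularized SGD trajectory tracks the
#'   ridge-like solution that generalizes.
#' @param momentum SGD momentum coefficient (ignored by Adam).
#' @param l2 coupled L2 penalty coefficient on weight matrices (never
#'   biases or layer-norm parameters): `l2 * W` is added to each weight
#'   gradient before the optimizer step.
#' @param p_rna,p_txt structured modality dropout probabilities: per
#'   sample and per epoch, the RNA / text modality is marked unavailable
#'   with this probability during training (the image anchor is never
#'   droppable), teaching the gate to operate under missing data.
#' @param weight_decay decoupled (AdamW-style) weight decay applied to
#'   weight matrices after the optimizer step (independent of `l2`).
#' @param patience early-stopping patience in epochs without validation
#'   improvement (Inf disables).
#' @param seed training seed (init, shuffling, dropout streams).
#' @return list of class `sg_train_config`.
#' @export
train_config <- function(epochs = 60, batch_size = 32, lr = 3e-3,
                         optimizer = c("sgd", "adam"), momentum = 0.9,
                         l2 = 3.0, p_rna = 0.3, p_txt = 0.3,
                         weight_decay = 0, patience = 15, seed = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(p_rna >= 0, p_rna < 1, p_txt >= 0, p_txt < 1,
            epochs >= 1, batch_size >= 1, lr > 0,
            momentum >= 0, momentum < 1, l2 >= 0, weight_decay >= 0)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 optimizer = optimizer, momentum = momentum, l2 = l2,
                 p_rna = p_rna, p_txt = p_txt,
                 weight_decay = weight_decay, patience = patience, seed = seed),
            class = "sg_train_config")
}

#' Structured modality dropout
#'
#' Independently per sample, marks the RNA modality unavailable with
#' probability `p_rna` and the text modality with `p_txt` (then
#' zero-substitutes the corresponding feature rows). The image column is
#' never droppable. Draws from the current RNG stream, so masks are
#' resampled every epoch and reproducible given the stream state.
#'
#' @param batch an `sg_batch`.
#' @param p_rna,p_txt drop probabilities in [0, 1).
#' @return the batch with updated mask and zeroed feature rows.
#' @export
modality_dropout <- function(batch, p_rna = 0.3, p_txt = 0.3) {
  if (p_rna >= 1 || p_txt >= 1) stop("dropout probabilities must be < 1")
  B <- nrow(batch$mask)
  keep_rna <- stats::rbinom(B, 1, 1 - p_rna)
  keep_txt <- stats::rbinom(B, 1, 1 - p_txt)
  batch$mask[, 2] <- batch$mask[, 2] * keep_rna
  batch$mask[, 3] <- batch$mask[, 3] * keep_txt
  batch$x$rna <- batch$x$rna * batch$mask[, 2]
  batch$x$txt <- batch$x$txt * batch$mask[, 3]
  batch
}

# decoupled weight decay on weight matrices only (p - eta*wd*p)
decay_weights <- function(params, amount) {
  dec <- function(p) {
    if (is.list(p)) {
      nm <- names(p)
      for (i in seq_along(p)) {
        if (!is.null(nm) && nm[i] %in% c("ln1", "ln2")) next
        p[[i]] <- dec(p[[i]])
      }
      p
    } else if (is.matrix(p)) p * (1 - amount) else p
  }
  structure(dec(unclass(params)), class = "sg_params")
}

adam_init <- function(params) {
  list(m = zero_like(unclass(params)), v = zero_like(unclass(params)), t = 0)
}

sgd_init <- function(params) {
  list(vel = zero_like(unclass(params)))
}

sgd_step <- function(params, grads, state, lr, momentum) {
  state$vel <- param_map(function(v, g) momentum * v + g, state$vel, grads)
  new_p <- param_map(function(p, v) p - lr * v, unclass(params), state$vel)
  list(params = structure(new_p, class = "sg_params"), state = state)
}

# coupled L2: add l2 * W to the gradient of every weight matrix
# (biases and layer-norm gain/shift vectors are left unpenalized)
add_l2_grads <- function(grads, params, l2) {
  param_map(function(g, p) if (is.matrix(p)) g + l2 * p else g,
            grads, unclass(params))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- param_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- param_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  new_p <- param_map(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                     unclass(params), state$m, state$v)
  list(params = structure(new_p, class = "sg_params"), state = state)
}

#' Train the gated multimodal hazard model
#'
#' Seeded minibatch training: momentum SGD (default) or Adam on the
#' L2-regularized censored discrete-time NLL with
#' structured modality dropout, validation-based model selection (the
#' checkpoint with the best validation mean C-index across cancer types is
#' returned) and early stopping. Bit-reproducible for a given seed;
#' validation and test records are never mutated.
#'
#' @param cohort an `sg_cohort`.
#' @param train_idx,val_idx disjoint patient row indices.
#' @param config an `sg_config`.
#' @param tcfg an `sg_train_config`.
#' @param disc optional pre-fitted discretizer; by default fitted on the
#'   training split only.
#' @return object of class `survgate_fit`: `params`, `config`, `disc`,
#'   `history` (per-epoch loss and validation C-index), `best_epoch`,
#'   `seed`.
#' @export
sg_train <- function(cohort, train_idx, val_idx, config = model_config(),
                     tcfg = train_config(), disc = NULL) {
  if (length(intersect(train_idx, val_idx)) > 0) {
    stop("train and validation indices must be disjoint")
  }
  if (is.null(disc)) {
    disc <- fit_discretizer(cohort$meta[train_idx, ], n_bins = config$n_bins)
  }
  with_seed(tcfg$seed, {
    params <- init_params(config, seed = stats::runif(1, 1, 2^30))
    state <- if (tcfg$optimizer == "adam") adam_init(params) else sgd_init(params)
    val_batch <- make_batch(cohort, val_idx, disc)
    best <- list(val = -Inf, params = params, epoch = 0)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_cindex = numeric(0))
    stall <- 0
    for (epoch in seq_len(tcfg$epochs)) {
      ord <- sample(train_idx)
      n_seen <- 0; loss_sum <- 0
      for (start in seq(1, length(ord), by = tcfg$batch_size)) {
        ids <- ord[start:min(start + tcfg$batch_size - 1, length(ord))]
        b <- make_batch(cohort, ids, disc)
        b <- modality_dropout(b, tcfg$p_rna, tcfg$p_txt)
        lg <- loss_and_grads(params, b, config, training = TRUE)
        if (!is.finite(lg$loss)) {
          stop("NaN/Inf loss at epoch ", epoch,
               ": try a smaller learning rate (current lr = ", tcfg$lr, ")")
        }
        g <- if (tcfg$l2 > 0) add_l2_grads(lg$grads, params, tcfg$l2) else lg$grads
        upd <- if (tcfg$optimizer == "adam") {
          adam_step(params, g, state, tcfg$lr)
        } else {
          sgd_step(params, g, state, tcfg$lr, tcfg$momentum)
        }
        params <- upd$params; state <- upd$state
        if (tcfg$weight_decay > 0) params <- decay_weights(params, tcfg$lr * tcfg$weight_decay)
        loss_sum <- loss_sum + lg$loss * length(ids)
        n_seen <- n_seen + length(ids)
      }
      fwd <- model_forward(params, val_batch, config, training = FALSE)
      val_ci <- mean_cindex_by_cancer(fwd$risk, val_batch)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = loss_sum / n_seen,
                                           val_cindex = val_ci))
      if (val_ci > best$val) {
        best <- list(val = val_ci, params = params, epoch = epoch)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= tcfg$patience) break
      }
    }
    structure(list(params = best$params, config = config, disc = disc,
                   history = history, best_epoch = best$epoch,
                   best_val_cindex = best$val, seed = tcfg$seed,
                   train_config = tcfg),
              class = "survgate_fit")
  })
}

# Unweighted mean C-index across the cancer types present in a batch;
# cancer types with no comparable pair are skipped.
mean_cindex_by_cancer <- function(risks, batch) {
  vals <- c()
  for (cc in unique(batch$cancer)) {
    s <- batch$cancer == cc
    ci <- tryCatch(c_index(risks[s], batch$time_days[s], batch$event[s]),
                   error = function(e) NA_real_)
    vals <- c(vals, ci)
  }
  mean(vals, na.rm = TRUE)
}

#' @export
print.survgate_fit <- function(x, ...) {
  cat("survgate fit:", x$config$fusion, "fusion,", nrow(x$history),
      "epochs run, best epoch", x$best_epoch,
      sprintf("(val C-index %.3f), seed %d\n", x$best_val_cindex, x$seed))
  invisible(x)
}
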