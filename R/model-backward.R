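# Hand-written reverse pass matching model_forward(). Gradients come back
# in the same nested structure as the parameters.

zero_like <- function(p) param_map(function(x) x * 0, p)

model_backward <- function(params, batch, config, fwd) {
  cache <- fwd$cache
  dlogit <- nll_grad_logits(fwd$hazards, batch$tau, batch$event)
  g <- zero_like(unclass(params))
  H <- cache$H
  dH <- matrix(0, nrow(H), ncol(H))
  for (cc in unique(batch$cancer)) {
    idx <- which(batch$cancer == cc)
    dl <- dlogit[idx, , drop = FALSE]
    g$heads[[cc]]$W <- t(dl) %*% H[idx, , drop = FALSE]
    g$heads[[cc]]$b <- colSums(dl)
    dH[idx, ] <- dl %*% params$heads[[cc]]$W
  }
  Ltok <- length(cache$enc$tokens)
  dtokens <- lapply(seq_len(Ltok), function(i) dH / Ltok)
  eb <- encoder_bwd(dtokens, cache$enc$caches, params$enc, config$n_heads)
  g$enc <- eb$grads
  Z <- cache$Z
  if (config$fusion == "gated") {
    G <- cache$G
    if (config$encoder_tokens == "fused") {
      dzf <- eb$dtokens[[1]]
      dG <- cbind(rowSums(dzf * Z$img), rowSums(dzf * Z$rna),
                  rowSums(dzf * Z$txt))
      dZ <- list(img = G[, 1] * dzf, rna = G[, 2] * dzf, txt = G[, 3] * dzf)
    } else {
      dt <- eb$dtokens
      dG <- cbind(rowSums(dt[[1]] * Z$img), rowSums(dt[[2]] * Z$rna),
                  rowSums(dt[[3]] * Z$txt))
      dZ <- list(img = G[, 1] * dt[[1]], rna = G[, 2] * dt[[2]],
                 txt = G[, 3] * dt[[3]])
    }
    # softmax backward (the mask penalty is an additive constant)
    dLm <- G * (dG - rowSums(dG * G))
    g$gate$W <- t(dLm) %*% cbind(Z$img, Z$rna, Z$txt)
    dzc <- dLm %*% params$gate$W
    d <- config$d
    dZ$img <- dZ$img + dzc[, 1:d, drop = FALSE]
    dZ$rna <- dZ$rna + dzc[, (d + 1):(2 * d), drop = FALSE]
    dZ$txt <- dZ$txt + dzc[, (2 * d + 1):(3 * d), drop = FALSE]
  } else {
    dzf <- eb$dtokens[[1]]
    g$fuse_early$W <- t(dzf) %*% cache$zc
    g$fuse_early$b <- colSums(dzf)
    dzc <- dzf %*% params$fuse_early$W
    d <- config$d
    dZ <- list(img = dzc[, 1:d, drop = FALSE],
               rna = dzc[, (d + 1):(2 * d), drop = FALSE],
               txt = dzc[, (2 * d + 1):(3 * d), drop = FALSE])
  }
  # zero-substitution: gradient blocked where the modality is absent
  dZ$rna <- dZ$rna * cache$mask[, 2]
  dZ$txt <- dZ$txt * cache$mask[, 3]
  for (m in c("img", "rna", "txt")) {
    pf <- cache$pr[[m]]
    dz <- dZ[[m]]
    if (!is.null(pf$drop_mask)) dz <- dz * pf$drop_mask
    da <- dz * pf$relu_mask
    g$proj[[m]]$W <- t(da) %*% pf$x
    g$proj[[m]]$b <- colSums(da)
  }
  g
}

#' Loss and gradients for one batch
#'
#' Convenience wrapper: forward pass, censored discrete-time NLL and the
#' full backward pass in one call.
#'
#' @param params `sg_params`.
#' @param batch `sg_batch`.
#' @param config `sg_config`.
#' @param training logical (projection dropout).
#' @return list with `loss`, `grads`, `fwd`.
#' @export
loss_and_grads <- function(params, batch, config, training = FALSE) {
  fwd <- model_forward(params, batch, config, training = training)
  list(loss = nll_loss(fwd$hazards, batch$tau, batch$event),
       grads = model_backward(params, batch, config, fwd),
       fwd = fwd)
}

#' Finite-difference gradient check
#'
#' Compares the analytic backward pass of the full forward + censored NLL
#' against central finite differences, on a random subset of coordinates
#' from every parameter group (in eval mode, so the check is
#' deterministic). Returns the worst relative discrepancy
#' `|a - b| / max(|a|, |b|, floor)` over all sampled coordinates.
#'
#' @param params,batch,config as in [loss_and_grads()].
#' @param n_per_leaf coordinates sampled per parameter array.
#' @param h finite-difference step.
#' @param seed seed for coordinate sampling.
#' @param floor denominator floor guarding near-zero gradients.
#' @return list with `max_rel_err` and a data.frame of per-leaf worst errors.
#' @export
check_gradients <- function(params, batch, config, n_per_leaf = 5,
                            h = 1e-5, seed = 1, floor = 1e-6) {
  loss_fn <- function(p) {
    fwd <- model_forward(p, batch, config, training = FALSE)
    nll_loss(fwd$hazards, batch$tau, batch$event)
  }
  analytic <- loss_and_grads(params, batch, config, training = FALSE)$grads
  leaves <- list()
  walk <- function(path, p) {
    if (is.list(p)) {
      for (nm in seq_along(p)) {
        walk(c(path, if (is.null(names(p)[nm]) || names(p)[nm] == "")
          as.character(nm) else names(p)[nm]), p[[nm]])
      }
    } else {
      leaves[[paste(path, collapse = "$")]] <<- path
    }
  }
  walk(character(0), unclass(params))
  get_leaf <- function(p, path) {
    for (k in path) p <- if (grepl("^[0-9]+$", k)) p[[as.integer(k)]] else p[[k]]
    p
  }
  set_leaf <- function(p, path, val) {
    k <- path[1]
    key <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
    if (length(path) == 1) p[[key]] <- val
    else p[[key]] <- set_leaf(p[[key]], path[-1], val)
    p
  }
  rows <- with_seed(seed, {
    lapply(names(leaves), function(nm) {
      path <- leaves[[nm]]
      arr <- get_leaf(unclass(params), path)
      ga <- get_leaf(analytic, path)
      ii <- sample(length(arr), min(n_per_leaf, length(arr)))
      errs <- vapply(ii, function(i) {
        pp <- unclass(params)
        a2 <- arr; a2[i] <- arr[i] + h
        pp <- set_leaf(pp, path, a2)
        lp <- loss_fn(pp)
        a2[i] <- arr[i] - h
        pp <- set_leaf(pp, path, a2)
        lm <- loss_fn(pp)
        fd <- (lp - lm) / (2 * h)
        abs(fd - ga[i]) / max(abs(fd), abs(ga[i]), floor)
      }, numeric(1))
      data.frame(leaf = nm, max_rel_err = max(errs))
    })
  })
  tab <- do.call(rbind, rows)
  list(max_rel_err = max(tab$max_rel_err), by_leaf = tab)
}
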