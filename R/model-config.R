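#' Model configuration
#'
#' Dimensions and architectural switches for the gated multimodal
#' discrete-time hazard model. Defaults follow the reference architecture:
#' unified embedding dimension d = 32, T = 4 time bins, C = 10 cancer
#' types, input widths 2048/256/768 for histopathology / RNA / clinical
#' text, projection dropout 0.25, a 2-layer 4-head pre-norm transformer
#' encoder with feed-forward width 64, and a -1e9 additive logit penalty
#' for unavailable modalities.
#'
#' @param d unified embedding dimension.
#' @param n_bins number of discrete time bins T.
#' @param n_cancers number of cancer-type-specific hazard heads C.
#' @param d_img,d_rna,d_txt input feature widths per modality.
#' @param dropout projection dropout rate (training only).
#' @param n_layers,n_heads,d_ff transformer encoder depth, heads and
#'   feed-forward width.
#' @param penalty additive logit penalty for masked modalities; must be
#'   <= -1e6 so that the softmax weight of a missing modality underflows
#'   to numerical zero.
#' @param fusion `"gated"` (availability-masked softmax gate; default) or
#'   `"early"` (unmasked concatenation + linear map: the robustness foil).
#' @param encoder_tokens `"fused"` (default: the fused vector is a single
#'   encoder token) or `"modality"` (the three gate-weighted modality
#'   embeddings form a 3-token sequence).
#' @return object of class `sg_config`.
#' @export
model_config <- function(d = 32, n_bins = 4, n_cancers = 10,
                         d_img = 2048, d_rna = 256, d_txt = 768,
                         dropout = 0.25, n_layers = 2, n_heads = 4,
                         d_ff = 64, penalty = -1e9,
                         fusion = c("gated", "early"),
                         encoder_tokens = c("fused", "modality")) {
  fusion <- match.arg(fusion)
  encoder_tokens <- match.arg(encoder_tokens)
  stopifnot(d >= 1, n_bins >= 2, n_cancers >= 1, penalty <= -1e6,
            dropout >= 0, dropout < 1, d %% n_heads == 0)
  structure(list(d = d, n_bins = n_bins, n_cancers = n_cancers,
                 d_img = d_img, d_rna = d_rna, d_txt = d_txt,
                 dropout = dropout, n_layers = n_layers, n_heads = n_heads,
                 d_ff = d_ff, penalty = penalty, fusion = fusion,
                 encoder_tokens = encoder_tokens, schema = "survgate-ckpt-1"),
            class = "sg_config")
}

# U(-1/sqrt(fan_in), 1/sqrt(fan_in)) weight matrix.
rand_w <- function(nout, nin) {
  lim <- 1 / sqrt(nin)
  matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
}

#' Initialise model parameters
#'
#' Seeded uniform fan-in initialisation for all weight matrices; biases and
#' layer-norm shifts start at zero, layer-norm scales at one.
#'
#' @param config an `sg_config`.
#' @param seed integer seed.
#' @return nested parameter list (class `sg_params`).
#' @export
init_params <- function(config, seed = 1) {
  d <- config$d
  with_seed(seed, {
    p <- list(
      proj = list(
        img = list(W = rand_w(d, config$d_img), b = numeric(d)),
        rna = list(W = rand_w(d, config$d_rna), b = numeric(d)),
        txt = list(W = rand_w(d, config$d_txt), b = numeric(d))
      ),
      gate = list(W = rand_w(3, 3 * d)),
      enc = list(layers = lapply(seq_len(config$n_layers), function(l) list(
        ln1 = list(g = rep(1, d), b = numeric(d)),
        attn = list(Wq = rand_w(d, d), bq = numeric(d),
                    Wk = rand_w(d, d), bk = numeric(d),
                    Wv = rand_w(d, d), bv = numeric(d),
                    Wo = rand_w(d, d), bo = numeric(d)),
        ln2 = list(g = rep(1, d), b = numeric(d)),
        ffn = list(W1 = rand_w(config$d_ff, d), b1 = numeric(config$d_ff),
                   W2 = rand_w(d, config$d_ff), b2 = numeric(d))
      ))),
      heads = lapply(seq_len(config$n_cancers), function(cc) list(
        W = rand_w(config$n_bins, d), b = numeric(config$n_bins)
      ))
    )
    if (config$fusion == "early") {
      p$fuse_early <- list(W = rand_w(d, 3 * d), b = numeric(d))
    }
    structure(p, class = "sg_params")
  })
}

#' Save a model checkpoint
#'
#' Writes parameters and configuration to a single JSON file with a
#' versioned schema string; [load_checkpoint()] restores them exactly.
#'
#' @param params an `sg_params` list.
#' @param config the matching `sg_config`.
#' @param path output file.
#' @param meta optional named list of provenance fields (seed, epoch, ...).
#' @export
save_checkpoint <- function(params, config, path, meta = list()) {
  ser <- function(p) {
    if (is.list(p)) lapply(p, ser)
    else list(.dim = dim(p) %||% length(p), .data = as.vector(p),
              .mat = is.matrix(p))
  }
  jsonlite::write_json(list(schema = config$schema,
                            config = unclass(config),
                            meta = meta,
                            params = ser(unclass(params))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return list with `params`, `config`, `meta`.
#' @export
load_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  deser <- function(p) {
    if (is.list(p) && !is.null(p$.data)) {
      dat <- as.numeric(unlist(p$.data))
      dims <- as.integer(unlist(p$.dim))
      if (isTRUE(p$.mat)) matrix(dat, dims[1], dims[2]) else dat
    } else lapply(p, deser)
  }
  cfg <- lapply(x$config, function(v) if (is.list(v)) unlist(v) else v)
  config <- do.call(model_config, cfg[setdiff(names(cfg), "schema")])
  params <- structure(deser(x$params), class = "sg_params")
  list(params = params, config = config, meta = x$meta)
}
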