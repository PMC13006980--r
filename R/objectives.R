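#' Fit a survival-time discretizer
#'
#' Maps continuous follow-up times (days) to `T` discrete bins using
#' quantiles of the uncensored event times, fitted per cancer type on the
#' training split only. A cancer type with fewer than `T` uncensored events
#' falls back to the pooled (all-cancer) cut points.
#'
#' @param labels data.frame with columns `time_days`, `event` and
#'   `cancer_type`.
#' @param n_bins number of time bins T (default 4).
#' @param per_cancer fit separate cut points per cancer type (default TRUE).
#' @return object of class `sg_discretizer`: list of strictly increasing
#'   cut-point vectors (length T-1), one per cancer type plus `.pooled`.
#' @export
fit_discretizer <- function(labels, n_bins = 4, per_cancer = TRUE) {
  stopifnot(all(c("time_days", "event", "cancer_type") %in% names(labels)))
  if (any(labels$time_days <= 0)) stop("survival times must be positive")
  ev_times <- labels$time_days[labels$event == 1]
  if (length(ev_times) == 0) stop("no uncensored events: cannot fit time bins")
  probs <- seq_len(n_bins - 1) / n_bins
  make_cuts <- function(tt, where) {
    cuts <- unname(stats::quantile(tt, probs = probs, type = 7))
    if (any(diff(cuts) <= 0)) {
      stop("degenerate cut points (", where,
           "): event times have too many ties to form ", n_bins, " bins")
    }
    cuts
  }
  pooled <- make_cuts(ev_times, "pooled")
  cuts <- list(.pooled = pooled)
  if (per_cancer) {
    for (cc in sort(unique(labels$cancer_type))) {
      sub <- labels$time_days[labels$cancer_type == cc & labels$event == 1]
      cuts[[as.character(cc)]] <- if (length(sub) >= n_bins)
        make_cuts(sub, paste("cancer", cc)) else pooled
    }
  }
  structure(list(cuts = cuts, n_bins = n_bins, per_cancer = per_cancer),
            class = "sg_discretizer")
}

#' Assign discrete time bins
#'
#' Maps each time to the half-open interval `[cut_{k-1}, cut_k)`, with the
#' first bin unbounded below and the last unbounded above.
#'
#' @param disc an `sg_discretizer`.
#' @param time_days numeric vector of follow-up times.
#' @param cancer_type vector of cancer ids (recycled if length 1).
#' @return integer bins in 1..T.
#' @export
assign_bins <- function(disc, time_days, cancer_type = NULL) {
  stopifnot(inherits(disc, "sg_discretizer"))
  n <- length(time_days)
  if (is.null(cancer_type)) cancer_type <- rep(".pooled", n)
  cancer_type <- rep_len(as.character(cancer_type), n)
  tau <- integer(n)
  for (cc in unique(cancer_type)) {
    cuts <- disc$cuts[[cc]] %||% disc$cuts$.pooled
    idx <- cancer_type == cc
    tau[idx] <- pmin(findInterval(time_days[idx], cuts) + 1L, disc$n_bins)
  }
  tau
}

#' Save / load a discretizer as JSON
#' @param disc an `sg_discretizer`.
#' @param path file path.
#' @export
save_discretizer <- function(disc, path) {
  jsonlite::write_json(list(cuts = disc$cuts, n_bins = disc$n_bins,
                            per_cancer = disc$per_cancer),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_discretizer
#' @export
load_discretizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(cuts = as.list(x$cuts), n_bins = x$n_bins,
                 per_cancer = x$per_cancer),
            class = "sg_discretizer")
}

#' Censored discrete-time negative log-likelihood
#'
#' Mean over the batch of the standard censored discrete-time survival
#' likelihood: an observed event in bin tau contributes
#' `-log S(tau-1) - log h_tau` (survive the earlier bins, fail in bin tau);
#' a censored observation contributes `-log S(tau)` (survive through the
#' bin in which follow-up ended). `S(t) = prod_{k<=t}(1 - h_k)`, `S(0) = 1`.
#' Hazards are clamped to `[eps, 1-eps]` before taking logs.
#'
#' @param hazards B x T matrix of per-bin hazards in [0, 1].
#' @param tau integer event/censoring bins in 1..T.
#' @param event 0/1 event indicators (1 = event observed).
#' @param eps clamping constant (default 1e-7).
#' @return non-negative scalar loss.
#' @export
nll_loss <- function(hazards, tau, event, eps = 1e-7) {
  h <- as.matrix(hazards)
  B <- nrow(h); Tb <- ncol(h)
  tau <- as.integer(tau); event <- as.integer(event)
  stopifnot(length(tau) == B, length(event) == B, all(event %in% 0:1))
  if (any(tau < 1 | tau > Tb)) stop("tau out of range 1..", Tb)
  if (any(h < 0 | h > 1)) stop("hazards must lie in [0, 1]")
  h <- pmin(pmax(h, eps), 1 - eps)
  log1mh <- log(1 - h)
  total <- 0
  for (i in seq_len(B)) {
    ti <- tau[i]
    if (event[i] == 1) {
      s_prev <- if (ti > 1) sum(log1mh[i, seq_len(ti - 1)]) else 0
      total <- total - (s_prev + log(h[i, ti]))
    } else {
      total <- total - sum(log1mh[i, seq_len(ti)])
    }
  }
  total / B
}

# Gradient of nll_loss w.r.t. the pre-sigmoid hazard logits.
# For events: d/dz_k = h_k for k < tau, h_tau - 1 at k = tau;
# for censored: d/dz_k = h_k for k <= tau; zero beyond. Mean over batch.
nll_grad_logits <- function(hazards, tau, event) {
  h <- as.matrix(hazards)
  B <- nrow(h)
  g <- matrix(0, B, ncol(h))
  for (i in seq_len(B)) {
    ti <- tau[i]
    if (event[i] == 1) {
      if (ti > 1) g[i, seq_len(ti - 1)] <- h[i, seq_len(ti - 1)]
      g[i, ti] <- h[i, ti] - 1
    } else {
      g[i, seq_len(ti)] <- h[i, seq_len(ti)]
    }
  }
  g / B
}

#' Survival curve from discrete hazards
#'
#' `S(t) = prod_{k<=t}(1 - h_k)` with `S(0) := 1`; always non-increasing.
#'
#' @param hazards vector of T hazards in [0, 1], or a B x T matrix.
#' @return vector (or matrix) of survival probabilities, same shape.
#' @export
survival_curve <- function(hazards) {
  if (any(hazards < 0 | hazards > 1)) stop("hazards must lie in [0, 1]")
  if (is.matrix(hazards)) {
    s <- t(apply(1 - hazards, 1, cumprod))
    dimnames(s) <- NULL
    return(s)
  }
  unname(cumprod(1 - hazards))
}

#' Scalar risk score from a hazard curve
#'
#' `risk = -sum_t S(t)`: the negative area under the discrete survival
#' curve, so higher risk means lower expected survival. Monotone: raising
#' any single hazard never decreases the risk. An alternative summary
#' `sum_t h_t` is available via `method = "cumhaz"`.
#'
#' @param hazards vector of T hazards, or B x T matrix.
#' @param method `"negsurv"` (default) or `"cumhaz"`.
#' @return scalar risk (or vector of B risks).
#' @export
risk_score <- function(hazards, method = c("negsurv", "cumhaz")) {
  method <- match.arg(method)
  s <- survival_curve(hazards)
  if (method == "cumhaz") {
    if (is.matrix(hazards)) return(unname(rowSums(hazards))) else return(sum(hazards))
  }
  if (is.matrix(s)) unname(-rowSums(s)) else -sum(s)
}

#' Concordance index for right-censored data
#'
#' Fraction of comparable pairs whose predicted risk ordering matches the
#' observed survival ordering. A pair (i, j) is comparable when
#' `t_i < t_j` and patient i had an observed event; it is concordant when
#' `risk_i > risk_j`, and risk ties contribute 0.5. 0.5 is random,
#' 1.0 perfect.
#'
#' @param risks numeric risk scores (higher = worse prognosis).
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @return C-index in [0, 1].
#' @export
c_index <- function(risks, times, events) {
  n <- length(risks)
  stopifnot(length(times) == n, length(events) == n, all(events %in% 0:1))
  comp <- outer(times, times, `<`) & matrix(events == 1, n, n)
  n_comp <- sum(comp)
  if (n_comp == 0) stop("no comparable pairs: C-index undefined")
  conc <- outer(risks, risks, `>`)
  tied <- outer(risks, risks, `==`)
  (sum(comp & conc) + 0.5 * sum(comp & tied)) / n_comp
}

#' Brute-force concordance index (pair-loop oracle)
#'
#' Literal O(n^2) double loop over ordered pairs with the same comparability
#' and tie conventions as [c_index()]; retained as a reference
#' implementation for verification.
#'
#' @inheritParams c_index
#' @return C-index in [0, 1].
#' @export
c_index_naive <- function(risks, times, events) {
  n <- length(risks)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (i == j || times[i] >= times[j]) next
      den <- den + 1
      if (risks[i] > risks[j]) num <- num + 1
      else if (risks[i] == risks[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs: C-index undefined")
  num / den
}
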