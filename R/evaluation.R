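#' Construct a train/validation/test split
#'
#' Patient mode stratifies by cancer type so each split matches the target
#' ratio within one patient per cancer. Institution mode assigns entire
#' tissue source sites to a single split (largest site first, to the most
#' under-filled split, with seed-shuffled tie-breaking), so no institution
#' ever appears in two splits.
#'
#' @param meta data.frame with `patient_id`, `cancer_type` and (for
#'   institution mode) `institution`.
#' @param ratios integer ratios summing to 10 parts, e.g. `c(4, 2, 4)` or
#'   `c(7, 1, 2)`.
#' @param mode `"patient"` or `"institution"`.
#' @param seed shuffling seed.
#' @return object of class `sg_split`: id lists `train`, `val`, `test`
#'   plus provenance.
#' @export
make_split <- function(meta, ratios = c(4, 2, 4),
                       mode = c("patient", "institution"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(length(ratios) == 3, all(ratios > 0))
  if (sum(ratios) != 10) stop("split ratios must sum to 10 parts (e.g. 4:2:4, 7:1:2)")
  prop <- ratios / sum(ratios)
  ids <- as.character(meta$patient_id)
  assign <- setNames(rep(NA_character_, nrow(meta)), ids)
  with_seed(seed, {
    if (mode == "patient") {
      small <- table(meta$cancer_type)
      bad <- names(small)[small < 3]
      if (length(bad) > 0) {
        stop("cancer type(s) with fewer patients than splits: ",
             paste(bad, collapse = ", "))
      }
      for (cc in unique(meta$cancer_type)) {
        sub <- sample(ids[meta$cancer_type == cc])
        n <- length(sub)
        base <- floor(prop * n)
        rem <- n - sum(base)
        frac <- prop * n - base
        extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
        grp <- rep(c("train", "val", "test"), times = base)
        assign[sub] <- grp
      }
    } else {
      if (!"institution" %in% names(meta)) stop("institution mode requires an institution column")
      sizes <- table(meta$institution)
      inst <- sample(names(sizes))           # seed-shuffled tie-break order
      inst <- inst[order(-as.integer(sizes[inst]))]
      total <- nrow(meta)
      target <- prop * total
      fill <- c(train = 0, val = 0, test = 0)
      inst_assign <- setNames(character(length(inst)), inst)
      for (s in inst) {
        deficit <- target - fill
        pick <- names(deficit)[which.max(deficit)]
        inst_assign[s] <- pick
        fill[pick] <- fill[pick] + sizes[[s]]
      }
      assign[ids] <- inst_assign[as.character(meta$institution)]
    }
  })
  out <- list(mode = mode, ratios = ratios, seed = seed,
              train = ids[assign == "train"], val = ids[assign == "val"],
              test = ids[assign == "test"])
  class(out) <- "sg_split"
  out
}

#' Row indices of a split within a cohort
#' @param split an `sg_split`.
#' @param cohort an `sg_cohort`.
#' @param which one of `"train"`, `"val"`, `"test"`.
#' @export
split_idx <- function(split, cohort, which = c("train", "val", "test")) {
  which <- match.arg(which)
  match(split[[which]], as.character(cohort$meta$patient_id))
}

#' Save / load a split definition as JSON
#' @param split an `sg_split`.
#' @param path file path.
#' @export
save_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_split
#' @export
load_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$ratios <- as.numeric(x$ratios)
  structure(x, class = "sg_split")
}

#' Missing-modality evaluation protocol
#'
#' Marks the chosen auxiliary modality absent for exactly
#' `round-half-up(fraction * n)` of the given patients, sampled without
#' replacement under the seed, and zeroes the corresponding feature rows.
#' Copy-on-mask: the input cohort is untouched; labels and the image
#' anchor are never altered.
#'
#' @param cohort an `sg_cohort`.
#' @param idx patient row indices the protocol applies to (e.g. the test
#'   split).
#' @param modality `"rna"` or `"txt"`.
#' @param fraction missing fraction in [0, 1].
#' @param seed sampling seed.
#' @return a modified copy of the cohort.
#' @export
missing_modality_protocol <- function(cohort, idx, modality = c("rna", "txt"),
                                      fraction, seed = 1) {
  modality <- match.arg(modality)
  if (fraction < 0 || fraction > 1) stop("missing fraction must lie in [0, 1]")
  n <- length(idx)
  k <- floor(fraction * n + 0.5)
  col <- if (modality == "rna") 2L else 3L
  masked <- with_seed(seed, sample(idx, k))
  out <- cohort
  out$mask[masked, col] <- 0L
  out$features[[modality]][masked, ] <- 0
  out
}

#' Evaluate a fitted model on a set of patients
#'
#' Scores risks in eval mode and computes the concordance index per cancer
#' type, plus the unweighted mean and sd across cancer types (sd with the
#' n-1 denominator; reported as 0 with `sd_defined = FALSE` when only one
#' cancer type is present). Side-effect free.
#'
#' @param fit a `survgate_fit` (or list with `params`, `config`).
#' @param cohort an `sg_cohort`.
#' @param idx patient row indices (e.g. the test split).
#' @return list with `per_cancer`, `mean`, `sd`, `sd_defined`, `risks`.
#' @export
sg_evaluate <- function(fit, cohort, idx) {
  batch <- make_batch(cohort, idx, fit$disc)
  fwd <- model_forward(fit$params, batch, fit$config, training = FALSE)
  per <- lapply(sort(unique(batch$cancer)), function(cc) {
    s <- batch$cancer == cc
    data.frame(cancer_type = cc,
               cindex = c_index(fwd$risk[s], batch$time_days[s],
                                batch$event[s]),
               n = sum(s))
  })
  per <- do.call(rbind, per)
  list(per_cancer = per, mean = mean(per$cindex),
       sd = if (nrow(per) > 1) stats::sd(per$cindex) else 0,
       sd_defined = nrow(per) > 1, risks = fwd$risk)
}

#' Missing-rate sweep on the test split
#'
#' Applies [missing_modality_protocol()] at each rate and re-evaluates,
#' returning the mean C-index per rate.
#'
#' @param fit a `survgate_fit`.
#' @param cohort an `sg_cohort`.
#' @param idx test row indices.
#' @param modality `"rna"` or `"txt"`.
#' @param rates missing fractions (default 0, 0.2, 0.5, 0.8).
#' @param seed protocol seed.
#' @return data.frame with `rate` and `cindex`.
#' @export
sweep_missing <- function(fit, cohort, idx, modality = "rna",
                          rates = c(0, 0.2, 0.5, 0.8), seed = 1) {
  rows <- lapply(rates, function(r) {
    ch <- missing_modality_protocol(cohort, idx, modality, r, seed = seed)
    data.frame(rate = r, cindex = sg_evaluate(fit, ch, idx)$mean)
  })
  do.call(rbind, rows)
}

#' Multi-seed experiment
#'
#' Runs the full protocol once per seed -- generate cohort, split, train,
#' evaluate (optionally under a missing-modality protocol) -- and
#' aggregates per-cancer C-indices as mean and sd (n-1) across seeds. All
#' raw per-seed values are retained.
#'
#' @param scfg an `sg_sim_config`.
#' @param config an `sg_config`.
#' @param tcfg an `sg_train_config` (its seed is overridden per run).
#' @param seeds integer seeds; default the canonical five
#'   (123, 132, 213, 231, 321).
#' @param ratios,split_mode split specification.
#' @param missing optional list(modality=, fraction=) applied to the test
#'   split at evaluation time.
#' @return object of class `sg_experiment`: `per_seed` (cancers x seeds
#'   matrix), `mean_by_cancer`, `sd_by_cancer`, `overall_mean`,
#'   `overall_sd`, provenance fields.
#' @export
multi_seed_experiment <- function(scfg, config = NULL, tcfg = train_config(),
                                  seeds = c(123, 132, 213, 231, 321),
                                  ratios = c(4, 2, 4),
                                  split_mode = "patient", missing = NULL) {
  if (is.null(config)) config <- model_config(n_cancers = scfg$n_cancers)
  res <- matrix(NA_real_, scfg$n_cancers, length(seeds),
                dimnames = list(paste0("cancer_", seq_len(scfg$n_cancers)),
                                paste0("seed_", seeds)))
  fits <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    sd_k <- seeds[k]
    cohort <- generate_cohort(scfg, seed = sd_k)
    split <- make_split(cohort$meta, ratios = ratios, mode = split_mode,
                        seed = sd_k)
    tcfg_k <- tcfg; tcfg_k$seed <- sd_k
    fit <- sg_train(cohort, split_idx(split, cohort, "train"),
                    split_idx(split, cohort, "val"), config, tcfg_k)
    test_idx <- split_idx(split, cohort, "test")
    ch_eval <- cohort
    if (!is.null(missing)) {
      ch_eval <- missing_modality_protocol(cohort, test_idx,
                                           missing$modality,
                                           missing$fraction, seed = sd_k)
    }
    ev <- sg_evaluate(fit, ch_eval, test_idx)
    res[ev$per_cancer$cancer_type, k] <- ev$per_cancer$cindex
    fits[[k]] <- fit
  }
  overall_per_seed <- colMeans(res, na.rm = TRUE)
  structure(list(per_seed = res,
                 mean_by_cancer = rowMeans(res, na.rm = TRUE),
                 sd_by_cancer = apply(res, 1, stats::sd, na.rm = TRUE),
                 overall_per_seed = overall_per_seed,
                 overall_mean = mean(overall_per_seed),
                 overall_sd = stats::sd(overall_per_seed),
                 seeds = seeds, ratios = ratios, split_mode = split_mode,
                 missing = missing, fusion = config$fusion,
                 fits = fits),
            class = "sg_experiment")
}

#' Paired t-tests with Bonferroni correction
#'
#' Two-sided paired t-test on per-seed C-indices for each cancer type,
#' declared significant when `p < alpha / m`. Degenerate zero-variance
#' differences are flagged: all-zero differences give t = 0, p = 1; a
#' constant non-zero shift is reported significant with a flag.
#'
#' @param results_a,results_b cancers x seeds matrices (same seed order)
#'   or `sg_experiment` objects.
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons in the family (default 7).
#' @return data.frame with `cancer`, `t`, `p`, `threshold`, `significant`,
#'   `flag`.
#' @export
paired_ttest_bonferroni <- function(results_a, results_b, alpha = 0.05, m = 7) {
  a <- if (inherits(results_a, "sg_experiment")) results_a$per_seed else as.matrix(results_a)
  b <- if (inherits(results_b, "sg_experiment")) results_b$per_seed else as.matrix(results_b)
  stopifnot(all(dim(a) == dim(b)))
  if (ncol(a) < 2) stop("paired t-test needs at least 2 seeds")
  thr <- alpha / m
  rows <- lapply(seq_len(nrow(a)), function(i) {
    d <- a[i, ] - b[i, ]
    # guard relative to the shift size: a constant shift of floating-point
    # values leaves rounding residue of order |d| * eps in sd(d)
    if (stats::sd(d) <= 1e-10 * max(abs(d), 1)) {
      if (all(abs(d) <= 1e-12)) {
        data.frame(cancer = i, t = 0, p = 1, threshold = thr,
                   significant = FALSE, flag = "zero-variance, zero shift")
      } else {
        data.frame(cancer = i, t = sign(mean(d)) * Inf, p = 0, threshold = thr,
                   significant = TRUE, flag = "zero-variance, constant shift")
      }
    } else {
      tt <- stats::t.test(a[i, ], b[i, ], paired = TRUE)
      data.frame(cancer = i, t = unname(tt$statistic), p = tt$p.value,
                 threshold = thr, significant = tt$p.value < thr, flag = "")
    }
  })
  do.call(rbind, rows)
}

#' Variance F-test between two result sets
#'
#' Directional test of whether `a` is more variable than `b`:
#' `F = var(a) / var(b)`, rejected when F exceeds the one-sided critical
#' value of the F distribution at `alpha` (6.39 for five values per arm,
#' df (4, 4)). The max/min variance ratio is also reported. A zero
#' denominator variance is flagged as infinite F.
#'
#' @param a,b numeric vectors of per-seed values (>= 2 each).
#' @param alpha test level (default 0.05).
#' @return list with `F`, `F_maxmin`, `df`, `p`, `critical`,
#'   `significant`, `flag`.
#' @export
variance_f_test <- function(a, b, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per side")
  va <- stats::var(a); vb <- stats::var(b)
  df <- c(length(a) - 1, length(b) - 1)
  critical <- stats::qf(1 - alpha, df[1], df[2])
  if (vb == 0) {
    return(list(F = Inf, F_maxmin = Inf, df = df, p = 0, critical = critical,
                significant = va > 0, flag = "zero variance in denominator"))
  }
  Fv <- va / vb
  list(F = Fv, F_maxmin = max(va, vb) / min(va, vb), df = df,
       p = stats::pf(Fv, df[1], df[2], lower.tail = FALSE),
       critical = critical, significant = Fv > critical, flag = "")
}
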