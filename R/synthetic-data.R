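#' Synthetic cohort configuration
#'
#' Describes the generative model for synthetic multimodal survival
#' cohorts: each patient carries one latent prognostic factor per modality
#' (standard normal); observed features are the factor times a fixed
#' modality loading direction, plus an institution-specific mean shift and
#' i.i.d. Gaussian noise; the true log-relative hazard is the
#' cancer-type-weighted sum of the factors; survival is exponential with
#' rate `lambda0 * exp(risk)` and censoring is an independent exponential
#' tuned to the target censoring fraction. Site shifts move feature means
#' only -- never the latent risk -- so institution-grouped splits probe
#' covariate-shift robustness, not label shift.
#'
#' @param n number of patients.
#' @param n_cancers number of cancer types.
#' @param institutions_per_cancer tissue-source sites per cancer type.
#' @param beta C x 3 matrix of per-cancer signal coefficients
#'   (columns img, rna, txt); a length-3 vector is recycled to all
#'   cancers. Defaults (0.5, 1.0, 0.5): RNA carries the dominant signal.
#' @param lambda0 baseline hazard (per day).
#' @param censoring_target target censoring fraction in [0, 1).
#' @param site_sd per-dimension sd of institutional feature mean shifts.
#' @param noise_sd per-dimension feature noise sd.
#' @param signal_strength Euclidean norm of each modality loading vector.
#' @param d_img,d_rna,d_txt feature widths.
#' @param n_patch_range range of patch counts per patient (raw level).
#' @param n_genes,l_txt_range raw RNA row count and text length range.
#' @param raw_noise_sd per-dimension noise of raw patch/token/gene rows
#'   around the patient mean.
#' @return list of class `sg_sim_config`.
#' @export
sim_config <- function(n = 600, n_cancers = 3, institutions_per_cancer = 4,
                       beta = c(0.5, 1.0, 0.5), lambda0 = 1 / 365,
                       censoring_target = 0.35, site_sd = 0.5,
                       noise_sd = 1, signal_strength = 3,
                       d_img = 2048, d_rna = 256, d_txt = 768,
                       n_patch_range = c(96, 128), n_genes = 2048,
                       l_txt_range = c(50, 200), raw_noise_sd = 1) {
  if (censoring_target < 0 || censoring_target >= 1) {
    stop("censoring target must lie in [0, 1); with exponential censoring ",
         "any value in that range is achievable")
  }
  if (is.vector(beta) && length(beta) == 3) {
    beta <- matrix(beta, n_cancers, 3, byrow = TRUE)
  }
  stopifnot(is.matrix(beta), nrow(beta) == n_cancers, ncol(beta) == 3)
  colnames(beta) <- c("img", "rna", "txt")
  structure(list(n = n, n_cancers = n_cancers,
                 institutions_per_cancer = institutions_per_cancer,
                 beta = beta, lambda0 = lambda0,
                 censoring_target = censoring_target, site_sd = site_sd,
                 noise_sd = noise_sd, signal_strength = signal_strength,
                 d_img = d_img, d_rna = d_rna, d_txt = d_txt,
                 n_patch_range = n_patch_range, n_genes = n_genes,
                 l_txt_range = l_txt_range, raw_noise_sd = raw_noise_sd),
            class = "sg_sim_config")
}

# Exponential censoring rate such that mean_i lc/(lc + lambda_i) = target.
tune_censoring_rate <- function(lambda_i, target) {
  if (target == 0) return(0)
  f <- function(log_lc) mean(exp(log_lc) / (exp(log_lc) + lambda_i)) - target
  r <- stats::uniroot(f, lower = log(min(lambda_i)) - 40,
                      upper = log(max(lambda_i)) + 40, tol = 1e-12)
  exp(r$root)
}

#' Generate a synthetic multimodal survival cohort
#'
#' See [sim_config()] for the generative model. At `level = "pooled"`
#' (default) the per-patient features are the pooled modality vectors the
#' model consumes. At `level = "raw"` the cohort additionally carries,
#' per patient, the raw arrays the preprocessing path expects: patch
#' features (N_i x d_img), gene embeddings (G x d_rna) and token
#' embeddings (L x d_txt), each drawn around the patient's pooled mean so
#' that mean pooling recovers it up to noise. Raw arrays are large; use
#' small n.
#'
#' @param config an `sg_sim_config`.
#' @param seed integer seed; the same seed reproduces the cohort
#'   byte-identically.
#' @param level `"pooled"` or `"raw"`.
#' @return an `sg_cohort` with ground truth in `$truth` (separate from the
#'   observable records so no pipeline stage can consume it by accident).
#' @export
generate_cohort <- function(config, seed = 1, level = c("pooled", "raw")) {
  level <- match.arg(level)
  stopifnot(inherits(config, "sg_sim_config"))
  with_seed(seed, {
    n <- config$n
    dims <- c(img = config$d_img, rna = config$d_rna, txt = config$d_txt)
    # fixed modality loading directions, norm = signal_strength
    u <- lapply(dims, function(D) {
      v <- stats::rnorm(D)
      v / sqrt(sum(v^2)) * config$signal_strength
    })
    cancer <- sample.int(config$n_cancers, n, replace = TRUE)
    inst_local <- sample.int(config$institutions_per_cancer, n, replace = TRUE)
    institution <- sprintf("site_c%d_i%d", cancer, inst_local)
    # institutional mean shifts per (site, modality)
    sites <- unique(institution)
    shifts <- lapply(c("img", "rna", "txt"), function(m) {
      s <- matrix(stats::rnorm(length(sites) * dims[[m]], 0, config$site_sd),
                  length(sites), dims[[m]])
      rownames(s) <- sites
      s
    })
    names(shifts) <- c("img", "rna", "txt")
    f <- matrix(stats::rnorm(n * 3), n, 3,
                dimnames = list(NULL, c("img", "rna", "txt")))
    risk <- rowSums(config$beta[cancer, , drop = FALSE] * f)
    mu <- lapply(c("img", "rna", "txt"), function(m) {
      f[, m] %o% u[[m]] + shifts[[m]][institution, , drop = FALSE]
    })
    names(mu) <- c("img", "rna", "txt")
    features <- lapply(c("img", "rna", "txt"), function(m) {
      x <- mu[[m]] + matrix(stats::rnorm(n * dims[[m]], 0, config$noise_sd),
                            n, dims[[m]])
      dimnames(x) <- NULL
      x
    })
    names(features) <- c("img", "rna", "txt")
    lambda_i <- config$lambda0 * exp(risk)
    t_surv <- stats::rexp(n, rate = lambda_i)
    lambda_c <- tune_censoring_rate(lambda_i, config$censoring_target)
    t_cens <- if (lambda_c > 0) stats::rexp(n, rate = lambda_c) else rep(Inf, n)
    event <- as.integer(t_surv < t_cens)
    time_days <- pmin(t_surv, t_cens)
    meta <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                       cancer_type = cancer, institution = institution,
                       time_days = time_days, event = event,
                       stringsAsFactors = FALSE)
    truth <- data.frame(patient_id = meta$patient_id, risk_true = risk,
                        f_img = f[, 1], f_rna = f[, 2], f_txt = f[, 3],
                        lambda = lambda_i)
    raw <- NULL
    if (level == "raw") {
      raw <- lapply(seq_len(n), function(i) {
        np <- sample(seq(config$n_patch_range[1], config$n_patch_range[2]), 1)
        lt <- sample(seq(config$l_txt_range[1], config$l_txt_range[2]), 1)
        list(
          img = matrix(rep(features$img[i, ], each = np), np) +
            matrix(stats::rnorm(np * dims[["img"]], 0, config$raw_noise_sd),
                   np, dims[["img"]]),
          rna = matrix(rep(features$rna[i, ], each = config$n_genes),
                       config$n_genes) +
            matrix(stats::rnorm(config$n_genes * dims[["rna"]], 0,
                                config$raw_noise_sd),
                   config$n_genes, dims[["rna"]]),
          txt = matrix(rep(features$txt[i, ], each = lt), lt) +
            matrix(stats::rnorm(lt * dims[["txt"]], 0, config$raw_noise_sd),
                   lt, dims[["txt"]])
        )
      })
      names(raw) <- meta$patient_id
    }
    mask <- cbind(rep(1L, n), rep(1L, n), rep(1L, n))
    ch <- new_cohort(features, mask, meta, truth = truth, raw = raw,
                     config = config, seed = seed)
    ch$lambda_c <- lambda_c
    ch
  })
}

#' Observed censoring fraction
#'
#' @param x an `sg_cohort` or a data.frame with an `event` column.
#' @return `1 - mean(event)`.
#' @export
censoring_rate <- function(x) {
  ev <- if (inherits(x, "sg_cohort")) x$meta$event else x$event
  if (length(ev) < 1) stop("need at least one record")
  1 - mean(ev)
}

#' Oracle C-index ceiling of a synthetic cohort
#'
#' Concordance of the true latent risks against the simulated outcomes --
#' the ceiling any fitted model can approach on this cohort, recomputed
#' per cancer type and overall. Used to set parameter-recovery thresholds.
#'
#' @param cohort an `sg_cohort` carrying `$truth`.
#' @param idx optional row subset (e.g. the test split).
#' @return list with `per_cancer` data.frame and `overall` (unweighted
#'   mean across cancer types).
#' @export
oracle_cindex_ceiling <- function(cohort, idx = seq_len(nrow(cohort$meta))) {
  if (is.null(cohort$truth)) stop("cohort has no ground-truth risks")
  meta <- cohort$meta[idx, ]
  risk <- cohort$truth$risk_true[idx]
  per <- lapply(sort(unique(meta$cancer_type)), function(cc) {
    s <- meta$cancer_type == cc
    data.frame(cancer_type = cc,
               cindex = c_index(risk[s], meta$time_days[s], meta$event[s]),
               n = sum(s))
  })
  per <- do.call(rbind, per)
  list(per_cancer = per, overall = mean(per$cindex))
}
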