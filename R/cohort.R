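# Cohort and batch containers. A cohort holds pooled per-patient modality
# features, the availability mask, and the metadata table; batches are
# row-slices stacked for the model with discretized survival labels.

new_cohort <- function(features, mask, meta, truth = NULL, raw = NULL,
                       config = NULL, seed = NULL) {
  stopifnot(is.matrix(features$img), nrow(features$img) == nrow(meta),
            nrow(mask) == nrow(meta), ncol(mask) == 3)
  colnames(mask) <- c("img", "rna", "txt")
  structure(list(features = features, mask = mask, meta = meta,
                 truth = truth, raw = raw, config = config, seed = seed),
            class = "sg_cohort")
}

#' @export
print.sg_cohort <- function(x, ...) {
  cat("survgate cohort:", nrow(x$meta), "patients,",
      length(unique(x$meta$cancer_type)), "cancer types,",
      length(unique(x$meta$institution)), "institutions\n")
  cat("  censoring:", round(1 - mean(x$meta$event), 3),
      " rna available:", round(mean(x$mask[, 2]), 3),
      " txt available:", round(mean(x$mask[, 3]), 3), "\n")
  invisible(x)
}

#' Build a model batch from a cohort
#'
#' Stacks pooled features, the availability mask and labels for the given
#' patients, zeroing feature rows of unavailable modalities (the batch
#' contract: zero rows exactly where the mask is 0, image column all
#' ones). Time bins are assigned with the supplied discretizer.
#'
#' @param cohort an `sg_cohort`.
#' @param idx integer row indices (default all).
#' @param disc an `sg_discretizer` fitted on the training split.
#' @return object of class `sg_batch`.
#' @export
make_batch <- function(cohort, idx = seq_len(nrow(cohort$meta)), disc = NULL) {
  mask <- cohort$mask[idx, , drop = FALSE]
  if (any(mask[, 1] != 1)) stop("image (anchor) modality missing for some patients")
  x <- list(img = cohort$features$img[idx, , drop = FALSE],
            rna = cohort$features$rna[idx, , drop = FALSE] * mask[, 2],
            txt = cohort$features$txt[idx, , drop = FALSE] * mask[, 3])
  meta <- cohort$meta[idx, , drop = FALSE]
  tau <- if (!is.null(disc)) assign_bins(disc, meta$time_days, meta$cancer_type)
         else rep(NA_integer_, length(idx))
  structure(list(x = x, mask = mask, cancer = as.integer(meta$cancer_type),
                 tau = tau, event = as.integer(meta$event),
                 time_days = meta$time_days,
                 patient_id = meta$patient_id, idx = idx),
            class = "sg_batch")
}

#' Write / read a cohort as plain-text CSV artifacts
#'
#' `labels.csv` holds `patient_id, cancer_type, institution, time_days,
#' event`; `features.csv` the pooled feature table with availability
#' flags; `truth.csv` (if ground truth is present) the latent risks, kept
#' in a separate file so no pipeline stage can consume it by accident.
#'
#' @param cohort an `sg_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$meta, file.path(dir, "labels.csv"), row.names = FALSE)
  feat <- data.frame(patient_id = cohort$meta$patient_id)
  for (m in c("img", "rna", "txt")) {
    fm <- cohort$features[[m]]
    colnames(fm) <- paste0(m, "_", seq_len(ncol(fm)) - 1L)
    feat <- cbind(feat, fm)
  }
  feat$has_rna <- cohort$mask[, 2] == 1
  feat$has_txt <- cohort$mask[, 3] == 1
  utils::write.csv(feat, file.path(dir, "features.csv"), row.names = FALSE)
  if (!is.null(cohort$truth)) {
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @param with_truth read truth.csv if present.
#' @export
read_cohort <- function(dir, with_truth = FALSE) {
  meta <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  feat <- utils::read.csv(file.path(dir, "features.csv"), stringsAsFactors = FALSE)
  stopifnot(identical(as.character(meta$patient_id), as.character(feat$patient_id)))
  grab <- function(prefix) {
    cols <- grep(paste0("^", prefix, "_[0-9]+$"), names(feat), value = TRUE)
    as.matrix(feat[, cols[order(as.integer(sub(paste0(prefix, "_"), "", cols)))]])
  }
  features <- list(img = grab("img"), rna = grab("rna"), txt = grab("txt"))
  mask <- cbind(1, as.integer(feat$has_rna), as.integer(feat$has_txt))
  truth <- NULL
  tp <- file.path(dir, "truth.csv")
  if (with_truth && file.exists(tp)) truth <- utils::read.csv(tp)
  new_cohort(features, mask, meta, truth = truth)
}

#' Prediction table for a set of patients
#'
#' Runs the model in eval mode and returns the per-patient prediction
#' table: hazards, survival curve, scalar risk and gate weights.
#'
#' @param params,config model parameters and configuration.
#' @param cohort an `sg_cohort`.
#' @param idx patient row indices.
#' @param disc optional discretizer (only needed for labelled outputs).
#' @return data.frame with `patient_id`, `cancer_type`,
#'   `hazard_1..hazard_T`, `surv_1..surv_T`, `risk`, `w_img`, `w_rna`,
#'   `w_txt`.
#' @export
predict_table <- function(params, config, cohort,
                          idx = seq_len(nrow(cohort$meta)), disc = NULL) {
  batch <- make_batch(cohort, idx, disc)
  fwd <- model_forward(params, batch, config, training = FALSE)
  Tb <- config$n_bins
  out <- data.frame(patient_id = batch$patient_id,
                    cancer_type = batch$cancer)
  hz <- fwd$hazards; colnames(hz) <- paste0("hazard_", seq_len(Tb))
  sv <- fwd$surv; colnames(sv) <- paste0("surv_", seq_len(Tb))
  gw <- fwd$gates; colnames(gw) <- c("w_img", "w_rna", "w_txt")
  cbind(out, hz, sv, risk = fwd$risk, gw)
}
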