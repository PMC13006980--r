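#' Shannon entropy of a grayscale patch
#'
#' Computes the base-2 Shannon entropy of the 256-bin intensity histogram of
#' an 8-bit grayscale patch. Background tissue patches are nearly uniform in
#' intensity and therefore have low entropy; foreground tissue is textured
#' and scores high. Values lie in [0, 8] bits.
#'
#' @param patch numeric matrix or vector of integer intensities in [0, 255].
#' @return entropy in bits.
#' @export
patch_entropy <- function(patch) {
  v <- as.vector(patch)
  if (length(v) == 0) stop("patch is empty: cannot compute entropy")
  if (anyNA(v) || !is.numeric(v)) stop("patch intensities must be numeric and non-missing")
  if (any(v != floor(v))) {
    stop("patch intensities must be integers in [0, 255]; quantize (e.g. round()) before calling patch_entropy")
  }
  if (any(v < 0 | v > 255)) stop("patch intensities must lie in [0, 255]")
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts[counts > 0] / length(v)
  -sum(p * log2(p))
}

#' Filter background patches by entropy
#'
#' Discards patches whose intensity entropy falls below `threshold` bits
#' (default 5), the standard background heuristic for whole-slide-image
#' tiles. Input order of the surviving patches is preserved, and the filter
#' is idempotent.
#'
#' @param patches list of grayscale intensity matrices.
#' @param threshold entropy threshold in bits; patches with entropy
#'   strictly below it are discarded.
#' @return the retained sublist of `patches`.
#' @export
filter_patches <- function(patches, threshold = 5) {
  if (!is.list(patches) || length(patches) == 0) stop("patches must be a non-empty list")
  ent <- vapply(patches, patch_entropy, numeric(1))
  keep <- ent >= threshold
  if (!any(keep)) {
    stop("all patches discarded (entropy < ", threshold,
         "): patient has no foreground tissue")
  }
  patches[keep]
}

#' Aggregate patch features by K-means
#'
#' Clusters the N x 2048 patch-feature matrix of one patient into
#' `k' = min(k, N)` clusters and returns both the center matrix (the
#' fixed-size patch representation used when the model consumes patch
#' sequences) and their unweighted mean (the single patient-level image
#' vector). Rows are put into a canonical order before clustering so the
#' result is invariant to the order in which patches arrive.
#'
#' @param patch_features numeric matrix, one row per patch.
#' @param k target number of clusters (default 128).
#' @param seed integer seed for the K-means initialisation.
#' @param iter_max,tol K-means iteration cap and convergence tolerance.
#' @return list with `centers` (k' x D matrix), `pooled` (length-D vector),
#'   `k` (the k' actually used) and `seed`.
#' @export
kmeans_aggregate <- function(patch_features, k = 128, seed = 1,
                             iter_max = 300, tol = 1e-4) {
  x <- as.matrix(patch_features)
  if (nrow(x) < 1 || k < 1) stop("need at least one patch and k >= 1")
  if (!all(is.finite(x))) stop("non-finite patch features")
  # canonical row order: row sums, ties broken by leading columns
  ord <- do.call(order, c(list(rowSums(x)),
                          lapply(seq_len(min(3L, ncol(x))), function(j) x[, j])))
  x <- x[ord, , drop = FALSE]
  kk <- min(k, nrow(x))
  if (kk == nrow(x)) {
    centers <- x
  } else {
    fit <- with_seed(seed, stats::kmeans(x, centers = kk, iter.max = iter_max,
                                         nstart = 1, algorithm = "Lloyd"))
    centers <- fit$centers
  }
  dimnames(centers) <- NULL
  list(centers = centers, pooled = colMeans(centers), k = kk, seed = seed)
}

#' Mean pooling over rows
#'
#' Arithmetic mean over the first axis of an L x D matrix. Used identically
#' for image patch features (D = 2048), clinical-text token embeddings
#' (D = 768) and per-gene RNA embeddings (D = 256). An absent modality must
#' be flagged absent, never pooled: an empty matrix is an error.
#'
#' @param x numeric matrix with at least one row.
#' @return numeric vector of column means.
#' @export
mean_pool <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("cannot pool an empty matrix: flag the modality as absent instead")
  colMeans(x)
}

#' Pool one patient's modality arrays to fixed-size vectors
#'
#' Runs the preprocessing path for a single patient: K-means aggregation +
#' center mean for image patch features, mean pooling for RNA gene
#' embeddings and clinical-text token embeddings (text truncated at
#' `l_max` tokens; shorter sequences are pooled over their true length
#' only, so padding never enters the mean).
#'
#' @param img N x 2048 patch-feature matrix (required).
#' @param rna G x 256 gene-embedding matrix or NULL if missing.
#' @param txt L x 768 token-embedding matrix or NULL if missing.
#' @param k image cluster count.
#' @param l_max maximum text sequence length (default 200).
#' @param seed K-means seed.
#' @return list with `img` (2048), `rna` (256 or NULL), `txt` (768 or NULL),
#'   `has_rna`, `has_txt`.
#' @export
pool_patient <- function(img, rna = NULL, txt = NULL, k = 128,
                         l_max = 200, seed = 1) {
  agg <- kmeans_aggregate(img, k = k, seed = seed)
  out <- list(img = agg$pooled, rna = NULL, txt = NULL,
              has_rna = !is.null(rna), has_txt = !is.null(txt))
  if (!is.null(rna)) out$rna <- mean_pool(rna)
  if (!is.null(txt)) {
    txt <- as.matrix(txt)
    if (nrow(txt) > l_max) txt <- txt[seq_len(l_max), , drop = FALSE]
    out$txt <- mean_pool(txt)
  }
  out
}

#' Preprocess a directory of per-patient feature files
#'
#' Reads `<patient_id>.<modality>.csv` numeric matrices (modality one of
#' `img`, `rna`, `txt`; `img` required) and writes/returns the pooled
#' feature table with one row per patient: `patient_id`,
#' `img_0..img_2047`, optional `rna_*` / `txt_*` blocks (zero-filled when
#' absent) and availability flags `has_rna`, `has_txt`.
#'
#' @param dir directory containing the per-patient CSV matrices.
#' @param k,l_max,seed passed to [pool_patient()].
#' @param out optional path for the pooled CSV.
#' @return data.frame of pooled features (invisibly if `out` given).
#' @export
preprocess_features <- function(dir, k = 128, l_max = 200, seed = 1, out = NULL) {
  files <- list.files(dir, pattern = "\\.img\\.csv$")
  if (length(files) == 0) stop("no <patient_id>.img.csv files found in ", dir)
  ids <- sub("\\.img\\.csv$", "", files)
  read_mat <- function(p) as.matrix(utils::read.csv(p, header = FALSE))
  rows <- lapply(ids, function(id) {
    img <- read_mat(file.path(dir, paste0(id, ".img.csv")))
    rna_p <- file.path(dir, paste0(id, ".rna.csv"))
    txt_p <- file.path(dir, paste0(id, ".txt.csv"))
    pool_patient(img,
                 rna = if (file.exists(rna_p)) read_mat(rna_p) else NULL,
                 txt = if (file.exists(txt_p)) read_mat(txt_p) else NULL,
                 k = k, l_max = l_max, seed = seed)
  })
  d_rna <- 256L; d_txt <- 768L
  tab <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  img_m <- do.call(rbind, lapply(rows, `[[`, "img"))
  colnames(img_m) <- paste0("img_", seq_len(ncol(img_m)) - 1L)
  rna_m <- do.call(rbind, lapply(rows, function(r) r$rna %||% numeric(d_rna)))
  colnames(rna_m) <- paste0("rna_", seq_len(d_rna) - 1L)
  txt_m <- do.call(rbind, lapply(rows, function(r) r$txt %||% numeric(d_txt)))
  colnames(txt_m) <- paste0("txt_", seq_len(d_txt) - 1L)
  tab <- cbind(tab, img_m, rna_m, txt_m)
  tab$has_rna <- vapply(rows, `[[`, logical(1), "has_rna")
  tab$has_txt <- vapply(rows, `[[`, logical(1), "has_txt")
  if (!is.null(out)) {
    utils::write.csv(tab, out, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
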