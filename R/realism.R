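# Realism metrics: spectral MAE distance, recall against a reference spectra
# set, threshold selection, hierarchical subject/class aggregation, and PCA
# manifold projection.

#' Annotated spectra set
#'
#' A matrix of spectra on a shared wavelength grid with optional per-spectrum
#' annotations (subject id, class label, image id).
#'
#' @param spectra numeric matrix, one spectrum per row, values in \[0, 1\].
#' @param wavelengths shared wavelength grid (nm), length `ncol(spectra)`.
#' @param subject_id,class_label,image_id optional per-row annotations.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(spectra, wavelengths, subject_id = NULL,
                        class_label = NULL, image_id = NULL) {
  spectra <- as.matrix(spectra)
  stopifnot(length(wavelengths) == ncol(spectra))
  chk <- function(a) is.null(a) || length(a) == nrow(spectra)
  stopifnot(chk(subject_id), chk(class_label), chk(image_id))
  structure(list(spectra = spectra, wavelengths = as.numeric(wavelengths),
                 subject_id = subject_id, class_label = class_label,
                 image_id = image_id),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("Spectra set: %d spectra x %d bands (%g-%g nm)\n",
              nrow(x$spectra), ncol(x$spectra), min(x$wavelengths),
              max(x$wavelengths)))
  invisible(x)
}

#' Spectral mean-absolute-error distance
#'
#' \eqn{d(a, b) = \frac{1}{n_\lambda}\sum_\lambda |a_\lambda - b_\lambda|}:
#' symmetric, zero iff the spectra are identical.
#'
#' @param a,b spectra on the same wavelength grid.
#' @return The distance.
#' @export
spectral_mae <- function(a, b) {
  if (length(a) != length(b)) stop("spectra are on different grids")
  mean(abs(a - b))
}

#' Spectral recall
#'
#' Fraction of reference spectra in `A` that have at least one candidate
#' spectrum in `B` strictly within the distance threshold `d_max` under the
#' spectral MAE distance. Nearest-neighbour search is exact (ties at exactly
#' `d_max` count as misses).
#'
#' @param A reference [spectra_set()] (or matrix).
#' @param B candidate [spectra_set()] (or matrix) on the same grid.
#' @param d_max distance threshold, > 0.
#' @return Recall fraction in \[0, 1\].
#' @export
spectral_recall <- function(A, B, d_max = 0.02) {
  stopifnot(d_max > 0)
  a <- if (inherits(A, "spectra_set")) A$spectra else as.matrix(A)
  b <- if (inherits(B, "spectra_set")) B$spectra else as.matrix(B)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty spectra set")
  if (ncol(a) != ncol(b)) stop("spectra sets are on different grids")
  nn <- nn_mae_cpp(a, b)
  mean(nn$distance < d_max)
}

#' Hierarchical spectral recall
#'
#' Three-level aggregation of the binary per-spectrum recall decision: first
#' per spectrum, then averaged per (subject, class), finally averaged across
#' subjects to give one score per class. Subjects without spectra of a class
#' are skipped at that class (not zero-filled), so each subject contributes
#' equally regardless of its pixel count.
#'
#' @param A annotated reference [spectra_set()] with `subject_id` and
#'   `class_label`.
#' @param B candidate [spectra_set()] (or matrix).
#' @param d_max distance threshold.
#' @return Data frame with `class`, `n_subjects`, `recall`.
#' @export
hierarchical_recall <- function(A, B, d_max = 0.02) {
  stopifnot(inherits(A, "spectra_set"))
  if (is.null(A$subject_id) || is.null(A$class_label)) {
    stop("reference set must carry subject_id and class_label annotations")
  }
  b <- if (inherits(B, "spectra_set")) B$spectra else as.matrix(B)
  nn <- nn_mae_cpp(A$spectra, b)
  hit <- nn$distance < d_max
  per_subject_class <- stats::aggregate(
    hit, by = list(subject = A$subject_id, class = A$class_label), FUN = mean)
  per_class <- stats::aggregate(
    per_subject_class$x, by = list(class = per_subject_class$class),
    FUN = mean)
  counts <- stats::aggregate(
    per_subject_class$subject,
    by = list(class = per_subject_class$class), FUN = length)
  data.frame(class = per_class$class, n_subjects = counts$x,
             recall = per_class$x)
}

#' Select the recall distance threshold
#'
#' For each candidate set the recall curve over the threshold grid is
#' computed and the grid point with the steepest recall increase (maximal
#' forward difference) is taken as that model's optimal threshold; the final
#' threshold is the lowest across candidates. A flat recall curve signals a
#' warning and contributes the smallest grid point.
#'
#' @param A reference [spectra_set()] (or matrix).
#' @param candidate_sets list of candidate sets.
#' @param grid monotone increasing threshold grid; default 50 log-spaced
#'   points on \[1e-3, 1e-1\].
#' @return The selected threshold (scalar), with attribute `per_model` giving
#'   each candidate's steepest-increase threshold.
#' @export
select_threshold <- function(A, candidate_sets,
                             grid = 10^seq(-3, -1, length.out = 50)) {
  stopifnot(length(grid) >= 2, all(diff(grid) > 0))
  a <- if (inherits(A, "spectra_set")) A$spectra else as.matrix(A)
  per_model <- vapply(candidate_sets, function(B) {
    b <- if (inherits(B, "spectra_set")) B$spectra else as.matrix(B)
    dmin <- nn_mae_cpp(a, b)$distance
    recall <- vapply(grid, function(t) mean(dmin < t), numeric(1))
    inc <- diff(recall)
    if (all(inc == 0)) {
      warning("flat recall curve; returning the smallest grid point")
      return(grid[1])
    }
    grid[which.max(inc) + 1L]
  }, numeric(1))
  structure(min(per_model), per_model = per_model)
}

#' PCA realism projection
#'
#' Fits a principal-component basis to the reference spectra averaged per
#' (image, class) — approximating the measured reflectance manifold — and
#' projects every candidate set with the frozen loadings. Returns 2-D
#' embeddings, per-class mean coordinates of the reference, and a descriptive
#' coverage summary (fraction of candidate projections inside the reference
#' bounding box, per set).
#'
#' @param reference annotated [spectra_set()] with `image_id` and
#'   `class_label`.
#' @param candidates list of candidate sets (matrices or [spectra_set()]s).
#' @param components number of principal components (default 2).
#' @return List with `rotation`, `center`, `explained`, `reference_scores`,
#'   `reference_class_means`, `candidate_scores`, `coverage`.
#' @export
pca_realism <- function(reference, candidates = list(), components = 2) {
  stopifnot(inherits(reference, "spectra_set"))
  if (is.null(reference$image_id) || is.null(reference$class_label)) {
    stop("reference set must carry image_id and class_label annotations")
  }
  key <- interaction(reference$image_id, reference$class_label, drop = TRUE)
  avg <- rowsum(reference$spectra, key) / as.vector(table(key))
  if (nrow(avg) < components) {
    stop("fewer image/class-averaged spectra than components")
  }
  pca <- stats::prcomp(avg, center = TRUE, scale. = FALSE)
  rot <- pca$rotation[, seq_len(components), drop = FALSE]
  ctr <- pca$center
  project <- function(m) sweep(as.matrix(m), 2, ctr) %*% rot
  ref_scores <- project(reference$spectra)
  class_means <- rowsum(ref_scores, reference$class_label) /
    as.vector(table(reference$class_label))
  box_lo <- apply(ref_scores, 2, min)
  box_hi <- apply(ref_scores, 2, max)
  cand_scores <- lapply(candidates, function(B) {
    b <- if (inherits(B, "spectra_set")) B$spectra else as.matrix(B)
    project(b)
  })
  coverage <- vapply(cand_scores, function(s) {
    inside <- rep(TRUE, nrow(s))
    for (j in seq_len(ncol(s))) {
      inside <- inside & s[, j] >= box_lo[j] & s[, j] <= box_hi[j]
    }
    mean(inside)
  }, numeric(1))
  explained <- pca$sdev^2 / sum(pca$sdev^2)
  list(rotation = rot, center = ctr,
       explained = explained[seq_len(components)],
       reference_scores = ref_scores,
       reference_class_means = class_means,
       candidate_scores = cand_scores, coverage = coverage)
}

#' Seeded equal-size subsampling of a spectra set
#'
#' Uniformly subsamples a set to a configured count so that sets of different
#' sizes can be compared without a size confounder.
#'
#' @param set a [spectra_set()].
#' @param size target spectrum count (<= available).
#' @param seed integer seed.
#' @return A [spectra_set()] with `size` rows.
#' @export
subsample_spectra <- function(set, size, seed) {
  stopifnot(inherits(set, "spectra_set"), size >= 1,
            size <= nrow(set$spectra))
  set.seed(seed)
  idx <- sample(nrow(set$spectra), size)
  spectra_set(set$spectra[idx, , drop = FALSE], set$wavelengths,
              subject_id = set$subject_id[idx],
              class_label = set$class_label[idx],
              image_id = set$image_id[idx])
}
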