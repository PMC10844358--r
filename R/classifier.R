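new_classifier <- function(kind, threshold = 0.5, model = NULL, meta = list()) {
  stopifnot(kind %in% c("trained", "heuristic", "oracle", "constant"),
            is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 1)
  structure(list(kind = kind, decision_threshold = threshold,
                 model = model, meta = meta),
            class = "lumen_classifier")
}

#' @export
print.lumen_classifier <- function(x, ...) {
  cat(sprintf("lumen_classifier (%s), decision threshold %.2f\n",
              x$kind, x$decision_threshold))
  if (!is.null(x$meta$holdout_accuracy))
    cat(sprintf("  held-out accuracy: %.3f (n = %d)\n",
                x$meta$holdout_accuracy, x$meta$holdout_n))
  invisible(x)
}

#' Constant classifier
#'
#' Assigns the same probability to every candidate. With \code{p = 1} it
#' accepts everything, which turns the pipeline into pure phase-I detection.
#'
#' @param p constant probability in \[0, 1\].
#' @param threshold decision threshold.
#' @return A \code{"lumen_classifier"}.
#' @export
constant_classifier <- function(p = 1, threshold = 0.5) {
  stopifnot(p >= 0, p <= 1)
  new_classifier("constant", threshold, model = list(p = p))
}

#' Ground-truth oracle classifier
#'
#' Classifies a candidate as a true lumen exactly when at least half of its
#' pixels fall inside a ground-truth true-lumen void of a synthetic stack.
#' Used to test the pipeline independently of any trained model.
#'
#' @param truth a \code{"synthetic_ground_truth"} from
#'   \code{\link{generate_stack}}.
#' @param threshold decision threshold.
#' @return A \code{"lumen_classifier"}.
#' @export
oracle_classifier <- function(truth, threshold = 0.5) {
  stopifnot(inherits(truth, "synthetic_ground_truth"))
  new_classifier("oracle", threshold, model = list(truth = truth))
}

#' Rule-based baseline classifier
#'
#' Scores candidates with a fixed, documented logistic rule (see
#' \code{\link{heuristic_score}}) combining interior darkness, shape solidity
#' and rim contrast. Requires no training data.
#'
#' @param threshold decision threshold.
#' @return A \code{"lumen_classifier"}.
#' @export
heuristic_classifier <- function(threshold = 0.5) {
  new_classifier("heuristic", threshold)
}

#' Logistic score of the rule-based baseline
#'
#' A true lumen is a dark, compact void surrounded by a bright cell wall. The
#' baseline scores this as
#' \deqn{p = logistic(-2 - 3 \cdot interior + 2 \cdot solidity + 5 \cdot rim)}
#' where \code{interior} is the mean fused intensity inside the candidate
#' (lower is more lumen-like), \code{solidity} is candidate area divided by
#' its convex-hull area (higher is more lumen-like) and \code{rim} is the
#' mean intensity in a thin dilation ring minus the interior mean (higher is
#' more lumen-like). Coefficients are fixed constants of the package.
#'
#' @param interior_mean mean interior intensity in \[0, 1\].
#' @param solidity area / convex-hull area in \[0, 1\].
#' @param rim_contrast rim-minus-interior intensity difference in \[-1, 1\].
#' @return probability in \[0, 1\].
#' @export
heuristic_score <- function(interior_mean, solidity, rim_contrast) {
  plogis(-2 - 3 * interior_mean + 2 * solidity + 5 * rim_contrast)
}

# Shoelace area of a polygon given vertex coordinates.
polygon_area <- function(y, x) {
  n <- length(y)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Geometric and photometric features of a candidate on its fused slice
#'
#' Computes the three inputs of \code{\link{heuristic_score}}: mean interior
#' intensity, solidity (pixel count over convex-hull area, hull area estimated
#' from pixel centers with a half-pixel boundary correction, capped at 1) and
#' rim contrast (mean intensity in a ~2 px dilation ring minus the interior
#' mean).
#'
#' @param candidate a \code{"candidate_lumen2d"}.
#' @param fused the matching \code{"fused_slice"}.
#' @param calibration a \code{\link{calibration}}.
#' @return named numeric vector \code{(interior_mean, solidity,
#'   rim_contrast)}.
#' @export
candidate_features <- function(candidate, fused, calibration) {
  stopifnot(inherits(candidate, "candidate_lumen2d"),
            inherits(fused, "fused_slice"))
  if (candidate$z_index != fused$z_index)
    stop("candidate and fused slice are from different z-indices")
  idx <- candidate$idx
  H <- candidate$dim[1]
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  interior <- mean(fused$raster[idx])
  hp <- chull(cols, rows)
  hull_area <- polygon_area(rows[hp], cols[hp]) + length(hp) / 2 + 1
  solidity <- min(1, length(idx) / max(hull_area, length(idx)))
  ring <- close_ring_indices(candidate, 2L)
  rim <- if (length(ring)) mean(fused$raster[ring]) else interior
  c(interior_mean = interior, solidity = solidity,
    rim_contrast = rim - interior)
}

# Pixels within `width` px of the candidate but not inside it (dilation ring).
close_ring_indices <- function(candidate, width = 2L) {
  m <- candidate_mask(candidate)
  d <- cpp_edt2d_sq(m)
  which(d > 0 & d <= as.numeric(width)^2)
}

# Pixel-only feature vector used by the trainable backend: radial zone
# statistics of the standardized patch. The center zone covers the void, the
# outer zone the wall, so contrast-style features are learnable from patches
# alone (geometry is not available at training time).
patch_features <- function(patch) {
  px <- patch$pixels
  s <- nrow(px)
  ctr <- (s + 1) / 2
  rr <- sqrt(outer(((seq_len(s) - ctr))^2, ((seq_len(s) - ctr))^2, "+")) / (s / 2)
  center <- px[rr <= 0.33]
  mid <- px[rr > 0.33 & rr <= 0.66]
  outer_z <- px[rr > 0.66 & rr <= 1]
  gy <- diff(px)
  gx <- t(diff(t(px)))
  c(center_mean = mean(center), center_sd = sd(center),
    center_dark_frac = mean(center < 0.2),
    mid_mean = mean(mid), mid_sd = sd(mid),
    outer_mean = mean(outer_z), outer_sd = sd(outer_z),
    ring_contrast = mean(outer_z) - mean(center),
    mid_contrast = mean(mid) - mean(center),
    q10 = unname(quantile(px, 0.1)), q50 = unname(quantile(px, 0.5)),
    q90 = unname(quantile(px, 0.9)),
    grad_energy = mean(gy^2) + mean(gx^2),
    global_sd = sd(px))
}

#' Train the feature-based lumen classifier
#'
#' Trains a random forest (via \pkg{ranger}) on radial-zone intensity
#' features of labeled patches. The data are split 80/20 with stratification
#' by label (seeded, reproducible); the model is fit on the 80% split and its
#' accuracy on the held-out 20% is stored in the training log
#' (\code{meta$holdout_accuracy}).
#'
#' @param patches list of \code{"labeled_patch"} objects containing both
#'   classes.
#' @param seed integer seed controlling the split and the forest.
#' @param num_trees number of trees. Default 300.
#' @param threshold decision threshold of the resulting classifier.
#' @return A \code{"lumen_classifier"} of kind \code{"trained"}.
#' @importFrom ranger ranger
#' @export
train_classifier <- function(patches, seed, num_trees = 300, threshold = 0.5) {
  stopifnot(length(patches) >= 2,
            all(vapply(patches, inherits, logical(1), "labeled_patch")))
  labels <- vapply(patches, function(p) p$label, character(1))
  if (length(unique(labels)) < 2)
    stop("training requires both true_lumen and false_lumen examples")
  feats <- t(vapply(patches, function(p) patch_features(p$patch),
                    numeric(length(patch_features(patches[[1]]$patch)))))
  df <- as.data.frame(feats)
  df$label <- factor(labels, levels = c("false_lumen", "true_lumen"))
  test_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(df)), df$label), function(ii) {
      k <- max(1L, round(0.2 * length(ii)))
      sample(ii, k)
    }), use.names = FALSE)
  })
  train_df <- df[-test_idx, , drop = FALSE]
  test_df <- df[test_idx, , drop = FALSE]
  fit <- ranger::ranger(label ~ ., data = train_df, num.trees = num_trees,
                        probability = TRUE, seed = seed, num.threads = 1)
  pred <- predict(fit, data = test_df, num.threads = 1)$predictions
  acc <- mean((pred[, "true_lumen"] >= threshold) ==
                (test_df$label == "true_lumen"))
  new_classifier("trained", threshold, model = list(fit = fit),
                 meta = list(holdout_accuracy = acc,
                             holdout_n = nrow(test_df),
                             n_train = nrow(train_df), seed = seed,
                             feature_names = colnames(feats)))
}

#' Probability that a candidate patch is a true lumen
#'
#' Dispatches on the classifier kind. The heuristic and oracle kinds need the
#' originating candidate (and, for the heuristic, its fused slice) to compute
#' geometry or look up ground truth; the trained and constant kinds use the
#' patch alone. Predictions are deterministic given the classifier state.
#'
#' @param object a \code{"lumen_classifier"}.
#' @param patch a \code{"lumen_patch"} (side length must match the trained
#'   model's, if trained).
#' @param candidate optional \code{"candidate_lumen2d"}.
#' @param fused optional \code{"fused_slice"}.
#' @param calibration optional \code{\link{calibration}}.
#' @param ... unused.
#' @return probability in \[0, 1\]; accept when it is at least
#'   \code{object$decision_threshold}.
#' @export
predict.lumen_classifier <- function(object, patch, candidate = NULL,
                                     fused = NULL, calibration = NULL, ...) {
  stopifnot(inherits(patch, "lumen_patch"))
  switch(object$kind,
    constant = object$model$p,
    heuristic = {
      if (is.null(candidate) || is.null(fused))
        stop("heuristic classifier needs the candidate and its fused slice")
      f <- candidate_features(candidate, fused, calibration)
      unname(heuristic_score(f["interior_mean"], f["solidity"],
                             f["rim_contrast"]))
    },
    oracle = {
      if (is.null(candidate))
        stop("oracle classifier needs the candidate")
      truth_label_prob(object$model$truth, candidate)
    },
    trained = {
      mdl <- object$model$fit
      f <- patch_features(patch)
      if (!identical(names(f), object$meta$feature_names))
        stop("patch does not match the classifier's expected feature layout")
      df <- as.data.frame(as.list(f))
      unname(predict(mdl, data = df, num.threads = 1)$predictions[, "true_lumen"])
    })
}

# Fraction of candidate pixels inside a ground-truth true lumen; oracle
# probability is the 0/1 indicator of that fraction reaching one half.
truth_label_prob <- function(truth, candidate) {
  if (length(truth$labels) == 0) return(0)
  lab_slice <- truth$void_masks[, , candidate$z_index + 1L]
  ids <- lab_slice[candidate$idx]
  frac <- mean(ids > 0 & truth$labels[pmax(ids, 1L)] == "true_lumen")
  as.numeric(frac >= 0.5)
}

#' Serialize a classifier to a single file
#'
#' Writes a version-stamped container so that \code{\link{load_classifier}}
#' can validate the format. Round-tripping preserves predictions exactly.
#'
#' @param clf a \code{"lumen_classifier"}.
#' @param path output file path.
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "lumen_classifier"))
  saveRDS(list(format = "lumenr_classifier", version = 1L, classifier = clf),
          path)
  invisible(path)
}

#' @rdname save_classifier
#' @return \code{load_classifier} returns the deserialized
#'   \code{"lumen_classifier"}.
#' @export
load_classifier <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || !identical(x$format, "lumenr_classifier"))
    stop("not a lumenr classifier file: ", path)
  if (!identical(x$version, 1L))
    stop("unsupported classifier format version: ", x$version)
  x$classifier
}
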