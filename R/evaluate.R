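# Pipeline-level evaluation: the selection filter used before expert
# studies, the flip-rate sweep over the regularisation strength, and
# lesion-count deltas measured with the phantom lesion oracle.

#' Filter counterfactual pairs for study inclusion
#'
#' Keeps pairs for which the classifier correctly classifies the original
#' image AND the counterfactual's target-class confidence strictly exceeds
#' the threshold. Filtering is idempotent and kept/excluded counts
#' reconcile with the input.
#'
#' @param X0 Matrix of original images (rows, `[0,1]`).
#' @param labels True class labels of the originals (1-based).
#' @param result A `counterfactual_result` for the same rows.
#' @param classifier The classifier used for the correctness check.
#' @param threshold Confidence threshold (strict inequality), default 0.5.
#' @return List with `kept` (row indices), `report` (a data frame with
#'   per-pair `correct_original`, `confidence`, `kept`), and counts
#'   `n_kept` / `n_excluded`.
#' @export
filter_counterfactuals <- function(X0, labels, result, classifier,
                                   threshold = 0.5) {
  pred <- predict(classifier, X0, type = "class")
  correct <- pred == labels
  conf <- result$target_confidence
  keep <- correct & conf > threshold
  report <- data.frame(correct_original = correct, confidence = conf,
                       kept = keep)
  list(kept = which(keep), report = report,
       n_kept = sum(keep), n_excluded = sum(!keep))
}

#' Flip-rate table over the regularisation strength
#'
#' For each `lambda_d` and each direction (healthy-to-diseased and
#' diseased-to-healthy in the binary referable task), generates diffusion
#' counterfactuals and reports the fraction whose predicted class does not
#' change to the target. Denominators are the correctly classified
#' originals. The same seed is reused across `lambda_d` values (common
#' random numbers), so rows are comparable.
#'
#' @param X_normal,X_referable Matrices of original images per direction.
#' @param lambdas Decreasing vector of regularisation strengths.
#' @param denoiser,classifiers,schedule,config Passed to [generate_dvc()];
#'   `config$lambda_d` and `config$target` are overridden per cell.
#' @return Data frame with columns `lambda_d`, `healthy_to_diseased`,
#'   `diseased_to_healthy` (non-flip fractions in `[0,1]`), plus the two
#'   denominators, sorted by `lambda_d` descending.
#' @export
flip_rate_table <- function(X_normal, X_referable, lambdas,
                            denoiser, classifiers,
                            schedule = denoiser$schedule,
                            config = guidance_config()) {
  lambdas <- sort(lambdas, decreasing = TRUE)
  ok_n <- predict(classifiers$plain, X_normal, type = "class") == 1L
  ok_r <- predict(classifiers$plain, X_referable, type = "class") == 2L
  res <- data.frame(lambda_d = lambdas, healthy_to_diseased = NA_real_,
                    diseased_to_healthy = NA_real_,
                    n_healthy = sum(ok_n), n_diseased = sum(ok_r))
  for (i in seq_along(lambdas)) {
    cfg <- config
    cfg$lambda_d <- lambdas[i]
    r_hd <- generate_dvc(X_normal[ok_n, , drop = FALSE], k = 2L, denoiser,
                         classifiers, schedule, cfg)
    r_dh <- generate_dvc(X_referable[ok_r, , drop = FALSE], k = 1L, denoiser,
                         classifiers, schedule, cfg)
    res$healthy_to_diseased[i] <- mean(!r_hd$flipped)
    res$diseased_to_healthy[i] <- mean(!r_dh$flipped)
  }
  res
}

#' Median lesion-count changes between originals and counterfactuals
#'
#' Runs the lesion oracle on each original and counterfactual and reports
#' the median per-type and total count change (counterfactual minus
#' original). The median is robust to occasional guidance failures.
#'
#' @param X0 Matrix of original images (rows).
#' @param X_cf Matrix of counterfactual images (rows, same order).
#' @param modality `"fundus"` or `"oct"`.
#' @param img_dim Image dimensions used to reshape rows, e.g. `c(32, 32, 3)`.
#' @return List with `median_delta` (named, per type plus `total`) and the
#'   per-pair delta matrix.
#' @export
lesion_delta_report <- function(X0, X_cf, modality, img_dim) {
  stopifnot(nrow(X0) == nrow(X_cf))
  count1 <- function(row) {
    px <- array(row, dim = img_dim)
    if (modality == "oct" && length(img_dim) == 2L) px <- matrix(row, img_dim[1])
    lesion_oracle(px, modality)
  }
  c0 <- t(apply(X0, 1L, count1))
  c1 <- t(apply(X_cf, 1L, count1))
  delta <- c1 - c0
  med <- apply(delta, 2L, stats::median)
  list(median_delta = c(med, total = stats::median(rowSums(delta))),
       delta = delta)
}
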