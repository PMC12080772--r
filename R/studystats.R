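# Statistics for the expert studies: Wilson binomial intervals for
# odd-one-out detection rates, odds ratios from 2x2 tables, a logistic GLM
# over trial-level predictors, and a simulator of odd-one-out studies for
# testing parameter recovery.

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes Number of successes, `0 <= successes <= n`.
#' @param n Number of trials, `>= 1`.
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(lower, upper)`, both inside `[0, 1]`.
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (n < 1) stop("n must be at least 1")
  if (successes < 0 || successes > n) stop("successes must lie in [0, n]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Odds ratio of a 2x2 contingency table with a Wald interval
#'
#' Rows are the two conditions, columns are (correct, incorrect) counts:
#' `OR = (a/b) / (c/d)` for table `rbind(c(a, b), c(c, d))`, with
#' `CI = exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param table 2x2 numeric matrix of non-negative counts.
#' @param level Confidence level.
#' @param continuity If `TRUE`, add 0.5 to every cell (required when any
#'   cell is zero).
#' @return List with `or`, `ci` (lower/upper), and `level`.
#' @export
odds_ratio_2x2 <- function(table, level = 0.95, continuity = FALSE) {
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(table == 0)) {
    if (!continuity) stop("zero cell; set continuity = TRUE to add 0.5 to all cells")
    table <- table + 0.5
  }
  or <- (table[1, 1] / table[1, 2]) / (table[2, 1] / table[2, 2])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / table))
  ci <- exp(log(or) + c(-1, 1) * z * se)
  list(or = or, ci = c(lower = ci[1], upper = ci[2]), level = level)
}

#' Logistic regression over trial-level predictors
#'
#' Maximum-likelihood logistic fit (`stats::glm`, IRLS) of a binary outcome
#' on the given predictor columns; reports exponentiated coefficients as
#' odds ratios with Wald intervals and p-values. Errors on rank-deficient
#' designs and on perfect separation, naming the offending predictor.
#'
#' @param trials Data frame of trials.
#' @param predictors Character vector of predictor column names.
#' @param outcome Name of the 0/1 outcome column (default `"correct"`).
#' @param level Confidence level for the Wald intervals.
#' @return Data frame with one row per coefficient (excluding the
#'   intercept): `term`, `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`.
#' @export
logistic_glm <- function(trials, predictors, outcome = "correct",
                         level = 0.95) {
  stopifnot(all(c(predictors, outcome) %in% names(trials)))
  if (length(unique(trials[[outcome]])) < 2) {
    stop("outcome must take two distinct values")
  }
  const <- predictors[vapply(predictors, function(p)
    length(unique(trials[[p]])) < 2, TRUE)]
  if (length(const)) {
    stop("rank-deficient design; constant predictor: ",
         paste(const, collapse = ", "))
  }
  fml <- stats::as.formula(paste(outcome, "~", paste(predictors, collapse = "+")))
  mm <- stats::model.matrix(fml, trials)
  if (qr(mm)$rank < ncol(mm)) {
    stop("rank-deficient design; aliased predictors among: ",
         paste(predictors, collapse = ", "))
  }
  fit <- withCallingHandlers(
    stats::glm(fml, data = trials, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("perfect separation detected for predictors: ",
             paste(predictors, collapse = ", "), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  if (any(abs(stats::coef(fit)[-1]) > 15)) {
    bad <- names(which(abs(stats::coef(fit)[-1]) > 15))
    stop("perfect separation detected for predictor: ",
         paste(bad, collapse = ", "))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  keep <- rownames(sm) != "(Intercept)"
  data.frame(term = rownames(sm)[keep],
             odds_ratio = exp(sm[keep, "Estimate"]),
             ci_lower = exp(sm[keep, "Estimate"] - z * sm[keep, "Std. Error"]),
             ci_upper = exp(sm[keep, "Estimate"] + z * sm[keep, "Std. Error"]),
             p_value = sm[keep, "Pr(>|z|)"],
             row.names = NULL)
}

#' Chance level of an n-alternative forced choice
#'
#' @param n_alternatives Number of alternatives (>= 1).
#' @return `1 / n_alternatives`; 3 alternatives give 1/3 (prints as 33%).
#' @export
chance_level <- function(n_alternatives) {
  if (n_alternatives < 1) stop("n_alternatives must be at least 1")
  1 / n_alternatives
}

#' Simulate an odd-one-out study
#'
#' Generates Bernoulli trial outcomes from a logistic model
#' `logit P(correct) = logit(base_p) + log(arm_or) [SVC] +
#' log(label_or) [healthy] + log(group_or) [ophthalmologist]`.
#' Each rater answers `trials_per_rater` trials, split evenly between the
#' DVC and SVC arms and between the two image classes.
#'
#' @param n_raters Total raters; the first `n_ophthalmologists` are
#'   ophthalmologists, the rest AI researchers.
#' @param n_ophthalmologists Number of ophthalmologist raters.
#' @param trials_per_rater Trials per rater (even).
#' @param base_p Baseline success probability (DVC arm, DR image, AI
#'   researcher); the default is the three-alternative chance level.
#' @param arm_or,label_or,group_or Odds ratios of the three factors.
#' @param seed Integer seed.
#' @return Data frame of trials: `rater_id`, `rater_group`, `arm`,
#'   `image_class`, `correct`.
#' @export
simulate_study <- function(n_raters = 10L, n_ophthalmologists = 6L,
                           trials_per_rater = 80L,
                           base_p = chance_level(3),
                           arm_or = 1, label_or = 1, group_or = 1,
                           seed = 1L) {
  grid <- expand.grid(rater_id = seq_len(n_raters),
                      arm = c("DVC", "SVC"),
                      image_class = c("DR", "healthy"),
                      rep = seq_len(trials_per_rater %/% 4L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rater_group <- ifelse(grid$rater_id <= n_ophthalmologists,
                             "ophthalmologist", "ai_researcher")
  eta <- stats::qlogis(base_p) +
    log(arm_or) * (grid$arm == "SVC") +
    log(label_or) * (grid$image_class == "healthy") +
    log(group_or) * (grid$rater_group == "ophthalmologist")
  withr::with_seed(seed, {
    grid$correct <- stats::rbinom(nrow(grid), 1L, stats::plogis(eta))
  })
  grid[, c("rater_id", "rater_group", "arm", "image_class", "correct")]
}
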