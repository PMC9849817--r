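#' Reference per-run confusion indicators of a yes/no disease classifier
#'
#' Percent-scale sensitivity, specificity, precision, accuracy and F1 score
#' of ten runs of 10-fold cross-validation of the reference fruit-tree
#' disease yes/no classifier. Used to exercise and check the mean/SD
#' aggregation in [confusion_stats()].
#'
#' @format data frame with 10 rows and columns `run`, `sensitivity`,
#'   `specificity`, `precision`, `accuracy`, `f1`.
#' @export
yesno_cv_runs <- data.frame(
  run = 1:10,
  sensitivity = c(91.25, 94.29, 92.04, 93.10, 94.93, 93.69, 94.12, 94.55, 91.75, 95.08),
  specificity = c(93.11, 92.39, 93.73, 91.38, 94.19, 92.09, 92.34, 96.35, 92.75, 94.38),
  precision   = c(92.98, 93.38, 92.53, 91.24, 94.09, 92.21, 92.47, 96.28, 92.66, 95.06),
  accuracy    = c(92.12, 93.34, 93.09, 92.24, 94.56, 92.89, 93.23, 95.45, 92.15, 94.73),
  f1          = c(92.23, 93.34, 92.42, 92.23, 94.55, 92.88, 93.22, 95.44, 92.15, 95.24)
)
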