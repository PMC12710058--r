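# Evaluation metrics: regression (R^2, RMSE) and risk-level classification
# (confusion matrix, overall accuracy, Cohen's kappa).

#' Regression metrics
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)` and
#' `RMSE = sqrt(mean((yhat - y)^2))`.
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @return List with `r2` and `rmse`. Zero-variance `y_true` gives
#'   `r2 = NA` with a warning.
#' @export
evaluate_regression <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2)
    cp_stop("evaluate_regression(): need equal lengths >= 2")
  ss_res <- sum((y_true - y_pred)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot == 0) {
    warning("evaluate_regression(): zero-variance y_true, R2 undefined")
    NA_real_
  } else 1 - ss_res / ss_tot
  list(r2 = r2, rmse = sqrt(mean((y_pred - y_true)^2)))
}

#' Classification metrics for risk levels
#'
#' Confusion matrix over the class set, overall accuracy
#' `ACC = Po * 100 %` with `Po = sum_i T_i / n`, and Cohen's kappa
#' `(Po - Pe) / (1 - Pe)` with `Pe = sum_i a_i b_i / n^2` (actual and
#' predicted class totals).
#'
#' @param levels_true,levels_pred Integer class labels of equal length.
#' @param classes Class set (default the five risk levels `0:4`).
#' @return List with `confusion` (actual rows x predicted columns), `acc`
#'   (percent), `kappa`.
#' @export
evaluate_classification <- function(levels_true, levels_pred, classes = 0:4) {
  if (length(levels_true) != length(levels_pred))
    cp_stop("evaluate_classification(): length mismatch")
  conf <- table(factor(levels_true, levels = classes),
                factor(levels_pred, levels = classes))
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (pe >= 1) 1 else (po - pe) / (1 - pe)
  list(confusion = conf, acc = po * 100, kappa = kappa)
}

#' Predict CDRI and risk levels from the two phenotype models
#'
#' `CDRI = predicted PPPI - predicted RNAT / 650`; negative RNAT
#' predictions are clipped at 0 (RNAT is nonnegative by definition).
#' Both models must have been trained on the same feature columns.
#'
#' @param pppi_model,rnat_model `model_bundle`s (or `tree_ensemble`s) for
#'   PPPI and RNAT.
#' @param features Feature matrix/data.frame with the training columns.
#' @return data.frame with `pppi_pred`, `rnat_pred`, `cdri`, `level`.
#' @export
predict_risk <- function(pppi_model, rnat_model, features) {
  f1 <- pppi_model$feature_names; f2 <- rnat_model$feature_names
  if (!identical(sort(f1), sort(f2)))
    cp_stop("predict_risk(): models were trained on different feature sets")
  pp <- predict(pppi_model, features)
  rn <- pmax(predict(rnat_model, features), 0)
  res <- cdri(pp, rn)
  data.frame(pppi_pred = pp, rnat_pred = rn, cdri = res$cdri,
             level = res$level)
}
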