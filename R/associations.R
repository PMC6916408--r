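#' Collapse the four-level diet-breadth coding to three levels
#'
#' Category 4 is merged into category 3 (used when the top category holds a
#' single species); other levels are unchanged.
#'
#' @param diet Integer-valued vector with values in 1..4.
#' @return The collapsed vector with values in 1..3.
#' @export
collapse_diet <- function(diet) {
  ok <- is.na(diet) | (diet %in% 1:4)
  if (!all(ok))
    stop("diet breadth values out of range 1..4: ",
         paste(unique(diet[!ok]), collapse = ", "))
  pmin(diet, 3)
}

#' PGLS association suite: components vs ecological predictors
#'
#' For each (response, predictor) pair fits `response ~ control + predictor`
#' by PGLS; the predictor's slope, t and p are reported. Ordinal predictors
#' (diet breadth) enter as a single numeric covariate. Per-model failures
#' (e.g. a constant predictor) are recorded and the suite continues.
#'
#' @param table Data frame with `species`, the response and control columns,
#'   and the predictor columns.
#' @param tree A `phylo` tree.
#' @param responses Character vector of response column names (default
#'   `c("log_cx", "log_cb")`).
#' @param predictors Character vector of predictor column names.
#' @param control Control column entered alongside each predictor (default
#'   `"log_rob"`; `NULL` for none).
#' @param lambda Passed to [fit_pgls()].
#' @return An `association_report`: data frame with one row per pair
#'   (`response`, `predictor`, `slope`, `se`, `t`, `p`, `n`, `df`,
#'   `lambda`, `error`), attribute `"fits"` holding the `pgls_fit`s and
#'   attribute `"n_tests"` the number of models attempted (reported because
#'   no multiplicity correction is applied).
#' @export
run_association_suite <- function(table, tree,
                                  responses = c("log_cx", "log_cb"),
                                  predictors, control = "log_rob",
                                  lambda = 1) {
  stopifnot("species" %in% names(table))
  rows <- list(); fits <- list()
  for (resp in responses) {
    for (pred in predictors) {
      rhs <- paste(c(control, pred), collapse = " + ")
      f <- stats::as.formula(paste(resp, "~", rhs))
      fit <- tryCatch(pgls(f, table, tree, lambda = lambda),
                      error = function(e) e)
      key <- paste(resp, pred, sep = "~")
      if (inherits(fit, "error")) {
        rows[[key]] <- data.frame(response = resp, predictor = pred,
                                  slope = NA_real_, se = NA_real_,
                                  t = NA_real_, p = NA_real_,
                                  n = NA_integer_, df = NA_integer_,
                                  lambda = NA_real_,
                                  error = conditionMessage(fit),
                                  stringsAsFactors = FALSE)
        next
      }
      fits[[key]] <- fit
      co <- fit$coefficients
      j <- match(pred, co$term)
      rows[[key]] <- data.frame(response = resp, predictor = pred,
                                slope = co$estimate[j], se = co$se[j],
                                t = co$t[j], p = co$p[j], n = fit$n,
                                df = fit$df, lambda = fit$lambda,
                                error = "", stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  structure(rep, fits = fits, n_tests = nrow(rep),
            class = c("association_report", "data.frame"))
}

#' Whole-brain models: brain vs body and vs components
#'
#' Fits `log_brain ~ log_body` (+ optional ecological trait),
#' `log_brain ~ log_cx + log_cb + log_rob` and the same plus `log_body`,
#' and reports the AIC change from dropping body mass (positive means the
#' model without body mass fits better).
#'
#' @param table Data frame with the required log10 columns and `species`.
#' @param tree A `phylo` tree.
#' @param eco_trait Optional ecological column added to the brain~body
#'   model.
#' @param lambda Passed to [fit_pgls()].
#' @return List of `pgls_fit`s (`brain_body`, `brain_components`,
#'   `brain_components_body`) and `delta_aic_drop_body`.
#' @export
brain_body_models <- function(table, tree, eco_trait = NULL, lambda = 1) {
  rhs_bb <- paste(c("log_body", eco_trait), collapse = " + ")
  f_bb <- stats::as.formula(paste("log_brain ~", rhs_bb))
  fit_bb <- pgls(f_bb, table, tree, lambda = lambda)
  fit_comp <- pgls(log_brain ~ log_cx + log_cb + log_rob, table, tree,
                   lambda = lambda)
  fit_comp_body <- pgls(log_brain ~ log_cx + log_cb + log_rob + log_body,
                        table, tree, lambda = lambda)
  list(brain_body = fit_bb, brain_components = fit_comp,
       brain_components_body = fit_comp_body,
       delta_aic_drop_body = delta_aic(fit_comp_body, fit_comp))
}
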