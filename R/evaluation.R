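# Cross-validation protocol: identify the SESC on one set of static
# postures, score CoM estimates on a disjoint validation set against the
# measured CoP (the ground-truth CoM projection during static holds).
# Metrics follow the field's reporting conventions: planar rmse in mm, its
# anterior-posterior / medio-lateral decomposition, and the coefficient of
# determination.

#' Split windows into identification and validation sets
#'
#' Deterministic seeded split: `n_identify` windows are drawn without
#' replacement for identification; the remainder validate.
#'
#' @param windows List of static windows.
#' @param n_identify Number of identification windows (default 40).
#' @param seed Integer seed.
#' @return List with `identify` and `validate` window lists and the index
#'   vectors `identify_idx`, `validate_idx`.
#' @export
split_identification_validation <- function(windows, n_identify = 40,
                                            seed = 1) {
  m <- length(windows)
  if (m < n_identify + 1)
    stop("need at least n_identify + 1 = ", n_identify + 1,
         " windows, got ", m)
  set.seed(seed)
  idx <- sample.int(m, n_identify)
  list(identify = windows[idx], validate = windows[-idx],
       identify_idx = sort(idx), validate_idx = setdiff(seq_len(m), idx))
}

#' Score planar CoM estimates against measured CoP
#'
#' `rmse` is the root mean square of the planar residual norms; `ap_rmse`
#' and `ml_rmse` are per-axis rmse values (x = anterior-posterior,
#' y = medio-lateral), so `rmse^2 = ap_rmse^2 + ml_rmse^2`. R-squared is
#' computed per axis against the CoP series (`1 - SS_res/SS_tot`) and
#' aggregated across the two axes; it is not clamped and can be negative
#' when the estimate is worse than the CoP mean.
#'
#' @param estimates m x 2 matrix of estimated ground projections (m).
#' @param cop m x 2 matrix of measured CoP (m).
#' @param r2_aggregate `"mean"` (default) or `"min"` across the two axes.
#' @return An object of class `evaluation_report` with fields `rmse_mm`,
#'   `ap_rmse_mm`, `ml_rmse_mm`, `r_squared`, `r_squared_axes`,
#'   `n_postures`, `residuals_mm` (per-posture planar residual norms).
#' @export
evaluate_estimates <- function(estimates, cop, r2_aggregate = c("mean", "min")) {
  r2_aggregate <- match.arg(r2_aggregate)
  estimates <- as.matrix(estimates)
  cop <- as.matrix(cop)
  if (!all(dim(estimates) == dim(cop)))
    stop("estimates and cop must have matching dimensions")
  if (nrow(cop) < 2) stop("need at least 2 postures")
  res <- estimates - cop
  res_mm <- sqrt(rowSums(res^2)) * 1000
  per_axis_rmse <- sqrt(colMeans(res^2)) * 1000
  ss_res <- colSums(res^2)
  ss_tot <- colSums(sweep(cop, 2, colMeans(cop))^2)
  r2_axes <- ifelse(ss_tot == 0, ifelse(ss_res == 0, 1, -Inf),
                    1 - ss_res / ss_tot)
  structure(
    list(rmse_mm = sqrt(mean(rowSums(res^2))) * 1000,
         ap_rmse_mm = per_axis_rmse[1], ml_rmse_mm = per_axis_rmse[2],
         r_squared = if (r2_aggregate == "mean") mean(r2_axes)
                     else min(r2_axes),
         r_squared_axes = stats::setNames(r2_axes, c("ap", "ml")),
         n_postures = nrow(cop), residuals_mm = res_mm),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> n = %d: rmse %.2f mm ",
                     "(AP %.2f, ML %.2f), R^2 = %.3f\n"),
              x$n_postures, x$rmse_mm, x$ap_rmse_mm, x$ml_rmse_mm,
              x$r_squared))
  invisible(x)
}

#' Compare the identified SESC against the literature estimate
#'
#' Runs the full calibrate-then-validate protocol on one virtual session:
#' per-hold windows are split, the SESC is identified on the identification
#' set, and both the identified and the literature (anthropometric-table)
#' estimators are scored on the validation set.
#'
#' @param session A [generate_session()] result.
#' @param n_identify Identification windows (default 40).
#' @param split_seed Seed of the split.
#' @param windows Optional pre-computed windows (default
#'   [windows_from_labels()] of the session).
#' @param table Anthropometric table for the literature estimator.
#' @return List with `reports` (named `evaluation_report`s for
#'   `sesc_identified` and `literature`), `params` (identified
#'   [sesc_parameters()]), `diagnostics`, `split`, and `ordering` (method
#'   names sorted by rmse, best first).
#' @export
compare_methods <- function(session, n_identify = 40, split_seed = 1,
                            windows = NULL, table = winter_table()) {
  stopifnot(inherits(session, "virtual_session"))
  if (is.null(windows)) windows <- windows_from_labels(session)
  split <- split_identification_validation(windows, n_identify, split_seed)
  system <- assemble_identification_system(split$identify)
  params <- identify_sesc(system, height = session$model$height)
  diagnostics <- compute_diagnostics(system, params)
  lit_params <- denormalize_by_height(
    literature_sesc(session$model$height, table))
  val <- split$validate
  cop <- t(vapply(val, function(w) as.numeric(w$mean_cop), numeric(2)))
  est_sesc <- t(vapply(val, function(w)
    estimate_com(params, w$mean_posture)[1:2], numeric(2)))
  est_lit <- t(vapply(val, function(w)
    estimate_com(lit_params, w$mean_posture)[1:2], numeric(2)))
  reports <- list(sesc_identified = evaluate_estimates(est_sesc, cop),
                  literature = evaluate_estimates(est_lit, cop))
  ord <- names(sort(vapply(reports, `[[`, numeric(1), "rmse_mm")))
  list(reports = reports, params = params, diagnostics = diagnostics,
       split = split, ordering = ord)
}

#' Serialize an evaluation report
#'
#' @param report An [evaluate_estimates()] result.
#' @param path JSON output path.
#' @param residuals_csv Optional CSV path for per-posture residuals.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path, residuals_csv = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(
    list(rmse_mm = report$rmse_mm, ap_rmse_mm = report$ap_rmse_mm,
         ml_rmse_mm = report$ml_rmse_mm, r_squared = report$r_squared,
         r_squared_axes = as.list(report$r_squared_axes),
         n_postures = report$n_postures),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(residuals_csv))
    utils::write.csv(
      data.frame(posture = seq_along(report$residuals_mm),
                 residual_mm = report$residuals_mm),
      residuals_csv, row.names = FALSE)
  invisible(path)
}
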