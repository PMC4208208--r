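# Identification-quality diagnostics for the linear system y = D R + rho.
# The condition number of the regressor flags poor numerical excitation;
# per-parameter standard deviations (from the residual variance and the
# regressor's information matrix) flag parameters the posture set cannot
# pin down.

#' Condition number of a regressor matrix
#'
#' Ratio of the largest to the smallest singular value (2-norm condition
#' number). Returns `Inf` when the matrix is numerically rank deficient.
#'
#' @param D Numeric matrix.
#' @return Dimensionless scalar `>= 1` (or `Inf`).
#' @export
condition_number <- function(D) {
  if (!is.matrix(D) || length(D) == 0) stop("D must be a non-empty matrix")
  if (all(D == 0)) stop("D must be nonzero")
  d <- svd(D, nu = 0, nv = 0)$d
  smin <- min(d)
  if (smin <= max(d) * 1e-300) return(Inf)
  max(d) / smin
}

#' Least-squares error analysis of a linear system
#'
#' Ordinary least-squares diagnostics for `y = W x + rho`: residual
#' standard deviation `sigma_rho^2 = ||y - W x_hat||^2 / (r - c)`,
#' parameter covariance `C = sigma_rho^2 (W'W)^-1` (computed by SVD),
#' per-parameter standard deviations, relative standard deviations in
#' percent (`100 sigma_j / |x_j|`), their ratios to the smallest one
#' (`k_j`), and a two-sided t-test of each parameter against zero with
#' `r - c` degrees of freedom. `k_j > 10` marks a parameter as poorly
#' identified; `p > 0.01` marks it as not significant to the model. A zero
#' estimate with nonzero sigma gets an infinite relative standard deviation
#' and is flagged.
#'
#' @param W r x c regressor matrix, `r > c`, numerically full rank.
#' @param y Length-r measurement vector.
#' @param estimate Length-c least-squares estimate of x.
#' @return An object of class `identification_diagnostics` with fields
#'   `cond`, `sigma_rho`, `param_sigma`, `rel_std_pct`, `k_ratio`,
#'   `t_stat`, `t_pvalues`, `dof`, `poorly_identified`, `not_significant`,
#'   `estimates`.
#' @export
least_squares_diagnostics <- function(W, y, estimate) {
  r <- nrow(W)
  cc <- ncol(W)
  estimate <- as.numeric(estimate)
  stopifnot(length(y) == r, length(estimate) == cc)
  if (r <= cc)
    stop("diagnostics need more measurement rows (", r,
         ") than parameters (", cc, ")")
  resid <- y - as.numeric(W %*% estimate)
  dof <- r - cc
  sigma_rho2 <- sum(resid^2) / dof
  s <- svd(W, nu = 0)
  if (min(s$d) <= max(s$d) * 1e-10)
    stop("regressor is numerically rank deficient; ",
         "parameter covariance is undefined")
  # (W'W)^-1 = V diag(1/d^2) V'
  Cx <- s$v %*% (t(s$v) / s$d^2) * sigma_rho2
  param_sigma <- sqrt(pmax(diag(Cx), 0))
  rel_std_pct <- ifelse(estimate == 0, Inf,
                        100 * param_sigma / abs(estimate))
  finite_rel <- rel_std_pct[is.finite(rel_std_pct)]
  k_ratio <- if (length(finite_rel) > 0 && min(finite_rel) > 0)
    rel_std_pct / min(finite_rel) else rep(NaN, cc)
  t_stat <- ifelse(param_sigma == 0,
                   ifelse(estimate == 0, 0, Inf) * sign(estimate),
                   estimate / param_sigma)
  t_pvalues <- 2 * stats::pt(-abs(t_stat), df = dof)
  nm <- colnames(W)
  if (!is.null(nm)) {
    names(estimate) <- names(param_sigma) <- names(rel_std_pct) <-
      names(k_ratio) <- names(t_stat) <- names(t_pvalues) <- nm
  }
  structure(
    list(cond = condition_number(W), sigma_rho = sqrt(sigma_rho2),
         param_sigma = param_sigma, rel_std_pct = rel_std_pct,
         k_ratio = k_ratio, t_stat = t_stat, t_pvalues = t_pvalues,
         dof = dof,
         poorly_identified = (is.finite(k_ratio) & k_ratio > 10) |
           !is.finite(rel_std_pct),
         not_significant = t_pvalues > 0.01,
         estimates = estimate),
    class = "identification_diagnostics")
}

#' Diagnostics for an identified SESC
#'
#' Applies [least_squares_diagnostics()] to an identification system and
#' the SESC parameters identified from it.
#'
#' @param system An [assemble_identification_system()] result with more rows
#'   than parameters.
#' @param params The [sesc_parameters()] identified from this system.
#' @return An `identification_diagnostics` object (see
#'   [least_squares_diagnostics()]).
#' @export
compute_diagnostics <- function(system, params) {
  stopifnot(inherits(system, "identification_system"),
            inherits(params, "sesc_parameters"))
  least_squares_diagnostics(system$D, system$y,
                            as_vector.sesc_parameters(params))
}

#' @export
print.identification_diagnostics <- function(x, digits = 4, ...) {
  cat(sprintf("<identification_diagnostics> cond(D) = %.2f, sigma_rho = %.4g m, dof = %d\n",
              x$cond, x$sigma_rho, x$dof))
  nm <- names(x$estimates)
  if (is.null(nm)) nm <- paste0("x", seq_along(x$estimates))
  df <- data.frame(
    parameter = nm,
    estimate = signif(x$estimates, digits),
    sigma = signif(x$param_sigma, digits),
    rel_std_pct = signif(x$rel_std_pct, digits),
    k = signif(x$k_ratio, digits),
    p_value = signif(x$t_pvalues, digits),
    flag = ifelse(x$poorly_identified, "poorly identified",
                  ifelse(x$not_significant, "not significant", "")))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Grade an identification
#'
#' Structured pass/warn report: regressor conditioning against a threshold
#' (default 20), plus per-parameter flags for `k_j > 10` (poorly identified)
#' and `p > 0.01` (not significant).
#'
#' @param diag An [compute_diagnostics()] result.
#' @param cond_threshold Conditioning warning threshold (default 20).
#' @return An object of class `identification_grade` with fields `pass`
#'   (logical), `cond_ok`, `cond`, `cond_threshold`, `flagged` (data frame of
#'   per-parameter flags), `messages`.
#' @export
grade_identification <- function(diag, cond_threshold = 20) {
  stopifnot(inherits(diag, "identification_diagnostics"))
  cond_ok <- is.finite(diag$cond) && diag$cond < cond_threshold
  nm <- names(diag$estimates)
  if (is.null(nm)) nm <- paste0("x", seq_along(diag$estimates))
  flagged <- data.frame(
    parameter = nm,
    k_ratio = diag$k_ratio,
    poorly_identified = diag$poorly_identified,
    p_value = diag$t_pvalues,
    not_significant = diag$not_significant,
    row.names = NULL)
  msgs <- character(0)
  if (!cond_ok)
    msgs <- c(msgs, sprintf(
      "condition number %.3g exceeds threshold %g: postures are not varied enough",
      diag$cond, cond_threshold))
  bad_k <- nm[diag$poorly_identified]
  if (length(bad_k))
    msgs <- c(msgs, paste0("poorly identified (k > 10): ",
                           paste(bad_k, collapse = ", ")))
  bad_p <- nm[diag$not_significant]
  if (length(bad_p))
    msgs <- c(msgs, paste0("not significant (p > 0.01): ",
                           paste(bad_p, collapse = ", ")))
  structure(list(pass = cond_ok && !any(diag$poorly_identified),
                 cond_ok = cond_ok, cond = diag$cond,
                 cond_threshold = cond_threshold, flagged = flagged,
                 messages = msgs),
            class = "identification_grade")
}

#' @export
print.identification_grade <- function(x, ...) {
  cat(sprintf("<identification_grade> %s (cond = %.2f, threshold %g)\n",
              if (x$pass) "PASS" else "WARN", x$cond, x$cond_threshold))
  for (m in x$messages) cat(" -", m, "\n")
  invisible(x)
}

#' Serialize a diagnostics report as JSON
#'
#' @param diag An [compute_diagnostics()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(diag, path) {
  stopifnot(inherits(diag, "identification_diagnostics"))
  nm <- names(diag$estimates)
  if (is.null(nm)) nm <- paste0("x", seq_along(diag$estimates))
  jsonlite::write_json(
    list(cond = diag$cond, sigma_rho_m = diag$sigma_rho, dof = diag$dof,
         parameters = nm,
         estimate_m = as.numeric(diag$estimates),
         sigma_m = as.numeric(diag$param_sigma),
         rel_std_pct = as.numeric(diag$rel_std_pct),
         k_ratio = as.numeric(diag$k_ratio),
         t_pvalue = as.numeric(diag$t_pvalues),
         poorly_identified = as.logical(diag$poorly_identified),
         not_significant = as.logical(diag$not_significant)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
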