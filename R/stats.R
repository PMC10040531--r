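# Cohort statistics: effects-coded multiple linear regression and
# Spearman rank correlation.
#
# Repeated measurements on the same subjects are handled with fixed
# subject effects under effects coding: subject i (i < n) gets a dummy
# that is 1 on its own rows and -1 on the last subject's rows, so the
# subject effects sum to zero and the intercept is the grand mean. The
# regression itself is ordinary least squares solved by QR decomposition,
# with classical normal-theory standard errors and t-based p-values.

#' Effects-coded dummy matrix for subject identifiers
#'
#' @param subject_ids Vector (factor, character or integer) of subject
#'   labels, one per observation.
#' @param levels Optional explicit level ordering; the last level is the
#'   one coded -1.
#' @return A numeric matrix with `n_subjects - 1` columns named
#'   `subj<level>`; rows of subject i carry 1 in column i, rows of the
#'   last subject carry -1 everywhere.
#' @examples
#' effects_code(c("a", "b", "c", "c"))
#' @export
effects_code <- function(subject_ids, levels = NULL) {
  f <- factor(subject_ids, levels = levels %||% unique(subject_ids))
  n <- nlevels(f)
  if (n == 1) return(matrix(numeric(0), length(f), 0))
  D <- matrix(0, length(f), n - 1,
              dimnames = list(NULL, paste0("subj", levels(f)[-n])))
  ix <- as.integer(f)
  last <- ix == n
  D[cbind(which(!last), ix[!last])] <- 1
  D[last, ] <- -1
  D
}

# Core OLS via QR with classical inference. X must include the intercept.
ols_fit <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinearity error: rank-deficient design (columns: ",
         paste(bad, collapse = ", "), ")")
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df_res <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df_res
  XtX_inv <- chol2inv(qr.R(qrX))          # (R'R)^-1 for pivoted columns
  unpiv <- order(qrX$pivot)
  XtX_inv <- XtX_inv[unpiv, unpiv, drop = FALSE]
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df_res)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / tss
  adj_r2 <- 1 - (1 - r2) * (nrow(X) - 1) / df_res
  list(beta = beta, se = se, t = tval, p = pval, residuals = as.vector(res),
       sigma = sqrt(sigma2), df = df_res, r2 = r2, adj_r2 = adj_r2)
}

# Assemble a regression_result from an ols_fit, separating subject effects.
make_regression_result <- function(fit, predictor_names, subject_levels) {
  is_subj <- grepl("^subj", names(fit$beta))
  gamma <- fit$beta[is_subj]
  gamma_all <- c(gamma, -sum(gamma))
  names(gamma_all) <- subject_levels
  structure(list(
    coefficients = fit$beta[!is_subj], se = fit$se[!is_subj],
    t = fit$t[!is_subj], p = fit$p[!is_subj],
    subject_effects = gamma_all, adj_r2 = fit$adj_r2, r2 = fit$r2,
    sigma = fit$sigma, df = fit$df, residuals = fit$residuals,
    all_beta = fit$beta, all_se = fit$se, all_p = fit$p),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t, p = x$p)
  cat("<regression_result> adj-R^2 =", round(x$adj_r2, 3),
      " residual df =", x$df, "\n")
  print(signif(as.matrix(tab), 4))
  invisible(x)
}

#' Waveform-pulsatility regression (outcome on CO, SysP, RevP)
#'
#' Fits `outcome = alpha + b_CO * CO + b_Sys * SysP + b_Rev * RevP +
#' subject effects` by OLS with effects-coded subject dummies.
#'
#' @param table Data frame with columns `subject_id`, `co`, `sysp`,
#'   `revp` and the outcome.
#' @param outcome Name of the outcome column (default `"t_m"`).
#' @return A `regression_result` with coefficients `(Intercept)`, `co`,
#'   `sysp`, `revp`, subject effects, adjusted R^2 and p-values.
#' @export
fit_waveform_model <- function(table, outcome = "t_m") {
  stopifnot(all(c("subject_id", "co", "sysp", "revp", outcome) %in%
                  names(table)))
  if (length(unique(table$co)) < 2)
    stop("need >= 2 distinct CO values")
  D <- effects_code(table$subject_id)
  X <- cbind("(Intercept)" = 1, co = table$co, sysp = table$sysp,
             revp = table$revp, D)
  fit <- ols_fit(X, table[[outcome]])
  make_regression_result(fit, c("co", "sysp", "revp"),
                         unique(as.character(table$subject_id)))
}

#' Hematocrit-by-rheology regression
#'
#' Fits `outcome = alpha + b_Hct * Hct + b_N * D_N + b_HD * Hct * D_N +
#' subject effects`, where `D_N` codes the rheology model (1 =
#' non-Newtonian/Quemada, 0 = Newtonian). Hematocrit is used in percent so
#' slope units are per hematocrit point.
#'
#' @param table Data frame with columns `subject_id`, `hct` (fraction or
#'   percent), `rheology` (`"newtonian"`/`"quemada"`) and the outcome.
#' @param outcome Name of the outcome column (default `"t_m"`).
#' @return A `regression_result` with coefficients `(Intercept)`, `hct`,
#'   `d_n`, `hct_x_dn` plus subject effects.
#' @export
fit_rheology_model <- function(table, outcome = "t_m") {
  stopifnot(all(c("subject_id", "hct", "rheology", outcome) %in%
                  names(table)))
  dn <- as.numeric(table$rheology != "newtonian")
  if (length(unique(dn)) < 2) stop("need both rheology levels")
  hct <- ifelse(table$hct <= 1, table$hct * 100, table$hct)
  if (length(unique(hct)) < 2) stop("need >= 2 hematocrit levels")
  D <- effects_code(table$subject_id)
  X <- cbind("(Intercept)" = 1, hct = hct, d_n = dn, hct_x_dn = hct * dn, D)
  fit <- ols_fit(X, table[[outcome]])
  make_regression_result(fit, c("hct", "d_n", "hct_x_dn"),
                         unique(as.character(table$subject_id)))
}

#' Spearman rank correlation with average-rank tie handling
#'
#' Pearson correlation of the (mid-)ranks, with the p-value from the
#' t-distribution approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return A list with `rho`, `p` and `n`. If either vector has zero rank
#'   variance, `rho` and `p` are `NA` with a warning.
#' @examples
#' spearman(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  vx <- sum((rx - mean(rx))^2); vy <- sum((ry - mean(ry))^2)
  if (vx == 0 || vy == 0) {
    warning("undefined correlation: zero rank variance")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) / sqrt(vx * vy)
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Serialize a regression result to JSON
#' @param x A `regression_result`.
#' @param file Output path.
#' @export
write_regression_json <- function(x, file) {
  jsonlite::write_json(list(
    coefficients = as.list(x$coefficients), se = as.list(x$se),
    p = as.list(x$p), subject_effects = as.list(x$subject_effects),
    adj_r2 = x$adj_r2, df = x$df), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
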