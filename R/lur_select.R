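# Model-development engine: Spearman/direction pre-screen, univariate R^2
# ranking, and supervised forward-backward stepwise OLS under a coefficient
# p-value gate, a VIF collinearity gate, and a-priori sign consistency.

design_data <- function(design) {
  if (inherits(design, "lur_design")) design$data else as.data.frame(design)
}

design_priors <- function(design, vars) {
  if (inherits(design, "lur_design")) {
    setNames(design$candidates$direction_prior, design$candidates$name)[vars]
  } else {
    setNames(rep(0L, length(vars)), vars)
  }
}

#' Ordinary least squares fit with inference
#'
#' Fits `pm25 ~ intercept + vars` by QR decomposition and returns
#' coefficient estimates, standard errors, two-sided t-test p-values,
#' R-squared, adjusted R-squared and RMSE (root mean squared residual,
#' `sqrt(SSE/n)`). Rows with a missing response are dropped.
#'
#' @param design A `lur_design` or data.frame containing `response` and
#'   `vars` columns.
#' @param vars Character vector of predictor names (may be empty for an
#'   intercept-only model).
#' @param response Response column name (default `"pm25"`).
#' @return A list of class `lur_fit` with elements `coefficients`, `se`,
#'   `t`, `p_value` (all named, intercept first), `r2`, `adj_r2`, `rmse`,
#'   `n`, `k`, `df_residual`, `fitted`, `residuals`.
#' @export
fit_ols <- function(design, vars = character(0), response = "pm25") {
  df <- design_data(design)
  df <- df[!is.na(df[[response]]), , drop = FALSE]
  y <- df[[response]]
  n <- length(y)
  k <- length(vars)
  if (n <= k + 1) stop("need more observations than coefficients", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(df[vars]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- as.vector(X %*% beta)
  res <- y - fitted
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  df_res <- n - k - 1
  sigma2 <- sse / df_res
  XtX_inv <- chol2inv(qr.R(qx)[, order(qx$pivot), drop = FALSE])
  se <- sqrt(pmax(0, diag(XtX_inv)) * sigma2)
  tval <- beta / se
  p <- 2 * pt(abs(tval), df_res, lower.tail = FALSE)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  structure(list(
    coefficients = beta, se = setNames(se, names(beta)),
    t = setNames(tval, names(beta)), p_value = setNames(p, names(beta)),
    r2 = r2,
    adj_r2 = if (sst > 0) 1 - (1 - r2) * (n - 1) / df_res else NA_real_,
    rmse = sqrt(sse / n), n = n, k = k, df_residual = df_res,
    fitted = fitted, residuals = res, vars = vars, response = response
  ), class = "lur_fit")
}

#' @export
print.lur_fit <- function(x, ...) {
  cat(sprintf("<lur_fit> n=%d, k=%d, R2=%.3f, adj R2=%.3f, RMSE=%.3f\n",
              x$n, x$k, x$r2, x$adj_r2, x$rmse))
  print(data.frame(beta = x$coefficients, se = x$se, p_value = x$p_value))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing predictor
#' `j` on the remaining predictors (with intercept). A single predictor
#' has VIF 1 by convention; perfect collinearity yields `Inf`.
#'
#' @inheritParams fit_ols
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(design, vars) {
  df <- design_data(design)
  if (length(vars) < 2) return(setNames(rep(1, length(vars)), vars))
  out <- vapply(vars, function(v) {
    others <- setdiff(vars, v)
    x <- df[[v]]
    X <- cbind(1, as.matrix(df[others]))
    fit <- stats::lm.fit(X, x)
    sse <- sum(fit$residuals^2)
    sst <- sum((x - mean(x))^2)
    if (sst == 0) return(Inf)
    r2j <- 1 - sse / sst
    if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
  }, numeric(1))
  setNames(pmax(1, out), vars)
}

#' Spearman correlation and direction pre-screen
#'
#' Computes the Spearman rank correlation (average ranks for ties) of
#' every candidate with the response and keeps a candidate if its
#' direction prior is unconstrained (0) or the correlation sign matches
#' the prior. Zero-variance candidates are dropped with a reason.
#'
#' @param design A `lur_design`.
#' @param vars Candidates to screen (default: all).
#' @return data.frame with columns `name`, `spearman_rho`,
#'   `direction_prior`, `keep`, `reason`.
#' @export
spearman_screen <- function(design, vars = NULL) {
  df <- design_data(design)
  df <- df[!is.na(df$pm25), , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 observations to screen", call. = FALSE)
  if (is.null(vars)) vars <- design$candidates$name
  priors <- design_priors(design, vars)
  rho <- vapply(vars, function(v) {
    x <- df[[v]]
    if (sd(x) == 0) return(NA_real_)
    suppressWarnings(cor(x, df$pm25, method = "spearman"))
  }, numeric(1))
  keep <- !is.na(rho) & (priors == 0L | sign(rho) == priors)
  reason <- ifelse(is.na(rho), "zero_variance",
                   ifelse(keep, "", "sign_mismatch"))
  data.frame(name = vars, spearman_rho = rho, direction_prior = priors,
             keep = keep, reason = reason, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rank candidates by single-predictor R-squared
#'
#' @param design A `lur_design` (or data.frame with `pm25`).
#' @param vars Candidate names (non-empty).
#' @return data.frame ordered by descending univariate R-squared with
#'   deterministic lexicographic tie-break on the name.
#' @export
univariate_rank <- function(design, vars) {
  if (length(vars) == 0) stop("no candidates to rank", call. = FALSE)
  r2 <- vapply(vars, function(v) fit_ols(design, v)$r2, numeric(1))
  ord <- order(-r2, vars)
  data.frame(name = vars[ord], r2 = r2[ord], rank = seq_along(vars),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partial R-squared of fitted model terms
#'
#' Squared partial correlation of each term with the response given the
#' other terms, computed as `t^2 / (t^2 + df_residual)` from the term's
#' t statistic; always in `[0, 1]`.
#'
#' @param fit A `lur_fit`.
#' @return Named numeric vector (one value per non-intercept term).
#' @export
partial_r2 <- function(fit) {
  stopifnot(inherits(fit, "lur_fit"))
  if (fit$k == 0) return(setNames(numeric(0), character(0)))
  t2 <- fit$t[-1]^2
  setNames(t2 / (t2 + fit$df_residual), names(fit$coefficients)[-1])
}

# gate check for a fitted candidate model; returns "" when all gates pass
check_gates <- function(design, fit, priors, p_enter, vif_max,
                        focus = NULL) {
  betas <- fit$coefficients[-1]
  ps <- fit$p_value[-1]
  if (!is.null(focus) && ps[[focus]] >= p_enter) {
    return(sprintf("p=%.3f >= %g", ps[[focus]], p_enter))
  }
  vv <- vif(design, fit$vars)
  if (any(vv >= vif_max)) {
    w <- names(vv)[which.max(vv)]
    return(sprintf("VIF(%s)=%.2f >= %g", w, max(vv), vif_max))
  }
  pr <- priors[fit$vars]
  bad <- pr != 0L & sign(betas) != pr
  if (any(bad)) {
    return(sprintf("sign flip: %s", paste(fit$vars[bad], collapse = ",")))
  }
  ""
}

trace_row <- function(step, action, variable, reason = "", p_value = NA,
                      max_vif = NA, r2 = NA) {
  data.frame(step = step, action = action, variable = variable,
             reason = reason, p_value = p_value, max_vif = max_vif, r2 = r2,
             stringsAsFactors = FALSE)
}

#' Supervised stepwise LUR model selection
#'
#' Forward-backward greedy selection under three gates: every
#' coefficient p-value below `p_enter`, every VIF below `vif_max`, and
#' every coefficient whose candidate has a nonzero direction prior
#' keeping that sign. Candidates first pass the Spearman direction
#' screen; at each forward step the remaining candidates are ranked by
#' the R-squared of the model with that candidate added (conditional
#' gain; equivalently univariate R-squared at the first step) with
#' lexicographic tie-break, and the best candidate passing all gates is
#' added. After each addition, terms whose p-value has risen to
#' `p_enter` or above are removed (highest p first). Selection stops
#' when no remaining candidate is addable; the final model is re-fit and
#' every gate re-verified.
#'
#' @param design A `lur_design` with response filled.
#' @param p_enter Coefficient p-value threshold (default 0.1).
#' @param vif_max VIF threshold (default 3).
#' @param max_steps Safety cap on forward steps.
#' @return A list of class `lur_model`: `intercept`, `terms` (data.frame
#'   `name`, `beta`, `p_value`, `vif`, `partial_r2`), `r2`, `adj_r2`,
#'   `rmse`, `n_observations`, `fit` (the final `lur_fit`), `screen`
#'   (the pre-screen table) and `trace` (the ordered decision log).
#' @export
supervised_stepwise <- function(design, p_enter = 0.1, vif_max = 3,
                                max_steps = 100) {
  stopifnot(inherits(design, "lur_design"))
  screen <- spearman_screen(design)
  pool <- screen$name[screen$keep]
  priors <- design_priors(design, design$candidates$name)
  trace <- do.call(rbind, c(
    list(trace_row(0L, "screen", "", sprintf("%d of %d candidates kept",
                                             length(pool), nrow(screen)))),
    lapply(which(!screen$keep), function(i) {
      trace_row(0L, "drop", screen$name[i], screen$reason[i])
    })
  ))
  model <- character(0)
  step <- 0L
  seen_states <- character(0)
  if (length(pool) == 0) {
    warning("no candidate survives screening; returning intercept-only model")
  }
  while (step < max_steps && length(setdiff(pool, model)) > 0) {
    step <- step + 1L
    remaining <- setdiff(pool, model)
    # rank remaining candidates by R^2 of model + candidate
    fits <- lapply(remaining, function(v) fit_ols(design, c(model, v)))
    r2s <- vapply(fits, `[[`, numeric(1), "r2")
    ord <- order(-r2s, remaining)
    added <- FALSE
    for (idx in ord) {
      cand <- remaining[idx]
      fit <- fits[[idx]]
      fail <- check_gates(design, fit, priors, p_enter, vif_max, focus = cand)
      if (nzchar(fail)) {
        trace <- rbind(trace, trace_row(step, "skip", cand, fail,
                                        fit$p_value[[cand]],
                                        max(vif(design, fit$vars)), fit$r2))
        next
      }
      model <- c(model, cand)
      trace <- rbind(trace, trace_row(step, "add", cand, "",
                                      fit$p_value[[cand]],
                                      max(vif(design, fit$vars)), fit$r2))
      # backward pass: drop terms that lost significance
      repeat {
        f <- fit_ols(design, model)
        ps <- f$p_value[-1]
        if (all(ps < p_enter)) break
        worst <- names(ps)[which.max(ps)]
        model <- setdiff(model, worst)
        trace <- rbind(trace, trace_row(step, "remove", worst,
                                        sprintf("p=%.3f >= %g", max(ps), p_enter),
                                        max(ps), NA, f$r2))
        if (length(model) == 0) break
      }
      added <- TRUE
      break
    }
    if (!added) break
    state <- paste(sort(model), collapse = "|")
    if (state %in% seen_states) {
      trace <- rbind(trace, trace_row(step, "stop", "", "model state revisited"))
      break
    }
    seen_states <- c(seen_states, state)
  }
  # final re-fit and gate re-verification; drop offenders if any remain
  repeat {
    fit <- fit_ols(design, model)
    if (length(model) == 0) break
    fail <- check_gates(design, fit, priors, p_enter, vif_max)
    ps <- fit$p_value[-1]
    if (!nzchar(fail) && all(ps < p_enter)) break
    vv <- vif(design, model)
    worst <- if (any(vv >= vif_max)) names(vv)[which.max(vv)]
             else names(ps)[which.max(ps)]
    model <- setdiff(model, worst)
    trace <- rbind(trace, trace_row(step, "remove", worst,
                                    paste("final gate check:", fail)))
  }
  vv <- vif(design, model)
  pr2 <- partial_r2(fit)
  terms <- if (length(model) > 0) {
    data.frame(name = model,
               beta = unname(fit$coefficients[model]),
               p_value = unname(fit$p_value[model]),
               vif = unname(vv[model]),
               partial_r2 = unname(pr2[model]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(), beta = numeric(), p_value = numeric(),
               vif = numeric(), partial_r2 = numeric())
  }
  structure(list(intercept = unname(fit$coefficients[1]), terms = terms,
                 r2 = fit$r2, adj_r2 = fit$adj_r2, rmse = fit$rmse,
                 n_observations = fit$n, fit = fit, screen = screen,
                 trace = trace, p_enter = p_enter, vif_max = vif_max),
            class = "lur_model")
}

#' @export
print.lur_model <- function(x, ...) {
  cat(sprintf("<lur_model> %d terms, n=%d, R2=%.3f, adj R2=%.3f, RMSE=%.2f\n",
              nrow(x$terms), x$n_observations, x$r2, x$adj_r2, x$rmse))
  cat(sprintf("  intercept %.3f; gates: p < %g, VIF < %g\n",
              x$intercept, x$p_enter, x$vif_max))
  if (nrow(x$terms) > 0) print(x$terms, digits = 4)
  invisible(x)
}

#' Model report table
#'
#' The final-model summary in the conventional LUR reporting layout:
#' one row per term with coefficient, p-value, VIF and partial
#' R-squared, plus an intercept row, with overall fit metrics attached
#' as attributes and repeated in columns.
#'
#' @param model A `lur_model`.
#' @return data.frame report.
#' @export
model_report <- function(model) {
  rows <- rbind(
    data.frame(Variable = "Intercept", beta = model$intercept,
               p_value = model$fit$p_value[[1]], VIF = NA_real_,
               partial_R2 = NA_real_),
    data.frame(Variable = model$terms$name, beta = model$terms$beta,
               p_value = model$terms$p_value, VIF = model$terms$vif,
               partial_R2 = model$terms$partial_r2)
  )
  rows$R2 <- model$r2
  rows$adj_R2 <- model$adj_r2
  rows$RMSE <- model$rmse
  rownames(rows) <- NULL
  rows
}
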