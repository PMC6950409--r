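# Independent oracles used across the suite. They re-derive every result
# from first principles (distance inequalities, normal equations, explicit
# enumeration) and never call the code paths they check.

# sequential IEEE-double summation (accumulator order = element order)
sum_seq <- function(v) Reduce(`+`, v, 0)

# Brute-force circular focal statistic: per-cell nested enumeration of the
# square neighborhood with the center-in-circle distance test. Offsets are
# visited di-fastest within dj (column-major), summing sequentially.
oracle_focal_cell <- function(values, radius, cell_size, stat = "sum") {
  nr <- nrow(values); nc <- ncol(values)
  m <- floor(radius / cell_size)
  out <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    vals <- numeric(0)
    for (dj in -m:m) for (di in -m:m) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if ((di^2 + dj^2) * cell_size^2 > radius^2) next
      v <- values[ii, jj]
      if (!is.na(v)) vals <- c(vals, v)
    }
    if (length(vals)) {
      out[i, j] <- if (stat == "sum") sum_seq(vals)
                   else sum_seq(vals) / length(vals)
    }
  }
  out
}

# Same brute force, organised as shift-and-accumulate so larger rasters are
# affordable: per offset (visited in the same column-major order) the whole
# shifted matrix is added at once. Per-cell accumulation order and precision
# are identical to the per-cell form.
oracle_focal_shift <- function(values, radius, cell_size, stat = "sum") {
  nr <- nrow(values); nc <- ncol(values)
  m <- min(floor(radius / cell_size), max(nr, nc) - 1L)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  filled <- ifelse(is.na(values), 0, values)
  present <- !is.na(values)
  for (dj in -m:m) for (di in -m:m) {
    if ((di^2 + dj^2) * cell_size^2 > radius^2) next
    src_i <- max(1, 1 + di):min(nr, nr + di)
    src_j <- max(1, 1 + dj):min(nc, nc + dj)
    dst_i <- src_i - di; dst_j <- src_j - dj
    acc[dst_i, dst_j] <- acc[dst_i, dst_j] + filled[src_i, src_j]
    cnt[dst_i, dst_j] <- cnt[dst_i, dst_j] + present[src_i, src_j]
  }
  out <- if (stat == "sum") acc else acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

# Normal-equations OLS oracle: beta = (X'X)^-1 X'y with explicit inference
oracle_ols <- function(X, y) {
  X1 <- cbind(1, X)
  XtX <- t(X1) %*% X1
  beta <- solve(XtX, t(X1) %*% y)
  res <- y - X1 %*% beta
  df <- nrow(X1) - ncol(X1)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  list(beta = as.vector(beta), se = as.vector(se),
       p = as.vector(2 * pt(abs(tval), df, lower.tail = FALSE)),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Auxiliary-regression VIF oracle via lm()
oracle_vif <- function(df, vars) {
  vapply(vars, function(v) {
    r2 <- summary(lm(reformulate(setdiff(vars, v), v), data = df))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

# Exhaustive best-subset search under the stepwise gates: enumerate every
# subset of candidates, keep those whose fit satisfies p < p_enter for all
# terms, all VIF < vif_max and prior-consistent signs, return the subset
# with the highest R^2 (ties: smaller, then lexicographic).
oracle_best_subset <- function(design, candidates, p_enter = 0.1, vif_max = 3) {
  priors <- setNames(design$candidates$direction_prior, design$candidates$name)
  best <- character(0); best_r2 <- -Inf
  for (size in seq_along(candidates)) {
    for (idx in utils::combn(length(candidates), size, simplify = FALSE)) {
      vars <- candidates[idx]
      fit <- try(fit_ols(design, vars), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (any(fit$p_value[-1] >= p_enter)) next
      if (any(vif(design, vars) >= vif_max)) next
      pr <- priors[vars]
      if (any(pr != 0 & sign(fit$coefficients[-1]) != pr)) next
      if (fit$r2 > best_r2 + 1e-12) { best <- vars; best_r2 <- fit$r2 }
    }
  }
  sort(best)
}

# small helper: a lur_design built directly from a data.frame of candidates
make_design <- function(df, pm25, priors = NULL) {
  structure(list(
    data = cbind(data.frame(station_id = sprintf("s%02d", seq_len(nrow(df))),
                            year = 2016, month = 1),
                 df, pm25 = pm25),
    candidates = candidate_table(names(df), priors),
    response = "pm25"), class = "lur_design")
}
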