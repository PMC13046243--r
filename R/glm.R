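#' Ordinary least squares with closed-form inference
#'
#' Thin OLS engine used by every model in the package: fits
#' `response ~ design` (the design must already contain its intercept
#' column), and returns coefficientwise `t = coef / se` statistics with
#' two-sided p-values from the t distribution on `n - k` degrees of freedom.
#'
#' @param design Numeric `n x k` design matrix including the intercept.
#' @param response Numeric length-n response.
#' @return A `laminar_fit` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
fit_ols <- function(design, response) {
  design <- as.matrix(design)
  response <- as.numeric(response)
  n <- nrow(design); k <- ncol(design)
  if (length(response) != n) stop_contract("design and response sizes differ")
  if (n <= k) stop_contract("need more observations than parameters")
  if (is.null(colnames(design))) {
    colnames(design) <- c("(Intercept)", paste0("x", seq_len(k - 1L)))[seq_len(k)]
  }
  qr_x <- qr(design)
  if (qr_x$rank < k) {
    bad <- colnames(design)[qr_x$pivot[(qr_x$rank + 1L):k]]
    stop_contract(sprintf("design is rank deficient; collinear columns: %s",
                          paste(bad, collapse = ", ")),
                  class = "neolaminar_collinearity_error")
  }
  fit <- stats::lm.fit(design, response)
  res <- fit$residuals
  rss <- sum(res^2)
  # An RSS at rounding-noise level relative to the response scale is an
  # exact fit; without this, t statistics become ratios of rounding errors.
  if (rss <= 1e-20 * max(sum(response^2), 1)) rss <- 0
  df <- n - k
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- stats::setNames(sqrt(sigma2 * diag(xtx_inv)), colnames(design))
  coef <- fit$coefficients
  # Zero residual variance: a zero coefficient carries no evidence (t = 0);
  # a nonzero one is fit exactly (t = +-Inf, p = 0).
  tval <- ifelse(se > 0, coef / se,
                 ifelse(abs(coef) < 1e-10, 0, sign(coef) * Inf))
  pval <- 2 * stats::pt(-abs(tval), df)
  tss <- sum((response - mean(response))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  aic <- n * log(max(rss, .Machine$double.xmin) / n) + 2 * (k + 1) +
    n * (log(2 * pi) + 1)
  structure(
    list(coef = coef, se = se, t = tval, p = pval, n = n, k = k,
         df = df, r2 = r2, aic = aic, rss = rss, terms = colnames(design)),
    class = "laminar_fit")
}

#' @export
print.laminar_fit <- function(x, ...) {
  cat(sprintf("<laminar_fit> n = %d, k = %d, R^2 = %.4f\n", x$n, x$k, x$r2))
  print(tibble::tibble(term = x$terms, estimate = x$coef, se = x$se,
                       statistic = x$t, p.value = x$p))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.laminar_fit <- function(x, ...) {
  tibble::tibble(term = x$terms, estimate = unname(x$coef), std.error = unname(x$se),
                 statistic = unname(x$t), p.value = unname(x$p))
}

#' @export
glance.laminar_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, AIC = x$aic, df.residual = x$df,
                 nobs = x$n, n.terms = x$k)
}

#' Benjamini-Hochberg step-up rejections
#'
#' Rejects the hypotheses with the `k` smallest p-values, where `k` is the
#' largest index with `p_(k) <= alpha * k / m` over the sorted p-values.
#' Equivalent to `p.adjust(p, "BH") <= alpha`, which is how the adjusted
#' q-values are reported elsewhere in the package.
#'
#' @param p Numeric p-values.
#' @param alpha FDR level.
#' @return Logical rejection vector, aligned with `p`.
#' @export
bh_reject <- function(p, alpha = 0.025) {
  m <- length(p)
  ord <- order(p)
  ok <- p[ord] <= alpha * seq_len(m) / m
  k <- if (any(ok)) max(which(ok)) else 0L
  out <- logical(m)
  if (k > 0L) out[ord[seq_len(k)]] <- TRUE
  out
}

# ---- model specification ---------------------------------------------------

model_predictors <- c("pma", "ga", "pna", "sex", "thickness", "ga_pna")

# Build a design matrix from cohort covariates. The GA x PNA product is
# computed after mean-centering both ages so its test is invariant to
# covariate shifts. PMA together with both GA and PNA is exact collinearity
# (PMA = GA + PNA) and is rejected up front.
build_design <- function(cohort, predictors) {
  predictors <- tolower(predictors)
  unknown <- setdiff(predictors, model_predictors)
  if (length(unknown)) {
    stop_parameter(sprintf("unknown predictors: %s", paste(unknown, collapse = ", ")))
  }
  if ("pma" %in% predictors && all(c("ga", "pna") %in% predictors)) {
    stop_contract("PMA with both GA and PNA is perfectly collinear (PMA = GA + PNA)",
                  class = "neolaminar_collinearity_error")
  }
  cols <- list("(Intercept)" = rep(1, nrow(cohort)))
  for (p in predictors) {
    cols[[p]] <- switch(p,
      pma = cohort$pma_weeks,
      ga = cohort$ga_weeks,
      pna = cohort$pna_weeks,
      sex = as.numeric(cohort$sex),
      thickness = {
        if (all(is.na(cohort$thickness_mm))) {
          stop_parameter("cohort has no thickness values")
        }
        cohort$thickness_mm
      },
      ga_pna = {
        (cohort$ga_weeks - mean(cohort$ga_weeks)) *
          (cohort$pna_weeks - mean(cohort$pna_weeks))
      })
  }
  do.call(cbind, cols)
}

# Shared-design OLS over a matrix of responses (one column per parcel):
# a single QR serves every parcel.
ols_multi <- function(design, Y) {
  n <- nrow(design); k <- ncol(design)
  qr_x <- qr(design)
  if (qr_x$rank < k) {
    bad <- colnames(design)[qr_x$pivot[(qr_x$rank + 1L):k]]
    stop_contract(sprintf("design is rank deficient; collinear columns: %s",
                          paste(bad, collapse = ", ")),
                  class = "neolaminar_collinearity_error")
  }
  coef <- qr.coef(qr_x, Y)
  rownames(coef) <- colnames(design)
  res <- Y - design %*% coef
  df <- n - k
  rss <- colSums(res^2)
  rss[rss <= 1e-20 * pmax(colSums(Y^2), 1)] <- 0
  sigma2 <- rss / df
  d <- diag(chol2inv(qr.R(qr_x)))
  se <- sqrt(outer(d, sigma2))
  dimnames(se) <- dimnames(coef)
  tval <- coef / se
  z <- se == 0
  tval[z] <- ifelse(abs(coef[z]) < 1e-10, 0, sign(coef[z]) * Inf)
  pval <- 2 * stats::pt(-abs(tval), df)
  list(coef = coef, se = se, t = tval, p = pval, df = df)
}

#' Parcel-wise developmental linear models with FDR control
#'
#' Fits one linear model per parcel (moment response on the requested
#' developmental predictors plus sex), extracts the term of interest, and
#' applies Benjamini-Hochberg step-up control across the analyzed parcels.
#' The FDR family is the set of analyzed parcels for one
#' (response, term, model) triple at level `alpha` (default 0.025: two
#' moments are conventionally tested at an overall 0.05).
#'
#' @param moments Long tibble with columns `subject_id`, `parcel_id`, and
#'   the response column (`mu1` or `mu2`).
#' @param cohort Cohort tibble (see [simulate_cohort()]).
#' @param predictors Character vector from
#'   `c("pma","ga","pna","sex","thickness","ga_pna")`.
#' @param term Predictor whose effect map is wanted (must be in
#'   `predictors`).
#' @param response `"mu1"` or `"mu2"`.
#' @param alpha BH level (default 0.025).
#' @return An effect-map tibble: `parcel_id`, `term`, `estimate`, `se`,
#'   `statistic`, `p.value`, `q.value`, `significant`, with attribute
#'   `alpha`.
#' @export
parcelwise_effects <- function(moments, cohort, predictors = c("ga", "pna", "sex"),
                               term = "ga", response = c("mu1", "mu2"),
                               alpha = 0.025) {
  response <- match.arg(response)
  term <- tolower(term)
  if (!term %in% tolower(predictors)) {
    stop_parameter("`term` must be one of the model predictors")
  }
  wide <- tidyr::pivot_wider(
    moments[, c("subject_id", "parcel_id", response)],
    names_from = "parcel_id", values_from = dplyr::all_of(response))
  if (!setequal(wide$subject_id, cohort$subject_id)) {
    stop_contract("subject ids in `moments` and `cohort` do not match")
  }
  wide <- wide[match(cohort$subject_id, wide$subject_id), ]
  Y <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(Y)) stop_contract("missing moment values; drop incomplete parcels first")
  X <- build_design(cohort, predictors)
  fit <- ols_multi(X, Y)
  est <- unname(fit$coef[term, ])
  se <- unname(fit$se[term, ])
  tv <- unname(fit$t[term, ])
  p <- unname(fit$p[term, ])
  q <- stats::p.adjust(p, method = "BH")
  tibble::tibble(
    parcel_id = colnames(Y), term = rep(term, ncol(Y)),
    estimate = est, se = se, statistic = tv, p.value = p, q.value = q,
    significant = bh_reject(p, alpha)) |>
    structure(alpha = alpha)
}

#' GA x PNA interaction effect map
#'
#' Same engine as [parcelwise_effects()] with predictors
#' `{GA, PNA, GA x PNA, sex}`; the product term is computed after
#' mean-centering GA and PNA.
#'
#' @inheritParams parcelwise_effects
#' @return Effect-map tibble for the interaction term.
#' @export
interaction_effects <- function(moments, cohort, response = c("mu1", "mu2"),
                                alpha = 0.025) {
  parcelwise_effects(moments, cohort,
                     predictors = c("ga", "pna", "ga_pna", "sex"),
                     term = "ga_pna", response = response, alpha = alpha)
}

#' Compare global developmental models
#'
#' Fits each candidate predictor set to a single (cortex-wide) response,
#' reports fit summaries, ranks by AIC, and runs nested F-tests for every
#' nested candidate pair (or only the requested pairs).
#'
#' @param response Numeric per-subject response (e.g. parcel-averaged `mu1`).
#' @param cohort Cohort tibble, aligned with `response`.
#' @param specs List of character vectors of predictors.
#' @param f_pairs Optional list of index pairs `c(reduced, full)` for nested
#'   F-tests; defaults to all nested pairs. Requesting a non-nested pair is
#'   an error.
#' @return A list with `models` (tibble: predictors, r2, aic, rank) and
#'   `f_tests` (tibble: reduced, full, F, p.value).
#' @export
compare_models <- function(response, cohort, specs, f_pairs = NULL) {
  if (length(specs) < 2L) stop_contract("need at least two candidate models")
  labels <- vapply(specs, function(s) paste(s, collapse = "+"), character(1))
  fits <- lapply(specs, function(s) fit_ols(build_design(cohort, s), response))
  models <- tibble::tibble(
    model = labels,
    predictors = vapply(specs, function(s) paste(sort(s), collapse = "+"), character(1)),
    r.squared = vapply(fits, function(f) f$r2, numeric(1)),
    AIC = vapply(fits, function(f) f$aic, numeric(1)))
  models$rank <- rank(models$AIC, ties.method = "min")
  is_nested <- function(i, j) all(specs[[i]] %in% specs[[j]]) &&
    length(specs[[i]]) < length(specs[[j]])
  if (is.null(f_pairs)) {
    f_pairs <- list()
    for (i in seq_along(specs)) for (j in seq_along(specs)) {
      if (is_nested(i, j)) f_pairs[[length(f_pairs) + 1L]] <- c(i, j)
    }
  } else {
    for (pr in f_pairs) {
      if (!is_nested(pr[1], pr[2])) {
        stop_contract(sprintf("models %d and %d are not nested", pr[1], pr[2]))
      }
    }
  }
  ftab <- purrr::map_dfr(f_pairs, function(pr) {
    f0 <- fits[[pr[1]]]; f1 <- fits[[pr[2]]]
    df1 <- f1$k - f0$k
    df2 <- f1$n - f1$k
    Fstat <- ((f0$rss - f1$rss) / df1) / (f1$rss / df2)
    tibble::tibble(reduced = labels[pr[1]], full = labels[pr[2]],
                   statistic = Fstat, df1 = df1, df2 = df2,
                   p.value = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
  })
  list(models = models, f_tests = ftab)
}

#' Depth-wise age correlations
#'
#' Pearson (product-moment) correlation between age and the intensity at
#' each sampling depth, across subjects. Depths with zero intensity variance
#' are flagged undefined rather than raising an error.
#'
#' @param profiles Numeric matrix, subjects x depths.
#' @param age Numeric vector of subject ages (weeks).
#' @return Tibble with `depth`, `r`, `p.value`, `undefined`.
#' @export
depthwise_age_correlation <- function(profiles, age) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3L) stop_contract("need at least 3 subjects")
  if (length(age) != nrow(profiles)) stop_contract("`age` must match profile rows")
  if (stats::sd(age) == 0) stop_contract("`age` has zero variance")
  out <- lapply(seq_len(ncol(profiles)), function(d) {
    y <- profiles[, d]
    if (stats::sd(y) == 0) {
      tibble::tibble(depth = d, r = NA_real_, p.value = NA_real_, undefined = TRUE)
    } else {
      ct <- stats::cor.test(age, y)
      tibble::tibble(depth = d, r = unname(ct$estimate),
                     p.value = ct$p.value, undefined = FALSE)
    }
  })
  dplyr::bind_rows(out)
}
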