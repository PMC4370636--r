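#' Ordinary least squares fit with named terms
#'
#' Thin wrapper around [stats::lm()] returning the quantities the pipeline
#' reports: per-term coefficient, SE, t, two-sided p, residuals, R-squared
#' and Ezekiel-adjusted R-squared.
#'
#' @param y Response vector.
#' @param X Data.frame or matrix of named predictor columns.
#' @param intercept Include an intercept (default TRUE).
#' @return A list of class `ols_fit`: `coefficients` (data.frame term /
#'   estimate / se / t / p), `residuals`, `fitted`, `r2`, `adj_r2`, `n`,
#'   `df_model`, `df_residual`, and the underlying `lm` object.
#' @export
ols_fit <- function(y, X, intercept = TRUE) {
  X <- as.data.frame(X)
  stopifnot(length(y) == nrow(X))
  if (nrow(X) <= ncol(X) + intercept)
    stop("more terms than observations", call. = FALSE)
  dat <- cbind(data.frame(.y = y), X)
  fml <- stats::as.formula(
    paste(".y ~", if (intercept) "" else "0 +",
          paste(sprintf("`%s`", names(X)), collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(gsub("`", "", bad), collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(
    term = gsub("`", "", rownames(ct)),
    estimate = ct[, 1], se = ct[, 2], t = ct[, 3], p = ct[, 4],
    row.names = NULL, stringsAsFactors = FALSE
  )
  n <- length(y)
  p_terms <- length(stats::coef(fit)) - intercept
  r2 <- sm$r.squared
  structure(list(
    coefficients = coefs,
    residuals = stats::resid(fit),
    fitted = stats::fitted(fit),
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p_terms - 1),
    n = n, df_model = p_terms, df_residual = fit$df.residual,
    lm = fit
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit: n =", x$n, " R2 =", signif(x$r2, 4),
      " adj R2 =", signif(x$adj_r2, 4), "\n")
  print(transform(x$coefficients,
                  estimate = signif(estimate, 4), se = signif(se, 4),
                  t = signif(t, 3), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Variance-inflation-factor screen for multicollinearity
#'
#' VIF_k = 1/(1 - R^2_k) from regressing predictor k on the remaining
#' predictors. Predictors are dropped one at a time (largest VIF first,
#' infinite VIF — perfect collinearity — before anything else) until all
#' remaining VIFs are at or below `threshold`.
#'
#' @param X Data.frame/matrix of candidate predictors (>= 2 columns, each
#'   with nonzero variance).
#' @param threshold Maximum acceptable VIF (default 10).
#' @return A list: `retained` (column names kept), `dropped` (in drop
#'   order), `vif` (final VIFs), `steps` (data.frame of the drop sequence).
#' @export
vif_screen <- function(X, threshold = 10) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 2)
  if (any(vapply(X, stats::var, numeric(1)) == 0))
    stop("constant predictor has no VIF", call. = FALSE)
  vifs_of <- function(X) {
    if (ncol(X) == 1L) return(stats::setNames(1, names(X)))
    vapply(names(X), function(k) {
      r2 <- summary(stats::lm(X[[k]] ~ ., data = X[setdiff(names(X), k)]))$r.squared
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  dropped <- character(0)
  steps <- list()
  repeat {
    v <- vifs_of(X)
    steps[[length(steps) + 1L]] <-
      data.frame(step = length(steps) + 1L, predictor = names(v), vif = v,
                 row.names = NULL)
    if (all(v <= threshold) || ncol(X) == 1L) break
    worst <- names(v)[which.max(v)]
    dropped <- c(dropped, worst)
    X <- X[setdiff(names(X), worst)]
  }
  list(retained = names(X), dropped = dropped, vif = vifs_of(X),
       steps = do.call(rbind, steps))
}

#' ANCOVA of a phylogenetic diversity index on climate and edaphic class
#'
#' Fits index ~ intercept + climate terms + edaphic dummies + one spatial
#' filter. The edaphic factor is treatment-coded with `reference_class`
#' (default sedimentary) as baseline, so the reported dummies (e.g.
#' `crystalline`, `inselberg`) are mean shifts relative to the reference.
#' Coefficients with p < `alpha` are flagged.
#'
#' @param y Index vector, one value per site (in `sites` order).
#' @param sites Site table with a `substrate` column and the climate
#'   covariates named in `climate_terms`.
#' @param climate_terms Character vector of climate column names (may be
#'   empty).
#' @param filter Optional spatial filter vector (one value per site), e.g.
#'   the first PCNM eigenvector.
#' @param reference_class Edaphic reference level.
#' @param alpha Significance level for flags (the study tables use 0.10).
#' @return An `ols_fit` whose `coefficients` gain a logical `sig` column.
#' @export
ancova <- function(y, sites, climate_terms = character(), filter = NULL,
                   reference_class = "sedimentary", alpha = 0.10) {
  sites <- check_sites(sites)
  stopifnot(length(y) == nrow(sites), "substrate" %in% names(sites))
  classes <- unique(sites$substrate)
  if (length(classes) < 2)
    stop("need >= 2 edaphic classes represented", call. = FALSE)
  if (!reference_class %in% classes) {
    warning("reference class '", reference_class,
            "' absent; using '", classes[1], "'")
    reference_class <- classes[1]
  }
  X <- sites[, climate_terms, drop = FALSE]
  for (cl in setdiff(sort(classes), reference_class))
    X[[cl]] <- as.numeric(sites$substrate == cl)
  if (!is.null(filter)) {
    stopifnot(length(filter) == nrow(sites))
    X[["spatial_filter"]] <- filter
  }
  fit <- ols_fit(y, X, intercept = TRUE)
  fit$coefficients$sig <- fit$coefficients$p < alpha
  fit$alpha <- alpha
  fit$reference_class <- reference_class
  fit
}

#' Partition explained variation between climate and edaphic components
#'
#' Decomposes the explained variation of an index Y into the fraction due
#' purely to climate \[a\], shared between climate and edaphic environment
#' \[b\], purely edaphic \[c\], and unexplained \[d\], from three fits:
#' R2(Y~X) = a+b, R2(Y~W) = b+c, R2(Y~X,W) = a+b+c, so that
#' b = (a+b) + (b+c) - (a+b+c) and d = 1 - (a+b+c). With the adjusted-R2
#' flavour (Ezekiel correction, the default) fractions can be slightly
#' negative.
#'
#' @param y Index vector.
#' @param X Climate predictor data.frame/matrix.
#' @param W Edaphic predictor data.frame/matrix (e.g. treatment dummies).
#' @param r2_flavour `"adjusted"` (default) or `"raw"`.
#' @return A list: fractions `a`, `b`, `c`, `d`, `r2_full` (a+b+c),
#'   `flavour`, and the three component R2 values.
#' @export
variance_partition <- function(y, X, W, r2_flavour = c("adjusted", "raw")) {
  r2_flavour <- match.arg(r2_flavour)
  X <- as.data.frame(X)
  W <- as.data.frame(W)
  # tolerant R2: terms of X duplicated in W (total overlap) are aliased out
  # of the joint fit rather than raising the strict rank error
  r2_of <- function(df) {
    fit <- stats::lm(y ~ ., data = df, singular.ok = TRUE)
    r2 <- summary(fit)$r.squared
    if (r2_flavour == "raw") return(r2)
    rank <- fit$rank - 1L
    1 - (1 - r2) * (length(y) - 1) / (length(y) - rank - 1)
  }
  ab <- r2_of(X)
  bc <- r2_of(W)
  abc <- r2_of(stats::setNames(cbind(X, W),
                               make.unique(c(names(X), names(W)))))
  b <- ab + bc - abc
  list(a = ab - b, b = b, c = bc - b, d = 1 - abc,
       r2_full = abc, r2_climate = ab, r2_edaphic = bc,
       flavour = r2_flavour)
}

#' Edaphic treatment-coded dummy matrix for a site table
#'
#' @param sites Site table with a `substrate` column.
#' @param reference_class Baseline level (no dummy).
#' @return Data.frame of 0/1 dummies, one per non-reference class.
#' @export
edaphic_dummies <- function(sites, reference_class = "sedimentary") {
  sites <- check_sites(sites)
  out <- list()
  for (cl in setdiff(sort(unique(sites$substrate)), reference_class))
    out[[cl]] <- as.numeric(sites$substrate == cl)
  as.data.frame(out)
}
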