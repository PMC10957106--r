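#' Monotone I-spline basis for one predictor
#'
#' Quadratic (order-3) I-splines with knots at the observed minimum, median
#' and maximum (quantiles for other spline counts). Each basis function is
#' monotone non-decreasing, 0 at/below the first knot and 1 at/above the
#' last; I-splines are trailing partial sums of the order-3 B-spline basis.
#'
#' @param values numeric vector of observed predictor values.
#' @param n_splines number of I-splines (default 3).
#' @return object of class `ispline_basis`.
#' @export
build_basis <- function(values, n_splines = 3) {
  values <- values[is.finite(values)]
  ud <- sort(unique(values))
  if (length(ud) < 2) stop("predictor is constant; cannot build a basis")
  qs <- stats::quantile(values, probs = seq(0, 1, length.out = max(n_splines, 2)),
                        names = FALSE, type = 7)
  ord <- 3L
  lo <- qs[1]; hi <- qs[length(qs)]
  interior <- qs[-c(1, length(qs))]
  interior <- interior[interior > lo & interior < hi]  # dedupe degenerate knots
  knots <- c(rep(lo, ord), interior, rep(hi, ord))
  structure(list(knots = knots, order = ord, lo = qs[1], hi = qs[length(qs)],
                 n_splines = length(knots) - ord - 1L),
            class = "ispline_basis")
}

#' Evaluate an I-spline basis
#' @param basis an `ispline_basis`.
#' @param x numeric vector.
#' @return matrix `length(x) x n_splines`, values in `[0, 1]`.
#' @export
eval_basis <- function(basis, x) {
  xx <- pmin(pmax(x, basis$lo), basis$hi)
  B <- splines::splineDesign(basis$knots, xx, ord = basis$order,
                             outer.ok = TRUE)
  nb <- ncol(B)
  I <- vapply(seq_len(nb - 1L), function(j) rowSums(B[, (j + 1L):nb, drop = FALSE]),
              numeric(length(xx)))
  I <- matrix(I, nrow = length(xx))
  I <- pmin(pmax(I, 0), 1)  # guard rounding at the boundaries
  colnames(I) <- paste0("s", seq_len(nb - 1L))
  I
}

# build the site-pair design matrix: for predictors present as <p>_i/<p>_j
# columns the regressor is |I(x_i) - I(x_j)|; for pre-paired distances
# (a single column, e.g. geographic or biome distance) the distance enters
# its own basis directly
gdm_design <- function(table, predictors, n_splines = 3, bases = NULL) {
  X <- NULL; cols <- character(0); index <- character(0)
  if (is.null(bases)) bases <- list()
  for (p in predictors) {
    if (all(c(paste0(p, "_i"), paste0(p, "_j")) %in% names(table))) {
      xi <- table[[paste0(p, "_i")]]; xj <- table[[paste0(p, "_j")]]
      if (is.null(bases[[p]])) bases[[p]] <- build_basis(c(xi, xj), n_splines)
      M <- abs(eval_basis(bases[[p]], xi) - eval_basis(bases[[p]], xj))
    } else if (p %in% names(table)) {
      d <- table[[p]]
      if (is.null(bases[[p]])) bases[[p]] <- build_basis(d, n_splines)
      M <- eval_basis(bases[[p]], d)
    } else stop("predictor not found in table: ", p)
    X <- cbind(X, M)
    cols <- c(cols, paste0(p, ".", colnames(M)))
    index <- c(index, rep(p, ncol(M)))
  }
  colnames(X) <- cols
  list(X = X, bases = bases, index = index)
}

# binomial deviance relative to the saturated model, with 0 log 0 = 0
binomial_deviance <- function(d, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  t1 <- ifelse(d > 0, d * log(d / mu), 0)
  t2 <- ifelse(d < 1, (1 - d) * log((1 - d) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

#' Fit a generalized dissimilarity model
#'
#' Models pairwise dissimilarity as `d = 1 - exp(-eta)` with
#' `eta = b0 + sum_pk a_pk |I_pk(x_pi) - I_pk(x_pj)|`, all coefficients
#' constrained non-negative, fitted by iteratively reweighted non-negative
#' least squares on the binomial deviance.
#'
#' @param table a `dissimilarity_table` (or any data.frame with the needed
#'   columns).
#' @param response name of the response column (values in `[0, 1]`).
#' @param predictors character vector; each either a per-cell predictor with
#'   `<p>_i`/`<p>_j` columns or a pre-paired distance column.
#' @param n_splines I-splines per predictor (default 3).
#' @param max_iter,tol IRLS control: stop when the relative deviance change
#'   drops below `tol` (default 1e-8) or after `max_iter` iterations.
#' @return object of class `gdm_fit`.
#' @export
fit_gdm <- function(table, response, predictors, n_splines = 3,
                    max_iter = 200, tol = 1e-8) {
  d <- table[[response]]
  keep <- is.finite(d)
  des <- gdm_design(table, predictors, n_splines)
  keep <- keep & apply(is.finite(des$X), 1, all)
  if (any(!keep)) message(sum(!keep), " pairs with missing values dropped")
  d <- d[keep]; X <- des$X[keep, , drop = FALSE]
  stopifnot(all(d >= 0), all(d <= 1))
  n <- length(d)
  mu_null <- mean(d)
  null_dev <- binomial_deviance(d, rep(mu_null, n))

  if (stats::var(d) == 0 || null_dev < 1e-12) {
    beta <- c(intercept = max(-log(1 - min(mu_null, 1 - 1e-12)), 0),
              stats::setNames(rep(0, ncol(X)), colnames(X)))
    fit <- list(intercept = beta[1], coefficients = beta[-1],
                bases = des$bases, predictor_index = des$index,
                predictors = predictors, response = response,
                null_deviance = null_dev, residual_deviance = null_dev,
                pct_deviance_explained = 0,
                importance = tapply(beta[-1], des$index, sum)[predictors],
                fitted = rep(mu_null, n), converged = TRUE, iterations = 0L)
    class(fit) <- "gdm_fit"
    return(fit)
  }

  Xf <- cbind(intercept = 1, X)
  mu <- pmin(pmax(d, 1e-4), 1 - 1e-4)
  mu <- (mu + mu_null) / 2
  eta <- -log(1 - mu)
  dev <- binomial_deviance(d, mu)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- pmin(pmax(1 - exp(-eta), 1e-10), 1 - 1e-10)
    w <- (1 - mu) / mu                      # (dmu/deta)^2 / (mu (1 - mu))
    z <- eta + (d - mu) / (1 - mu)
    sw <- sqrt(w)
    beta <- pracma::lsqnonneg(sw * Xf, sw * z)$x
    eta_new <- drop(Xf %*% beta)
    mu_new <- pmin(pmax(1 - exp(-eta_new), 1e-10), 1 - 1e-10)
    dev_new <- binomial_deviance(d, mu_new)
    if (is.finite(dev_new) && abs(dev - dev_new) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE; eta <- eta_new; dev <- dev_new; break
    }
    eta <- eta_new; dev <- dev_new
  }
  if (!converged && max_iter > 1)
    warning("IRLS did not converge in ", max_iter,
            " iterations; last deviance ", signif(dev, 6))
  names(beta) <- colnames(Xf)
  pct <- 100 * (1 - dev / null_dev)
  fit <- list(intercept = unname(beta[1]), coefficients = beta[-1],
              bases = des$bases, predictor_index = des$index,
              predictors = predictors, response = response,
              null_deviance = null_dev, residual_deviance = dev,
              pct_deviance_explained = pct,
              importance = tapply(beta[-1], des$index, sum)[predictors],
              fitted = 1 - exp(-eta), converged = converged, iterations = it)
  class(fit) <- "gdm_fit"
  fit
}

#' Predict dissimilarities from a fitted GDM
#' @param object a `gdm_fit`.
#' @param newdata data.frame with the predictor columns used in the fit.
#' @param ... unused.
#' @return predicted dissimilarities in `[0, 1)`.
#' @export
predict.gdm_fit <- function(object, newdata, ...) {
  des <- gdm_design(newdata, object$predictors, bases = object$bases)
  eta <- object$intercept + drop(des$X %*% object$coefficients)
  1 - exp(-eta)
}

#' @export
print.gdm_fit <- function(x, ...) {
  cat("GDM fit:", x$response, "~", paste(x$predictors, collapse = " + "), "\n")
  cat(sprintf("  deviance explained: %.2f%% (null %.3f, residual %.3f)\n",
              x$pct_deviance_explained, x$null_deviance, x$residual_deviance))
  cat("  predictor importance (coefficient sums):\n")
  print(round(x$importance, 4))
  invisible(x)
}

#' Variation partitioning between two predictor sets
#'
#' Fits GDMs with A and B together, A alone and B alone, and decomposes the
#' joint percent deviance explained into unique and shared fractions.
#' Negative components arising from numerical noise are clamped to zero with
#' a warning.
#'
#' @param table site-pair table.
#' @param response response column name.
#' @param set_A,set_B disjoint non-empty predictor sets.
#' @param ... passed to [fit_gdm()].
#' @return list with the three fits' deviance explained (`D_AB`, `D_A`,
#'   `D_B`), `unique_A`, `unique_B`, `shared_AB`, `unexplained`
#'   (percentages), and `rescaled` (unique_A, unique_B, shared scaled to sum
#'   to 1).
#' @export
variation_partition <- function(table, response, set_A, set_B, ...) {
  stopifnot(length(set_A) >= 1, length(set_B) >= 1,
            length(intersect(set_A, set_B)) == 0)
  D_AB <- fit_gdm(table, response, c(set_A, set_B), ...)$pct_deviance_explained
  D_A <- fit_gdm(table, response, set_A, ...)$pct_deviance_explained
  D_B <- fit_gdm(table, response, set_B, ...)$pct_deviance_explained
  clamp <- function(x) {
    if (x < 0) {
      if (x < -1e-6) warning("negative partition component clamped to 0: ",
                             signif(x, 4))
      0
    } else x
  }
  uA <- clamp(D_AB - D_B); uB <- clamp(D_AB - D_A)
  sh <- clamp(D_A + D_B - D_AB)
  tot <- uA + uB + sh
  list(D_AB = D_AB, D_A = D_A, D_B = D_B,
       unique_A = uA, unique_B = uB, shared_AB = sh,
       unexplained = 100 - D_AB,
       rescaled = if (tot > 0) c(unique_A = uA, unique_B = uB,
                                 shared_AB = sh) / tot
                  else c(unique_A = NA, unique_B = NA, shared_AB = NA))
}

#' Geographic residuals of turnover
#'
#' Ordinary least-squares regression of the response on great-circle
#' distance; the residuals are the fraction of turnover not explained by
#' spatial distance. A min-max rescaled copy (to `[0.001, 0.999]`, as the
#' negative-exponential link needs an open unit interval) is returned for use
#' as a GDM response.
#'
#' @param table site-pair table with a `geographic_distance_km` column.
#' @param response response column name.
#' @return data.frame with `residual` and `residual_rescaled`; attributes
#'   `intercept` and `slope` hold the OLS coefficients.
#' @export
geographic_residuals <- function(table, response) {
  stopifnot("geographic_distance_km" %in% names(table))
  d <- table[[response]]
  ok <- is.finite(d) & is.finite(table$geographic_distance_km)
  fit <- stats::lm(d[ok] ~ table$geographic_distance_km[ok])
  res <- rep(NA_real_, length(d))
  res[ok] <- stats::residuals(fit)
  rng <- range(res, na.rm = TRUE)
  rescaled <- if (diff(rng) < 1e-12) rep(0.5, length(res)) else
    0.001 + 0.998 * (res - rng[1]) / diff(rng)
  out <- data.frame(residual = res, residual_rescaled = rescaled)
  attr(out, "intercept") <- unname(stats::coef(fit)[1])
  attr(out, "slope") <- unname(stats::coef(fit)[2])
  out
}
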