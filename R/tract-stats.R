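# Group statistics: ROI-level and pointwise linear regressions with
# covariates, Bonferroni control, and partial correlations with clinical
# scores.

# Design matrix [intercept, group(patient=1), age, education, duration].
.group_design <- function(subjects) {
  need <- c("group", "age", "education", "duration")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("subject table lacks columns: ",
                         paste(miss, collapse = ", "))
  g <- as.integer(subjects$group == "patient")
  cbind(intercept = 1, group = g, age = subjects$age,
        education = subjects$education, duration = subjects$duration)
}

# OLS of each column of Y on X; returns coefficient, t and p for `term`.
# QR is computed once, so the pointwise analyses are a single pass.
.ols_term <- function(X, Y, term = "group") {
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) stop("too few subjects for the regression model (need n > ",
                        p + 1L, ")")
  qx <- qr(X)
  if (qx$rank < p) stop("collinear design matrix")
  Y <- as.matrix(Y)
  coefs <- qr.coef(qx, Y)
  res <- Y - X %*% coefs
  df <- n - p
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  j <- match(term, colnames(X))
  se <- sqrt(sigma2 * XtXinv[j, j])
  b <- coefs[j, ]
  t <- ifelse(se > 0, b / se, 0)
  p_two <- 2 * pt(-abs(t), df)
  p_two[se == 0] <- 1
  list(coefficient = unname(b), t = unname(t), p = unname(p_two), df = df)
}

#' Group-difference linear regression with covariates
#'
#' Ordinary least squares of a per-subject outcome on an intercept, the
#' diagnostic-group indicator (control = 0, patient = 1) and the covariates
#' age, years of education and illness duration (0 in controls). Reports the
#' group term.
#'
#' @param y Numeric outcome, one value per subject.
#' @param subjects Subject table with columns `group`, `age`, `education`,
#'   `duration`.
#' @return List with `coefficient`, `t`, `p` (two-sided, t distribution with
#'   n - 5 df) and `df`.
#' @export
group_regression <- function(y, subjects) {
  X <- .group_design(subjects)
  if (length(y) != nrow(X)) stop("y and subject table differ in length")
  r <- .ols_term(X, matrix(y, ncol = 1L))
  lapply(r, function(v) if (length(v) == 1L) v[[1]] else v)
}

#' ROI-level (whole-bundle mean) group analysis
#'
#' One [group_regression()] per bundle x metric on the per-subject mean
#' metric value over the bundle. P values are reported uncorrected at this
#' level.
#'
#' @param means Long data frame with columns `id`, `bundle`, `metric`,
#'   `value`: one mean value per subject, bundle and metric.
#' @param subjects Subject table (must contain every `id` in `means`).
#' @return Data frame with one row per bundle x metric: `bundle`, `metric`,
#'   `coefficient`, `t`, `p`, sorted by bundle then metric.
#' @export
roi_analysis <- function(means, subjects) {
  need <- c("id", "bundle", "metric", "value")
  if (!all(need %in% names(means))) stop("means must have columns ",
                                         paste(need, collapse = ", "))
  out <- list()
  for (b in sort(unique(means$bundle))) for (m in sort(unique(means$metric))) {
    cell <- means[means$bundle == b & means$metric == m, ]
    miss <- setdiff(subjects$id, cell$id)
    if (length(miss)) stop("missing subjects for ", b, "/", m, ": ",
                           paste(miss, collapse = ", "))
    y <- cell$value[match(subjects$id, cell$id)]
    r <- group_regression(y, subjects)
    out[[length(out) + 1L]] <- data.frame(bundle = b, metric = m,
                                          coefficient = r$coefficient,
                                          t = r$t, p = r$p)
  }
  do.call(rbind, out)
}

#' Pointwise (tract-based) group analysis along a bundle
#'
#' Smooths every subject's profile (unless already flagged smoothed), fits
#' the group regression at each of the 30 arc-length points, and flags
#' points with Bonferroni-corrected significance, the correction family
#' being the points within one bundle x metric (size configurable).
#'
#' @param profiles Either a long data frame with columns `id`, `bundle`,
#'   `metric`, `point`, `value` and optionally `smoothed` (logical), or a
#'   subjects x points numeric matrix for a single bundle x metric (then
#'   give `bundle`/`metric` labels).
#' @param subjects Subject table.
#' @param alpha Overall significance level.
#' @param family Bonferroni family size; default the number of points.
#' @param smoothed Set `TRUE` if a matrix input is already smoothed.
#' @param bundle,metric Labels used with matrix input.
#' @return An object of class `pointwise_result`: data frame with `bundle`,
#'   `metric`, `point` (1-based), `coefficient`, `t`, `p`, `significant`;
#'   attributes `alpha` and `family`.
#' @export
tractwise_analysis <- function(profiles, subjects, alpha = 0.05,
                               family = NULL, smoothed = FALSE,
                               bundle = "bundle", metric = "fa") {
  X <- .group_design(subjects)
  cells <- list()
  if (is.matrix(profiles)) {
    if (nrow(profiles) != nrow(subjects))
      stop("profile matrix rows must match the subject table")
    cells[[paste(bundle, metric, sep = "|")]] <-
      list(bundle = bundle, metric = metric, mat = profiles,
           smoothed = smoothed)
  } else {
    need <- c("id", "bundle", "metric", "point", "value")
    if (!all(need %in% names(profiles)))
      stop("profiles must have columns ", paste(need, collapse = ", "))
    for (b in unique(profiles$bundle)) for (m in unique(profiles$metric)) {
      cell <- profiles[profiles$bundle == b & profiles$metric == m, ]
      if (nrow(cell) == 0L) next
      pts <- sort(unique(cell$point))
      mat <- matrix(NA_real_, nrow(subjects), length(pts))
      for (si in seq_len(nrow(subjects))) {
        rows <- cell[cell$id == subjects$id[si], ]
        mat[si, ] <- rows$value[match(pts, rows$point)]
      }
      if (any(is.na(mat))) stop("incomplete profiles for ", b, "/", m)
      sm <- if ("smoothed" %in% names(cell)) all(cell$smoothed) else FALSE
      cells[[paste(b, m, sep = "|")]] <-
        list(bundle = b, metric = m, mat = mat, smoothed = sm)
    }
  }

  out <- list()
  for (cl in cells) {
    mat <- cl$mat
    if (!cl$smoothed) {
      message("smoothing profiles for ", cl$bundle, "/", cl$metric,
              " before pointwise analysis")
      mat <- t(apply(mat, 1L, smooth_profile, n_expected = ncol(mat)))
    }
    fam <- if (is.null(family)) ncol(mat) else family
    r <- .ols_term(X, mat)
    out[[length(out) + 1L]] <- data.frame(
      bundle = cl$bundle, metric = cl$metric, point = seq_len(ncol(mat)),
      coefficient = r$coefficient, t = r$t, p = r$p,
      significant = r$p < alpha / fam)
  }
  res <- do.call(rbind, out)
  structure(res, alpha = alpha,
            family = if (is.null(family)) ncol(cells[[1]]$mat) else family,
            class = c("pointwise_result", "data.frame"))
}

#' Partial correlation controlling for covariates
#'
#' Residualizes `x` and `y` on an intercept plus the covariates by least
#' squares and reports the Pearson correlation of the residuals, with the
#' two-sided p value from `t = r * sqrt((n - 2 - k) / (1 - r^2))`.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix / data frame with k columns, or NULL
#'   (plain Pearson correlation).
#' @return List with `r`, `p`, `df` (`n - 2 - k`).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length")
  C <- if (is.null(covariates)) matrix(1, n, 1L)
       else cbind(1, as.matrix(covariates))
  k <- ncol(C) - 1L
  if (n <= k + 3L) stop("too few observations: need n > k + 3")
  qc <- qr(C)
  rx <- qr.resid(qc, x)
  ry <- qr.resid(qc, y)
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  if (sx <= 1e-12 * sqrt(n) * (abs(mean(x)) + 1) ||
      sy <= 1e-12 * sqrt(n) * (abs(mean(y)) + 1))
    stop("zero residual variance: correlation undefined")
  r <- sum(rx * ry) / (sx * sy)
  df <- n - 2L - k
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(t), df), df = df)
}

#' Pointwise partial correlation with clinical scores (patients only)
#'
#' At every profile point, the partial correlation between the metric value
#' and each clinical score, controlling for age, years of education and
#' illness duration, restricted to patients, with Bonferroni flags over the
#' points of one bundle x metric x score.
#'
#' @param profiles As in [tractwise_analysis()] (matrix input covers one
#'   bundle x metric).
#' @param subjects Subject table including the score columns.
#' @param scores Character vector of score column names.
#' @param alpha Overall significance level.
#' @param family Bonferroni family size; default the number of points.
#' @param smoothed,bundle,metric As in [tractwise_analysis()].
#' @return Data frame with `bundle`, `metric`, `score`, `point`, `r`, `p`,
#'   `significant`.
#' @export
clinical_correlation <- function(profiles, subjects,
                                 scores = c("panss_positive",
                                            "panss_negative",
                                            "panss_general", "panss_total"),
                                 alpha = 0.05, family = NULL,
                                 smoothed = FALSE, bundle = "bundle",
                                 metric = "fa") {
  miss <- setdiff(scores, names(subjects))
  if (length(miss)) stop("score column(s) missing: ",
                         paste(miss, collapse = ", "))
  pat <- subjects$group == "patient"
  if (sum(pat) < 8L) stop("need at least 8 patients")
  if (is.matrix(profiles)) {
    if (nrow(profiles) != nrow(subjects))
      stop("profile matrix rows must match the subject table")
    mat <- profiles[pat, , drop = FALSE]
    if (!smoothed)
      mat <- t(apply(mat, 1L, smooth_profile, n_expected = ncol(mat)))
    cells <- list(list(bundle = bundle, metric = metric, mat = mat))
  } else {
    need <- c("id", "bundle", "metric", "point", "value")
    if (!all(need %in% names(profiles)))
      stop("profiles must have columns ", paste(need, collapse = ", "))
    cells <- list()
    for (b in unique(profiles$bundle)) for (m in unique(profiles$metric)) {
      cell <- profiles[profiles$bundle == b & profiles$metric == m, ]
      if (nrow(cell) == 0L) next
      pts <- sort(unique(cell$point))
      ids <- subjects$id[pat]
      mat <- matrix(NA_real_, length(ids), length(pts))
      for (si in seq_along(ids)) {
        rows <- cell[cell$id == ids[si], ]
        mat[si, ] <- rows$value[match(pts, rows$point)]
      }
      if (any(is.na(mat))) stop("incomplete patient profiles for ", b, "/", m)
      sm <- if ("smoothed" %in% names(cell)) all(cell$smoothed) else smoothed
      if (!sm) mat <- t(apply(mat, 1L, smooth_profile,
                              n_expected = ncol(mat)))
      cells[[length(cells) + 1L]] <- list(bundle = b, metric = m, mat = mat)
    }
  }
  covs <- as.matrix(subjects[pat, c("age", "education", "duration")])
  out <- list()
  for (cl in cells) {
    fam <- if (is.null(family)) ncol(cl$mat) else family
    for (sc in scores) {
      yv <- subjects[[sc]][pat]
      for (j in seq_len(ncol(cl$mat))) {
        pc <- partial_correlation(cl$mat[, j], yv, covs)
        out[[length(out) + 1L]] <- data.frame(
          bundle = cl$bundle, metric = cl$metric, score = sc, point = j,
          r = pc$r, p = pc$p, significant = pc$p < alpha / fam)
      }
    }
  }
  do.call(rbind, out)
}
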