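#' Column preprocessing for latent-variable models
#'
#' Mean-centers and scales a data matrix. Unit-variance scaling (`"uv"`,
#' the default) divides each column by its standard deviation; `"pareto"`
#' divides by the square root of the standard deviation; `"none"` leaves
#' the spread untouched. Zero-variance columns cannot be scaled and are
#' dropped with a warning.
#'
#' @param X numeric matrix (observations x variables).
#' @param scaling one of `"uv"`, `"pareto"`, `"none"`.
#' @param center mean-center columns (logical).
#' @return List with the preprocessed matrix `Xs`, the per-column `means`
#'   and `scales`, the retained column names `kept`, and the settings.
#' @export
preprocess_matrix <- function(X, scaling = c("uv", "pareto", "none"),
                              center = TRUE) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, sd)
  keep <- if (scaling == "none") rep(TRUE, ncol(X)) else sds > 0
  if (!all(keep)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  if (ncol(X) == 0) stop("no variable with nonzero variance left")
  means <- if (center) colMeans(X) else rep(0, ncol(X))
  scales <- switch(scaling, uv = sds, pareto = sqrt(sds),
                   none = rep(1, ncol(X)))
  names(scales) <- colnames(X)
  Xs <- sweep(sweep(X, 2, means, "-"), 2, scales, "/")
  list(Xs = Xs, means = means, scales = scales, kept = colnames(X),
       scaling = scaling, center = center)
}

# apply a stored preprocessing spec to new data
apply_preprocess <- function(pre, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(pre$kept))
      stop("new data must have the model's ", length(pre$kept), " variables")
    colnames(X) <- pre$kept
  }
  X <- X[, pre$kept, drop = FALSE]
  sweep(sweep(X, 2, pre$means, "-"), 2, pre$scales, "/")
}

#' Principal component analysis by NIPALS
#'
#' Extracts `A` principal components one at a time with the NIPALS
#' algorithm (iterate loading/score regressions, deflate, repeat), the
#' same procedure chemometrics software uses for score-plot models.
#' Convergence is declared when the relative score change falls below
#' `tol` (default 1e-10) or after 500 iterations. If the matrix rank is
#' exhausted before `A` components the model is truncated with a warning.
#'
#' @param X numeric matrix (observations x variables); no missing values.
#' @param A number of components.
#' @param scaling,center see [preprocess_matrix()].
#' @param tol,max_iter NIPALS convergence controls.
#' @return An object of class `mv_model`: scores `T` (n x A), unit-norm
#'   loadings `P` (k x A), explained fractions `R2X`, the preprocessing
#'   spec, and the preprocessed matrix.
#' @export
fit_pca <- function(X, A = 2, scaling = c("uv", "pareto", "none"),
                    center = TRUE, tol = 1e-10, max_iter = 500) {
  pre <- preprocess_matrix(X, scaling = scaling, center = center)
  Xs <- pre$Xs
  n <- nrow(Xs); k <- ncol(Xs)
  if (n < A + 1) stop("need at least A + 1 observations")
  tss <- sum(Xs^2)
  if (tss < 1e-12) stop("matrix is constant after preprocessing")
  Tm <- matrix(0, n, A); Pm <- matrix(0, k, A); r2 <- numeric(A)
  E <- Xs
  a <- 0
  while (a < A) {
    ssq <- colSums(E^2)
    if (max(ssq) / tss < 1e-12) {
      warning("rank exhausted after ", a, " component(s); truncating")
      break
    }
    t <- E[, which.max(ssq)]
    for (it in seq_len(max_iter)) {
      p <- crossprod(E, t) / sum(t^2)
      p <- p / sqrt(sum(p^2))
      t_new <- E %*% p
      if (sqrt(sum((t_new - t)^2)) < tol * sqrt(sum(t_new^2))) {
        t <- t_new
        break
      }
      t <- t_new
    }
    a <- a + 1
    Tm[, a] <- t
    Pm[, a] <- p
    r2[a] <- sum(t^2) / tss
    E <- E - t %*% t(p)
  }
  Tm <- Tm[, seq_len(a), drop = FALSE]
  Pm <- Pm[, seq_len(a), drop = FALSE]
  rownames(Pm) <- colnames(Xs)
  rownames(Tm) <- rownames(Xs)
  structure(list(scores = Tm, loadings = Pm, R2X = r2[seq_len(a)],
                 A = a, n = n, preprocess = pre, Xs = Xs),
            class = "mv_model")
}

#' @export
print.mv_model <- function(x, ...) {
  cat(sprintf("NIPALS PCA: %d observations, %d variables, %d component(s)\n",
              x$n, ncol(x$Xs), x$A))
  cat("R2X per component:", paste(sprintf("%.3f", x$R2X), collapse = " "),
      "\n")
  invisible(x)
}

#' Hotelling T-squared control limit
#'
#' Critical value of the T-squared statistic of `A` latent scores from a
#' model fitted on `N` observations, at level `alpha`:
#' `A (N-1)(N+1) / (N (N-A)) * F(1-alpha; A, N-A)` -- the constant that
#' defines the confidence ellipse drawn on chemometrics score plots. As
#' `N` grows it approaches the chi-squared quantile with `A` degrees of
#' freedom.
#'
#' @param N number of observations the model was fitted on.
#' @param A number of components.
#' @param alpha significance level (0.01 for a 99\% ellipse).
#' @return Scalar critical value.
#' @export
hotelling_limit <- function(N, A, alpha = 0.01) {
  if (!(N > A && A >= 1)) stop("need N > A >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  A * (N - 1) * (N + 1) / (N * (N - A)) * qf(1 - alpha, A, N - A)
}

#' Per-observation Hotelling T-squared statistic
#'
#' `T2_i = sum_a t_ia^2 / var(t_a)` over the model components, i.e. the
#' squared Mahalanobis distance of an observation's scores from the model
#' center.
#'
#' @param model a fitted [fit_pca()] model.
#' @param scores optional score matrix (defaults to the training scores).
#' @return Numeric vector of T-squared values.
#' @export
hotelling_t2 <- function(model, scores = model$scores) {
  s2 <- apply(model$scores, 2, var)
  rowSums(sweep(scores^2, 2, s2, "/"))
}

#' Questionnaire reliability screen
#'
#' Fits a NIPALS PCA to one questionnaire's records, computes the
#' Hotelling T-squared statistic of every patient against the
#' `1 - alpha` control ellipse, and judges the questionnaire against the
#' acceptance rule: it passes when at most `accept_limit` percent of
#' patients fall outside the ellipse (the study used a 99\% ellipse and a
#' 10\% allowance).
#'
#' @param x either a numeric matrix (patients x variables) or a scored
#'   cohort data.frame (see [score_cohort()]) combined with `timepoint`.
#' @param timepoint which questionnaire to screen when `x` is a scored
#'   cohort.
#' @param variables variable columns used when `x` is a scored cohort;
#'   defaults to the 25 adjusted items plus SBP and DBP.
#' @param A,alpha,scaling model settings (2 components, 99\% ellipse,
#'   unit-variance scaling by default).
#' @param accept_limit maximal acceptable percentage outside the ellipse.
#' @return An object of class `hotelling_screen`: `t2`, `limit`, `flags`,
#'   flagged `ids`, `outside_fraction` (percent, half-up 2 decimals),
#'   `pass`, and the underlying `model`.
#' @export
screen_questionnaire <- function(x, timepoint = NULL,
                                 variables = c(questionnaire_items, "sbp", "dbp"),
                                 A = 2, alpha = 0.01,
                                 scaling = "uv", accept_limit = 10) {
  if (is.data.frame(x) && !is.null(timepoint)) {
    sub <- x[x$timepoint == timepoint, , drop = FALSE]
    if (nrow(sub) == 0) stop("no records at timepoint ", timepoint)
    ids <- sub$patient_id
    X <- as.matrix(sub[variables])
    rownames(X) <- ids
  } else {
    X <- as.matrix(x)
    if (is.null(rownames(X))) rownames(X) <- seq_len(nrow(X))
  }
  if (all(apply(X, 2, sd) == 0)) {
    # every observation sits at the center: trivially nothing to flag
    warning("all observations identical; nothing can fall outside the ellipse")
    n <- nrow(X)
    return(structure(list(t2 = rep(0, n), limit = hotelling_limit(n, A, alpha),
                          flags = rep(FALSE, n), ids = character(0),
                          alpha = alpha, outside_fraction = 0,
                          accept_limit = accept_limit, pass = TRUE,
                          model = NULL),
                     class = "hotelling_screen"))
  }
  model <- fit_pca(X, A = A, scaling = scaling)
  t2 <- hotelling_t2(model)
  lim <- hotelling_limit(model$n, model$A, alpha)
  flags <- t2 > lim
  frac <- round_half_up(100 * mean(flags), 2)
  structure(list(t2 = t2, limit = lim, flags = flags,
                 ids = rownames(X)[flags], alpha = alpha,
                 outside_fraction = frac, accept_limit = accept_limit,
                 pass = frac <= accept_limit, model = model),
            class = "hotelling_screen")
}

#' @export
print.hotelling_screen <- function(x, ...) {
  cat(sprintf("Hotelling T2 screen: %d/%d outside the %.0f%% ellipse (%.2f%%) -> %s\n",
              sum(x$flags), length(x$flags), 100 * (1 - x$alpha),
              x$outside_fraction,
              if (x$pass) sprintf("PASS (<= %g%%)", x$accept_limit)
              else sprintf("FAIL (> %g%%)", x$accept_limit)))
  if (length(x$ids)) cat("flagged:", paste(x$ids, collapse = ", "), "\n")
  invisible(x)
}

#' Per-variable contribution of a flagged observation
#'
#' Decomposes why an observation sits far from the model center: for each
#' retained variable the score-distance weight
#' `sum_a (t_ia / var(t_a)) p_ka` is combined with the observation's
#' preprocessed value; the contribution keeps the sign of the preprocessed
#' deviation (below the column mean gives a negative contribution) and its
#' magnitude ranks the variables that drive the T-squared excess.
#'
#' @param model a fitted [fit_pca()] model (or a `hotelling_screen`).
#' @param observation row index or row name of the observation.
#' @return Named numeric vector of signed contributions, one per retained
#'   variable.
#' @export
contribution_profile <- function(model, observation) {
  if (inherits(model, "hotelling_screen")) model <- model$model
  stopifnot(inherits(model, "mv_model"))
  if (is.character(observation)) {
    idx <- match(observation, rownames(model$Xs))
    if (is.na(idx)) stop("unknown observation id: ", observation)
  } else {
    idx <- observation
    if (is.na(idx) || idx < 1 || idx > nrow(model$Xs))
      stop("observation index out of range")
  }
  x <- model$Xs[idx, ]
  s2 <- apply(model$scores, 2, var)
  wt <- as.vector(model$loadings %*% (model$scores[idx, ] / s2))
  out <- x * abs(wt)
  names(out) <- colnames(model$Xs)
  out
}
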