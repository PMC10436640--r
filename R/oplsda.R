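#' Two-class OPLS-DA
#'
#' Orthogonal projections to latent structures discriminant analysis for
#' two classes: variation in `X` orthogonal to the class vector is
#' removed component by component (orthogonal signal correction), after
#' which a single predictive PLS component is fitted. With
#' `n_ortho = 0` the model is exactly one-component PLS1.
#'
#' The class vector is encoded -1/+1 (second factor level = +1) and
#' centered; `X` is preprocessed as in [fit_pca()].
#'
#' @param X numeric matrix (observations x variables).
#' @param y two-class factor, or vector coercible to one, of length
#'   `nrow(X)`; each class needs at least 3 observations.
#' @param n_ortho number of orthogonal components (default 1).
#' @param scaling,center see [preprocess_matrix()].
#' @return An object of class `oplsda`: predictive weight `w`, loading
#'   `p`, scores `t_p`, regression `q`, orthogonal scores/loadings
#'   `T_o`/`P_o`/`W_o`, explained class variance `R2Y`, the encoded
#'   class vector `y`, the preprocessing spec and both the original and
#'   orthogonal-corrected preprocessed matrices.
#' @export
fit_oplsda <- function(X, y, n_ortho = 1, scaling = c("uv", "pareto", "none"),
                       center = TRUE) {
  y <- as.factor(y)
  if (nlevels(y) != 2)
    stop("y must have exactly two classes, got ", nlevels(y))
  if (min(table(y)) < 3) stop("each class needs at least 3 observations")
  levels_y <- levels(y)
  ynum <- ifelse(y == levels_y[2], 1, -1)
  ynum <- ynum - mean(ynum)
  pre <- preprocess_matrix(X, scaling = scaling, center = center)
  Xs <- pre$Xs
  if (n_ortho < 0 || n_ortho >= min(dim(Xs)))
    stop("n_ortho must be in 0..min(dim(X)) - 1")
  E <- Xs
  To <- Po <- Wo <- NULL
  o <- 0
  while (o < n_ortho) {
    w <- crossprod(E, ynum); w <- w / sqrt(sum(w^2))
    t <- E %*% w
    p <- crossprod(E, t) / sum(t^2)
    wo <- p - c(crossprod(w, p)) * w
    if (sqrt(sum(wo^2)) < 1e-10) {
      warning("no orthogonal variation left after ", o, " component(s)")
      break
    }
    wo <- wo / sqrt(sum(wo^2))
    to <- E %*% wo
    po <- crossprod(E, to) / sum(to^2)
    E <- E - to %*% t(po)
    To <- cbind(To, to); Po <- cbind(Po, po); Wo <- cbind(Wo, wo)
    o <- o + 1
  }
  w <- crossprod(E, ynum)
  if (sqrt(sum(w^2)) < 1e-12) stop("X carries no covariance with the classes")
  w <- w / sqrt(sum(w^2))
  t_p <- E %*% w
  p <- crossprod(E, t_p) / sum(t_p^2)
  q <- c(crossprod(ynum, t_p)) / sum(t_p^2)
  r2y <- 1 - sum((ynum - t_p * q)^2) / sum(ynum^2)
  structure(list(w = w[, 1], p = p[, 1], t_p = t_p[, 1], q = q,
                 T_o = To, P_o = Po, W_o = Wo, n_ortho = o,
                 R2Y = r2y, y = ynum, classes = levels_y,
                 preprocess = pre, Xs = Xs, Xcorr = E),
            class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA: 1 predictive + %d orthogonal component(s), %d variables\n",
              x$n_ortho, length(x$w)))
  cat(sprintf("classes: %s (-1) vs %s (+1); R2Y = %.3f\n",
              x$classes[1], x$classes[2], x$R2Y))
  invisible(x)
}

#' S-plot coordinates
#'
#' For every variable, the covariance and the correlation of the
#' preprocessed variable with the predictive score: `p_cov(k) =
#' cov(t_p, x_k)` (magnitude of the change) and `p_corr(k) = p_cov(k) /
#' (sd(t_p) sd(x_k))` (reliability of the change). The S-shaped scatter
#' of the two is the S-plot used to pick influential, reliable variables.
#'
#' @param model a fitted [fit_oplsda()] model.
#' @return data.frame with `variable`, `p_cov`, `p_corr`.
#' @export
splot <- function(model) {
  stopifnot(inherits(model, "oplsda"))
  if (sd(model$t_p) < 1e-12) stop("predictive score has zero variance")
  p_cov <- as.vector(cov(model$t_p, model$Xs))
  sds <- apply(model$Xs, 2, sd)
  p_corr <- p_cov / (sd(model$t_p) * sds)
  data.frame(variable = colnames(model$Xs), p_cov = p_cov, p_corr = p_corr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signed VIP report
#'
#' Variable importance in projection for the single predictive component:
#' `VIP_k = sqrt(K) |w_k|` with the unit-norm predictive weight vector,
#' so that the mean squared VIP over the `K` retained variables is 1.
#' Each VIP is given the sign of its S-plot covariance (a variable that
#' decreased after the intervention gets a negative signed VIP), and
#' variables with `|signed VIP| >= threshold` (default 0.5) are selected.
#'
#' @param model a fitted [fit_oplsda()] model.
#' @param threshold selection threshold on `|signed VIP|`.
#' @return data.frame with `variable`, `vip`, `signed_vip`, `p_cov`,
#'   `p_corr`, `selected`.
#' @export
vip <- function(model, threshold = 0.5) {
  stopifnot(inherits(model, "oplsda"))
  sp <- splot(model)
  v <- sqrt(length(model$w)) * abs(model$w)
  signed <- v * sign(sp$p_cov)
  data.frame(variable = sp$variable, vip = as.vector(v),
             signed_vip = as.vector(signed),
             p_cov = sp$p_cov, p_corr = sp$p_corr,
             selected = abs(signed) >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Before/after OPLS-DA comparison of two questionnaires
#'
#' Builds the discriminant problem the study used to find what the
#' intervention changed: observations are patients present at both
#' questionnaires (complete cases), variables are the 25 adjusted item
#' scores plus SBP and DBP, the class is questionnaire membership
#' (the later questionnaire encoded +1, so improvement is positive).
#' Fits OPLS-DA, computes S-plot coordinates and signed VIPs, and reports
#' the final variable selection. Because VIPs are normalised to mean
#' square 1, a bare magnitude cutoff also fires on unreliable variables
#' when there is little class separation; following standard S-plot
#' practice the reported selection therefore requires both
#' `|signed VIP| >= vip_threshold` and `|p_corr| >= pcorr_min`.
#'
#' @param scored scored cohort data.frame (see [score_cohort()]).
#' @param timepoint_a,timepoint_b the two questionnaires to compare
#'   (defaults: first vs fourth).
#' @param variables variable columns (default adjusted items + SBP + DBP).
#' @param n_ortho orthogonal components (default 1).
#' @param vip_threshold cutoff on `|signed VIP|` (default 0.5).
#' @param pcorr_min reliability cutoff on the S-plot correlation
#'   (default 0.35).
#' @return List of class `oplsda_comparison`: the VIP `report` (with a
#'   `selected` column applying both cutoffs), the fitted `model`,
#'   `selected` variable names, and the number of paired patients
#'   `n_patients`.
#' @export
compare_timepoints <- function(scored, timepoint_a = 1, timepoint_b = 4,
                               variables = c(questionnaire_items, "sbp", "dbp"),
                               n_ortho = 1, vip_threshold = 0.5,
                               pcorr_min = 0.35) {
  if (timepoint_a == timepoint_b)
    stop("timepoint_a and timepoint_b must differ (degenerate classes)")
  for (tp in c(timepoint_a, timepoint_b))
    if (!any(scored$timepoint == tp)) stop("no records at timepoint ", tp)
  a <- scored[scored$timepoint == timepoint_a, ]
  b <- scored[scored$timepoint == timepoint_b, ]
  both <- intersect(a$patient_id, b$patient_id)
  a <- a[match(both, a$patient_id), ]
  b <- b[match(both, b$patient_id), ]
  X <- rbind(as.matrix(a[variables]), as.matrix(b[variables]))
  cls <- factor(rep(c("before", "after"), each = length(both)),
                levels = c("before", "after"))
  model <- fit_oplsda(X, cls, n_ortho = n_ortho)
  report <- vip(model, threshold = vip_threshold)
  report$selected <- report$selected & abs(report$p_corr) >= pcorr_min
  structure(list(report = report, model = model,
                 selected = report$variable[report$selected],
                 n_patients = length(both),
                 timepoints = c(timepoint_a, timepoint_b)),
            class = "oplsda_comparison")
}

#' @export
print.oplsda_comparison <- function(x, ...) {
  cat(sprintf("OPLS-DA, questionnaire %d vs %d, %d paired patients, R2Y = %.3f\n",
              x$timepoints[1], x$timepoints[2], x$n_patients, x$model$R2Y))
  sel <- x$report[x$report$selected, ]
  if (nrow(sel) == 0) {
    cat("no variable selected\n")
  } else {
    cat("selected variables (signed VIP):\n")
    for (i in seq_len(nrow(sel)))
      cat(sprintf("  %-4s %+0.2f\n", sel$variable[i], sel$signed_vip[i]))
  }
  invisible(x)
}
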