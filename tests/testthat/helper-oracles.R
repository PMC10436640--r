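# Independent oracles used to cross-check the latent-variable and Markov code.

# PCA oracle: loadings/scores from a dense eigendecomposition of the
# covariance of the preprocessed matrix.
eigen_pca_oracle <- function(Xs, A) {
  ev <- eigen(stats::cov(Xs), symmetric = TRUE)
  P <- ev$vectors[, seq_len(A), drop = FALSE]
  list(loadings = P, scores = Xs %*% P)
}

# align the sign of each column of B to match A
sign_align <- function(A, B) {
  for (j in seq_len(ncol(B))) {
    if (sum(A[, j] * B[, j]) < 0) B[, j] <- -B[, j]
  }
  B
}

# textbook one-component PLS1 on centered/scaled data
pls1_oracle <- function(Xs, y) {
  y <- y - mean(y)
  w <- crossprod(Xs, y)
  w <- w / sqrt(sum(w^2))
  t <- Xs %*% w
  p <- crossprod(Xs, t) / sum(t^2)
  list(w = w[, 1], t = t[, 1], p = p[, 1])
}

# Markov oracle: occupancy fractions by explicit matrix powers
matrix_power_trace <- function(M, horizon) {
  v <- c(1, 0, 0)
  out <- matrix(0, horizon + 1, 3)
  out[1, ] <- v
  Mp <- diag(3)
  for (t in seq_len(horizon)) {
    Mp <- Mp %*% M
    out[t + 1, ] <- c(1, 0, 0) %*% Mp
  }
  out
}

# random valid markov parameter sets for property tests
random_markov_params <- function() {
  markov_params(arm = sample(c("ipc", "none"), 1),
                control_prob = runif(1),
                relapse_prob = runif(1),
                mort_poor = runif(1, 0, 0.3),
                mort_well = runif(1, 0, 0.3),
                horizon = sample(5:30, 1),
                transition_style = sample(c("relapse", "redistribute",
                                            "incremental"), 1))
}

# small random cohort configs for generator property tests
random_cohort_config <- function(seed) {
  set.seed(seed * 1000)
  nm <- sample(5:20, 1)
  nf <- sample(5:20, 1)
  k <- sample(3:12, 1)
  cohort_config(
    n_patients = nm + nf, n_male = nm, n_female = nf,
    sbp_mean = c(male = runif(1, 120, 160), female = runif(1, 120, 160)),
    sbp_sd = c(male = runif(1, 5, 20), female = runif(1, 5, 20)),
    dbp_mean = c(male = runif(1, 70, 95), female = runif(1, 70, 95)),
    dbp_sd = c(male = runif(1, 4, 15), female = runif(1, 4, 15)),
    sbp_effect_3mo = runif(1, 0, 20), dbp_effect_3mo = runif(1, 0, 10),
    score_mean = c(male = runif(1, 60, 100), female = runif(1, 60, 100)),
    score_sd = c(male = runif(1, 6, 16), female = runif(1, 6, 16)),
    score_effect_12mo = runif(1, 0, 20),
    improved_items = sample(questionnaire_items, k),
    dropout_count = sample(0:2, 1),
    rho = runif(1, 0.2, 0.8),
    seed = seed)
}

# variables entering the multivariate screens
screen_variables <- c(questionnaire_items, "sbp", "dbp")
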