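# Independent, deliberately naive reference implementations used as oracles.
# These share no code with the package kernels: string slicing and plain loops
# only.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Sum over offsets of exp(window energy) by direct substring scoring.
oracle_mode_affinity <- function(seq, beta, gamma = NULL) {
  w <- ncol(beta)
  noff <- nchar(seq) - w + 1
  if (is.null(gamma)) gamma <- numeric(noff)
  tot <- 0
  for (x in seq_len(noff)) {
    win <- substr(seq, x, x + w - 1)
    e <- gamma[x]
    for (p in seq_len(w))
      e <- e + unname(beta[substr(win, p, p), p])
    tot <- tot + exp(e)
  }
  tot
}

oracle_kappa <- function(peptide, beta_s, beta_ns, gamma, alpha_ns, alpha_s,
                         flank_left = "GQSGQ", flank_right = "GGQSG", f_s = 5) {
  lf <- if (f_s > 0) substr(flank_left, nchar(flank_left) - f_s + 1, nchar(flank_left)) else ""
  rf <- if (f_s > 0) substr(flank_right, 1, f_s) else ""
  alpha_ns * oracle_mode_affinity(peptide, beta_ns, gamma) +
    alpha_s * oracle_mode_affinity(paste0(lf, peptide, rf), beta_s)
}

# Per-read product-of-probabilities evaluation of the scaled binomial
# log-likelihood: expand every count into individual reads.
oracle_log_likelihood <- function(model, tables) {
  total <- 0
  for (ci in seq_along(tables)) {
    tab <- tables[[ci]]
    act <- model$activities[ci, ]
    k_c <- sum(tab$input) + sum(tab$bound)
    ll <- 0
    for (i in seq_len(nrow(tab))) {
      kap <- oracle_kappa(tab$sequence[i], model$beta_s, model$beta_ns,
                          model$gamma, act$alpha_ns, act$alpha_s,
                          model$flank_left, model$flank_right,
                          model$flank_overlap)
      p_bound <- act$eta_bound * kap / (act$eta_input + act$eta_bound * kap)
      for (r in seq_len(tab$input[i])) ll <- ll + log(1 - p_bound)
      for (r in seq_len(tab$bound[i])) ll <- ll + log(p_bound)
    }
    total <- total + ll / k_c
  }
  total
}

# Random peptides for tests.
random_peptides <- function(n, L = 11, fixed = NULL) {
  m <- matrix(sample(AA20, n * L, replace = TRUE), n, L)
  if (!is.null(fixed))
    for (j in seq_along(fixed)) m[, as.integer(names(fixed)[j])] <- fixed[[j]]
  apply(m, 1, paste, collapse = "")
}

# A small random unconstrained model with matching activities rows.
random_test_model <- function(n_tables = 1, w_s = 11, w_ns = 3, var_len = 11,
                              f_s = 5, sd = 0.5) {
  binding_model(
    energy_matrix(w_s, matrix(rnorm(20 * w_s, 0, sd), 20)),
    energy_matrix(w_ns, matrix(rnorm(20 * w_ns, 0, sd), 20)),
    gamma = rnorm(var_len - w_ns + 1, 0, 0.2),
    activities = tibble::tibble(round = paste0("R", seq_len(n_tables)),
                                alpha_ns = exp(rnorm(n_tables, 0, 0.3)),
                                alpha_s = exp(rnorm(n_tables, 0, 0.3)),
                                eta_input = exp(rnorm(n_tables, 0, 0.3)),
                                eta_bound = 1),
    flank_overlap = f_s, var_len = var_len)
}

random_count_tables <- function(n_tables, n_seqs, L = 11, max_count = 10) {
  lapply(seq_len(n_tables), function(ci) {
    seqs <- random_peptides(n_seqs, L)
    pepbound:::new_count_table(
      seqs,
      sample.int(max_count, n_seqs, replace = TRUE),
      sample.int(max_count, n_seqs, replace = TRUE) - 1L,
      round_label = paste0("R", ci))
  })
}
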