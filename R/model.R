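#' Construct an energy matrix
#'
#' An energy matrix holds per-residue, per-position additive coefficients on
#' the log-affinity scale; for the specific binding mode these are the
#' negative binding free-energy contributions (-ddG/RT).
#'
#' @param width Number of positions.
#' @param coeffs Optional 20 x `width` numeric matrix (rows in the canonical
#'   alphabetical residue order `ACDEFGHIKLMNPQRSTVWY`); zeros by default.
#' @return A 20 x `width` matrix with residue row names.
#' @export
energy_matrix <- function(width, coeffs = NULL) {
  width <- as.integer(width)
  if (is.null(coeffs)) coeffs <- matrix(0, 20L, width)
  coeffs <- as.matrix(coeffs)
  if (nrow(coeffs) != 20L || ncol(coeffs) != width)
    abort("coeffs must be a 20 x width matrix")
  if (is.null(rownames(coeffs))) rownames(coeffs) <- PB_ALPHABET
  if (!identical(rownames(coeffs), PB_ALPHABET))
    coeffs <- coeffs[PB_ALPHABET, , drop = FALSE]
  coeffs
}

#' Freeze the central column of an energy matrix to recognise one residue
#'
#' Sets the centre column to 0 for `residue` and -10 for every other residue,
#' and marks it frozen (excluded from optimisation, penalties and reporting
#' gauge). Used to focus the specific mode on phosphotyrosine recognition.
#'
#' @param matrix An [energy_matrix()] with odd width.
#' @param residue Residue recognised at the centre (default `"Y"`).
#' @return The constrained matrix, with attribute `frozen_col`.
#' @export
apply_central_constraint <- function(matrix, residue = "Y") {
  w <- ncol(matrix)
  if (w %% 2L == 0L) abort("matrix width must be odd to have a central column")
  centre <- (w + 1L) %/% 2L
  matrix[, centre] <- -10
  matrix[residue, centre] <- 0
  attr(matrix, "frozen_col") <- centre
  matrix
}

#' Energy of a single window under an energy matrix
#'
#' The dot product of the window's one-hot encoding with the coefficient
#' matrix: the sum over positions of the coefficient of the residue observed
#' there.
#'
#' @param matrix An [energy_matrix()].
#' @param window Peptide string of length `ncol(matrix)`.
#' @return A scalar energy (log-affinity units).
#' @export
window_energy <- function(matrix, window) {
  if (nchar(window) != ncol(matrix)) abort("window length must equal matrix width")
  idx <- pb_encode(window)
  sum(matrix[cbind(as.integer(idx), seq_len(ncol(matrix)))])
}

#' Construct a two-mode binding model
#'
#' The model predicts the enrichment of a peptide in a bound library as
#' `kappa = alpha_NS * A_NS(s) + alpha_S * A_S(s)`: a non-specific mode
#' scanning short windows of the variable region (with positional bias
#' `gamma`), plus a sequence-specific mode scanning full-width windows of the
#' peptide padded with up to `flank_overlap` residues of the constant
#' displayed flanks. Per-table activities (`alpha`) and sequencing-depth
#' parameters (`eta`) scale the modes within the binomial likelihood.
#'
#' @param beta_s Specific-mode [energy_matrix()] (entries are -ddG/RT).
#' @param beta_ns Non-specific-mode energy matrix; default zero 20 x 3.
#' @param gamma Positional bias of the non-specific mode, one value per
#'   offset (`var_len - ncol(beta_ns) + 1`); default zeros.
#' @param activities Tibble with one row per count table: columns `round`,
#'   `alpha_ns`, `alpha_s`, `eta_input`, `eta_bound` (all positive).
#' @param flank_left,flank_right Constant displayed flanks.
#' @param flank_overlap Number of flank residues the specific mode may
#'   overlap on each side.
#' @param var_len Variable-region length the model scores.
#' @param constrained Whether the central specific column is frozen (see
#'   [apply_central_constraint()]).
#' @param center_residue Residue recognised by the frozen centre.
#' @return An object of class `binding_model`.
#' @export
binding_model <- function(beta_s,
                          beta_ns = energy_matrix(3L),
                          gamma = NULL,
                          activities = NULL,
                          flank_left = "GQSGQ",
                          flank_right = "GGQSG",
                          flank_overlap = 5L,
                          var_len = ncol(beta_s),
                          constrained = FALSE,
                          center_residue = "Y") {
  beta_s <- energy_matrix(ncol(beta_s), beta_s)
  beta_ns <- energy_matrix(ncol(beta_ns), beta_ns)
  var_len <- as.integer(var_len)
  flank_overlap <- as.integer(flank_overlap)
  if (flank_overlap > nchar(flank_left) || flank_overlap > nchar(flank_right))
    abort("flank_overlap exceeds flank length")
  n_off_ns <- var_len - ncol(beta_ns) + 1L
  if (n_off_ns < 1L) abort("non-specific window wider than the variable region")
  if (is.null(gamma)) gamma <- numeric(n_off_ns)
  if (length(gamma) != n_off_ns)
    abort("gamma must have one entry per non-specific offset")
  if (var_len + 2L * flank_overlap - ncol(beta_s) + 1L < 1L)
    abort("specific window wider than the padded sequence")
  if (is.null(activities))
    activities <- tibble(round = "R1", alpha_ns = 1, alpha_s = 1,
                         eta_input = 1, eta_bound = 1)
  pb_check_activities(activities)
  structure(
    list(beta_s = beta_s, beta_ns = beta_ns, gamma = gamma,
         activities = activities,
         flank_left = flank_left, flank_right = flank_right,
         flank_overlap = flank_overlap, var_len = var_len,
         constrained = isTRUE(constrained), center_residue = center_residue,
         fit = NULL),
    class = "binding_model")
}

pb_check_activities <- function(activities) {
  need <- c("round", "alpha_ns", "alpha_s", "eta_input", "eta_bound")
  if (!all(need %in% names(activities)))
    abort("activities must have columns round, alpha_ns, alpha_s, eta_input, eta_bound")
  vals <- unlist(activities[c("alpha_ns", "alpha_s", "eta_input", "eta_bound")])
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("activities and depth parameters must be strictly positive")
  invisible(activities)
}

pb_center_col <- function(model) (ncol(model$beta_s) + 1L) %/% 2L

# Integer-encode peptides padded with the flank overlap used by the specific mode.
pb_codes_specific <- function(model, peptides) {
  f <- model$flank_overlap
  if (f > 0L) {
    lf <- substr(model$flank_left, nchar(model$flank_left) - f + 1L,
                 nchar(model$flank_left))
    rf <- substr(model$flank_right, 1L, f)
    peptides <- paste0(lf, peptides, rf)
  }
  pb_encode(peptides)
}

pb_log_specific <- function(model, peptides, codes = NULL) {
  if (is.null(codes)) codes <- pb_codes_specific(model, peptides)
  noff <- ncol(codes) - ncol(model$beta_s) + 1L
  pb_mode_logaff(codes, model$beta_s, numeric(noff))
}

pb_log_nonspecific <- function(model, peptides, codes = NULL) {
  if (is.null(codes)) codes <- pb_encode(peptides)
  pb_mode_logaff(codes, model$beta_ns, model$gamma)
}

pb_check_peptides <- function(model, peptides) {
  if (any(nchar(peptides) != model$var_len))
    abort("peptide length must equal the model's variable-region length")
  invisible(peptides)
}

#' Mode affinities and predicted enrichment of peptides
#'
#' `specific_affinity()` sums `exp(window energy)` over all specific-mode
#' offsets of the flank-padded peptide; `nonspecific_affinity()` does the
#' same over variable-region windows of the non-specific mode including its
#' positional bias; `predicted_enrichment()` combines both modes with the
#' activities of one count table:
#' `kappa = alpha_NS * A_NS + alpha_S * A_S`.
#'
#' @param model A [binding_model()].
#' @param peptides Character vector of peptides of length `model$var_len`.
#' @param table_index Which activities row to use.
#' @return Numeric vector of strictly positive affinities.
#' @export
specific_affinity <- function(model, peptides) {
  pb_check_peptides(model, peptides)
  codes <- pb_codes_specific(model, peptides)
  noff <- ncol(codes) - ncol(model$beta_s) + 1L
  pb_mode_aff(codes, model$beta_s, numeric(noff))
}

#' @rdname specific_affinity
#' @export
nonspecific_affinity <- function(model, peptides) {
  pb_check_peptides(model, peptides)
  pb_mode_aff(pb_encode(peptides), model$beta_ns, model$gamma)
}

#' @rdname specific_affinity
#' @export
predicted_enrichment <- function(model, peptides, table_index = 1L) {
  act <- model$activities[table_index, ]
  pb_check_activities(act)
  act$alpha_ns * nonspecific_affinity(model, peptides) +
    act$alpha_s * specific_affinity(model, peptides)
}

#' Scaled binomial log-likelihood of count tables under a model
#'
#' Each table is treated as a single-round selection: every read of sequence
#' `s_i` falls in the bound column with probability
#' `eta_B * kappa(s_i) / (eta_I + eta_B * kappa(s_i))`. The per-table
#' binomial log-likelihood is scaled by the table's total read count and
#' summed across tables. Computation is carried out in log space so large
#' energies cannot overflow.
#'
#' @param model A [binding_model()] with one activities row per table.
#' @param tables List of `pb_count_table` (or a single table).
#' @return A scalar, always `<= 0`.
#' @export
data_log_likelihood <- function(model, tables) {
  if (inherits(tables, "pb_count_table")) tables <- list(tables)
  if (nrow(model$activities) != length(tables))
    abort("model must carry one activities row per count table")
  ll <- 0
  for (ci in seq_along(tables)) {
    tab <- tables[[ci]]
    k_c <- total_reads(tab)
    if (k_c == 0L) abort("count table with zero total reads")
    pb_check_peptides(model, tab$sequence)
    act <- model$activities[ci, ]
    logk <- pb_lse2(log(act$alpha_ns) + pb_log_nonspecific(model, tab$sequence),
                    log(act$alpha_s) + pb_log_specific(model, tab$sequence))
    t <- log(act$eta_bound) + logk - log(act$eta_input)
    sp <- pb_softplus(t)
    ll <- ll + sum(tab$input * (-sp) + tab$bound * (t - sp)) / k_c
  }
  ll
}

#' Regularization settings for model fitting
#'
#' @param l2_weight Weight of the L2 penalty on free energy coefficients and
#'   positional bias.
#' @param barrier_bound Location of the exponential barrier keeping
#'   coefficients in a bounded range.
#' @param dirichlet_count Pseudo-count of the Dirichlet penalty on the
#'   per-table activity fractions.
#' @return A `reg_config` list.
#' @export
reg_config <- function(l2_weight = 1e-6, barrier_bound = 20, dirichlet_count = 5) {
  stopifnot(is.finite(l2_weight), l2_weight >= 0,
            is.finite(barrier_bound), barrier_bound > 0,
            is.finite(dirichlet_count), dirichlet_count >= 0)
  structure(list(l2_weight = l2_weight, barrier_bound = barrier_bound,
                 dirichlet_count = dirichlet_count), class = "reg_config")
}

# Free coefficient vector penalized by L2/barrier: non-frozen beta_s entries,
# all beta_ns entries, gamma.
pb_free_coeffs <- function(model) {
  bs <- model$beta_s
  if (model$constrained) bs <- bs[, -pb_center_col(model), drop = FALSE]
  c(as.numeric(bs), as.numeric(model$beta_ns), model$gamma)
}

#' Regularization penalty of a model
#'
#' The sum of an L2 term, an exponential barrier term over the free
#' coefficients (frozen constrained columns excluded), and a Dirichlet
#' penalty on each table's activity fractions:
#' `-count * sum_m log(alpha_m / sum alpha)`.
#'
#' @param model A [binding_model()].
#' @param config A [reg_config()].
#' @return A non-negative scalar.
#' @export
regularization_penalty <- function(model, config = reg_config()) {
  th <- pb_free_coeffs(model)
  pen <- config$l2_weight * sum(th^2) +
    sum(exp(th - config$barrier_bound) + exp(-th - config$barrier_bound))
  a <- model$activities
  frac_ns <- a$alpha_ns / (a$alpha_ns + a$alpha_s)
  pen - config$dirichlet_count * sum(log(frac_ns) + log1p(-frac_ns))
}

#' @export
print.binding_model <- function(x, ...) {
  cat("<binding_model> specific mode 20 x ", ncol(x$beta_s),
      if (x$constrained) paste0(" (centre frozen to ", x$center_residue, ")"),
      "; non-specific mode 20 x ", ncol(x$beta_ns),
      "; ", nrow(x$activities), " count table(s)\n", sep = "")
  if (!is.null(x$fit))
    cat("  fitted: loss ", format(x$fit$loss, digits = 8),
        ", convergence ", x$fit$convergence, "\n", sep = "")
  invisible(x)
}
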