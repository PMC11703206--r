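# Synthetic multi-round selection experiments with known ground truth.

# Residue sampling frequencies implied by an NNS degenerate codon (third base
# C or G), from the standard genetic code.
pb_nns_freqs <- function() {
  gc <- Biostrings::GENETIC_CODE
  nns <- gc[substr(names(gc), 3L, 3L) %in% c("C", "G")]
  nns <- nns[nns != "*"]
  tab <- table(factor(nns, levels = PB_ALPHABET))
  as.numeric(tab) / sum(tab)
}

#' Draw a random peptide library
#'
#' Samples `n_unique` distinct peptides from a library design's sequence
#' space, respecting fixed positions.
#'
#' @param design A [library_design()].
#' @param n_unique Number of distinct peptides.
#' @param seed Integer seed.
#' @param residue_freqs `"uniform"` over the 20 residues or `"nns"`
#'   (degenerate-codon-weighted).
#' @return Character vector of `n_unique` distinct peptides.
#' @export
draw_library <- function(design, n_unique, seed = 1L,
                         residue_freqs = c("uniform", "nns")) {
  stopifnot(n_unique >= 1L)
  residue_freqs <- match.arg(residue_freqs)
  prob <- if (residue_freqs == "nns") pb_nns_freqs() else NULL
  withr::with_seed(as.integer(seed), {
    out <- character(0)
    while (length(out) < n_unique) {
      n_draw <- max(1000L, ceiling(1.2 * (n_unique - length(out))))
      m <- matrix(sample(PB_ALPHABET, n_draw * design$var_len_aa,
                         replace = TRUE, prob = prob),
                  n_draw, design$var_len_aa)
      fp <- design$fixed_positions
      if (!is.null(fp))
        for (j in seq_along(fp)) m[, as.integer(names(fp)[j])] <- fp[[j]]
      out <- unique(c(out, apply(m, 1L, paste, collapse = "")))
    }
    out[seq_len(n_unique)]
  })
}

#' Draw a random ground-truth binding model
#'
#' Non-central specific coefficients are drawn i.i.d. normal (the frozen
#' centre recognises `center_residue` when the design fixes one); the
#' non-specific mode is flat. Activities are placeholders until calibrated by
#' [simulate_experiment()].
#'
#' @param design A [library_design()].
#' @param effect_sd Standard deviation of the true -ddG/RT coefficients.
#' @param w_s,w_ns Mode widths.
#' @param f_s Flank overlap.
#' @param constrain_center Freeze the central column (default: whether the
#'   design fixes a central residue, else TRUE).
#' @param seed Integer seed.
#' @return A [binding_model()].
#' @export
random_binding_model <- function(design = x5yx5_design(), effect_sd = 1,
                                 w_s = 11L, w_ns = 3L, f_s = 5L,
                                 constrain_center = TRUE, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    beta <- energy_matrix(w_s, matrix(rnorm(20L * w_s, 0, effect_sd), 20L, w_s))
    if (constrain_center) beta <- apply_central_constraint(beta, "Y")
    binding_model(beta, energy_matrix(w_ns),
                  flank_left = design$left_flank_aa,
                  flank_right = design$right_flank_aa,
                  flank_overlap = f_s, var_len = design$var_len_aa,
                  constrained = constrain_center, center_residue = "Y")
  })
}

# Per-sequence enrichment with optional suppression of the specific term for
# phosphorylation-incompetent members.
pb_kappa <- function(model, peptides, competent = NULL, table_index = 1L) {
  act <- model$activities[min(table_index, nrow(model$activities)), ]
  s <- exp(pb_log_specific(model, peptides))
  if (!is.null(competent)) s <- s * competent
  act$alpha_ns * exp(pb_log_nonspecific(model, peptides)) + act$alpha_s * s
}

#' Simulate one round of affinity selection
#'
#' Selection is linear (non-saturating), matching the likelihood's generative
#' assumption: bound pool frequencies are proportional to
#' `pool frequency x kappa`. The input and bound sequencing columns are
#' independent multinomial draws of `reads_per_column` reads from the
#' respective pools, and the next round's pool equals the bound frequencies
#' (noiseless re-amplification).
#'
#' @param pool Tibble with columns `sequence` and `freq` (summing to 1).
#' @param model A [binding_model()] (true model).
#' @param reads_per_column Sequencing depth of each column.
#' @param round_label Label for the emitted count table.
#' @param competent Optional 0/1 vector suppressing the specific term of
#'   phosphorylation-incompetent members.
#' @param table_index Activities row of `model` to use.
#' @param seed Optional integer seed.
#' @return List with `table` (a `pb_count_table`) and `next_pool`.
#' @export
run_selection_round <- function(pool, model, reads_per_column,
                                round_label = "R1", competent = NULL,
                                table_index = 1L, seed = NULL) {
  if (!nrow(pool)) abort("empty pool")
  stopifnot(abs(sum(pool$freq) - 1) < 1e-8)
  kappa <- pb_kappa(model, pool$sequence, competent, table_index)
  bound_freq <- pool$freq * kappa
  bound_freq <- bound_freq / sum(bound_freq)
  draw <- function() {
    input_counts <- as.integer(rmultinom(1L, reads_per_column, pool$freq))
    bound_counts <- as.integer(rmultinom(1L, reads_per_column, bound_freq))
    new_count_table(pool$sequence, input_counts, bound_counts,
                    round_label = round_label)
  }
  tab <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  list(table = tab,
       next_pool = tibble(sequence = pool$sequence, freq = bound_freq),
       kappa = kappa)
}

#' Simulate a multi-round selection experiment with known truth
#'
#' Draws a library, calibrates the true model's activities so that the
#' requested fraction of the initial selected mass is non-specific, flags a
#' fraction of tyrosine-containing members as phosphorylation-incompetent
#' (their specific term is suppressed), and chains
#' [run_selection_round()] for the requested number of rounds.
#'
#' @param design A [library_design()].
#' @param n_unique Number of distinct library members.
#' @param rounds Number of selection rounds.
#' @param reads_per_column Sequencing depth per column per round.
#' @param true_model Optional [binding_model()]; a random one is drawn when
#'   `NULL`.
#' @param effect_sd Passed to [random_binding_model()] when drawing a truth.
#' @param nonspecific_fraction Fraction of the initially selected mass
#'   attributed to the non-specific mode (in `[0, 1)`).
#' @param phospho_efficiency Fraction of tyrosine-containing members
#'   competent for specific binding (in `(0, 1]`).
#' @param residue_freqs Library residue frequencies (see [draw_library()]).
#' @param seed Integer seed governing all randomness.
#' @return A `pb_simulation`: list with `tables` (list of `pb_count_table`),
#'   and `truth` (true model with calibrated activities, library, competence
#'   flags, per-round pool frequencies, per-sequence `kappa`).
#' @export
simulate_experiment <- function(design = x5yx5_design(), n_unique = 50000L,
                                rounds = 3L, reads_per_column = 200000L,
                                true_model = NULL, effect_sd = 1,
                                nonspecific_fraction = 0.2,
                                phospho_efficiency = 1,
                                residue_freqs = "uniform", seed = 1L) {
  stopifnot(n_unique >= 1L, rounds >= 1L, reads_per_column >= 1L,
            nonspecific_fraction >= 0, nonspecific_fraction < 1,
            phospho_efficiency > 0, phospho_efficiency <= 1)
  seed <- as.integer(seed)
  lib <- draw_library(design, n_unique, seed = seed, residue_freqs = residue_freqs)
  if (is.null(true_model))
    true_model <- random_binding_model(design, effect_sd = effect_sd,
                                       seed = seed + 1L)
  competent <- withr::with_seed(seed + 2L, {
    has_y <- stringr::str_detect(lib, stringr::fixed("Y"))
    as.numeric(!has_y | runif(n_unique) < phospho_efficiency)
  })
  # Calibrate activities: alpha_S = 1; alpha_NS set so the non-specific mode
  # carries `nonspecific_fraction` of the initially selected mass.
  s_mass <- mean(exp(pb_log_specific(true_model, lib)) * competent)
  ns_mass <- mean(exp(pb_log_nonspecific(true_model, lib)))
  f <- max(nonspecific_fraction, 1e-12)
  alpha_ns <- f / (1 - f) * s_mass / ns_mass
  true_model$activities <- tibble(
    round = paste0("R", seq_len(rounds)),
    alpha_ns = alpha_ns, alpha_s = 1, eta_input = 1, eta_bound = 1)
  pool <- tibble(sequence = lib, freq = rep(1 / n_unique, n_unique))
  tables <- vector("list", rounds)
  pools <- vector("list", rounds)
  kappa <- NULL
  for (r in seq_len(rounds)) {
    pools[[r]] <- pool
    res <- run_selection_round(pool, true_model, reads_per_column,
                               round_label = paste0("R", r),
                               competent = competent, table_index = r,
                               seed = seed + 10L + r)
    tables[[r]] <- res$table
    pool <- res$next_pool
    if (r == 1L) kappa <- res$kappa
  }
  structure(list(tables = tables,
                 truth = list(model = true_model, library = lib,
                              competent = competent, pools = pools,
                              kappa = kappa,
                              nonspecific_fraction = nonspecific_fraction,
                              phospho_efficiency = phospho_efficiency,
                              seed = seed)),
            class = "pb_simulation")
}

#' @export
print.pb_simulation <- function(x, ...) {
  cat("<pb_simulation> ", length(x$tables), " round(s), ",
      length(x$truth$library), " library members, seed ", x$truth$seed,
      "\n", sep = "")
  invisible(x)
}
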