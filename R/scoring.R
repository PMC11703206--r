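#' Extract the binding free-energy matrix of a fitted model
#'
#' Returns the specific-mode coefficients as ddG/RT (the negated specific
#' energy matrix), with every non-frozen column mean-centred (the reporting
#' gauge: adding a constant to a full column is absorbed by the specific
#' activity and does not change any prediction). A frozen constrained column
#' is reported as-is and flagged.
#'
#' @param model A [binding_model()].
#' @return A `ddg_matrix`: list with `values` (20 x width matrix, positions
#'   labelled relative to the centre for odd widths) and `frozen_col`
#'   (`NA` when unconstrained).
#' @export
ddg_matrix <- function(model) {
  v <- -model$beta_s
  w <- ncol(v)
  frozen <- if (model$constrained) pb_center_col(model) else NA_integer_
  for (j in seq_len(w))
    if (is.na(frozen) || j != frozen) v[, j] <- v[, j] - mean(v[, j])
  colnames(v) <- if (w %% 2L == 1L)
    sprintf("%+d", seq_len(w) - (w + 1L) %/% 2L) else as.character(seq_len(w))
  structure(list(values = v, frozen_col = frozen), class = "ddg_matrix")
}

#' @export
print.ddg_matrix <- function(x, ...) {
  cat("<ddg_matrix> 20 x ", ncol(x$values),
      if (!is.na(x$frozen_col)) paste0(" (column ", colnames(x$values)[x$frozen_col],
                                       " frozen)"), "\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' @export
as_tibble.ddg_matrix <- function(x, ...) {
  w <- ncol(x$values)
  tibble(residue = rep(rownames(x$values), w),
         position = rep(colnames(x$values), each = 20L),
         ddg = as.numeric(x$values),
         frozen = rep(seq_len(w) == (x$frozen_col %||% 0L), each = 20L))
}

#' @export
tidy.ddg_matrix <- function(x, ...) as_tibble(x)

#' @export
autoplot.ddg_matrix <- function(object, ...) {
  d <- as_tibble(object)
  d$position <- factor(d$position, levels = colnames(object$values))
  d$residue <- factor(d$residue, levels = rev(PB_ALPHABET))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$residue,
                                  fill = .data$ddg)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = "position relative to centre", y = NULL,
                  fill = "ddG/RT") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.binding_model <- function(object, ...) autoplot(ddg_matrix(object), ...)

#' Write a ddG matrix as position-by-residue TSV
#'
#' A plain text export (positions as rows, residues as columns) compatible
#' with sequence-logo tools.
#'
#' @param ddg A [ddg_matrix()].
#' @param path File path.
#' @export
write_ddg_tsv <- function(ddg, path) {
  d <- as.data.frame(t(ddg$values))
  d <- cbind(position = rownames(d), d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Amino-acid log-enrichment matrix (PSSM baseline)
#'
#' For each residue and position, the natural log of the pseudocount-adjusted
#' residue frequency in the bound library over the same frequency in the
#' input library. This is the position-specific scoring approach the
#' free-energy regression improves upon: it pre-defines the register and does
#' not control for non-specific binding or secondary binding offsets.
#'
#' @param input_table `pb_count_table` supplying the input-column counts.
#' @param bound_table `pb_count_table` supplying the bound-column counts
#'   (defaults to the same table).
#' @param pseudocount Added to every residue-position count cell before
#'   normalisation; must be positive if a residue seen in the bound library
#'   can be absent from the input library.
#' @return A 20 x L matrix (residues by positions). Cells unobserved in both
#'   libraries (possible only at `pseudocount = 0`) are `NA`.
#' @export
enrichment_matrix <- function(input_table, bound_table = input_table, pseudocount = 0.5) {
  L <- nchar(input_table$sequence[1L])
  if (nchar(bound_table$sequence[1L]) != L) abort("tables must share sequence length")
  counts <- function(tab, col) {
    codes <- pb_encode(tab$sequence)
    wts <- as.numeric(tab[[col]])
    cnt <- matrix(pseudocount, 20L, L, dimnames = list(PB_ALPHABET, NULL))
    for (p in seq_len(L)) {
      s <- rowsum(wts, codes[, p])
      cnt[as.integer(rownames(s)), p] <- cnt[as.integer(rownames(s)), p] + s[, 1L]
    }
    cnt
  }
  ci <- counts(input_table, "input")
  cb <- counts(bound_table, "bound")
  if (any(ci == 0 & cb > 0))
    abort("zero input frequency for an enriched cell; use a positive pseudocount")
  fi <- sweep(ci, 2L, colSums(ci), "/")
  fb <- sweep(cb, 2L, colSums(cb), "/")
  out <- log(fb) - log(fi)
  out[ci == 0 & cb == 0] <- NA_real_
  out
}

#' Score peptides with a fitted model
#'
#' `mode = "total"` returns the log of the total specific affinity, summed
#' over all binding offsets including flank overlap (this controls for
#' non-central tyrosines and secondary sites); `mode = "central"` returns the
#' energy of the centrally aligned window only.
#'
#' @param model A [binding_model()].
#' @param peptides Character vector, each of length `model$var_len`.
#' @param mode `"total"` or `"central"`.
#' @return Numeric vector of log relative affinities.
#' @export
score_peptide <- function(model, peptides, mode = c("total", "central")) {
  mode <- match.arg(mode)
  pb_check_peptides(model, peptides)
  if (mode == "total") return(pb_log_specific(model, peptides))
  if (model$var_len != ncol(model$beta_s))
    abort("central mode requires the peptide length to equal the matrix width")
  codes <- pb_encode(peptides)
  vapply(seq_len(nrow(codes)), function(i)
    sum(model$beta_s[cbind(codes[i, ], seq_len(ncol(codes)))]), numeric(1))
}

#' Scan a table of phosphosites with a fitted model
#'
#' Scores each site's peptide window and returns them sorted by predicted log
#' affinity (descending), ties broken by `site_id`. `keep_ids` acts as a
#' pre-computed co-expression (or any other) filter.
#'
#' @param model A [binding_model()].
#' @param sites Data frame with columns `site_id` and `peptide`.
#' @param keep_ids Optional character vector; only these sites are scored.
#' @param mode Scoring mode, see [score_peptide()].
#' @return Tibble `site_id`, `peptide`, `log_affinity`, sorted.
#' @export
scan_sites <- function(model, sites, keep_ids = NULL, mode = "total") {
  sites <- as_tibble(sites)
  if (!all(c("site_id", "peptide") %in% names(sites)))
    abort("sites must have columns site_id and peptide")
  if (!is.null(keep_ids)) sites <- filter(sites, .data$site_id %in% keep_ids)
  if (!nrow(sites))
    return(tibble(site_id = character(), peptide = character(),
                  log_affinity = numeric()))
  sites$log_affinity <- score_peptide(model, sites$peptide, mode = mode)
  arrange(sites[c("site_id", "peptide", "log_affinity")],
          desc(.data$log_affinity), .data$site_id)
}

#' Predicted effect of a missense variant on binding
#'
#' Scores the wild-type and variant peptide windows and reports the log
#' affinity ratio (variant minus wild type), the larger of the two log
#' affinities, and a direction call (`gain` / `loss` / `neutral` within
#' `neutral_band`). Variants substituting the constrained central residue
#' itself are rejected: the model cannot meaningfully compare a
#' phosphorylatable centre with a non-phosphorylatable one.
#'
#' @param model A [binding_model()].
#' @param site_id Identifier carried through to the output.
#' @param wt_peptide,var_peptide Equal-length peptides differing at >= 1
#'   position.
#' @param mode Scoring mode, see [score_peptide()].
#' @param neutral_band Absolute log-ratio below which the call is `neutral`.
#' @return One-row tibble: `site_id`, `wt_peptide`, `var_peptide`,
#'   `log_ratio`, `max_log_affinity`, `direction`.
#' @export
variant_effect <- function(model, site_id, wt_peptide, var_peptide,
                           mode = "total", neutral_band = 0.1) {
  if (nchar(wt_peptide) != nchar(var_peptide))
    abort("wild-type and variant peptides must have equal length")
  diffs <- which(strsplit(wt_peptide, "")[[1]] != strsplit(var_peptide, "")[[1]])
  if (!length(diffs)) abort("variant peptide is identical to wild type")
  if (model$constrained && pb_center_col(model) %in% diffs)
    abort("substitution of the central residue itself is not scoreable")
  s <- score_peptide(model, c(wt_peptide, var_peptide), mode = mode)
  log_ratio <- s[2L] - s[1L]
  tibble(site_id = site_id, wt_peptide = wt_peptide, var_peptide = var_peptide,
         log_ratio = log_ratio, max_log_affinity = max(s),
         direction = if (log_ratio > neutral_band) "gain"
                     else if (log_ratio < -neutral_band) "loss" else "neutral")
}

#' @rdname variant_effect
#' @param variants Data frame with columns `site_id`, `wt_peptide`,
#'   `var_peptide`.
#' @export
variant_effects <- function(model, variants, mode = "total", neutral_band = 0.1) {
  variants <- as_tibble(variants)
  bind_rows(purrr::pmap(variants[c("site_id", "wt_peptide", "var_peptide")],
                        variant_effect, model = model, mode = mode,
                        neutral_band = neutral_band))
}

#' Compare two free-energy matrices
#'
#' Squared Pearson correlation over all residue-position coefficient pairs,
#' excluding frozen central columns when `exclude_center`.
#'
#' @param a,b `ddg_matrix` objects of the same shape.
#' @param exclude_center Drop columns frozen in either matrix.
#' @return List with `r2` and `data` (tibble of paired values).
#' @export
compare_models <- function(a, b, exclude_center = TRUE) {
  if (!identical(dim(a$values), dim(b$values))) abort("matrices differ in shape")
  cols <- seq_len(ncol(a$values))
  if (exclude_center)
    cols <- setdiff(cols, c(a$frozen_col, b$frozen_col))
  va <- as.numeric(a$values[, cols])
  vb <- as.numeric(b$values[, cols])
  d <- tibble(residue = rep(rownames(a$values), length(cols)),
              position = rep(colnames(a$values)[cols], each = 20L),
              a = va, b = vb)
  list(r2 = cor(va, vb)^2, data = d)
}

#' Regress measured dissociation constants on model predictions
#'
#' Ordinary least squares of `ln(K_D)` on the predicted relative log
#' affinities (ddG/RT scale), the standard validation of a fitted model
#' against low-throughput binding measurements.
#'
#' @param predicted Numeric predictions (non-constant, length >= 3).
#' @param measured_kd Positive measured dissociation constants.
#' @return A `kd_fit` list: `slope`, `intercept`, `r2`, `n`, and the
#'   underlying `lm` fit.
#' @export
fit_kd_regression <- function(predicted, measured_kd) {
  stopifnot(length(predicted) == length(measured_kd), length(predicted) >= 3L)
  if (any(measured_kd <= 0)) abort("measured K_D must be positive")
  if (sd(predicted) == 0) abort("degenerate regressor: constant predictions")
  fit <- lm(log(measured_kd) ~ predicted)
  y <- log(measured_kd)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r2 = r2,
                 n = length(predicted), lm = fit),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("<kd_fit> ln(K_D) = ", format(x$slope, digits = 4), " * predicted + ",
      format(x$intercept, digits = 4), "  (r2 = ", format(x$r2, digits = 4),
      ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.kd_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2, n = x$n)
}

#' Cluster free-energy matrices
#'
#' Average-linkage hierarchical clustering of models under the distance
#' `1 - Pearson r` over flattened non-central coefficients; models of the
#' same domain fitted from different library designs should cluster together.
#'
#' @param models List of `ddg_matrix` objects of identical shape (>= 2).
#' @param labels Optional labels (defaults to list names).
#' @return An [stats::hclust] object.
#' @export
cluster_models <- function(models, labels = names(models)) {
  stopifnot(length(models) >= 2L)
  flat <- vapply(models, function(m) {
    cols <- setdiff(seq_len(ncol(m$values)), m$frozen_col)
    as.numeric(m$values[, cols])
  }, numeric(length(models[[1L]]$values) -
             20L * !is.na(models[[1L]]$frozen_col)))
  d <- as.dist(1 - cor(flat))
  hc <- hclust(d, method = "average")
  hc$labels <- labels %||% paste0("model", seq_along(models))
  hc
}
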