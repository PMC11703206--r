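#' Serialize a binding model to JSON
#'
#' Writes the full model (both energy matrices with an explicit residue-order
#' header, positional bias, flanks, constraint status, and per-table
#' activities keyed by round label) as plain JSON.
#'
#' @param model A [binding_model()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    format = "pepbound-model",
    version = 1L,
    alphabet = paste(PB_ALPHABET, collapse = ""),
    var_len = model$var_len,
    flank_left = model$flank_left,
    flank_right = model$flank_right,
    flank_overlap = model$flank_overlap,
    constrained = model$constrained,
    center_residue = model$center_residue,
    beta_s = unname(apply(model$beta_s, 1L, identity, simplify = FALSE)),
    beta_ns = unname(apply(model$beta_ns, 1L, identity, simplify = FALSE)),
    gamma = model$gamma,
    activities = model$activities)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$alphabet, paste(PB_ALPHABET, collapse = "")))
    abort("model file uses an unexpected residue order")
  beta_s <- matrix(as.numeric(t(obj$beta_s)), nrow = 20L, byrow = TRUE,
                   dimnames = list(PB_ALPHABET, NULL))
  beta_ns <- matrix(as.numeric(t(obj$beta_ns)), nrow = 20L, byrow = TRUE,
                    dimnames = list(PB_ALPHABET, NULL))
  m <- binding_model(beta_s = beta_s, beta_ns = beta_ns, gamma = obj$gamma,
                     activities = as_tibble(obj$activities),
                     flank_left = obj$flank_left, flank_right = obj$flank_right,
                     flank_overlap = obj$flank_overlap, var_len = obj$var_len,
                     constrained = obj$constrained,
                     center_residue = obj$center_residue)
  m
}
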