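# Joint maximum-likelihood fitting of the two-mode binding model.
#
# Free parameters: non-frozen specific coefficients, all non-specific
# coefficients, the positional bias gamma, and per-table log(alpha_NS),
# log(alpha_S), log(eta_I) (eta_B is fixed to 1; it multiplies both
# activities and is not identifiable). The loss is -l_data + l_reg and is
# minimised with L-BFGS-B using analytic gradients.

# Precompute everything the objective needs: encoded sequences, counts, and
# the parameter packing layout.
pb_fit_context <- function(tables, w_s = 11L, w_ns = 3L, f_s = 5L,
                           flank_left = "GQSGQ", flank_right = "GGQSG",
                           constrain_center = TRUE, center_residue = "Y",
                           reg = reg_config()) {
  if (inherits(tables, "pb_count_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  L <- nchar(tables[[1L]]$sequence[1L])
  for (tab in tables)
    if (any(nchar(tab$sequence) != L)) abort("tables must share sequence length")
  proto <- binding_model(energy_matrix(w_s), energy_matrix(w_ns),
                         flank_left = flank_left, flank_right = flank_right,
                         flank_overlap = f_s, var_len = L,
                         constrained = constrain_center,
                         center_residue = center_residue)
  n_c <- length(tables)
  ctx <- list(
    tables = tables, n_c = n_c, L = L,
    w_s = as.integer(w_s), w_ns = as.integer(w_ns), f_s = as.integer(f_s),
    flank_left = flank_left, flank_right = flank_right,
    constrain = isTRUE(constrain_center), center_residue = center_residue,
    center_col = if (isTRUE(constrain_center)) (as.integer(w_s) + 1L) %/% 2L else NA_integer_,
    reg = reg,
    codes_s = lapply(tables, function(t) pb_codes_specific(proto, t$sequence)),
    codes_ns = lapply(tables, function(t) pb_encode(t$sequence)),
    k_input = lapply(tables, function(t) as.numeric(t$input)),
    k_bound = lapply(tables, function(t) as.numeric(t$bound)),
    k_c = vapply(tables, total_reads, numeric(1)),
    n_off_ns = L - as.integer(w_ns) + 1L)
  if (ctx$constrain && ctx$w_s %% 2L == 0L)
    abort("central constraint requires an odd specific width")
  ctx$n_bs_free <- 20L * (ctx$w_s - if (ctx$constrain) 1L else 0L)
  ctx$n_bns <- 20L * ctx$w_ns
  ctx$n_par <- ctx$n_bs_free + ctx$n_bns + ctx$n_off_ns + 3L * n_c
  ctx
}

pb_frozen_column <- function(center_residue) {
  col <- rep(-10, 20L)
  col[match(center_residue, PB_ALPHABET)] <- 0
  col
}

# par -> list(beta_s, beta_ns, gamma, la_ns, la_s, le_i)
pb_unpack <- function(par, ctx) {
  i <- 0L
  take <- function(k) {
    out <- par[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  free <- matrix(take(ctx$n_bs_free), 20L)
  if (ctx$constrain) {
    beta_s <- matrix(0, 20L, ctx$w_s)
    beta_s[, -ctx$center_col] <- free
    beta_s[, ctx$center_col] <- pb_frozen_column(ctx$center_residue)
  } else beta_s <- free
  rownames(beta_s) <- PB_ALPHABET
  beta_ns <- matrix(take(ctx$n_bns), 20L, dimnames = list(PB_ALPHABET, NULL))
  gamma <- take(ctx$n_off_ns)
  la_ns <- take(ctx$n_c)
  la_s <- take(ctx$n_c)
  le_i <- take(ctx$n_c)
  list(beta_s = beta_s, beta_ns = beta_ns, gamma = gamma,
       la_ns = la_ns, la_s = la_s, le_i = le_i)
}

# Loss and analytic gradient in one pass.
pb_eval <- function(par, ctx) {
  p <- pb_unpack(par, ctx)
  zero_gs <- numeric(ctx$L + 2L * ctx$f_s - ctx$w_s + 1L)
  g_bs <- matrix(0, 20L, ctx$w_s)
  g_bns <- matrix(0, 20L, ctx$w_ns)
  g_gamma <- numeric(ctx$n_off_ns)
  g_la_ns <- g_la_s <- g_le <- numeric(ctx$n_c)
  l_data <- 0
  for (ci in seq_len(ctx$n_c)) {
    logB <- pb_mode_logaff(ctx$codes_s[[ci]], p$beta_s, zero_gs)
    logA <- pb_mode_logaff(ctx$codes_ns[[ci]], p$beta_ns, p$gamma)
    l_ns <- p$la_ns[ci] + logA
    l_s <- p$la_s[ci] + logB
    logk <- pb_lse2(l_ns, l_s)
    t <- logk - p$le_i[ci]
    sp <- pb_softplus(t)
    kI <- ctx$k_input[[ci]]
    kB <- ctx$k_bound[[ci]]
    l_data <- l_data + sum(kI * (-sp) + kB * (t - sp)) / ctx$k_c[ci]
    sig <- exp(t - sp)
    u <- (kB - (kI + kB) * sig) / ctx$k_c[ci]    # d l_data / d log kappa_i
    r_s <- exp(l_s - logk)                       # specific share of kappa
    g_la_s[ci] <- sum(u * r_s)
    g_la_ns[ci] <- sum(u * (1 - r_s))
    g_le[ci] <- -sum(u)
    gs <- pb_mode_grad(ctx$codes_s[[ci]], p$beta_s, zero_gs, u, logk - p$la_s[ci])
    g_bs <- g_bs + gs$beta
    gn <- pb_mode_grad(ctx$codes_ns[[ci]], p$beta_ns, p$gamma, u, logk - p$la_ns[ci])
    g_bns <- g_bns + gn$beta
    g_gamma <- g_gamma + gn$gamma
  }
  if (ctx$constrain) g_bs <- g_bs[, -ctx$center_col, drop = FALSE]
  grad_data <- c(as.numeric(g_bs), as.numeric(g_bns), g_gamma,
                 g_la_ns, g_la_s, g_le)

  # Regularization and its gradient.
  reg <- ctx$reg
  n_coef <- ctx$n_bs_free + ctx$n_bns + ctx$n_off_ns
  th <- par[seq_len(n_coef)]
  pen <- reg$l2_weight * sum(th^2) +
    sum(exp(th - reg$barrier_bound) + exp(-th - reg$barrier_bound))
  g_reg <- numeric(ctx$n_par)
  g_reg[seq_len(n_coef)] <- 2 * reg$l2_weight * th +
    exp(th - reg$barrier_bound) - exp(-th - reg$barrier_bound)
  ia_ns <- n_coef + seq_len(ctx$n_c)
  ia_s <- ia_ns + ctx$n_c
  la_ns <- par[ia_ns]
  la_s <- par[ia_s]
  lse <- pb_lse2(la_ns, la_s)
  pen <- pen - reg$dirichlet_count * sum(la_ns + la_s - 2 * lse)
  f_ns <- exp(la_ns - lse)
  g_reg[ia_ns] <- -reg$dirichlet_count * (1 - 2 * f_ns)
  g_reg[ia_s] <- -reg$dirichlet_count * (1 - 2 * (1 - f_ns))

  list(loss = -l_data + pen, gradient = -grad_data + g_reg,
       l_data = l_data, l_reg = pen)
}

pb_init_par <- function(ctx, scale = 0.1) {
  th <- rnorm(ctx$n_bs_free + ctx$n_bns, 0, scale)
  par <- c(th, numeric(ctx$n_off_ns), numeric(2L * ctx$n_c), numeric(ctx$n_c))
  # eta_I from the observed input/bound read ratio at the initial parameters
  p <- pb_unpack(par, ctx)
  for (ci in seq_len(ctx$n_c)) {
    logk <- pb_lse2(p$la_ns[ci] + pb_mode_logaff(ctx$codes_ns[[ci]], p$beta_ns, p$gamma),
                    p$la_s[ci] + pb_mode_logaff(ctx$codes_s[[ci]], p$beta_s,
                                                numeric(ctx$L + 2L * ctx$f_s - ctx$w_s + 1L)))
    ratio <- sum(ctx$k_input[[ci]]) / max(sum(ctx$k_bound[[ci]]), 1)
    par[ctx$n_bs_free + ctx$n_bns + ctx$n_off_ns + 2L * ctx$n_c + ci] <-
      mean(logk) + log(ratio)
  }
  par
}

#' Fit a binding model to one or more count tables
#'
#' Jointly maximises the scaled binomial log-likelihood minus the
#' regularization penalty over all tables of a multi-round experiment, using
#' L-BFGS-B with analytic gradients. Positivity of activities and depth
#' parameters is enforced by optimising their logarithms; the best of
#' `n_starts` seeded restarts is returned. After fitting, each non-frozen
#' specific column is mean-centred and the aggregate shift absorbed into the
#' specific activities (a pure gauge transformation that leaves every
#' predicted enrichment unchanged).
#'
#' @param tables A `pb_count_table` or list of them (one per selection round).
#' @param design Optional [library_design()] supplying the flank sequences.
#' @param constrain_center Freeze the central specific column to recognise
#'   `center_residue` (0 for it, -10 otherwise).
#' @param center_residue Residue recognised by the frozen centre.
#' @param w_s,w_ns Widths of the specific and non-specific energy matrices.
#' @param f_s Flank overlap of the specific mode.
#' @param reg A [reg_config()].
#' @param n_starts Number of random restarts; the lowest-loss fit wins.
#' @param max_iter Maximum L-BFGS-B iterations per start.
#' @param tol Projected-gradient tolerance passed to the optimiser.
#' @param seed Integer seed controlling initialisation.
#' @param gauge_fix Mean-centre non-frozen specific columns after fitting.
#' @return A fitted [binding_model()]; the `fit` element records the loss,
#'   log-likelihood, penalty, convergence code, evaluation counts and
#'   per-start losses.
#' @export
fit_binding_model <- function(tables, design = NULL,
                              constrain_center = TRUE, center_residue = "Y",
                              w_s = 11L, w_ns = 3L, f_s = 5L,
                              reg = reg_config(), n_starts = 1L,
                              max_iter = 1000L, tol = 1e-7, seed = 1L,
                              gauge_fix = TRUE) {
  stopifnot(n_starts >= 1L, tol > 0)
  flank_left <- if (!is.null(design)) design$left_flank_aa else "GQSGQ"
  flank_right <- if (!is.null(design)) design$right_flank_aa else "GGQSG"
  ctx <- pb_fit_context(tables, w_s = w_s, w_ns = w_ns, f_s = f_s,
                        flank_left = flank_left, flank_right = flank_right,
                        constrain_center = constrain_center,
                        center_residue = center_residue, reg = reg)
  # fn/gr share one evaluation via a small memo
  memo <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(memo$par) && identical(par, memo$par)) return(memo$val)
    memo$par <- par
    memo$val <- pb_eval(par, ctx)
    memo$val
  }
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    res <- withr::with_seed(as.integer(seed) + s - 1L, {
      scale <- 0.1
      par0 <- pb_init_par(ctx, scale)
      for (try in 1:5) {
        if (is.finite(pb_eval(par0, ctx)$loss)) break
        scale <- scale / 10
        par0 <- pb_init_par(ctx, scale)
      }
      loss0 <- pb_eval(par0, ctx)$loss
      if (!is.finite(loss0)) abort("non-finite loss at initialization")
      opt <- optim(par0, fn = function(p) evaluate(p)$loss,
                   gr = function(p) evaluate(p)$gradient,
                   method = "L-BFGS-B",
                   control = list(maxit = max_iter, pgtol = tol, factr = 1e7))
      list(opt = opt, loss0 = loss0)
    })
    starts[[s]] <- res
  }
  losses <- vapply(starts, function(s) s$opt$value, numeric(1))
  if (all(!is.finite(losses))) abort("all optimisation starts failed")
  best <- starts[[which.min(losses)]]
  p <- pb_unpack(best$opt$par, ctx)
  la_s <- p$la_s
  beta_s <- p$beta_s
  if (gauge_fix) {
    cols <- seq_len(ctx$w_s)
    if (ctx$constrain) cols <- cols[-ctx$center_col]
    shift <- 0
    for (j in cols) {
      mu <- mean(beta_s[, j])
      beta_s[, j] <- beta_s[, j] - mu
      shift <- shift + mu
    }
    la_s <- la_s + shift
  }
  labels <- vapply(ctx$tables, function(t) attr(t, "round_label") %||% "R?",
                   character(1))
  model <- binding_model(
    beta_s = if (ctx$constrain) apply_central_constraint(beta_s, center_residue)
             else beta_s,
    beta_ns = p$beta_ns, gamma = p$gamma,
    activities = tibble(round = labels,
                        alpha_ns = exp(p$la_ns), alpha_s = exp(la_s),
                        eta_input = exp(p$le_i), eta_bound = 1),
    flank_left = flank_left, flank_right = flank_right,
    flank_overlap = ctx$f_s, var_len = ctx$L,
    constrained = ctx$constrain, center_residue = center_residue)
  final <- pb_eval(best$opt$par, ctx)
  model$fit <- list(
    loss = best$opt$value, l_data = final$l_data, l_reg = final$l_reg,
    loss_init = best$loss0,
    convergence = best$opt$convergence, message = best$opt$message,
    counts = best$opt$counts,
    start_losses = losses, n_starts = n_starts, seed = as.integer(seed),
    n_par = ctx$n_par,
    config = list(constrain_center = ctx$constrain, w_s = ctx$w_s,
                  w_ns = ctx$w_ns, f_s = ctx$f_s, max_iter = max_iter,
                  tol = tol, reg = ctx$reg))
  model
}

#' @export
glance.binding_model <- function(x, ...) {
  if (is.null(x$fit)) abort("model carries no fit information")
  tibble(loss = x$fit$loss, log_lik = x$fit$l_data, penalty = x$fit$l_reg,
         convergence = x$fit$convergence,
         n_eval = unname(x$fit$counts["function"]),
         n_par = x$fit$n_par, n_tables = nrow(x$activities),
         n_starts = x$fit$n_starts)
}

#' @export
tidy.binding_model <- function(x, ...) {
  as_tibble(ddg_matrix(x))
}
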