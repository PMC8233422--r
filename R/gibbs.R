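# Bayesian threshold (probit) animal model fitted by Gibbs sampling with data
# augmentation. The liability is z = eta + e with e ~ N(0,1) and Y = 1 iff
# z > 0; eta = X beta + Z1 a + Z2 ss with a ~ N(0, H sigma2_a) and
# ss ~ N(0, I sigma2_ss). The residual variance is fixed at 1 and the single
# threshold at 0 (probit identification). The first factor of the fixed part
# absorbs the overall mean (all its levels are estimated); every later factor
# gets a corner constraint (first level fixed at 0) since X is otherwise
# rank-deficient.

#' Gibbs sampler configuration
#'
#' Defaults match routine practice for threshold-model evaluations of binary
#' fertility traits: 600,000 iterations of which the first 100,000 are
#' discarded as burn-in, and a thinning interval of 100 for posterior
#' statistics. Variance priors are weakly informative scaled inverse
#' chi-square distributions (4 degrees of freedom, scale 0.03, mode 0.02):
#' enough mass near zero that a null variance can shrink away, while the
#' polynomial tail damps the long right tail that threshold-model variance
#' posteriors carry under sparse binary information. Set `prior_df_* = 0`
#' for a flat (scale-reference) prior, or pass `prior_scale_* = NULL` to
#' centre the prior mode on the start value.
#'
#' @param n_iter Total Gibbs iterations (including burn-in).
#' @param burn_in Iterations discarded before storing samples.
#' @param thin Thinning interval for stored samples.
#' @param seed Integer seed; fits are deterministic given the seed.
#' @param prior_df_a,prior_df_ss Prior degrees of freedom per variance.
#' @param prior_scale_a,prior_scale_ss Prior scales; `NULL` derives the scale
#'   from the start value so the prior mode sits there.
#' @param start_sigma2_a,start_sigma2_ss Start values for the variances.
#' @param include_ss_in_h2 Whether the service-sire variance enters the
#'   phenotypic denominator of the heritability (see [heritability()]); the
#'   choice is recorded in the fit's metadata.
#' @return A list of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 600000L, burn_in = 100000L, thin = 100L,
                         seed = 1L,
                         prior_df_a = 4, prior_scale_a = 0.03,
                         prior_df_ss = 4, prior_scale_ss = 0.03,
                         start_sigma2_a = 0.1, start_sigma2_ss = 0.05,
                         include_ss_in_h2 = TRUE) {
  if (burn_in >= n_iter) config_error("burn_in must be smaller than n_iter")
  if (thin < 1L) config_error("thin must be >= 1")
  if (prior_df_a < 0 || prior_df_ss < 0)
    config_error("prior degrees of freedom must be >= 0")
  mode_scale <- function(df, start) if (df > 0) start * (df + 2) / df else 0
  if (is.null(prior_scale_a))
    prior_scale_a <- mode_scale(prior_df_a, start_sigma2_a)
  if (is.null(prior_scale_ss))
    prior_scale_ss <- mode_scale(prior_df_ss, start_sigma2_ss)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_df_a = prior_df_a, prior_scale_a = prior_scale_a,
                 prior_df_ss = prior_df_ss, prior_scale_ss = prior_scale_ss,
                 start_sigma2_a = start_sigma2_a,
                 start_sigma2_ss = start_sigma2_ss,
                 include_ss_in_h2 = include_ss_in_h2),
            class = "gibbs_config")
}

#' Build the model design from a formula and phenotype table
#'
#' The response must be binary (0/1; `NA` allowed, leaving that record's
#' liability unconstrained). Every term on the right-hand side must be a
#' column of `data` and is treated as a factor. Records with `NA` in a
#' constrained factor (e.g. DIM class for nulliparous records) contribute
#' nothing for that factor. The first term absorbs the overall mean; later
#' terms are corner-constrained.
#'
#' @param formula e.g. `y ~ year_season + breed_type`.
#' @param data Phenotype `data.frame`.
#' @param animal,service_sire Column names identifying the animal and the
#'   service sire of each record.
#' @param animal_ids Full vector of animal ids (the order of the rows of
#'   H-inverse); record animals must appear in it.
#' @return A list of class `model_design`.
#' @export
model_design <- function(formula, data, animal = "animal_id",
                         service_sire = "service_sire", animal_ids) {
  resp <- as.character(formula[[2L]])
  terms_ <- attr(stats::terms(formula), "term.labels")
  for (v in c(resp, terms_, animal, service_sire))
    if (!v %in% names(data)) data_error("column '%s' not found in data", v)
  y <- data[[resp]]
  if (!all(y %in% c(0L, 1L) | is.na(y)))
    data_error("response must be binary 0/1 (NA allowed)")
  n <- nrow(data)

  level_names <- list()
  nlev <- integer(0)
  constrained <- logical(0)
  fidx <- matrix(0L, n, length(terms_))
  for (k in seq_along(terms_)) {
    v <- as.character(data[[terms_[k]]])
    lv <- sort(unique(v[!is.na(v)]))
    if (length(lv) == 0L) data_error("factor '%s' is entirely NA", terms_[k])
    idx <- match(v, lv)
    if (k == 1L && anyNA(idx))
      data_error("the first (mean-absorbing) factor may not contain NA")
    idx[is.na(idx)] <- 1L  # constrained reference level contributes 0
    fidx[, k] <- idx
    level_names[[terms_[k]]] <- lv
    nlev <- c(nlev, length(lv))
    constrained <- c(constrained, k > 1L)
  }

  aid <- as.character(data[[animal]])
  a_idx <- match(aid, as.character(animal_ids))
  if (anyNA(a_idx))
    data_error("record animal(s) absent from animal_ids: %s",
               paste(unique(aid[is.na(a_idx)]), collapse = ", "))
  sid <- as.character(data[[service_sire]])
  sire_ids <- sort(unique(sid))
  s_idx <- match(sid, sire_ids)

  structure(list(y = as.integer(y), factor_idx = fidx, nlev = nlev,
                 constrained = constrained, level_names = level_names,
                 factors = terms_, response = resp,
                 animal_col = animal, sire_col = service_sire,
                 animal_idx = a_idx, animal_ids = as.character(animal_ids),
                 sire_idx = s_idx, sire_ids = sire_ids),
            class = "model_design")
}

#' Fit the liability threshold animal model by Gibbs sampling
#'
#' Iterates truncated-normal augmentation of the latent liabilities,
#' single-site updates of all location effects from their full conditionals,
#' and scaled inverse chi-square draws of the two variance components (the
#' residual variance stays fixed at 1). Deterministic given
#' `config$seed`.
#'
#' @inheritParams model_design
#' @param hinv Sparse symmetric H-inverse (or A-inverse) whose dimnames are
#'   the animal ids; typically from [h_inverse()] or [a_inverse()].
#' @param config A [gibbs_config()] object.
#' @param update_z,update_var Internal switches that freeze the liabilities
#'   or the variances at their start values (used for algorithm checks).
#' @param store_effects Also store the per-sample animal and service-sire
#'   effects (columns `a:<id>` / `ss:<id>`); intended for small problems.
#' @param z_init Optional start liabilities (defaults to a truncated draw at
#'   eta = 0).
#' @return An object of class `threshold_fit`; see [summary.threshold_fit()].
#' @export
fit_threshold <- function(formula, data, hinv, animal = "animal_id",
                          service_sire = "service_sire",
                          config = gibbs_config(),
                          update_z = TRUE, update_var = TRUE,
                          store_effects = FALSE, z_init = NULL) {
  if (is.null(rownames(hinv)))
    data_error("hinv must carry animal ids as dimnames")
  design <- model_design(formula, data, animal, service_sire, rownames(hinv))
  set.seed(config$seed)
  if (is.null(z_init))
    z_init <- .cpp_rtruncnorm(numeric(length(design$y)), design$y)
  H <- as(as(forceSymmetric(hinv), "generalMatrix"), "CsparseMatrix")
  res <- .cpp_gibbs_core(
    design$y, design$factor_idx, design$nlev, design$constrained,
    design$animal_idx, design$sire_idx,
    H, nrow(hinv), length(design$sire_ids),
    config$start_sigma2_a, config$start_sigma2_ss,
    config$prior_df_a, config$prior_scale_a,
    config$prior_df_ss, config$prior_scale_ss,
    config$n_iter, config$burn_in, config$thin,
    update_z, update_var, store_effects, z_init)

  beta_names <- unlist(lapply(seq_along(design$factors), function(k)
    paste(design$factors[k], design$level_names[[k]], sep = ":")),
    use.names = FALSE)
  effect_names <- if (store_effects)
    c(paste0("a:", design$animal_ids), paste0("ss:", design$sire_ids))
  else character(0)
  samples <- res$samples
  colnames(samples) <- c("sigma2_a", "sigma2_ss", beta_names, effect_names)
  h2 <- heritability(samples[, "sigma2_a"], samples[, "sigma2_ss"],
                     include_ss = config$include_ss_in_h2)
  structure(list(
    samples = samples, h2_samples = h2,
    gebv = setNames(res$mean_a, design$animal_ids),
    ss_effects = setNames(res$mean_ss, design$sire_ids),
    design = design, config = config,
    h2_denominator = if (config$include_ss_in_h2)
      "sigma2_a + sigma2_ss + 1" else "sigma2_a + 1",
    n_beta = length(beta_names),
    n_records = length(design$y), n_animals = nrow(hinv),
    n_service_sires = length(design$sire_ids),
    violations = res$violations, empty_levels = res$empty_levels,
    final_z = res$final_z,
    call = match.call()), class = "threshold_fit")
}

#' Liability-scale heritability
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_ss + 1)`, the additive share of the
#' liability variance with the residual fixed at 1. Setting
#' `include_ss = FALSE` drops the service-sire variance from the denominator.
#'
#' @param sigma2_a,sigma2_ss Variance components (vectorised).
#' @param include_ss Include `sigma2_ss` in the phenotypic denominator.
#' @return Heritability value(s) in `[0, 1)`.
#' @export
heritability <- function(sigma2_a, sigma2_ss = 0, include_ss = TRUE) {
  denom <- sigma2_a + if (include_ss) sigma2_ss else 0
  sigma2_a / (denom + 1)
}

#' Draw latent liabilities
#'
#' Truncated-normal data augmentation: `z ~ N(eta, 1)` restricted to
#' `(0, Inf)` where `y = 1`, to `(-Inf, 0]` where `y = 0`, untruncated where
#' `y` is `NA`. Numerically robust for |eta| well beyond 6 (tail draws use a
#' shifted-exponential rejection sampler).
#'
#' @param eta Linear predictor per record.
#' @param y Binary outcomes (0/1/NA).
#' @return Vector of liability draws.
#' @export
sample_liabilities <- function(eta, y) {
  .cpp_rtruncnorm(as.numeric(eta), as.integer(y))
}

#' Draw a variance component from its full conditional
#'
#' Scaled inverse chi-square draws with `df = n_effects + prior_df` and
#' numerator `q + prior_df * prior_scale`, where `q` is the quadratic form of
#' the effects (e.g. `a' H^{-1} a`). Draws are floored at 1e-8 to guard the
#' degenerate `q = 0`, flat-prior case.
#'
#' @param q Quadratic form of the current effects.
#' @param n_effects Number of effects in the quadratic form.
#' @param prior_df,prior_scale Scaled inverse chi-square prior parameters.
#' @param n Number of draws.
#' @return Vector of variance draws.
#' @export
sample_variance <- function(q, n_effects, prior_df = 0, prior_scale = 0,
                            n = 1L) {
  .cpp_rscinvchi2(as.integer(n), n_effects + prior_df,
                  q + prior_df * prior_scale)
}

# ---- methods ----------------------------------------------------------------

posterior_table <- function(draws) {
  t(apply(draws, 2L, function(x)
    c(mean = mean(x), sd = sd(x),
      `2.5%` = unname(quantile(x, 0.025)),
      `97.5%` = unname(quantile(x, 0.975)))))
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("Liability threshold animal model (Gibbs)\n")
  cat(sprintf("  %d records, %d animals, %d service sires\n",
              x$n_records, x$n_animals, x$n_service_sires))
  cat(sprintf("  %d stored samples (n_iter %d, burn-in %d, thin %d)\n",
              nrow(x$samples), x$config$n_iter, x$config$burn_in,
              x$config$thin))
  pt <- posterior_table(cbind(x$samples[, c("sigma2_a", "sigma2_ss")],
                              h2 = x$h2_samples))
  print(round(pt, 4))
  cat(sprintf("  h2 denominator: %s\n", x$h2_denominator))
  invisible(x)
}

#' Posterior summary of a threshold-model fit
#'
#' Posterior mean, SD and 95% equal-tail interval for the variance
#' components, the heritability and every fixed-effect level, computed from
#' the stored post-burn-in thinned samples.
#'
#' @param object A `threshold_fit`.
#' @param ... Unused.
#' @return A `summary.threshold_fit` object (matrix plus metadata).
#' @export
summary.threshold_fit <- function(object, ...) {
  draws <- cbind(object$samples[, c("sigma2_a", "sigma2_ss"), drop = FALSE],
                 h2 = object$h2_samples,
                 object$samples[, 2L + seq_len(object$n_beta), drop = FALSE])
  structure(list(table = posterior_table(draws),
                 h2_denominator = object$h2_denominator,
                 n_samples = nrow(object$samples),
                 violations = object$violations),
            class = "summary.threshold_fit")
}

#' @export
print.summary.threshold_fit <- function(x, ...) {
  cat(sprintf("Posterior summaries (%d retained samples; h2 = sigma2_a / (%s))\n",
              x$n_samples, x$h2_denominator))
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.threshold_fit <- function(object, ...) {
  colMeans(object$samples[, 2L + seq_len(object$n_beta), drop = FALSE])
}

#' Posterior-mean linear predictor or event probability
#'
#' @param object A `threshold_fit`.
#' @param newdata Phenotype table with the model's factor, animal and
#'   service-sire columns; defaults to refusing unseen levels/animals.
#' @param type `"link"` for the liability-scale predictor, `"response"` for
#'   the event probability `pnorm(eta)`.
#' @param ... Unused.
#' @return Numeric vector, one value per record.
#' @export
predict.threshold_fit <- function(object, newdata, type = c("link", "response"),
                                  ...) {
  type <- match.arg(type)
  d <- object$design
  bmean <- coef(object)
  eta <- numeric(nrow(newdata))
  for (k in seq_along(d$factors)) {
    v <- as.character(newdata[[d$factors[k]]])
    lv <- d$level_names[[k]]
    idx <- match(v, lv)
    if (any(is.na(idx) & !is.na(v)))
      data_error("unseen level(s) in factor '%s'", d$factors[k])
    contrib <- bmean[paste(d$factors[k], lv, sep = ":")][idx]
    contrib[is.na(contrib)] <- 0
    eta <- eta + contrib
  }
  aid <- as.character(newdata[[d$animal_col]])
  ai <- match(aid, names(object$gebv))
  if (anyNA(ai)) data_error("unknown animal(s) in newdata")
  eta <- eta + object$gebv[ai]
  si <- match(as.character(newdata[[d$sire_col]]), names(object$ss_effects))
  eta <- eta + ifelse(is.na(si), 0, object$ss_effects[si])
  eta <- unname(eta)
  if (type == "response") pnorm(eta) else eta
}

#' Trace plots for a threshold-model fit
#'
#' @param x A `threshold_fit`.
#' @param pars Parameters to plot (columns of the sample matrix or `"h2"`).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.threshold_fit <- function(x, pars = c("sigma2_a", "sigma2_ss", "h2"),
                               ...) {
  old <- par(mfrow = c(length(pars), 1L), mar = c(3, 4, 2, 1))
  on.exit(par(old))
  for (p in pars) {
    tr <- if (p == "h2") x$h2_samples else x$samples[, p]
    plot(tr, type = "l", xlab = "stored sample", ylab = p, main = p, ...)
  }
  invisible(x)
}

# ---- convergence diagnostics ------------------------------------------------

#' Effective sample size of an MCMC trace
#'
#' Geyer initial positive sequence estimator: autocorrelations are summed in
#' consecutive pairs until a pair turns negative. White noise gives ESS close
#' to n; an AR(1) trace with coefficient rho gives roughly
#' `n (1 - rho) / (1 + rho)`.
#'
#' @param x Numeric trace.
#' @return Effective sample size (`NA` for a constant trace).
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 3L || sd(x) == 0) return(NA_real_)
  rho <- as.numeric(acf(x, lag.max = min(n - 2L, 2000L), plot = FALSE,
                        demean = TRUE)$acf)[-1L]
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

#' Convergence diagnostics for stored traces
#'
#' Effective sample size and Geweke z-score (first 10% vs last 50% of the
#' trace, variances scaled by ESS) per parameter; optionally writes trace
#' plots to a file. Reports are flagged unreliable below 50 retained samples.
#'
#' @param x A `threshold_fit` or a numeric matrix of traces (one column per
#'   parameter).
#' @param plot_file Optional PNG path for trace plots.
#' @return A `data.frame` with `parameter`, `ess`, `geweke_z`, `reliable`.
#' @export
convergence_diagnostics <- function(x, plot_file = NULL) {
  traces <- if (inherits(x, "threshold_fit"))
    cbind(x$samples[, c("sigma2_a", "sigma2_ss"), drop = FALSE],
          h2 = x$h2_samples)
  else as.matrix(x)
  if (is.null(colnames(traces)))
    colnames(traces) <- paste0("par", seq_len(ncol(traces)))
  n <- nrow(traces)
  geweke <- function(v) {
    if (sd(v) == 0) return(NA_real_)
    a <- v[seq_len(max(2L, floor(0.1 * n)))]
    b <- v[seq.int(floor(0.5 * n) + 1L, n)]
    va <- var(a) / max(1, effective_size(a))
    vb <- var(b) / max(1, effective_size(b))
    (mean(a) - mean(b)) / sqrt(va + vb)
  }
  out <- data.frame(
    parameter = colnames(traces),
    ess = vapply(seq_len(ncol(traces)), function(j)
      effective_size(traces[, j]), numeric(1)),
    geweke_z = vapply(seq_len(ncol(traces)), function(j)
      geweke(traces[, j]), numeric(1)),
    reliable = n >= 50L,
    row.names = NULL)
  if (!is.null(plot_file)) {
    png(plot_file, width = 900, height = 300 * ncol(traces))
    old <- par(mfrow = c(ncol(traces), 1L), mar = c(3, 4, 2, 1))
    for (j in seq_len(ncol(traces)))
      plot(traces[, j], type = "l", ylab = colnames(traces)[j],
           main = colnames(traces)[j])
    par(old)
    dev.off()
  }
  out
}
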