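# Enzyme kinetics: the three rate laws of the saturation-curve analysis
# (Michaelis-Menten, substrate inhibition, allosteric sigmoidal), weighted
# nonlinear least-squares fitting with multi-start initialization, AICc
# model selection, and catalytic efficiency kcat/Km.

.KINETIC_MODELS <- c("michaelis_menten", "substrate_inhibition",
                     "allosteric_sigmoidal")

#' Rate law evaluation
#'
#' * `michaelis_menten`: v = Vmax S / (Km + S)
#' * `allosteric_sigmoidal`: v = Vmax S^h / (S0.5^h + S^h)
#' * `substrate_inhibition`: v = Vmax S / (Km + S (1 + S/Ki)); unimodal
#'   with its maximum at S = sqrt(Km Ki).
#'
#' @param model One of `"michaelis_menten"`, `"substrate_inhibition"`,
#'   `"allosteric_sigmoidal"`.
#' @param S Substrate concentrations (mM), non-negative.
#' @param params Named list/vector: `Vmax` plus `Km` (MM), `Km` and `Ki`
#'   (inhibition), or `S05` and `h` (sigmoid).
#' @return Rates, same length as `S`.
#' @export
#' @examples
#' rate("michaelis_menten", 5.6, c(Vmax = 40, Km = 5.6))  # Vmax/2
rate <- function(model, S, params) {
  model <- match.arg(model, .KINETIC_MODELS)
  S <- as.numeric(S)
  p <- as.list(params)
  if (any(S < 0)) stop("negative substrate concentration", call. = FALSE)
  if (any(unlist(p) <= 0))
    stop("rate-law parameters must be positive", call. = FALSE)
  switch(model,
    michaelis_menten = p$Vmax * S / (p$Km + S),
    substrate_inhibition = p$Vmax * S / (p$Km + S * (1 + S / p$Ki)),
    allosteric_sigmoidal = p$Vmax * S^p$h / (p$S05^p$h + S^p$h))
}

#' Assemble a substrate-saturation dataset
#'
#' @param substrate_mM Substrate concentrations, mM, all positive, at least
#'   5 distinct values.
#' @param rate Observed rates (s^-1 per site, or raw units with
#'   `enzyme_uM` supplied for conversion downstream).
#' @param replicate Optional replicate ids.
#' @param substrate Substrate name (`"OAA"`, `"PYR"`, or other).
#' @param enzyme_uM Optional enzyme site concentration for Vmax -> kcat.
#' @return A `saturation_dataset` data frame with metadata attributes.
#' @export
saturation_dataset <- function(substrate_mM, rate, replicate = NULL,
                               substrate = "OAA", enzyme_uM = NULL) {
  substrate_mM <- as.numeric(substrate_mM); rate <- as.numeric(rate)
  stopifnot(length(substrate_mM) == length(rate))
  if (any(substrate_mM <= 0))
    stop("substrate concentrations must be positive", call. = FALSE)
  if (length(unique(substrate_mM)) < 5)
    stop("need at least 5 distinct substrate concentrations", call. = FALSE)
  out <- data.frame(substrate_mM = substrate_mM, rate = rate,
                    replicate = if (is.null(replicate)) 1L else replicate)
  attr(out, "substrate") <- substrate
  attr(out, "enzyme_uM") <- enzyme_uM
  class(out) <- c("saturation_dataset", "data.frame")
  out
}

#' Read a saturation dataset from CSV
#'
#' Expects columns `substrate_mM`, `rate`, optional `replicate`; header
#' comment lines `# substrate: X` and `# enzyme_uM: Y` carry metadata.
#'
#' @param path CSV file.
#' @return A `saturation_dataset`.
#' @export
read_saturation_csv <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10), value = TRUE)
  meta <- function(key, cast = identity) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) NULL else cast(trimws(sub(".*:", "", m[1])))
  }
  df <- utils::read.csv(path, comment.char = "#")
  saturation_dataset(df$substrate_mM, df$rate,
                     replicate = df$replicate,
                     substrate = meta("substrate") %||% "OAA",
                     enzyme_uM = meta("enzyme_uM", as.numeric))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# residual sum of squares for a parameter vector on log scale
.kin_rss <- function(logp, model, S, v, w, pnames) {
  p <- stats::setNames(as.list(exp(logp)), pnames)
  pred <- tryCatch(rate(model, S, p), error = function(e) rep(NA_real_,
                                                              length(S)))
  if (anyNA(pred) || any(!is.finite(pred))) return(1e30)
  sum(w * (v - pred)^2)
}

.aicc <- function(rss, n, k) {
  # k model parameters + 1 for the error variance
  kk <- k + 1
  n * log(rss / n) + 2 * kk + if (n - kk - 1 > 0) 2 * kk * (kk + 1) /
    (n - kk - 1) else Inf
}

#' Fit a rate law to a saturation dataset
#'
#' Nonlinear least squares (unweighted by default, matching common
#' Prism-style practice; optionally 1/v^2-weighted) with multi-start
#' initialization: Vmax starts at 1.1 x max(v); the half-saturation
#' parameter at the S whose rate is nearest half that estimate; Hill h at
#' 1.5 and 2.5; Ki at 10 x the Km estimate; plus seeded log-normal jitter
#' for 8 restarts.  `model = "auto"` fits all three laws and selects by
#' AICc with a parsimony rule: among models within `parsimony_delta` AICc
#' units of the best, the one with fewest parameters wins (the sigmoid law
#' nests the hyperbola at h = 1, so raw AICc alone would occasionally
#' promote a spurious Hill coefficient).
#'
#' @param dataset A `saturation_dataset` (or data frame with
#'   `substrate_mM`, `rate`).
#' @param model Rate-law name or `"auto"`.
#' @param weighting `"none"` or `"1/v2"`.
#' @param n_starts Number of multi-start restarts.
#' @param seed Seed for start-point jitter.
#' @param parsimony_delta AICc band within which a simpler model is
#'   preferred (default 2, the conventional "substantial support" cutoff).
#' @return A `kinetic_fit`: list with `model`, `parameters`, `se`,
#'   `kcat`, `efficiency` (M^-1 s^-1, when computable), `rss`, `aicc`,
#'   `converged`, `candidates` (per-model AICc for `"auto"`), `n`, `seed`.
#'   Non-convergence yields `converged = FALSE` with `NA` parameters,
#'   never silent NaNs.
#' @export
fit_kinetics <- function(dataset, model = "auto",
                         weighting = c("none", "1/v2"),
                         n_starts = 8L, seed = 1L, parsimony_delta = 2) {
  weighting <- match.arg(weighting)
  S <- dataset$substrate_mM; v <- dataset$rate
  if (length(unique(S)) < 5)
    stop("need at least 5 distinct substrate concentrations", call. = FALSE)
  w <- if (weighting == "1/v2") 1 / pmax(v, 1e-12)^2 else rep(1, length(v))

  models <- if (identical(model, "auto")) .KINETIC_MODELS else
    match.arg(model, .KINETIC_MODELS)

  Vmax0 <- 1.1 * max(v)
  half_idx <- which.min(abs(v - Vmax0 / 2))
  K0 <- max(S[half_idx], min(S))

  fit_one <- function(mod) {
    starts <- switch(mod,
      michaelis_menten = list(c(Vmax = Vmax0, Km = K0)),
      substrate_inhibition = list(c(Vmax = Vmax0, Km = K0, Ki = 10 * K0),
                                  c(Vmax = 2 * Vmax0, Km = K0, Ki = 2 * K0)),
      allosteric_sigmoidal = list(c(Vmax = Vmax0, S05 = K0, h = 1.5),
                                  c(Vmax = Vmax0, S05 = K0, h = 2.5)))
    pnames <- names(starts[[1]])
    set.seed(seed)
    jitters <- lapply(seq_len(max(0, n_starts - length(starts))), function(i)
      starts[[1 + (i - 1) %% length(starts)]] *
        exp(stats::rnorm(length(pnames), 0, 0.4)))
    starts <- c(starts, jitters)

    best <- NULL
    for (st in starts) {
      opt <- tryCatch(
        stats::optim(log(st), .kin_rss, model = mod, S = S, v = v, w = w,
                     pnames = pnames, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$value)) next
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (is.null(best) || best$value >= 1e29)
      return(list(model = mod, converged = FALSE, rss = NA_real_,
                  aicc = Inf, parameters = stats::setNames(
                    rep(NA_real_, length(pnames)), pnames)))
    # polish with Gauss-Newton (nls port) from the optim solution
    p0 <- stats::setNames(as.list(exp(best$par)), pnames)
    form <- switch(mod,
      michaelis_menten = v ~ Vmax * S / (Km + S),
      substrate_inhibition = v ~ Vmax * S / (Km + S * (1 + S / Ki)),
      allosteric_sigmoidal = v ~ Vmax * S^h / (S05^h + S^h))
    nf <- tryCatch(stats::nls(form, data = list(S = S, v = v), start = p0,
                              weights = w, algorithm = "port",
                              lower = rep(1e-10, length(pnames)),
                              control = list(warnOnly = TRUE)),
                   error = function(e) NULL)
    if (!is.null(nf) && sum(w * stats::resid(nf)^2) <= best$value + 1e-12) {
      pars <- stats::coef(nf)
      rss <- sum(w * stats::resid(nf)^2)
      se <- tryCatch(sqrt(diag(stats::vcov(nf))), error = function(e)
        stats::setNames(rep(NA_real_, length(pars)), names(pars)))
    } else {
      pars <- stats::setNames(exp(best$par), pnames)
      rss <- best$value
      se <- stats::setNames(rep(NA_real_, length(pars)), names(pars))
    }
    at_bound <- any(pars <= 1e-9)
    list(model = mod, converged = TRUE, parameters = pars, se = se,
         rss = rss, aicc = .aicc(rss, length(v), length(pars)),
         at_bound = at_bound)
  }

  fits <- lapply(models, fit_one)
  names(fits) <- models
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  if (all(!vapply(fits, function(f) isTRUE(f$converged), logical(1))))
    return(structure(list(model = NA_character_, converged = FALSE,
                          parameters = NULL, candidates = aiccs,
                          n = length(v), seed = seed),
                     class = "kinetic_fit"))
  npar <- vapply(fits, function(f) length(f$parameters), integer(1))
  in_band <- which(aiccs <= min(aiccs) + parsimony_delta)
  pick <- fits[[in_band[order(npar[in_band], aiccs[in_band])[1]]]]

  enzyme_uM <- attr(dataset, "enzyme_uM")
  # rates in s^-1 per site: Vmax is kcat directly; with enzyme_uM the rates
  # are raw (e.g. uM/s) and kcat = Vmax / [E]
  kcat <- if (is.null(enzyme_uM)) unname(pick$parameters["Vmax"]) else
    unname(pick$parameters["Vmax"]) / enzyme_uM
  half_par <- if (pick$model == "allosteric_sigmoidal") "S05" else "Km"
  eff <- kcat / (unname(pick$parameters[half_par]) * 1e-3)

  structure(c(pick,
              list(kcat = kcat, efficiency = eff,
                   half_saturation_mM = unname(pick$parameters[half_par]),
                   candidates = aiccs, n = length(v), seed = seed,
                   substrate = attr(dataset, "substrate"))),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<kinetic_fit> FAILED to converge\n"); return(invisible(x))
  }
  cat("<kinetic_fit> ", x$model, " (n = ", x$n, ")\n", sep = "")
  for (p in names(x$parameters))
    cat(sprintf("  %-5s %s%s\n", p, signif(x$parameters[p], 4),
                if (!is.na(x$se[p])) paste0(" +/- ", signif(x$se[p], 2)) else ""))
  cat(sprintf("  kcat %s s^-1; kcat/Km %s M^-1 s^-1; AICc %.1f\n",
              signif(x$kcat, 2), signif(x$efficiency, 2), x$aicc))
  invisible(x)
}

#' Catalytic efficiency kcat/Km
#'
#' `kcat / (Km_mM * 1e-3)` in M^-1 s^-1; for sigmoidal fits the
#' half-saturation S0.5 stands in for Km, as kinetics tables in this field
#' do.  Printed at 2 significant figures, full precision returned.
#'
#' @param fit A `kinetic_fit`, or a named list/vector with `kcat` and `Km`
#'   (or `S05`) in s^-1 and mM.
#' @return Efficiency in M^-1 s^-1 (full precision; see
#'   `signif(x, 2)` for table-style display).
#' @export
#' @examples
#' efficiency(c(kcat = 21, Km = 100))   # 210
#' signif(efficiency(c(kcat = 40, Km = 5.6)), 2)  # 7100
efficiency <- function(fit) {
  if (inherits(fit, "kinetic_fit")) {
    if (!isTRUE(fit$converged) || is.null(fit$kcat) || is.na(fit$kcat))
      stop("fit carries no kcat (missing enzyme concentration or failed fit)",
           call. = FALSE)
    return(fit$kcat / (fit$half_saturation_mM * 1e-3))
  }
  p <- as.list(fit)
  kcat <- p$kcat
  km <- p$Km %||% p$S05
  if (is.null(kcat) || is.null(km))
    stop("need kcat and Km (or S05)", call. = FALSE)
  kcat / (km * 1e-3)
}

#' Export a fit report (JSON) and predicted curve (CSV)
#'
#' @param fit A `kinetic_fit`.
#' @param dataset The dataset it was fitted to.
#' @param path_prefix Output path without extension.
#' @export
write_kinetic_fit <- function(fit, dataset, path_prefix) {
  stopifnot(inherits(fit, "kinetic_fit"))
  jsonlite::write_json(
    list(model = fit$model, converged = fit$converged,
         parameters = as.list(fit$parameters), se = as.list(fit$se),
         kcat_per_s = fit$kcat, efficiency_M_s = fit$efficiency,
         rss = fit$rss, aicc = fit$aicc, n = fit$n, seed = fit$seed,
         candidates_aicc = as.list(fit$candidates)),
    paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA)
  if (isTRUE(fit$converged)) {
    Sgrid <- exp(seq(log(min(dataset$substrate_mM)),
                     log(max(dataset$substrate_mM)), length.out = 100))
    utils::write.csv(
      data.frame(substrate_mM = Sgrid,
                 rate = rate(fit$model, Sgrid, fit$parameters)),
      paste0(path_prefix, "_curve.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(path_prefix)
}
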