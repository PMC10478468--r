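#' Monod batch-model parameters
#'
#' Parameter container for the batch fermentation model: Monod growth on a
#' single limiting substrate (d-glucose), substrate consumption partitioned
#' into growth and product formation (Herbert-Pirt balance without a
#' maintenance term), and substrate-saturated product (l-histidine) formation.
#'
#' @param mu_max maximum specific growth rate \[1/h\].
#' @param Ks Monod (half-saturation) constant for glucose \[g/L\].
#' @param Yxs biomass yield on glucose \[g CDW / g glucose\].
#' @param qP_max maximum specific product formation rate
#'   \[mmol / (g CDW h)\].
#' @return named numeric vector of class `monod_parameters`.
#' @export
monod_params <- function(mu_max = 0.15, Ks = 1.0, Yxs = 0.21, qP_max = 0.13) {
  p <- c(mu_max = mu_max, Ks = Ks, Yxs = Yxs, qP_max = qP_max)
  if (any(p[c("mu_max", "Ks", "Yxs")] <= 0) || qP_max < 0) {
    stop("Monod parameters must be positive (qP_max may be zero)")
  }
  structure(p, class = "monod_parameters")
}

.MONOD_PARAM_NAMES <- c("mu_max", "Ks", "Yxs", "qP_max")

## Substrate drain by product formation assumes 1 mol glucose per mol
## histidine (both C6): qP [mmol/(g h)] * X [g/L] * M_glc/1000 [g/mmol] g/L/h.
## A fixed stoichiometric constant, not a fitted parameter. The right-hand
## side lives in src/monod.c (deSolve compiled-model interface): the
## bootstrap machinery integrates it hundreds of thousands of times.

#' Simulate one batch fermentation
#'
#' Numerically integrates the Monod batch model
#' \deqn{dX/dt = \mu(S) X, \quad \mu(S) = \mu_{max} S / (K_S + S)}
#' \deqn{dS/dt = -(\mu/Y_{XS}) X - q_P X M_{glc}/1000}
#' \deqn{dP/dt = q_P(S) X, \quad q_P(S) = q_{P,max} S / (K_S + S)}
#' with biomass X \[g CDW/L\], glucose S \[g/L\] and product P \[mM\];
#' glucose is floored at zero, after which growth and production stop.
#'
#' @param params a [monod_params()] object (or named vector with the same
#'   elements).
#' @param init named vector `c(X = , S = , P = )` of initial biomass, glucose
#'   and product.
#' @param times time grid in hours.
#' @param rtol,atol integrator tolerances (lsoda).
#' @return data frame of class `batch_time_course` with columns `time`,
#'   `biomass`, `glucose`, `histidine`.
#' @export
simulate_batch <- function(params, init = c(X = 0.25, S = 40, P = 0),
                           times = seq(0, 48, by = 1), rtol = 1e-8,
                           atol = 1e-8) {
  if (init[["X"]] <= 0 || init[["S"]] <= 0) {
    stop("initial biomass and glucose must be positive")
  }
  p <- as.numeric(params)[match(.MONOD_PARAM_NAMES, names(params))]
  names(p) <- .MONOD_PARAM_NAMES
  if (anyNA(p) || any(p[c("mu_max", "Ks", "Yxs")] <= 0) || p[["qP_max"]] < 0) {
    stop("invalid Monod parameters")
  }
  sol <- deSolve::lsoda(
    y = c(X = init[["X"]], S = init[["S"]],
          P = if ("P" %in% names(init)) init[["P"]] else 0),
    times = times, func = "monod_derivs", parms = p,
    dllname = "evohotspot", initfunc = "monod_init",
    rtol = rtol, atol = atol
  )
  if (any(!is.finite(sol))) {
    stop("non-finite state in batch simulation: bad parameters or stiffness")
  }
  out <- data.frame(time = sol[, "time"],
                    biomass = sol[, "X"],
                    glucose = pmax(sol[, "S"], 0),
                    histidine = pmax(sol[, "P"], 0))
  class(out) <- c("batch_time_course", "data.frame")
  out
}

## Per-point relative residuals of one batch against the model prediction at
## its own time grid. Dividing by the predicted level (floored at a small
## fraction of the observable's maximum) matches a constant-CV noise model
## and keeps the short but highly informative glucose-depletion phase from
## being drowned out by the large early concentrations.
batch_residuals <- function(params, batch, init, floors) {
  pred <- simulate_batch(params, init = init, times = batch$time)
  unlist(lapply(c("biomass", "glucose", "histidine"), function(obs) {
    (pred[[obs]] - batch[[obs]]) / pmax(abs(pred[[obs]]), floors[[obs]])
  }), use.names = FALSE)
}

## Expand a log-parameter vector theta into per-batch parameter sets.
theta_to_params <- function(theta, global, n_batches) {
  local <- setdiff(.MONOD_PARAM_NAMES, global)
  lapply(seq_len(n_batches), function(b) {
    p <- numeric(4)
    names(p) <- .MONOD_PARAM_NAMES
    for (nm in global) p[nm] <- exp(theta[[nm]])
    for (nm in local) p[nm] <- exp(theta[[paste0(nm, ".", b)]])
    p
  })
}

## Data-driven starting guesses: growth rate from the early log-linear biomass
## phase, biomass yield from the overall X/S balance, production rate from the
## product increment over the biomass integral; Ks starts at a generic 0.5 g/L
## (identifiable only from the deceleration phase, so data cannot prime it).
initial_guess <- function(batch) {
  X <- batch$biomass; S <- batch$glucose; P <- batch$histidine; t <- batch$time
  t_span <- diff(range(t))
  early <- which(S > S[1] / 2 & X > 0)
  mu0 <- if (length(early) >= 3) {
    max(stats::coef(stats::lm(log(X[early]) ~ t[early]))[2], 0.2 / t_span)
  } else 2 / t_span
  dS <- S[1] - min(S)
  Yxs0 <- if (dS > 0) max((max(X) - X[1]) / dS, 0.05) else 0.3
  intX <- sum(diff(t) * (utils::head(X, -1) + utils::tail(X, -1)) / 2)
  qP0 <- if (intX > 0 && max(P) > P[1]) (max(P) - P[1]) / intX else
    mu0 / 10
  c(mu_max = mu0, Ks = 0.5, Yxs = min(Yxs0, 0.6), qP_max = qP0)
}

#' Fit the Monod model to one or more batches
#'
#' Weighted nonlinear least-squares fit of the batch model to multiple batch
#' time courses with a global/local parameter structure: parameters named in
#' `global` take one shared value across all batches, all others are estimated
#' per batch (suffixed `.1`, `.2`, ...). The loss is the sum of squared
#' per-point relative residuals (each residual divided by the predicted
#' level, floored at `floor_frac` of the observable's maximum), which matches
#' a constant-CV noise model, weighs observables in different units
#' comparably, and preserves the information in the short glucose-depletion
#' phase. Optimisation uses Levenberg-Marquardt on
#' log-parameters (which enforces positivity) with seeded multi-start around a
#' data-driven initial guess.
#'
#' @param batches list of batch data frames (`time`, `biomass`, `glucose`,
#'   `histidine`), at least 5 time points each; initial conditions are taken
#'   from each batch's first row.
#' @param global character vector of parameter names shared across batches
#'   (default `c("Ks", "Yxs", "qP_max")`).
#' @param n_starts number of multi-start launches (default 3).
#' @param seed RNG seed for the start perturbations.
#' @param init_guess optional named vector overriding the automatic guess.
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @param floor_frac lower floor on the relative-residual denominator, as a
#'   fraction of each observable's maximum (default 0.005).
#' @return object of class `monod_fit`: list with `estimates` (named vector on
#'   the natural scale), `global`, `n_batches`, `loss`, `residual_cv`
#'   (per-observable relative residual SD, the bootstrap noise model),
#'   `batches`, `inits`, `floors`, `seed`, `converged`.
#' @export
fit_batches <- function(batches, global = c("Ks", "Yxs", "qP_max"),
                        n_starts = 3, seed = 1, init_guess = NULL,
                        max_iter = 100, floor_frac = 0.005) {
  if (inherits(batches, "data.frame")) batches <- list(batches)
  n_b <- length(batches)
  if (n_b < 1L) stop("need at least one batch")
  for (b in batches) {
    if (nrow(b) < 5L) stop("each batch needs at least 5 time points")
    if (any(diff(b$time) <= 0)) stop("batch times must be strictly increasing")
  }
  stopifnot(all(global %in% .MONOD_PARAM_NAMES))
  local <- setdiff(.MONOD_PARAM_NAMES, global)

  inits <- lapply(batches, function(b) {
    c(X = b$biomass[1], S = b$glucose[1], P = b$histidine[1])
  })
  floors <- lapply(batches, function(b) {
    c(biomass = max(floor_frac * max(abs(b$biomass)), 1e-9),
      glucose = max(floor_frac * max(abs(b$glucose)), 1e-9),
      histidine = max(floor_frac * max(abs(b$histidine)), 1e-9))
  })

  guesses <- lapply(batches, initial_guess)
  base <- colMeans(do.call(rbind, guesses))
  if (!is.null(init_guess)) base[names(init_guess)] <- init_guess

  theta_names <- c(global,
                   unlist(lapply(local, function(nm) paste0(nm, ".", seq_len(n_b)))))
  base_theta <- numeric(length(theta_names))
  names(base_theta) <- theta_names
  for (nm in global) base_theta[nm] <- log(base[[nm]])
  for (nm in local) {
    for (b in seq_len(n_b)) {
      base_theta[paste0(nm, ".", b)] <- log(guesses[[b]][[nm]] %||% base[[nm]])
    }
  }

  objective <- function(theta) {
    pars <- theta_to_params(theta, global, n_b)
    res <- tryCatch(
      unlist(lapply(seq_len(n_b), function(b) {
        batch_residuals(pars[[b]], batches[[b]], inits[[b]], floors[[b]])
      })),
      error = function(e) NULL
    )
    if (is.null(res) || any(!is.finite(res))) {
      return(rep(1e6, sum(vapply(batches, nrow, 1L)) * 3L))
    }
    res
  }

  set.seed(seed)
  best <- NULL
  any_converged <- FALSE
  for (s in seq_len(n_starts)) {
    theta0 <- if (s == 1L) base_theta else
      base_theta + stats::rnorm(length(base_theta), sd = 0.3)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = theta0, fn = objective,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    converged <- fit$info %in% 1:3
    any_converged <- any_converged || converged
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("Monod fit failed in all starts")
  if (!any_converged) {
    stop("Monod fit did not converge after ", n_starts,
         " starts (best deviance ", signif(best$deviance, 4), ")")
  }

  theta_hat <- best$par
  estimates <- exp(theta_hat)
  ## per-observable relative residual SD at the optimum (bootstrap noise model)
  pars_hat <- theta_to_params(theta_hat, global, n_b)
  cvs <- lapply(c("biomass", "glucose", "histidine"), function(obs) {
    unlist(lapply(seq_len(n_b), function(b) {
      pred <- simulate_batch(pars_hat[[b]], inits[[b]], batches[[b]]$time)
      denom <- pmax(abs(pred[[obs]]), floors[[b]][[obs]])
      (pred[[obs]] - batches[[b]][[obs]]) / denom
    }))
  })
  residual_cv <- vapply(cvs, stats::sd, numeric(1))
  names(residual_cv) <- c("biomass", "glucose", "histidine")

  structure(
    list(estimates = estimates, global = global, n_batches = n_b,
         loss = best$deviance, residual_cv = residual_cv,
         batches = batches, inits = inits, floors = floors, seed = seed,
         converged = any_converged, bounds = NULL),
    class = "monod_fit"
  )
}

#' @export
print.monod_fit <- function(x, ...) {
  cat("monod_fit over", x$n_batches, "batch(es); global:",
      paste(x$global, collapse = ", "), "\n")
  if (!is.null(x$bounds)) {
    b <- x$bounds
    for (i in seq_len(nrow(b))) {
      cat(sprintf("  %-12s %.4g [%.4g, %.4g]\n", b$parameter[i],
                  b$estimate[i], b$low[i], b$high[i]))
    }
  } else {
    for (nm in names(x$estimates)) {
      cat(sprintf("  %-12s %.4g\n", nm, x$estimates[[nm]]))
    }
  }
  cat("  loss", signif(x$loss, 4), "\n")
  invisible(x)
}

#' Parametric-bootstrap confidence bounds for a Monod fit
#'
#' Simulates `n_boot` synthetic datasets from the fitted model plus its
#' estimated per-observable relative noise, refits each one (single start from
#' the point estimate), and takes percentile bounds per parameter. Bounds are
#' generally asymmetric about the estimate; with noise-free data they collapse
#' onto it.
#'
#' @param fit a `monod_fit`.
#' @param n_boot number of bootstrap replicates (>= 10).
#' @param seed RNG seed.
#' @param level coverage of the percentile interval (default 0.95, i.e.
#'   2.5/97.5 percentiles).
#' @return the fit with a `bounds` data frame added (`parameter`, `estimate`,
#'   `low`, `high`, `n_boot`).
#' @export
bootstrap_bounds <- function(fit, n_boot = 200, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "monod_fit"))
  if (n_boot < 10L) stop("n_boot must be at least 10")
  set.seed(seed)
  pars <- theta_to_params(log(fit$estimates), fit$global, fit$n_batches)
  preds <- lapply(seq_len(fit$n_batches), function(b) {
    simulate_batch(pars[[b]], fit$inits[[b]], fit$batches[[b]]$time)
  })
  cv <- fit$residual_cv
  boot <- matrix(NA_real_, nrow = n_boot, ncol = length(fit$estimates),
                 dimnames = list(NULL, names(fit$estimates)))
  for (r in seq_len(n_boot)) {
    sim_batches <- lapply(seq_len(fit$n_batches), function(b) {
      p <- preds[[b]]
      data.frame(
        time = p$time,
        biomass = pmax(p$biomass * (1 + stats::rnorm(nrow(p), 0, cv[["biomass"]])), 0),
        glucose = pmax(p$glucose * (1 + stats::rnorm(nrow(p), 0, cv[["glucose"]])), 0),
        histidine = pmax(p$histidine * (1 + stats::rnorm(nrow(p), 0, cv[["histidine"]])), 0)
      )
    })
    refit <- tryCatch(
      fit_batches(sim_batches, global = fit$global, n_starts = 1,
                  seed = seed + r,
                  init_guess = fit$estimates[fit$global], max_iter = 60),
      error = function(e) NULL
    )
    if (!is.null(refit)) boot[r, ] <- refit$estimates[colnames(boot)]
  }
  ok <- stats::complete.cases(boot)
  if (sum(ok) < n_boot / 2) {
    stop("bootstrap refits failed in more than half the replicates")
  }
  alpha <- (1 - level) / 2
  qs <- apply(boot[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(alpha, 1 - alpha), names = FALSE)
  fit$bounds <- data.frame(
    parameter = names(fit$estimates),
    estimate = unname(fit$estimates),
    low = qs[1, ], high = qs[2, ],
    n_boot = sum(ok),
    stringsAsFactors = FALSE
  )
  rownames(fit$bounds) <- NULL
  fit$boot_seed <- seed
  fit
}

#' Key performance indicators of a batch fermentation
#'
#' Derives the standard bioprocess KPIs from end-point measurements: titer in
#' g/L (`mM * M(His) / 1000` with M(His) = 155.15 g/mol), product yields on
#' glucose in C-mol/C-mol, mol/mol and g/g (M(glc) = 180.16 g/mol; glucose and
#' histidine both carry 6 carbons, so the C-molar and molar yields coincide
#' exactly), and volumetric productivity in g/(L h). Values are returned
#' unrounded; the print method displays them rounded to two decimals, the
#' conventional reporting precision.
#'
#' @param titer_mM final product titer \[mM\].
#' @param glucose_g_l initial glucose \[g/L\] (must be positive).
#' @param duration_h batch duration \[h\] (optional; `NA` skips productivity).
#' @param final_cdw final cell dry weight \[g/L\] (optional).
#' @return list of class `kpi_report`.
#' @export
#' @examples
#' compute_kpis(29.1, 40, duration_h = 90)  # 0.13 C-mol/C-mol, 4.5 g/L
compute_kpis <- function(titer_mM, glucose_g_l, duration_h = NA_real_,
                         final_cdw = NA_real_) {
  if (glucose_g_l <= 0) stop("initial glucose must be positive")
  if (titer_mM < 0) stop("titer must be non-negative")
  titer_g_l <- titer_mM * .M_HIS / 1000
  mol_glc <- glucose_g_l / .M_GLC              # mol/L
  yield_mol <- (titer_mM / 1000) / mol_glc     # mol His / mol glc
  yield_cmol <- (titer_mM / 1000 * 6) / (mol_glc * 6)
  yield_g_g <- titer_g_l / glucose_g_l
  structure(
    list(titer_mM = titer_mM, titer_g_l = titer_g_l,
         yield_cmol = yield_cmol, yield_mol = yield_mol,
         yield_g_g = yield_g_g,
         volumetric_productivity = titer_g_l / duration_h,
         final_cdw = final_cdw),
    class = "kpi_report"
  )
}

#' @export
print.kpi_report <- function(x, ...) {
  cat(sprintf("titer:                   %.1f mM (%.1f g/L)\n",
              x$titer_mM, x$titer_g_l))
  cat(sprintf("yield:                   %.2f C-mol/C-mol (%.2f g/g)\n",
              x$yield_cmol, x$yield_g_g))
  if (is.finite(x$volumetric_productivity)) {
    cat(sprintf("volumetric productivity: %.2f g/(L h)\n",
                x$volumetric_productivity))
  }
  if (is.finite(x$final_cdw)) {
    cat(sprintf("final CDW:               %.1f g/L\n", x$final_cdw))
  }
  invisible(x)
}
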