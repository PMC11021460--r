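## Model calibration against time-course measurements of PHB and residual
## maltodextrin: a reproducible bounded-least-squares counterpart of the
## study's two rounds of manual parameter adjustment.

#' Address-based access to kinetic parameters
#'
#' Free parameters of a fit are named by dotted addresses:
#' `"<reaction>.keq"`, `"<reaction>.km.<species>"`, `"PhaC.c_bind"`,
#' `"PhaC.n"` (and `"<reaction>.vmax"`, though loadings are normally fixed by
#' the scenario).
#'
#' @param params A `kinetic_parameters` object.
#' @param address Dotted address string.
#' @param value Replacement value (for `param_set`).
#' @return `param_get`: the numeric value; `param_set`: the modified object.
#' @export
param_get <- function(params, address) {
  parts <- strsplit(address, ".", fixed = TRUE)[[1]]
  pr <- params$reactions[[parts[1]]]
  if (is.null(pr)) stop("unknown reaction in address ", address)
  if (parts[2] == "km") {
    v <- pr$km[[parts[3]]]
  } else {
    v <- pr[[parts[2]]]
  }
  if (is.null(v)) stop("unknown parameter address ", address)
  v
}

#' @rdname param_get
#' @export
param_set <- function(params, address, value) {
  parts <- strsplit(address, ".", fixed = TRUE)[[1]]
  if (is.null(params$reactions[[parts[1]]])) {
    stop("unknown reaction in address ", address)
  }
  if (parts[2] == "km") {
    params$reactions[[parts[1]]]$km[[parts[3]]] <- value
  } else {
    params$reactions[[parts[1]]][[parts[2]]] <- value
  }
  params
}

#' Define a calibration problem
#'
#' @param free Character vector of dotted parameter addresses to fit (see
#'   [param_get()]); non-empty. The study's round-1 free set covers the
#'   phosphoketolase/transketolase, PTA and reductase substrate Km plus the
#'   synthase `c_bind` and `n`; round 2 adds the phosphorylase `keq`.
#' @param lower,upper Bounds: scalars or vectors matching `free`. Defaults
#'   are x1/100 and x100 of the starting value, applied at fit time.
#' @return A `fit_spec` list.
#' @export
fit_spec <- function(free, lower = NULL, upper = NULL) {
  if (length(free) == 0) stop("free parameter set must be non-empty")
  if (!is.null(lower) && any(lower <= 0)) stop("bounds must be positive")
  structure(list(free = free, lower = lower, upper = upper),
            class = "fit_spec")
}

.dataset_condition <- function(dataset) {
  sc <- attr(dataset, "scenario")
  vmax <- attr(dataset, "vmax")
  if (is.null(sc)) stop("dataset lacks a 'scenario' attribute")
  list(scenario = sc, vmax = vmax)
}

.dataset_means <- function(dataset) {
  agg <- stats::aggregate(value_mM ~ time_h + observable, data = dataset,
                          FUN = mean)
  agg[order(agg$observable, agg$time_h), ]
}

.simulate_for_dataset <- function(network, params, dataset, rtol = 1e-7,
                                  atol = 1e-9) {
  cond <- .dataset_condition(dataset)
  if (!is.null(cond$vmax)) params <- set_vmax(params, cond$vmax)
  sc <- cond$scenario
  sc$t_end <- max(max(dataset$time_h) * 60, 60)
  sc$grid_dt <- max(sc$grid_dt, 5)
  simulate_cascade(network, params, sc, rtol = rtol, atol = atol)
}

.residuals_for <- function(network, params, datasets, rtol = 1e-7) {
  res <- numeric(0)
  for (ds in datasets) {
    sim <- .simulate_for_dataset(network, params, ds, rtol = rtol)
    means <- .dataset_means(ds)
    for (obs in unique(means$observable)) {
      sub <- means[means$observable == obs, ]
      scale <- max(sub$value_mM)
      if (scale <= 0) scale <- 1
      model <- conc_at(sim, obs, sub$time_h * 60)
      res <- c(res, (model - sub$value_mM) / scale)
    }
  }
  res
}

#' Calibration loss
#'
#' Weighted sum of squared residuals between the simulated trajectories and
#' the replicate means, over all datasets, time points and observables
#' (PHB monomer and residual maltodextrin, both mM). Residuals are scaled by
#' the maximum observed value per observable per dataset so the two
#' observables contribute comparably. Replicate standard deviations are
#' carried for reporting only, not as weights.
#'
#' @param network A `phb_network`.
#' @param params `kinetic_parameters`.
#' @param datasets List of time-course datasets (see
#'   [generate_timecourse()] / [read_timecourse()]); each carries its
#'   scenario and Vmax condition as attributes.
#' @return Scalar loss (dimensionless); `Inf` with a `diagnostic` attribute
#'   if a simulation fails.
#' @export
objective <- function(network, params, datasets) {
  r <- try(.residuals_for(network, params, datasets), silent = TRUE)
  if (inherits(r, "try-error")) {
    out <- Inf
    attr(out, "diagnostic") <- conditionMessage(attr(r, "condition"))
    return(out)
  }
  sum(r^2)
}

#' Fit kinetic parameters to time-course data
#'
#' Bounded local least squares (Levenberg-Marquardt on log-transformed
#' parameters) over the free set of a [fit_spec()], with optional seeded
#' multistart for robustness. The returned fit is never worse than its
#' starting point.
#'
#' @param network A `phb_network`.
#' @param datasets List of time-course datasets.
#' @param spec A `fit_spec`.
#' @param start `kinetic_parameters` supplying the starting point (and all
#'   fixed parameters).
#' @param n_starts Number of starts (default 5): the supplied start plus
#'   `n_starts - 1` log-uniform random points between the bounds.
#' @param seed Seed for the multistart draws (default 1).
#' @param maxiter Iteration cap per start.
#' @param rtol Integration tolerance used while fitting (tight by default:
#'   finite-difference Jacobians need residuals smooth to well below the
#'   step size).
#' @return A `phb_fit`: list with `params` (fitted `kinetic_parameters`),
#'   `estimate` (named vector over free addresses), `loss`, `start_loss`,
#'   `converged`, `starts` (per-start diagnostics).
#' @export
fit_parameters <- function(network, datasets, spec, start, n_starts = 5,
                           seed = 1, maxiter = 50, rtol = 1e-9) {
  stopifnot(inherits(spec, "fit_spec"))
  validate_parameters(start, network)
  p0 <- vapply(spec$free, function(a) param_get(start, a), numeric(1))
  lower <- if (is.null(spec$lower)) p0 / 100 else rep_len(spec$lower,
                                                          length(p0))
  upper <- if (is.null(spec$upper)) p0 * 100 else rep_len(spec$upper,
                                                          length(p0))
  if (any(p0 < lower | p0 > upper)) stop("start outside bounds")

  apply_free <- function(params, values) {
    for (i in seq_along(spec$free)) {
      params <- param_set(params, spec$free[i], values[i])
    }
    params
  }
  resid_fn <- function(logv) {
    p <- apply_free(start, exp(logv))
    r <- try(.residuals_for(network, p, datasets, rtol = rtol),
             silent = TRUE)
    if (inherits(r, "try-error")) rep(1e6, 10) else r
  }

  set.seed(seed)
  starts <- list(p0)
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1)) {
      starts[[k + 1]] <- exp(stats::runif(length(p0), log(lower), log(upper)))
    }
  }

  runs <- lapply(starts, function(s) {
    out <- try(minpack.lm::nls.lm(
      par = log(s), lower = log(lower), upper = log(upper), fn = resid_fn,
      ## epsfcn widens the finite-difference step so solver noise does not
      ## corrupt the Jacobian
      control = minpack.lm::nls.lm.control(maxiter = maxiter, epsfcn = 1e-6)
    ), silent = TRUE)
    if (inherits(out, "try-error")) {
      return(list(ok = FALSE,
                  message = conditionMessage(attr(out, "condition"))))
    }
    list(ok = TRUE, par = exp(out$par), loss = sum(out$fvec^2),
         info = out$info, message = out$message)
  })

  ok <- vapply(runs, function(r) isTRUE(r$ok), logical(1))
  if (!any(ok)) {
    stop("all fit starts failed:\n",
         paste(vapply(runs, function(r) r$message, character(1)),
               collapse = "\n"))
  }
  losses <- vapply(runs, function(r) if (isTRUE(r$ok)) r$loss else Inf,
                   numeric(1))
  best <- runs[[which.min(losses)]]
  start_loss <- sum(resid_fn(log(p0))^2)
  if (best$loss <= start_loss) {
    est <- best$par
    loss <- best$loss
  } else {
    est <- p0
    loss <- start_loss
  }
  names(est) <- spec$free
  structure(list(params = apply_free(start, est), estimate = est,
                 loss = loss, start_loss = start_loss,
                 converged = best$info %in% 1:4, starts = runs,
                 spec = spec),
            class = "phb_fit")
}

#' @export
print.phb_fit <- function(x, ...) {
  cat("phb_fit:", length(x$estimate), "free parameters; loss",
      signif(x$loss, 4), "(start", paste0(signif(x$start_loss, 4), ")"),
      if (x$converged) "converged" else "not converged", "\n")
  print(signif(x$estimate, 4))
  invisible(x)
}

#' Goodness-of-fit report
#'
#' Per-dataset root-mean-square error of the fitted (or any) model against
#' replicate means, per observable, plus an overlay table of model versus
#' data for plotting.
#'
#' @param fit A `phb_fit`, or a `kinetic_parameters` object.
#' @param network A `phb_network`.
#' @param datasets List of time-course datasets.
#' @return List with `rmse` (data frame: dataset, observable, rmse_mM) and
#'   `overlay` (data frame: dataset, time_h, observable, data_mM, model_mM).
#' @export
compare_fit <- function(fit, network, datasets) {
  params <- if (inherits(fit, "phb_fit")) fit$params else fit
  rmse <- NULL
  overlay <- NULL
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    label <- attr(ds, "label")
    if (is.null(label)) label <- paste0("dataset", i)
    sim <- .simulate_for_dataset(network, params, ds)
    means <- .dataset_means(ds)
    for (obs in unique(means$observable)) {
      sub <- means[means$observable == obs, ]
      model <- conc_at(sim, obs, sub$time_h * 60)
      rmse <- rbind(rmse, data.frame(
        dataset = label, observable = obs,
        rmse_mM = sqrt(mean((model - sub$value_mM)^2))))
      overlay <- rbind(overlay, data.frame(
        dataset = label, time_h = sub$time_h, observable = obs,
        data_mM = sub$value_mM, model_mM = model))
    }
  }
  list(rmse = rmse, overlay = overlay)
}
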