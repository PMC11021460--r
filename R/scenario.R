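## Reaction scenarios: initial conditions, timed additions, stop event.

#' Define a simulation scenario
#'
#' @param initial Named numeric vector of initial concentrations (mM) for
#'   dynamic species; merged over the standard defaults
#'   `MD = 100, Pi = 10, NADP = 2, CoA = 0.5` with all intermediates at 0.
#' @param t_end Simulation horizon in minutes (> 0).
#' @param additions List of timed substrate/cofactor additions, each a list
#'   `(time, species, amount)` with time in minutes and amount in mM, applied
#'   as concentration discontinuities (plumbing for fed-batch protocols).
#' @param stop_threshold Residual-substrate fraction triggering the stop
#'   event: the reaction ceases when maltodextrin falls to no more than this
#'   fraction of the (cumulative) initial maltodextrin. In `(0, 1]`, or `NA`
#'   to disable. Default 0.40, reflecting the observed ~60% ceiling of
#'   maltodextrin consumption by alpha-GP.
#' @param stop_reference Absolute maltodextrin reference (mM) for the stop
#'   event instead of the scenario's own cumulative initial value; used when
#'   restarting a run from an intermediate state so the event keeps its
#'   original meaning. Default `NA` (use the cumulative initial).
#' @param grid_dt Output grid spacing in minutes (default 1).
#' @param label Optional scenario label.
#' @return A `phb_scenario` object.
#' @export
scenario_spec <- function(initial = c(), t_end = 480, additions = list(),
                          stop_threshold = 0.4, stop_reference = NA_real_,
                          grid_dt = 1, label = "custom") {
  base <- c(MD = 100, Pi = 10, NADP = 2, CoA = 0.5)
  if (length(initial)) {
    if (is.null(names(initial))) stop("initial must be a named vector")
    base[names(initial)] <- initial
  }
  if (any(base < 0)) stop("initial concentrations must be >= 0")
  if (t_end <= 0) stop("t_end must be > 0")
  if (!is.na(stop_threshold) &&
      (stop_threshold <= 0 || stop_threshold > 1)) {
    stop("stop_threshold must be in (0, 1] or NA")
  }
  for (a in additions) {
    stopifnot(is.list(a), all(c("time", "species", "amount") %in% names(a)))
    if (a$time < 0 || a$amount < 0) stop("invalid timed addition")
  }
  structure(list(initial = base, t_end = t_end, additions = additions,
                 stop_threshold = stop_threshold,
                 stop_reference = stop_reference, grid_dt = grid_dt,
                 label = label),
            class = "phb_scenario")
}

#' The four study loading scenarios
#'
#' Enumerates the experimental loading conditions of the cascade as
#' (scenario, Vmax set) pairs, all with initial concentrations 100 mM
#' maltodextrin glucose equivalents, 10 mM Pi, 2 mM NADP+ and 0.5 mM CoA:
#' \describe{
#'   \item{1x}{every enzyme at Vmax 1 mM/min (FPK at the coupled 0.12);}
#'   \item{5x}{every enzyme at 5 mM/min (FPK 0.6);}
#'   \item{round1_opt}{the loadings selected by the first parameter-scan
#'     round under model1;}
#'   \item{round2_opt}{the loadings selected by the second round under
#'     model2.}
#' }
#' The optimized loading tables are read from the package's shipped tables
#' (themselves produced by [run_round()]; see `inst/extdata/models/`).
#'
#' @param t_end Horizon in minutes applied to every scenario (default 1440).
#' @return Named list of entries, each with elements `scenario`
#'   (a `phb_scenario`), `model` (parameter-set label) and `vmax`
#'   (named numeric).
#' @export
paper_scenarios <- function(t_end = 1440) {
  flat <- function(level) {
    p <- default_parameters("model1")
    get_vmax(set_vmax(p, level))
  }
  loadings <- function(round) {
    path <- system.file("extdata", "models",
                        paste0("loadings_round", round, ".yaml"),
                        package = "phbcascade")
    if (path == "") {
      path <- file.path("inst", "extdata", "models",
                        paste0("loadings_round", round, ".yaml"))
    }
    unlist(yaml::read_yaml(path)$vmax)
  }
  sc <- function(label) scenario_spec(t_end = t_end, label = label)
  list(
    `1x` = list(scenario = sc("1x"), model = "model1", vmax = flat(1)),
    `5x` = list(scenario = sc("5x"), model = "model1", vmax = flat(5)),
    round1_opt = list(scenario = sc("round1_opt"), model = "model1",
                      vmax = loadings(1)),
    round2_opt = list(scenario = sc("round2_opt"), model = "model2",
                      vmax = loadings(2))
  )
}
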