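## In silico optimization of enzyme loadings: one-at-a-time Vmax parameter
## scans with coupled bifunctional groups and the minimal-Vmax-at-99%-of-peak
## acceptance rule.

.scan_targets <- function(network) {
  ids <- reaction_ids(network)
  grouped <- c("XPK", "FPK", "TK1", "TK2")
  c(if (any(c("XPK", "FPK") %in% ids)) "PKL",
    if (any(c("TK1", "TK2") %in% ids)) "TK",
    setdiff(ids, grouped))
}

.apply_scan_vmax <- function(params, target, v) {
  if (target == "PKL") {
    ## bifunctional phosphoketolase: both activities move together at the
    ## specific-activity ratio Vmax(FPK) = 0.12 Vmax(XPK)
    if ("XPK" %in% names(params$reactions)) params$reactions$XPK$vmax <- v
    if ("FPK" %in% names(params$reactions)) {
      params$reactions$FPK$vmax <- 0.12 * v
    }
  } else if (target == "TK") {
    for (id in intersect(c("TK1", "TK2"), names(params$reactions))) {
      params$reactions[[id]]$vmax <- v
    }
  } else {
    if (!target %in% names(params$reactions)) {
      stop("unknown scan target ", target)
    }
    params$reactions[[target]]$vmax <- v
  }
  params
}

#' Define an enzyme Vmax scan
#'
#' @param target Reaction id, or one of the coupled bifunctional groups
#'   `"PKL"` (XPK and FPK at the fixed 1:0.12 Vmax ratio) or `"TK"` (TK1 and
#'   TK2 at 1:1).
#' @param grid Strictly increasing positive Vmax grid (mM/min); default
#'   integer steps 1..10.
#' @param timescale Simulation horizon per grid point, minutes.
#' @param metric `"final_PHB"` (the yield screen) or `"initial_rate"` (PHB
#'   formed in the first hour).
#' @return A `scan_spec` list.
#' @export
scan_spec <- function(target, grid = 1:10, timescale = 240,
                      metric = c("final_PHB", "initial_rate")) {
  metric <- match.arg(metric)
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing and positive")
  }
  if (timescale <= 0) stop("timescale must be > 0")
  if (metric == "initial_rate" && timescale < 60) {
    stop("initial_rate metric needs a timescale of at least 60 min")
  }
  structure(list(target = target, grid = grid, timescale = timescale,
                 metric = metric), class = "scan_spec")
}

#' Scan one enzyme's Vmax
#'
#' Runs one simulation per grid point with the target enzyme's Vmax (or the
#' coupled group's, at its fixed ratio) replaced and every other enzyme held
#' at its current value, extracts the metric, and applies the optimal-Vmax
#' rule. The shared parameter set is never mutated. A simulation failure at a
#' grid point is recorded as `NA` and the scan continues.
#'
#' @param network A `phb_network`.
#' @param params Baseline `kinetic_parameters` (current Vmax values).
#' @param scenario A `phb_scenario`; its `t_end` is overridden by the scan
#'   timescale.
#' @param spec A [scan_spec()].
#' @return A `phb_scan`: list with `grid`, `metric` (values per grid point),
#'   `optimal` (Vmax by the 99% rule), `peak`, `target`, `metric_name`.
#' @export
scan_enzyme <- function(network, params, scenario, spec) {
  stopifnot(inherits(spec, "scan_spec"))
  sc <- scenario
  sc$t_end <- spec$timescale
  vals <- rep(NA_real_, length(spec$grid))
  failures <- character()
  for (i in seq_along(spec$grid)) {
    p <- .apply_scan_vmax(params, spec$target, spec$grid[i])
    sim <- try(simulate_cascade(network, p, sc), silent = TRUE)
    if (inherits(sim, "try-error")) {
      failures <- c(failures, paste0("v=", spec$grid[i], ": ",
                                     conditionMessage(attr(sim, "condition"))))
      next
    }
    vals[i] <- switch(spec$metric,
                      final_PHB = final_phb(sim),
                      initial_rate = initial_phb_rate(sim))
  }
  res <- structure(list(grid = spec$grid, metric = vals,
                        target = spec$target, metric_name = spec$metric,
                        timescale = spec$timescale, failures = failures),
                   class = "phb_scan")
  res$peak <- if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  res$optimal <- tryCatch(optimal_vmax(res), error = function(e) NA_real_)
  res
}

#' @export
print.phb_scan <- function(x, ...) {
  cat("phb_scan of ", x$target, " (", x$metric_name, ", ", x$timescale,
      " min): optimal Vmax ", x$optimal, " mM/min (peak metric ",
      round(x$peak, 3), ")\n", sep = "")
  invisible(x)
}

#' Optimal Vmax from a scan
#'
#' The minimal Vmax on the grid whose metric is no less than
#' `threshold` (default 99%) of the highest metric achieved within the
#' scanned range. For a flat or decreasing response this degenerates to the
#' smallest grid value -- the behaviour that flags a kinetic-trap enzyme as
#' one whose loading should be reduced.
#'
#' @param scan A `phb_scan`.
#' @param threshold Fraction of the peak (default 0.99).
#' @return Optimal Vmax in mM/min.
#' @export
optimal_vmax <- function(scan, threshold = 0.99) {
  ok <- !is.na(scan$metric)
  if (!any(ok)) stop("no valid metric values in scan")
  peak <- max(scan$metric[ok])
  hit <- which(ok & scan$metric >= threshold * peak)
  scan$grid[hit[1]]
}

#' Define an optimization round
#'
#' @param round 1 or 2. Round 1 starts from a flat loading (default
#'   5 mM/min) and scans the synthase over 240 min; round 2 starts from the
#'   previous round's optima and scans the synthase over 480 min.
#' @param start Starting Vmax values: scalar (applied flat, FPK coupled) or
#'   named vector (e.g. a previous round's loading table).
#' @param yield_grid Grid for the synthase yield screen (default 1:10).
#' @param rate_grid Grid for the initial-rate scans (default 1:5).
#' @param rate_timescale Horizon of the rate scans, minutes (default 60).
#' @param phac_timescale Horizon of the synthase screen; defaults to 240
#'   (round 1) or 480 (round 2).
#' @return A `round_spec` list.
#' @export
round_spec <- function(round = 1, start = 5, yield_grid = 1:10,
                       rate_grid = 1:5, rate_timescale = 60,
                       phac_timescale = NULL) {
  stopifnot(round %in% c(1, 2))
  if (is.null(phac_timescale)) phac_timescale <- if (round == 1) 240 else 480
  structure(list(round = round, start = start, yield_grid = yield_grid,
                 rate_grid = rate_grid, rate_timescale = rate_timescale,
                 phac_timescale = phac_timescale), class = "round_spec")
}

#' Run one optimization round
#'
#' Executes the two-phase loading-optimization procedure: (1) yield screen --
#' scan the synthase Vmax on final PHB titer and fix it at its optimum;
#' (2) rate optimization -- scan every remaining enzyme (phosphoketolase and
#' transketolase as coupled groups) one at a time on the initial PHB
#' production rate, each against the baseline with the synthase fixed.
#' Accepted optima are applied explicitly at the end, never during the
#' scans, so the procedure is deterministic and order-independent.
#'
#' @param network A `phb_network`.
#' @param params `kinetic_parameters` (the calibrated model of this round).
#' @param spec A [round_spec()].
#' @param scenario Base `phb_scenario` (default: the standard 100 mM run).
#' @return List with `loading_table` (data frame: target, vmax_mM_min,
#'   loading_U_mL), `vmax` (named vector over reactions), `scans` (all
#'   `phb_scan` objects).
#' @export
run_round <- function(network, params, spec, scenario = scenario_spec()) {
  stopifnot(inherits(spec, "round_spec"))
  if (length(spec$start) == 1L && is.null(names(spec$start))) {
    params <- set_vmax(params, spec$start)
  } else {
    params <- set_vmax(params, spec$start)
  }
  scans <- list()

  has_phac <- "PhaC" %in% names(params$reactions)
  if (has_phac) {
    s1 <- scan_enzyme(network, params, scenario,
                      scan_spec("PhaC", grid = spec$yield_grid,
                                timescale = spec$phac_timescale,
                                metric = "final_PHB"))
    scans$PhaC <- s1
    params <- .apply_scan_vmax(params, "PhaC", s1$optimal)
  }

  targets <- setdiff(.scan_targets(network), "PhaC")
  optima <- c(if (has_phac) c(PhaC = scans$PhaC$optimal))
  for (tg in targets) {
    s <- scan_enzyme(network, params, scenario,
                     scan_spec(tg, grid = spec$rate_grid,
                               timescale = spec$rate_timescale,
                               metric = "initial_rate"))
    scans[[tg]] <- s
    optima[tg] <- s$optimal
  }

  final <- params
  for (tg in names(optima)) {
    final <- .apply_scan_vmax(final, tg, optima[[tg]])
  }
  vmax <- get_vmax(final)
  tab <- data.frame(target = names(optima),
                    vmax_mM_min = unname(optima),
                    loading_U_mL = vmax_to_loading(unname(optima)),
                    stringsAsFactors = FALSE)
  list(loading_table = tab, vmax = vmax, scans = scans)
}

#' Write a loading table as delimited text
#' @param round_result Result of [run_round()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_loading_table <- function(round_result, path) {
  utils::write.table(round_result$loading_table, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
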