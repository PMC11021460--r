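## Synthetic time-course datasets with the statistical structure of the
## study's triplicate measurements (small relative SDs on PHB and residual
## maltodextrin), so calibration and everything downstream is testable with
## no external data.

#' Measurement noise model
#'
#' Multiplicative Gaussian noise with an additive floor: the SD applied to a
#' true value `m` is `max(cv * m, floor)`, and draws are truncated at 0
#' (truncations are counted and reported; at the default CV they are rare).
#' The default CV of 0.02 matches the magnitude of the printed replicate
#' SDs, e.g. a titer of 74.9 +/- 0.5 mM.
#'
#' @param cv Coefficient of variation (>= 0, default 0.02).
#' @param floor Absolute SD floor in mM (>= 0, default 0.1).
#' @return A `noise_model` list.
#' @export
noise_model <- function(cv = 0.02, floor = 0.1) {
  if (cv < 0 || floor < 0) stop("cv and floor must be >= 0")
  structure(list(cv = cv, floor = floor), class = "noise_model")
}

#' Sampling design
#'
#' @param times_h Sampling times in hours (default the study's grid
#'   0,1,2,4,6,8,10,24; times beyond the scenario horizon are dropped at
#'   generation time).
#' @param replicates Number of replicates per time point (default 3).
#' @return A `design_spec` list.
#' @export
design_spec <- function(times_h = c(0, 1, 2, 4, 6, 8, 10, 24),
                        replicates = 3) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (any(times_h < 0) || is.unsorted(times_h)) {
    stop("times_h must be non-negative and increasing")
  }
  structure(list(times_h = times_h, replicates = replicates),
            class = "design_spec")
}

#' Generate a synthetic time-course dataset
#'
#' Simulates the ground-truth trajectory under the given scenario, samples
#' PHB (monomer equivalents) and residual maltodextrin (glucose equivalents)
#' at the design times, and applies independent truncated-Gaussian noise per
#' replicate and observable. The seed and generating condition are recorded
#' in the dataset's attributes (provenance `"synthetic"`).
#'
#' @param network A `phb_network`.
#' @param params `kinetic_parameters` (ground truth).
#' @param scenario A `phb_scenario`.
#' @param design A [design_spec()].
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param label Dataset label (default the scenario label).
#' @return Data frame with columns `time_h`, `observable` (`"PHB"`/`"MD"`),
#'   `replicate`, `value_mM`, carrying attributes `scenario`, `vmax`
#'   (the generating Vmax table), `label`, `provenance`, `seed`,
#'   `truncations`.
#' @examples
#' \donttest{
#' net <- build_network("full")
#' p <- set_vmax(default_parameters("model1"), 5)
#' ds <- generate_timecourse(net, p, scenario_spec(t_end = 480), seed = 42)
#' head(ds)
#' }
#' @export
generate_timecourse <- function(network, params, scenario,
                                design = design_spec(),
                                noise = noise_model(), seed = 1,
                                label = NULL) {
  stopifnot(inherits(design, "design_spec"), inherits(noise, "noise_model"))
  times_h <- design$times_h[design$times_h * 60 <= scenario$t_end]
  sim <- simulate_cascade(network, params, scenario)
  truth <- rbind(
    data.frame(time_h = times_h, observable = "PHB",
               truth = conc_at(sim, "PHB", times_h * 60)),
    data.frame(time_h = times_h, observable = "MD",
               truth = conc_at(sim, "MD", times_h * 60))
  )
  set.seed(seed)
  rows <- NULL
  truncations <- 0L
  for (i in seq_len(nrow(truth))) {
    sd <- max(noise$cv * truth$truth[i], noise$floor)
    draws <- truth$truth[i] + stats::rnorm(design$replicates, 0, sd)
    truncations <- truncations + sum(draws < 0)
    draws <- pmax(draws, 0)
    rows <- rbind(rows, data.frame(
      time_h = truth$time_h[i], observable = truth$observable[i],
      replicate = seq_len(design$replicates), value_mM = draws))
  }
  if (is.null(label)) label <- scenario$label
  structure(rows,
            scenario = scenario, vmax = get_vmax(params), label = label,
            provenance = "synthetic", seed = seed,
            truncations = truncations, class = class(rows))
}

#' Read/write time-course datasets as delimited text
#'
#' CSV with columns `time_h, observable, replicate, value_mM`; the
#' generating condition (scenario label, t_end, provenance, seed) travels in
#' `#`-prefixed header comments.
#'
#' @param dataset A time-course data frame (see [generate_timecourse()]).
#' @param path File path.
#' @return `write_timecourse`: `path`, invisibly. `read_timecourse`: the
#'   data frame (scenario attribute rebuilt from the header when present).
#' @export
write_timecourse <- function(dataset, path) {
  sc <- attr(dataset, "scenario")
  hdr <- c(
    paste0("# label: ", attr(dataset, "label")),
    paste0("# provenance: ", attr(dataset, "provenance")),
    paste0("# seed: ", attr(dataset, "seed")),
    if (!is.null(sc)) paste0("# t_end_min: ", sc$t_end),
    if (!is.null(sc)) paste0("# initial: ",
                             paste(names(sc$initial), sc$initial,
                                   sep = "=", collapse = " ")),
    if (!is.null(attr(dataset, "vmax"))) {
      paste0("# vmax: ", paste(names(attr(dataset, "vmax")),
                               attr(dataset, "vmax"),
                               sep = "=", collapse = " "))
    }
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(dataset), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                     collapse = "\n"))
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, ": "), "", m[1]) else NULL
  }
  pairs_field <- function(key) {
    raw <- get_field(key)
    if (is.null(raw)) return(NULL)
    kv <- strsplit(strsplit(raw, " ")[[1]], "=")
    stats::setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                    vapply(kv, `[`, character(1), 1))
  }
  attr(df, "label") <- get_field("label")
  attr(df, "provenance") <- get_field("provenance")
  seed <- get_field("seed")
  if (!is.null(seed)) attr(df, "seed") <- as.integer(seed)
  t_end <- get_field("t_end_min")
  init <- pairs_field("initial")
  if (!is.null(t_end)) {
    attr(df, "scenario") <- scenario_spec(
      initial = init, t_end = as.numeric(t_end),
      label = attr(df, "label"))
  }
  attr(df, "vmax") <- pairs_field("vmax")
  df
}
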