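## Kinetic parameter containers and model config files.

#' Construct a kinetic parameter set
#'
#' @param reactions Named list (by reaction id). Each entry is a list with
#'   `vmax` (mM/min), `km` (named numeric, mM, keyed by species id for every
#'   substrate and -- for reversible laws -- product slot of the reaction's
#'   rate law), `keq` (dimensionless, reversible laws only), and for the PHB
#'   synthase additionally `c_bind` (mM^n) and `n` (dimensionless exponent of
#'   the PHB concentration).
#' @param model Optional model label (e.g. `"model1"`).
#' @return A `kinetic_parameters` object.
#' @export
kinetic_parameters <- function(reactions, model = NULL) {
  obj <- structure(list(reactions = reactions, model = model),
                   class = "kinetic_parameters")
  validate_parameters(obj)
  obj
}

#' Validate kinetic parameters
#'
#' Checks positivity constraints: `Vmax >= 0`, `Km > 0`, `keq > 0`,
#' `C_bind > 0`, `n >= 0`.
#'
#' @param params A `kinetic_parameters` object.
#' @param network Optionally a `phb_network`; if given, additionally verifies
#'   that every substrate/product slot of every reaction's rate law has a Km
#'   entry (model-assembly time check, so evaluation never fails mid-run).
#' @return The object, invisibly; errors on violation.
#' @export
validate_parameters <- function(params, network = NULL) {
  stopifnot(inherits(params, "kinetic_parameters"))
  for (id in names(params$reactions)) {
    pr <- params$reactions[[id]]
    if (is.null(pr$vmax) || pr$vmax < 0) stop(id, ": Vmax must be >= 0")
    if (!is.null(pr$km) && any(pr$km <= 0)) stop(id, ": Km must be > 0")
    if (!is.null(pr$keq) && pr$keq <= 0) stop(id, ": keq must be > 0")
    if (!is.null(pr$c_bind) && pr$c_bind <= 0) stop(id, ": C_bind must be > 0")
    if (!is.null(pr$n) && pr$n < 0) stop(id, ": n must be >= 0")
  }
  if (!is.null(network)) {
    for (r in network$reactions) {
      pr <- params$reactions[[r$id]]
      if (is.null(pr)) stop("no parameters for reaction ", r$id)
      need <- unique(c(r$substrates, r$products))
      missing <- setdiff(need, names(pr$km))
      if (length(missing)) {
        stop(r$id, ": missing Km for ", paste(missing, collapse = ", "))
      }
      if (r$reversible && is.null(pr$keq)) stop(r$id, ": missing keq")
      if (r$law == "phac" && (is.null(pr$c_bind) || is.null(pr$n))) {
        stop(r$id, ": missing C_bind or n")
      }
    }
  }
  invisible(params)
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("kinetic_parameters",
      if (!is.null(x$model)) paste0("(", x$model, ")"),
      "for", length(x$reactions), "reactions\n")
  invisible(x)
}

#' Load kinetic parameters from a YAML model file
#'
#' The schema mirrors the parameter tables of the cascade model: a top-level
#' `model` label and a `reactions` map with per-reaction `vmax`, `keq`, `km`
#' (species -> mM) and, for the synthase, `c_bind` and `n`. Unknown keys are
#' rejected.
#'
#' @param path Path to a YAML file (see `system.file("extdata", "models",
#'   package = "phbcascade")` for the shipped Model 0/1/2 sets).
#' @return A `kinetic_parameters` object.
#' @export
read_parameters <- function(path) {
  doc <- yaml::read_yaml(path)
  allowed_top <- c("model", "description", "reactions")
  unknown <- setdiff(names(doc), allowed_top)
  if (length(unknown)) {
    stop("unknown top-level keys in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  allowed_rxn <- c("vmax", "keq", "km", "c_bind", "n")
  rxns <- lapply(doc$reactions, function(r) {
    ## YAML 1.1 parses a bare key `n` as a boolean; map it back
    names(r)[names(r) %in% c("FALSE", "no")] <- "n"
    unknown <- setdiff(names(r), allowed_rxn)
    if (length(unknown)) {
      stop("unknown reaction keys: ", paste(unknown, collapse = ", "))
    }
    r$km <- unlist(r$km)
    r
  })
  kinetic_parameters(rxns, model = doc$model)
}

#' Write kinetic parameters to YAML
#' @param params A `kinetic_parameters` object.
#' @param path Output path.
#' @param description Optional free-text description stored in the file.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path, description = NULL) {
  doc <- list(model = params$model)
  if (!is.null(description)) doc$description <- description
  doc$reactions <- lapply(params$reactions, function(r) {
    r$km <- as.list(r$km)
    r
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Shipped default parameter sets
#'
#' Loads one of the three semi-quantitative parameter sets shipped with the
#' package: `model0` (pre-calibration initial values: literature-style keq,
#' BRENDA-style or 0.1 mM default Km, C_bind 1000, n 1), `model1` (first
#' calibration round: reduced phosphoketolase/transketolase and
#' PTA/reductase Km values plus adjusted synthase parameters) and `model2`
#' (second round: adjusted alpha-GP keq and synthase C_bind). These are
#' package-authored synthetic stand-in values chosen so the simulated cascade
#' reproduces the reported macroscopic behaviour of the system; see the
#' vignette for the rationale behind each value.
#'
#' @param model `"model0"`, `"model1"` or `"model2"`.
#' @return A `kinetic_parameters` object.
#' @export
default_parameters <- function(model = c("model1", "model0", "model2")) {
  model <- match.arg(model)
  path <- system.file("extdata", "models", paste0(model, ".yaml"),
                      package = "phbcascade")
  if (path == "") {
    ## not installed (e.g. sourced in development): fall back to repo layout
    path <- file.path("inst", "extdata", "models", paste0(model, ".yaml"))
  }
  read_parameters(path)
}

#' Set enzyme Vmax values
#'
#' Returns a copy of `params` with maximal rates replaced. The bifunctional
#' couplings of the cascade are honoured when requested: phosphoketolase's
#' two activities keep `Vmax(FPK) = 0.12 Vmax(XPK)` (specific-activity ratio
#' of the bifunctional enzyme) and the two transketolase reactions move at a
#' 1:1 ratio.
#'
#' @param params A `kinetic_parameters` object.
#' @param vmax Either a single value applied to every reaction, or a named
#'   numeric vector of per-reaction values.
#' @param couple_fpk If `TRUE` (default) and XPK is being set, FPK is set to
#'   0.12 x the XPK value unless explicitly named in `vmax`.
#' @param couple_tk If `TRUE` (default) and TK1 is being set, TK2 follows at
#'   1:1 unless explicitly named.
#' @return Modified `kinetic_parameters`.
#' @examples
#' p <- set_vmax(default_parameters("model1"), 5)  # the "5x" loading
#' p$reactions$FPK$vmax  # 0.6
#' @export
set_vmax <- function(params, vmax, couple_fpk = TRUE, couple_tk = TRUE) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (length(vmax) == 1L && is.null(names(vmax))) {
    for (id in names(params$reactions)) params$reactions[[id]]$vmax <- vmax
    if (couple_fpk && "FPK" %in% names(params$reactions)) {
      params$reactions$FPK$vmax <- 0.12 * vmax
    }
  } else {
    if (is.null(names(vmax))) stop("vmax must be scalar or named")
    unknown <- setdiff(names(vmax), names(params$reactions))
    if (length(unknown)) stop("unknown reactions: ",
                              paste(unknown, collapse = ", "))
    for (id in names(vmax)) params$reactions[[id]]$vmax <- vmax[[id]]
    if (couple_fpk && "XPK" %in% names(vmax) && !"FPK" %in% names(vmax) &&
        "FPK" %in% names(params$reactions)) {
      params$reactions$FPK$vmax <- 0.12 * vmax[["XPK"]]
    }
    if (couple_tk && "TK1" %in% names(vmax) && !"TK2" %in% names(vmax) &&
        "TK2" %in% names(params$reactions)) {
      params$reactions$TK2$vmax <- vmax[["TK1"]]
    }
  }
  validate_parameters(params)
  params
}

#' Get the Vmax table of a parameter set
#' @param params A `kinetic_parameters` object.
#' @return Named numeric vector of Vmax values (mM/min).
#' @export
get_vmax <- function(params) {
  vapply(params$reactions, function(r) r$vmax, numeric(1))
}

#' Convert a Vmax value to an enzyme loading concentration
#'
#' Maximal rates in mM/min convert to loading concentrations in U/mL at a 1:1
#' numerical ratio (1 U/mL = 1 umol/(mL min) = 1 mM/min in the 1-mL basis of
#' the cascade reactions).
#'
#' @param vmax Numeric vector of Vmax values (mM/min), all `>= 0`.
#' @return Numeric vector of loadings in U/mL (numerically identical).
#' @export
vmax_to_loading <- function(vmax) {
  if (any(vmax < 0)) stop("Vmax must be non-negative")
  vmax
}
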