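## Rate-law library.
##
## Units: concentrations mM, Vmax mM/min (numerically equal to enzyme loading
## in U/mL, since 1 U/mL = 1 umol/(mL min) = 1 mM/min), Km mM, keq
## dimensionless (mass-action ratio at equilibrium in mM units).
##
## Law families:
##   irr_uni      Vmax S / (Km_S + S)
##   irr_bi       Vmax A B / ((Km_A + A)(Km_B + B))
##   rev_uni_uni  (Vmax/Km_S)(S - P/keq) / (1 + S/Km_S + P/Km_P)
##   rev_bi_uni   (Vmax/(Km_A Km_B))(A B - P/keq) /
##                  ((1 + A/Km_A)(1 + B/Km_B) + (1 + P/Km_P) - 1)
##   rev_bi_bi    (Vmax/(Km_A Km_B))(A B - P Q/keq) /
##                  ((1 + A/Km_A)(1 + B/Km_B) + (1 + P/Km_P)(1 + Q/Km_Q) - 1)
##   phac         Vmax S / (Km + S) * C_bind / (C_bind + PHB^n)
##
## The reversible forms are rapid-equilibrium random laws: they vanish exactly
## when the mass-action ratio equals keq, are positive below it and negative
## above it. The phac law is Henri-Michaelis-Menten damped by a product
## binding term modelling loss of synthase activity as it binds accumulating
## PHB granules; at PHB = 0 (or C_bind -> Inf) it reduces to plain HMM.

.rate_law_value <- function(law, vmax, keq, km_s, km_p, S, P, extra = NULL) {
  switch(law,
    irr_uni = vmax * S[1] / (km_s[1] + S[1]),
    irr_bi = vmax * S[1] * S[2] / ((km_s[1] + S[1]) * (km_s[2] + S[2])),
    rev_uni_uni = {
      (vmax / km_s[1]) * (S[1] - P[1] / keq) /
        (1 + S[1] / km_s[1] + P[1] / km_p[1])
    },
    rev_bi_uni = {
      (vmax / (km_s[1] * km_s[2])) * (S[1] * S[2] - P[1] / keq) /
        ((1 + S[1] / km_s[1]) * (1 + S[2] / km_s[2]) + (1 + P[1] / km_p[1]) - 1)
    },
    rev_bi_bi = {
      (vmax / (km_s[1] * km_s[2])) * (S[1] * S[2] - P[1] * P[2] / keq) /
        ((1 + S[1] / km_s[1]) * (1 + S[2] / km_s[2]) +
           (1 + P[1] / km_p[1]) * (1 + P[2] / km_p[2]) - 1)
    },
    phac = {
      vmax * S[1] / (km_s[1] + S[1]) *
        extra$c_bind / (extra$c_bind + extra$phb^extra$n)
    },
    stop("unknown rate law ", law)
  )
}

#' Evaluate the rate of one reaction
#'
#' @param reaction A reaction entry of a `phb_network` (element of
#'   `network$reactions`).
#' @param state Named numeric vector of species concentrations (mM); must
#'   contain every species the reaction's law binds to (and `PHB` for the
#'   synthase law).
#' @param params A `kinetic_parameters` object covering the reaction.
#' @return Signed rate in mM/min. Negative values occur only for reversible
#'   laws operated above their equilibrium mass-action ratio.
#' @examples
#' net <- build_network("full")
#' p <- default_parameters("model1")
#' evaluate_rate(net$reactions$PGI, c(G6P = 1, F6P = 0), p)
#' @export
evaluate_rate <- function(reaction, state, params) {
  pr <- params$reactions[[reaction$id]]
  if (is.null(pr)) stop("no kinetic parameters for reaction ", reaction$id)
  subs <- reaction$substrates
  prods <- reaction$products
  need <- unique(c(subs, prods, if (reaction$law == "phac") "PHB"))
  missing <- setdiff(need, names(state))
  if (length(missing)) {
    stop("state lacks concentrations for: ", paste(missing, collapse = ", "))
  }
  if (any(state[need] < 0)) stop("negative concentrations supplied")
  S <- unname(state[subs])
  P <- if (length(prods)) unname(state[prods]) else numeric()
  extra <- NULL
  if (reaction$law == "phac") {
    extra <- list(c_bind = pr$c_bind, n = pr$n, phb = unname(state[["PHB"]]))
  }
  .rate_law_value(reaction$law, pr$vmax, pr$keq,
                  unname(pr$km[subs]), if (length(prods)) unname(pr$km[prods]),
                  S, P, extra)
}
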