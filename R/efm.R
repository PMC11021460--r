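## Exact elementary-flux-mode analysis.
##
## Flux modes are carried as integer numerator vectors plus a scalar positive
## denominator, so every coefficient is an exact rational and S_internal %*% v
## can be verified to be identically zero (no floating-point residue). All
## magnitudes in this cascade are tiny, far below the 2^53 limit of exact
## double-precision integer arithmetic.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

.vec_gcd <- function(v) {
  v <- abs(v[v != 0])
  if (length(v) == 0) return(1)
  Reduce(.gcd2, v)
}

## continued-fraction rationalization of a (user-supplied) scalar
.as_rational <- function(x, max_den = 1e6, tol = 1e-9) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  sign <- if (x < 0) -1 else 1
  x <- abs(x)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; b <- x
  repeat {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) break
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(x - h1 / k1) < tol) break
    if (b == a) break
    b <- 1 / (b - a)
  }
  c(num = sign * h1, den = k1)
}

.new_flux_mode <- function(num, den = 1, normalization = NULL) {
  g <- .gcd2(.vec_gcd(num), den)
  if (g > 1) { num <- num / g; den <- den / g }
  structure(list(fluxes = num, den = den, normalization = normalization),
            class = "flux_mode")
}

#' Flux values of a mode
#' @param mode A `flux_mode`.
#' @return Named numeric vector of (exact rational) flux values per reaction.
#' @export
mode_fluxes <- function(mode) mode$fluxes / mode$den

#' @rdname mode_fluxes
#' @export
mode_flux_numerators <- function(mode) mode$fluxes

#' @rdname mode_fluxes
#' @export
mode_denominator <- function(mode) mode$den

#' @export
print.flux_mode <- function(x, ...) {
  v <- mode_fluxes(x)
  v <- v[v != 0]
  cat("flux_mode (", length(v), " active reactions",
      if (!is.null(x$normalization)) {
        paste0("; normalized ", x$normalization$reference, " = ",
               x$normalization$value)
      }, ")\n", sep = "")
  print(round(v, 6))
  invisible(x)
}

#' Elementary flux modes of a network
#'
#' Enumerates all elementary flux modes of the internal stoichiometric matrix
#' by the double-description (tableau) method in exact integer arithmetic.
#' Reversible reactions are split into forward/backward half-reactions for the
#' pointed-cone enumeration and recombined into single signed fluxes
#' afterwards, so a net-reverse step (such as the transketolase TK2 reaction
#' in the XPK pathway mode) is reported with a literal negative coefficient.
#'
#' @param network A `phb_network`.
#' @return List of `flux_mode` objects, deterministically ordered
#'   (lexicographically by reaction support). Each satisfies
#'   `S_internal %*% v == 0` exactly, non-negativity on irreversible
#'   reactions, and minimal support.
#' @examples
#' modes <- elementary_modes(build_network("xpk_only"))
#' length(modes)
#' @export
elementary_modes <- function(network) {
  S <- stoichiometric_matrix(network, scope = "internal")
  rxn <- reaction_ids(network)
  n <- length(rxn)
  if (n == 0) return(list())
  rev <- vapply(network$reactions, function(r) r$reversible, logical(1))

  ## split reversible columns: [all forward | backward copies of reversibles]
  Ssplit <- cbind(S, -S[, rev, drop = FALSE])
  split_origin <- c(seq_len(n), which(rev))
  split_sign <- c(rep(1, n), rep(-1, sum(rev)))
  m <- ncol(Ssplit)

  R <- diag(m)                     # rays x split fluxes
  B <- t(Ssplit)                   # rays x species residuals

  for (k in seq_len(nrow(S))) {
    bk <- B[, k]
    keep <- which(bk == 0)
    pos <- which(bk > 0)
    neg <- which(bk < 0)
    supports <- lapply(seq_len(nrow(R)), function(i) which(R[i, ] != 0))
    newR <- list(); newB <- list()
    if (length(pos) && length(neg)) {
      for (i in pos) for (j in neg) {
        cs <- union(supports[[i]], supports[[j]])
        ## minimal-support (adjacency) test against all other current rays
        minimal <- TRUE
        for (r in seq_len(nrow(R))) {
          if (r == i || r == j) next
          if (all(supports[[r]] %in% cs)) { minimal <- FALSE; break }
        }
        if (!minimal) next
        a <- bk[i]; b <- -bk[j]
        rr <- b * R[i, ] + a * R[j, ]
        rb <- b * B[i, ] + a * B[j, ]
        g <- .vec_gcd(c(rr, rb))
        if (g > 1) { rr <- rr / g; rb <- rb / g }
        newR[[length(newR) + 1L]] <- rr
        newB[[length(newB) + 1L]] <- rb
      }
    }
    R <- rbind(R[keep, , drop = FALSE], do.call(rbind, newR))
    B <- rbind(B[keep, , drop = FALSE], do.call(rbind, newB))
    if (is.null(R) || nrow(R) == 0) return(list())
  }

  ## recombine split columns into signed net fluxes
  nets <- matrix(0, nrow = nrow(R), ncol = n)
  for (c in seq_len(m)) {
    nets[, split_origin[c]] <- nets[, split_origin[c]] + split_sign[c] * R[, c]
  }
  colnames(nets) <- rxn

  keep <- rowSums(nets != 0) > 0            # drop forward/backward 2-cycles
  nets <- nets[keep, , drop = FALSE]
  if (nrow(nets) == 0) return(list())

  ## canonical sign for fully reversible modes; reduce; deduplicate
  canon <- list()
  seen <- character()
  for (i in seq_len(nrow(nets))) {
    v <- nets[i, ]
    g <- .vec_gcd(v)
    if (g > 1) v <- v / g
    supp <- which(v != 0)
    if (all(rev[supp]) && v[supp[1]] < 0) v <- -v
    key <- paste(v, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    canon[[length(canon) + 1L]] <- v
  }

  ## final strict minimal-support filter (defensive; usually a no-op)
  supps <- lapply(canon, function(v) which(v != 0))
  minimal <- rep(TRUE, length(canon))
  for (i in seq_along(canon)) for (j in seq_along(canon)) {
    if (i != j && minimal[i] &&
        length(supps[[j]]) < length(supps[[i]]) &&
        all(supps[[j]] %in% supps[[i]])) minimal[i] <- FALSE
  }
  canon <- canon[minimal]
  supps <- supps[minimal]

  ord <- order(vapply(supps, function(s) {
    paste(sprintf("%02d", s), collapse = "")
  }, character(1)))
  lapply(canon[ord], .new_flux_mode)
}

#' Normalize a flux mode to a reference reaction
#'
#' Rescales all fluxes so that the reference reaction carries the given value
#' (the paper convention reports pathway coefficients on the alpha-GP = 3
#' scale). Exact rational scaling; two successive normalizations equal a
#' single normalization to the final reference.
#'
#' @param mode A `flux_mode`.
#' @param reference Reaction id with nonzero flux in the mode.
#' @param value Target flux value (rational; default 3).
#' @return The rescaled `flux_mode`.
#' @export
normalize_mode <- function(mode, reference, value = 3) {
  stopifnot(inherits(mode, "flux_mode"))
  if (!reference %in% names(mode$fluxes)) {
    stop("unknown reference reaction ", reference)
  }
  ref_num <- mode$fluxes[[reference]]
  if (ref_num == 0) stop("reference reaction ", reference,
                         " carries zero flux; cannot normalize")
  q <- .as_rational(value)
  num <- mode$fluxes * q[["num"]] * sign(ref_num)
  den <- abs(ref_num) * q[["den"]]
  .new_flux_mode(num, den,
                 normalization = list(reference = reference, value = value))
}

.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.fraction_string <- function(num, den) {
  g <- .gcd2(num, den)
  if (g > 0) { num <- num / g; den <- den / g }
  if (den == 1) sprintf("%d", num) else sprintf("%d/%d", num, den)
}

#' Theoretical yields of a flux mode
#'
#' Computes the molar yield (100 x PHB monomer flux / glucose-unit consumption
#' flux), the carbon conversion efficiency (100 x 4 C_PHB / 6 C_glucose,
#' exactly 2/3 of the molar yield) and the CO2 released per 3 glucose units,
#' all from the boundary net exchange of the mode in exact arithmetic.
#'
#' @param mode A `flux_mode` consuming glucose units.
#' @param network The `phb_network`.
#' @return List with `molar_yield` and `carbon_yield` (exact percent values),
#'   `molar_yield_display`/`carbon_yield_display` (one decimal, half-up),
#'   `molar_yield_fraction` (string, exact), and `co2_per_3_glucose`.
#' @examples
#' net <- build_network("xpk_only")
#' m <- pathway_modes(elementary_modes(net), net)[[1]]
#' mode_yields(m, net)$molar_yield_display  # 133.3
#' @export
mode_yields <- function(mode, network) {
  nq <- net_equation(mode, network)
  glc <- if ("MD" %in% names(nq)) -nq[["MD"]] else 0
  if (glc <= 0) {
    stop("mode does not consume glucose units; molar yield is undefined")
  }
  phb <- if ("PHB" %in% names(nq)) nq[["PHB"]] else 0
  co2 <- if ("CO2" %in% names(nq)) nq[["CO2"]] else 0
  den <- attr(nq, "den")
  molar <- 100 * phb / glc
  list(
    molar_yield = molar,
    carbon_yield = molar * 4 / 6,
    molar_yield_display = .round_half_up(molar, 1),
    carbon_yield_display = .round_half_up(molar * 4 / 6, 1),
    molar_yield_fraction = .fraction_string(100 * phb * den, glc * den),
    co2_per_3_glucose = 3 * co2 / glc
  )
}

#' Cofactor moiety closure of a flux mode
#'
#' Reports the net production flux of the NADP(H), CoA and phosphate moieties,
#' computed from the boundary net exchange weighted by each boundary species'
#' moiety content. Zero for all three certifies self-sustained cofactor
#' cycling: the pathway neither consumes nor accumulates redox equivalents,
#' CoA thioester capacity, or phosphate.
#'
#' @param mode A `flux_mode` at steady state.
#' @param network The `phb_network`.
#' @return Named numeric vector with elements `NADP`, `CoA`, `phosphate`.
#' @export
cofactor_closure <- function(mode, network) {
  nq <- net_equation(mode, network)
  sp <- network$species
  rownames(sp) <- sp$id
  out <- c(NADP = 0, CoA = 0, phosphate = 0)
  for (s in names(nq)) {
    out["NADP"] <- out["NADP"] + nq[[s]] * sp[s, "NADP"]
    out["CoA"] <- out["CoA"] + nq[[s]] * sp[s, "CoA"]
    out["phosphate"] <- out["phosphate"] + nq[[s]] * sp[s, "P"]
  }
  out
}

#' Select the PHB-producing pathway modes
#'
#' Among a set of elementary modes, returns those with strictly positive flux
#' through both the substrate-consuming step (alpha-GP) and the synthase
#' (PhaC), i.e. the productive maltodextrin-to-PHB routes as opposed to
#' internal cycles.
#'
#' @param modes List of `flux_mode`s (from [elementary_modes()]).
#' @param network The `phb_network`.
#' @return List of productive `flux_mode`s (possibly of length one).
#' @export
pathway_modes <- function(modes, network) {
  Filter(function(m) {
    v <- mode_fluxes(m)
    all(c("aGP", "PhaC") %in% names(v)) && v[["aGP"]] > 0 && v[["PhaC"]] > 0
  }, modes)
}

#' Tabulate flux modes
#'
#' @param modes List of `flux_mode`s.
#' @param network The `phb_network`.
#' @return Data frame, one row per reaction and one column per mode.
#' @export
mode_table <- function(modes, network) {
  rxn <- reaction_ids(network)
  out <- data.frame(reaction = rxn, stringsAsFactors = FALSE)
  for (i in seq_along(modes)) {
    out[[paste0("mode", i)]] <- mode_fluxes(modes[[i]])[rxn]
  }
  out
}
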