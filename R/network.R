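#' @keywords internal
"_PACKAGE"

## Species and reaction catalogue for the maltodextrin -> PHB cascade.
##
## Maltodextrin is modelled as a boundary pool of glucose units (mM glucose
## equivalent) and PHB as a boundary pool of monomer units (mM monomer
## equivalent), so alpha-glucan phosphorylase is written
## MD + Pi -> G1P and the synthase 3HB-CoA -> PHB + CoA. The CoA and NADP
## moieties are carried as opaque tokens plus the explicit C/H/O/P counts of
## the transferable part, which makes every reaction exactly element-balanced
## (C, H, O, P) once H2O and a boundary H+ are included.

.species_catalogue <- function() {
  ## columns: id, name, role, C, H, O, P, CoA, NADP, initial_conc (mM)
  df <- data.frame(
    id = c("MD", "G1P", "G6P", "6PG", "Ru5P", "Xu5P", "R5P", "F6P", "E4P",
           "S7P", "G3P", "DHAP", "F16P", "AcP", "AcCoA", "AcAcCoA", "HBCoA",
           "NADP", "NADPH", "CoA", "Pi", "PHB", "CO2", "H2O", "Hplus"),
    name = c("maltodextrin glucose-unit pool", "glucose 1-phosphate",
             "glucose 6-phosphate", "6-phosphogluconate",
             "ribulose 5-phosphate", "xylulose 5-phosphate",
             "ribose 5-phosphate", "fructose 6-phosphate",
             "erythrose 4-phosphate", "sedoheptulose 7-phosphate",
             "glyceraldehyde 3-phosphate", "dihydroxyacetone phosphate",
             "fructose 1,6-bisphosphate", "acetyl phosphate", "acetyl-CoA",
             "acetoacetyl-CoA", "3-hydroxybutyryl-CoA", "NADP+", "NADPH",
             "coenzyme A", "inorganic phosphate", "PHB monomer pool",
             "carbon dioxide", "water", "proton"),
    role = "internal",
    C = c(6, 6, 6, 6, 5, 5, 5, 6, 4, 7, 3, 3, 6, 2, 2, 4, 4,
          0, 0, 0, 0, 4, 1, 0, 0),
    H = c(10, 13, 13, 13, 11, 11, 11, 13, 9, 15, 7, 7, 14, 5, 3, 5, 7,
          0, 1, 1, 3, 6, 0, 2, 1),
    O = c(5, 9, 9, 10, 8, 8, 8, 9, 7, 10, 6, 6, 12, 5, 1, 2, 2,
          0, 0, 0, 4, 2, 2, 1, 0),
    P = c(0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 1, 0, 0, 0,
          0, 0, 0, 1, 0, 0, 0, 0),
    CoA = c(rep(0, 14), 1, 1, 1, 0, 0, 1, 0, 0, 0, 0, 0),
    NADP = c(rep(0, 17), 1, 1, 0, 0, 0, 0, 0, 0),
    initial_conc = 0,
    stringsAsFactors = FALSE
  )
  df$role[df$id %in% c("MD", "PHB", "CO2", "H2O", "Hplus")] <- "boundary"
  df
}

.reaction_catalogue <- function() {
  ## stoich: named numeric, negative = consumed.
  ## law: rate-law family used by the kinetics engine.
  ## substrates/products: ordered bindings for the law's Km slots.
  r <- list(
    aGP = list(name = "alpha-glucan phosphorylase",
               stoich = c(MD = -1, Pi = -1, G1P = 1),
               reversible = TRUE, law = "rev_bi_uni",
               substrates = c("MD", "Pi"), products = "G1P"),
    PGM = list(name = "phosphoglucomutase",
               stoich = c(G1P = -1, G6P = 1),
               reversible = TRUE, law = "rev_uni_uni",
               substrates = "G1P", products = "G6P"),
    PGI = list(name = "phosphoglucose isomerase",
               stoich = c(G6P = -1, F6P = 1),
               reversible = TRUE, law = "rev_uni_uni",
               substrates = "G6P", products = "F6P"),
    G6PDH = list(name = "glucose 6-phosphate dehydrogenase",
                 stoich = c(G6P = -1, NADP = -1, H2O = -1,
                            `6PG` = 1, NADPH = 1, Hplus = 1),
                 reversible = FALSE, law = "irr_bi",
                 substrates = c("G6P", "NADP"), products = character()),
    `6PGDH` = list(name = "6-phosphogluconate dehydrogenase",
                   stoich = c(`6PG` = -1, NADP = -1,
                              Ru5P = 1, CO2 = 1, NADPH = 1, Hplus = 1),
                   reversible = FALSE, law = "irr_bi",
                   substrates = c("6PG", "NADP"), products = character()),
    RPE = list(name = "ribulose 5-phosphate 3-epimerase",
               stoich = c(Ru5P = -1, Xu5P = 1),
               reversible = TRUE, law = "rev_uni_uni",
               substrates = "Ru5P", products = "Xu5P"),
    RPI = list(name = "ribose 5-phosphate isomerase",
               stoich = c(Ru5P = -1, R5P = 1),
               reversible = TRUE, law = "rev_uni_uni",
               substrates = "Ru5P", products = "R5P"),
    TK1 = list(name = "transketolase reaction 1",
               stoich = c(Xu5P = -1, R5P = -1, S7P = 1, G3P = 1),
               reversible = TRUE, law = "rev_bi_bi",
               substrates = c("Xu5P", "R5P"), products = c("S7P", "G3P")),
    TK2 = list(name = "transketolase reaction 2",
               stoich = c(Xu5P = -1, E4P = -1, G3P = 1, F6P = 1),
               reversible = TRUE, law = "rev_bi_bi",
               substrates = c("Xu5P", "E4P"), products = c("G3P", "F6P")),
    TAL = list(name = "transaldolase",
               stoich = c(S7P = -1, G3P = -1, E4P = 1, F6P = 1),
               reversible = TRUE, law = "rev_bi_bi",
               substrates = c("S7P", "G3P"), products = c("E4P", "F6P")),
    TIM = list(name = "triose phosphate isomerase",
               stoich = c(G3P = -1, DHAP = 1),
               reversible = TRUE, law = "rev_uni_uni",
               substrates = "G3P", products = "DHAP"),
    ALD = list(name = "fructose-bisphosphate aldolase",
               stoich = c(DHAP = -1, G3P = -1, F16P = 1),
               reversible = TRUE, law = "rev_bi_uni",
               substrates = c("DHAP", "G3P"), products = "F16P"),
    FBP = list(name = "fructose 1,6-bisphosphatase",
               stoich = c(F16P = -1, H2O = -1, F6P = 1, Pi = 1),
               reversible = FALSE, law = "irr_uni",
               substrates = "F16P", products = character()),
    XPK = list(name = "phosphoketolase (Xu5P activity)",
               stoich = c(Xu5P = -1, Pi = -1, AcP = 1, G3P = 1, H2O = 1),
               reversible = FALSE, law = "irr_bi",
               substrates = c("Xu5P", "Pi"), products = character()),
    FPK = list(name = "phosphoketolase (F6P activity)",
               stoich = c(F6P = -1, Pi = -1, AcP = 1, E4P = 1, H2O = 1),
               reversible = FALSE, law = "irr_bi",
               substrates = c("F6P", "Pi"), products = character()),
    PTA = list(name = "phosphate acetyltransferase",
               stoich = c(AcP = -1, CoA = -1, AcCoA = 1, Pi = 1),
               reversible = TRUE, law = "rev_bi_bi",
               substrates = c("AcP", "CoA"), products = c("AcCoA", "Pi")),
    PhaA = list(name = "acetyl-CoA acetyltransferase",
                stoich = c(AcCoA = -2, AcAcCoA = 1, CoA = 1),
                reversible = TRUE, law = "rev_bi_bi",
                substrates = c("AcCoA", "AcCoA"),
                products = c("AcAcCoA", "CoA")),
    PhaB = list(name = "acetoacetyl-CoA reductase",
                stoich = c(AcAcCoA = -1, NADPH = -1, Hplus = -1,
                           HBCoA = 1, NADP = 1),
                reversible = FALSE, law = "irr_bi",
                substrates = c("AcAcCoA", "NADPH"), products = character()),
    PhaC = list(name = "PHB synthase",
                stoich = c(HBCoA = -1, PHB = 1, CoA = 1),
                reversible = FALSE, law = "phac",
                substrates = "HBCoA", products = character())
  )
  for (id in names(r)) r[[id]]$id <- id
  r
}

#' Valid network variant labels
#'
#' @return Character vector of the variant labels accepted by
#'   [build_network()].
#' @export
network_variants <- function() {
  c("full", "xpk_only", "fpk_only", "xpk_essential", "fpk_essential")
}

#' Build a cascade network variant
#'
#' Constructs the declarative reaction network of the 19-reaction
#' maltodextrin-to-PHB cascade, or one of its restrictions:
#' \describe{
#'   \item{full}{all 19 reactions;}
#'   \item{xpk_only}{phosphoketolase restricted to its Xu5P activity (FPK
#'     removed);}
#'   \item{fpk_only}{phosphoketolase restricted to its F6P activity (XPK
#'     removed);}
#'   \item{xpk_essential}{the essential XPK pathway: TK1, TK2, TIM, ALD, FBP,
#'     TAL, RPI, PGI and FPK removed. G3P becomes a boundary byproduct pool,
#'     and NADP+/NADPH and Pi are treated as boundary because the truncated
#'     pathway produces three NADPH (and buries one phosphate in G3P) per two
#'     glucose units with no internal consumer;}
#'   \item{fpk_essential}{the essential FPK pathway: TK1, TK2, TIM, ALD, FBP,
#'     TAL, RPI, RPE and XPK removed. Ru5P and E4P become boundary byproduct
#'     pools and Pi boundary; NADP(H) remains internal, which enforces the
#'     4:1 PGI:G6PDH split of G6P.}
#' }
#'
#' @param variant One of [network_variants()].
#' @return An object of class `phb_network` with elements `species`
#'   (data frame), `reactions` (named list) and `variant`.
#' @examples
#' net <- build_network("full")
#' length(net$reactions)  # 19
#' @export
build_network <- function(variant = "full") {
  valid <- network_variants()
  if (!is.character(variant) || length(variant) != 1L || !variant %in% valid) {
    stop("unknown network variant ", deparse(variant),
         "; valid variants are: ", paste(valid, collapse = ", "))
  }
  species <- .species_catalogue()
  reactions <- .reaction_catalogue()

  drop <- switch(variant,
    full = character(),
    xpk_only = "FPK",
    fpk_only = "XPK",
    xpk_essential = c("TK1", "TK2", "TIM", "ALD", "FBP", "TAL", "RPI",
                      "PGI", "FPK"),
    fpk_essential = c("TK1", "TK2", "TIM", "ALD", "FBP", "TAL", "RPI",
                      "RPE", "XPK")
  )
  extra_boundary <- switch(variant,
    xpk_essential = c("G3P", "NADP", "NADPH", "Pi"),
    fpk_essential = c("Ru5P", "E4P", "Pi"),
    character()
  )

  reactions <- reactions[setdiff(names(reactions), drop)]
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  species <- species[species$id %in% used, , drop = FALSE]
  species$role[species$id %in% extra_boundary] <- "boundary"
  rownames(species) <- NULL

  net <- structure(
    list(species = species, reactions = reactions, variant = variant),
    class = "phb_network"
  )
  validate_network(net)
  net
}

#' Validate a cascade network
#'
#' Checks the structural invariants: unique species ids, non-negative integer
#' compositions, every reaction referencing known species with at least one
#' reactant and one product.
#'
#' @param network A `phb_network`.
#' @return The network, invisibly; errors on violation.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "phb_network"))
  sp <- network$species
  if (anyDuplicated(sp$id)) stop("duplicated species ids")
  comp <- as.matrix(sp[, c("C", "H", "O", "P", "CoA", "NADP")])
  if (any(comp < 0) || any(comp != round(comp))) {
    stop("species compositions must be non-negative integers")
  }
  for (r in network$reactions) {
    if (!all(names(r$stoich) %in% sp$id)) {
      stop("reaction ", r$id, " references unknown species")
    }
    if (!any(r$stoich < 0) || !any(r$stoich > 0)) {
      stop("reaction ", r$id, " must consume and produce at least one species")
    }
  }
  invisible(network)
}

#' @export
print.phb_network <- function(x, ...) {
  cat("phb_network variant '", x$variant, "': ",
      nrow(x$species), " species (",
      sum(x$species$role == "internal"), " internal), ",
      length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Reaction identifiers of a network
#' @param network A `phb_network`.
#' @return Character vector of reaction ids, in canonical order.
#' @export
reaction_ids <- function(network) names(network$reactions)

#' Stoichiometric matrix
#'
#' @param network A `phb_network`.
#' @param scope `"internal"` (default) restricts rows to internal species --
#'   the matrix whose exact nullspace cone carries the elementary flux
#'   modes -- while `"all"` includes boundary species rows.
#' @return Numeric matrix, rows = species in scope, columns = reactions.
#'   Entries are exact (integer) stoichiometric coefficients.
#' @export
stoichiometric_matrix <- function(network, scope = c("internal", "all")) {
  scope <- match.arg(scope)
  sp <- network$species
  if (scope == "internal") sp <- sp[sp$role == "internal", , drop = FALSE]
  S <- matrix(0, nrow = nrow(sp), ncol = length(network$reactions),
              dimnames = list(sp$id, names(network$reactions)))
  for (j in seq_along(network$reactions)) {
    st <- network$reactions[[j]]$stoich
    keep <- names(st) %in% rownames(S)
    S[names(st)[keep], j] <- st[keep]
  }
  S
}

#' Element balance check
#'
#' Computes, for every reaction, the net change of each tracked element or
#' moiety token (C, H, O, P, CoA, NADP) implied by its stoichiometry and the
#' species compositions. A balanced reaction has all-zero deltas; nonzero
#' entries localize the imbalance. Species lacking a composition entry make
#' the affected elements `NA` ("unchecked") rather than silently zero.
#'
#' @param network A `phb_network`.
#' @return Numeric matrix, rows = reactions, columns = elements/moieties.
#' @examples
#' balance <- atom_balance_check(build_network("full"))
#' all(balance == 0)
#' @export
atom_balance_check <- function(network) {
  elements <- c("C", "H", "O", "P", "CoA", "NADP")
  sp <- network$species
  comp <- as.matrix(sp[, elements])
  rownames(comp) <- sp$id
  out <- matrix(NA_real_, nrow = length(network$reactions),
                ncol = length(elements),
                dimnames = list(names(network$reactions), elements))
  for (i in seq_along(network$reactions)) {
    st <- network$reactions[[i]]$stoich
    known <- names(st) %in% rownames(comp)
    if (all(known)) {
      out[i, ] <- as.numeric(st[known] %*% comp[names(st)[known], , drop = FALSE])
    }
  }
  out
}

#' Net boundary equation of a flux mode
#'
#' Aggregates stoichiometry times flux over all reactions of a steady-state
#' flux mode. Internal species must net to exactly zero (checked in exact
#' rational arithmetic); the boundary exchanges are returned, e.g. the
#' overall equation 3 glucose units -> 4 PHB + 2 CO2 + 3 H2O of the intact
#' pathway on the alpha-GP = 3 scale.
#'
#' @param mode A `flux_mode` (see [elementary_modes()]).
#' @param network The `phb_network` the mode belongs to.
#' @return Named numeric vector of net coefficients for boundary species
#'   (negative = consumed). Exact rationals; see `attr(, "den")` for the
#'   common denominator of the underlying integer representation.
#' @export
net_equation <- function(mode, network) {
  stopifnot(inherits(mode, "flux_mode"))
  S <- stoichiometric_matrix(network, scope = "all")
  v <- mode_flux_numerators(mode)[colnames(S)]
  num <- as.numeric(S %*% v)
  names(num) <- rownames(S)
  internal <- network$species$id[network$species$role == "internal"]
  if (any(num[internal] != 0)) {
    stop("mode is not at steady state: nonzero net flux for internal species ",
         paste(internal[num[internal] != 0], collapse = ", "))
  }
  boundary <- setdiff(rownames(S), internal)
  out <- num[boundary] / mode_denominator(mode)
  keep <- out != 0
  res <- out[keep]
  attr(res, "den") <- mode_denominator(mode)
  res
}

#' Write species and reaction tables as delimited text
#'
#' @param network A `phb_network`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (`species.tsv`, `reactions.tsv`).
#' @export
write_network_tables <- function(network, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp_path <- file.path(dir, "species.tsv")
  utils::write.table(network$species, sp_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rx <- do.call(rbind, lapply(network$reactions, function(r) {
    data.frame(id = r$id, name = r$name, reversible = r$reversible,
               law = r$law,
               equation = paste0(
                 paste(ifelse(abs(r$stoich[r$stoich < 0]) == 1, "",
                              paste0(abs(r$stoich[r$stoich < 0]), " ")),
                       names(r$stoich)[r$stoich < 0], collapse = " + "),
                 if (r$reversible) " <-> " else " -> ",
                 paste(ifelse(r$stoich[r$stoich > 0] == 1, "",
                              paste0(r$stoich[r$stoich > 0], " ")),
                       names(r$stoich)[r$stoich > 0], collapse = " + ")),
               stringsAsFactors = FALSE)
  }))
  rx_path <- file.path(dir, "reactions.tsv")
  utils::write.table(rx, rx_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sp_path, rx_path))
}
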