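# Builders for small ad-hoc networks used across tests.

toy_network <- function(species, reactions, variant = "toy") {
  # species: data.frame(id, role); compositions default to zero
  sp <- data.frame(
    id = species$id, name = species$id, role = species$role,
    C = 0, H = 0, O = 0, P = 0, CoA = 0, NADP = 0, initial_conc = 0,
    stringsAsFactors = FALSE
  )
  rx <- lapply(reactions, function(r) {
    r$name <- r$id
    if (is.null(r$law)) r$law <- "irr_uni"
    if (is.null(r$substrates)) {
      r$substrates <- names(r$stoich)[r$stoich < 0][1]
    }
    if (is.null(r$products)) r$products <- character()
    r
  })
  names(rx) <- vapply(rx, function(r) r$id, character(1))
  net <- structure(list(species = sp, reactions = rx, variant = variant),
                   class = "phb_network")
  validate_network(net)
  net
}

# A -> x -> B linear chain, both steps irreversible unless stated.
toy_chain <- function(rev = c(FALSE, FALSE)) {
  toy_network(
    data.frame(id = c("A", "x", "B"),
               role = c("boundary", "internal", "boundary")),
    list(list(id = "r1", stoich = c(A = -1, x = 1), reversible = rev[1]),
         list(id = "r2", stoich = c(x = -1, B = 1), reversible = rev[2]))
  )
}

# Random small network generator for the brute-force equivalence checks.
# Guarantees every reaction has at least one consumed and one produced
# species; coefficients in {-2,...,2}.
random_toy_network <- function(n_internal, n_reactions, rev_prob = 0.4) {
  ids <- c(paste0("m", seq_len(n_internal)), "Xin", "Xout")
  roles <- c(rep("internal", n_internal), "boundary", "boundary")
  rx <- list()
  for (j in seq_len(n_reactions)) {
    repeat {
      k <- sample(2:3, 1)
      sp <- sample(ids, k)
      coef <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
      if (any(coef < 0) && any(coef > 0)) break
    }
    rx[[j]] <- list(id = paste0("r", j),
                    stoich = stats::setNames(coef, sp),
                    reversible = stats::runif(1) < rev_prob)
  }
  toy_network(data.frame(id = ids, role = roles), rx)
}
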