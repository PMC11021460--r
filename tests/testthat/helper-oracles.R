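# Independent brute-force oracle for elementary flux modes on tiny networks:
# enumerate every reaction-support subset, keep those whose restricted
# stoichiometric matrix has a one-dimensional nullspace with all-nonzero
# entries satisfying the irreversibility signs, then filter to minimal
# supports. Entirely independent of the tableau enumeration it checks.

brute_force_efms <- function(network, tol = 1e-9) {
  S <- stoichiometric_matrix(network, "internal")
  n <- ncol(S)
  rev <- vapply(network$reactions, function(r) r$reversible, logical(1))
  candidates <- list()
  for (mask in seq_len(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    Ssub <- S[, sel, drop = FALSE]
    sv <- svd(Ssub, nu = 0, nv = ncol(Ssub))
    d <- c(sv$d, rep(0, ncol(Ssub) - length(sv$d)))
    null_dim <- sum(d < tol * max(1, max(d)))
    if (null_dim != 1) next
    v <- sv$v[, ncol(Ssub)]
    if (any(abs(v) < tol)) next      # support would be smaller than sel
    # orient: irreversible members must be positive
    irr <- !rev[sel]
    if (any(irr)) {
      if (all(v[irr] < 0)) v <- -v
      if (any(v[irr] < 0)) next      # sign-infeasible
    } else if (v[1] < 0) {
      v <- -v                        # canonical sign for reversible modes
    }
    full <- numeric(n)
    full[sel] <- v
    candidates[[length(candidates) + 1]] <- list(supp = sel, v = full)
  }
  # minimal supports only
  keep <- rep(TRUE, length(candidates))
  for (i in seq_along(candidates)) for (j in seq_along(candidates)) {
    if (i != j && keep[i] &&
        length(candidates[[j]]$supp) < length(candidates[[i]]$supp) &&
        all(candidates[[j]]$supp %in% candidates[[i]]$supp)) {
      keep[i] <- FALSE
    }
  }
  lapply(candidates[keep], function(c) {
    stats::setNames(c$v, colnames(S))
  })
}

# set comparison up to positive scaling
same_mode_set <- function(pkg_modes, oracle_modes, tol = 1e-8) {
  pv <- lapply(pkg_modes, mode_fluxes)
  if (length(pv) != length(oracle_modes)) return(FALSE)
  used <- rep(FALSE, length(oracle_modes))
  for (v in pv) {
    found <- FALSE
    for (k in seq_along(oracle_modes)) {
      if (used[k]) next
      w <- oracle_modes[[k]]
      if (!identical(unname(which(v != 0)), unname(which(w != 0)))) next
      i <- which(v != 0)[1]
      ratio <- v[i] / w[i]
      if (ratio > 0 && max(abs(v - ratio * w)) < tol * max(abs(v))) {
        used[k] <- TRUE; found <- TRUE; break
      }
    }
    if (!found) return(FALSE)
  }
  all(used)
}
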