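# Shared fixtures. Ensembles are kept at a few hundred spins: the Bloch
# properties under test are insensitive to the offset-quadrature density
# beyond ~200 points over the +-100 MHz box.

ens_fine <- function(n = 401) spin_ensemble(seq(-100, 100, length.out = n))
ens_coarse <- function(n = 201) spin_ensemble(seq(-100, 100, length.out = n))

# standard four-pulse SIFTER pathway and companions
PW_SIFTER <- "0,1;1,-1;-1,-1;-1,1"
PW_HAHN <- "0,1;1,-1"
PW_REFOC <- "0,1;1,-1;-1,1"

# brute-force oracle: all primitive positive integer length vectors up to
# `bound` with zero residual for every pathway and every sign kept fixed
brute_force_solutions <- function(signs, pathways, bound) {
  n <- length(signs)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(bound)), n)))
  keep <- apply(grid, 1, function(t)
    all(vapply(pathways, function(pw) eq8_residual(t, signs, pw),
               numeric(1)) == 0))
  sols <- grid[keep, , drop = FALSE]
  if (nrow(sols) == 0L) return(matrix(numeric(0), 0, n))
  gcd2 <- function(a, b) { while (b > 0) { r <- a %% b; a <- b; b <- r }; a }
  prim <- unique(t(apply(sols, 1, function(v) v / Reduce(gcd2, v))))
  prim[order(apply(prim, 1, paste, collapse = ",")), , drop = FALSE]
}

solver_integer_solutions <- function(signs, pathways, bound) {
  sol <- solve_ratios(length(signs), signs, pathways, max_coef = bound)
  if (!sol$feasible) return(matrix(numeric(0), 0, length(signs)))
  m <- do.call(rbind, lapply(sol$solutions, `[[`, "integer_form"))
  m[order(apply(m, 1, paste, collapse = ",")), , drop = FALSE]
}
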