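# Independent oracles used across tests.

# element/charge balance residual of a half reaction, recomputed from
# compositions (independent of the balancing code)
half_reaction_residual <- function(hr) {
  reg <- compound_registry()
  species <- list(donor = hr$donor, H2O = reg$H2O, HCO3 = reg$HCO3,
                  NH4 = compound("NH4", "NH4", 1L), `H+` = reg$`H+`)
  bal <- c(C = 0, H = 0, O = 0, N = 0, charge = 0)
  for (nm in names(hr$coefficients)) {
    cp <- species[[nm]]
    bal[1:4] <- bal[1:4] + hr$coefficients[[nm]] * cp$composition
    bal["charge"] <- bal["charge"] + hr$coefficients[[nm]] * cp$charge
  }
  bal["charge"] <- bal["charge"] - hr$electrons  # electrons on the RHS
  max(abs(bal))
}

# fine-grained Riemann sum on the piecewise-linear interpolant of a
# trace; the refined grid keeps every original knot so the interpolant
# is represented exactly
riemann_charge <- function(trace, refine = 100L) {
  t <- trace$time_s
  tt <- unique(sort(unlist(lapply(seq_len(length(t) - 1), function(k)
    seq(t[k], t[k + 1], length.out = refine + 1)))))
  ii <- approx(t, trace$current_A, tt)$y
  sum(diff(tt) * (head(ii, -1) + tail(ii, -1)) / 2)
}

# naive per-sample diversity formulas, written independently
naive_diversity <- function(counts, base = 2) {
  N <- sum(counts)
  p <- counts[counts > 0] / N
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s <- sum(counts > 0)
  list(observed = s,
       chao1 = s + f1 * (f1 - 1) / (2 * (f2 + 1)),
       shannon = -sum(p * log(p) / log(base)),
       simpson = 1 - sum(p * p),
       coverage = 100 * (1 - f1 / N))
}

# build three OTU id sets with prescribed Venn region sizes
# (regions: a,b,c only; ab, ac, bc pairs; abc core)
make_venn_sets <- function(a_only, b_only, c_only, ab, ac, bc, abc) {
  n <- 0
  take <- function(k) {
    ids <- as.character(seq(n + 1, n + k))
    n <<- n + k
    ids
  }
  core <- take(abc)
  p_ab <- take(ab); p_ac <- take(ac); p_bc <- take(bc)
  list(a = c(core, p_ab, p_ac, take(a_only)),
       b = c(core, p_ab, p_bc, take(b_only)),
       c = c(core, p_ac, p_bc, take(c_only)))
}
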