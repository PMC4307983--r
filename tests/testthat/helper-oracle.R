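# Independent dense-grid equilibrium oracle.
#
# At steady state the full system collapses to a 1-D self-consistency
# relation in free G4: the repressor level and every total pool are explicit
# functions of free G4, and the G80 conservation law closes the loop.  The
# oracle enumerates roots by sign changes on a dense grid, a brute-force
# path entirely separate from the package's multistart Newton search.

oracle_equilibria <- function(p, glu, gal, ngrid = 2000) {
  ha <- function(x, K, n) ifelse(x <= 0, 0, x^n / (K^n + x^n))
  hr <- function(x, K, n) K^n / (K^n + pmax(x, 0)^n)
  if (p$variant == "dilution") {
    hg <- ha(glu, p$K_g, p$n_g)
    d1 <- p$d * (1 + p$s1 * hg); d80 <- p$d * (1 + p$s80 * hg)
    d4 <- p$d * (1 + p$s4 * hg)
    rstar <- 0
    prod1 <- function(g4f) p$b1 + p$alpha1 * ha(g4f, p$K_A, p$n_A)
    prod80 <- function(g4f) p$b80 + p$alpha80 * ha(g4f, p$K_A, p$n_A)
    G4T <- (p$b4 + p$alpha4) / d4
  } else {
    d1 <- d80 <- d4 <- p$d
    rstar <- p$R_total * p$k_R * glu / (p$k_R * glu + p$k_Rd)
    prod1 <- function(g4f) p$b1 +
      p$alpha1 * ha(g4f, p$K_A, p$n_A) * hr(rstar, p$K_R1, p$n_R)
    prod80 <- if (p$variant == "gal80_open_loop")
      function(g4f) p$g80_const
    else function(g4f) p$b80 + p$alpha80 * ha(g4f, p$K_A, p$n_A)
    G4T <- (p$b4 + p$alpha4 * hr(rstar, p$K_R4, p$n_R)) / d4
  }
  resid <- function(g4f) {
    G1T <- prod1(g4f) / d1
    G80T <- prod80(g4f) / d80
    g1s <- G1T * ha(gal, p$K_gal, p$m)
    g80f <- p$K_seq4 * (G4T - g4f) / g4f
    g80f + g1s * g80f / (p$K_seq80 + g80f) + (G4T - g4f) - G80T
  }
  g <- G4T * exp(seq(log(1e-10), 0, length.out = ngrid))
  v <- vapply(g, resid, 0)
  idx <- which(diff(sign(v)) != 0)
  g4f <- vapply(idx, function(i)
    uniroot(resid, c(g[i], g[i + 1]), tol = 1e-12)$root, 0)
  data.frame(g4_free = g4f,
             g1_total = vapply(g4f, function(x) prod1(x) / d1, 0),
             r_active = rstar)
}

# expected regime sequence along a glucose grid from the oracle's counts
oracle_counts <- function(p, gal, glu_grid) {
  vapply(glu_grid, function(glu) nrow(oracle_equilibria(p, glu, gal)), 0L)
}
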