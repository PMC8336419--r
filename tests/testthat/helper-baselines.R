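# Shared parameter sets used throughout the suite. The "fig4/fig6/fig8"
# names refer to the three study regimes: cooperation favoured at medium
# r and m (r=8, m=8), disfavoured at large r and small m (r=10, m=2), and
# disfavoured at medium r and m (r=5, m=5), all with d=15, c=1, tau=0.25,
# alpha=1, N=100.

baseline_gp <- function(m = 8, r = 8, d = 15, N = 100, c = 1, tau = 0.25) {
  game_params(N = N, d = d, m = m, r = r, c = c, tau = tau)
}

baseline_ap <- function(omega = 4, alpha = 1, delta = 0.03) {
  aspiration_params(omega = omega, alpha = alpha, delta = delta)
}

regime_sets <- list(
  fig4 = list(gp = function() baseline_gp(m = 8, r = 8),
              omegas = c(2, 4, 6, 9)),
  fig6 = list(gp = function() baseline_gp(m = 2, r = 10),
              omegas = c(1.5, 3, 6, 9)),
  fig8 = list(gp = function() baseline_gp(m = 5, r = 5),
              omegas = c(4, 6, 9))
)

# Independent stationary-law oracle: build the full (N+1)x(N+1) tridiagonal
# transition matrix from transition_probs() and solve the stationary
# equations directly (least squares with the normalization row appended).
stationary_oracle <- function(gp, ap) {
  N <- gp$N
  P <- matrix(0, N + 1L, N + 1L)
  for (i in 0:N) {
    tr <- transition_probs(i, gp, ap)
    if (i < N) P[i + 1L, i + 2L] <- tr[["Tplus"]]
    if (i > 0) P[i + 1L, i] <- tr[["Tminus"]]
    P[i + 1L, i + 1L] <- tr[["Tzero"]]
  }
  A <- rbind(t(P) - diag(N + 1L), rep(1, N + 1L))
  b <- c(rep(0, N + 1L), 1)
  as.vector(qr.solve(A, b))
}
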