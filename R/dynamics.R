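#' Aspiration-dynamics transition probabilities
#'
#' One-step transition probabilities of the birth-death chain on the number
#' of cooperators \code{i}. With probability \eqn{1-\delta} the chosen
#' individual compares its expected payoff \eqn{\pi} to the aspiration level
#' \eqn{\alpha} through the Fermi function
#' \eqn{1/(1+e^{-\omega(\alpha-\pi)})} and switches when dissatisfied; with
#' probability \eqn{\delta} it switches at random (mutation):
#' \deqn{T_i^+ = (1-\delta)\frac{N-i}{N}\frac{1}{1+e^{-\omega(\alpha-\pi_B(i))}}
#'       + \delta\frac{N-i}{N},}
#' and symmetrically for \eqn{T_i^-} with \eqn{i/N} and \eqn{\pi_A(i)};
#' \eqn{T_i^0 = 1 - T_i^+ - T_i^-}.
#'
#' @param i Number of cooperators, \code{0 <= i <= N}.
#' @param gp A [game_params()] object.
#' @param ap An [aspiration_params()] object.
#' @param tab A [payoff_table()]; defaults to the redistribution table of
#'   \code{gp}.
#'
#' @return Named numeric vector \code{c(Tplus, Tminus, Tzero)}, each in
#'   \code{[0, 1]}. \code{Tplus} is 0 at \code{i = N} and \code{Tminus} is 0
#'   at \code{i = 0}.
#' @examples
#' gp <- game_params(N = 100, d = 15, m = 8, r = 8, c = 1, tau = 0.25)
#' ap <- aspiration_params(omega = 4, alpha = 1, delta = 0.03)
#' transition_probs(50, gp, ap)
#' @export
transition_probs <- function(i, gp, ap, tab = payoff_table(gp)) {
  stopifnot(inherits(gp, "game_params"), inherits(ap, "aspiration_params"))
  if (length(i) != 1L || i < 0L || i > gp$N)
    stop("i must be a single count in 0..N", call. = FALSE)
  N <- gp$N
  tp <- if (i == N) 0 else {
    fB <- fermi(expected_payoff_B(i, gp, tab), ap)
    (1 - ap$delta) * (N - i) / N * fB + ap$delta * (N - i) / N
  }
  tm <- if (i == 0L) 0 else {
    fA <- fermi(expected_payoff_A(i, gp, tab), ap)
    (1 - ap$delta) * i / N * fA + ap$delta * i / N
  }
  c(Tplus = tp, Tminus = tm, Tzero = 1 - tp - tm)
}

# Fermi switching probability 1 / (1 + exp(-omega * (alpha - pi))),
# evaluated through plogis for numerical stability at large |omega * gap|.
fermi <- function(pi_val, ap) {
  stats::plogis(ap$omega * (ap$alpha - pi_val))
}

#' Stepwise stationary ratio of the aspiration chain
#'
#' The detailed-balance ratio \eqn{h(i,\omega) = T_i^+ / T_{i+1}^-} of the
#' birth-death chain, in the closed form
#' \deqn{h(i,\omega) = \frac{N-i}{i+1}\cdot
#'   \frac{1+e^{-\omega(\alpha-\pi_A(i+1))}}{1+e^{-\omega(\alpha-\pi_B(i))}}
#'   \cdot
#'   \frac{1+\delta e^{-\omega(\alpha-\pi_B(i))}}
#'        {1+\delta e^{-\omega(\alpha-\pi_A(i+1))}}.}
#' Evaluated in log space, so it is finite and positive for any
#' \eqn{\omega}.
#'
#' @inheritParams transition_probs
#' @param i Index \code{0 <= i <= N-1}; may be a vector.
#' @return Positive ratio(s) \eqn{h(i,\omega)}.
#' @export
h_factor <- function(i, gp, ap, tab = payoff_table(gp)) {
  if (any(i < 0L | i > gp$N - 1L))
    stop("i must lie in 0..N-1", call. = FALSE)
  prof <- payoff_profiles(gp, tab)
  exp(log_h(gp, ap, prof)[i + 1L])
}

# log h(i, omega) for i = 0..N-1 as a vector. xA = -omega*(alpha - pi_A(i+1))
# and xB likewise for pi_B(i); each factor becomes a difference of
# softplus terms: log(1 + e^x) = softplus(x), log(1 + delta e^x) =
# softplus(x + log delta) (0 when delta = 0).
log_h <- function(gp, ap, prof = payoff_profiles(gp)) {
  N <- gp$N
  i <- 0:(N - 1L)
  xA <- -ap$omega * (ap$alpha - prof$piA_next)
  xB <- -ap$omega * (ap$alpha - prof$piB)
  lh <- log(N - i) - log(i + 1) + softplus(xA) - softplus(xB)
  if (ap$delta > 0) {
    ld <- log(ap$delta)
    lh <- lh + softplus(xB + ld) - softplus(xA + ld)
  }
  lh
}

# Numerically safe log(1 + exp(x)).
softplus <- function(x) {
  out <- numeric(length(x))
  big <- x > 33          # exp(-x) below double eps: softplus(x) = x
  out[big] <- x[big]
  out[!big] <- log1p(exp(x[!big]))
  out
}

# log(sum(exp(x))) without overflow.
log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Stationary distribution of the aspiration chain
#'
#' The mutation-selection stationary law \eqn{\vartheta_j} of the number of
#' cooperators \eqn{j = 0,\dots,N}, obtained from detailed balance as the
#' normalized running product \eqn{\vartheta_j \propto \prod_{i<j}
#' h(i,\omega)}. Products are accumulated as sums of \eqn{\log h} and
#' normalized by log-sum-exp, so no overflow can occur even for strong
#' selection.
#'
#' @inheritParams transition_probs
#' @param log_h_values Optional precomputed vector of \eqn{\log h(i,\omega)}
#'   for \code{i = 0..N-1}; used by the strong-selection approximation to
#'   reuse this machinery with its own ratio.
#' @return An object of class \code{"stationary_distribution"}: list with
#'   \code{probs} (length \code{N+1}, summing to 1) and \code{j = 0:N}.
#' @examples
#' gp <- game_params(N = 100, d = 15, m = 8, r = 8, c = 1, tau = 0.25)
#' ap <- aspiration_params(omega = 4, alpha = 1, delta = 0.03)
#' th <- stationary_distribution(gp, ap)
#' sum(th$probs)
#' @export
stationary_distribution <- function(gp, ap, tab = payoff_table(gp),
                                    log_h_values = NULL) {
  stopifnot(inherits(gp, "game_params"), inherits(ap, "aspiration_params"))
  lh <- if (is.null(log_h_values)) log_h(gp, ap, payoff_profiles(gp, tab))
        else log_h_values
  if (anyNA(lh))
    stop("NaN in log h(i, omega); parameters: N=", gp$N, " d=", gp$d,
         " m=", gp$m, " r=", gp$r, " c=", gp$c, " tau=", gp$tau,
         " omega=", ap$omega, " alpha=", ap$alpha, " delta=", ap$delta,
         call. = FALSE)
  ltheta <- c(0, cumsum(lh))            # log theta_j up to a constant
  ltheta <- ltheta - log_sum_exp(ltheta)
  structure(list(probs = exp(ltheta), j = 0:gp$N),
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, ...) {
  N <- length(x$probs) - 1L
  cat("Stationary distribution over j = 0..", N, " cooperators\n", sep = "")
  cat(sprintf("  mean fraction %.4f, mode at j = %d\n",
              sum(x$j / N * x$probs), x$j[which.max(x$probs)]))
  invisible(x)
}

#' Exact average abundance of cooperators
#'
#' The expected long-run fraction of cooperators
#' \eqn{X_A(\omega) = \sum_j (j/N)\,\vartheta_j} under the exact
#' detailed-balance stationary distribution.
#'
#' @inheritParams transition_probs
#' @return An [abundance_result()] with \code{method = "exact"}.
#' @examples
#' gp <- game_params(N = 100, d = 15, m = 8, r = 8, c = 1, tau = 0.25)
#' ap <- aspiration_params(omega = 4, alpha = 1, delta = 0.03)
#' average_abundance_exact(gp, ap)
#' @export
average_abundance_exact <- function(gp, ap, tab = payoff_table(gp)) {
  th <- stationary_distribution(gp, ap, tab)
  abundance_result(sum(th$j / gp$N * th$probs), method = "exact")
}

#' Average abundance result container
#'
#' @param value The average abundance \eqn{X_A} in \code{[0, 1]}.
#' @param method One of \code{"exact"}, \code{"weak"}, \code{"strong"},
#'   \code{"piecewise"}, \code{"monte_carlo"}.
#' @param diagnostics Optional [approximation_validity()] report (attached by
#'   the approximation methods).
#' @return An object of class \code{"abundance_result"}.
#' @details The value is truncated to \code{[0, 1]}: the weak-selection
#'   linear expansion can leave the unit interval when extrapolated far
#'   beyond its regime, and an abundance is a population fraction.
#' @export
abundance_result <- function(value, method, diagnostics = NULL) {
  method <- match.arg(method,
                      c("exact", "weak", "strong", "piecewise", "monte_carlo"))
  if (!is.finite(value))
    stop("non-finite abundance value", call. = FALSE)
  structure(list(value = min(max(value, 0), 1), method = method,
                 diagnostics = diagnostics),
            class = "abundance_result")
}

#' @export
print.abundance_result <- function(x, ...) {
  cat(sprintf("Average abundance X_A = %.6f  [method: %s]\n",
              x$value, x$method))
  if (!is.null(x$diagnostics))
    cat("  validity regime:", x$diagnostics$regime, "\n")
  invisible(x)
}
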