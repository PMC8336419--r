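#' Weak-selection average abundance (closed form)
#'
#' First-order expansion of the average abundance in the selection intensity
#' \eqn{\omega}, valid as \eqn{\omega \to 0}. Two equivalent evaluation
#' paths are provided: the threshold-game closed form
#' \deqn{X_A = \tfrac12 + \omega\,\frac{1-\delta}{1+\delta}\,
#'   \frac{1}{2^{d+2}}\,\frac{c}{d}\left[
#'   \left(\frac{m(r-\tau)+d\tau}{r-\tau+d\tau}\binom{d-1}{m-1}
#'   + \sum_{k=m}^{d-1}\binom{d-1}{k}\right)(r-\tau+d\tau)
#'   - d\sum_{k=m}^{d-1}\binom{d-1}{k}\right],}
#' and the generic payoff-difference form
#' \eqn{X_A = \tfrac12 + \omega\,\frac{1-\delta}{1+\delta}\,
#' 2^{-(d+2)} \sum_k \binom{d-1}{k}(a_k - b_k)} applied to any payoff
#' table. For threshold-game tables the two agree to machine precision.
#'
#' @inheritParams transition_probs
#' @param path \code{"threshold"} for the closed form, \code{"generic"} for
#'   the payoff-table sum.
#' @return An [abundance_result()] with \code{method = "weak"}.
#' @examples
#' gp <- game_params(N = 100, d = 15, m = 1, r = 8, c = 1, tau = 0.25)
#' ap <- aspiration_params(omega = 0.5, alpha = 1, delta = 0.03)
#' weak_selection_abundance(gp, ap)   # ~ 0.4863
#' @export
weak_selection_abundance <- function(gp, ap, tab = payoff_table(gp),
                                     path = c("threshold", "generic")) {
  stopifnot(inherits(gp, "game_params"), inherits(ap, "aspiration_params"))
  path <- match.arg(path)
  pref <- ap$omega * (1 - ap$delta) / (1 + ap$delta) / 2^(gp$d + 2)
  x <- if (path == "generic") {
    k <- 0:(gp$d - 1L)
    0.5 + pref * sum(choose(gp$d - 1, k) * (tab$a - tab$b))
  } else {
    d <- gp$d; m <- gp$m; r <- gp$r; tau <- gp$tau
    s <- upper_tail_binom_sum(d, m)
    0.5 + pref * gp$c / d *
      (((m * (r - tau) + d * tau) / (r - tau + d * tau) * choose(d - 1, m - 1)
        + s) * (r - tau + d * tau) - d * s)
  }
  abundance_result(x, method = "weak")
}

# sum_{k=m}^{d-1} C(d-1, k); empty (0) when m = d.
upper_tail_binom_sum <- function(d, m) {
  if (m > d - 1L) 0 else sum(choose(d - 1, m:(d - 1L)))
}

#' Strong-selection stationary ratio
#'
#' The large-\eqn{\omega} approximation \eqn{h_a(i,\omega)} of the stepwise
#' stationary ratio, obtained by dropping the 1 against the dominant
#' exponentials in the Fermi factors:
#' \deqn{h_a(i,\omega) = \frac{N-i}{i+1}\cdot
#'   \frac{1+\delta e^{-\omega(\alpha-\pi_B(i))}}
#'        {1+\delta e^{-\omega(\alpha-\pi_A(i+1))}}\cdot
#'   e^{-\omega(\pi_B(i)-\pi_A(i+1))}.}
#' Evaluated in log space.
#'
#' @inheritParams h_factor
#' @return Positive ratio(s) \eqn{h_a(i,\omega)}.
#' @export
strong_h_factor <- function(i, gp, ap, tab = payoff_table(gp)) {
  if (any(i < 0L | i > gp$N - 1L))
    stop("i must lie in 0..N-1", call. = FALSE)
  prof <- payoff_profiles(gp, tab)
  exp(log_h_strong(gp, ap, prof)[i + 1L])
}

# log h_a(i, omega) for i = 0..N-1.
log_h_strong <- function(gp, ap, prof = payoff_profiles(gp)) {
  N <- gp$N
  i <- 0:(N - 1L)
  xA <- -ap$omega * (ap$alpha - prof$piA_next)
  xB <- -ap$omega * (ap$alpha - prof$piB)
  lh <- log(N - i) - log(i + 1) - ap$omega * (prof$piB - prof$piA_next)
  if (ap$delta > 0) {
    ld <- log(ap$delta)
    lh <- lh + softplus(xB + ld) - softplus(xA + ld)
  }
  lh
}

#' Strong-selection average abundance
#'
#' The exact stationary-sum formula evaluated with the strong-selection
#' ratio [strong_h_factor()] in place of the exact ratio. Attaches an
#' [approximation_validity()] report describing whether the parameters are
#' in the regime where the approximation is trustworthy.
#'
#' @inheritParams transition_probs
#' @return An [abundance_result()] with \code{method = "strong"} and a
#'   validity report in \code{$diagnostics}.
#' @export
strong_selection_abundance <- function(gp, ap, tab = payoff_table(gp)) {
  prof <- payoff_profiles(gp, tab)
  th <- stationary_distribution(gp, ap, tab,
                                log_h_values = log_h_strong(gp, ap, prof))
  abundance_result(sum(th$j / gp$N * th$probs), method = "strong",
                   diagnostics = approximation_validity(gp, ap, tab))
}

#' Piecewise combined abundance estimator
#'
#' Uses the weak-selection closed form below \code{omega_switch} and the
#' strong-selection approximation above it. The default switch point of 2
#' reflects where the strong approximation typically becomes reliable at the
#' baseline parameters; it is a user-settable convenience, not a claim.
#'
#' @inheritParams transition_probs
#' @param omega_switch Selection intensity at which to change formula
#'   (default 2).
#' @return An [abundance_result()] with \code{method = "piecewise"}.
#' @export
piecewise_abundance <- function(gp, ap, omega_switch = 2,
                                tab = payoff_table(gp)) {
  res <- if (ap$omega <= omega_switch)
    weak_selection_abundance(gp, ap, tab)
  else strong_selection_abundance(gp, ap, tab)
  abundance_result(res$value, method = "piecewise",
                   diagnostics = res$diagnostics)
}

#' Validity diagnostics for the strong-selection approximation
#'
#' The strong-selection ratio is derived by assuming
#' \eqn{e^{-\omega(\alpha-\pi)} \gg 1} and
#' \eqn{\delta e^{-\omega(\alpha-\pi)} > 1} along the chain, i.e. expected
#' payoffs well above the aspiration level at a selection intensity
#' exceeding \eqn{\ln(1/\delta)/(\pi - \alpha)}. This report computes the
#' minimum scaled payoff-aspiration gap \eqn{\min_i \omega(\pi(\cdot)-\alpha)}
#' over both payoff profiles, the implied selection-intensity floor, and a
#' regime tag: \code{"strong_ok"} when every gap is positive and
#' \eqn{\omega} clears the floor, \code{"weak_ok"} when \eqn{\omega \le 1}
#' (the linearization regime), \code{"neither"} otherwise — the latter is
#' the known failure regime (small \eqn{r}, large \eqn{m}, appreciable
#' mutation), where the approximation is meaningless.
#'
#' @inheritParams transition_probs
#' @return An object of class \code{"validity_report"}: list with
#'   \code{min_scaled_gap}, \code{omega_floor} (may be \code{Inf}), and
#'   \code{regime}.
#' @export
approximation_validity <- function(gp, ap, tab = payoff_table(gp)) {
  prof <- payoff_profiles(gp, tab)
  gaps <- c(prof$piA_next, prof$piB) - ap$alpha
  min_scaled_gap <- ap$omega * min(gaps)
  pos <- gaps[gaps > 0]
  omega_floor <- if (ap$delta <= 0 || ap$delta >= 1) {
    if (length(pos)) 0 else Inf
  } else if (length(pos)) log(1 / ap$delta) / min(pos) else Inf
  regime <- if (min_scaled_gap > 0 && ap$omega > omega_floor) "strong_ok"
            else if (ap$omega <= 1) "weak_ok"
            else "neither"
  structure(list(min_scaled_gap = min_scaled_gap, omega_floor = omega_floor,
                 regime = regime),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf(
    "Approximation validity: regime %s (min scaled gap %.3g, omega floor %.3g)\n",
    x$regime, x$min_scaled_gap, x$omega_floor))
  invisible(x)
}

#' Critical multiplication factor
#'
#' The value of \eqn{r} at which the weak-selection abundance equals 1/2,
#' separating the regime where cooperation is favoured by selection
#' (\eqn{X_A > 1/2}, requires \eqn{r} above the critical value) from where
#' it is not:
#' \deqn{r^* = \frac{(m-d)\tau\binom{d-1}{m-1}
#'   + (\tau-d\tau+d)\sum_{k=m}^{d-1}\binom{d-1}{k}}
#'   {m\binom{d-1}{m-1} + \sum_{k=m}^{d-1}\binom{d-1}{k}}.}
#'
#' @param d Group size (integer \code{>= 2}).
#' @param m Threshold, \code{1 <= m <= d-1} (\code{m = d} makes the sums
#'   empty and the condition degenerate).
#' @param tau Redistribution proportion in \code{[0, 1]}.
#' @return The critical multiplication factor (a single number).
#' @examples
#' critical_r(d = 15, m = 8, tau = 0.25)  # ~ 2.02
#' @export
critical_r <- function(d, m, tau) {
  check_count(d, "d", lower = 2L); check_count(m, "m", lower = 1L)
  check_scalar(tau, "tau")
  if (m >= d)
    stop("critical_r requires m <= d-1: at m = d the defector payoff ",
         "vector is identically zero and the critical condition degenerates",
         call. = FALSE)
  s <- upper_tail_binom_sum(d, m)
  ((m - d) * tau * choose(d - 1, m - 1) + (tau - d * tau + d) * s) /
    (m * choose(d - 1, m - 1) + s)
}

#' Is cooperation favoured by selection?
#'
#' Cooperation (strategy A) is favoured when the stationary chain spends
#' more than half its mass-weighted time on cooperators,
#' \eqn{X_A(\omega) > 1/2}. In \code{"weak"} mode this reduces to comparing
#' \eqn{r} with [critical_r()]; in \code{"exact"} mode the exact abundance
#' is compared with 1/2.
#'
#' @inheritParams transition_probs
#' @param method \code{"weak"} or \code{"exact"}.
#' @param tol Abundances within \code{tol} of 1/2 (exact mode) report
#'   \code{favoured = NA} ("neutral").
#' @return List with \code{favoured} (logical, \code{NA} if neutral) and the
#'   signed \code{margin} (\eqn{r - r^*} in weak mode, \eqn{X_A - 1/2} in
#'   exact mode).
#' @export
is_A_favoured <- function(gp, ap, method = c("weak", "exact"), tol = 1e-9) {
  method <- match.arg(method)
  margin <- if (method == "weak") {
    gp$r - critical_r(gp$d, gp$m, gp$tau)
  } else {
    average_abundance_exact(gp, ap)$value - 0.5
  }
  favoured <- if (method == "exact" && abs(margin) < tol) NA else margin > 0
  list(favoured = favoured, margin = margin)
}

#' Abundance-maximising threshold under weak selection
#'
#' Closed-form expression for the threshold \eqn{m} at which the
#' weak-selection average abundance is maximal:
#' \deqn{m^* = \left\lfloor \frac{d}{4(r-\tau)}\left[r - 2\tau - 1 +
#'   \sqrt{(r-2\tau+3)^2 + 8(\tau-1)}\right]\right\rfloor + 1.}
#'
#' @param d Group size.
#' @param r Multiplication factor.
#' @param tau Redistribution proportion.
#' @return The optimal threshold (integer).
#' @examples
#' optimal_threshold(d = 15, r = 8, tau = 0.25)  # 9
#' @export
optimal_threshold <- function(d, r, tau) {
  check_count(d, "d", lower = 2L)
  check_scalar(r, "r"); check_scalar(tau, "tau")
  radicand <- (r - 2 * tau + 3)^2 + 8 * (tau - 1)
  if (radicand < 0)
    stop("negative radicand (", radicand,
         "): no real abundance-maximising threshold at these parameters",
         call. = FALSE)
  as.integer(floor(d / (4 * (r - tau)) *
                     (r - 2 * tau - 1 + sqrt(radicand))) + 1L)
}
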