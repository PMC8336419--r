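#' Build the payoff table of the threshold public goods game
#'
#' Computes the multi-player game payoff vectors \eqn{a_k} (cooperator) and
#' \eqn{b_k} (defector), where \eqn{k = 0, \dots, d-1} counts cooperating
#' co-players in the group. Below the threshold nobody is paid. At or above
#' it, with the redistribution mechanism each member pays a fraction
#' \eqn{\tau} of its gross payoff into a group pot that is shared equally, so
#' \deqn{a_k = \frac{k+1}{d}(r-\tau)c + \tau c \quad (k \ge m-1), \qquad
#'       b_k = \frac{k}{d}(r-\tau)c + c \quad (k \ge m),}
#' and with redistribution off (\eqn{\tau} treated as 0)
#' \eqn{a_k = \frac{k+1}{d} r c}, \eqn{b_k = \frac{k}{d} r c + c}.
#'
#' @param p A [game_params()] object.
#' @param redistribution Logical; apply the second-order payment mechanism
#'   (default \code{TRUE}). When \code{FALSE}, \code{tau} is ignored.
#'
#' @return An object of class \code{"payoff_table"}: a list with numeric
#'   vectors \code{a} and \code{b} of length \code{d}, indexed by
#'   \code{k = 0..d-1} (element \code{k + 1} holds index \code{k}).
#' @examples
#' gp <- game_params(N = 100, d = 15, m = 4, r = 8, c = 1, tau = 0.25)
#' tab <- payoff_table(gp)
#' tab$a[4]  # a_3, the lowest paid cooperator entry when m = 4
#' @export
payoff_table <- function(p, redistribution = TRUE) {
  stopifnot(inherits(p, "game_params"))
  k <- 0:(p$d - 1L)
  tau <- if (redistribution) p$tau else 0
  a <- ifelse(k >= p$m - 1L, (k + 1) / p$d * (p$r - tau) * p$c + tau * p$c, 0)
  b <- ifelse(k >= p$m, k / p$d * (p$r - tau) * p$c + p$c, 0)
  structure(list(a = a, b = b, d = p$d, m = p$m), class = "payoff_table")
}

#' @export
print.payoff_table <- function(x, ...) {
  cat("Threshold public goods payoff table (d =", x$d, ", m =", x$m, ")\n")
  print(data.frame(k = 0:(x$d - 1L), a_k = x$a, b_k = x$b), row.names = FALSE)
  invisible(x)
}

#' Hypergeometric group-composition probabilities
#'
#' Probability that a focal player of the given strategy finds exactly
#' \code{k} cooperators among its \eqn{d-1} co-players, when the group is
#' sampled without replacement from a population with \code{i} cooperators:
#' \deqn{P_A(k) = \frac{\binom{i-1}{k}\binom{N-i}{d-1-k}}{\binom{N-1}{d-1}},
#'   \qquad
#'   P_B(k) = \frac{\binom{i}{k}\binom{N-i-1}{d-1-k}}{\binom{N-1}{d-1}},}
#' with the convention \eqn{\binom{n}{k} = 0} for \eqn{k < 0} or
#' \eqn{k > n}.
#'
#' @param k Count(s) of cooperating co-players, in \code{0..d-1}. May be a
#'   vector.
#' @param focal \code{"A"} (cooperator focal, requires \code{1 <= i <= N}) or
#'   \code{"B"} (defector focal, requires \code{0 <= i <= N-1}).
#' @param i Number of cooperators in the population.
#' @param p A [game_params()] object.
#'
#' @return Numeric vector of probabilities in \code{[0, 1]}, one per
#'   \code{k}.
#' @export
group_composition_prob <- function(k, focal = c("A", "B"), i, p) {
  stopifnot(inherits(p, "game_params"))
  focal <- match.arg(focal)
  if (any(k < 0L | k > p$d - 1L))
    stop("k must lie in 0..d-1", call. = FALSE)
  check_focal_i(focal, i, p$N)
  N <- p$N; d <- p$d
  if (focal == "A") {
    choose(i - 1, k) * choose(N - i, d - 1 - k) / choose(N - 1, d - 1)
  } else {
    choose(i, k) * choose(N - i - 1, d - 1 - k) / choose(N - 1, d - 1)
  }
}

check_focal_i <- function(focal, i, N) {
  if (focal == "A" && (i < 1L || i > N))
    stop("focal = \"A\" requires 1 <= i <= N (got i = ", i, ")",
         call. = FALSE)
  if (focal == "B" && (i < 0L || i > N - 1L))
    stop("focal = \"B\" requires 0 <= i <= N-1 (got i = ", i, ")",
         call. = FALSE)
  invisible(TRUE)
}

#' Expected payoffs under hypergeometric group sampling
#'
#' Expected payoff of a focal cooperator (\code{expected_payoff_A}) or
#' defector (\code{expected_payoff_B}) when the population contains \code{i}
#' cooperators: the payoff vector averaged over the hypergeometric
#' group-composition weights of [group_composition_prob()].
#'
#' @param i Number of cooperators in the population
#'   (\code{1 <= i <= N} for a focal cooperator, \code{0 <= i <= N-1} for a
#'   focal defector).
#' @param p A [game_params()] object.
#' @param tab A [payoff_table()]; built from \code{p} (with redistribution)
#'   when omitted.
#'
#' @return A single expected payoff value.
#' @examples
#' gp <- game_params(N = 100, d = 15, m = 8, r = 8, c = 1, tau = 0.25)
#' expected_payoff_A(50, gp)
#' expected_payoff_B(50, gp)
#' @export
expected_payoff_A <- function(i, p, tab = payoff_table(p)) {
  k <- 0:(p$d - 1L)
  sum(group_composition_prob(k, "A", i, p) * tab$a)
}

#' @rdname expected_payoff_A
#' @export
expected_payoff_B <- function(i, p, tab = payoff_table(p)) {
  k <- 0:(p$d - 1L)
  sum(group_composition_prob(k, "B", i, p) * tab$b)
}

# Shifted expected payoffs pi_A(i+1) and pi_B(i) for i = 0..N-1, computed
# from the shared weight matrix C(i,k) C(N-i-1, d-1-k) / C(N-1, d-1).
# These are the two payoff profiles entering the stepwise ratio h(i, omega),
# returned as vectors indexed by i + 1.
payoff_profiles <- function(p, tab = payoff_table(p)) {
  N <- p$N; d <- p$d
  i <- 0:(N - 1L)
  k <- 0:(d - 1L)
  w <- outer(i, k, function(ii, kk)
    choose(ii, kk) * choose(N - ii - 1, d - 1 - kk)) / choose(N - 1, d - 1)
  list(piA_next = as.vector(w %*% tab$a),  # pi_A(i+1), i = 0..N-1
       piB      = as.vector(w %*% tab$b))  # pi_B(i),   i = 0..N-1
}
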