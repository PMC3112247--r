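#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for \eqn{\int e^{-x^2} f(x)\,dx \approx \sum_q w_q f(x_q)}
#' (physicists' convention), computed by the Golub-Welsch eigenvalue method.
#' Used internally by the adaptive quadrature of [marginal_loglik()].
#'
#' @param n number of nodes (order of the rule).
#' @return list with `nodes` and `weights`, each of length `n`.
#' @examples
#' r <- gh_rule(10)
#' sum(r$weights)              # sqrt(pi)
#' sum(r$weights * r$nodes^2)  # sqrt(pi)/2
#' @export
gh_rule <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  if (n == 1L) {
    return(list(nodes = 0, weights = sqrt(pi)))
  }
  i <- seq_len(n - 1L)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}
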