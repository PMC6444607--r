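# Adaptive-LASSO weights from univariate marginal regression coefficients.

#' Construct adaptive-LASSO weights
#'
#' Pilot estimates are the univariate marginal (covariance) coefficients
#' \eqn{\hat\beta_j = x_j' y / n}, which remain well defined when p >> n.
#' Weights are \eqn{w_j = 1/|\hat\beta_j|^\gamma}, capped at
#' \code{weight_cap} (a zero marginal coefficient would give an infinite
#' weight; the cap keeps the penalty finite while numerically forcing the
#' coefficient to zero). \code{gamma = 0} gives unit weights, i.e. the
#' ordinary LASSO; \code{gamma = 1} approximates an l0 penalty.
#'
#' @param X numeric matrix or \code{design_matrix}.
#' @param y numeric vector or \code{phenotype_vector} (centred).
#' @param gamma nonnegative exponent (default 1).
#' @param weight_cap upper bound on weights (default 1e12).
#' @return Object of class \code{adaptive_weights}: list with \code{w},
#'   \code{gamma}, \code{beta_marginal} and \code{capped_indices}.
#' @export
marginal_weights <- function(X, y, gamma = 1, weight_cap = 1e12) {
  if (inherits(X, "design_matrix")) X <- X$values
  if (inherits(y, "phenotype_vector")) y <- y$values
  stopifnot(is.matrix(X), length(y) == nrow(X), gamma >= 0, weight_cap > 0)
  beta_hat <- drop(crossprod(X, y)) / nrow(X)
  w <- if (gamma == 0) rep(1, ncol(X)) else 1 / abs(beta_hat)^gamma
  capped <- which(!is.finite(w) | w > weight_cap)
  w[capped] <- weight_cap
  structure(list(w = w, gamma = gamma, beta_marginal = beta_hat,
                 capped_indices = capped),
            class = "adaptive_weights")
}

#' @export
print.adaptive_weights <- function(x, ...) {
  cat(sprintf("adaptive_weights: q = %d, gamma = %g, %d capped\n",
              length(x$w), x$gamma, length(x$capped_indices)))
  invisible(x)
}

#' Write weights to a TSV file for audit
#'
#' @param weights an \code{adaptive_weights} object.
#' @param path output file.
#' @param columns optional provenance data.frame (from a
#'   \code{design_matrix}).
#' @export
write_weights <- function(weights, path, columns = NULL) {
  stopifnot(inherits(weights, "adaptive_weights"))
  tab <- data.frame(column = seq_along(weights$w),
                    beta_marginal = weights$beta_marginal,
                    weight = weights$w,
                    capped = seq_along(weights$w) %in%
                      weights$capped_indices)
  if (!is.null(columns)) tab <- cbind(columns, tab[-1])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
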