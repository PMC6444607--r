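# lambda_max, test-error evaluation and golden-section search over the
# regularization factor, with warm-started ADMM fits.

#' Smallest penalty that zeroes the unweighted LASSO solution
#'
#' \eqn{\lambda_{max} = \|X'y\|_\infty} on the centred phenotype. With
#' adaptive weights the all-zero guarantee at lambda_max holds only for the
#' unweighted problem; the quantity is still the conventional upper bracket.
#'
#' @param X numeric matrix or \code{design_matrix}.
#' @param y numeric vector or \code{phenotype_vector}.
#' @return Nonnegative scalar; 0 with a warning when y is identically zero.
#' @export
lambda_max <- function(X, y) {
  if (inherits(X, "design_matrix")) X <- X$values
  if (inherits(y, "phenotype_vector")) y <- y$values
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (all(y == 0)) {
    warning("y is identically zero: lambda_max = 0 (degenerate)")
    return(0)
  }
  max(abs(crossprod(X, y)))
}

#' Halved squared test error
#'
#' \eqn{SE = \frac12 \|X_{test}\theta - y_{test}\|_2^2}; the golden-section
#' objective. \code{y_test} must be centred by the training mean.
#'
#' @param theta coefficient vector.
#' @param X_test numeric matrix or \code{design_matrix}.
#' @param y_test centred numeric vector.
#' @return Nonnegative scalar.
#' @export
se_test <- function(theta, X_test, y_test) {
  if (inherits(X_test, "design_matrix")) X_test <- X_test$values
  if (inherits(y_test, "phenotype_vector")) y_test <- y_test$values
  stopifnot(length(theta) == ncol(X_test), length(y_test) == nrow(X_test))
  0.5 * sum((drop(X_test %*% theta) - y_test)^2)
}

#' Golden-section search for the regularization factor
#'
#' Minimizes a unimodal test-error curve SE(lambda) over
#' \code{[lam_a, lam_b]} by bracket narrowing at the golden ratio
#' \eqn{\varphi = (1+\sqrt5)/2}: both endpoints and both interior points are
#' evaluated first; thereafter exactly one new evaluation per iteration (the
#' flagged interior point), the other being reused. Shrinks toward the
#' smaller-SE side (ties move the left endpoint, a fixed rule for
#' determinism) and stops when
#' \eqn{|\lambda_d - \lambda_c| / ((\lambda_c + \lambda_d)/2) <
#' \epsilon_{GSS}}, then refits once at
#' \eqn{\lambda_{opt} = (\lambda_c + \lambda_d)/2}.
#'
#' @param fit function of lambda returning \code{list(theta =, se =)};
#'   typically a warm-started ADMM closure, but any evaluator works.
#' @param lam_a,lam_b bracket endpoints, 0 < lam_a < lam_b.
#' @param eps_gss relative stopping tolerance (recommended 0.01 to 0.001).
#' @param fit_endpoints evaluate lam_a and lam_b first (the fitting
#'   procedure's step that also seeds warm starts); set FALSE to skip.
#' @return Object of class \code{search_result}: \code{lam_opt},
#'   \code{theta_opt}, \code{se_test_opt}, \code{n_lambda_evaluated},
#'   \code{n_evaluations}, \code{trace} (data.frame of lambda, se in
#'   evaluation order) and \code{bracket_history}.
#' @export
golden_section_search <- function(fit, lam_a, lam_b, eps_gss = 1e-2,
                                  fit_endpoints = TRUE) {
  stopifnot(is.function(fit), lam_a > 0, lam_a < lam_b,
            eps_gss > 0, eps_gss < 1)
  phi <- (1 + sqrt(5)) / 2
  evals <- list()
  evaluate <- function(lam) {
    res <- fit(lam)
    if (!is.list(res) || is.null(res$se) || !is.finite(res$se) ||
        res$se < 0) {
      stop("fit failed at lambda = ", lam)
    }
    evals[[length(evals) + 1L]] <<- c(lambda = lam, se = res$se)
    res
  }
  if (fit_endpoints) {
    evaluate(lam_a)
    evaluate(lam_b)
  }
  lam_c <- lam_b - (lam_b - lam_a) / phi
  lam_d <- lam_a + (lam_b - lam_a) / phi
  fc <- evaluate(lam_c); fd <- evaluate(lam_d)
  se_c <- fc$se; se_d <- fd$se
  theta_c <- fc$theta; theta_d <- fd$theta
  flag <- NA_integer_
  history <- list(c(lam_a = lam_a, lam_c = lam_c, lam_d = lam_d,
                    lam_b = lam_b))
  repeat {
    if (se_c < se_d) {         # minimum in [lam_a, lam_d]
      lam_b <- lam_d
      se_d <- se_c; theta_d <- theta_c
      flag <- 1L               # new lam_c must be evaluated next
    } else {                   # minimum in [lam_c, lam_b]; ties go here
      lam_a <- lam_c
      se_c <- se_d; theta_c <- theta_d
      flag <- 0L               # new lam_d must be evaluated next
    }
    lam_c <- lam_b - (lam_b - lam_a) / phi
    lam_d <- lam_a + (lam_b - lam_a) / phi
    history[[length(history) + 1L]] <-
      c(lam_a = lam_a, lam_c = lam_c, lam_d = lam_d, lam_b = lam_b)
    if (abs(lam_d - lam_c) / ((lam_c + lam_d) / 2) < eps_gss) break
    if (flag == 1L) {
      fc <- evaluate(lam_c); se_c <- fc$se; theta_c <- fc$theta
    } else {
      fd <- evaluate(lam_d); se_d <- fd$se; theta_d <- fd$theta
    }
  }
  lam_opt <- (lam_c + lam_d) / 2
  final <- evaluate(lam_opt)
  trace <- as.data.frame(do.call(rbind, evals))
  structure(list(
    lam_opt = lam_opt,
    theta_opt = final$theta,
    se_test_opt = final$se,
    n_lambda_evaluated = length(unique(trace$lambda)),
    n_evaluations = nrow(trace),
    trace = trace,
    bracket_history = as.data.frame(do.call(rbind, history))),
    class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "search_result: lambda_opt = %.6g, SE_test = %.6g (%d lambda values)\n",
    x$lam_opt, x$se_test_opt, x$n_lambda_evaluated))
  invisible(x)
}

#' Automatic adaptive LASSO: full fit with tuned lambda
#'
#' Composes adaptive-weight construction, \code{\link{lambda_max}} and
#' \code{\link{golden_section_search}} over warm-started
#' \code{\link{admm_fit}} evaluations: each new lambda starts from the most
#' recent (beta, theta) with the dual u reset to 0. The regularization
#' factor is tuned by minimizing the halved squared error on the held-out
#' test split, reproducing the tuning-on-test protocol of the method; pass a
#' separate validation split as the "test" arguments if a third split is
#' preferred.
#'
#' @param X_train,X_test numeric matrices or \code{design_matrix} objects
#'   with identical column provenance.
#' @param y_train raw numeric training phenotype (or a
#'   \code{phenotype_vector}, taken as already centred).
#' @param y_test raw numeric test phenotype; centred internally by the
#'   TRAINING mean.
#' @param config a \code{\link{fit_config}} (gamma and weight_cap control
#'   the adaptive weights; gamma = 0 gives the ordinary LASSO).
#' @param lam_a_frac,lam_b_frac bracket endpoints as fractions of
#'   lambda_max; defaults 0.001 and 1 (the experiments' wider bracket uses
#'   \code{lam_a_frac = 1e-4}).
#' @param eps_gss golden-section relative stopping tolerance (default 1e-2).
#' @param center centre the training phenotype (default TRUE).
#' @return A \code{search_result} augmented with \code{weights},
#'   \code{lambda_max}, \code{training_mean}, \code{columns} (provenance, if
#'   available), \code{config} and \code{converged} (final fit).
#' @export
autalasso_fit <- function(X_train, y_train, X_test, y_test,
                          config = fit_config(), lam_a_frac = 0.001,
                          lam_b_frac = 1, eps_gss = 1e-2, center = TRUE) {
  stopifnot(lam_a_frac > 0, lam_a_frac < lam_b_frac, lam_b_frac <= 1)
  columns <- if (inherits(X_train, "design_matrix")) X_train$columns
  Xtr <- if (inherits(X_train, "design_matrix")) X_train$values else X_train
  Xte <- if (inherits(X_test, "design_matrix")) X_test$values else X_test
  if (ncol(Xtr) != ncol(Xte)) stop("train/test column mismatch")
  ph <- if (inherits(y_train, "phenotype_vector")) y_train
        else center_phenotype(y_train, center = center)
  ytr <- ph$values
  yte <- as.numeric(y_test) - ph$training_mean

  weights <- marginal_weights(Xtr, ytr, gamma = config$gamma,
                              weight_cap = config$weight_cap)
  lmax <- lambda_max(Xtr, ytr)
  if (lmax == 0) stop("lambda_max is 0: centred phenotype is degenerate")
  cache <- quadratic_cache(Xtr, ytr)

  warm <- NULL
  last_converged <- TRUE
  fit <- function(lam) {
    st <- admm_fit(Xtr, ytr, lam, weights = weights, config = config,
                   warm = warm, cache = cache)
    warm <<- list(beta = st$beta, theta = st$theta)
    last_converged <<- st$converged
    list(theta = st$theta, se = se_test(st$theta, Xte, yte))
  }
  res <- golden_section_search(fit, lam_a = lam_a_frac * lmax,
                               lam_b = lam_b_frac * lmax,
                               eps_gss = eps_gss)
  res$weights <- weights
  res$lambda_max <- lmax
  res$training_mean <- ph$training_mean
  res$columns <- columns
  res$config <- config
  res$converged <- last_converged
  res
}
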