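# Translate one-hot genotype-class coefficients into additive and dominance
# SNP effects; predict phenotypes; evaluation metrics.

#' Additive and dominance effects from genotype-class coefficients
#'
#' For each SNP the additive effect contrasts the homozygote classes,
#' \eqn{a = -\theta_{gen=0} + \theta_{gen=2}}, and the dominance effect is
#' the heterozygote coefficient, \eqn{d = \theta_{gen=1}}. Covariate columns
#' are excluded. Sparsity is exact (soft-thresholding produces literal
#' zeros); \code{zero_tol} exists for coefficients imported from dense
#' solvers.
#'
#' @param theta fitted coefficient vector.
#' @param columns provenance data.frame from \code{\link{one_hot_encode}}
#'   (or a \code{design_matrix} / \code{search_result} carrying one).
#' @param zero_tol magnitude below which a coefficient counts as zero for
#'   the nonzero flags (default 0: exact).
#' @return Object of class \code{effects_table}: data.frame with
#'   \code{snp_id}, \code{a}, \code{d}, \code{nonzero_a}, \code{nonzero_d}.
#' @export
extract_effects <- function(theta, columns, zero_tol = 0) {
  if (inherits(columns, "design_matrix")) columns <- columns$columns
  if (inherits(columns, "search_result")) columns <- columns$columns
  stopifnot(is.data.frame(columns), nrow(columns) == length(theta))
  snp <- columns$type == "snp"
  sc <- columns[snp, ]
  th <- theta[snp]
  ids <- unique(sc$id)
  idx0 <- match(paste0(ids, ":0"), paste0(sc$id, ":", sc$genotype_class))
  idx1 <- match(paste0(ids, ":1"), paste0(sc$id, ":", sc$genotype_class))
  idx2 <- match(paste0(ids, ":2"), paste0(sc$id, ":", sc$genotype_class))
  if (anyNA(idx0) || anyNA(idx1) || anyNA(idx2)) {
    stop("provenance missing a genotype class for some SNP")
  }
  a <- -th[idx0] + th[idx2]
  d <- th[idx1]
  out <- data.frame(snp_id = ids, a = a, d = d,
                    nonzero_a = abs(th[idx0]) > zero_tol |
                      abs(th[idx2]) > zero_tol,
                    nonzero_d = abs(d) > zero_tol,
                    stringsAsFactors = FALSE)
  class(out) <- c("effects_table", "data.frame")
  out
}

#' Predict phenotypes from a fitted coefficient vector
#'
#' \eqn{\hat y = X_{new}\theta + \bar y_{train}}: the training mean removed
#' by centring is added back.
#'
#' @param X_new numeric matrix or \code{design_matrix}; when both carry
#'   provenance it must match the fitted design.
#' @param theta fitted coefficient vector.
#' @param training_mean mean subtracted from the training phenotype.
#' @param columns optional provenance of the fitted design, checked against
#'   \code{X_new} when both are available.
#' @return Numeric vector of predictions.
#' @export
predict_phenotype <- function(X_new, theta, training_mean = 0,
                              columns = NULL) {
  if (inherits(X_new, "design_matrix")) {
    if (!is.null(columns) &&
        !identical(X_new$columns[c("id", "type", "genotype_class")],
                   columns[c("id", "type", "genotype_class")])) {
      stop("column provenance of X_new does not match the fitted design")
    }
    X_new <- X_new$values
  }
  if (ncol(X_new) != length(theta)) {
    stop("X_new has ", ncol(X_new), " columns but theta has length ",
         length(theta))
  }
  drop(X_new %*% theta) + training_mean
}

#' @param object a \code{search_result} from \code{\link{autalasso_fit}}.
#' @param newdata matrix or \code{design_matrix} of new observations.
#' @param ... unused.
#' @rdname predict_phenotype
#' @export
predict.search_result <- function(object, newdata, ...) {
  predict_phenotype(newdata, object$theta_opt,
                    training_mean = object$training_mean,
                    columns = object$columns)
}

#' Prediction accuracy metrics
#'
#' \code{mse_test} is the plain mean of squared residuals (no 1/2 factor —
#' it sits on the variance scale of the phenotype, unlike the halved
#' \code{\link{se_test}} used inside the golden-section search). \code{r_test}
#' is the Pearson correlation, also reported through its decomposition
#' \eqn{r = \sigma_{\hat y y} / (\sigma_{\hat y}\sigma_y)} with population
#' (1/n) variance convention (the convention cancels in r itself).
#'
#' @param y_hat predicted phenotypes.
#' @param y observed phenotypes (same length, >= 2).
#' @return Object of class \code{evaluation_result}: list with
#'   \code{mse_test}, \code{r_test}, \code{sd_yhat}, \code{sd_y},
#'   \code{cov_yhat_y}. \code{r_test} is NaN (with a warning) when
#'   \code{y_hat} has zero variance.
#' @export
evaluate <- function(y_hat, y) {
  y_hat <- as.numeric(y_hat); y <- as.numeric(y)
  if (length(y_hat) != length(y)) stop("length mismatch")
  if (length(y) < 2) stop("need at least 2 observations")
  n <- length(y)
  mse <- mean((y_hat - y)^2)
  sd_yhat <- sqrt(sum((y_hat - mean(y_hat))^2) / n)
  sd_y <- sqrt(sum((y - mean(y))^2) / n)
  cov_hy <- sum((y_hat - mean(y_hat)) * (y - mean(y))) / n
  r <- if (sd_yhat == 0 || sd_y == 0) {
    warning("zero variance in y_hat or y: r_test is undefined (NaN)")
    NaN
  } else cov_hy / (sd_yhat * sd_y)
  structure(list(mse_test = mse, r_test = r, sd_yhat = sd_yhat,
                 sd_y = sd_y, cov_yhat_y = cov_hy),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("mse_test = %.6g, r_test = %.4g (sd_yhat = %.4g, sd_y = %.4g, cov = %.4g)\n",
              x$mse_test, x$r_test, x$sd_yhat, x$sd_y, x$cov_yhat_y))
  invisible(x)
}

#' Write an effects table as TSV
#'
#' @param effects an \code{effects_table}.
#' @param path output file.
#' @export
write_effects <- function(effects, path) {
  utils::write.table(as.data.frame(effects), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
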