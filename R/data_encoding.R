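# Genotype/phenotype ingestion, MAF filtering, one-hot encoding and splits.

#' Construct a genotype matrix object
#'
#' Container for raw SNP genotypes coded as minor-allele counts 0/1/2.
#' Missing values are not representable; impute upstream.
#'
#' @param values integer matrix, individuals x SNPs, entries in \{0, 1, 2\}.
#' @param snp_ids character vector of unique SNP identifiers (columns).
#' @param individual_ids character vector of unique individual identifiers
#'   (rows).
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(values, snp_ids = colnames(values),
                            individual_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(values)))
  if (is.null(individual_ids)) {
    individual_ids <- paste0("ind", seq_len(nrow(values)))
  }
  snp_ids <- as.character(snp_ids)
  individual_ids <- as.character(individual_ids)
  if (length(snp_ids) != ncol(values)) {
    stop("length(snp_ids) must equal ncol(values)")
  }
  if (length(individual_ids) != nrow(values)) {
    stop("length(individual_ids) must equal nrow(values)")
  }
  if (anyDuplicated(snp_ids)) {
    stop("duplicated SNP ids: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  }
  if (anyDuplicated(individual_ids)) {
    stop("duplicated individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]),
               collapse = ", "))
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing genotype at row %d (%s), column %d (%s)",
                 bad[1], individual_ids[bad[1]], bad[2], snp_ids[bad[2]]))
  }
  ok <- values == 0 | values == 1 | values == 2
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "genotype not in {0,1,2} at row %d (%s), column %d (%s): value %s",
      bad[1], individual_ids[bad[1]], bad[2], snp_ids[bad[2]],
      format(values[bad[1], bad[2]])))
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- NULL
  structure(list(values = values, snp_ids = snp_ids,
                 individual_ids = individual_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (0/1/2 coding)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Read a genotype table from delimited text
#'
#' Expected layout: header row of SNP ids, first column individual ids, body
#' integer genotype counts in \{0, 1, 2\}.
#'
#' @param path path to the file.
#' @param delimiter field delimiter (default tab).
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  tab <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("genotype file needs an id column plus >=1 SNP")
  ids <- tab[[1]]
  body <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric genotype at row %d, SNP '%s': '%s'",
                 bad[1], colnames(tab)[-1][bad[2]], body[bad[1], bad[2]]))
  }
  g <- genotype_matrix(num, snp_ids = colnames(tab)[-1],
                       individual_ids = ids)
  message(sprintf("read %d individuals x %d SNPs from %s",
                  nrow(g$values), ncol(g$values), path))
  g
}

#' Read a two-column phenotype table (individual id, value)
#'
#' @param path path to the file.
#' @param delimiter field delimiter.
#' @return Named numeric vector of phenotype values.
#' @export
read_phenotypes <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           check.names = FALSE)
  if (ncol(tab) < 2) stop("phenotype file needs (id, value) columns")
  y <- as.numeric(tab[[2]])
  if (anyNA(y)) stop("non-numeric phenotype value in ", path)
  names(y) <- as.character(tab[[1]])
  y
}

#' Filter SNPs by minor allele frequency
#'
#' Allele frequency per SNP is \eqn{\hat p = \sum g / (2n)} and
#' MAF \eqn{= \min(\hat p, 1 - \hat p)}. Columns with MAF >= \code{threshold}
#' are retained (inclusive boundary); monomorphic columns (MAF = 0) are always
#' removed.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param threshold MAF threshold in \[0, 0.5\] (default 0.01).
#' @return A \code{genotype_matrix} of retained SNPs, with attribute
#'   \code{removed_snp_ids} listing the dropped columns.
#' @export
maf_filter <- function(G, threshold = 0.01) {
  stopifnot(inherits(G, "genotype_matrix"),
            is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 0.5)
  n <- nrow(G$values)
  p_hat <- colSums(G$values) / (2 * n)
  maf <- pmin(p_hat, 1 - p_hat)
  keep <- maf >= threshold & maf > 0
  if (!any(keep)) stop("MAF filter removed every SNP (empty design)")
  out <- genotype_matrix(G$values[, keep, drop = FALSE],
                         snp_ids = G$snp_ids[keep],
                         individual_ids = G$individual_ids)
  attr(out, "removed_snp_ids") <- G$snp_ids[!keep]
  out
}

#' One-hot encode genotypes into a design matrix
#'
#' Each SNP expands into three 0/1 indicator columns for genotype classes
#' 0, 1, 2 in that fixed order, so per-SNP blocks sum to one in every row.
#' Indicator columns are deliberately not centred or standardized: the fitted
#' coefficients stay directly interpretable as genotype-class effects
#' (a = -theta_gen0 + theta_gen2, d = theta_gen1), with phenotype centring
#' absorbing the intercept. Optional covariates are appended after the SNP
#' blocks; continuous covariates are standardized to mean 0, SD 1.
#'
#' @param G a \code{\link{genotype_matrix}} (after MAF filtering).
#' @param covariates optional data.frame of covariates (one row per
#'   individual).
#' @param covariate_kinds character vector, one of \code{"indicator"} or
#'   \code{"continuous"} per covariate column; defaults to
#'   \code{"continuous"} for numeric non-0/1 columns, \code{"indicator"}
#'   otherwise.
#' @return An object of class \code{design_matrix}: list with \code{values}
#'   (real matrix n x q) and \code{columns} (provenance data.frame with
#'   \code{id}, \code{type}, \code{genotype_class}, \code{kind}).
#' @export
one_hot_encode <- function(G, covariates = NULL, covariate_kinds = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$values)
  p <- ncol(G$values)
  X <- matrix(0, nrow = n, ncol = 3L * p)
  for (cls in 0:2) {
    # class columns interleaved as (snp1:0, snp1:1, snp1:2, snp2:0, ...)
    X[, seq(cls + 1L, by = 3L, length.out = p)] <- (G$values == cls) + 0
  }
  columns <- data.frame(
    id = rep(G$snp_ids, each = 3L),
    type = "snp",
    genotype_class = rep(0:2, times = p),
    kind = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) {
      stop("covariates must have one row per individual")
    }
    if (is.null(covariate_kinds)) {
      covariate_kinds <- vapply(covariates, function(v) {
        if (is.numeric(v) && !all(v %in% c(0, 1))) "continuous"
        else "indicator"
      }, character(1))
    }
    stopifnot(length(covariate_kinds) == ncol(covariates),
              all(covariate_kinds %in% c("indicator", "continuous")))
    C <- matrix(0, nrow = n, ncol = ncol(covariates))
    for (j in seq_len(ncol(covariates))) {
      v <- as.numeric(covariates[[j]])
      if (anyNA(v)) stop("missing value in covariate ", names(covariates)[j])
      if (covariate_kinds[j] == "continuous") {
        s <- stats::sd(v)
        if (s == 0) stop("constant continuous covariate cannot be ",
                         "standardized: ", names(covariates)[j])
        v <- (v - mean(v)) / s
      } else if (!all(v %in% c(0, 1))) {
        stop("indicator covariate must be 0/1: ", names(covariates)[j])
      }
      C[, j] <- v
    }
    X <- cbind(X, C)
    columns <- rbind(columns, data.frame(
      id = names(covariates), type = "covariate",
      genotype_class = NA_integer_,
      kind = ifelse(covariate_kinds == "continuous",
                    "standardized_continuous", "indicator"),
      stringsAsFactors = FALSE))
  }
  structure(list(values = X, columns = columns,
                 individual_ids = G$individual_ids),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  n_snp <- sum(x$columns$type == "snp") / 3
  n_cov <- sum(x$columns$type == "covariate")
  cat(sprintf(
    "design_matrix: %d x %d (%d SNPs one-hot -> %d columns, %d covariates)\n",
    nrow(x$values), ncol(x$values), n_snp, 3 * n_snp, n_cov))
  invisible(x)
}

#' @export
dim.design_matrix <- function(x) dim(x$values)

#' Subset rows of a design matrix
#'
#' @param X a \code{design_matrix}.
#' @param rows integer or logical row index.
#' @return A \code{design_matrix} with the selected rows, same provenance.
#' @export
subset_rows <- function(X, rows) {
  stopifnot(inherits(X, "design_matrix"))
  structure(list(values = X$values[rows, , drop = FALSE],
                 columns = X$columns,
                 individual_ids = X$individual_ids[rows]),
            class = "design_matrix")
}

#' Centre a phenotype vector, retaining the training mean
#'
#' The stored mean is added back at prediction time.
#'
#' @param y raw numeric phenotype vector (length >= 2, finite).
#' @param center logical; set \code{FALSE} to skip centring (training mean
#'   recorded as 0).
#' @return An object of class \code{phenotype_vector}: list with
#'   \code{values} and \code{training_mean}.
#' @export
center_phenotype <- function(y, center = TRUE) {
  y <- as.numeric(y)
  if (length(y) < 2) stop("phenotype needs length >= 2")
  if (!all(is.finite(y))) stop("non-finite phenotype values")
  m <- if (center) mean(y) else 0
  structure(list(values = y - m, training_mean = m),
            class = "phenotype_vector")
}

#' Build train/test split plans
#'
#' \code{holdout_tail} reproduces a generation-style split: the last
#' \code{ceiling(n * test_fraction)} rows (or exactly \code{test_n} rows) form
#' the test set. \code{random_repeats} draws \code{repeats} independent random
#' partitions from the seed.
#'
#' @param n number of rows.
#' @param mode \code{"holdout_tail"} or \code{"random_repeats"}.
#' @param test_fraction fraction of rows held out (0 < f < 1).
#' @param repeats number of random partitions (ignored for holdout_tail).
#' @param seed integer RNG seed for random_repeats.
#' @param test_n optional exact test-set size, overriding
#'   \code{test_fraction}.
#' @return An object of class \code{split_plan}: list with \code{repeats}
#'   (list of \code{list(train, test)} index pairs) and \code{seed}.
#' @export
make_splits <- function(n, mode = c("holdout_tail", "random_repeats"),
                        test_fraction = 0.3, repeats = 10, seed = 1,
                        test_n = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 2)
  if (is.null(test_n)) {
    stopifnot(test_fraction > 0, test_fraction < 1)
    test_n <- ceiling(n * test_fraction)
  }
  if (test_n < 1 || test_n >= n) stop("empty train or test side")
  reps <- if (mode == "holdout_tail") {
    list(list(train = seq_len(n - test_n),
              test = seq.int(n - test_n + 1L, n)))
  } else {
    withr_seed <- function(expr) { # local RNG, do not disturb global state
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
              else rm(".Random.seed", envir = globalenv()))
      set.seed(seed)
      expr
    }
    withr_seed(lapply(seq_len(repeats), function(i) {
      test <- sort(sample.int(n, test_n))
      list(train = setdiff(seq_len(n), test), test = test)
    }))
  }
  structure(list(repeats = reps, seed = seed), class = "split_plan")
}
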