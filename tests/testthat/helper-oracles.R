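# Shared fixtures and independent oracles for the solver tests.

# Penalized objective: (1/2)||Xb - y||^2 + lam * sum(w |b|)
lasso_obj <- function(X, y, lam, b, w = rep(1, ncol(X))) {
  0.5 * sum((drop(X %*% b) - y)^2) + lam * sum(w * abs(b))
}

rand_instance <- function(n, q, seed) {
  set.seed(seed)
  list(X = matrix(rnorm(n * q), n, q), y = rnorm(n))
}

# Independent convex-solver oracle (glmnet coordinate descent). Bridges the
# scaling conventions: glmnet minimizes (1/(2n))||y - Xb||^2 +
# lam_g * sum(pf'_j |b_j|) with pf' internally renormalized to sum to q,
# so lam_g = lam * sum(w) / (n q) with penalty.factor = w matches
# (1/2)||Xb - y||^2 + lam * sum(w |b|).
glmnet_oracle <- function(X, y, lam, w = rep(1, ncol(X))) {
  fit <- glmnet::glmnet(X, y, standardize = FALSE, intercept = FALSE,
                        penalty.factor = w,
                        lambda = lam * sum(w) / (nrow(X) * ncol(X)),
                        thresh = 1e-14, maxit = 1e7)
  as.numeric(stats::coef(fit))[-1]
}

# KKT residual check for the weighted LASSO at tolerance tol (relative to
# lam * w_j per coordinate).
kkt_ok <- function(X, y, lam, theta, w = rep(1, ncol(X)), tol = 1e-3) {
  g <- drop(crossprod(X, drop(X %*% theta) - y))
  zero <- theta == 0
  ok_zero <- all(abs(g[zero]) <= lam * w[zero] * (1 + tol))
  ok_nz <- all(abs(g[!zero] + lam * w[!zero] * sign(theta[!zero])) <=
                 tol * lam * w[!zero])
  ok_zero && ok_nz
}

# Small deterministic simulated dataset for module tests; the polygenic QTL
# count shrinks with p so tiny marker panels stay valid.
tiny_sim <- function(n = 200, p = 80, seed = 11,
                     n_random_qtl = min(28L, max(0L, p %/% 8L)), ...) {
  simulate_dataset(simulation_config(n_individuals = n, n_snps = p,
                                     n_random_qtl = n_random_qtl,
                                     seed = seed, ...))
}

encoded_split <- function(sim, maf = 0.01) {
  G <- maf_filter(sim$genotypes, maf)
  X <- one_hot_encode(G)
  sp <- sim$split$repeats[[1]]
  list(X_train = subset_rows(X, sp$train),
       X_test = subset_rows(X, sp$test),
       y_train = sim$phenotypes[sp$train],
       y_test = sim$phenotypes[sp$test],
       X = X, split = sp)
}
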