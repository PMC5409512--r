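# Shared fixtures and independent oracles for the test suite.

# Toy schema: one continuous + one nominal(2) property.
toy_schema <- function() {
  property_schema(name = c("weight", "soluble"),
                  kind = c("continuous", "nominal"),
                  states = list(soluble = c("yes", "no")))
}

toy_table <- function() {
  property_table(toy_schema(),
                 id = c("a", "b", "c"),
                 label = c("positive", "unlabeled", "unlabeled"),
                 values = data.frame(weight = c(2, 4, 6),
                                     soluble = c("yes", "no", "yes"),
                                     stringsAsFactors = FALSE))
}

# Brute-force two-sample ECDF sup-difference (double loop over all
# observed points), independent of stats::ks.test.
brute_ks_D <- function(x, y) {
  pts <- c(x, y)
  d <- 0
  for (t in pts) {
    d <- max(d, abs(mean(x <= t) - mean(y <= t)))
  }
  d
}

# Dual objective of an SVM alpha vector: sum(a) - 1/2 (a*y)' K (a*y).
dual_objective_of <- function(alpha, y, K) {
  v <- alpha * y
  sum(alpha) - 0.5 * sum(v * (K %*% v))
}

rbf_K <- function(X, gamma) exp(-gamma * as.matrix(dist(X))^2)

# Dense QP oracle for the biased-SVM dual via kernlab::ipop.
qp_oracle_alpha <- function(X, y, gamma, C_plus, C_minus) {
  n <- nrow(X)
  K <- rbf_K(X, gamma)
  Q <- (y %o% y) * K
  sol <- kernlab::ipop(c = matrix(-1, n), H = Q,
                       A = matrix(y, 1), b = 0,
                       l = matrix(0, n),
                       u = matrix(ifelse(y > 0, C_plus, C_minus), n),
                       r = 0, sigf = 12, maxiter = 400)
  as.numeric(kernlab::primal(sol))
}

# Random small PU classification fixture with both classes present.
random_xy <- function(n, d = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), ncol = d)
  y <- sample(c(-1, 1), n, replace = TRUE)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  list(X = X, y = y)
}
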