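# Shared fixtures, all built in code.

# small synthetic world reused across test files
tiny_world <- function(seed = 42, n = 24) {
  make_synthetic_world(n_countries = n, n_colonies = max(4, round(n * 0.35)),
                       seed = seed)
}

# row-normalized k-nearest-neighbour network on random coordinates:
# lightweight sparse network for recovery and type-I simulations
knn_network <- function(n, k = 3, seed = 1, label = "K_adj") {
  set.seed(seed)
  xy <- cbind(runif(n), runif(n))
  d <- as.matrix(stats::dist(xy))
  adj <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  for (i in 1:n) adj[i, order(d[i, ])[2:(k + 1)]] <- 1
  adj <- 1 * ((adj + t(adj)) > 0)
  row_normalize(adj, label = label)
}

# brute-force multivariate-normal log-density oracle for the disturbances
# model: built directly from the covariance sigma2 * A^-1 A^-T, sharing no
# code with concentrated_loglik
mvn_loglik_oracle <- function(y, W_list, rho, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  A <- diag(n)
  for (k in seq_along(W_list)) A <- A - rho[k] * unclass(W_list[[k]])
  Ay <- A %*% y; AX <- A %*% X
  beta <- solve(crossprod(AX), crossprod(AX, Ay))
  sigma2 <- sum((Ay - AX %*% beta)^2) / n
  S <- sigma2 * solve(A) %*% t(solve(A))
  r <- y - X %*% beta
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(S)$modulus +
                       t(r) %*% solve(S, r)))
}
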