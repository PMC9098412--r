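# Independent dense-matrix REML oracle for variance-component models with
# independent scalar random-intercept blocks. Used to cross-check the fitting
# engine on small problems; deliberately brute-force and self-contained.

# profiled REML deviance at relative SDs `theta` (one per Z block)
dense_reml_deviance <- function(theta, y, X, Zlist) {
  n <- length(y); p <- ncol(X)
  V <- diag(n)
  for (i in seq_along(Zlist)) {
    Z <- Zlist[[i]]
    V <- V + theta[i]^2 * tcrossprod(Z)
  }
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  A <- XtVi %*% X
  beta <- solve(A, XtVi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  as.numeric(determinant(V)$modulus + determinant(A)$modulus +
               (n - p) * (1 + log(2 * pi * rss / (n - p))))
}

# brute-force REML fit: multi-start Nelder-Mead over theta >= 0
dense_reml_fit <- function(y, X, Zlist, starts = list(rep(0.5, length(Zlist)),
                                                      rep(2, length(Zlist)),
                                                      rep(0.05, length(Zlist)))) {
  obj <- function(th) dense_reml_deviance(abs(th), y, X, Zlist)
  best <- NULL
  for (s in starts) {
    o <- optim(s, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  theta <- abs(best$par)
  n <- length(y); p <- ncol(X)
  V <- diag(n)
  for (i in seq_along(Zlist)) V <- V + theta[i]^2 * tcrossprod(Zlist[[i]])
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  sigma2 <- drop(t(r) %*% Vi %*% r) / (n - p)
  list(theta = theta, beta = drop(beta), sigma2 = sigma2,
       vc = sigma2 * theta^2, deviance = best$value)
}

# closed-form conditional modes for intercept blocks at given theta/beta
dense_modes <- function(theta, beta, y, X, Zlist) {
  n <- length(y)
  V <- diag(n)
  for (i in seq_along(Zlist)) V <- V + theta[i]^2 * tcrossprod(Zlist[[i]])
  Vi <- solve(V)
  r <- y - X %*% beta
  lapply(seq_along(Zlist), function(i) {
    drop(theta[i]^2 * t(Zlist[[i]]) %*% Vi %*% r)
  })
}

indicator_matrix <- function(f) {
  f <- factor(f)
  Z <- model.matrix(~ 0 + f)
  colnames(Z) <- levels(f)
  Z
}
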