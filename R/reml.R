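# Fisher-scoring REML for the volume variance-component model.
#
# V(y) = sum_k s2_k Z_k Z_k' + s2_res I with X = [1, time]. Because V is
# linear in the variance parameters, Fisher scoring converges in a handful
# of iterations to near machine precision (on balanced complete designs the
# solution equals the expected-mean-squares estimator exactly, which a
# generic deviance optimizer only reaches to ~1e-6). Non-negativity is
# enforced by projection with an active-set rule on the score.

mk_indicator <- function(f) {
  f <- factor(f)
  m <- matrix(0, length(f), nlevels(f))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

# y: response; X: fixed-effect design; Zs: named list of indicator matrices
reml_fit <- function(y, X, Zs, tol = 1e-9, maxit = 200) {
  n <- length(y)
  Gs <- c(lapply(Zs, tcrossprod), list(residual = diag(n)))
  K <- length(Gs)
  vy <- var(y)
  floor_res <- 1e-10 * vy
  s2 <- rep(vy / K, K)
  trace <- numeric(0)
  ch <- Inf
  for (it in seq_len(maxit)) {
    s2[K] <- max(s2[K], floor_res)
    V <- Reduce(`+`, Map(`*`, Gs, s2))
    Vi <- tryCatch(solve(V), error = function(e) solve(V + diag(1e-8 * vy, n)))
    XtViX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
    r <- P %*% y
    score <- vapply(seq_len(K), function(k)
      -0.5 * (sum(P * Gs[[k]]) - as.numeric(crossprod(r, Gs[[k]] %*% r))),
      numeric(1))
    PG <- lapply(Gs, function(G) P %*% G)
    Info <- matrix(0, K, K)
    for (i in seq_len(K)) for (j in i:K)
      Info[i, j] <- Info[j, i] <- 0.5 * sum(PG[[i]] * t(PG[[j]]))
    act <- s2 > 0 | score > 0
    delta <- rep(0, K)
    # solve the scoring system in diagonally normalized form so a huge
    # information entry (e.g. a floored residual) cannot drown the others
    A <- Info[act, act, drop = FALSE]
    dsc <- sqrt(pmax(diag(A), 1e-300))
    An <- A / tcrossprod(dsc) + diag(1e-10, sum(act))
    delta[act] <- tryCatch(
      solve(An, score[act] / dsc) / dsc,
      error = function(e) rep(NA_real_, sum(act)))
    if (anyNA(delta)) stop("REML scoring failed: singular information matrix")
    # healthy fits converge quadratically within ~10 iterations; damp later
    # steps so boundary chattering on degenerate data settles instead of
    # cycling
    if (it > 20) delta <- delta * 0.5^((it - 20) / 5)
    new <- pmax(s2 + delta, 0)
    ch <- max(abs(new - s2)) / max(vy, 1e-300)
    trace <- c(trace, ch)
    s2 <- new
    if (ch < tol) break
  }
  if (ch >= tol)
    stop("REML scoring did not converge in ", maxit,
         " iterations; relative step sizes: ",
         paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
  s2[s2 < 1e-8 * vy] <- 0
  # GLS fixed effects at the converged covariance
  s2v <- s2; s2v[K] <- max(s2v[K], floor_res)
  V <- Reduce(`+`, Map(`*`, Gs, s2v))
  Vi <- solve(V)
  beta <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
  list(s2 = setNames(s2, names(Gs)), beta = as.numeric(beta), iter = it)
}
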