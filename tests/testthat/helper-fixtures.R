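# Shared fixtures, built once per test run and cached in an environment.
.fixture_env <- new.env(parent = emptyenv())

fixture_cache <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small complete study for unit tests
small_study <- function() fixture_cache("small_study", {
  simulate_study(n = 120, n_genes = 300, missing = "none", seed = 42)
})

# small study with default (Table-1-like) MCAR missingness
small_study_missing <- function() fixture_cache("small_study_missing", {
  simulate_study(n = 160, n_genes = 300, missing = "MCAR", seed = 43)
})

# desk-scale fixture for the reduction-identity acceptance check
desk_fixture <- function() fixture_cache("desk_fixture", {
  simulate_study(n = 600, n_genes = 2000, missing = "none", seed = 7)
})

# desk-scale fixture with missingness for the concordance acceptance check
desk_fixture_missing <- function() fixture_cache("desk_fixture_missing", {
  simulate_study(n = 600, n_genes = 2000, missing = "MCAR", seed = 8)
})

# independent naive TMM oracle: step-by-step doubly trimmed weighted mean
naive_tmm <- function(counts, lib_size = colSums(counts), ref,
                      trim_M = 0.3, trim_A = 0.05) {
  ns <- ncol(counts)
  f <- numeric(ns)
  for (i in seq_len(ns)) {
    obs <- counts[, i] / lib_size[i]
    refc <- counts[, ref] / lib_size[ref]
    M <- log2(obs / refc)
    A <- 0.5 * log2(obs * refc)
    v <- (lib_size[i] - counts[, i]) / lib_size[i] / counts[, i] +
      (lib_size[ref] - counts[, ref]) / lib_size[ref] / counts[, ref]
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (max(abs(M)) < 1e-6) {
      f[i] <- 0
      next
    }
    n <- length(M)
    loL <- floor(n * trim_M) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * trim_A) + 1
    hiS <- n + 1 - loS
    keep <- rank(M) >= loL & rank(M) <= hiL &
      rank(A) >= loS & rank(A) <= hiS
    f[i] <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
  }
  fct <- 2^f
  fct / exp(mean(log(fct)))
}

# brute-force weighted least squares via the normal equations
naive_wls <- function(X, y, w) {
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(w * res^2) / df
  v <- diag(solve(XtW %*% X))
  list(beta = drop(beta), s2 = s2, v_unscaled = v, df = df)
}

# exact ORA by enumeration of all overlap outcomes (universe <= 15)
enum_ora <- function(universe_n, set_n, sig_n, observed_overlap) {
  probs <- vapply(0:min(set_n, sig_n), function(k) {
    choose(set_n, k) * choose(universe_n - set_n, sig_n - k) /
      choose(universe_n, sig_n)
  }, 0)
  sum(probs[(observed_overlap:min(set_n, sig_n)) + 1])
}

# hand BH step-up
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
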