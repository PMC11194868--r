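# Independent oracles and small fixtures used across the suite.

## path graph 1-2-...-n
make_path_graph <- function(n) {
  nb <- lapply(seq_len(n), function(i)
    c(if (i > 1) i - 1L, if (i < n) i + 1L))
  area_graph(sprintf("P%02d", seq_len(n)), nb)
}

## cycle graph
make_cycle_graph <- function(n) {
  nb <- lapply(seq_len(n), function(i)
    sort(c(if (i > 1) i - 1L else n, if (i < n) i + 1L else 1L)))
  area_graph(sprintf("C%02d", seq_len(n)), nb)
}

## Moran's I straight from the definition, double loop over a dense matrix
oracle_moran <- function(values, Wdense) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + Wdense[i, j] * z[i] * z[j]
  (n / sum(Wdense)) * num / sum(z^2)
}

## all permutations by iterative insertion (independent of the package's
## recursive generator)
oracle_perms <- function(n) {
  out <- matrix(1L, 1L, 1L)
  for (k in 2:n) {
    nxt <- matrix(0L, nrow(out) * k, k)
    r <- 0L
    for (row in seq_len(nrow(out))) {
      for (pos in seq_len(k)) {
        r <- r + 1L
        nxt[r, ] <- append(out[row, ], k, after = pos - 1L)
      }
    }
    out <- nxt
  }
  out
}

## textbook chi-square statistic: sum (O - E)^2 / E
oracle_chi2 <- function(counts) {
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - E)^2 / E)
}

## standard generating coefficients: baseline prevalence 6.27% and the
## published prevalence-ratio pattern for the covariates
beta_reference <- function() {
  log(c(0.0627, 0.99, 1.01, 1.04, 1.10, 1.13))
}

## dense weight matrix of an area_weights object
dense_W <- function(w) as.matrix(w$W)

## a small valid area table on an arbitrary graph
make_toy_table <- function(graph, seed = 1) {
  derive_analysis_variables(simulate_covariates(graph, seed = seed),
                            require_counts = FALSE)
}

## the documented pseudo-p rule: one-sided in the direction of departure,
## ties up to numerical round-off counted as extreme
oracle_pseudo_p <- function(obs, perm, expected) {
  tol <- 1e-8 * max(diff(range(perm)), abs(obs), 1e-300)
  r <- if (obs >= expected) sum(perm >= obs - tol) else sum(perm <= obs + tol)
  (r + 1) / (length(perm) + 1)
}
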