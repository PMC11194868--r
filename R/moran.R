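#' Global Moran's I
#'
#' `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the deviations
#' from the mean. Row-standardised weights are the convention for this
#' statistic and are used throughout the exploratory analysis.
#'
#' @param values numeric vector, one value per area; not all equal.
#' @param weights an `area_weights` (or `area_graph`, converted to
#'   row-standardised weights).
#' @return The Moran's I statistic (numeric scalar).
#' @export
global_moran <- function(values, weights) {
  w <- .as_weights(weights, if (inherits(weights, "area_weights"))
    weights$style else "row_standardised")
  n <- length(values)
  if (n != length(w$graph$ids))
    stop("`values` length does not match the number of areas", call. = FALSE)
  if (n < 3L) stop("need at least 3 areas", call. = FALSE)
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0) stop("values have zero variance; Moran's I is undefined",
                    call. = FALSE)
  (n / w$S0) * as.numeric(Matrix::crossprod(z, w$W %*% z)) / ss
}

## all permutations of 1..n as an n! x n matrix (small n only)
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, factorial(n), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- matrix(0L, rows, n)
    block[, 1L] <- k
    rest <- seq_len(n)[-k]
    block[, -1L] <- matrix(rest[sub], rows, n - 1L)
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

.moran_all <- function(Z, w) {
  n <- nrow(Z)
  (n / w$S0) * colSums(as.matrix(w$W %*% Z) * Z) / colSums(Z^2)
}

## permuted statistics tied with the observed value up to numerical
## round-off count as at least as extreme
.pseudo_p <- function(obs, perm, expected, alternative) {
  if (alternative == "directional")
    alternative <- if (obs >= expected) "greater" else "less"
  tol <- 1e-8 * max(diff(range(perm)), abs(obs), 1e-300)
  r <- if (alternative == "greater") sum(perm >= obs - tol)
       else sum(perm <= obs + tol)
  (r + 1) / (length(perm) + 1)
}

#' Monte-Carlo test of Moran's I
#'
#' Permutes the values across areas `n_perm` times and reports the pseudo
#' p-value `(r + 1) / (n_perm + 1)`, where `r` counts permuted statistics at
#' least as extreme as the observed one. By default the test is one-sided in
#' the direction of the observed departure from the expectation
#' `-1/(n - 1)`; fix `alternative = "greater"` to test specifically for
#' positive spatial autocorrelation.
#'
#' @inheritParams global_moran
#' @param n_perm number of random permutations (default 999).
#' @param seed optional integer seed.
#' @param alternative `"directional"` (default), `"greater"`, or `"less"`.
#' @param exact enumerate all `n!` permutations instead of sampling
#'   (requires `n <= 8`); `n_perm` is then ignored.
#' @return An object of class `moran_test` with elements `I_obs`,
#'   `expected_I`, `n_perm`, `perm_values`, `pseudo_p`, `alternative`.
#' @export
moran_mc <- function(values, weights, n_perm = 999, seed = NULL,
                     alternative = c("directional", "greater", "less"),
                     exact = FALSE) {
  alternative <- match.arg(alternative)
  if (!exact && (length(n_perm) != 1L || n_perm < 1))
    stop("`n_perm` must be a positive integer", call. = FALSE)
  w <- .as_weights(weights, if (inherits(weights, "area_weights"))
    weights$style else "row_standardised")
  I_obs <- global_moran(values, w)
  n <- length(values)
  z <- values - mean(values)
  if (exact) {
    if (n > 8L) stop("exact enumeration supported only for n <= 8", call. = FALSE)
    P <- .all_perms(n)
    Z <- matrix(z[t(P)], n, nrow(P))
    perm <- .moran_all(Z, w)
    n_perm <- length(perm)
  } else {
    if (!is.null(seed)) set.seed(seed)
    Z <- vapply(seq_len(n_perm), function(k) z[sample.int(n)], numeric(n))
    perm <- .moran_all(Z, w)
  }
  expected <- -1 / (n - 1)
  structure(list(I_obs = I_obs, expected_I = expected, n_perm = n_perm,
                 perm_values = perm,
                 pseudo_p = .pseudo_p(I_obs, perm, expected, alternative),
                 alternative = alternative, exact = exact),
            class = "moran_test")
}

#' @method print moran_test
#' @export
print.moran_test <- function(x, ...) {
  cat("Moran's I Monte-Carlo test (",
      if (x$exact) "exact enumeration" else paste0(x$n_perm, " permutations"),
      ")\n", sep = "")
  cat("  I = ", format(x$I_obs, digits = 4),
      "  (expectation ", format(x$expected_I, digits = 4), ")\n", sep = "")
  cat("  pseudo p = ", format(x$pseudo_p, digits = 4),
      "  [", x$alternative, "]\n", sep = "")
  invisible(x)
}

#' Local Moran statistics (LISA)
#'
#' `I_i = z_i * sum_j w_ij z_j`, with `z` standardised by the global mean
#' and the population (divide-by-n) standard deviation. Per-area pseudo
#' p-values come from conditional permutation: area `i`'s value is held
#' fixed while the remaining `n - 1` values are permuted across its
#' neighbour slots, using the `(r + 1)/(M + 1)` rule one-sided in the
#' direction of each area's departure from its permutation mean.
#'
#' @inheritParams moran_mc
#' @param exact enumerate all `(n - 1)!` conditional permutations
#'   (requires `n <= 8`).
#' @return An object of class `lisa_result`: a data frame with `area_id`,
#'   `local_I`, `pseudo_p`, plus the standardised values and spatial lags as
#'   attributes. Labels are added by [classify_lisa()].
#' @export
local_moran <- function(values, weights, n_perm = 999, seed = NULL,
                        exact = FALSE) {
  w <- .as_weights(weights, if (inherits(weights, "area_weights"))
    weights$style else "row_standardised")
  n <- length(values)
  if (n != length(w$graph$ids))
    stop("`values` length does not match the number of areas", call. = FALSE)
  if (n < 3L) stop("need at least 3 areas", call. = FALSE)
  zc <- values - mean(values)
  s_pop <- sqrt(sum(zc^2) / n)
  if (s_pop == 0) stop("values have zero variance", call. = FALSE)
  z <- zc / s_pop
  lag <- as.numeric(w$W %*% z)
  local_I <- z * lag
  if (exact && n > 8L)
    stop("exact enumeration supported only for n <= 8", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- numeric(n)
  Wmat <- w$W
  for (i in seq_len(n)) {
    nbr <- w$graph$nb[[i]]
    d <- length(nbr)
    wvals <- Wmat[i, nbr]
    others <- z[-i]
    if (exact) {
      P <- .all_perms(n - 1L)
      M <- matrix(others[P[, seq_len(d), drop = FALSE]], nrow(P), d)
      lag_perm <- drop(M %*% wvals)
    } else {
      lag_perm <- vapply(seq_len(n_perm), function(k)
        sum(wvals * others[sample.int(n - 1L, d)]), numeric(1))
    }
    Ip <- z[i] * lag_perm
    p[i] <- .pseudo_p(local_I[i], Ip, mean(Ip), "directional")
  }
  out <- data.frame(area_id = w$graph$ids, local_I = local_I, pseudo_p = p,
                    stringsAsFactors = FALSE)
  attr(out, "z") <- z
  attr(out, "lag") <- lag
  attr(out, "n_perm") <- if (exact) factorial(n - 1L) else n_perm
  class(out) <- c("lisa_result", "data.frame")
  out
}

#' Classify LISA results into the five cluster types
#'
#' Quadrants come from the signs of the standardised value and its spatial
#' lag: (+,+) high-high, (-,-) low-low, (+,-) high-low, (-,+) low-high.
#' An area is labelled with its quadrant when its pseudo p-value is at most
#' `alpha`, and `non_significant` otherwise. Values exactly at the mean take
#' the quadrant of the lag alone; if the lag is also zero the area is
#' non-significant.
#'
#' @param lisa a [local_moran()] result.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param adjust `"none"` (default) or `"fdr"` (Benjamini-Hochberg across
#'   areas before thresholding).
#' @return The `lisa_result` with `quadrant` and `label` columns added.
#' @export
classify_lisa <- function(lisa, alpha = 0.05, adjust = c("none", "fdr")) {
  adjust <- match.arg(adjust)
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  z <- attr(lisa, "z"); lag <- attr(lisa, "lag")
  if (is.null(z) || is.null(lag))
    stop("`lisa` must come from local_moran()", call. = FALSE)
  hi <- ifelse(z != 0, z > 0, lag > 0)
  lag_hi <- lag > 0
  quadrant <- ifelse(hi & lag_hi, "HH",
              ifelse(!hi & !lag_hi, "LL",
              ifelse(hi & !lag_hi, "HL", "LH")))
  p <- lisa$pseudo_p
  if (adjust == "fdr") p <- stats::p.adjust(p, method = "BH")
  sig <- p <= alpha & !(z == 0 & lag == 0)
  label_map <- c(HH = "high_high", LL = "low_low",
                 HL = "high_low", LH = "low_high")
  lisa$quadrant <- quadrant
  lisa$label <- ifelse(sig, label_map[quadrant], "non_significant")
  lisa
}

#' @method print lisa_result
#' @export
print.lisa_result <- function(x, ...) {
  cat("Local Moran (LISA) result: ", nrow(x), " areas, ",
      attr(x, "n_perm"), " conditional permutations\n", sep = "")
  if ("label" %in% names(x)) print(table(x$label))
  else cat("  (unclassified; run classify_lisa())\n")
  invisible(x)
}
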