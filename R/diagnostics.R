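## stable log(mean(exp(x)))
.log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Watanabe-Akaike information criterion
#'
#' `lppd = sum_i log mean_s p(y_i | draw_s)`, computed with a stable
#' log-mean-exp; `p_waic = sum_i var_s log p(y_i | draw_s)`;
#' `waic = -2 (lppd - p_waic)`. Lower WAIC indicates better fit.
#'
#' @param x a `car_fit`, or a draws-by-areas pointwise log-likelihood matrix.
#' @return An object of class `waic_result` with `lppd`, `p_waic`, `waic`.
#' @export
compute_waic <- function(x) {
  ll <- if (inherits(x, "car_fit")) {
    if (is.null(x$loglik))
      stop("fit carries no pointwise log-likelihood (prior-only run?)",
           call. = FALSE)
    x$loglik
  } else as.matrix(x)
  if (nrow(ll) < 2L)
    stop("need at least 2 retained draws for WAIC", call. = FALSE)
  lppd <- sum(apply(ll, 2, .log_mean_exp))
  p_waic <- sum(apply(ll, 2, stats::var))
  structure(list(lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic)),
            class = "waic_result")
}

#' @method print waic_result
#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC = %.2f  (lppd = %.2f, p_waic = %.2f)\n",
              x$waic, x$lppd, x$p_waic))
  invisible(x)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `frac1` of a chain with the mean of the
#' last `frac2`: `z = (m1 - m2) / sqrt(se1^2 + se2^2)`, with the standard
#' errors of each segment mean estimated by batch means (an estimate of the
#' spectral density at frequency zero). For a converged chain `z` is
#' approximately standard normal.
#'
#' @param chain numeric vector of at least 100 retained draws.
#' @param frac1,frac2 leading and trailing fractions (defaults 0.1, 0.5).
#' @return The z score; `NA` (with a warning) for a constant chain.
#' @export
geweke_diagnostic <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  chain <- as.numeric(chain)
  m <- length(chain)
  if (m < 100L) stop("chain must have at least 100 draws", call. = FALSE)
  a <- chain[seq_len(max(2L, floor(frac1 * m)))]
  b <- chain[(m - floor(frac2 * m) + 1L):m]
  se <- function(x) {
    nb <- max(2L, floor(sqrt(length(x))))
    bl <- length(x) %/% nb
    bm <- vapply(seq_len(nb), function(k)
      mean(x[((k - 1L) * bl + 1L):(k * bl)]), numeric(1))
    stats::sd(bm) / sqrt(nb)
  }
  s1 <- se(a); s2 <- se(b)
  if (!is.finite(s1) || !is.finite(s2) || (s1 == 0 && s2 == 0)) {
    if (stats::var(chain) == 0) {
      warning("constant chain: Geweke z is undefined", call. = FALSE)
      return(NA_real_)
    }
  }
  (mean(a) - mean(b)) / sqrt(s1^2 + s2^2)
}

#' Posterior summary table with prevalence ratios
#'
#' Per coefficient: posterior mean, median, 2.5% and 97.5% quantiles, the
#' prevalence ratio `PR = exp(coefficient)` with its 95% credible interval,
#' and the Geweke z score. Reference levels of factor covariates are
#' reported as `PR = 1.00` with no interval, mirroring the conventional
#' regression table layout.
#'
#' @param fit a `car_fit`.
#' @param prob credible level (default 0.95).
#' @return A data frame, one row per (reference or estimated) coefficient.
#' @export
posterior_summary <- function(fit, prob = 0.95) {
  if (!inherits(fit, "car_fit")) stop("`fit` must be a car_fit", call. = FALSE)
  draws <- fit$chains$beta
  if (is.null(draws) || !nrow(draws)) stop("fit has no retained draws", call. = FALSE)
  a <- (1 - prob) / 2
  rows <- list()
  add_row <- function(variable, d = NULL, reference = FALSE) {
    if (reference) {
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = variable, mean = 0, median = 0,
        lower = NA_real_, upper = NA_real_,
        PR = 1, PR_lower = NA_real_, PR_upper = NA_real_,
        geweke_z = NA_real_, reference = TRUE, stringsAsFactors = FALSE)
    } else {
      q <- stats::quantile(d, c(a, 0.5, 1 - a), names = FALSE)
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = variable, mean = mean(d), median = q[2],
        lower = q[1], upper = q[3],
        PR = exp(q[2]), PR_lower = exp(q[1]), PR_upper = exp(q[3]),
        geweke_z = if (length(d) >= 100) geweke_diagnostic(d) else NA_real_,
        reference = FALSE, stringsAsFactors = FALSE)
    }
  }
  done <- character(0)
  for (v in names(fit$xlevels)) {
    levs <- fit$xlevels[[v]]
    coefs <- paste0(v, levs)
    if (!any(coefs %in% colnames(draws))) next
    add_row(paste0(v, levs[1]), reference = TRUE)
    for (k in seq_along(levs)[-1]) {
      if (coefs[k] %in% colnames(draws)) {
        add_row(coefs[k], draws[, coefs[k]])
        done <- c(done, coefs[k])
      }
    }
    done <- c(done, coefs)
  }
  for (nm in setdiff(colnames(draws), done)) add_row(nm, draws[, nm])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
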