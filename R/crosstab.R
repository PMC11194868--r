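#' Cross-tabulate LISA clusters against a sociodemographic grouping
#'
#' Restricts the areas to cold spots (`low_low`) and hot spots (`high_high`)
#' — outliers and non-significant areas are excluded, as in the cluster-by-
#' covariate tables of small-area asthma analyses — and counts areas per
#' group. Column percentages (count / column total) are reported to one
#' decimal place.
#'
#' @param labels character vector of LISA labels (from [classify_lisa()]),
#'   or a classified `lisa_result`.
#' @param categories factor of per-area sociodemographic groups, aligned
#'   with `labels`.
#' @return An object of class `cluster_crosstab` with the count matrix
#'   (rows = groups, columns = `cold_spot`, `hot_spot`), column percentages,
#'   and margins. Run [chi_square_test()] to attach the test.
#' @export
crosstab_clusters <- function(labels, categories) {
  if (inherits(labels, "lisa_result")) {
    if (!("label" %in% names(labels)))
      stop("run classify_lisa() before cross-tabulating", call. = FALSE)
    labels <- labels$label
  }
  if (length(labels) != length(categories))
    stop("`labels` and `categories` must be aligned by area", call. = FALSE)
  categories <- as.factor(categories)
  keep <- labels %in% c("low_low", "high_high")
  cluster <- factor(ifelse(labels[keep] == "low_low", "cold_spot", "hot_spot"),
                    levels = c("cold_spot", "hot_spot"))
  counts <- table(group = categories[keep], cluster = cluster)
  counts <- unclass(counts)
  col_tot <- colSums(counts)
  degenerate <- any(col_tot == 0)
  if (degenerate)
    warning("degenerate table: empty ",
            paste(colnames(counts)[col_tot == 0], collapse = " and "),
            " column; chi-square skipped", call. = FALSE)
  pct <- sweep(counts, 2, pmax(col_tot, 1), "/") * 100
  structure(list(counts = counts,
                 percent = round(pct, 1),
                 row_totals = rowSums(counts),
                 col_totals = col_tot,
                 degenerate = degenerate,
                 chi2 = NULL, df = NULL, p_value = NULL),
            class = "cluster_crosstab")
}

#' Construct a cluster cross-tab from a count matrix
#'
#' For applying the cross-tab utilities to an externally tabulated
#' cluster-by-group count matrix (e.g. a published reference table).
#'
#' @param counts numeric matrix of nonnegative counts; rows are groups,
#'   columns cold/hot spots.
#' @return A `cluster_crosstab`.
#' @export
as_cluster_crosstab <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  col_tot <- colSums(counts)
  structure(list(counts = counts,
                 percent = round(sweep(counts, 2, pmax(col_tot, 1), "/") * 100, 1),
                 row_totals = rowSums(counts),
                 col_totals = col_tot,
                 degenerate = any(col_tot == 0),
                 chi2 = NULL, df = NULL, p_value = NULL),
            class = "cluster_crosstab")
}

#' Chi-square test of independence on a cluster cross-tab
#'
#' Pearson's statistic `sum (O - E)^2 / E` with expected counts from the
#' product of the margins, `(r - 1)(c - 1)` degrees of freedom and no
#' continuity correction.
#'
#' @param tab a `cluster_crosstab`.
#' @return `tab` with `chi2`, `df` and `p_value` filled in.
#' @export
chi_square_test <- function(tab) {
  if (!inherits(tab, "cluster_crosstab"))
    stop("`tab` must be a cluster_crosstab", call. = FALSE)
  counts <- tab$counts
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: a margin is zero", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tab$chi2 <- unname(ht$statistic)
  tab$df <- unname(ht$parameter)
  tab$p_value <- unname(ht$p.value)
  tab
}

#' @method print cluster_crosstab
#' @export
print.cluster_crosstab <- function(x, ...) {
  cat("Cluster x group cross-tabulation\n")
  disp <- matrix(sprintf("%d (%.1f%%)", x$counts, x$percent),
                 nrow = nrow(x$counts),
                 dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  cat("Column totals:", paste(colnames(x$counts), x$col_totals,
                              collapse = ", ", sep = " = "), "\n")
  if (!is.null(x$chi2))
    cat(sprintf("Chi-square = %.4f, df = %d, p %s\n", x$chi2, x$df,
                if (x$p_value < 0.001) "< 0.001"
                else paste0("= ", format(x$p_value, digits = 3))))
  invisible(x)
}

#' Reference cluster-by-sociodemography cross-tabulation
#'
#' Loads the published cold-spot/hot-spot count table from the national
#' 2021 census SA2-level childhood asthma analysis (548 cold spots, 465 hot
#' spots over 2,321 analysed areas), shipped with the package as a
#' plain-text fixture. Three blocks are available: the five disadvantage
#' categories, the Indigenous dichotomy, and their interaction.
#'
#' @param block `"seifa"`, `"indigenous"` or `"interaction"`.
#' @return A `cluster_crosstab` for the requested block.
#' @export
reference_crosstab <- function(block = c("seifa", "indigenous", "interaction")) {
  block <- match.arg(block)
  path <- system.file("extdata", "cluster_crosstab_reference.csv",
                      package = "asthmamap", mustWork = TRUE)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  ref <- ref[ref$block == block, ]
  m <- as.matrix(ref[, c("cold_spot", "hot_spot")])
  rownames(m) <- ref$group
  as_cluster_crosstab(m)
}
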