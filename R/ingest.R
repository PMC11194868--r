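#' Read an area-level table from CSV
#'
#' Required columns: `area_id`, `child_pop`, `total_pop`, `indigenous_pct`,
#' `seifa_score`, `seifa_decile`, and at least one of `asthma_count` or
#' `prevalence_pct` (counts are mandatory for the regression stage;
#' prevalence alone supports hotspot analysis). Missing disadvantage scores
#' must be encoded as empty/NA, never as zero.
#'
#' @param path CSV file path.
#' @return A `data.frame`, validated.
#' @export
read_area_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("area_id", "child_pop", "total_pop", "indigenous_pct",
                "seifa_score", "seifa_decile")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!("asthma_count" %in% names(tab)) && !("prevalence_pct" %in% names(tab)))
    stop("table needs an 'asthma_count' or 'prevalence_pct' column",
         call. = FALSE)
  tab$area_id <- as.character(tab$area_id)
  validate_area_table(tab)
  tab
}

#' Validate area-table invariants
#'
#' Checks non-negative counts, `asthma_count <= child_pop <= total_pop`,
#' decile range, and percentage bounds. Missing SEIFA scores are allowed.
#'
#' @param tab an area table.
#' @return `tab`, invisibly; errors on violation.
#' @export
validate_area_table <- function(tab) {
  bad <- function(msg, which) {
    stop("invalid area table: ", msg,
         " (e.g. area ", tab$area_id[which(which)[1L]], ")", call. = FALSE)
  }
  if (any(tab$child_pop < 0, na.rm = TRUE)) bad("negative child_pop", tab$child_pop < 0)
  if (any(tab$total_pop < 0, na.rm = TRUE)) bad("negative total_pop", tab$total_pop < 0)
  if ("asthma_count" %in% names(tab)) {
    if (any(tab$asthma_count < 0, na.rm = TRUE))
      bad("negative asthma_count", tab$asthma_count < 0)
    over <- !is.na(tab$asthma_count) & tab$asthma_count > tab$child_pop
    if (any(over)) bad("asthma_count exceeds child_pop", over)
  }
  if (any(tab$child_pop > tab$total_pop, na.rm = TRUE))
    bad("child_pop exceeds total_pop", tab$child_pop > tab$total_pop)
  dec <- tab$seifa_decile
  if (any(!is.na(dec) & (dec < 1 | dec > 10 | dec != floor(dec))))
    bad("seifa_decile outside 1..10", !is.na(dec) & (dec < 1 | dec > 10))
  if (any(tab$indigenous_pct < 0 | tab$indigenous_pct > 100, na.rm = TRUE))
    bad("indigenous_pct outside [0, 100]",
        tab$indigenous_pct < 0 | tab$indigenous_pct > 100)
  invisible(tab)
}

#' Apply the small-area exclusion rules
#'
#' Drops areas with fewer than `min_children` children aged 0-14, total
#' population below `min_population`, a missing disadvantage score, or no
#' remaining neighbour among the retained areas (isolation is re-checked
#' iteratively until stable, since dropping an area can isolate another).
#' A log records one reason per dropped area.
#'
#' @param table an area table.
#' @param graph the matching `area_graph` (same area ids).
#' @param min_children,min_population exclusion thresholds (defaults 5
#'   children and 200 residents).
#' @return A list with `table` and `graph` restricted to the retained areas,
#'   and `log` (a data frame `area_id`, `reason`).
#' @export
apply_exclusions <- function(table, graph, min_children = 5,
                             min_population = 200) {
  if (!setequal(table$area_id, graph$ids))
    stop("table and graph do not share the same area ids", call. = FALSE)
  ## align table to graph order
  table <- table[match(graph$ids, table$area_id), , drop = FALSE]
  reason <- rep(NA_character_, nrow(table))
  reason[is.na(reason) & table$child_pop < min_children] <-
    sprintf("children < %g", min_children)
  reason[is.na(reason) & table$total_pop < min_population] <-
    sprintf("population < %g", min_population)
  reason[is.na(reason) & is.na(table$seifa_score)] <- "missing SEIFA"
  keep <- is.na(reason)
  ## iterate the connectivity rule to a fixed point
  repeat {
    kept_idx <- which(keep)
    if (!length(kept_idx)) break
    has_nb <- vapply(kept_idx, function(i) any(keep[graph$nb[[i]]]), logical(1))
    if (all(has_nb)) break
    iso <- kept_idx[!has_nb]
    reason[iso] <- "isolated"
    keep[iso] <- FALSE
  }
  if (!any(keep))
    stop("all areas excluded; pipeline aborted", call. = FALSE)
  log <- data.frame(area_id = table$area_id[!keep],
                    reason = reason[!keep],
                    stringsAsFactors = FALSE)
  rownames(log) <- NULL
  out_tab <- table[keep, , drop = FALSE]
  rownames(out_tab) <- NULL
  list(table = out_tab, graph = subset_graph(graph, keep), log = log)
}

#' Derive the analysis variables
#'
#' Computes the prevalence (per 100 children), dichotomises the Indigenous
#' percentage at the median of the retained areas (ties go to the `high`
#' group), and maps disadvantage deciles to the five analysis categories:
#' deciles 1-2 most disadvantaged, 3-4 disadvantaged, 5-6 medium,
#' 7-8 advantaged, 9-10 most advantaged. The median threshold actually used
#' is attached as attribute `indigenous_threshold`.
#'
#' @param table an area table, exclusions already applied.
#' @param indigenous_threshold optional fixed threshold; default is the
#'   median of `indigenous_pct` in `table`.
#' @param require_counts error if `asthma_count` is absent (default the
#'   column is optional and prevalence is left as supplied).
#' @return `table` with `prevalence_pct`, `indigenous_group` and
#'   `seifa_category` columns.
#' @export
derive_analysis_variables <- function(table, indigenous_threshold = NULL,
                                      require_counts = FALSE) {
  if ("asthma_count" %in% names(table)) {
    if (any(table$child_pop == 0))
      stop("zero child population encountered after exclusions", call. = FALSE)
    table$prevalence_pct <- 100 * table$asthma_count / table$child_pop
  } else if (require_counts) {
    stop("asthma counts are required at this stage", call. = FALSE)
  }
  thr <- if (is.null(indigenous_threshold))
    stats::median(table$indigenous_pct) else indigenous_threshold
  table$indigenous_group <- factor(
    ifelse(table$indigenous_pct >= thr, "high", "low"),
    levels = c("low", "high"))
  cat_levels <- c("most_advantaged", "advantaged", "medium",
                  "disadvantaged", "most_disadvantaged")
  ## decile 1-2 -> most_disadvantaged ... 9-10 -> most_advantaged
  map <- rev(rep(cat_levels, each = 2))
  table$seifa_category <- factor(map[table$seifa_decile], levels = cat_levels)
  attr(table, "indigenous_threshold") <- thr
  table
}

#' Design matrix for the spatial regression
#'
#' Intercept, four disadvantage-category indicators (reference: most
#' advantaged, increasing disadvantage order as in the analysis tables), and
#' the high-Indigenous indicator.
#'
#' @param table an area table with derived analysis variables.
#' @return A numeric matrix with named columns.
#' @export
car_design <- function(table) {
  if (!all(c("seifa_category", "indigenous_group") %in% names(table)))
    stop("derived analysis variables are missing; call derive_analysis_variables()",
         call. = FALSE)
  s <- table$seifa_category
  cbind(`(Intercept)` = 1,
        seifa_categoryadvantaged = as.numeric(s == "advantaged"),
        seifa_categorymedium = as.numeric(s == "medium"),
        seifa_categorydisadvantaged = as.numeric(s == "disadvantaged"),
        seifa_categorymost_disadvantaged = as.numeric(s == "most_disadvantaged"),
        indigenous_grouphigh = as.numeric(table$indigenous_group == "high"))
}
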