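#' Spatial weights from an area graph
#'
#' Builds the weight matrix used by the spatial statistics: `binary`
#' (w_ij = 1 for neighbours, symmetric; the form entering the CAR precision)
#' or `row_standardised` (w_ij = 1/deg(i); the form entering Moran/LISA).
#'
#' @param graph an `area_graph` with no isolated areas.
#' @param style `"binary"` or `"row_standardised"`.
#' @return An object of class `area_weights`: the graph, the style, the
#'   sparse weight matrix `W`, and the total weight `S0`.
#' @export
build_weights <- function(graph, style = c("binary", "row_standardised")) {
  style <- match.arg(style)
  n <- length(graph$ids)
  deg <- lengths(graph$nb)
  if (any(deg == 0L))
    stop("graph has isolated areas (", paste(graph$ids[deg == 0L], collapse = ", "),
         "); rerun exclusions before building weights", call. = FALSE)
  i <- rep.int(seq_len(n), deg)
  j <- unlist(graph$nb, use.names = FALSE)
  x <- if (style == "binary") rep(1, length(i)) else 1 / deg[i]
  W <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                            dimnames = list(graph$ids, graph$ids))
  structure(list(graph = graph, style = style, W = W, S0 = sum(x)),
            class = "area_weights")
}

#' @method print area_weights
#' @export
print.area_weights <- function(x, ...) {
  cat("Spatial weights (", x$style, ")\n", sep = "")
  cat("  areas: ", length(x$graph$ids), ", S0 = ", format(x$S0), "\n", sep = "")
  invisible(x)
}

## binary adjacency matrix of the graph behind any weights object
.binary_W <- function(weights) {
  if (weights$style == "binary") weights$W
  else build_weights(weights$graph, "binary")$W
}

.as_weights <- function(x, style) {
  if (inherits(x, "area_weights")) {
    if (x$style == style) x else build_weights(x$graph, style)
  } else if (inherits(x, "area_graph")) {
    build_weights(x, style)
  } else stop("expected an `area_weights` or `area_graph` object", call. = FALSE)
}
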