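#' Node degrees
#'
#' @param net a network.
#' @return Named integer vector of degrees; isolated nodes report 0.
#' @export
node_degrees <- function(net) {
  .check_network(net)
  d <- igraph::degree(net)
  storage.mode(d) <- "integer"
  d
}

#' Normalized betweenness centrality
#'
#' Fraction of shortest paths between other node pairs that pass through
#' each node, normalized by `(n-1)(n-2)/2` so values lie in `[0, 1]`.
#' Unreachable pairs contribute nothing.  Networks with fewer than three
#' nodes have no interior pairs and return all zeros.
#'
#' @param net a network.
#' @return Named numeric vector in `[0, 1]`.
#' @export
node_betweenness <- function(net) {
  .check_network(net)
  n <- igraph::vcount(net)
  if (n == 0) return(setNames(numeric(), character()))
  if (n < 3) return(setNames(numeric(n), .node_names(net)))
  igraph::betweenness(net, directed = FALSE, normalized = TRUE)
}

#' Closeness centrality (component-restricted)
#'
#' Reciprocal of the mean shortest-path distance from a node to the nodes
#' reachable from it.  Unreachable nodes are excluded from the mean, so the
#' value stays in `[0, 1]` on disconnected networks; isolated nodes are
#' assigned 0 by convention.
#'
#' @param net a network.
#' @return Named numeric vector in `[0, 1]`.
#' @export
node_closeness <- function(net) {
  .check_network(net)
  n <- igraph::vcount(net)
  if (n == 0) return(setNames(numeric(), character()))
  D <- igraph::distances(net)
  cc <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else 1 / mean(d)
  }, numeric(1))
  setNames(cc, .node_names(net))
}

#' Per-node centrality table
#'
#' Combines degree, betweenness and closeness into one data frame, one row
#' per network node, optionally joined with gene symbols from an annotation
#' table.
#'
#' @param net a network.
#' @param annotations optional annotation data frame; when given, gene
#'   symbols are attached by accession.
#' @return Data frame with columns `accession`, `gene_symbol`, `degree`,
#'   `betweenness`, `closeness`.
#' @export
centrality_table <- function(net, annotations = NULL) {
  .check_network(net)
  nodes <- .node_names(net)
  tbl <- data.frame(
    accession = nodes,
    gene_symbol = nodes,
    degree = as.integer(node_degrees(net)[nodes]),
    betweenness = as.numeric(node_betweenness(net)[nodes]),
    closeness = as.numeric(node_closeness(net)[nodes]),
    stringsAsFactors = FALSE
  )
  if (!is.null(annotations)) {
    m <- match(tbl$accession, annotations$accession)
    hit <- !is.na(m)
    tbl$gene_symbol[hit] <- annotations$gene_symbol[m[hit]]
  }
  rownames(tbl) <- NULL
  tbl
}

#' Shortest-path length distribution and characteristic path length
#'
#' Computes the histogram of shortest-path lengths over all connected
#' unordered node pairs and the characteristic path length (their mean).
#' Unreachable pairs are excluded rather than given a penalty distance.  A
#' network with no connected pair returns an empty histogram and an
#' undefined (`NA`) characteristic path length.
#'
#' @param net a network.
#' @return An object of class `path_stats`: a list with `histogram` (named
#'   integer vector, names are path lengths) and
#'   `characteristic_path_length` (numeric, `NA` if undefined).
#' @export
path_stats <- function(net) {
  .check_network(net)
  n <- igraph::vcount(net)
  if (n < 2) {
    return(structure(list(histogram = setNames(integer(), character()),
                          characteristic_path_length = NA_real_),
                     class = "path_stats"))
  }
  D <- igraph::distances(net)
  d <- D[upper.tri(D)]
  d <- d[is.finite(d) & d > 0]
  if (length(d) == 0) {
    hist <- setNames(integer(), character())
    cpl <- NA_real_
  } else {
    tab <- table(d)
    hist <- setNames(as.integer(tab), names(tab))
    cpl <- mean(d)
  }
  structure(list(histogram = hist, characteristic_path_length = cpl),
            class = "path_stats")
}

#' @export
print.path_stats <- function(x, ...) {
  cat("Shortest-path statistics\n")
  if (length(x$histogram) == 0) {
    cat("  no connected node pairs\n")
  } else {
    cat(sprintf("  connected pairs: %d\n", sum(x$histogram)))
    cat(sprintf("  characteristic path length: %.4g\n",
                x$characteristic_path_length))
    print(x$histogram)
  }
  invisible(x)
}

#' Least-squares power-law fit of a degree distribution
#'
#' Builds the empirical degree distribution `P(k)` over the positive degrees
#' (degree-0 nodes are excluded; `log 0` is undefined) and fits ordinary
#' least squares of `log10 P(k)` on `log10 k`, one point per observed
#' degree, with no binning.  The slope is the degree exponent; `r_squared`
#' is the coefficient of determination of the regression.
#'
#' @param deg named integer vector of node degrees (e.g. [node_degrees()]).
#' @return An object of class `powerlaw_fit` with elements `exponent`,
#'   `intercept`, `r_squared`, `n_points`, and the fitted points `points`
#'   (data frame with `k`, `p`).
#' @export
fit_power_law <- function(deg) {
  deg <- as.numeric(deg)
  n <- length(deg)
  kpos <- deg[deg > 0]
  tab <- table(kpos)
  k <- as.numeric(names(tab))
  if (length(k) < 2) {
    stop("power-law fit needs at least 2 distinct positive degrees",
         call. = FALSE)
  }
  p <- as.numeric(tab) / n
  fit <- lm(log10(p) ~ log10(k))
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((log10(p) - mean(log10(p)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(exponent = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = r2,
         n_points = length(k),
         points = data.frame(k = k, p = p)),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Power-law degree-distribution fit (log-log least squares)\n")
  cat(sprintf("  exponent (slope): %.4g\n", x$exponent))
  cat(sprintf("  intercept:        %.4g\n", x$intercept))
  cat(sprintf("  R-squared:        %.4g\n", x$r_squared))
  cat(sprintf("  points fitted:    %d\n", x$n_points))
  invisible(x)
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(intercept = object$intercept, exponent = object$exponent)
}

#' @export
#' @importFrom graphics abline plot
plot.powerlaw_fit <- function(x, ...) {
  plot(log10(x$points$k), log10(x$points$p),
       xlab = "log10 k", ylab = "log10 P(k)",
       main = "Degree distribution (log-log)", ...)
  abline(x$intercept, x$exponent, lty = 2)
  invisible(x)
}
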