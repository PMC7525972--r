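#' Node centralities of a consensus network
#'
#' Computed on the unweighted directed graph (edge presence only): degree =
#' in + out; betweenness over directed unweighted shortest paths; closeness
#' as outgoing harmonic centrality (mean of 1/distance over all other nodes),
#' which handles disconnected graphs gracefully and scores isolated nodes 0.
#' With `weighted = TRUE` shortest paths use distance 1/|mean_strength|.
#'
#' @param network a `consensus_network`.
#' @param weighted use interaction strength as inverse edge length?
#' @return data.frame: taxon, degree, betweenness, closeness.
#' @export
centralities <- function(network, weighted = FALSE) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (n < 1L) abort("network has no nodes")
  w <- if (weighted && igraph::ecount(g) > 0)
    1 / abs(igraph::E(g)$mean_strength) else NA
  deg <- igraph::degree(g, mode = "all")
  btw <- if (igraph::ecount(g) > 0)
    igraph::betweenness(g, directed = TRUE, weights = w)
  else rep(0, n)
  clo <- if (n > 1L)
    igraph::harmonic_centrality(g, mode = "out", weights = w,
                                normalized = TRUE)
  else 0
  data.frame(taxon = igraph::V(g)$name, degree = as.integer(deg),
             betweenness = as.numeric(btw), closeness = as.numeric(clo),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate centrality ranks and flag key microbes
#'
#' Each centrality is ranked descending (1 = best) with ties averaged; the
#' total rank is the sum of the three component ranks; the final rank is the
#' dense rank of the total (ascending), so nodes tying on total rank share a
#' final rank. Nodes with final rank 1 are flagged as key microbes.
#'
#' @param x a centrality data.frame from [centralities()] or a
#'   `consensus_network` (centralities are computed first).
#' @return data.frame of class `centrality_report` with the scores, the three
#'   component ranks, `total_rank`, `final_rank` and logical `key`.
#' @export
rank_aggregate <- function(x) {
  if (inherits(x, "consensus_network")) x <- centralities(x)
  need <- c("taxon", "degree", "betweenness", "closeness")
  if (!all(need %in% names(x)))
    abort("need columns %s", paste(need, collapse = ", "))
  if (nrow(x) < 1L) abort("no nodes to rank")
  rk <- function(v) rank(-v, ties.method = "average")
  out <- x
  out$rank_degree <- rk(x$degree)
  out$rank_betweenness <- rk(x$betweenness)
  out$rank_closeness <- rk(x$closeness)
  out$total_rank <- out$rank_degree + out$rank_betweenness + out$rank_closeness
  out$final_rank <- match(out$total_rank, sort(unique(out$total_rank)))
  out$key <- out$final_rank == 1L
  class(out) <- c("centrality_report", "data.frame")
  out
}

#' Key microbes of a report
#' @param report a [rank_aggregate()] result.
#' @return character vector of taxa with final rank 1.
#' @export
key_microbes <- function(report) report$taxon[report$key]

#' Regress final rank on the three component ranks
#'
#' Ordinary least squares of the final rank on the degree, closeness and
#' betweenness ranks; used to confirm that the aggregated rank is concordant
#' with its components. Predictors dropped by R for collinearity are
#' reported via a message.
#'
#' @param report a [rank_aggregate()] result with >= 5 nodes.
#' @return list with `r_squared`, `p_value` (overall F) and the `lm` fit.
#' @export
rank_regression <- function(report) {
  need <- c("final_rank", "rank_degree", "rank_closeness", "rank_betweenness")
  if (!all(need %in% names(report))) abort("not a centrality report")
  if (nrow(report) < 5L)
    abort("need >= 5 nodes for 3 predictors (got %d)", nrow(report))
  fit <- stats::lm(final_rank ~ rank_degree + rank_closeness + rank_betweenness,
                   data = report)
  dropped <- names(which(is.na(stats::coef(fit))))
  if (length(dropped))
    message("collinear predictors dropped: ", paste(dropped, collapse = ", "))
  s <- summary(fit)
  p <- if (is.null(s$fstatistic)) NA_real_ else
    unname(stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                     lower.tail = FALSE))
  list(r_squared = s$r.squared, p_value = p, model = fit)
}

#' Number of weakly connected components
#'
#' 1 means the network is unfragmented; every isolated node adds one.
#'
#' @param network a `consensus_network`.
#' @return integer component count.
#' @export
fragmentation <- function(network) {
  g <- as_igraph(network)
  if (igraph::vcount(g) < 1L) abort("network has no nodes")
  as.integer(igraph::components(g, mode = "weak")$no)
}

#' Focal-taxon interaction report
#'
#' Splits the focal taxon's incident edges into the four lists used by the
#' study's per-genus tables: who influences it (incoming edges) and whom it
#' influences (outgoing edges), by interaction sign. Lists are alphabetical.
#'
#' @param network a `consensus_network`.
#' @param focal_taxon a node label.
#' @return object of class `focal_report` with the four lists and `counts`
#'   (in_positive, in_negative, out_positive, out_negative).
#' @export
focal_report <- function(network, focal_taxon) {
  stopifnot(inherits(network, "consensus_network"))
  if (!(focal_taxon %in% network$taxa))
    abort("'%s' is not a network node; available: %s", focal_taxon,
          paste(network$taxa, collapse = ", "))
  e <- network$edges
  pick <- function(rows, col) sort(unique(e[[col]][rows]))
  inc <- e$target == focal_taxon & e$source != focal_taxon
  out <- e$source == focal_taxon & e$target != focal_taxon
  res <- list(
    focal = focal_taxon,
    influenced_by_positive = pick(inc & e$sign == "+", "source"),
    influenced_by_negative = pick(inc & e$sign == "-", "source"),
    influences_positive = pick(out & e$sign == "+", "target"),
    influences_negative = pick(out & e$sign == "-", "target"))
  res$counts <- c(in_positive = length(res$influenced_by_positive),
                  in_negative = length(res$influenced_by_negative),
                  out_positive = length(res$influences_positive),
                  out_negative = length(res$influences_negative))
  structure(res, class = "focal_report")
}

#' @export
print.focal_report <- function(x, ...) {
  cat(sprintf("focal taxon %s: influenced by %d (+) / %d (-), influences %d (+) / %d (-)\n",
              x$focal, x$counts[1], x$counts[2], x$counts[3], x$counts[4]))
  invisible(x)
}

#' @export
as.data.frame.focal_report <- function(x, ...) {
  lists <- x[c("influenced_by_positive", "influenced_by_negative",
               "influences_positive", "influences_negative")]
  len <- max(lengths(lists), 1L)
  as.data.frame(lapply(lists, function(v) c(v, rep("", len - length(v)))),
                stringsAsFactors = FALSE)
}
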