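#' Fit the gLV regression to every assembly of a group
#'
#' @param table an [abundance_table()].
#' @param group group label.
#' @param assemblies integer matrix from [enumerate_assemblies()].
#' @param config a [glv_fit_config()].
#' @return object of class `glv_ensemble`: `b` (members x taxa growth
#'   matrix), `a` (taxa x taxa x members interaction array), `taxa`,
#'   `assemblies`, `config`, `group`.
#' @export
infer_ensemble <- function(table, group, assemblies,
                           config = glv_fit_config()) {
  stopifnot(inherits(table, "abundance_table"))
  assemblies <- as.matrix(assemblies)
  M <- nrow(assemblies)
  if (M < 1L) abort("'assemblies' is empty")
  n <- length(table$taxa)
  b <- matrix(NA_real_, M, n, dimnames = list(NULL, table$taxa))
  a <- array(NA_real_, c(n, n, M), dimnames = list(table$taxa, table$taxa, NULL))
  for (m in seq_len(M)) {
    fit <- tryCatch(
      fit_glv_series(assemble_series(table, group, assemblies[m, ]),
                     config = config),
      error = function(e) abort("assembly %d failed: %s", m, conditionMessage(e)))
    b[m, ] <- fit$growth
    a[, , m] <- fit$interactions
  }
  structure(list(b = b, a = a, taxa = table$taxa, assemblies = assemblies,
                 config = config, group = group),
            class = "glv_ensemble")
}

#' @export
print.glv_ensemble <- function(x, ...) {
  cat(sprintf("gLV coefficient ensemble: %d members, %d taxa (group %s, %s)\n",
              nrow(x$b), length(x$taxa), x$group, x$config$regression))
  invisible(x)
}

#' Smallest member count exceeding a consensus cutoff
#'
#' Returns the smallest integer m with `m > cutoff * ensemble_size` (strict
#' inequality), e.g. 124,003 members for a 70% cutoff over 177,147.
#'
#' @param ensemble_size number of ensemble members.
#' @param cutoff consensus fraction in (0, 1).
#' @return integer support count threshold.
#' @export
support_threshold_count <- function(ensemble_size, cutoff) {
  ensemble_size <- assert_count(ensemble_size, "ensemble_size")
  assert_fraction(cutoff, "cutoff", open_lo = TRUE, open_hi = TRUE)
  # tiny forward nudge so exact multiples (0.7 * 10 = 7) floor correctly
  as.integer(floor(cutoff * ensemble_size + 1e-9)) + 1L
}

new_consensus_network <- function(taxa, edges, cutoff = NA_real_,
                                  n_members = NA_integer_) {
  cols <- c("source", "target", "sign", "support", "mean_strength")
  for (cl in setdiff(cols, names(edges)))
    edges[[cl]] <- rep(if (cl == "sign") NA_character_ else NA_real_,
                       nrow(edges))
  edges <- edges[, cols, drop = FALSE]
  if (nrow(edges)) {
    if (!all(edges$sign %in% c("+", "-"))) abort("edge signs must be '+' or '-'")
    if (!all(edges$source %in% taxa) || !all(edges$target %in% taxa))
      abort("edge endpoints must be network taxa")
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(taxa = taxa, edges = edges, cutoff = cutoff,
                 n_members = n_members),
            class = "consensus_network")
}

#' Sign-consensus network from a coefficient ensemble
#'
#' An ordered interaction j -> i becomes an edge when strictly more than
#' `cutoff` of the ensemble members fitted `A[i, j]` with the same sign.
#' Edge support is that fraction and `mean_strength` is the mean coefficient
#' over the supporting members. Self-loops are excluded by default (the
#' fitted self-limitation `A[i, i]` stays in the ensemble).
#'
#' @param ensemble a [infer_ensemble()] result.
#' @param cutoff consensus fraction in (0, 1); default 0.7.
#' @param include_self keep i -> i edges? default FALSE.
#' @return object of class `consensus_network` with `taxa` and an `edges`
#'   data.frame (source, target, sign, support, mean_strength).
#' @export
consensus_network <- function(ensemble, cutoff = 0.7, include_self = FALSE) {
  stopifnot(inherits(ensemble, "glv_ensemble"))
  M <- dim(ensemble$a)[3]
  thr <- support_threshold_count(M, cutoff)
  pos <- apply(ensemble$a > 0, c(1, 2), sum)
  neg <- apply(ensemble$a < 0, c(1, 2), sum)
  keep_pos <- pos >= thr
  keep_neg <- neg >= thr
  both <- keep_pos & keep_neg            # possible only when cutoff < 0.5
  keep_pos[both] <- pos[both] > neg[both]
  keep_neg[both] <- neg[both] > pos[both]
  if (!include_self) {
    diag(keep_pos) <- FALSE
    diag(keep_neg) <- FALSE
  }
  edge_rows <- function(keep, sgn, count) {
    idx <- which(keep, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    ms <- vapply(seq_len(nrow(idx)), function(r) {
      v <- ensemble$a[idx[r, 1], idx[r, 2], ]
      mean(v[if (sgn == "+") v > 0 else v < 0])
    }, numeric(1))
    data.frame(source = ensemble$taxa[idx[, 2]],
               target = ensemble$taxa[idx[, 1]],
               sign = sgn, support = count[idx] / M, mean_strength = ms,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(edge_rows(keep_pos, "+", pos), edge_rows(keep_neg, "-", neg))
  if (is.null(edges))
    edges <- data.frame(source = character(0), target = character(0),
                        sign = character(0), support = numeric(0),
                        mean_strength = numeric(0))
  new_consensus_network(ensemble$taxa, edges, cutoff, M)
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("consensus network: %d taxa, %d edges (%d +, %d -), cutoff %s\n",
              length(x$taxa), nrow(x$edges), sum(x$edges$sign == "+"),
              sum(x$edges$sign == "-"),
              ifelse(is.na(x$cutoff), "?", format(x$cutoff))))
  invisible(x)
}

#' Convert a consensus network to an igraph graph
#'
#' @param network a `consensus_network`.
#' @return directed igraph graph with edge attributes sign, support,
#'   mean_strength; isolated taxa are kept as vertices.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "consensus_network"))
  igraph::graph_from_data_frame(network$edges,
                                vertices = data.frame(name = network$taxa),
                                directed = TRUE)
}

#' Write / read a consensus network edge list as CSV
#'
#' Columns: source, target, sign, support, mean_strength. Reading accepts
#' files without support/mean_strength (filled with 1 / signed 1).
#'
#' @param network a `consensus_network`.
#' @param path CSV file path.
#' @param taxa node set for reading; default = all endpoint labels.
#' @return [write_network_edges()] the path, invisibly;
#'   [read_network_edges()] a `consensus_network`.
#' @export
write_network_edges <- function(network, path) {
  stopifnot(inherits(network, "consensus_network"))
  utils::write.csv(network$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network_edges
#' @export
read_network_edges <- function(path, taxa = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  e <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("source", "target", "sign") %in% names(e)))
    abort("edge CSV needs columns source, target, sign")
  if (is.null(e$support)) e$support <- rep(1, nrow(e))
  if (is.null(e$mean_strength))
    e$mean_strength <- ifelse(e$sign == "+", 1, -1)
  taxa <- taxa %||% sort(unique(c(e$source, e$target)))
  new_consensus_network(taxa, e)
}

#' Export a consensus network for Gephi
#'
#' GraphML via igraph; GEXF 1.2 written directly (igraph has no GEXF
#' support). Edge weight is |mean_strength|, sign kept as an attribute.
#'
#' @param network a `consensus_network`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' @rdname write_network_graphml
#' @export
write_network_gexf <- function(network, path) {
  stopifnot(inherits(network, "consensus_network"))
  ids <- stats::setNames(seq_along(network$taxa) - 1L, network$taxa)
  e <- network$edges
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph mode="static" defaultedgetype="directed">',
    '    <attributes class="edge">',
    '      <attribute id="0" title="sign" type="string"/>',
    '      <attribute id="1" title="support" type="double"/>',
    '    </attributes>',
    '    <nodes>',
    sprintf('      <node id="%d" label="%s"/>', ids, xml_escape(names(ids))),
    '    </nodes>',
    '    <edges>',
    if (nrow(e)) sprintf(paste0(
      '      <edge id="%d" source="%d" target="%d" weight="%.8g">',
      '<attvalues><attvalue for="0" value="%s"/>',
      '<attvalue for="1" value="%.6g"/></attvalues></edge>'),
      seq_len(nrow(e)) - 1L, ids[e$source], ids[e$target],
      abs(e$mean_strength), e$sign, e$support),
    '    </edges>',
    '  </graph>',
    '</gexf>')
  writeLines(lines, path)
  invisible(path)
}
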