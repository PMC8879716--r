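#' Parse knowledge-graph triples from a file
#'
#' Reads a multi-relational graph as (head, relation, tail) statements from
#' either a headerless 3-column TSV (lines starting with `#` are comments) or
#' a restricted n-quads serialisation `<head> <relation> <tail> [<graph>] .`
#' where the optional fourth (named-graph) term is discarded and literal tails
#' are kept as plain entity strings.
#'
#' Malformed lines are skipped and counted; if their fraction exceeds
#' `malformed_threshold` parsing aborts with the offending line numbers.
#'
#' @param path path to the triple file.
#' @param dialect `"tsv"` or `"nquads"`.
#' @param malformed_threshold maximum tolerated fraction of malformed lines
#'   (default 0.05).
#' @return a data.frame with character columns `head`, `relation`, `tail` and
#'   attribute `n_malformed`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("DB00437\ttargets\tP12345", tf)
#' parse_triples(tf, "tsv")
parse_triples <- function(path, dialect = c("tsv", "nquads"),
                          malformed_threshold = 0.05) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_smilegnn("triple file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop_smilegnn("triple file is empty: %s", path)

  if (dialect == "tsv") {
    parts <- strsplit(lines[idx], "\t", fixed = TRUE)
    ok <- vapply(parts, function(p) length(p) == 3L && all(nzchar(trimws(p))),
                 logical(1))
    hrt <- do.call(rbind, parts[ok])
  } else {
    # <iri> <iri> (<iri> | "literal"...) [<iri>] .
    term <- "(<[^>]*>|\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^<[^>]*>|@[A-Za-z-]+)?)"
    pat <- paste0("^\\s*", term, "\\s+", term, "\\s+", term,
                  "(\\s+", term, ")?\\s*\\.\\s*$")
    m <- regmatches(lines[idx], regexec(pat, lines[idx], perl = TRUE))
    ok <- lengths(m) > 0L
    strip <- function(x) {
      x <- sub("^<(.*)>$", "\\1", x)
      x <- sub("^\"((?:[^\"\\\\]|\\\\.)*)\".*$", "\\1", x)
      x
    }
    hrt <- do.call(rbind, lapply(m[ok], function(g) strip(g[2:4])))
    if (!is.null(hrt)) ok <- ok & TRUE
  }

  bad <- idx[!ok]
  if (length(bad) / length(idx) > malformed_threshold) {
    stop_smilegnn(
      "%d of %d lines malformed (threshold %.1f%%); first bad lines: %s",
      length(bad), length(idx), 100 * malformed_threshold,
      paste(utils::head(bad, 5), collapse = ", "))
  }
  if (length(bad) > 0) {
    warning(sprintf("skipped %d malformed line(s) in %s", length(bad), path),
            call. = FALSE)
  }
  if (is.null(hrt) || nrow(hrt) == 0L) {
    stop_smilegnn("no well-formed triples found in %s", path)
  }
  out <- data.frame(head = hrt[, 1], relation = hrt[, 2], tail = hrt[, 3],
                    stringsAsFactors = FALSE)
  attr(out, "n_malformed") <- length(bad)
  out
}

#' Write triples as 3-column TSV
#' @param triples data.frame with `head`, `relation`, `tail`.
#' @param path output path.
#' @export
write_triples <- function(triples, path) {
  utils::write.table(triples[, c("head", "relation", "tail")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Index triples into a knowledge-graph object
#'
#' Assigns contiguous integer ids to entities (first-appearance order, heads
#' before tails within a triple) and relations, collapses duplicate triples,
#' drops self-loops, and builds an undirected adjacency view in which each
#' edge keeps its relation id. Drug entities are identified either by an
#' explicit character vector of ids or by a prefix rule (default: ids starting
#' with `"DB"`, the DrugBank convention).
#'
#' @param triples data.frame from [parse_triples()] or equivalent.
#' @param drug_ids optional character vector naming the drug entities.
#' @param drug_prefix prefix identifying drug entities when `drug_ids` is NULL.
#' @return an object of class `knowledge_graph`: entity/relation indices,
#'   adjacency lists (`$adj[[i]]` is a list with integer vectors `nbr`, `rel`),
#'   and `drug_idx`, the integer ids of drug entities.
#' @export
index_graph <- function(triples, drug_ids = NULL, drug_prefix = "DB") {
  stopifnot(nrow(triples) > 0)
  h <- as.character(triples$head)
  r <- as.character(triples$relation)
  t <- as.character(triples$tail)

  # entity ids in first-appearance order over the interleaved head/tail
  # stream, BEFORE dropping loops: an entity seen only in self-loops stays
  # indexed (isolated), it just has no edges
  ents <- unique(as.vector(rbind(h, t)))
  rels <- unique(r)

  self <- h == t
  n_self <- sum(self)
  if (n_self > 0) { h <- h[!self]; r <- r[!self]; t <- t[!self] }
  if (length(h) == 0L) stop_smilegnn("no non-loop triples to index")

  key <- paste(h, r, t, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup > 0) { h <- h[!dup]; r <- r[!dup]; t <- t[!dup] }
  hi <- match(h, ents); ti <- match(t, ents); ri <- match(r, rels)

  n <- length(ents)
  # undirected adjacency with relation retained; dedupe (node, nbr, rel)
  node <- c(hi, ti); nbr <- c(ti, hi); rel <- c(ri, ri)
  ekey <- paste(node, nbr, rel)
  keep <- !duplicated(ekey)
  node <- node[keep]; nbr <- nbr[keep]; rel <- rel[keep]
  o <- order(node)
  adj_nbr <- split(nbr[o], factor(node[o], levels = seq_len(n)))
  adj_rel <- split(rel[o], factor(node[o], levels = seq_len(n)))
  adj <- lapply(seq_len(n), function(i) {
    list(nbr = as.integer(adj_nbr[[i]]), rel = as.integer(adj_rel[[i]]))
  })

  if (is.null(drug_ids)) {
    drug_idx <- which(startsWith(ents, drug_prefix))
  } else {
    drug_idx <- which(ents %in% drug_ids)
  }
  if (length(drug_idx) == 0L) {
    stop_smilegnn("no drug entities identified (prefix '%s'); cannot train",
                  drug_prefix %||% "<none>")
  }

  structure(
    list(entities = ents, relations = rels, adj = adj,
         drug_idx = as.integer(drug_idx),
         n_edges = length(node) %/% 2L,
         n_dropped = c(self_loops = n_self, duplicates = n_dup)),
    class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf(
    "<knowledge_graph> %d entities (%d drugs), %d relations, %d edges\n",
    length(x$entities), length(x$drug_idx), length(x$relations), x$n_edges))
  invisible(x)
}

kg_entity_id <- function(kg, names) {
  i <- match(names, kg$entities)
  if (anyNA(i)) {
    stop_smilegnn("unknown entities: %s",
                  paste(utils::head(names[is.na(i)], 5), collapse = ", "))
  }
  i
}

#' Graph density
#'
#' For an undirected graph with `N` nodes and `L` edges the density is
#' \eqn{d(G) = 2L / (N(N-1))}, the fraction of possible edges present.
#'
#' @param n_nodes number of nodes, at least 2.
#' @param n_edges number of undirected edges.
#' @return an object of class `density_report` with fields `n_nodes`,
#'   `n_edges`, `density`.
#' @export
#' @examples
#' graph_density(1495, 36768)
graph_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop_smilegnn("density needs at least 2 nodes, got %s", n_nodes)
  if (n_edges < 0) stop_smilegnn("negative edge count")
  if (n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop_smilegnn("edge count %s exceeds simple-graph maximum %s",
                  format(n_edges), format(n_nodes * (n_nodes - 1) / 2))
  }
  structure(list(n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
                 density = 2 * n_edges / (n_nodes * (n_nodes - 1))),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("<density_report> N = %d, L = %d, d(G) = %s\n",
              x$n_nodes, x$n_edges, format(signif(x$density, 4))))
  invisible(x)
}

#' @export
format.density_report <- function(x, ...) format(signif(x$density, 4))

#' Density of the drug-drug interaction subgraph
#'
#' Treats the drug entities of the knowledge graph as nodes and the distinct
#' unordered positive pairs of `pairs` as edges, then delegates to
#' [graph_density()].
#'
#' @param pairs a pair dataset (see [pair_dataset()]) or data.frame with
#'   columns `drug1`, `drug2`, `label`.
#' @param kg a `knowledge_graph`.
#' @return a `density_report`.
#' @export
ddi_subgraph_density <- function(pairs, kg) {
  n_drugs <- length(kg$drug_idx)
  if (n_drugs < 2) stop_smilegnn("fewer than 2 drug entities in the graph")
  pos <- pairs[pairs$label == 1, , drop = FALSE]
  key <- pair_key(pos$drug1, pos$drug2)
  graph_density(n_drugs, length(unique(key)))
}

# canonical unordered-pair key
pair_key <- function(a, b) {
  paste(pmin(as.character(a), as.character(b)),
        pmax(as.character(a), as.character(b)), sep = "\r")
}
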