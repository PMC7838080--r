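# Sequence similarity network: build, threshold, cluster, assign, export.
# igraph supplies components and GraphML IO; thresholding semantics, the
# deterministic cluster numbering and query assignment live here.

#' Build a sequence similarity network
#'
#' Nodes are every id appearing in the alignment table (whether or not any of
#' its alignments pass) plus explicitly registered singletons; an edge is kept
#' iff its E-value is at or below the cutoff. The graph is simple and
#' undirected: self-alignments are dropped and duplicate undirected pairs
#' collapse to the first occurrence.
#'
#' @param alignments data frame from [all_vs_all()] (each unordered pair once).
#' @param evalue_cutoff positive E-value threshold; the canonical SSN
#'   visualization cutoff of the family analysis is `10^-51.5`.
#' @param singletons ids to register as nodes even without alignments.
#' @param labels optional named character vector id -> function label for
#'   characterized enzymes.
#' @param members optional named list id -> collapsed member ids (from
#'   [collapse_redundancy()]); defaults to each node representing itself.
#' @return A list of class `"ssn"` with `nodes` (id, label, member_count),
#'   `edges` (from, to, evalue, identity, bit_score), `members`,
#'   `evalue_cutoff`.
#' @export
build_ssn <- function(alignments, evalue_cutoff, singletons = character(),
                      labels = NULL, members = NULL) {
  if (!is.numeric(evalue_cutoff) || length(evalue_cutoff) != 1L ||
      evalue_cutoff <= 0) {
    stop("`evalue_cutoff` must be a single positive number")
  }
  ids <- sort(unique(c(alignments$query_id, alignments$subject_id,
                       singletons)))
  ed <- alignments[alignments$evalue <= evalue_cutoff &
                     alignments$query_id != alignments$subject_id, ,
                   drop = FALSE]
  if (nrow(ed)) {
    lo <- pmin(ed$query_id, ed$subject_id)
    hi <- pmax(ed$query_id, ed$subject_id)
    keep <- !duplicated(paste0(lo, "\r", hi))
    ed <- data.frame(from = lo[keep], to = hi[keep],
                     evalue = ed$evalue[keep],
                     identity = ed$identity[keep],
                     bit_score = ed$bit_score[keep],
                     stringsAsFactors = FALSE)
    ed <- ed[order(ed$from, ed$to), , drop = FALSE]
    rownames(ed) <- NULL
  } else {
    ed <- data.frame(from = character(), to = character(),
                     evalue = numeric(), identity = numeric(),
                     bit_score = numeric(), stringsAsFactors = FALSE)
  }
  if (is.null(members)) members <- stats::setNames(as.list(ids), ids)
  node_labels <- if (is.null(labels)) rep(NA_character_, length(ids)) else
    unname(labels[ids])
  nodes <- data.frame(id = ids,
                      label = node_labels,
                      member_count = vapply(ids, function(i) {
                        if (is.null(members[[i]])) 1L else
                          length(members[[i]])
                      }, integer(1L)),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = ed, members = members[ids],
                 evalue_cutoff = evalue_cutoff),
            class = "ssn")
}

#' @export
print.ssn <- function(x, ...) {
  cat(sprintf("SSN: %d nodes, %d edges (E-value cutoff %.3g)\n",
              nrow(x$nodes), nrow(x$edges), x$evalue_cutoff))
  invisible(x)
}

.ssn_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = graph$nodes)
}

#' Connected components of an SSN, with deterministic numbering
#'
#' Clusters are the connected components; indices are assigned by decreasing
#' size with ties broken by the lexicographically smallest member id, so the
#' numbering does not depend on input order.
#'
#' @param graph an `"ssn"` object.
#' @return A list of class `"ssn_clusters"` with `membership` (named integer
#'   vector node id -> cluster index), `clusters` (list of sorted member-id
#'   vectors) and `labels` (list of character labels present per cluster).
#' @export
ssn_components <- function(graph) {
  g <- .ssn_igraph(graph)
  comp <- igraph::components(g)
  raw <- split(names(comp$membership), comp$membership)
  raw <- lapply(raw, sort)
  ord <- order(-lengths(raw), vapply(raw, `[`, character(1L), 1L))
  clusters <- unname(raw[ord])
  membership <- integer(nrow(graph$nodes))
  names(membership) <- graph$nodes$id
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  lab <- stats::setNames(graph$nodes$label, graph$nodes$id)
  labels <- lapply(clusters, function(m) {
    l <- lab[m]
    sort(l[!is.na(l)])
  })
  structure(list(membership = membership, clusters = clusters,
                 labels = labels),
            class = "ssn_clusters")
}

#' @export
print.ssn_clusters <- function(x, ...) {
  cat(sprintf("SSN clusters: %d clusters, largest %d nodes\n",
              length(x$clusters), max(lengths(x$clusters))))
  invisible(x)
}

#' Sweep E-value cutoffs over an alignment table
#'
#' Rebuilds the SSN and its components at each cutoff over a fixed node set
#' (every id in the alignment table), returning one summary row per cutoff.
#' Because loosening the cutoff can only add edges, the number of clusters is
#' non-increasing as the cutoff loosens.
#'
#' @param alignments data frame from [all_vs_all()].
#' @param cutoffs numeric vector of E-value cutoffs (any order).
#' @param singletons ids to register as nodes even without alignments.
#' @return Data frame with columns `cutoff`, `n_edges`, `n_clusters`,
#'   `largest_cluster_size`.
#' @export
threshold_sweep <- function(alignments, cutoffs, singletons = character()) {
  rows <- lapply(cutoffs, function(ct) {
    g <- build_ssn(alignments, ct, singletons = singletons)
    cl <- ssn_components(g)
    data.frame(cutoff = ct, n_edges = nrow(g$edges),
               n_clusters = length(cl$clusters),
               largest_cluster_size = max(lengths(cl$clusters)))
  })
  do.call(rbind, rows)
}

#' Assign a query to an SSN cluster by co-membership
#'
#' The query is attached through its alignments that pass the cutoff; the
#' report lists the characterized labels present in the resulting cluster and
#' the best-E-value characterized direct neighbor. When no alignment passes,
#' the verdict is `"unclustered"`.
#'
#' @param graph an `"ssn"` object (query id must not already be a node).
#' @param query_alignments data frame of the query's local alignments against
#'   graph nodes (in [all_vs_all()] layout, query on either side).
#' @param query_id the query identifier.
#' @param evalue_cutoff defaults to the graph's cutoff.
#' @return A list of class `"ssn_assignment"`: `query_id`, `status`
#'   (`"clustered"`/`"unclustered"`), `cluster_members`, `labels`,
#'   `best_neighbor` (list with `id`, `label`, `evalue`, or `NULL`),
#'   `n_passing_edges`.
#' @export
assign_query <- function(graph, query_alignments, query_id,
                         evalue_cutoff = graph$evalue_cutoff) {
  if (query_id %in% graph$nodes$id) {
    stop("query id already present in the graph: ", query_id)
  }
  qa <- query_alignments[query_alignments$query_id == query_id |
                           query_alignments$subject_id == query_id, ,
                         drop = FALSE]
  other <- ifelse(qa$query_id == query_id, qa$subject_id, qa$query_id)
  pass <- qa$evalue <= evalue_cutoff & other %in% graph$nodes$id
  qa <- qa[pass, , drop = FALSE]
  other <- other[pass]
  if (nrow(qa) == 0L) {
    return(structure(list(query_id = query_id, status = "unclustered",
                          cluster_members = character(),
                          labels = character(), best_neighbor = NULL,
                          n_passing_edges = 0L),
                     class = "ssn_assignment"))
  }
  cl <- ssn_components(graph)
  joined <- unique(cl$membership[other])
  members <- sort(unique(unlist(cl$clusters[joined])))
  lab <- stats::setNames(graph$nodes$label, graph$nodes$id)
  labels <- sort(unique(lab[members][!is.na(lab[members])]))
  # best characterized direct neighbor by E-value
  charact <- !is.na(lab[other])
  best <- NULL
  if (any(charact)) {
    i <- which(charact)[which.min(qa$evalue[charact])]
    best <- list(id = other[i], label = unname(lab[other[i]]),
                 evalue = qa$evalue[i])
  }
  structure(list(query_id = query_id, status = "clustered",
                 cluster_members = members, labels = unname(labels),
                 best_neighbor = best, n_passing_edges = nrow(qa)),
            class = "ssn_assignment")
}

#' @export
print.ssn_assignment <- function(x, ...) {
  if (x$status == "unclustered") {
    cat(sprintf("Query %s: unclustered (no passing edges)\n", x$query_id))
  } else {
    cat(sprintf("Query %s: clustered with %d nodes; labels: %s\n",
                x$query_id, length(x$cluster_members),
                if (length(x$labels)) paste(x$labels, collapse = ", ") else
                  "(none characterized)"))
    if (!is.null(x$best_neighbor)) {
      cat(sprintf("  best characterized neighbor: %s (%s), E = %.3g\n",
                  x$best_neighbor$id, x$best_neighbor$label,
                  x$best_neighbor$evalue))
    }
  }
  invisible(x)
}

#' Export an SSN to GraphML or an edge TSV
#'
#' GraphML carries node attributes `label` and `member_count` and edge
#' attributes `evalue`, `pct_identity`, `bit_score`, plus the cutoff as a
#' graph attribute, and is importable by common graph viewers. The edge-TSV
#' dialect has columns `from`, `to`, `evalue`, `pct_identity`, `bit_score`
#' written at full precision; singleton nodes are retained in both formats
#' (TSV rows with an empty `to` field) because an unclustered node carries
#' prediction meaning.
#'
#' @param graph an `"ssn"` object.
#' @param path output path.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
export_ssn <- function(graph, path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- .ssn_igraph(graph)
    igraph::V(g)$label <- ifelse(is.na(graph$nodes$label), "",
                                 graph$nodes$label)
    igraph::V(g)$member_count <- graph$nodes$member_count
    if (nrow(graph$edges)) {
      igraph::E(g)$pct_identity <- 100 * graph$edges$identity
    }
    g <- igraph::set_graph_attr(g, "evalue_cutoff", graph$evalue_cutoff)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    deg_ids <- unique(c(graph$edges$from, graph$edges$to))
    single <- setdiff(graph$nodes$id, deg_ids)
    rows <- data.frame(
      from = c(graph$edges$from, single),
      to = c(graph$edges$to, rep("", length(single))),
      evalue = c(sprintf("%.17g", graph$edges$evalue),
                 rep("", length(single))),
      pct_identity = c(sprintf("%.17g", 100 * graph$edges$identity),
                       rep("", length(single))),
      bit_score = c(sprintf("%.17g", graph$edges$bit_score),
                    rep("", length(single))),
      stringsAsFactors = FALSE)
    attr_line <- sprintf("#evalue_cutoff=%.17g", graph$evalue_cutoff)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(attr_line, con)
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Import an SSN written by [export_ssn()]
#'
#' @param path input path.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @return An `"ssn"` object.
#' @export
import_ssn <- function(path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    ids <- igraph::V(g)$name
    lab <- igraph::V(g)$label
    lab[!nzchar(lab)] <- NA_character_
    el <- igraph::as_edgelist(g)
    edges <- if (nrow(el)) {
      data.frame(from = pmin(el[, 1], el[, 2]),
                 to = pmax(el[, 1], el[, 2]),
                 evalue = igraph::E(g)$evalue,
                 identity = igraph::E(g)$pct_identity / 100,
                 bit_score = igraph::E(g)$bit_score,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(), to = character(), evalue = numeric(),
                 identity = numeric(), bit_score = numeric())
    }
    cutoff <- igraph::graph_attr(g, "evalue_cutoff")
    al <- data.frame(query_id = edges$from, subject_id = edges$to,
                     raw_score = rep(NA_real_, nrow(edges)),
                     bit_score = edges$bit_score,
                     evalue = edges$evalue, identity = edges$identity,
                     aligned_columns = rep(NA_integer_, nrow(edges)),
                     stringsAsFactors = FALSE)
    out <- build_ssn(al, cutoff, singletons = ids,
                     labels = stats::setNames(lab, ids))
    out$nodes$member_count <- igraph::V(g)$member_count[
      match(out$nodes$id, ids)]
    out
  } else {
    first <- readLines(path, n = 1L)
    cutoff <- as.numeric(sub("^#evalue_cutoff=", "", first))
    x <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                           stringsAsFactors = FALSE,
                           colClasses = c(from = "character",
                                          to = "character"))
    single <- x$from[!nzchar(x$to)]
    e <- x[nzchar(x$to), , drop = FALSE]
    al <- data.frame(query_id = e$from, subject_id = e$to,
                     raw_score = rep(NA_real_, nrow(e)),
                     bit_score = as.numeric(e$bit_score),
                     evalue = as.numeric(e$evalue),
                     identity = as.numeric(e$pct_identity) / 100,
                     aligned_columns = rep(NA_integer_, nrow(e)),
                     stringsAsFactors = FALSE)
    build_ssn(al, cutoff, singletons = single)
  }
}

#' Write cluster membership as TSV
#'
#' Columns: `id`, `cluster`, `labels` (comma-separated characterized labels
#' present in the node's cluster).
#'
#' @param clusters an `"ssn_clusters"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(clusters, path) {
  ids <- names(clusters$membership)
  cl <- clusters$membership
  labs <- vapply(cl, function(k)
    paste(clusters$labels[[k]], collapse = ","), character(1L))
  utils::write.table(
    data.frame(id = ids, cluster = unname(cl), labels = unname(labs),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
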