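# Distance matrices from global identity, neighbor-joining trees (ape) and
# Newick IO with a fixed-precision writer.

#' Pairwise distance matrix from global identity
#'
#' `d = 1 - identity` (p-distance) by default; with `model = "poisson"` the
#' Poisson multiple-hit correction `-ln(identity)` is used, capped at
#' `max_distance` (with a warning) when the identity is zero or the corrected
#' value exceeds the cap. Identity is the terminal-overhang-trimmed global
#' convention of [global_align()].
#'
#' @param records protein-records data frame with at least 3 rows.
#' @param params see [alignment_params()].
#' @param model `"p"` or `"poisson"`.
#' @param max_distance cap for the Poisson correction as identity approaches 0.
#' @return A symmetric matrix with zero diagonal, dimnames = record ids.
#' @export
identity_distance_matrix <- function(records, params = alignment_params(),
                                     model = c("p", "poisson"),
                                     max_distance = 10) {
  model <- match.arg(model)
  n <- nrow(records)
  if (is.null(n) || n < 3L) stop("need at least 3 records")
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  n_capped <- 0L
  for (j in 2:n) {
    idx <- seq_len(j - 1L)
    r <- .align_batch(records$sequence[idx], records$sequence[j],
                      params, "global")
    idv <- ifelse(r$aligned_columns > 0, r$matches / r$aligned_columns, 0)
    dv <- switch(model,
                 p = 1 - idv,
                 poisson = -log(idv))
    if (model == "poisson") {
      over <- !is.finite(dv) | dv > max_distance
      n_capped <- n_capped + sum(over)
      dv[over] <- max_distance
    }
    d[idx, j] <- d[j, idx] <- dv
  }
  if (n_capped > 0L) {
    warning(n_capped, " Poisson-corrected distance(s) capped at ",
            max_distance, " for identity near 0")
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on a symmetric non-negative
#' distance matrix. Negative branch lengths, which NJ can produce on
#' non-additive input, are clamped to zero; the pre-clamp values are recorded
#' in the `"clamped_branch_lengths"` attribute and a warning flag is set.
#'
#' @param D symmetric numeric matrix with zero diagonal and dimnames
#'   (at least 3 taxa).
#' @return An unrooted `phylo` tree (leaves = taxa ids) with attribute
#'   `"clamped_branch_lengths"` (data frame of edge index and original
#'   length; zero rows when nothing was clamped).
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(D))) stop("D must have taxa ids as dimnames")
  if (any(!is.finite(D))) stop("D must be finite")
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")
  if (any(D < 0)) stop("D must be non-negative")
  tree <- ape::nj(D)
  neg <- which(tree$edge.length < 0)
  clamped <- data.frame(edge = neg, original = tree$edge.length[neg])
  if (length(neg)) {
    warning(length(neg), " negative branch length(s) clamped to zero")
    tree$edge.length[neg] <- 0
  }
  attr(tree, "clamped_branch_lengths") <- clamped
  tree
}

.quote_label <- function(x) {
  needs <- grepl("[][ \t():;,']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Write a tree in Newick format with fixed 6-decimal branch lengths
#'
#' Labels containing Newick metacharacters are single-quoted (embedded quotes
#' doubled). Returns the Newick string; writes it to `path` when given.
#'
#' @param tree a `phylo` object.
#' @param path optional output path.
#' @param digits decimal places for branch lengths.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 6L) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- paste0("%.", digits, "f")
  lab <- .quote_label(tree$tip.label)
  rec <- function(node, edge_idx) {
    body <- if (node <= ntip) {
      lab[node]
    } else {
      ch <- kids[[as.character(node)]]
      paste0("(", paste(vapply(ch, function(e)
        rec(tree$edge[e, 2L], e), character(1L)), collapse = ","), ")")
    }
    if (is.na(edge_idx)) body else
      paste0(body, ":", sprintf(fmt, tree$edge.length[edge_idx]))
  }
  s <- paste0(rec(root, NA_integer_), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Read a Newick tree
#'
#' Parsing is delegated to [ape::read.tree()] after a pre-pass that checks
#' bracket balance (reporting the position of the first unmatched bracket)
#' and substitutes single-quoted labels, which the ape parser does not accept
#' natively, for placeholders that are restored afterwards.
#'
#' @param path a file path, or a literal Newick string (anything containing
#'   `"("` and `";"` that is not an existing file).
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  s <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                    collapse = "") else path
  # extract quoted labels
  quoted <- character()
  repeat {
    m <- regexpr("'([^']|'')*'", s)
    if (m == -1L) break
    tok <- regmatches(s, m)
    quoted <- c(quoted, gsub("''", "'", substr(tok, 2L, nchar(tok) - 1L)))
    placeholder <- sprintf("BAHDSCOPEQL%d", length(quoted))
    regmatches(s, m) <- placeholder
  }
  depth <- 0L
  for (i in seq_len(nchar(s))) {
    ch <- substr(s, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("Newick parse error at position ", i,
                           ": unmatched ')'")
    }
  }
  if (depth != 0L) stop("Newick parse error: ", depth, " unclosed '('")
  if (!grepl(";", s)) stop("Newick parse error: missing terminal ';'")
  tree <- tryCatch(ape::read.tree(text = s),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: unparseable input")
  restore <- function(x) {
    for (k in seq_along(quoted)) {
      x[x == sprintf("BAHDSCOPEQL%d", k)] <- quoted[k]
    }
    x
  }
  tree$tip.label <- restore(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- restore(tree$node.label)
  tree
}
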