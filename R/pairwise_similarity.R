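# Pairwise alignment layer: global/local affine-gap alignment with
# Karlin-Altschul statistics. Biostrings supplies the dynamic programming;
# identity conventions, bit scores and E-values are defined here.

.bahdscope_cache <- new.env(parent = emptyenv())

.resolve_submat <- function(substitution_matrix) {
  if (is.matrix(substitution_matrix)) return(substitution_matrix)
  key <- paste0("submat_", substitution_matrix)
  if (!exists(key, envir = .bahdscope_cache)) {
    e <- new.env()
    utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
    assign(key, get(substitution_matrix, envir = e), envir = .bahdscope_cache)
  }
  get(key, envir = .bahdscope_cache)
}

#' Alignment parameters
#'
#' Scoring and statistical parameters for pairwise alignment. The defaults are
#' the standard gapped-BLOSUM62 setting (gap existence 11, extension 1) with
#' the matching Karlin-Altschul constants `lambda = 0.267` and `K = 0.041`, so
#' that local raw scores convert to bit scores as
#' `(lambda * S - ln K) / ln 2` and E-values as `m * n * 2^(-bit)`.
#'
#' @param substitution_matrix matrix name available in Biostrings (default
#'   `"BLOSUM62"`) or an explicit symmetric integer matrix.
#' @param gap_open positive gap-existence penalty; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param gap_extend positive per-residue gap-extension penalty
#'   (`gap_extend <= gap_open`).
#' @param lambda,K Karlin-Altschul parameters (strictly positive).
#' @return A list of class `"alignment_params"`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1,
                             lambda = 0.267, K = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, gap_extend <= gap_open,
            lambda > 0, K > 0)
  mat <- .resolve_submat(substitution_matrix)
  if (!isTRUE(all.equal(mat, t(mat)))) {
    stop("substitution matrix must be symmetric")
  }
  structure(list(substitution_matrix = substitution_matrix,
                 matrix = mat,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "alignment_params")
}

# Trim terminal-overhang columns (end-gap runs touching either alignment end)
# and return c(matches, columns) over the remaining core.
.identity_from_aligned <- function(pa, pb) {
  a <- strsplit(pa, "")[[1L]]
  b <- strsplit(pb, "")[[1L]]
  n <- length(a)
  gap_prefix <- function(x) {
    r <- rle(x == "-")
    if (length(r$values) && r$values[1L]) r$lengths[1L] else 0L
  }
  lead <- max(gap_prefix(a), gap_prefix(b))
  trail <- max(gap_prefix(rev(a)), gap_prefix(rev(b)))
  if (lead + trail >= n) return(c(0L, 0L))
  core <- (lead + 1L):(n - trail)
  matches <- sum(a[core] == b[core] & a[core] != "-")
  c(matches, length(core))
}

# Vectorized batch alignment of several patterns against one subject.
# Returns a data.frame with raw_score, identity, aligned_columns per pattern.
.align_batch <- function(patterns, subject, params, type) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(patterns),
    subject = subject,
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open,
    gapExtension = params$gap_extend,
    type = type)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  stats <- vapply(seq_along(patterns),
                  function(i) .identity_from_aligned(ap[i], as_[i]),
                  integer(2L))
  data.frame(raw_score = Biostrings::score(pa),
             matches = stats[1L, ],
             aligned_columns = stats[2L, ])
}

.alignment_result <- function(query_id, subject_id, raw_score, bit_score,
                              evalue, identity, aligned_columns, mode) {
  structure(list(query_id = query_id, subject_id = subject_id,
                 raw_score = raw_score, bit_score = bit_score,
                 evalue = evalue, identity = identity,
                 aligned_columns = aligned_columns, mode = mode),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s alignment %s vs %s: score %g, identity %.1f%% over %d cols",
              x$mode, x$query_id, x$subject_id, x$raw_score,
              100 * x$identity, x$aligned_columns))
  if (x$mode == "local") {
    cat(sprintf(", bit %.1f, E = %.3g", x$bit_score, x$evalue))
  }
  cat("\n")
  invisible(x)
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Percent identity is computed as identical aligned pairs divided by the
#' number of alignment columns after trimming terminal-overhang columns
#' (end-gap runs touching a sequence terminus). This single identity
#' convention is used everywhere in the package (redundancy collapse,
#' distance matrices, pocket mapping).
#'
#' @param a,b protein records (single rows) or sequence strings.
#' @param params see [alignment_params()].
#' @return An `alignment_result` with `mode = "global"` (`bit_score` and
#'   `evalue` are `NA`: Karlin-Altschul statistics apply to local scores).
#' @export
global_align <- function(a, b, params = alignment_params()) {
  sa <- .as_sequence(a); sb <- .as_sequence(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("cannot align an empty sequence")
  r <- .align_batch(sa, sb, params, "global")
  .alignment_result(.as_id(a, "a"), .as_id(b, "b"),
                    raw_score = r$raw_score,
                    bit_score = NA_real_, evalue = NA_real_,
                    identity = if (r$aligned_columns > 0)
                      r$matches / r$aligned_columns else 0,
                    aligned_columns = r$aligned_columns,
                    mode = "global")
}

.ka_bit <- function(raw, params) (params$lambda * raw - log(params$K)) / log(2)

#' Local pairwise alignment (Smith-Waterman, affine gaps) with E-value
#'
#' The optimal local score S converts to a bit score
#' `(lambda * S - ln K) / ln 2` and to an E-value `m * n * 2^(-bit)` where
#' `m`, `n` are the full (unaligned) sequence lengths.
#'
#' @inheritParams global_align
#' @return An `alignment_result` with `mode = "local"`.
#' @export
local_align <- function(a, b, params = alignment_params()) {
  sa <- .as_sequence(a); sb <- .as_sequence(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("cannot align an empty sequence")
  r <- .align_batch(sa, sb, params, "local")
  bit <- .ka_bit(r$raw_score, params)
  .alignment_result(.as_id(a, "a"), .as_id(b, "b"),
                    raw_score = r$raw_score,
                    bit_score = bit,
                    evalue = nchar(sa) * nchar(sb) * 2^(-bit),
                    identity = if (r$aligned_columns > 0)
                      r$matches / r$aligned_columns else 0,
                    aligned_columns = r$aligned_columns,
                    mode = "local")
}

#' All-vs-all local alignment
#'
#' Computes every unordered pair and reports those passing the E-value cutoff.
#' No heuristic prefilter is applied, so the result is exact at any cutoff.
#' Output is symmetric by construction (each pair reported once) and sorted by
#' query id then subject id.
#'
#' @param records protein-records data frame (at least 2 rows).
#' @param params see [alignment_params()].
#' @param evalue_cutoff report pairs with `evalue <= evalue_cutoff`
#'   (default: the family gathering cutoff 1e-25).
#' @return A data frame with columns `query_id`, `subject_id`, `raw_score`,
#'   `bit_score`, `evalue`, `identity`, `aligned_columns`.
#' @export
all_vs_all <- function(records, params = alignment_params(),
                       evalue_cutoff = 1e-25) {
  n <- nrow(records)
  if (is.null(n) || n < 2L) stop("need at least 2 records")
  len <- nchar(records$sequence)
  rows <- vector("list", n - 1L)
  for (j in 2:n) {
    idx <- seq_len(j - 1L)
    r <- .align_batch(records$sequence[idx], records$sequence[j],
                      params, "local")
    bit <- .ka_bit(r$raw_score, params)
    rows[[j - 1L]] <- data.frame(
      query_id = records$id[idx],
      subject_id = records$id[j],
      raw_score = r$raw_score,
      bit_score = bit,
      evalue = len[idx] * len[j] * 2^(-bit),
      identity = ifelse(r$aligned_columns > 0,
                        r$matches / r$aligned_columns, 0),
      aligned_columns = r$aligned_columns,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[out$evalue <= evalue_cutoff, , drop = FALSE]
  out <- out[order(out$query_id, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an all-vs-all alignment table as TSV
#'
#' Columns (a BLAST outfmt-6-like dialect): `query`, `subject`, `raw_score`,
#' `bit_score`, `evalue`, `pct_identity`, `aligned_columns`. Floating point
#' values are written with full precision so a read-back is exact.
#'
#' @param alignments data frame from [all_vs_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(alignments, path) {
  out <- data.frame(
    query = alignments$query_id,
    subject = alignments$subject_id,
    raw_score = alignments$raw_score,
    bit_score = sprintf("%.17g", alignments$bit_score),
    evalue = sprintf("%.17g", alignments$evalue),
    pct_identity = sprintf("%.17g", 100 * alignments$identity),
    aligned_columns = alignments$aligned_columns,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an alignment TSV written by [write_alignment_tsv()]
#'
#' @param path input path.
#' @return A data frame in [all_vs_all()] layout.
#' @export
read_alignment_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  data.frame(query_id = as.character(x$query),
             subject_id = as.character(x$subject),
             raw_score = x$raw_score,
             bit_score = x$bit_score,
             evalue = x$evalue,
             identity = x$pct_identity / 100,
             aligned_columns = x$aligned_columns,
             stringsAsFactors = FALSE)
}
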