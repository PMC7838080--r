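# Sequence IO, conserved-motif scanning and redundancy collapse.

#' The 20-letter amino-acid alphabet used throughout the package
#'
#' Residues outside this set are mapped to `X`; `X` never matches a
#' motif-anchor position.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET_20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.normalize_sequence <- function(seq) {
  seq <- toupper(seq)
  seq <- sub("\\*$", "", seq)  # terminal stop
  bad <- grepl("[^A-Z]", seq)
  if (any(bad)) {
    stop("illegal residue character in sequence(s): ",
         paste(which(bad), collapse = ", "))
  }
  # non-canonical letters (B, J, O, U, Z) map to X
  chartr("BJOUZ", "XXXXX", seq)
}

#' Construct a set of protein records
#'
#' The basic sequence container of the package: a plain data frame with one
#' row per protein. Sequences are uppercased, a terminal `*` stop is stripped
#' and non-canonical letters are mapped to `X`.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param description free-text description(s), recycled.
#' @param source provenance tag, one of `"user"`, `"bundled"`, `"synthetic"`.
#' @return A `data.frame` with columns `id`, `description`, `sequence`,
#'   `source`.
#' @export
protein_records <- function(id, sequence, description = "", source = "user") {
  source <- match.arg(source, c("user", "bundled", "synthetic"))
  if (length(id) != length(sequence)) {
    stop("`id` and `sequence` must have the same length")
  }
  if (anyDuplicated(id)) {
    stop("duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sequence <- .normalize_sequence(as.character(sequence))
  if (any(nchar(sequence) == 0)) stop("empty sequence(s)")
  data.frame(id = as.character(id),
             description = rep_len(as.character(description), length(id)),
             sequence = sequence,
             source = rep_len(source, length(id)),
             stringsAsFactors = FALSE)
}

# Accept either a records data.frame row / single-row subset or a bare string.
.as_sequence <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(x$sequence)
  }
  if (is.character(x) && length(x) == 1L) return(.normalize_sequence(x))
  stop("expected a single protein record or a sequence string")
}

.as_id <- function(x, default = "query") {
  if (is.data.frame(x) && "id" %in% names(x)) return(x$id[[1L]])
  default
}

#' Read protein sequences from a FASTA file
#'
#' A validating reader: it pre-scans the file so that malformed headers or
#' illegal residue characters are reported with their line number, then parses
#' with [Biostrings::readAAStringSet()]. Sequences are uppercased and a
#' terminal `*` is stripped; duplicate ids are rejected.
#'
#' @param path path to a FASTA file.
#' @param source provenance tag stored on the records.
#' @return A protein-records data frame (see [protein_records()]).
#' @export
read_fasta <- function(path, source = "user") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("FASTA parse error: empty file ", path)
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("FASTA parse error at line ", nonblank[1L],
         ": expected a '>' header")
  }
  for (i in nonblank) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      if (nchar(ln) == 1L) {
        stop("FASTA parse error at line ", i, ": empty header")
      }
    } else if (grepl("[^A-Za-z*]", ln)) {
      stop("FASTA parse error at line ", i,
           ": illegal residue character in sequence")
    }
  }
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  protein_records(ids, as.character(aas), desc, source = source)
}

#' Write protein records to FASTA
#'
#' Output is wrapped at 60 columns.
#'
#' @param records protein-records data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- ifelse(nzchar(records$description),
                    paste(records$id, records$description),
                    records$id)
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Scan a sequence for the BAHD conserved motifs
#'
#' Reports every occurrence of `HXXXD` (literal H and D anchors, any three
#' middle residues) and every length-5 window within `max_dfgwg_mismatch`
#' substitutions of `DFGWG`. `X` never matches an anchor position, so it
#' counts as a mismatch everywhere in `DFGWG` and never satisfies the H/D
#' anchors.
#'
#' @param record a protein record (single row) or a sequence string.
#' @param max_dfgwg_mismatch allowed substitutions in `DFGWG` (0 or 1).
#' @return A data frame with columns `motif`, `start` (1-based), `matched`,
#'   `mismatches`, sorted by `start`. Zero rows when nothing matches.
#' @export
scan_motifs <- function(record, max_dfgwg_mismatch = 1L) {
  stopifnot(max_dfgwg_mismatch %in% c(0L, 1L))
  seq <- .as_sequence(record)
  n <- nchar(seq)
  out <- data.frame(motif = character(), start = integer(),
                    matched = character(), mismatches = integer(),
                    stringsAsFactors = FALSE)
  if (n < 5L) return(out)
  chars <- strsplit(seq, "")[[1L]]
  starts <- seq_len(n - 4L)
  win <- function(k) chars[starts + k]  # k-th window column, 0-based
  # HXXXD: anchors literal
  hx <- win(0L) == "H" & win(4L) == "D"
  if (any(hx)) {
    s <- starts[hx]
    out <- rbind(out, data.frame(
      motif = "HXXXD", start = s,
      matched = substring(seq, s, s + 4L),
      mismatches = 0L, stringsAsFactors = FALSE))
  }
  # DFGWG with mismatch budget; X counts as mismatch at every position
  target <- c("D", "F", "G", "W", "G")
  mm <- Reduce(`+`, lapply(0:4, function(k) {
    w <- win(k)
    as.integer(w != target[k + 1L] | w == "X")
  }))
  df <- mm <= max_dfgwg_mismatch
  if (any(df)) {
    s <- starts[df]
    out <- rbind(out, data.frame(
      motif = "DFGWG", start = s,
      matched = substring(seq, s, s + 4L),
      mismatches = mm[df], stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default configuration of the BAHD family-membership gate
#'
#' @param hxxxd_window fractional sequence window (start, end) in which the
#'   HXXXD catalytic motif must begin; the default central window reflects the
#'   position of the catalytic His in characterized family members.
#' @param dfgwg_min_frac fraction of the sequence length after which the
#'   DFGWG motif must begin (C-terminal third by default).
#' @param max_dfgwg_mismatch allowed substitutions in DFGWG (distant family
#'   members degrade this motif, hence 1 by default).
#' @return A list used by [is_bahd_candidate()].
#' @export
bahd_gate_config <- function(hxxxd_window = c(0.25, 0.60),
                             dfgwg_min_frac = 2 / 3,
                             max_dfgwg_mismatch = 1L) {
  stopifnot(length(hxxxd_window) == 2L, hxxxd_window[1] < hxxxd_window[2])
  list(hxxxd_window = hxxxd_window,
       dfgwg_min_frac = dfgwg_min_frac,
       max_dfgwg_mismatch = as.integer(max_dfgwg_mismatch))
}

#' Gate family membership by the conserved BAHD motifs
#'
#' A sequence passes when an HXXXD hit begins inside the configured central
#' window *and* a DFGWG hit (with the configured mismatch budget) begins in
#' the C-terminal region.
#'
#' @param record a protein record or sequence string.
#' @param config gate configuration, see [bahd_gate_config()].
#' @return A list of class `"bahd_gate"` with elements `pass` (logical),
#'   `rationale` (character), `hxxxd` and `dfgwg` (the qualifying motif hits,
#'   or `NULL`).
#' @export
is_bahd_candidate <- function(record, config = bahd_gate_config()) {
  seq <- .as_sequence(record)
  n <- nchar(seq)
  hits <- scan_motifs(seq, max_dfgwg_mismatch = config$max_dfgwg_mismatch)
  hx <- hits[hits$motif == "HXXXD" &
               hits$start >= config$hxxxd_window[1] * n &
               hits$start <= config$hxxxd_window[2] * n, , drop = FALSE]
  df <- hits[hits$motif == "DFGWG" &
               hits$start >= config$dfgwg_min_frac * n, , drop = FALSE]
  fails <- character()
  if (nrow(hx) == 0L) fails <- c(fails, "no HXXXD motif in central window")
  if (nrow(df) == 0L) fails <- c(fails, "no DFGWG motif in C-terminal region")
  structure(list(
    id = .as_id(record, NA_character_),
    pass = length(fails) == 0L,
    rationale = if (length(fails)) paste(fails, collapse = "; ") else
      "HXXXD and DFGWG motifs found at canonical positions",
    hxxxd = if (nrow(hx)) hx[1L, ] else NULL,
    dfgwg = if (nrow(df)) df[1L, ] else NULL
  ), class = "bahd_gate")
}

#' @export
print.bahd_gate <- function(x, ...) {
  cat(sprintf("BAHD gate [%s]: %s\n  %s\n",
              ifelse(is.na(x$id), "?", x$id),
              if (x$pass) "PASS" else "FAIL", x$rationale))
  invisible(x)
}

#' Collapse redundant sequences
#'
#' At `identity_threshold = 1` only exactly identical sequences are collapsed.
#' Below 1, greedy clustering in input order: each record joins the first
#' representative with global identity at or above the threshold, otherwise it
#' becomes a new representative. The result is deterministic for a fixed input
#' order (and order-dependent below threshold 1, as greedy clustering is).
#'
#' @param records protein-records data frame.
#' @param identity_threshold fraction in (0, 1].
#' @param params alignment parameters used for sub-1 thresholds, see
#'   [alignment_params()].
#' @return A list of class `"redundancy_map"` with `map` (named list:
#'   representative id -> member ids, representative included),
#'   `representatives` (records data frame) and `identity_threshold`.
#' @export
collapse_redundancy <- function(records, identity_threshold = 1,
                                params = alignment_params()) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (is.null(records) || nrow(records) == 0L) {
    return(structure(list(map = list(),
                          representatives = records,
                          identity_threshold = identity_threshold),
                     class = "redundancy_map"))
  }
  if (identity_threshold == 1) {
    rep_idx <- match(records$sequence, records$sequence)  # first occurrence
    map <- split(records$id, records$id[rep_idx])
    # keep input order of representatives
    reps <- records[!duplicated(records$sequence), , drop = FALSE]
    map <- map[reps$id]
  } else {
    reps_i <- integer()
    assign <- integer(nrow(records))
    for (i in seq_len(nrow(records))) {
      joined <- FALSE
      for (r in reps_i) {
        idv <- global_align(records[r, ], records[i, ], params)$identity
        if (idv >= identity_threshold) {
          assign[i] <- r
          joined <- TRUE
          break
        }
      }
      if (!joined) {
        reps_i <- c(reps_i, i)
        assign[i] <- i
      }
    }
    reps <- records[reps_i, , drop = FALSE]
    map <- split(records$id, factor(records$id[assign], levels = reps$id))
    map <- lapply(map, as.character)
  }
  structure(list(map = map, representatives = reps,
                 identity_threshold = identity_threshold),
            class = "redundancy_map")
}

#' @export
print.redundancy_map <- function(x, ...) {
  cat(sprintf("Redundancy map: %d representatives, %d members (threshold %.2f)\n",
              length(x$map), sum(lengths(x$map)), x$identity_threshold))
  invisible(x)
}
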