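# Structure handling: PDB IO (bio3d), Kabsch superposition, CA-RMSD through
# sequence alignment, acyl-acceptor pocket extraction, charge classification
# and alignment-based pocket mapping onto homologous sequences.

.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

.aa321 <- function(x) {
  out <- suppressWarnings(bio3d::aa321(x))
  out[is.na(out) | out == ""] <- "X"
  out
}

.aa123 <- function(x) {
  out <- bio3d::aa123(x)
  out[is.na(out)] <- "UNK"
  out
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records with [bio3d::read.pdb()]. Alternate locations
#' are resolved to the highest-occupancy conformer (ties: altloc `A`, then
#' blank); HETATM ligands are retained separately, keyed by residue name;
#' waters are tagged and kept apart. Per-chain one-letter sequences are
#' derived from CA-bearing protein residues.
#'
#' @param path path to a PDB-format file.
#' @return A list of class `"structure"`: `atoms` (all retained atoms),
#'   `protein` (ATOM records), `ligands` (named list of atom data frames),
#'   `waters`, `chains` (per chain: `sequence`, `resno`), `path`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                     rm.alt = FALSE)),
    error = function(e) {
      lines <- readLines(path, warn = FALSE)
      rec <- grepl("^(ATOM|HETATM)", lines)
      for (i in which(rec)) {
        coords <- suppressWarnings(as.numeric(c(
          substr(lines[i], 31, 38), substr(lines[i], 39, 46),
          substr(lines[i], 47, 54))))
        if (any(is.na(coords))) {
          stop("PDB parse error at line ", i,
               ": unparseable coordinate field")
        }
      }
      stop("PDB parse error: ", conditionMessage(e))
    })
  at <- pdb$atom
  if (!any(at$type == "ATOM")) stop("no ATOM records in ", path)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    stop("non-finite coordinates in ", path)
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc resolution: highest occupancy, ties prefer 'A' then blank
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  alt_rank <- match(at$alt, c("A", "", LETTERS[-1L]), nomatch = 99L)
  ord <- order(key, -at$o, alt_rank)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$chain, at$resno, at$insert, at$eleno), , drop = FALSE]
  rownames(at) <- NULL
  water <- at$resid %in% .WATER_NAMES
  protein <- at[at$type == "ATOM" & !water, , drop = FALSE]
  het <- at[at$type == "HETATM" & !water, , drop = FALSE]
  ligands <- if (nrow(het)) split(het, het$resid) else list()
  ca <- protein[protein$elety == "CA", , drop = FALSE]
  chains <- lapply(split(ca, ca$chain), function(cc) {
    cc <- cc[order(cc$resno, cc$insert), , drop = FALSE]
    list(sequence = paste(.aa321(cc$resid), collapse = ""),
         resno = cc$resno)
  })
  structure(list(atoms = at, protein = protein, ligands = ligands,
                 waters = at[water, , drop = FALSE],
                 chains = chains, path = path),
            class = "structure")
}

#' @export
print.structure <- function(x, ...) {
  cat(sprintf(
    "Structure: %d atoms, %d chain(s) [%s], ligands: %s, %d waters\n",
    nrow(x$atoms), length(x$chains),
    paste(names(x$chains), collapse = ","),
    if (length(x$ligands)) paste(names(x$ligands), collapse = ",") else
      "none", nrow(x$waters)))
  invisible(x)
}

#' Write a structure to a PDB file
#'
#' @param x a `"structure"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  at <- x$atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = at$type,
                   resno = at$resno, resid = at$resid, eleno = at$eleno,
                   elety = at$elety, chain = at$chain, o = at$o,
                   b = if ("b" %in% names(at)) at$b else 0)
  invisible(path)
}

# n x 3 coordinate matrix of the CA atoms of one chain, residue order
.chain_ca_xyz <- function(s, chain) {
  ca <- s$protein[s$protein$elety == "CA" & s$protein$chain == chain, ,
                  drop = FALSE]
  ca <- ca[order(ca$resno, ca$insert), , drop = FALSE]
  as.matrix(ca[, c("x", "y", "z")])
}

#' Kabsch superposition of two paired coordinate sets
#'
#' Closed-form least-squares optimal rigid superposition (rotation +
#' translation, reflections excluded) of `P` onto `Q`, via SVD of the
#' covariance matrix. The transformed coordinates are
#' `P %*% rotation + translation` (row-wise).
#'
#' @param P,Q numeric matrices of identical dimension `n x 3`, `n >= 3`,
#'   not all collinear.
#' @return A list of class `"superposition"`: `rotation` (3x3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom), `n_pairs`.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("coordinate sets differ in size")
  if (ncol(P) != 3L) stop("coordinates must be n x 3")
  n <- nrow(P)
  if (n < 3L) stop("need at least 3 paired points")
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2L, cP); Qc <- sweep(Q, 2L, cQ)
  for (M in list(Pc, Qc)) {
    sv <- svd(M)$d
    if (sv[2L] < 1e-8 * max(sv[1L], 1)) {
      stop("degenerate (collinear) coordinate set")
    }
  }
  H <- crossprod(Pc, Qc)          # t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cQ - cP %*% R),
                 rmsd = rmsd, n_pairs = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d pairs: RMSD %.3f A\n",
              x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp a `"superposition"` object.
#' @param P an `n x 3` coordinate matrix.
#' @return The transformed `n x 3` matrix.
#' @export
apply_superposition <- function(sp, P) {
  sweep(as.matrix(P) %*% sp$rotation, 2L, sp$translation, `+`)
}

#' CA RMSD between two structures through sequence alignment
#'
#' Chains are paired greedily by best global sequence identity; CA atoms are
#' paired at non-gap aligned columns; a single Kabsch superposition is run
#' over all pairs. All aligned CA atoms enter the fit (no outlier rejection).
#'
#' @param A,B `"structure"` objects, each with at least one chain carrying
#'   `min_chain_length` CA atoms.
#' @param params see [alignment_params()].
#' @param min_chain_length minimum CA count for a chain to participate.
#' @return A `"superposition"` augmented with `chain_pairs` (data frame:
#'   chain_a, chain_b, identity, n_pairs) and `coverage` (fraction of the CA
#'   atoms of A and of B entering the fit).
#' @export
ca_rmsd_by_alignment <- function(A, B, params = alignment_params(),
                                 min_chain_length = 30L) {
  use_chains <- function(s) {
    ch <- names(s$chains)[vapply(s$chains, function(c_)
      nchar(c_$sequence), integer(1L)) >= min_chain_length]
    if (length(ch) == 0L) {
      # fall back to any CA-bearing chain (self/toy comparisons)
      ch <- names(s$chains)[vapply(s$chains, function(c_)
        nchar(c_$sequence), integer(1L)) > 0L]
    }
    if (length(ch) == 0L) stop("structure has no CA atoms")
    ch
  }
  cha <- use_chains(A); chb <- use_chains(B)
  idm <- matrix(0, length(cha), length(chb), dimnames = list(cha, chb))
  for (i in cha) for (j in chb) {
    idm[i, j] <- global_align(A$chains[[i]]$sequence,
                              B$chains[[j]]$sequence, params)$identity
  }
  pairs <- list()
  while (length(dim(idm)) == 2L && nrow(idm) && ncol(idm)) {
    k <- arrayInd(which.max(idm), dim(idm))
    pairs[[length(pairs) + 1L]] <- c(rownames(idm)[k[1L]],
                                     colnames(idm)[k[2L]])
    idm <- idm[-k[1L], -k[2L], drop = FALSE]
  }
  Pall <- NULL; Qall <- NULL
  rep_rows <- list()
  for (pr in pairs) {
    sa <- A$chains[[pr[1L]]]$sequence
    sb <- B$chains[[pr[2L]]]$sequence
    pa <- Biostrings::pairwiseAlignment(
      pattern = sa, subject = sb,
      substitutionMatrix = params$matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      type = "global")
    av <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    bv <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    ia <- cumsum(av != "-"); ib <- cumsum(bv != "-")
    both <- av != "-" & bv != "-"
    xa <- .chain_ca_xyz(A, pr[1L]); xb <- .chain_ca_xyz(B, pr[2L])
    Pall <- rbind(Pall, xa[ia[both], , drop = FALSE])
    Qall <- rbind(Qall, xb[ib[both], , drop = FALSE])
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      chain_a = pr[1L], chain_b = pr[2L],
      identity = sum(av[both] == bv[both]) / sum(both),
      n_pairs = sum(both), stringsAsFactors = FALSE)
  }
  sp <- kabsch_superpose(Pall, Qall)
  n_ca <- function(s, ch) sum(vapply(s$chains[ch], function(c_)
    nchar(c_$sequence), integer(1L)))
  sp$chain_pairs <- do.call(rbind, rep_rows)
  sp$coverage <- c(a = sp$n_pairs / n_ca(A, vapply(pairs, `[`, "", 1L)),
                   b = sp$n_pairs / n_ca(B, vapply(pairs, `[`, "", 2L)))
  sp
}

#' Residue charge model for pocket classification
#'
#' Formal charge at neutral pH with a fractional histidine: Asp/Glu -1,
#' Lys/Arg +1, His +0.1 by default; all other residues 0. The
#' electrostatic class thresholds are `net <= -1` acidic, `net >= +1` basic,
#' otherwise neutral.
#'
#' @param acidic,basic,his per-residue charges.
#' @return A named numeric vector (one-letter residue -> charge).
#' @export
charge_model <- function(acidic = -1, basic = 1, his = 0.1) {
  c(D = acidic, E = acidic, K = basic, R = basic, H = his)
}

.residue_class_sets <- list(
  acidic = c("D", "E"),
  basic = c("K", "R", "H"),
  polar = c("S", "T", "C", "Y", "N", "Q"),
  hydrophobic = c("A", "G", "I", "L", "M", "F", "P", "V", "W"))

#' Build a pocket profile from residue positions
#'
#' A pocket profile is a list of (residue number, one-letter residue name,
#' role tag) positions with the charge composition and electrostatic class
#' computed under the declared charge model. Role tags follow the
#' interaction taxonomy `h-bond`, `vdw`, `catalytic`, `water-mediated`;
#' water-mediated contacts are role tags only — waters never contribute
#' charge.
#'
#' @param positions data frame with columns `resno`, `resname` (one- or
#'   three-letter) and optionally `role`.
#' @param model see [charge_model()].
#' @return A list of class `"pocket_profile"`: `positions`, `net_charge`,
#'   `counts` (acidic/basic/polar/hydrophobic/other), `electro_class`,
#'   `model`.
#' @export
pocket_profile <- function(positions, model = charge_model()) {
  stopifnot(is.data.frame(positions))
  resname <- as.character(positions$resname)
  long <- nchar(resname) == 3L
  resname[long] <- .aa321(resname[long])
  resname <- toupper(resname)
  unknown <- !(resname %in% AA_ALPHABET_20)
  if (any(unknown)) {
    warning("unknown residue name(s) treated as charge 0: ",
            paste(unique(resname[unknown]), collapse = ", "))
  }
  pos <- data.frame(resno = as.integer(positions$resno),
                    resname = resname,
                    role = if ("role" %in% names(positions))
                      as.character(positions$role) else
                        rep("vdw", length(resname)),
                    stringsAsFactors = FALSE)
  ch <- model[pos$resname]
  ch[is.na(ch)] <- 0
  counts <- vapply(.residue_class_sets, function(set)
    sum(pos$resname %in% set), integer(1L))
  counts <- c(counts, other = sum(unknown))
  net <- sum(ch)
  eps <- 1e-9
  cls <- if (net <= -1 + eps) "acidic" else if (net >= 1 - eps) "basic" else
    "neutral"
  structure(list(positions = pos, net_charge = net, counts = counts,
                 electro_class = cls, model = model),
            class = "pocket_profile")
}

#' @export
print.pocket_profile <- function(x, ...) {
  cat(sprintf(
    "Pocket profile: %d positions, net charge %+.1f (%s)\n  %s\n",
    nrow(x$positions), x$net_charge, x$electro_class,
    paste(paste0(x$positions$resname, x$positions$resno), collapse = " ")))
  invisible(x)
}

#' Net charge and electrostatic class of a pocket
#'
#' Permutation-invariant and additive over disjoint position sets.
#'
#' @param x a `"pocket_profile"` or a positions data frame
#'   (see [pocket_profile()]).
#' @param model see [charge_model()].
#' @return A list with `net_charge`, `electro_class`, `counts`.
#' @export
pocket_charge <- function(x, model = charge_model()) {
  if (!inherits(x, "pocket_profile")) x <- pocket_profile(x, model)
  x[c("net_charge", "electro_class", "counts")]
}

#' Extract the acyl-acceptor pocket of a structure
#'
#' In ligand mode, pocket residues are those with any non-hydrogen atom
#' within `radius` of any ligand atom (waters are excluded from the position
#' list but counted). In list mode, the supplied positions are taken
#' verbatim — this is how in-text interaction-residue lists from structural
#' studies are represented, and it is never overridden by the radius rule.
#'
#' @param S a `"structure"` object (ligand mode) or `NULL` (list mode).
#' @param ligand HETATM residue name anchoring the pocket (e.g. `"SPD"`
#'   spermidine, `"COA"`).
#' @param residues explicit positions data frame (list mode), see
#'   [pocket_profile()].
#' @param radius contact radius in Angstrom (default 4.5).
#' @param model see [charge_model()].
#' @return A `"pocket_profile"`; in ligand mode with an extra
#'   `n_water_contacts` element.
#' @export
extract_pocket <- function(S = NULL, ligand = NULL, residues = NULL,
                           radius = 4.5, model = charge_model()) {
  if (!is.null(residues)) {
    if (nrow(residues) == 0L) stop("empty residue list")
    return(pocket_profile(residues, model))
  }
  stopifnot(inherits(S, "structure"), !is.null(ligand))
  if (!ligand %in% names(S$ligands)) {
    stop("ligand '", ligand, "' not found; available HETATM codes: ",
         if (length(S$ligands)) paste(names(S$ligands), collapse = ", ")
         else "(none)")
  }
  lig <- as.matrix(S$ligands[[ligand]][, c("x", "y", "z")])
  prot <- S$protein
  if ("elesy" %in% names(prot)) {
    prot <- prot[is.na(prot$elesy) | prot$elesy != "H", , drop = FALSE]
  }
  prot <- prot[!grepl("^[0-9]*H", prot$elety), , drop = FALSE]
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  mind <- function(X) {
    # min distance of each row of X to any ligand atom
    apply(X, 1L, function(p)
      sqrt(min(colSums((t(lig) - p)^2))))
  }
  within <- if (nrow(pxyz)) mind(pxyz) <= radius else logical(0)
  sel <- prot[within, , drop = FALSE]
  key <- !duplicated(paste(sel$chain, sel$resno, sel$insert))
  sel <- sel[key, , drop = FALSE]
  sel <- sel[order(sel$resno), , drop = FALSE]
  n_waters <- 0L
  if (nrow(S$waters)) {
    wxyz <- as.matrix(S$waters[, c("x", "y", "z")])
    wmin <- mind(wxyz)
    n_waters <- length(unique(paste(S$waters$chain[wmin <= radius],
                                    S$waters$resno[wmin <= radius])))
  }
  pos <- data.frame(resno = sel$resno, resname = .aa321(sel$resid),
                    role = rep("vdw", nrow(sel)), stringsAsFactors = FALSE)
  if (nrow(pos) == 0L) {
    prof <- structure(list(positions = pos, net_charge = 0,
                           counts = c(acidic = 0L, basic = 0L, polar = 0L,
                                      hydrophobic = 0L, other = 0L),
                           electro_class = "neutral", model = model),
                      class = "pocket_profile")
  } else {
    prof <- pocket_profile(pos, model)
  }
  prof$n_water_contacts <- n_waters
  prof
}

#' Map a template pocket onto a homologous query sequence
#'
#' Each template pocket position is mapped through a global alignment to the
#' corresponding query column; positions falling on alignment gaps are
#' reported as unresolved. The pocket charge is recomputed on the mapped
#' query residues. Below the identity floor the mapping is refused
#' (prediction unreliable) with an error of class
#' `"bahdscope_low_identity"`.
#'
#' @param template template sequence (protein record or string); residue `i`
#'   of the sequence is residue number `i` of the profile.
#' @param profile the template's `"pocket_profile"`.
#' @param query query protein record or sequence string.
#' @param params see [alignment_params()].
#' @param min_identity identity floor (default 0.20).
#' @param model see [charge_model()].
#' @return A list of class `"pocket_mapping"`: `profile` (query-side
#'   `"pocket_profile"` over resolved positions), `mapped` (data frame
#'   template_resno, template_resname, query_resno, query_resname),
#'   `unresolved` (template positions lost to gaps), `identity`,
#'   `template_id`, `query_id`.
#' @export
map_pocket_to_query <- function(template, profile, query,
                                params = alignment_params(),
                                min_identity = 0.20,
                                model = charge_model()) {
  ts <- .as_sequence(template)
  qs <- .as_sequence(query)
  bad <- profile$positions$resno > nchar(ts)
  if (any(bad)) stop("profile positions beyond template length: ",
                     paste(profile$positions$resno[bad], collapse = ", "))
  pa <- Biostrings::pairwiseAlignment(
    pattern = ts, subject = qs,
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = "global")
  av <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  bv <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  idstat <- .identity_from_aligned(paste(av, collapse = ""),
                                   paste(bv, collapse = ""))
  identity <- if (idstat[2L] > 0) idstat[1L] / idstat[2L] else 0
  if (identity < min_identity) {
    stop(structure(class = c("bahdscope_low_identity", "error", "condition"),
                   list(message = sprintf(
                     paste0("template-query identity %.1f%% below the %.0f%%",
                            " floor; pocket mapping refused as unreliable"),
                     100 * identity, 100 * min_identity),
                     call = sys.call(-1L))))
  }
  ia <- cumsum(av != "-")
  ib <- cumsum(bv != "-")
  # alignment column of each template residue
  col_of_t <- match(seq_len(nchar(ts)), ifelse(av != "-", ia, NA))
  qchars <- strsplit(qs, "")[[1L]]
  tres <- profile$positions$resno
  cols <- col_of_t[tres]
  qpos <- ifelse(!is.na(cols) & bv[cols] != "-", ib[cols], NA_integer_)
  mapped <- data.frame(template_resno = tres,
                       template_resname = profile$positions$resname,
                       role = profile$positions$role,
                       query_resno = qpos,
                       query_resname = ifelse(is.na(qpos), NA_character_,
                                              qchars[qpos]),
                       stringsAsFactors = FALSE)
  ok <- !is.na(mapped$query_resno)
  qprof <- if (any(ok)) {
    pocket_profile(data.frame(resno = mapped$query_resno[ok],
                              resname = mapped$query_resname[ok],
                              role = mapped$role[ok]), model)
  } else {
    pocket_profile(data.frame(resno = integer(), resname = character(),
                              role = character())[FALSE, ], model)
  }
  structure(list(profile = qprof, mapped = mapped,
                 unresolved = mapped[!ok, , drop = FALSE],
                 identity = identity,
                 template_id = .as_id(template, "template"),
                 query_id = .as_id(query, "query")),
            class = "pocket_mapping")
}

#' @export
print.pocket_mapping <- function(x, ...) {
  cat(sprintf(
    "Pocket mapping %s -> %s (identity %.1f%%): net %+.1f (%s), %d unresolved\n",
    x$template_id, x$query_id, 100 * x$identity,
    x$profile$net_charge, x$profile$electro_class, nrow(x$unresolved)))
  invisible(x)
}

#' Write a pocket report TSV
#'
#' Columns: `resno`, `resname`, `role`, `charge`.
#'
#' @param profile a `"pocket_profile"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pocket_tsv <- function(profile, path) {
  ch <- profile$model[profile$positions$resname]
  ch[is.na(ch)] <- 0
  utils::write.table(
    cbind(profile$positions, charge = unname(ch)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
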