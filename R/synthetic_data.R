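# Synthetic data generator: sequence families diverged from motif-carrying
# seeds, toy CA-trace structures, and pocket charge variants with known
# ground truth. Everything downstream is testable against these with zero
# downloads.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a random seed sequence with planted BAHD motifs
#'
#' Uniform-random background with `HXXXD` planted at `round(0.35 * length)`
#' and `DFGWG` at `round(0.85 * length)` — the canonical central-catalytic /
#' C-terminal-structural arrangement of the family. Uses the current RNG
#' stream (`set.seed()` beforehand for reproducibility).
#'
#' @param length sequence length (default 450; at least 60).
#' @param id record identifier.
#' @return A single protein record with `source = "synthetic"`.
#' @export
make_seed_sequence <- function(length = 450L, id = "seed") {
  if (length < 60L) stop("seed length must be at least 60")
  chars <- sample(AA_ALPHABET_20, length, replace = TRUE)
  h <- round(0.35 * length)
  chars[h] <- "H"; chars[h + 4L] <- "D"
  d <- round(0.85 * length)
  chars[d:(d + 4L)] <- c("D", "F", "G", "W", "G")
  protein_records(id, paste(chars, collapse = ""),
                  description = "synthetic motif-carrying seed",
                  source = "synthetic")
}

# 1-based positions protected from mutation: motif anchors (H and D of every
# exact HXXXD hit, all five DFGWG positions) plus any extra positions.
.protected_positions <- function(seq, extra = integer()) {
  hits <- scan_motifs(seq, max_dfgwg_mismatch = 0L)
  prot <- integer()
  hx <- hits[hits$motif == "HXXXD", , drop = FALSE]
  if (nrow(hx)) prot <- c(prot, hx$start, hx$start + 4L)
  df <- hits[hits$motif == "DFGWG", , drop = FALSE]
  if (nrow(df)) prot <- c(prot, unlist(lapply(df$start, function(s) s:(s + 4L))))
  sort(unique(c(prot, extra)))
}

#' Evolve a family of sequences from a seed
#'
#' Each member is mutated independently from the seed: every site is
#' substituted with probability `substitution_rate` to a uniformly chosen
#' *different* residue, except protected positions (motif anchors by
#' default — the H/D of HXXXD and all of DFGWG — plus any
#' `protect_positions`). Uniform substitution keeps the expected identity to
#' the seed analytically simple (`1 - rate` per unprotected site). When
#' `indel_rate > 0`, insertion/deletion events (geometric length, mean 2)
#' are applied outside protected positions.
#'
#' @param seed a single protein record.
#' @param n number of members.
#' @param substitution_rate per-site substitution probability in \[0, 0.95\].
#' @param indel_rate per-site indel-event probability (default 0).
#' @param protect_motifs protect motif anchor positions (default TRUE).
#' @param protect_positions extra 1-based positions to protect.
#' @param family_id label recorded in the `family` column and member ids.
#' @return A protein-records data frame with an extra `family` column.
#' @export
evolve_family <- function(seed, n, substitution_rate, indel_rate = 0,
                          protect_motifs = TRUE,
                          protect_positions = integer(),
                          family_id = "fam") {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.95,
            indel_rate >= 0, indel_rate <= 0.2)
  sseq <- .as_sequence(seed)
  L <- nchar(sseq)
  chars0 <- strsplit(sseq, "")[[1L]]
  prot <- if (protect_motifs) .protected_positions(sseq, protect_positions)
  else sort(unique(protect_positions))
  members <- vector("list", n)
  for (i in seq_len(n)) {
    chars <- chars0
    mut <- stats::runif(L) < substitution_rate
    mut[prot] <- FALSE
    if (any(mut)) {
      chars[mut] <- vapply(chars[mut], function(cc)
        sample(setdiff(AA_ALPHABET_20, cc), 1L), character(1L))
    }
    if (indel_rate > 0) {
      ev <- which(stats::runif(L) < indel_rate)
      ev <- setdiff(ev, prot)
      for (p in rev(ev)) {  # right-to-left keeps positions valid
        len <- stats::rgeom(1L, 0.5) + 1L
        if (stats::runif(1L) < 0.5) {
          ins <- sample(AA_ALPHABET_20, len, replace = TRUE)
          chars <- append(chars, ins, after = p)
        } else {
          del <- p:min(p + len - 1L, length(chars))
          del <- setdiff(del, prot)
          if (length(del) < length(chars)) chars <- chars[-del]
        }
      }
    }
    members[[i]] <- paste(chars, collapse = "")
  }
  out <- protein_records(sprintf("%s_m%02d", family_id, seq_len(n)),
                         unlist(members),
                         description = sprintf("evolved from %s",
                                               .as_id(seed, "seed")),
                         source = "synthetic")
  out$family <- family_id
  out
}

#' Specification of a synthetic family set
#'
#' The defaults define the standard study conditions of the synthetic
#' experiments: two BAHD-like families of eight members, 450-residue seeds,
#' 10% per-site divergence from the seed, no indels.
#'
#' @param n_families number of families (independent seeds).
#' @param members_per_family members evolved per seed.
#' @param seed_length seed sequence length.
#' @param substitution_rate per-site substitution probability in \[0, 0.95\].
#' @param indel_rate per-site indel-event probability.
#' @param rng_seed integer RNG seed; identical specs give byte-identical
#'   output.
#' @return A list of class `"family_spec"`.
#' @export
family_spec <- function(n_families = 2L, members_per_family = 8L,
                        seed_length = 450L, substitution_rate = 0.1,
                        indel_rate = 0, rng_seed = 1L) {
  stopifnot(n_families >= 1L, members_per_family >= 1L, seed_length >= 60L,
            substitution_rate >= 0, substitution_rate <= 0.95)
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 seed_length = as.integer(seed_length),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "family_spec")
}

#' Generate a labeled family set with ground truth
#'
#' Independent seeds (one per family) are evolved into members; the truth
#' table maps every id to its family. With default rates, within-family
#' identity exceeds between-family identity because the seeds are
#' independent random sequences.
#'
#' @param spec a [family_spec()].
#' @return A list with `records` (all members, `family` column), `truth`
#'   (data frame id, family), `seeds` (the seed records).
#' @export
make_family_set <- function(spec = family_spec()) {
  .with_seed(spec$rng_seed, {
    seeds <- vector("list", spec$n_families)
    fams <- vector("list", spec$n_families)
    for (f in seq_len(spec$n_families)) {
      fid <- sprintf("fam%02d", f)
      seeds[[f]] <- make_seed_sequence(spec$seed_length,
                                       id = sprintf("%s_seed", fid))
      fams[[f]] <- evolve_family(seeds[[f]], spec$members_per_family,
                                 spec$substitution_rate, spec$indel_rate,
                                 family_id = fid)
    }
    records <- do.call(rbind, fams)
    list(records = records,
         truth = data.frame(id = records$id, family = records$family,
                            stringsAsFactors = FALSE),
         seeds = do.call(rbind, seeds))
  })
}

#' Generate a toy CA-trace structure (ideal alpha helix)
#'
#' CA positions on an ideal alpha-helical trace (rise 1.5 A per residue,
#' radius 2.3 A, 100 degrees of twist per residue), optionally perturbed by
#' isotropic Gaussian noise and/or moved by a random rigid transform. When
#' only a rigid transform is applied, the ground-truth superposed RMSD
#' against the unmoved trace is 0.
#'
#' @param n_residues number of residues (at least 10).
#' @param sigma isotropic Gaussian perturbation per coordinate (Angstrom).
#' @param rigid_transform apply a random rotation + translation.
#' @param sequence optional residue sequence (defaults to poly-alanine).
#' @param chain chain identifier.
#' @return A `"structure"` object; when a transform was applied, its
#'   `rotation`/`translation` are stored in the `"rigid_transform"`
#'   attribute.
#' @export
make_toy_structure <- function(n_residues, sigma = 0,
                               rigid_transform = FALSE, sequence = NULL,
                               chain = "A") {
  if (n_residues < 10L) stop("need at least 10 residues")
  i <- seq_len(n_residues) - 1L
  theta <- i * 100 * pi / 180
  xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  if (sigma > 0) {
    xyz <- xyz + matrix(stats::rnorm(3L * n_residues, sd = sigma),
                        ncol = 3L)
  }
  tr <- NULL
  if (rigid_transform) {
    # uniform random rotation via quaternion
    q <- stats::rnorm(4L); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)), 3L, 3L, byrow = TRUE)
    t <- stats::runif(3L, -20, 20)
    xyz <- sweep(xyz %*% t(R), 2L, t, `+`)
    tr <- list(rotation = R, translation = t)
  }
  res1 <- if (is.null(sequence)) rep("A", n_residues) else
    strsplit(.normalize_sequence(sequence), "")[[1L]]
  stopifnot(length(res1) == n_residues)
  at <- data.frame(type = "ATOM", eleno = seq_len(n_residues),
                   elety = "CA", alt = "", resid = .aa123(res1),
                   chain = chain, resno = seq_len(n_residues), insert = "",
                   x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                   o = 1, b = 0, elesy = "C", stringsAsFactors = FALSE)
  s <- structure(list(atoms = at, protein = at, ligands = list(),
                      waters = at[0L, ],
                      chains = stats::setNames(list(list(
                        sequence = paste(res1, collapse = ""),
                        resno = seq_len(n_residues))), chain),
                      path = NA_character_),
                 class = "structure")
  attr(s, "rigid_transform") <- tr
  s
}

#' Mutate pocket positions to shift the net charge by an exact delta
#'
#' Achieves the requested charge delta with the minimal number of pocket
#' substitutions using charge-inverting swaps (D/E -> R/K for +2 per swap,
#' K/R -> E/D for -2); all non-pocket positions are untouched. Substitutions
#' are applied at the smallest eligible residue numbers first, so the result
#' is deterministic.
#'
#' @param record protein record to mutate.
#' @param pocket_resno 1-based pocket positions within the sequence.
#' @param delta requested net-charge change (even; reachable range depends on
#'   the number of acidic/basic pocket residues).
#' @param model see [charge_model()].
#' @return The mutated record (same id with a `_dq` suffix).
#' @export
make_pocket_variant <- function(record, pocket_resno, delta,
                                model = charge_model()) {
  seq <- .as_sequence(record)
  chars <- strsplit(seq, "")[[1L]]
  stopifnot(all(pocket_resno >= 1L), all(pocket_resno <= length(chars)))
  if (delta == 0) return(record)
  res <- chars[pocket_resno]
  acidic <- pocket_resno[res %in% c("D", "E")]
  basic <- pocket_resno[res %in% c("K", "R")]
  max_up <- 2L * length(acidic)
  max_down <- -2L * length(basic)
  if (delta %% 2 != 0 || delta > max_up || delta < max_down) {
    stop("charge delta ", delta, " unreachable by D/E<->K/R swaps; ",
         "reachable range is [", max_down, ", ", max_up,
         "] in steps of 2")
  }
  swap <- c(D = "R", E = "K", K = "E", R = "D")
  targets <- if (delta > 0) sort(acidic)[seq_len(delta / 2)] else
    sort(basic)[seq_len(-delta / 2)]
  chars[targets] <- swap[chars[targets]]
  out <- record
  out$sequence <- paste(chars, collapse = "")
  out$id <- sprintf("%s_dq%+d", record$id, delta)
  out$source <- "synthetic"
  out
}

#' Planted-class prediction benchmark
#'
#' Builds, under one seed, a two-class benchmark with known ground truth:
#' an acidic-pocket scaffold family (polyamine/amine acceptors) and an
#' independent basic-pocket scaffold family (shikimate-type), each seed
#' serving as its own labeled reference while the evolved members are the
#' queries. Pocket and motif positions are protected during evolution so the
#' planted class is the ground truth by construction.
#'
#' @param n_per_class queries evolved per class.
#' @param substitution_rate per-site divergence of queries from their
#'   scaffold (default 0.1; the benchmark conditions cap this at 0.15).
#' @param rng_seed integer seed.
#' @param params see [alignment_params()].
#' @param cluster_cutoff reference SSN cutoff.
#' @return A list with `refs` (a `"reference_bundle"`-shaped list built from
#'   the two scaffolds), `queries` (records), `truth` (id -> verdict).
#' @export
make_prediction_benchmark <- function(n_per_class = 10L,
                                      substitution_rate = 0.1,
                                      rng_seed = 1L,
                                      params = alignment_params(),
                                      cluster_cutoff = 10^-51.5) {
  stopifnot(substitution_rate <= 0.15)
  .with_seed(rng_seed, {
    sdt_prof <- bahd_pocket("AtSDT")
    acidic_seed <- make_seed_sequence(450L, id = "acidic_ref")
    ac <- strsplit(acidic_seed$sequence, "")[[1L]]
    ac[sdt_prof$positions$resno] <- sdt_prof$positions$resname
    acidic_seed$sequence <- paste(ac, collapse = "")
    basic_seed <- make_seed_sequence(450L, id = "basic_ref")
    bs <- strsplit(basic_seed$sequence, "")[[1L]]
    swap <- c(D = "R", E = "K")
    inv <- sdt_prof$positions
    inv$resname <- ifelse(inv$resname %in% names(swap),
                          swap[inv$resname], inv$resname)
    bs[inv$resno] <- inv$resname
    basic_seed$sequence <- paste(bs, collapse = "")
    pocket_resno <- sdt_prof$positions$resno
    qa <- evolve_family(acidic_seed, n_per_class, substitution_rate,
                        protect_positions = pocket_resno,
                        family_id = "acidicQ")
    qb <- evolve_family(basic_seed, n_per_class, substitution_rate,
                        protect_positions = pocket_resno,
                        family_id = "basicQ")
    refs_records <- rbind(acidic_seed, basic_seed)
    labels <- data.frame(
      id = refs_records$id,
      enzyme = c("polyamine-reference", "shikimate-reference"),
      acceptor_class = c("polyamine/amine", "shikimate-type"),
      stringsAsFactors = FALSE)
    alignments <- all_vs_all(refs_records, params, evalue_cutoff = 1)
    graph <- build_ssn(alignments, cluster_cutoff,
                       singletons = refs_records$id,
                       labels = stats::setNames(labels$acceptor_class,
                                                labels$id))
    templates <- list()
    templates[[acidic_seed$id]] <- list(
      record = acidic_seed,
      profile = pocket_profile(sdt_prof$positions))
    templates[[basic_seed$id]] <- list(
      record = basic_seed, profile = pocket_profile(inv))
    refs <- structure(list(records = refs_records, labels = labels,
                           alignments = alignments, graph = graph,
                           templates = templates, params = params,
                           gather_cutoff = 1e-25,
                           cluster_cutoff = cluster_cutoff),
                      class = "reference_bundle")
    queries <- rbind(qa, qb)
    truth <- data.frame(
      id = queries$id,
      verdict = rep(c("polyamine/amine", "shikimate-type"),
                    each = n_per_class),
      stringsAsFactors = FALSE)
    list(refs = refs, queries = queries, truth = truth)
  })
}
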