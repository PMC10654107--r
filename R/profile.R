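# Position-specific profiles with decoy-calibrated E-values, and the
# iterative search-to-convergence mining loop.
#
# The profile is a calibrated position-specific scoring model (log-odds in
# bits against a background composition) with affine gap penalties, i.e. the
# procedure's semantics of a profile HMM search at desk scale; externally
# computed HMM-search tabular output can be imported with read_hits_tsv().

PROFILE_GAP_OPEN <- 4.0   # bits
PROFILE_GAP_EXT <- 0.5    # bits

#' Build a calibrated profile from a multiple alignment
#'
#' Match states are alignment columns with at most 50% gaps. Per-column
#' residue frequencies receive background-proportional pseudocounts of total
#' weight `pseudocount_weight`; scores are log2(frequency / background).
#' The score distribution is calibrated by scoring `n_decoys` shuffled
#' decoys (residues resampled from the training alignment's composition)
#' and fitting a Gumbel law by moments, from which E-values are computed.
#'
#' @param msa A `protein_msa` object (or named character vector of aligned
#'   rows).
#' @param pseudocount_weight Total pseudocount mass per column (default 1).
#' @param background Residue background frequencies over the 20 amino acids
#'   (default uniform).
#' @param family_id Identifier carried into hits.
#' @param n_decoys Number of shuffled decoys for calibration (default 1000).
#' @param decoy_len Decoy length in residues (default 150); E-values are
#'   length-corrected relative to this calibration length.
#' @param seed Seed for decoy generation.
#' @return A `hallmark_profile` object.
#' @export
build_profile <- function(msa, pseudocount_weight = 1,
                          background = NULL, family_id = "family",
                          n_decoys = 1000, decoy_len = 150, seed = 1) {
  if (!inherits(msa, "protein_msa")) msa <- msa_from_rows(msa)
  m <- msa_matrix(msa)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  assert_that(abs(sum(background) - 1) < 1e-8, "background must sum to 1")
  gap_frac <- colMeans(m == GAP_CHAR)
  match_cols <- which(gap_frac <= 0.5)
  assert_that(length(match_cols) > 0,
              "alignment has no columns with <= 50% gaps")
  scores <- matrix(0, length(match_cols), 20,
                   dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_along(match_cols)) {
    res <- m[, match_cols[k]]
    res <- res[res %in% AA_ALPHABET]
    tab <- as.numeric(table(factor(res, levels = AA_ALPHABET)))
    f <- (tab + pseudocount_weight * background) /
      (length(res) + pseudocount_weight)
    scores[k, ] <- log2(f / background)
  }
  prof <- structure(list(
    family_id = family_id, match_scores = scores,
    background = background, pseudocount_weight = pseudocount_weight,
    msa_col_map = match_cols, n_seqs = nrow(m),
    gap_open = PROFILE_GAP_OPEN, gap_ext = PROFILE_GAP_EXT,
    gumbel_mu = NA_real_, gumbel_lambda = NA_real_,
    calibration_len = decoy_len, n_decoys = n_decoys),
    class = "hallmark_profile")
  calibrate_profile(prof, m, n_decoys, decoy_len, seed)
}

#' @noRd
calibrate_profile <- function(prof, m, n_decoys, decoy_len, seed) {
  pool <- as.vector(m)
  pool <- pool[pool %in% AA_ALPHABET]
  with_stream(seed, paste0("calibrate_", prof$family_id), {
    scores <- vapply(seq_len(n_decoys), function(i) {
      decoy <- sample(pool, decoy_len, replace = TRUE)
      .pssm_score(prof$match_scores, aa_index(decoy),
                  prof$gap_open, prof$gap_ext)
    }, 0)
    lam <- pi / (stats::sd(scores) * sqrt(6))
    mu <- mean(scores) - 0.5772156649 / lam
    prof$gumbel_lambda <- lam
    prof$gumbel_mu <- mu
  })
  prof
}

#' @noRd
profile_evalue <- function(prof, score, target_len, n_targets) {
  x <- exp(-prof$gumbel_lambda * (score - prof$gumbel_mu)) *
    (target_len / prof$calibration_len)
  n_targets * (1 - exp(-x))
}

#' @export
print.hallmark_profile <- function(x, ...) {
  cat("<hallmark_profile> ", x$family_id, ": ", nrow(x$match_scores),
      " match columns, ", x$n_seqs, " training rows",
      if (!is.na(x$gumbel_lambda)) sprintf(
        ", Gumbel(mu=%.2f, lambda=%.3f)", x$gumbel_mu, x$gumbel_lambda),
      "\n", sep = "")
  invisible(x)
}

#' Search a calibrated profile against a protein set
#'
#' Computes the best local profile-to-sequence alignment for every protein
#' and reports those with E-value at most `max_evalue`, sorted by E-value
#' then protein id.
#'
#' @param profile A calibrated `hallmark_profile`.
#' @param proteins Tibble with `protein_id` and `sequence` columns (an
#'   extra `genome_id` column is carried through).
#' @param max_evalue Reporting threshold (default 1e-10, the mining
#'   threshold of the procedure).
#' @return Tibble of hits: `protein_id`, `genome_id` (if supplied),
#'   `family_id`, `bitscore`, `evalue`, `ali_start`, `ali_end` (0-based
#'   half-open residue coordinates on the target).
#' @export
search_profile <- function(profile, proteins, max_evalue = 1e-10) {
  assert_that(inherits(profile, "hallmark_profile"),
              "profile must be a hallmark_profile")
  assert_that(!is.na(profile$gumbel_lambda),
              "profile is not calibrated")
  proteins <- tibble::as_tibble(proteins)
  empty <- tibble::tibble(protein_id = character(),
                          genome_id = character(),
                          family_id = character(), bitscore = double(),
                          evalue = double(), ali_start = integer(),
                          ali_end = integer())
  if (nrow(proteins) == 0) return(empty)
  n_targets <- nrow(proteins)
  rows <- vector("list", n_targets)
  for (i in seq_len(n_targets)) {
    seq_idx <- aa_index(strsplit(proteins$sequence[i], "", fixed = TRUE)[[1]])
    seq_idx[is.na(seq_idx)] <- 0L
    s <- .pssm_score(profile$match_scores, seq_idx,
                     profile$gap_open, profile$gap_ext)
    ev <- profile_evalue(profile, s, length(seq_idx), n_targets)
    if (ev <= max_evalue) {
      al <- .pssm_align(profile$match_scores, seq_idx,
                        profile$gap_open, profile$gap_ext)
      rows[[i]] <- tibble::tibble(
        protein_id = proteins$protein_id[i],
        genome_id = if ("genome_id" %in% names(proteins))
          proteins$genome_id[i] else NA_character_,
        family_id = profile$family_id, bitscore = s, evalue = ev,
        ali_start = as.integer(al$sstart - 1L),
        ali_end = as.integer(al$send))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$evalue, .data$protein_id)
}

#' Iterative profile search to convergence
#'
#' The reference-guided mining loop: build a profile from the current
#' member alignment, search the database, add newly recruited hits to the
#' alignment by profile-guided insertion (or full realignment with
#' `realign = TRUE`), and repeat until the hit-identifier set stops
#' changing or `max_iter` is reached. The recruited hit set is accumulated
#' as a union across iterations, so it is monotonically non-decreasing.
#'
#' @param seed_sequences Named character vector of seed proteins.
#' @param database Tibble of candidate proteins (`protein_id`, `sequence`,
#'   optionally `genome_id`).
#' @param max_evalue Recruitment threshold (default 1e-10).
#' @param max_iter Maximum iterations (default 10).
#' @param family_id Profile/family identifier.
#' @param realign Rebuild the member alignment from scratch each iteration
#'   instead of guided insertion.
#' @param n_decoys,seed Calibration controls passed to [build_profile()].
#' @return List with `hits` (tibble of the final hit set), `n_iterations`,
#'   `converged` (FALSE carries a warning, not an error), and `profile`
#'   (the final calibrated profile).
#' @export
iterative_search <- function(seed_sequences, database, max_evalue = 1e-10,
                             max_iter = 10, family_id = "family",
                             realign = FALSE, n_decoys = 1000, seed = 1) {
  assert_that(length(seed_sequences) >= 1, "need at least one seed sequence")
  assert_that(max_iter >= 1, "max_iter must be >= 1")
  database <- tibble::as_tibble(database)
  aln <- if (length(seed_sequences) >= 2) build_msa(seed_sequences) else
    msa_from_rows(seed_sequences)
  members <- names(seed_sequences)
  hit_ids <- character(0)
  hits <- NULL
  n_it <- 0
  converged <- FALSE
  repeat {
    n_it <- n_it + 1
    prof <- build_profile(aln, family_id = family_id,
                          n_decoys = n_decoys, seed = seed + n_it)
    new_hits <- search_profile(prof, database, max_evalue)
    hits <- if (is.null(hits)) new_hits else
      dplyr::bind_rows(hits[!hits$protein_id %in% new_hits$protein_id, ,
                            drop = FALSE], new_hits)
    hit_ids <- union(hit_ids, new_hits$protein_id)
    recruits <- setdiff(hit_ids, members)
    if (length(recruits) == 0) { converged <- TRUE; break }
    if (realign) {
      seqs <- c(stats::setNames(
        gsub("-", "", aln$rows[members[members %in% names(aln$rows)]],
             fixed = TRUE), intersect(members, names(aln$rows))),
        stats::setNames(
          database$sequence[match(recruits, database$protein_id)], recruits))
      aln <- build_msa(seqs)
    } else {
      for (pid in recruits) {
        s <- database$sequence[match(pid, database$protein_id)]
        aln <- guided_insert(aln, prof, pid, s)
      }
    }
    members <- union(members, recruits)
    if (n_it >= max_iter) break
  }
  # a final confirmation pass can only re-find existing members, so the set
  # is converged whenever no recruit was added in the last iteration
  if (!converged && n_it >= max_iter) {
    warning("iterative_search did not converge in ", max_iter, " iterations")
  }
  hits <- dplyr::arrange(hits, .data$evalue, .data$protein_id)
  list(hits = hits, n_iterations = n_it, converged = converged,
       profile = if (exists("prof")) prof else NULL)
}

# Insert a sequence into an alignment by mapping its best local alignment
# onto the profile's match columns: match-state residues are placed in the
# corresponding alignment columns, deletions become gaps, insertions
# relative to the profile are discarded.
#' @noRd
guided_insert <- function(aln, prof, id, sequence) {
  seq_idx <- aa_index(strsplit(sequence, "", fixed = TRUE)[[1]])
  seq_idx[is.na(seq_idx)] <- 0L
  al <- .pssm_align(prof$match_scores, seq_idx,
                    prof$gap_open, prof$gap_ext)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  new_row <- rep(GAP_CHAR, aln$n_cols)
  placed <- al$colmap > 0
  new_row[prof$msa_col_map[placed]] <- chars[al$colmap[placed]]
  rows <- c(aln$rows, stats::setNames(paste(new_row, collapse = ""), id))
  msa_from_rows(rows)
}

#' Import profile-search hits from a tabular file
#'
#' Accepts the package's own TSV hit format (columns `protein_id`,
#' `family_id`, `bitscore`, `evalue`, `ali_start`, `ali_end`, optionally
#' `genome_id`), e.g. converted from an external HMM search's domain table.
#'
#' @param path TSV file.
#' @return Tibble of hits.
#' @export
read_hits_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
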