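# Candidate screening: the multi-step filter that turns profile-search hits
# into high-quality genome calls. Filter order follows the mining procedure:
# polymerase length -> conserved motif -> genome-wide deduplication ->
# seven-hallmark completeness with chimera flagging. Every removal carries a
# machine-readable reason.

#' Length filter for polymerase candidates
#'
#' Removes proteins shorter than `min_len` amino acids (default 2,500, the
#' cutoff that separates the giant virion RNA polymerase, 2,842-3,820 aa in
#' reference genomes, from distantly related T7-like polymerases).
#'
#' @param hits A data frame with at least `protein_id` and `sequence`
#'   columns (extra columns are passed through).
#' @param min_len Minimum retained length in amino acids.
#' @return A tibble of `hits` rows with `length >= min_len` plus a tibble of
#'   removals, as a list `list(kept, removed)`; `removed` carries a
#'   `reason = "length<min_len"` column.
#' @export
length_filter <- function(hits, min_len = 2500) {
  assert_that(min_len >= 1, "min_len must be >= 1")
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0) {
    return(list(kept = hits,
                removed = dplyr::mutate(hits, reason = character(0))))
  }
  len <- nchar(hits$sequence)
  kept <- hits[len >= min_len, , drop = FALSE]
  removed <- hits[len < min_len, , drop = FALSE]
  removed$reason <- sprintf("length<%d", min_len)
  list(kept = kept, removed = removed)
}

#' Scan a protein for a wildcard motif
#'
#' Finds all (possibly overlapping) occurrences of a motif written over the
#' 20 residue letters plus `x` as a single-residue wildcard, e.g. the
#' conserved polymerase motif `"ExDGxxxG"`.
#'
#' @param sequence Amino-acid string.
#' @param pattern Motif string; `x` matches any residue.
#' @return Integer vector of 0-based match start positions.
#' @export
motif_scan <- function(sequence, pattern = "ExDGxxxG") {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  assert_that(length(chars) >= 2, "pattern must have length >= 2")
  ok <- chars == "x" | chars %in% AA_ALPHABET
  assert_that(all(ok), paste0("pattern contains illegal characters: ",
                              paste(unique(chars[!ok]), collapse = "")))
  assert_that(any(chars != "x"), "pattern needs at least one non-wildcard")
  rx <- paste(ifelse(chars == "x", ".", chars), collapse = "")
  # lookahead makes overlapping matches visible
  m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Greedy deduplication of nucleotide sequences at a global identity cutoff
#'
#' Greedy incremental clustering in the style of genome-wide duplicate
#' removal: sequences are visited by decreasing length (ties broken by
#' lexicographic id); each joins the first existing cluster whose
#' representative it matches at global identity >= `identity_threshold`
#' (matches divided by global alignment length, end gaps penalized),
#' otherwise it founds a new cluster.
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param identity_threshold Fraction in (0, 1]; default 0.99.
#' @return A tibble with columns `id`, `cluster`, `representative`
#'   (logical), `identity_to_rep`.
#' @export
dedup <- function(sequences, identity_threshold = 0.99) {
  assert_that(identity_threshold > 0 && identity_threshold <= 1,
              "identity_threshold must be in (0, 1]")
  if (length(sequences) == 0) {
    return(tibble::tibble(id = character(), cluster = character(),
                          representative = logical(),
                          identity_to_rep = double()))
  }
  ids <- names(sequences)
  ord <- order(-nchar(sequences), ids)
  reps <- character(0)
  rows <- vector("list", length(sequences))
  # conservative screens that can only skip pairs whose global identity is
  # certainly below the threshold:
  # (1) matches <= min(len) and alignment length >= max(len), so identity
  #     <= min(len)/max(len);
  # (2) at identity t the shared-15-mer fraction of the shorter sequence is
  #     at least 1 - 15*(1-t) in the worst case, far above 0.5 for t=0.99.
  kmer_set <- function(s, k = 15) {
    if (nchar(s) < k) return(NULL)
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  }
  kmers <- lapply(sequences, kmer_set)
  may_match <- function(i, r) {
    la <- nchar(sequences[[i]]); lb <- nchar(sequences[[r]])
    if (min(la, lb) / max(la, lb) < identity_threshold) return(FALSE)
    bound <- 1 - 15 * (1 - identity_threshold)  # worst-case shared fraction
    if (bound <= 0.6) return(TRUE)              # screen uninformative
    ka <- kmers[[i]]; kb <- kmers[[r]]
    if (is.null(ka) || is.null(kb)) return(TRUE)
    length(intersect(ka, kb)) / min(length(ka), length(kb)) >= bound - 0.3
  }
  for (i in seq_along(ord)) {
    id <- ids[ord[i]]
    seq <- sequences[[ord[i]]]
    assigned <- NA_character_
    ident <- NA_real_
    for (r in reps) {
      if (!may_match(ord[i], match(r, ids))) next
      pid <- global_identity(seq, sequences[[r]])
      if (pid >= identity_threshold) {
        assigned <- r
        ident <- pid
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, id)
      rows[[i]] <- tibble::tibble(id = id, cluster = id,
                                  representative = TRUE,
                                  identity_to_rep = 1)
    } else {
      rows[[i]] <- tibble::tibble(id = id, cluster = assigned,
                                  representative = FALSE,
                                  identity_to_rep = ident)
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$id)
}

# Global identity = matches / global alignment length with end gaps
# penalized (overlap of the full sequences).
#' @noRd
global_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "global",
                                      substitutionMatrix =
                                        Biostrings::nucleotideSubstitutionMatrix(
                                          match = 1, mismatch = -1),
                                      gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(al) / Biostrings::nchar(al)
}

#' Classify a contig by its hallmark-gene completeness
#'
#' Applies the completeness rule: a contig is high quality (`HQ`) iff all
#' hallmark types are present with exactly one copy each; a contig with all
#' types but any multi-copy family is flagged as a probable assembly
#' chimera; otherwise `k`-core where `k` is the number of types present;
#' zero types is rejected.
#'
#' @param contig_hits Named list or tibble mapping `family_id` to hallmark
#'   hit counts for one contig; either a tibble with `family_id` rows or a
#'   named integer vector of copy counts.
#' @param hallmark_families Character vector of the hallmark family ids
#'   (default the seven lineage hallmarks).
#' @param contig_id Optional contig identifier carried into the result.
#' @return A one-row tibble: `contig_id`, `n_types`, per-family counts in a
#'   list column `hallmark_counts`, `label`, `reasons`.
#' @export
classify_completeness <- function(contig_hits,
                                  hallmark_families = HALLMARK_NAMES,
                                  contig_id = NA_character_) {
  counts <- if (is.data.frame(contig_hits)) {
    fam_col <- if ("family_id" %in% names(contig_hits))
      contig_hits$family_id else character(0)
    tab <- table(fam_col)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    vapply(contig_hits, length, 1L)
  }
  if (is.null(names(counts)) && length(counts) > 0)
    stop("contig_hits must be named by family id")
  unknown <- setdiff(names(counts), hallmark_families)
  assert_that(length(unknown) == 0,
              paste0("unknown hallmark family id: ",
                     paste(unknown, collapse = ", ")))
  full <- stats::setNames(integer(length(hallmark_families)),
                          hallmark_families)
  full[names(counts)] <- counts
  n_types <- sum(full > 0)
  n_all <- length(hallmark_families)
  if (n_types == n_all && all(full == 1)) {
    label <- "HQ"; reasons <- character(0)
  } else if (n_types == n_all) {
    label <- "chimera_flagged"
    reasons <- sprintf("multi_copy:%s",
                       paste(names(full)[full > 1], collapse = ","))
  } else if (n_types > 0) {
    label <- sprintf("%d-core", n_types)
    reasons <- sprintf("missing:%s",
                       paste(names(full)[full == 0], collapse = ","))
  } else {
    label <- "rejected"; reasons <- "no_hallmark_hits"
  }
  tibble::tibble(contig_id = contig_id, n_types = n_types,
                 hallmark_counts = list(full), label = label,
                 reasons = list(reasons))
}

#' Screen candidate contigs into high-quality genome calls
#'
#' Composes the full filter in procedure order: (1) polymerase-family hits
#' are length-filtered at `min_len`; (2) surviving polymerases are screened
#' for the conserved motif; (3) contigs whose polymerase survived are
#' deduplicated genome-wide at `dedup_identity` (global mode); (4) each
#' representative contig is classified by hallmark completeness. Contigs
#' removed along the way are retained in the report with their reasons.
#'
#' @param hits Tibble of profile hits with columns `protein_id`,
#'   `contig_id`, `family_id`, `sequence`.
#' @param contig_seqs Named character vector of candidate contig
#'   nucleotide sequences.
#' @param polymerase_family Family id the length/motif filters apply to.
#' @param min_len,motif,dedup_identity Filter parameters (defaults: 2,500
#'   aa, `"ExDGxxxG"`, 0.99).
#' @param hallmark_families Character vector of hallmark family ids.
#' @return A tibble with one row per input contig: `contig_id`, `n_types`,
#'   `hallmark_counts` (list), `label`, `reasons` (list). Labels are `HQ`,
#'   `k-core`, `chimera_flagged` or `rejected`.
#' @export
screen_candidates <- function(hits, contig_seqs,
                              polymerase_family = "vRNAP",
                              min_len = 2500, motif = "ExDGxxxG",
                              dedup_identity = 0.99,
                              hallmark_families = HALLMARK_NAMES) {
  hits <- tibble::as_tibble(hits)
  all_contigs <- names(contig_seqs)
  reasons_by_contig <- stats::setNames(
    vector("list", length(all_contigs)), all_contigs)

  pol <- hits[hits$family_id == polymerase_family, , drop = FALSE]
  lf <- length_filter(pol, min_len)
  for (cid in unique(lf$removed$contig_id)) {
    reasons_by_contig[[cid]] <- c(reasons_by_contig[[cid]],
                                  sprintf("polymerase_length<%d", min_len))
  }
  motif_ok <- vapply(lf$kept$sequence,
                     function(s) length(motif_scan(s, motif)) > 0, logical(1))
  for (cid in unique(lf$kept$contig_id[!motif_ok])) {
    reasons_by_contig[[cid]] <- c(reasons_by_contig[[cid]],
                                  sprintf("motif_absent:%s", motif))
  }
  pol_pass <- unique(lf$kept$contig_id[motif_ok])
  # contigs must carry a surviving polymerase to stay in the candidate set
  surviving <- intersect(all_contigs, pol_pass)

  dd <- dedup(contig_seqs[surviving], dedup_identity)
  dup_ids <- dd$id[!dd$representative]
  for (cid in dup_ids) {
    rep_id <- dd$cluster[dd$id == cid]
    reasons_by_contig[[cid]] <- c(reasons_by_contig[[cid]],
                                  sprintf("duplicate_of:%s", rep_id))
  }
  representatives <- dd$id[dd$representative]

  out <- vector("list", length(all_contigs))
  for (i in seq_along(all_contigs)) {
    cid <- all_contigs[i]
    pre_reasons <- reasons_by_contig[[cid]]
    if (cid %in% representatives) {
      ch <- hits[hits$contig_id == cid &
                   hits$family_id %in% hallmark_families, , drop = FALSE]
      # the polymerase filters remove individual failing proteins
      drop_pol <- ch$family_id == polymerase_family &
        (nchar(ch$sequence) < min_len |
           !vapply(ch$sequence,
                   function(s) length(motif_scan(s, motif)) > 0, logical(1)))
      ch <- ch[!drop_pol, , drop = FALSE]
      row <- classify_completeness(ch, hallmark_families, contig_id = cid)
      row$reasons <- list(c(pre_reasons, row$reasons[[1]]))
      out[[i]] <- row
    } else {
      out[[i]] <- tibble::tibble(
        contig_id = cid, n_types = NA_integer_,
        hallmark_counts = list(NULL), label = "rejected",
        reasons = list(if (length(pre_reasons)) pre_reasons else
          "no_surviving_polymerase"))
    }
  }
  dplyr::bind_rows(out)
}
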