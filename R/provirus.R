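# Proviral-region detection in host contigs and CRISPR-spacer host
# prediction.

#' Filter host contigs by length
#'
#' Keeps contigs strictly longer than `min_len` (default 100 kbp; "over
#' 100 kbp", so a contig of exactly `min_len` is removed).
#'
#' @param contigs Named character vector of nucleotide sequences, or a
#'   tibble with `contig_id` and `length` columns.
#' @param min_len Strict lower bound in bp.
#' @return Filtered object of the same shape as the input.
#' @export
host_contig_filter <- function(contigs, min_len = 100000) {
  assert_that(min_len > 0, "min_len must be positive")
  if (is.data.frame(contigs)) {
    contigs[contigs$length > min_len, , drop = FALSE]
  } else {
    contigs[nchar(contigs) > min_len]
  }
}

# All maximal non-overlapping positive-sum segments of a score sequence,
# by repeated extraction of the best remaining segment (prefix sums; ties
# broken toward the smallest start, then the smallest end). Returns
# (start, end, score) with 1-based inclusive indices, sorted by start.
#' @noRd
maximal_segments <- function(scores) {
  n <- length(scores)
  blocked <- rep(FALSE, n)
  rows <- list()
  repeat {
    best <- 0; bi <- 0; bj <- 0
    i <- 1
    while (i <= n) {
      if (blocked[i]) { i <- i + 1; next }
      run_end <- i
      while (run_end < n && !blocked[run_end + 1]) run_end <- run_end + 1
      cs <- cumsum(scores[i:run_end])
      for (jj in seq_along(cs)) {
        base <- if (jj == 1) 0 else min(0, min(cs[seq_len(jj - 1)]))
        # best segment ending at jj starts after the minimal prefix
        s <- cs[jj] - base
        if (s > best) {
          start_rel <- if (base == 0) 1 else
            which.min(cs[seq_len(jj - 1)]) + 1
          best <- s; bi <- i + start_rel - 1; bj <- i + jj - 1
        }
      }
      i <- run_end + 1
    }
    if (best <= 0) break
    rows[[length(rows) + 1]] <- tibble::tibble(start = bi, end = bj,
                                               score = best)
    blocked[bi:bj] <- TRUE
  }
  if (length(rows) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          score = double()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$start)
}

#' Detect integrated proviral regions in a host contig
#'
#' Each gene scores +1 when it hits any viral profile at E <= `max_evalue`
#' and `-host_penalty` otherwise; all maximal non-overlapping positive-sum
#' runs of consecutive genes (Ruzzo-Tompa segmentation) delimit candidate
#' regions. A region's nucleotide extent runs from the outermost
#' viral-scored gene's start to its end, and only regions containing at
#' least one hallmark-profile hit are reported.
#'
#' @param contig Host contig nucleotide sequence (used for bounds checks).
#' @param genes Tibble of genes (`protein_id`, `start`, `end`, `strand`,
#'   `sequence`), sorted by `start`.
#' @param viral_profiles List of calibrated `hallmark_profile` objects;
#'   profiles whose `family_id` is in `hallmark_families` count as hallmark
#'   evidence.
#' @param host_penalty Positive penalty for non-viral genes (default 1).
#' @param max_evalue Per-gene profile hit threshold (default 1e-5).
#' @param hallmark_families Family ids regarded as hallmark; defaults to
#'   the `family_id`s of `viral_profiles`.
#' @param contig_id Identifier for reporting.
#' @return Tibble of regions: `host_contig_id`, `start`, `end` (0-based
#'   half-open bp), `n_genes`, `n_viral_genes`, `n_hallmark_types`,
#'   `score`.
#' @export
detect_proviral_region <- function(contig, genes, viral_profiles,
                                   host_penalty = 1, max_evalue = 1e-5,
                                   hallmark_families = NULL,
                                   contig_id = "host") {
  assert_that(host_penalty > 0, "host_penalty must be positive")
  genes <- tibble::as_tibble(genes)
  empty <- tibble::tibble(host_contig_id = character(), start = integer(),
                          end = integer(), n_genes = integer(),
                          n_viral_genes = integer(),
                          n_hallmark_types = integer(), score = double())
  if (nrow(genes) == 0) return(empty)
  assert_that(!is.unsorted(genes$start), "genes must be sorted by start")
  if (is.null(hallmark_families)) {
    hallmark_families <- vapply(viral_profiles, `[[`, "", "family_id")
  }
  hit_families <- vector("list", nrow(genes))
  for (prof in viral_profiles) {
    h <- search_profile(prof, genes, max_evalue)
    idx <- match(h$protein_id, genes$protein_id)
    for (i in idx) {
      hit_families[[i]] <- c(hit_families[[i]], prof$family_id)
    }
  }
  viral <- vapply(hit_families, function(x) length(x) > 0, logical(1))
  # overlapping ORF calls are not independent loci (e.g. the reverse-strand
  # mirror of a gene): keep every viral-scored gene, then admit non-viral
  # ORFs longest-first only while they do not overlap an already kept call
  # by more than half of their own length
  keep <- viral
  ord <- order(viral, genes$end - genes$start, decreasing = TRUE)
  for (i in ord[!viral[ord]]) {
    kept <- which(keep)
    ov <- if (length(kept)) pmax(0, pmin(genes$end[kept], genes$end[i]) -
                                   pmax(genes$start[kept], genes$start[i]))
    else 0
    keep[i] <- max(ov) <= 0.5 * (genes$end[i] - genes$start[i])
  }
  genes <- genes[keep, , drop = FALSE]
  hit_families <- hit_families[keep]
  viral <- viral[keep]
  scores <- ifelse(viral, 1, -host_penalty)
  segs <- maximal_segments(scores)
  if (nrow(segs) == 0) return(empty)
  rows <- list()
  for (k in seq_len(nrow(segs))) {
    g <- segs$start[k]:segs$end[k]
    gv <- g[viral[g]]
    if (length(gv) == 0) next
    fams <- unique(unlist(hit_families[gv]))
    if (!any(fams %in% hallmark_families)) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      host_contig_id = contig_id,
      start = as.integer(genes$start[min(gv)]),
      end = as.integer(genes$end[max(gv)]),
      n_genes = length(g), n_viral_genes = length(gv),
      n_hallmark_types = sum(hallmark_families %in% fams),
      score = segs$score[k])
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  assert_that(all(out$start >= 0 & out$end <= nchar(contig)),
              "region outside contig bounds")
  out
}

#' Match CRISPR spacers against viral contigs
#'
#' Exact full-length substring matching on both strands (the 100% identity
#' / 100% coverage rule); every occurrence is reported and the spacer's
#' host taxon becomes a host prediction for the matched contig. Spacers
#' containing degenerate bases are skipped with a warning.
#'
#' @param spacers Tibble with `spacer_id`, `host_taxon`, `sequence`.
#' @param viral_contigs Named character vector of viral nucleotide
#'   sequences.
#' @return Tibble of matches: `spacer_id`, `host_taxon`,
#'   `viral_contig_id`, `position` (0-based on the forward strand),
#'   `strand`, `identity`, `coverage`.
#' @export
match_spacers <- function(spacers, viral_contigs) {
  spacers <- tibble::as_tibble(spacers)
  assert_that(all(nchar(spacers$sequence) >= 20),
              "spacers must be >= 20 bp")
  rows <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- toupper(spacers$sequence[i])
    if (grepl("[^ACGT]", sp)) {
      warning("spacer ", spacers$spacer_id[i],
              " contains degenerate bases; skipped")
      next
    }
    rc <- revcomp(sp)
    for (cid in names(viral_contigs)) {
      seq <- viral_contigs[[cid]]
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") sp else rc
        m <- gregexpr(pat, seq, fixed = TRUE)[[1]]
        if (m[1] == -1) next
        for (pos in as.integer(m)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            spacer_id = spacers$spacer_id[i],
            host_taxon = spacers$host_taxon[i],
            viral_contig_id = cid, position = pos - 1L,
            strand = strand, identity = 1, coverage = 1)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(spacer_id = character(), host_taxon = character(),
                          viral_contig_id = character(),
                          position = integer(), strand = character(),
                          identity = double(), coverage = double()))
  }
  dplyr::bind_rows(rows)
}

#' Aggregate spacer matches into per-contig host predictions
#'
#' All matching host taxa are reported per viral contig, ranked by the
#' number of supporting spacer matches.
#'
#' @param matches Tibble from [match_spacers()].
#' @return Tibble: `viral_contig_id`, `host_taxon`, `n_matches`, `rank`.
#' @export
predict_hosts <- function(matches) {
  matches |>
    dplyr::count(.data$viral_contig_id, .data$host_taxon,
                 name = "n_matches") |>
    dplyr::group_by(.data$viral_contig_id) |>
    dplyr::arrange(dplyr::desc(.data$n_matches), .data$host_taxon,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Flag lysogeny markers from functional annotations
#'
#' A genome is flagged lysogenic iff it carries an integrase or transposase
#' annotation. Diversity-generating retroelements (DGR) are recorded as
#' auxiliary evidence; an integrase adjacent to a DGR (consecutive
#' `gene_index`) is reported as an "integrase+DGR island".
#'
#' @param annotations Tibble with `genome_id`, `label` (vocabulary
#'   includes `integrase`, `transposase`, `DGR`) and optionally
#'   `gene_index` for adjacency.
#' @return Tibble per genome: `genome_id`, `lysogenic`, `evidence`,
#'   `dgr_evidence`, `note`.
#' @export
flag_lysogeny <- function(annotations) {
  annotations <- tibble::as_tibble(annotations)
  per_genome <- split(annotations, annotations$genome_id)
  rows <- lapply(names(per_genome), function(g) {
    a <- per_genome[[g]]
    ev <- intersect(c("integrase", "transposase"), a$label)
    dgr <- "DGR" %in% a$label
    note <- NA_character_
    if ("integrase" %in% a$label && dgr && "gene_index" %in% names(a)) {
      gi <- a$gene_index[a$label == "integrase"]
      gd <- a$gene_index[a$label == "DGR"]
      if (any(abs(outer(gi, gd, "-")) == 1)) note <- "integrase+DGR island"
    }
    tibble::tibble(genome_id = g, lysogenic = length(ev) > 0,
                   evidence = paste(ev, collapse = ","),
                   dgr_evidence = dgr, note = note)
  })
  dplyr::bind_rows(rows)
}
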