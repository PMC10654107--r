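# Deterministic six-frame ORF extraction (ATG starts, standard code).

#' Extract open reading frames from a contig
#'
#' Scans all six reading frames for ATG-initiated, stop-terminated ORFs with
#' a translated length of at least `min_len` amino acids (default 50, the
#' gene-calling floor of the pipeline). Coordinates are 0-based half-open on
#' the forward strand and include the stop codon.
#'
#' By default one ORF is reported per (frame, stop-codon) locus — the
#' outermost (longest) ATG — which matches how a gene caller reports loci
#' and keeps copy counting meaningful downstream. Set `longest_only =
#' FALSE` to report every in-frame ATG of every locus.
#'
#' @param contig Nucleotide sequence over `A, C, G, T, N`.
#' @param min_len Minimum translated length in amino acids (stop excluded).
#' @param contig_id Identifier used to mint protein ids.
#' @param longest_only Report only the outermost ATG per locus (default).
#' @return Tibble with `protein_id`, `genome_id`, `start`, `end`, `strand`,
#'   `sequence`, ordered by (start, strand).
#' @export
extract_orfs <- function(contig, min_len = 50, contig_id = "contig",
                         longest_only = TRUE) {
  assert_that(min_len >= 1, "min_len must be >= 1")
  contig <- toupper(contig)
  bad <- gsub("[ACGTN]", "", contig)
  assert_that(nchar(bad) == 0,
              paste0("non-IUPAC characters in contig: ",
                     paste(unique(strsplit(bad, "")[[1]]), collapse = "")))
  L <- nchar(contig)
  code <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")

  scan_strand <- function(seq, strand) {
    rows <- list()
    for (f in 0:2) {
      n_codons <- (nchar(seq) - f) %/% 3
      if (n_codons < 2) next
      codons <- substring(seq, f + 1 + 3 * (seq_len(n_codons) - 1),
                          f + 3 * seq_len(n_codons))
      is_stop <- codons %in% stops
      is_atg <- codons == "ATG"
      stop_idx <- which(is_stop)
      prev_stop <- 0L
      for (j in stop_idx) {
        atgs <- which(is_atg[(prev_stop + 1):(j - 1)]) + prev_stop
        prev_stop <- j
        if (length(atgs) == 0) next
        atgs <- atgs[(j - atgs) >= min_len]  # aa length = j - i
        if (length(atgs) == 0) next
        if (longest_only) atgs <- atgs[1]
        for (i in atgs) {
          aa <- code[codons[i:(j - 1)]]
          aa[is.na(aa)] <- "X"
          rows[[length(rows) + 1]] <- tibble::tibble(
            start_rel = f + (i - 1L) * 3L, end_rel = f + j * 3L,
            strand = strand, sequence = paste(aa, collapse = ""))
        }
      }
    }
    dplyr::bind_rows(rows)
  }

  fwd <- scan_strand(contig, "+")
  rev <- scan_strand(revcomp(contig), "-")
  if (nrow(rev) > 0) {
    tmp <- rev$start_rel
    rev$start_rel <- L - rev$end_rel
    rev$end_rel <- L - tmp
  }
  out <- dplyr::bind_rows(fwd, rev)
  if (nrow(out) == 0) {
    return(tibble::tibble(protein_id = character(), genome_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), sequence = character()))
  }
  out <- dplyr::arrange(out, .data$start_rel, .data$strand)
  tibble::tibble(
    protein_id = sprintf("%s_orf%04d", contig_id, seq_len(nrow(out))),
    genome_id = contig_id,
    start = as.integer(out$start_rel), end = as.integer(out$end_rel),
    strand = out$strand, sequence = out$sequence)
}
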