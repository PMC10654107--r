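# Progressive multiple alignment guided by a k-mer distance tree.
# Stand-in for an external aligner at desk scale; externally computed
# aligned FASTA can be imported with read_alignment().

#' Build a multiple sequence alignment
#'
#' Progressive alignment: a 3-mer-composition guide tree (average-linkage)
#' orders profile-profile merges; each merge is a global affine
#' Needleman-Wunsch between column profiles under BLOSUM62. Deterministic
#' for a fixed input order.
#'
#' @param sequences Named character vector of >= 2 amino-acid sequences.
#' @param gap_open,gap_ext Affine gap penalties (score units).
#' @return A `protein_msa` object: list with `rows` (named character vector
#'   of equal-length aligned strings) and `n_cols`.
#' @export
build_msa <- function(sequences, gap_open = 10, gap_ext = 1) {
  assert_that(length(sequences) >= 2, "need >= 2 sequences to align")
  assert_that(!is.null(names(sequences)) && !anyDuplicated(names(sequences)),
              "sequences must have unique names")
  n <- length(sequences)
  subst <- blosum62()

  kmer_counts <- function(s, k = 3) {
    if (nchar(s) < k) return(stats::setNames(1, s))
    km <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    table(km)
  }
  counts <- lapply(sequences, kmer_counts)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- counts[[i]]; b <- counts[[j]]
    keys <- union(names(a), names(b))
    va <- as.numeric(a[keys]); va[is.na(va)] <- 0
    vb <- as.numeric(b[keys]); vb[is.na(vb)] <- 0
    cs <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
    d[i, j] <- d[j, i] <- 1 - cs
  }
  merge_order <- stats::hclust(stats::as.dist(d), method = "average")$merge

  to_mat <- function(s) matrix(strsplit(s, "", fixed = TRUE)[[1]], nrow = 1)
  col_freq <- function(mat) {
    counts <- vapply(AA_ALPHABET, function(a) colSums(mat == a),
                     numeric(ncol(mat)))
    counts <- matrix(counts, ncol = 20)
    tot <- rowSums(counts)
    tot[tot == 0] <- 1
    counts / tot
  }
  merge_two <- function(ma, mb) {
    fa <- col_freq(ma)
    fb <- col_freq(mb)
    path <- .nw_profile(fa %*% subst %*% t(fb), gap_open, gap_ext)
    L <- length(path$path_a)
    out <- matrix(GAP_CHAR, nrow(ma) + nrow(mb), L)
    ia <- path$path_a > 0
    ib <- path$path_b > 0
    out[seq_len(nrow(ma)), ia] <- ma[, path$path_a[ia], drop = FALSE]
    out[nrow(ma) + seq_len(nrow(mb)), ib] <- mb[, path$path_b[ib],
                                                drop = FALSE]
    rownames(out) <- c(rownames(ma), rownames(mb))
    out
  }

  leaves <- lapply(seq_len(n), function(i) {
    m <- to_mat(sequences[[i]])
    rownames(m) <- names(sequences)[i]
    m
  })
  internal <- vector("list", nrow(merge_order))
  fetch <- function(x) if (x < 0) leaves[[-x]] else internal[[x]]
  for (r in seq_len(nrow(merge_order))) {
    internal[[r]] <- merge_two(fetch(merge_order[r, 1]),
                               fetch(merge_order[r, 2]))
  }
  final <- internal[[nrow(merge_order)]]
  final <- final[names(sequences), , drop = FALSE]
  rows <- apply(final, 1, paste, collapse = "")
  structure(list(rows = rows, n_cols = ncol(final)), class = "protein_msa")
}

#' @noRd
msa_from_rows <- function(rows) {
  assert_that(length(unique(nchar(rows))) == 1,
              "aligned rows must have equal length")
  structure(list(rows = rows, n_cols = nchar(rows[[1]])),
            class = "protein_msa")
}

#' @noRd
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
  rownames(m) <- names(msa$rows)
  m
}

#' Import an externally computed alignment from aligned FASTA
#'
#' @param path Aligned FASTA file (gaps as `-`).
#' @return A `protein_msa` object.
#' @export
read_alignment <- function(path) {
  msa_from_rows(read_fasta(path, "aa"))
}

#' Write an alignment as aligned FASTA
#'
#' @param msa A `protein_msa` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_alignment <- function(msa, path) {
  x <- Biostrings::AAStringSet(msa$rows)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @export
print.protein_msa <- function(x, ...) {
  cat("<protein_msa> ", length(x$rows), " rows x ", x$n_cols, " columns\n",
      sep = "")
  invisible(x)
}
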