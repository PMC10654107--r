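# Shared constants and small helpers used across the pipeline.

#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @useDynLib schitomine, .registration = TRUE
NULL

# 20 standard amino acids, fixed order used by every scoring matrix in the package
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# One fixed codon per amino acid so that planted proteins back-translate to
# exactly one ORF. Leu/Ser use TTA/TCA, whose reverse complements are stop
# codons, so reverse-strand mirror ORFs terminate quickly and spurious gene
# calls stay rare.
AA_CODON <- c(
  A = "GCA", C = "TGC", D = "GAC", E = "GAA", F = "TTC", G = "GGA",
  H = "CAC", I = "ATA", K = "AAA", L = "TTA", M = "ATG", N = "AAC",
  P = "CCA", Q = "CAA", R = "AGA", S = "TCA", T = "ACA", V = "GTA",
  W = "TGG", Y = "TAC"
)
STOP_CODON <- "TAA"

GAP_CHAR <- "-"

#' @noRd
aa_index <- function(chars) match(chars, AA_ALPHABET)

#' BLOSUM62 substitution matrix in package residue order
#' @noRd
blosum62 <- function() {
  m <- get_blosum62_biostrings()
  m[AA_ALPHABET, AA_ALPHABET]
}

# Pull BLOSUM62 from Biostrings' stored data without polluting the namespace.
#' @noRd
get_blosum62_biostrings <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Derive an independent child seed from a master seed
#'
#' Each output class of the generator (and each stage of the pipeline) draws
#' from its own stream so that, e.g., adding decoys does not perturb the
#' reference genomes. Streams are derived deterministically from the master
#' seed and a label via a small string hash, kept below 2^31.
#' @noRd
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647L)
}

#' Run code under a locally derived RNG stream
#' @noRd
with_stream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, label))
  force(code)
}

#' @noRd
random_protein <- function(n, first_m = TRUE) {
  s <- sample(AA_ALPHABET, n, replace = TRUE)
  if (first_m) s[1] <- "M"
  paste(s, collapse = "")
}

#' @noRd
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Substitute a fixed number of positions of a protein, never touching frozen
#' positions, always to a different residue.
#' @noRd
mutate_protein <- function(seq, identity, frozen = integer()) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  mutable <- setdiff(seq_along(chars), frozen)
  n_mut <- floor((1 - identity) * length(mutable))
  if (n_mut > 0) {
    pos <- sample(mutable, n_mut)
    for (p in pos) {
      alt <- setdiff(AA_ALPHABET, chars[p])
      chars[p] <- sample(alt, 1)
    }
  }
  paste(chars, collapse = "")
}

#' Back-translate a protein with the fixed codon table (appends a stop codon)
#' @noRd
protein_to_dna <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste0(paste(AA_CODON[chars], collapse = ""), STOP_CODON)
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @noRd
write_fasta <- function(seqs, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @noRd
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @noRd
write_tsv_plain <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @noRd
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
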