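# Intergenomic similarity, rank clustering, gene-content network, and
# protein-family accumulation curves.

#' Intergenomic similarity of two genomes
#'
#' Runs a seeded local nucleotide alignment (BLASTN: word size 7, reward 2,
#' penalty -3, gap open 5, gap extend 2) between the two genomes, merges
#' overlapping aligned blocks on each genome so repeated regions are
#' counted once, and normalizes the identical base count by the total
#' length of both genomes:
#' `similarity = 100 * (identical_a + identical_b) / (len_a + len_b)`.
#'
#' @param genome_a,genome_b Nucleotide sequences.
#' @param word_size,reward,penalty,gap_open,gap_extend BLASTN parameters.
#' @param id_a,id_b Identifiers for reporting.
#' @return One-row tibble: `genome_a`, `genome_b`, `similarity` (0-100),
#'   `identical_bases_a`, `identical_bases_b`.
#' @export
intergenomic_similarity <- function(genome_a, genome_b,
                                    word_size = 7, reward = 2, penalty = -3,
                                    gap_open = 5, gap_extend = 2,
                                    id_a = "genome_a", id_b = "genome_b") {
  assert_that(nchar(genome_a) > 0 && nchar(genome_b) > 0,
              "genomes must be non-empty")
  assert_that(nzchar(Sys.which("blastn")),
              "the 'blastn' executable is required on PATH")
  td <- tempfile("igs")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qa <- file.path(td, "a.fna"); qb <- file.path(td, "b.fna")
  write_fasta(c(a = genome_a), qa, "dna")
  write_fasta(c(b = genome_b), qb, "dna")
  out <- system2("blastn",
                 c("-query", qa, "-subject", qb,
                   "-word_size", word_size, "-reward", reward,
                   "-penalty", penalty, "-gapopen", gap_open,
                   "-gapextend", gap_extend, "-dust", "no",
                   "-outfmt", shQuote("6 qstart qend sstart send nident bitscore")),
                 stdout = TRUE)
  la <- nchar(genome_a); lb <- nchar(genome_b)
  if (length(out) == 0) {
    return(tibble::tibble(genome_a = id_a, genome_b = id_b, similarity = 0,
                          identical_bases_a = 0, identical_bases_b = 0))
  }
  hsp <- utils::read.table(text = out, col.names = c(
    "qstart", "qend", "sstart", "send", "nident", "bitscore"))
  hsp <- hsp[order(-hsp$bitscore), , drop = FALSE]
  ident_side <- function(starts, ends, nident) {
    covered <- matrix(numeric(0), ncol = 2)  # merged blocks
    total <- 0
    for (k in seq_along(starts)) {
      s <- min(starts[k], ends[k]); e <- max(starts[k], ends[k])
      len <- e - s + 1
      ov <- 0
      if (nrow(covered) > 0) {
        o <- pmax(0, pmin(covered[, 2], e) - pmax(covered[, 1], s) + 1)
        ov <- sum(o)
      }
      frac_new <- max(0, len - ov) / len
      total <- total + nident[k] * frac_new
      covered <- rbind(covered, c(s, e))
      covered <- covered[order(covered[, 1]), , drop = FALSE]
      merged <- covered[1, , drop = FALSE]
      if (nrow(covered) > 1) for (r in 2:nrow(covered)) {
        if (covered[r, 1] <= merged[nrow(merged), 2] + 1) {
          merged[nrow(merged), 2] <- max(merged[nrow(merged), 2],
                                         covered[r, 2])
        } else merged <- rbind(merged, covered[r, ])
      }
      covered <- merged
    }
    total
  }
  ia <- ident_side(hsp$qstart, hsp$qend, hsp$nident)
  ib <- ident_side(hsp$sstart, hsp$send, hsp$nident)
  tibble::tibble(genome_a = id_a, genome_b = id_b,
                 similarity = min(100, 100 * (ia + ib) / (la + lb)),
                 identical_bases_a = ia, identical_bases_b = ib)
}

#' All-pairs intergenomic similarity matrix
#'
#' @param genomes Named character vector of nucleotide sequences.
#' @param ... Passed to [intergenomic_similarity()].
#' @return Symmetric numeric matrix (percent, diagonal 100).
#' @export
similarity_matrix <- function(genomes, ...) {
  ids <- names(genomes)
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- intergenomic_similarity(genomes[[i]], genomes[[j]],
                                 id_a = ids[i], id_b = ids[j], ...)$similarity
    m[i, j] <- m[j, i] <- s
  }
  m
}

#' @noRd
threshold_components <- function(sim, ids, threshold) {
  n <- length(ids)
  comp <- integer(n)
  cur <- 0
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(sim[v, ] >= threshold & comp == 0)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Assign species / genus / subfamily ranks from a similarity matrix
#'
#' Single-linkage connected components at the three thresholds (defaults
#' 95 / 70 / 20 percent). Nesting is enforced by construction: genus
#' components are computed within each subfamily component, and species
#' components within each genus component. Cluster ids are the rank prefix
#' plus the lexicographically smallest member.
#'
#' @param similarities Symmetric percent matrix with dimnames, diagonal
#'   100 (asymmetries beyond 1e-9 are an error).
#' @param species_t,genus_t,subfamily_t Thresholds in percent.
#' @return Tibble: `genome_id`, `species_cluster`, `genus_cluster`,
#'   `subfamily_cluster`.
#' @export
cluster_ranks <- function(similarities, species_t = 95, genus_t = 70,
                          subfamily_t = 20) {
  sim <- as.matrix(similarities)
  assert_that(!is.null(rownames(sim)), "similarity matrix needs dimnames")
  assert_that(max(abs(sim - t(sim))) <= 1e-9,
              "similarity matrix is asymmetric beyond 1e-9")
  ids <- rownames(sim)
  label_of <- function(prefix, members) paste0(prefix, "_", min(members))
  assign_rank <- function(parent_groups, threshold, prefix) {
    out <- stats::setNames(character(length(ids)), ids)
    for (grp in parent_groups) {
      idx <- match(grp, ids)
      comp <- threshold_components(sim[idx, idx, drop = FALSE], grp,
                                   threshold)
      for (cc in unique(comp)) {
        members <- grp[comp == cc]
        out[members] <- label_of(prefix, members)
      }
    }
    out
  }
  subf <- assign_rank(list(ids), subfamily_t, "subfamily")
  genus <- assign_rank(split(ids, subf), genus_t, "genus")
  species <- assign_rank(split(ids, genus), species_t, "species")
  tibble::tibble(genome_id = ids,
                 species_cluster = unname(species[ids]),
                 genus_cluster = unname(genus[ids]),
                 subfamily_cluster = unname(subf[ids]))
}

#' Gene-content network with hypergeometric edge weights
#'
#' Edge weight between two genomes is `-log10 P[X >= k]` where `X` is
#' hypergeometric over a family universe of `universe_size`, the genomes
#' carry `|A|` and `|B|` families, and they share `k`. Edges below
#' `weight_cutoff` are dropped and the remaining graph is clustered with
#' [mcl_cluster()].
#'
#' @param pf_presence Named list: genome id -> character vector of family
#'   ids.
#' @param universe_size Total number of families in the universe.
#' @param weight_cutoff Minimum retained edge weight (default 1,
#'   i.e. P <= 0.1).
#' @param inflation MCL inflation (default 2).
#' @return A `content_network` object: list with `edges` tibble (`from`,
#'   `to`, `shared`, `weight`), `clusters` (list of genome id vectors) and
#'   `nodes`.
#' @export
content_network <- function(pf_presence, universe_size, weight_cutoff = 1,
                            inflation = 2) {
  sizes <- vapply(pf_presence, length, 1L)
  assert_that(universe_size >= max(c(0, sizes)),
              "universe_size smaller than a genome's family count")
  ids <- names(pf_presence)
  rows <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      A <- pf_presence[[i]]; B <- pf_presence[[j]]
      k <- length(intersect(A, B))
      w <- content_edge_weight(universe_size, length(A), length(B), k)
      if (w >= weight_cutoff) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          from = ids[i], to = ids[j], shared = k, weight = w)
      }
    }
  }
  edges <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(from = character(), to = character(),
                   shared = integer(), weight = double())
  clusters <- if (nrow(edges) > 0) {
    cl <- mcl_cluster(edges, inflation)
    isolated <- setdiff(ids, unlist(cl))
    c(cl, as.list(isolated))
  } else as.list(ids)
  structure(list(edges = edges, clusters = clusters, nodes = ids,
                 universe_size = universe_size),
            class = "content_network")
}

#' Hypergeometric tail weight for a shared-gene-content edge
#'
#' @param universe_size,size_a,size_b,shared Set sizes.
#' @return `-log10 P[X >= shared]`.
#' @export
content_edge_weight <- function(universe_size, size_a, size_b, shared) {
  if (shared == 0) return(0)
  p <- stats::phyper(shared - 1, size_a, universe_size - size_a, size_b,
                     lower.tail = FALSE)
  -log10(p)
}

#' @export
print.content_network <- function(x, ...) {
  cat("<content_network> ", length(x$nodes), " genomes, ",
      nrow(x$edges), " edges, ", length(x$clusters), " clusters\n", sep = "")
  invisible(x)
}

#' Protein-family accumulation curve
#'
#' For every sample size k, genomes are resampled without replacement
#' `n_resamples` times (default 300) and the number of distinct families
#' recorded; the median and quartiles are reported per k.
#'
#' @param pf_presence Named list: genome id -> character vector of family
#'   ids.
#' @param n_resamples Resamples per point (default 300).
#' @param seed Seed.
#' @return Tibble of class `pf_accumulation`: `k`, `median_families`,
#'   `q25`, `q75`.
#' @export
accumulation_curve <- function(pf_presence, n_resamples = 300, seed = 1) {
  assert_that(n_resamples >= 1, "n_resamples must be >= 1")
  ids <- names(pf_presence)
  n <- length(ids)
  with_stream(seed, "accumulation", {
    rows <- lapply(seq_len(n), function(k) {
      counts <- vapply(seq_len(n_resamples), function(r) {
        pick <- sample(ids, k)
        length(unique(unlist(pf_presence[pick], use.names = FALSE)))
      }, 1L)
      tibble::tibble(k = k,
                     median_families = stats::median(counts),
                     q25 = unname(stats::quantile(counts, 0.25)),
                     q75 = unname(stats::quantile(counts, 0.75)))
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("pf_accumulation", class(out))
    out
  })
}

#' Write a similarity matrix as TSV
#' @param sim Matrix from [similarity_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  df <- tibble::as_tibble(sim, rownames = "genome_id")
  write_tsv_plain(df, path)
}
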