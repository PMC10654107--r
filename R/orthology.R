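# Orthologous protein families from a reference genome collection:
# all-vs-all local search, reciprocal-best-hit pairs, Markov clustering,
# and core / single-copy / hallmark classification.

#' All-vs-all protein similarity search
#'
#' Seeded local alignment of every protein pair (BLOSUM62, gap open 11 /
#' extend 1): pairs sharing at least one 5-mer are aligned by
#' Smith-Waterman; E-values come from a Gumbel law fitted on shuffled-decoy
#' alignments of the same database. Returned hits satisfy
#' `evalue <= max_evalue` and `query_cover >= min_query_cover` (both
#' directions of a pair are reported, plus self-hits).
#'
#' @param proteins Tibble with `protein_id`, `genome_id`, `sequence`.
#' @param max_evalue E-value threshold (default 1e-10).
#' @param min_query_cover Minimum fraction of the query covered by the
#'   alignment (default 0.5).
#' @param n_decoys Shuffled-decoy alignments used for calibration
#'   (default 1000).
#' @param seed Seed for decoy sampling.
#' @param seed_kmer Length of the exact seed word a pair must share before
#'   alignment is attempted (default 5); set to 0 to align all pairs.
#' @return Tibble of hits: `query_id`, `subject_id`, `query_genome`,
#'   `subject_genome`, `bitscore`, `evalue`, `query_cover`, `identity`.
#' @export
all_vs_all_search <- function(proteins, max_evalue = 1e-10,
                              min_query_cover = 0.5, n_decoys = 1000,
                              seed = 1, seed_kmer = 5) {
  proteins <- tibble::as_tibble(proteins)
  assert_that(nrow(proteins) >= 2, "need at least two proteins")
  assert_that(max_evalue > 0 && min_query_cover > 0,
              "thresholds must be positive")
  assert_that(all(nchar(proteins$sequence) > 0), "empty sequence in input")
  n <- nrow(proteins)
  subst <- get_blosum62_biostrings()
  lens <- nchar(proteins$sequence)
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$protein_id

  # Gumbel calibration on shuffled decoys: score ~ (1/lambda) log(m n) with
  # Gumbel noise; lambda from the residual spread, location from the fit.
  calib <- with_stream(seed, "avas_calibration", {
    cap <- 400L
    qi <- sample(n, n_decoys, replace = TRUE)
    si <- sample(n, n_decoys, replace = TRUE)
    sc <- numeric(n_decoys); mn <- numeric(n_decoys)
    for (k in seq_len(n_decoys)) {
      q <- substr(proteins$sequence[qi[k]], 1, cap)
      s <- substr(proteins$sequence[si[k]], 1, cap)
      s <- paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
        substitutionMatrix = subst, gapOpening = 11, gapExtension = 1)
      sc[k] <- Biostrings::score(al)
      mn[k] <- nchar(q) * nchar(s)
    }
    fit <- stats::lm(sc ~ log(mn))
    lambda <- pi / (stats::sd(stats::residuals(fit)) * sqrt(6))
    list(lambda = lambda, coef = stats::coef(fit))
  })
  evalue_of <- function(score, m, s_len) {
    mu <- unname(calib$coef[1] + calib$coef[2] * log(m * s_len)) -
      0.5772156649 / calib$lambda
    x <- exp(-calib$lambda * (score - mu))
    n * (1 - exp(-x))
  }

  has_seed <- if (seed_kmer > 0) {
    kmers <- lapply(proteins$sequence, function(s) {
      if (nchar(s) < seed_kmer) return(s)
      unique(substring(s, 1:(nchar(s) - seed_kmer + 1),
                       seed_kmer:nchar(s)))
    })
    function(i, j) length(intersect(kmers[[i]], kmers[[j]])) > 0
  } else function(i, j) TRUE

  rows <- list()
  self_score <- vapply(proteins$sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(diag(subst[chars, chars, drop = FALSE]))
  }, 0)
  for (i in seq_len(n)) {
    ev <- evalue_of(self_score[i], lens[i], lens[i])
    rows[[length(rows) + 1]] <- tibble::tibble(
      query_id = proteins$protein_id[i], subject_id = proteins$protein_id[i],
      query_genome = proteins$genome_id[i],
      subject_genome = proteins$genome_id[i],
      bitscore = calib$lambda * self_score[i] / log(2),
      evalue = ev, query_cover = 1, identity = 1)
  }
  for (i in seq_len(n - 1)) {
    js <- which(vapply((i + 1):n, function(j) has_seed(i, j), logical(1))) + i
    for (j in js) {
      al <- Biostrings::pairwiseAlignment(
        aa[[i]], aa[[j]], type = "local",
        substitutionMatrix = subst, gapOpening = 11, gapExtension = 1)
      s <- Biostrings::score(al)
      ev <- evalue_of(s, lens[i], lens[j])
      if (ev > max_evalue) next
      qa <- Biostrings::width(Biostrings::pattern(al))
      sa <- Biostrings::width(Biostrings::subject(al))
      ident <- Biostrings::nmatch(al) / Biostrings::nchar(al)
      bits <- calib$lambda * s / log(2)
      cov_q <- qa / lens[i]
      cov_s <- sa / lens[j]
      if (cov_q >= min_query_cover) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          query_id = proteins$protein_id[i],
          subject_id = proteins$protein_id[j],
          query_genome = proteins$genome_id[i],
          subject_genome = proteins$genome_id[j],
          bitscore = bits, evalue = ev, query_cover = cov_q,
          identity = ident)
      }
      if (cov_s >= min_query_cover) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          query_id = proteins$protein_id[j],
          subject_id = proteins$protein_id[i],
          query_genome = proteins$genome_id[j],
          subject_genome = proteins$genome_id[i],
          bitscore = bits, evalue = ev, query_cover = cov_s,
          identity = ident)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Reciprocal-best-hit orthologous pairs
#'
#' `(a, b)` is reported iff the proteins come from different genomes, `b`
#' is `a`'s best-scoring hit in `b`'s genome and vice versa. Best-hit ties
#' are broken by higher bitscore then lexicographic subject id. Each pair
#' is reported once with `protein_a < protein_b`.
#'
#' @param hits Tibble as returned by [all_vs_all_search()].
#' @return Tibble: `protein_a`, `protein_b`, `genome_a`, `genome_b`,
#'   `bitscore`.
#' @export
rbb_pairs <- function(hits) {
  hits <- tibble::as_tibble(hits)
  empty <- tibble::tibble(protein_a = character(), protein_b = character(),
                          genome_a = character(), genome_b = character(),
                          bitscore = double())
  if (nrow(hits) == 0) return(empty)
  h <- hits[hits$query_id != hits$subject_id &
              hits$query_genome != hits$subject_genome, , drop = FALSE]
  if (nrow(h) == 0) return(empty)
  best <- h |>
    dplyr::group_by(.data$query_id, .data$subject_genome) |>
    dplyr::arrange(dplyr::desc(.data$bitscore), .data$subject_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  key <- paste(best$query_id, best$subject_id, sep = "\r")
  rev_key <- paste(best$subject_id, best$query_id, sep = "\r")
  mutual <- best[key %in% rev_key & best$query_id < best$subject_id, ,
                 drop = FALSE]
  tibble::tibble(protein_a = mutual$query_id, protein_b = mutual$subject_id,
                 genome_a = mutual$query_genome,
                 genome_b = mutual$subject_genome,
                 bitscore = mutual$bitscore)
}

#' Markov clustering of a weighted undirected graph
#'
#' Deterministic MCL: the column-normalized adjacency matrix (with
#' self-loops equal to each node's maximum incident weight, 1 for isolated
#' nodes) is alternately squared (expansion) and raised elementwise to
#' `inflation` with column renormalization, until the matrix changes by
#' less than 1e-6 (sup norm) or 200 iterations. Clusters are read off the
#' attractor rows; overlapping attractor sets are merged; isolated nodes
#' come back as singletons.
#'
#' @param graph Either a symmetric non-negative weight matrix with
#'   dimnames, or an edge tibble with columns `from`, `to`, `weight`.
#' @param inflation Inflation exponent (> 1; default 2).
#' @return List of character vectors (clusters), each sorted, ordered by
#'   first member.
#' @export
mcl_cluster <- function(graph, inflation = 2) {
  assert_that(inflation > 1, "inflation must be > 1")
  if (is.data.frame(graph)) {
    nodes <- sort(union(graph$from, graph$to))
    W <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (k in seq_len(nrow(graph))) {
      W[graph$from[k], graph$to[k]] <- graph$weight[k]
      W[graph$to[k], graph$from[k]] <- graph$weight[k]
    }
  } else {
    W <- as.matrix(graph)
    assert_that(!is.null(rownames(W)), "matrix graph needs dimnames")
    nodes <- rownames(W)
  }
  assert_that(all(is.finite(W)), "non-finite weight in graph")
  assert_that(all(W >= 0), "negative weight in graph")
  n <- nrow(W)
  if (n == 0) return(list())
  loops <- pmax(apply(W, 2, max), 1)
  M <- W + diag(loops, n)
  M <- sweep(M, 2, colSums(M), "/")
  for (it in seq_len(200)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < 1e-6) break
  }
  attractors <- which(diag(M) > 1e-6)
  clusters <- lapply(attractors, function(i) nodes[M[i, ] > 1e-6])
  # merge overlapping attractor systems
  merged <- list()
  for (cl in clusters) {
    hit <- which(vapply(merged, function(m) length(intersect(m, cl)) > 0,
                        logical(1)))
    if (length(hit) == 0) {
      merged[[length(merged) + 1]] <- cl
    } else {
      keep <- setdiff(seq_along(merged), hit)
      merged <- c(merged[keep],
                  list(Reduce(union, c(merged[hit], list(cl)))))
    }
  }
  assigned <- unlist(merged)
  for (nd in setdiff(nodes, assigned)) merged[[length(merged) + 1]] <- nd
  merged <- lapply(merged, sort)
  merged[order(vapply(merged, `[`, "", 1))]
}

#' Derive protein families from a protein set
#'
#' Convenience pipeline: all-vs-all search, reciprocal-best-hit pairs, MCL
#' on the RBB graph (bitscore weights), with unclustered proteins returned
#' as singletons.
#'
#' @inheritParams all_vs_all_search
#' @param inflation MCL inflation (default 2).
#' @return Membership tibble: `family_id`, `protein_id`, `genome_id`.
#' @export
cluster_families <- function(proteins, max_evalue = 1e-10,
                             min_query_cover = 0.5, inflation = 2,
                             n_decoys = 1000, seed = 1) {
  proteins <- tibble::as_tibble(proteins)
  hits <- all_vs_all_search(proteins, max_evalue, min_query_cover,
                            n_decoys = n_decoys, seed = seed)
  pairs <- rbb_pairs(hits)
  clusters <- if (nrow(pairs) > 0) {
    mcl_cluster(tibble::tibble(from = pairs$protein_a, to = pairs$protein_b,
                               weight = pairs$bitscore), inflation)
  } else list()
  clustered <- unlist(clusters)
  for (p in setdiff(proteins$protein_id, clustered)) {
    clusters[[length(clusters) + 1]] <- p
  }
  clusters <- clusters[order(-vapply(clusters, length, 1L),
                             vapply(clusters, `[`, "", 1))]
  rows <- lapply(seq_along(clusters), function(k) {
    tibble::tibble(family_id = sprintf("PF%05d", k),
                   protein_id = clusters[[k]])
  })
  out <- dplyr::bind_rows(rows)
  out$genome_id <- proteins$genome_id[match(out$protein_id,
                                            proteins$protein_id)]
  out
}

#' Flag core, single-copy and hallmark families
#'
#' A family is core when present in at least `ceil(core_fraction *
#' n_genomes)` genomes (the "nearly 95%" rule), single-copy when no genome
#' carries more than one member, and hallmark when present in every genome
#' and single-copy.
#'
#' @param membership Tibble with `family_id`, `protein_id`, `genome_id`.
#' @param n_genomes Number of genomes in the universe.
#' @param core_fraction Core presence fraction (default 0.95).
#' @return Tibble per family: `family_id`, `n_members`,
#'   `n_genomes_present`, `max_copies`, `is_core`, `is_single_copy`,
#'   `is_hallmark`.
#' @export
classify_families <- function(membership, n_genomes, core_fraction = 0.95) {
  assert_that(core_fraction > 0 && core_fraction <= 1,
              "core_fraction must be in (0, 1]")
  membership <- tibble::as_tibble(membership)
  per <- membership |>
    dplyr::count(.data$family_id, .data$genome_id, name = "copies") |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(n_members = sum(.data$copies),
                     n_genomes_present = dplyr::n(),
                     max_copies = max(.data$copies))
  core_min <- ceiling(core_fraction * n_genomes)
  per |>
    dplyr::mutate(
      is_core = .data$n_genomes_present >= core_min,
      is_single_copy = .data$max_copies <= 1,
      is_hallmark = .data$n_genomes_present == n_genomes &
        .data$is_single_copy)
}

#' Write a family membership + flags table as TSV
#'
#' @param membership Membership tibble ([cluster_families()]).
#' @param flags Family flag tibble ([classify_families()]).
#' @param path Output TSV.
#' @return The path, invisibly.
#' @export
write_families_tsv <- function(membership, flags, path) {
  out <- dplyr::left_join(membership, flags, by = "family_id")
  write_tsv_plain(out, path)
}
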