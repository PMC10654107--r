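# Shared fixtures and independent oracles used across the suite.

# A small community for fast unit tests (the polymerase stays above the
# 2,600-aa structural floor; everything else is scaled down).
tiny_config <- function(seed = 11) {
  community_config(
    n_reference_genomes = 5,
    hallmark_lengths = c(vDNAP = 220, MCP = 160, portal = 200, tail = 240,
                         TerL = 180, TerS = 120, vRNAP = 2600),
    n_accessory_families = 6,
    n_metagenome_contigs = 4,
    completeness_mix = c(1, 0, 1, 0, 0, 0, 2),
    n_decoys = 1,
    n_chimeras = 1,
    n_host_contigs = 1,
    host_contig_length = 102000,
    provirus_length = 30000,
    n_spacers_per_host = 3,
    amg_plant_rates = c("Nucleotide metabolism" = 2,
                        "Carbohydrate metabolism" = 1.5),
    seed = seed
  )
}

tiny_community <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_community(tiny_config())
    cache
  }
})

random_aa_seq <- function(n, seed) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
             "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
    collapse = ""))
}

random_dna_seq <- function(n, seed) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# Independent six-frame ORF oracle: naive scan over every frame of both
# strands, reporting every ATG..stop with aa length >= min_len.
orf_oracle <- function(contig, min_len) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig)))
  L <- nchar(contig)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else rc
    for (f in 0:2) {
      nc <- (nchar(s) - f) %/% 3
      if (nc < 2) next
      codons <- substring(s, f + 1 + 3 * (0:(nc - 1)), f + 3 * (1:nc))
      for (i in seq_len(nc)) {
        if (codons[i] != "ATG") next
        j <- i + 1
        while (j <= nc && !codons[j] %in% c("TAA", "TAG", "TGA")) j <- j + 1
        if (j > nc) next  # not stop-terminated
        if (j - i < min_len) next
        start <- f + (i - 1) * 3
        end <- f + j * 3
        if (strand == "-") {
          tmp <- start
          start <- L - end
          end <- L - tmp
        }
        aa <- paste(Biostrings::GENETIC_CODE[codons[i:(j - 1)]],
                    collapse = "")
        out[[length(out) + 1]] <- tibble::tibble(
          start = start, end = end, strand = strand, sequence = aa)
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), start, strand)
}

# Independent MCL implementation: straightforward loop-based matrix
# iteration following the documented algorithm (self-loops = max incident
# weight with floor 1, column normalization, expansion by squaring,
# elementwise inflation).
mcl_oracle <- function(W, inflation = 2) {
  n <- nrow(W)
  nodes <- rownames(W)
  M <- W
  for (i in 1:n) M[i, i] <- M[i, i] + max(max(W[, i]), 1)
  for (j in 1:n) M[, j] <- M[, j] / sum(M[, j])
  for (it in 1:200) {
    M2 <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) M2[i, j] <- sum(M[i, ] * M[, j])
    M2 <- M2^inflation
    for (j in 1:n) M2[, j] <- M2[, j] / sum(M2[, j])
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < 1e-6) break
  }
  clusters <- list()
  for (i in which(diag(M) > 1e-6)) {
    cl <- nodes[M[i, ] > 1e-6]
    placed <- FALSE
    for (k in seq_along(clusters)) {
      if (length(intersect(clusters[[k]], cl)) > 0) {
        clusters[[k]] <- union(clusters[[k]], cl)
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1]] <- cl
  }
  for (nd in setdiff(nodes, unlist(clusters))) {
    clusters[[length(clusters) + 1]] <- nd
  }
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, `[`, "", 1))]
}

# Independent global-alignment identity for the dedup oracle (same scoring
# as the implementation but via Biostrings directly).
identity_oracle <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(al) / Biostrings::nchar(al)
}

# Brute-force evaluation of the greedy dedup rule.
dedup_oracle <- function(sequences, threshold) {
  ids <- names(sequences)
  ord <- order(-nchar(sequences), ids)
  cluster_of <- stats::setNames(character(length(ids)), ids)
  reps <- character(0)
  for (i in ord) {
    id <- ids[i]
    hit <- NA_character_
    for (r in reps) {
      if (identity_oracle(sequences[[id]], sequences[[r]]) >= threshold) {
        hit <- r
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, id)
      cluster_of[id] <- id
    } else {
      cluster_of[id] <- hit
    }
  }
  cluster_of
}

# All 15 binary unrooted topologies on 5 labeled leaves.
five_leaf_topologies <- function() {
  leaves <- c("a", "b", "c", "d", "e")
  out <- list()
  # choose the cherry pair {x,y} and the second cherry {u,v} from the rest
  for (pair in utils::combn(5, 2, simplify = FALSE)) {
    rest <- setdiff(1:5, pair)
    for (pair2 in utils::combn(rest, 2, simplify = FALSE)) {
      mid <- setdiff(rest, pair2)
      nwk <- sprintf("((%s,%s),(%s,%s),%s);",
                     leaves[pair[1]], leaves[pair[2]],
                     leaves[pair2[1]], leaves[pair2[2]], leaves[mid])
      key <- paste(sort(c(paste(sort(leaves[pair]), collapse = ""),
                          paste(sort(leaves[pair2]), collapse = ""))),
                   collapse = "|")
      out[[key]] <- nwk
    }
  }
  lapply(out, function(t) ape::read.tree(text = t))
}

# Brute-force bipartition set of a tree (independent of tree_splits):
# enumerate all leaf subsets and keep those that are "convex" on the tree,
# i.e. splits induced by removing one internal edge, found via ape's
# edge-by-edge tip descent.
split_oracle <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  tips <- sort(tree$tip.label)
  internal_edges <- which(tree$edge[, 2] > n)
  out <- character(0)
  for (e in internal_edges) {
    node <- tree$edge[e, 2]
    desc <- ape::extract.clade(tree, node)$tip.label
    if (length(desc) < 2 || length(desc) > n - 2) next
    side <- if (tips[1] %in% desc) setdiff(tips, desc) else desc
    if (length(side) < 2) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

srfv_oracle <- function(ta, tb) {
  sa <- split_oracle(ta)
  sb <- split_oracle(tb)
  rf <- length(setdiff(sa, sb)) + length(setdiff(sb, sa))
  list(rf = rf, srfv = if (length(sa) + length(sb) == 0) 0 else
    rf / (length(sa) + length(sb)))
}

# Mutual information between two columns of a character matrix (oracle for
# the DCA argmax check).
mi_oracle <- function(x, y) {
  tab <- table(x, y) / length(x)
  px <- rowSums(tab); py <- colSums(tab)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
  }
  mi
}
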