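# All-vs-all search, reciprocal best hits, Markov clustering, family flags.

make_proteins <- function(seqs, genomes) {
  tibble::tibble(protein_id = names(seqs), genome_id = genomes,
                 sequence = unname(seqs))
}

test_that("identical proteins produce mutual full-identity hits and random ones none", {
  s <- random_aa_seq(300, 5)
  prot <- make_proteins(c(p1 = s, p2 = s,
                          r1 = random_aa_seq(100, 6),
                          r2 = random_aa_seq(100, 7)),
                        c("g1", "g2", "g3", "g4"))
  hits <- all_vs_all_search(prot, n_decoys = 300, seed = 2)
  pair <- hits[hits$query_id == "p1" & hits$subject_id == "p2", ]
  expect_equal(nrow(pair), 1)
  expect_equal(pair$identity, 1)
  expect_equal(pair$query_cover, 1)
  expect_lte(pair$evalue, 1e-10)
  # both directions present
  expect_equal(nrow(hits[hits$query_id == "p2" &
                           hits$subject_id == "p1", ]), 1)
  # unrelated random pair: no non-self hit at the mining threshold
  expect_equal(nrow(hits[hits$query_id == "r1" &
                           hits$subject_id == "r2", ]), 0)
  # self-hits are reported
  expect_true(all(prot$protein_id %in%
                    hits$query_id[hits$query_id == hits$subject_id]))
})

test_that("empty sequences are rejected", {
  prot <- make_proteins(c(a = "", b = "MKL"), c("g1", "g2"))
  expect_error(all_vs_all_search(prot), "empty sequence")
})

test_that("reciprocal-best-hit pairs match the exhaustive predicate", {
  toy <- tibble::tibble(
    query_id =      c("a", "b", "a", "c", "b", "c"),
    subject_id =    c("b", "a", "c", "a", "c", "b"),
    query_genome =  c("g1", "g2", "g1", "g3", "g2", "g3"),
    subject_genome = c("g2", "g1", "g3", "g1", "g3", "g2"),
    bitscore = c(100, 100, 80, 80, 60, 60),
    evalue = 1e-30, query_cover = 1, identity = 0.9)
  pairs <- rbb_pairs(toy)
  expect_setequal(paste(pairs$protein_a, pairs$protein_b),
                  c("a b", "a c", "b c"))

  # a's best is b but b's best is c -> no (a, b) pair
  asym <- tibble::tibble(
    query_id = c("a", "b", "b", "c"),
    subject_id = c("b", "c", "a", "b"),
    query_genome = c("g1", "g2", "g2", "g2b"),
    subject_genome = c("g2", "g2b", "g1", "g2"),
    bitscore = c(50, 90, 40, 90), evalue = 1e-20, query_cover = 1,
    identity = 0.8)
  # force b's best in g1 to exist but a not b's best overall in its genome
  expect_equal(nrow(rbb_pairs(asym[asym$query_id != "b" |
                                     asym$subject_id != "a", ])), 1)

  # randomized table vs brute-force evaluation of the predicate
  withr::with_seed(42, {
    for (rep in 1:5) {
      genomes <- paste0("g", 1:4)
      prot <- tibble::tibble(protein_id = paste0("p", 1:12),
                             genome_id = rep(genomes, each = 3))
      idx <- t(utils::combn(12, 2))
      hits <- dplyr::bind_rows(lapply(seq_len(nrow(idx)), function(r) {
        i <- idx[r, 1]; j <- idx[r, 2]
        if (prot$genome_id[i] == prot$genome_id[j]) return(NULL)
        if (stats::runif(1) < 0.4) return(NULL)
        bs <- round(stats::runif(1, 30, 200), 1)
        tibble::tibble(
          query_id = prot$protein_id[c(i, j)],
          subject_id = prot$protein_id[c(j, i)],
          query_genome = prot$genome_id[c(i, j)],
          subject_genome = prot$genome_id[c(j, i)],
          bitscore = bs, evalue = 1e-15, query_cover = 1, identity = 0.7)
      }))
      got <- rbb_pairs(hits)
      # oracle: direct predicate evaluation
      best_of <- function(q, g) {
        h <- hits[hits$query_id == q & hits$subject_genome == g, ]
        if (nrow(h) == 0) return(NA_character_)
        h <- h[order(-h$bitscore, h$subject_id), ]
        h$subject_id[1]
      }
      want <- character(0)
      for (r in seq_len(nrow(hits))) {
        a <- hits$query_id[r]; b <- hits$subject_id[r]
        if (a >= b) next
        ga <- hits$query_genome[r]; gb <- hits$subject_genome[r]
        if (identical(best_of(a, gb), b) && identical(best_of(b, ga), a)) {
          want <- c(want, paste(a, b))
        }
      }
      expect_setequal(paste(got$protein_a, got$protein_b), unique(want))
    }
  })
})

test_that("two disconnected triangles give exactly two MCL clusters", {
  edges <- tibble::tibble(
    from = c("a", "b", "c", "x", "y", "z"),
    to = c("b", "c", "a", "y", "z", "x"),
    weight = 1)
  cl <- mcl_cluster(edges, inflation = 2)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, paste, "", collapse = ""), c("abc", "xyz"))
})

test_that("MCL equals connected components on block-diagonal graphs", {
  withr::with_seed(9, {
    blocks <- list(paste0("a", 1:3), paste0("b", 1:4), paste0("c", 1:2))
    nodes <- unlist(blocks)
    W <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (blk in blocks) {
      for (i in blk) for (j in blk) if (i != j) W[i, j] <- 1
    }
    cl <- mcl_cluster(W, 2)
    expect_length(cl, 3)
    expect_setequal(lapply(cl, sort), lapply(blocks, sort))
  })
})

test_that("MCL rejects non-finite weights and unit inflation", {
  W <- matrix(c(0, Inf, Inf, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  expect_error(mcl_cluster(W), "non-finite")
  expect_error(mcl_cluster(matrix(0, 1, 1, dimnames = list("a", "a")),
                           inflation = 1), "inflation")
})

test_that("MCL partition matches an independent matrix-iteration run on random graphs", {
  withr::with_seed(2024, {
    for (rep in 1:8) {
      n <- 8
      nodes <- paste0("n", 1:n)
      W <- matrix(0, n, n, dimnames = list(nodes, nodes))
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (stats::runif(1) < 0.35) {
          w <- round(stats::runif(1, 0.5, 2), 2)
          W[i, j] <- W[j, i] <- w
        }
      }
      got <- mcl_cluster(W, 2)
      want <- mcl_oracle(W, 2)
      expect_identical(got, want, info = paste("graph", rep))
    }
  })
})

test_that("family flags implement the core / single-copy / hallmark rules", {
  mk <- function(fam, genome, n = 1) {
    tibble::tibble(family_id = fam,
                   protein_id = paste0(fam, "_", genome, "_", seq_len(n)),
                   genome_id = genome)
  }
  # present in 95 of 100 genomes -> core at the 95% rule
  m95 <- dplyr::bind_rows(lapply(sprintf("g%03d", 1:95), function(g)
    mk("F1", g)))
  f <- classify_families(m95, n_genomes = 100, core_fraction = 0.95)
  expect_true(f$is_core)
  expect_false(f$is_hallmark)
  # 94 genomes -> not core
  f94 <- classify_families(m95[m95$genome_id != "g095", ], 100, 0.95)
  expect_false(f94$is_core)
  # in all genomes but duplicated in one -> core, not hallmark
  mdup <- dplyr::bind_rows(mk("F2", "g1", 2),
                           lapply(paste0("g", 2:10), function(g) mk("F2", g)))
  fdup <- classify_families(mdup, 10)
  expect_true(fdup$is_core)
  expect_false(fdup$is_single_copy)
  expect_false(fdup$is_hallmark)
  # single copy in every genome -> hallmark
  mall <- dplyr::bind_rows(lapply(paste0("g", 1:10), function(g)
    mk("F3", g)))
  expect_true(classify_families(mall, 10)$is_hallmark)
  expect_error(classify_families(mall, 10, core_fraction = 0), "core_fraction")
})

test_that("clustering the tiny community recovers the planted hallmark families exactly", {
  com <- tiny_community()
  prot <- com$reference_proteins
  mem <- cluster_families(prot, n_decoys = 300, seed = 4)
  # partition property: every protein in exactly one family
  expect_setequal(mem$protein_id, prot$protein_id)
  expect_identical(anyDuplicated(mem$protein_id), 0L)
  flags <- classify_families(mem, com$config$n_reference_genomes)
  hall <- flags$family_id[flags$is_hallmark]
  expect_length(hall, com$config$n_hallmark_families)
  # recall and precision 1.0 versus the generator truth
  truth_fam <- prot$family_id[match(mem$protein_id, prot$protein_id)]
  for (h in hall) {
    planted <- unique(truth_fam[mem$family_id == h])
    expect_length(planted, 1)
    expect_true(planted %in% names(com$config$hallmark_lengths))
    # the detected family contains all planted members of that family
    expect_setequal(mem$protein_id[mem$family_id == h],
                    prot$protein_id[prot$family_id == planted])
  }
})
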