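# Intergenomic similarity, rank clustering, content network, accumulation.

test_that("intergenomic similarity has the stated closed forms", {
  withr::with_seed(7, {
    g <- random_dna_seq(10000, 71)
    # identical genomes
    same <- intergenomic_similarity(g, g)
    expect_equal(same$similarity, 100, tolerance = 0.01)
    # no shared 7-mer on either strand
    none <- intergenomic_similarity(strrep("A", 2000), strrep("C", 2000))
    expect_equal(none$similarity, 0)
    # B = exact copy of A's first half: 100*(10k+10k)/(20k+10k) = 66.67
    a <- random_dna_seq(20000, 72)
    b <- substr(a, 1, 10000)
    half <- intergenomic_similarity(a, b)
    expect_equal(half$similarity, 66.67, tolerance = 0.15)
  })
})

test_that("similarity is symmetric with self-similarity 100", {
  withr::with_seed(8, {
    base <- random_dna_seq(4000, 80)
    mutate_dna <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      pos <- sample(length(ch), k)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste(ch, collapse = "")
    }
    genomes <- c(g1 = base, g2 = mutate_dna(base, 100),
                 g3 = random_dna_seq(4000, 81))
    m <- similarity_matrix(genomes)
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 100))
    expect_true(all(m >= 0 & m <= 100))
    expect_gt(m["g1", "g2"], 80)
  })
})

test_that("rank clustering nests species within genus within subfamily", {
  ids <- c("a", "b", "c")
  m <- matrix(100, 3, 3, dimnames = list(ids, ids))
  r <- cluster_ranks(m)
  expect_equal(length(unique(r$species_cluster)), 1)
  expect_equal(length(unique(r$genus_cluster)), 1)
  expect_equal(length(unique(r$subfamily_cluster)), 1)

  # single linkage: the 96-96-60 chain is one species cluster
  chain <- matrix(c(100, 96, 60, 96, 100, 96, 60, 96, 100), 3, 3,
                  dimnames = list(ids, ids))
  rc <- cluster_ranks(chain)
  expect_equal(length(unique(rc$species_cluster)), 1)

  # two planted subfamily blocks: within > 95, across < 20
  ids6 <- paste0("g", 1:6)
  blocks <- matrix(5, 6, 6, dimnames = list(ids6, ids6))
  blocks[1:3, 1:3] <- 97
  blocks[4:6, 4:6] <- 97
  diag(blocks) <- 100
  rb <- cluster_ranks(blocks)
  expect_equal(length(unique(rb$subfamily_cluster)), 2)
  expect_equal(length(unique(rb$species_cluster)), 2)
  expect_equal(rb$subfamily_cluster[1], rb$subfamily_cluster[2])
  expect_false(rb$subfamily_cluster[1] == rb$subfamily_cluster[4])

  expect_error(cluster_ranks(matrix(c(100, 50, 60, 100), 2, 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b")))),
               "asymmetric")
})

test_that("rank nesting holds on random similarity matrices", {
  withr::with_seed(6, {
    for (rep in 1:100) {
      n <- sample(4:8, 1)
      ids <- paste0("g", seq_len(n))
      m <- matrix(stats::runif(n * n, 0, 100), n, n)
      m <- (m + t(m)) / 2
      diag(m) <- 100
      dimnames(m) <- list(ids, ids)
      r <- cluster_ranks(m)
      # genomes sharing a species share genus and subfamily; sharing a
      # genus share subfamily
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (r$species_cluster[i] == r$species_cluster[j]) {
          expect_equal(r$genus_cluster[i], r$genus_cluster[j])
        }
        if (r$genus_cluster[i] == r$genus_cluster[j]) {
          expect_equal(r$subfamily_cluster[i], r$subfamily_cluster[j])
        }
      }
    }
  })
})

test_that("content-network weights follow the hypergeometric closed form", {
  # universe 10, |A| = |B| = 5, k = 5: P = 1/C(10,5), weight = log10(252)
  expect_equal(content_edge_weight(10, 5, 5, 5), log10(252),
               tolerance = 1e-10)
  expect_equal(content_edge_weight(10, 5, 5, 0), 0)
  # monotone in shared count for fixed sizes
  w <- vapply(1:5, function(k) content_edge_weight(20, 8, 8, k), 0)
  expect_true(all(diff(w) > 0))
  # disjoint sets produce no edge
  net <- content_network(list(a = paste0("f", 1:5), b = paste0("h", 1:5)),
                         universe_size = 20)
  expect_equal(nrow(net$edges), 0)
  expect_length(net$clusters, 2)
  # two planted groups with disjoint accessory content
  pres <- list(a1 = paste0("x", 1:6), a2 = paste0("x", 1:6),
               b1 = paste0("y", 1:6), b2 = paste0("y", 1:6))
  net2 <- content_network(pres, universe_size = 40)
  expect_length(net2$clusters, 2)
  expect_setequal(vapply(net2$clusters, paste, "", collapse = ","),
                  c("a1,a2", "b1,b2"))
  expect_error(content_network(list(a = paste0("f", 1:9)), 5), "universe")
})

test_that("accumulation curves have the stated exact forms and match vegan", {
  shared <- list(g1 = paste0("f", 1:7), g2 = paste0("f", 1:7),
                 g3 = paste0("f", 1:7))
  cs <- accumulation_curve(shared, n_resamples = 50, seed = 1)
  expect_true(all(cs$median_families == 7))
  disjoint <- list(g1 = paste0("a", 1:4), g2 = paste0("b", 1:4),
                   g3 = paste0("c", 1:4))
  cd <- accumulation_curve(disjoint, n_resamples = 50, seed = 1)
  expect_equal(cd$median_families, 4 * (1:3))
  # monotone non-decreasing in k
  com <- tiny_community()
  prot <- com$reference_proteins
  pres <- lapply(split(prot$family_id, prot$genome_id), unique)
  curve <- accumulation_curve(pres, n_resamples = 300, seed = 2)
  expect_true(all(diff(curve$median_families) >= 0))
  # exhaustive oracle on 5 toy genomes
  withr::with_seed(10, {
    toy <- lapply(1:5, function(i)
      sample(paste0("f", 1:12), sample(3:8, 1)))
    names(toy) <- paste0("g", 1:5)
    got <- accumulation_curve(toy, n_resamples = 400, seed = 3)
    for (k in 1:5) {
      subsets <- utils::combn(5, k, simplify = FALSE)
      counts <- vapply(subsets, function(s)
        length(unique(unlist(toy[s]))), 1L)
      expect_lte(abs(got$median_families[k] - stats::median(counts)), 1)
    }
    # independent implementation: vegan::specaccum on the same data
    comm <- t(vapply(toy, function(fams)
      as.integer(paste0("f", 1:12) %in% fams), integer(12)))
    sp <- vegan::specaccum(comm, method = "random", permutations = 400)
    expect_true(all(abs(got$median_families - sp$richness) <= 1))
  })
})
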