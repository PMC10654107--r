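# Host-contig filtering, proviral-region segmentation, spacer matching,
# lysogeny flags.

test_that("the over-100-kbp host filter is strictly greater-than", {
  contigs <- c(exact = strrep("A", 5), above = strrep("A", 6),
               below = strrep("A", 4))
  kept <- host_contig_filter(contigs, min_len = 5)
  expect_setequal(names(kept), "above")
  expect_length(host_contig_filter(character(0), 5), 0)
  # tabular form
  tab <- tibble::tibble(contig_id = c("a", "b"),
                        length = c(100000, 100001))
  expect_equal(host_contig_filter(tab, 100000)$contig_id, "b")
})

test_that("maximal positive segments match an exhaustive enumeration", {
  # independent oracle: best set of disjoint segments found by repeated
  # exhaustive max-subarray extraction
  segs_oracle <- function(x) {
    out <- list()
    live <- x
    repeat {
      best <- 0; bi <- 0; bj <- 0
      for (i in seq_along(live)) for (j in i:length(live)) {
        s <- sum(live[i:j])
        if (s > best) { best <- s; bi <- i; bj <- j }
      }
      if (best <= 0) break
      out[[length(out) + 1]] <- c(bi, bj, best)
      live[bi:bj] <- -Inf
    }
    m <- do.call(rbind, out)
    m[order(m[, 1]), , drop = FALSE]
  }
  withr::with_seed(5, {
    for (rep in 1:20) {
      x <- sample(c(1, -1, 2, -2), 12, replace = TRUE)
      got <- schitomine:::maximal_segments(x)
      want <- segs_oracle(x)
      expect_equal(nrow(got), nrow(want), info = rep)
      expect_equal(got$score, unname(want[, 3]), info = rep)
    }
  })
})

# profiles for every planted family with >= 2 reference members, plus the
# lysogeny families trained on the provirus donors' own genes — the viral
# proteome evidence the segmentation runs on
community_profiles <- function(com, seed = 7) {
  prot <- com$reference_proteins
  fams <- unique(prot$family_id)
  profs <- list()
  for (f in fams) {
    fam <- prot[prot$family_id == f, ]
    if (nrow(fam) < 2) next
    profs[[f]] <- build_profile(
      build_msa(stats::setNames(fam$sequence, fam$protein_id)),
      family_id = f, n_decoys = 300, seed = seed)
  }
  profs
}

test_that("a planted provirus is recovered with gene-level boundaries", {
  com <- tiny_community()
  profiles <- community_profiles(com)
  hid <- names(com$hosts)[1]
  contig <- com$hosts[[hid]]
  genes <- extract_orfs(contig, min_len = 50, contig_id = hid)
  regions <- detect_proviral_region(contig, genes, profiles,
                                    host_penalty = 1,
                                    hallmark_families =
                                      names(com$config$hallmark_lengths),
                                    contig_id = hid)
  expect_equal(nrow(regions), 1)
  truth <- com$truth[com$truth$contig_id == hid, ]
  # reciprocal overlap with the truth interval >= 90%
  ov <- min(regions$end, truth$provirus_end) -
    max(regions$start, truth$provirus_start)
  expect_gte(ov / (truth$provirus_end - truth$provirus_start), 0.9)
  expect_gte(ov / (regions$end - regions$start), 0.9)
  # a contig with no viral hits yields no regions
  none <- detect_proviral_region(
    substr(contig, 1, truth$provirus_start),
    genes[genes$end <= truth$provirus_start, ], profiles,
    hallmark_families = names(com$config$hallmark_lengths),
    contig_id = hid)
  expect_equal(nrow(none), 0)
  expect_error(detect_proviral_region(contig, genes[c(2, 1), ], profiles),
               "sorted")
})

test_that("two separated proviruses give two disjoint regions", {
  com <- tiny_community()
  profiles <- community_profiles(com, seed = 8)
  hid <- names(com$hosts)[1]
  contig <- com$hosts[[hid]]
  # duplicate the host contig so the provirus appears twice, separated by
  # the full host backbone (dozens of host genes)
  double <- paste0(contig, contig)
  genes <- extract_orfs(double, min_len = 50, contig_id = "double")
  regions <- detect_proviral_region(double, genes, profiles,
                                    hallmark_families =
                                      names(com$config$hallmark_lengths),
                                    contig_id = "double")
  expect_equal(nrow(regions), 2)
  expect_lt(regions$end[1], regions$start[2])
})

test_that("spacer matching enforces the 100/100 rule on both strands", {
  withr::with_seed(3, {
    genome <- random_dna_seq(5000, 44)
    sp <- substr(genome, 1001, 1032)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sp)))
    mismatched <- sp
    substr(mismatched, 16, 16) <- if (substr(sp, 16, 16) == "A") "C" else "A"
    spacers <- tibble::tibble(
      spacer_id = c("fwd", "rev", "mut"),
      host_taxon = "Bacteria;X",
      sequence = c(sp, rc, mismatched))
    m <- match_spacers(spacers, c(vir = genome))
    expect_setequal(m$spacer_id, c("fwd", "rev"))
    expect_equal(m$position[m$spacer_id == "fwd"], 1000L)
    expect_equal(m$strand[m$spacer_id == "fwd"], "+")
    expect_equal(m$strand[m$spacer_id == "rev"], "-")
    # the reverse-strand hit maps to the forward coordinate where the
    # spacer's reverse complement occurs, per a naive substring scan
    oracle_pos <- as.integer(regexpr(sp, genome, fixed = TRUE)) - 1L
    expect_equal(m$position[m$spacer_id == "rev"], oracle_pos)
    expect_true(all(m$identity == 1 & m$coverage == 1))
    # degenerate bases: skipped with a warning
    expect_warning(
      m2 <- match_spacers(tibble::tibble(spacer_id = "bad",
                                         host_taxon = "t",
                                         sequence = strrep("N", 32)),
                          c(vir = genome)),
      "degenerate")
    expect_equal(nrow(m2), 0)
  })
})

test_that("planted spacers are all recovered with no false positives", {
  com <- tiny_community()
  viral <- c(com$references, com$contigs)
  m <- match_spacers(com$spacers, viral)
  # recall 1.0: every planted spacer matches its recorded source
  key_got <- paste(m$spacer_id, m$viral_contig_id)
  key_want <- paste(com$spacers$spacer_id, com$spacers$source_contig)
  expect_true(all(key_want %in% key_got))
  # zero false positives: every reported match is an exact occurrence
  for (i in seq_len(nrow(m))) {
    seq <- viral[[m$viral_contig_id[i]]]
    sp <- com$spacers$sequence[com$spacers$spacer_id == m$spacer_id[i]]
    pat <- if (m$strand[i] == "+") sp else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sp)))
    expect_identical(substr(seq, m$position[i] + 1,
                            m$position[i] + nchar(pat)), pat)
  }
  ranked <- predict_hosts(m)
  expect_true(all(ranked$rank >= 1))
})

test_that("lysogeny flags follow the integrase/transposase rule with DGR as evidence", {
  ann <- tibble::tibble(
    genome_id = c("g1", "g2", "g3", "g3", "g4", "g4"),
    label = c("integrase", "DGR", "integrase", "DGR", "transposase",
              "capsid"),
    gene_index = c(1L, 5L, 7L, 8L, 2L, 3L))
  fl <- flag_lysogeny(ann)
  get <- function(g, col) fl[[col]][fl$genome_id == g]
  expect_true(get("g1", "lysogenic"))
  expect_false(get("g2", "lysogenic"))
  expect_true(get("g2", "dgr_evidence"))
  expect_true(get("g3", "lysogenic"))
  expect_equal(get("g3", "note"), "integrase+DGR island")
  expect_true(get("g4", "lysogenic"))
  expect_equal(get("g4", "evidence"), "transposase")
})
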