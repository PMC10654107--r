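# Calibrated position-specific profiles and the iterative mining loop.

test_that("single-column profile scores follow the closed form", {
  msa <- schitomine:::msa_from_rows(c(r1 = "A", r2 = "A", r3 = "A"))
  p0 <- build_profile(msa, pseudocount_weight = 0, n_decoys = 50,
                      decoy_len = 30, seed = 1)
  expect_equal(unname(p0$match_scores[1, "A"]), log2(20))
  # heavy pseudocounts pull every score to 0
  pinf <- build_profile(msa, pseudocount_weight = 1e9, n_decoys = 50,
                        decoy_len = 30, seed = 1)
  expect_true(all(abs(pinf$match_scores) < 1e-6))
})

test_that("columns with more than half gaps are dropped from match states", {
  rows <- c(r1 = "MK-A", r2 = "M--A", r3 = "MKLA", r4 = "M--A")
  p <- build_profile(schitomine:::msa_from_rows(rows), n_decoys = 50,
                     decoy_len = 30, seed = 1)
  expect_equal(p$msa_col_map, c(1L, 2L, 4L))  # column 3 has 75% gaps
  expect_error(build_profile(schitomine:::msa_from_rows(c(a = "-", b = "-"))),
               "gaps")
})

test_that("every training sequence of a synthetic family is self-recognized", {
  com <- tiny_community()
  prot <- com$reference_proteins
  fam <- prot[prot$family_id == "portal", ]
  seqs <- stats::setNames(fam$sequence, fam$protein_id)
  msa <- build_msa(seqs)
  p <- build_profile(msa, family_id = "portal", n_decoys = 500, seed = 3)
  hits <- search_profile(p, fam, max_evalue = 1e-10)
  expect_setequal(hits$protein_id, fam$protein_id)
  expect_true(all(hits$evalue <= 1e-10))
  # a uniformly random 300-aa protein is not recruited
  rnd <- tibble::tibble(protein_id = "rnd", genome_id = "x",
                        sequence = random_aa_seq(300, 77))
  expect_equal(nrow(search_profile(p, rnd, 1e-10)), 0)
  # empty input, empty output
  expect_equal(nrow(search_profile(p, fam[0, ], 1e-10)), 0)
})

test_that("shuffled decoys are never called at the mining threshold", {
  com <- tiny_community()
  prot <- com$reference_proteins
  fam <- prot[prot$family_id == "TerL", ]
  p <- build_profile(build_msa(stats::setNames(fam$sequence,
                                               fam$protein_id)),
                     family_id = "TerL", n_decoys = 500, seed = 5)
  pool <- unlist(strsplit(fam$sequence, ""))
  decoys <- withr::with_seed(8, tibble::tibble(
    protein_id = sprintf("d%04d", 1:1000), genome_id = "shuffle",
    sequence = vapply(1:1000, function(i)
      paste(sample(pool, 180, replace = TRUE), collapse = ""), "")))
  expect_equal(nrow(search_profile(p, decoys, 1e-10)), 0)
})

test_that("an uncalibrated profile is rejected by search", {
  msa <- schitomine:::msa_from_rows(c(a = "MKLV", b = "MKLV"))
  p <- build_profile(msa, n_decoys = 50, decoy_len = 20, seed = 1)
  p$gumbel_lambda <- NA_real_
  expect_error(search_profile(p, tibble::tibble(protein_id = "x",
                                                sequence = "MKLV")),
               "not calibrated")
})

test_that("iterative search is a fixpoint when the database equals the seeds", {
  com <- tiny_community()
  prot <- com$reference_proteins
  fam <- prot[prot$family_id == "MCP", ]
  seeds <- stats::setNames(fam$sequence, fam$protein_id)
  res <- iterative_search(seeds, fam, family_id = "MCP", n_decoys = 300,
                          seed = 2)
  expect_equal(res$n_iterations, 1)
  expect_true(res$converged)
  expect_setequal(res$hits$protein_id, fam$protein_id)
})

test_that("iterative search recovers a planted family and no decoys", {
  withr::with_seed(21, {
    consensus <- random_aa_seq(240, 55)
    mutate_at <- function(s, ident) {
      ch <- strsplit(s, "")[[1]]
      k <- floor((1 - ident) * length(ch))
      pos <- sample(length(ch), k)
      for (p in pos) ch[p] <- sample(setdiff(strsplit(
        "ACDEFGHIKLMNPQRSTVWY", "")[[1]], ch[p]), 1)
      paste(ch, collapse = "")
    }
    homologs <- vapply(1:20, function(i) mutate_at(consensus, 0.6), "")
    decoys <- vapply(1:200, function(i)
      paste(sample(strsplit(consensus, "")[[1]]), collapse = ""), "")
    db <- tibble::tibble(
      protein_id = c(sprintf("hom%02d", 1:20), sprintf("dec%03d", 1:200)),
      genome_id = "db",
      sequence = c(homologs, decoys))
    seeds <- stats::setNames(vapply(1:4, function(i)
      mutate_at(consensus, 0.75), ""), paste0("seed", 1:4))
    res <- iterative_search(seeds, db, max_evalue = 1e-10, max_iter = 10,
                            family_id = "planted", n_decoys = 500, seed = 9)
    expect_true(res$converged)
    expect_lte(res$n_iterations, 5)
    expect_setequal(res$hits$protein_id, sprintf("hom%02d", 1:20))
    # complement test: removing the recovered hits empties the hit set
    db2 <- db[!db$protein_id %in% res$hits$protein_id, ]
    res2 <- iterative_search(seeds, db2, max_evalue = 1e-10, max_iter = 10,
                             family_id = "planted", n_decoys = 500, seed = 9)
    expect_equal(nrow(res2$hits), 0)
  })
})

test_that("recruitment is monotone across iterations", {
  com <- tiny_community()
  prot <- com$reference_proteins
  fam <- prot[prot$family_id == "vDNAP", ]
  db <- dplyr::bind_rows(lapply(
    names(com$contigs)[grepl("^MG", names(com$contigs))],
    function(cid) extract_orfs(com$contigs[[cid]], 50, cid)))
  seeds <- stats::setNames(fam$sequence, fam$protein_id)
  # trace hit sets by rerunning with increasing max_iter
  ids_at <- function(k) {
    suppressWarnings(
      iterative_search(seeds, db, max_iter = k, family_id = "vDNAP",
                       n_decoys = 300, seed = 6))$hits$protein_id
  }
  h1 <- ids_at(1)
  h2 <- ids_at(2)
  expect_true(all(h1 %in% h2))
})
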