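# Synthetic community generator: determinism, truth bookkeeping, motif
# properties, and the paired-MSA fixture generator.

test_that("contradictory configurations fail with the offending field named", {
  expect_error(community_config(within_family_identity = 0.4),
               "within_family_identity")
  expect_error(community_config(n_chimeras = -1), "n_chimeras")
  expect_error(community_config(host_contig_length = 90000),
               "host_contig_length")
  expect_error(community_config(host_contig_length = 120000,
                                provirus_length = 130000),
               "provirus_length")
  expect_error(community_config(completeness_mix = c(1, 1, 1, 1, 1, 1, 1)),
               "completeness_mix")
  expect_error(community_config(hallmark_lengths = c(vDNAP = 100,
                                                     vRNAP = 2700)),
               "hallmark_lengths")
  expect_error(community_config(
    hallmark_lengths = c(vDNAP = 750, MCP = 380, portal = 700, tail = 900,
                         TerL = 550, TerS = 180, vRNAP = 2000)),
    "2,600")
})

test_that("identical config and seed reproduce byte-identical outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_community(tiny_config(seed = 5), outdir = d1)
  generate_community(tiny_config(seed = 5), outdir = d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # a different seed changes the sequences
  d3 <- withr::local_tempdir()
  generate_community(tiny_config(seed = 6), outdir = d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "references.fna"))),
    unname(tools::md5sum(file.path(d3, "references.fna")))))
})

test_that("truth table counts equal config counts for every class", {
  com <- tiny_community()
  cfg <- com$config
  counts <- table(com$truth$true_class)
  expect_equal(unname(counts["reference"]), cfg$n_reference_genomes)
  expect_equal(unname(counts["decoy"]), cfg$n_decoys)
  expect_equal(unname(counts["chimera"]), cfg$n_chimeras)
  expect_equal(unname(counts["host"]), cfg$n_host_contigs)
  expect_equal(unname(counts["HQ"]),
               cfg$completeness_mix[cfg$n_hallmark_families])
  for (k in seq_len(cfg$n_hallmark_families - 1)) {
    expected <- cfg$completeness_mix[k]
    got <- sum(com$truth$true_class == sprintf("%d-core", k))
    expect_equal(got, expected, info = paste0(k, "-core"))
  }
  expect_identical(anyDuplicated(com$truth$contig_id), 0L)
})

test_that("every polymerase carries the motif and no decoy does", {
  com <- tiny_community()
  vr <- com$reference_proteins[com$reference_proteins$family_id == "vRNAP", ]
  # regex-style oracle, independent of motif_scan
  oracle <- function(s) grepl("E.DG...G", s)
  expect_true(all(vapply(vr$sequence, oracle, logical(1))))
  decoys <- com$contigs[grepl("^DEC", names(com$contigs))]
  for (d in names(decoys)) {
    orfs <- extract_orfs(decoys[[d]], min_len = 50, contig_id = d)
    long <- orfs$sequence[nchar(orfs$sequence) >= 2500]
    expect_gt(length(long), 0)
    expect_false(any(vapply(long, oracle, logical(1))), label = d)
  }
})

test_that("planted full-completeness contigs carry all hallmark families at the configured identity", {
  com <- tiny_community()
  cfg <- com$config
  hq <- com$truth$contig_id[com$truth$true_class == "HQ"]
  fams <- com$families[com$families$role == "hallmark", ]
  for (cid in hq) {
    # all-ORFs mode so the planted gene's own ATG is among the calls even
    # when an upstream in-frame start extends the locus call
    orfs <- extract_orfs(com$contigs[[cid]], min_len = 50, contig_id = cid,
                         longest_only = FALSE)
    for (k in seq_len(nrow(fams))) {
      cons <- fams$consensus[k]
      cand <- orfs$sequence[nchar(orfs$sequence) == nchar(cons)]
      idents <- vapply(cand, function(s) {
        mean(strsplit(s, "")[[1]] == strsplit(cons, "")[[1]])
      }, 0)
      expect_true(any(idents >= cfg$within_family_identity),
                  label = paste(cid, fams$family_id[k]))
    }
  }
})

test_that("host contigs embed the provirus verbatim at the recorded interval", {
  com <- tiny_community()
  hostrows <- com$truth[com$truth$true_class == "host", ]
  for (i in seq_len(nrow(hostrows))) {
    cid <- hostrows$contig_id[i]
    s <- hostrows$provirus_start[i]
    e <- hostrows$provirus_end[i]
    contig <- com$hosts[[cid]]
    expect_true(s >= 0 && e <= nchar(contig) && s < e)
    expect_identical(substr(contig, s + 1, e), com$provirus_donors[[cid]])
  }
})

test_that("spacers are exact substrings of their recorded viral source", {
  com <- tiny_community()
  sp <- com$spacers
  expect_gt(nrow(sp), 0)
  pool <- c(com$references, com$contigs)
  for (i in seq_len(nrow(sp))) {
    src <- pool[[sp$source_contig[i]]]
    sub <- substr(src, sp$source_start[i] + 1,
                  sp$source_start[i] + nchar(sp$sequence[i]))
    expected <- if (sp$source_strand[i] == "+") sp$sequence[i] else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sp$sequence[i])))
    expect_identical(sub, expected)
  }
})

test_that("paired MSA fixture plants exact covariation at zero noise", {
  pm <- generate_paired_msa(60, 8, 9, planted_pairs = list(c(3, 7)),
                            noise = 0, seed = 2)
  expect_equal(dim(pm$msa), c(60, 17))
  a <- pm$msa[, 3]
  b <- pm$msa[, 8 + 7]
  # a fixed residue bijection: each a-state maps to exactly one b-state
  expect_true(all(rowSums(table(a, b) > 0) == 1))
  expect_error(generate_paired_msa(60, 8, 9,
                                   planted_pairs = list(c(3, 7), c(3, 2))),
               "duplicate")
  expect_error(generate_paired_msa(10, 8, 9), "n_rows")
})

test_that("planted-pair mismatch fraction matches the noise level", {
  pm <- generate_paired_msa(500, 10, 10, planted_pairs = list(c(2, 5)),
                            noise = 0.1, seed = 31)
  a <- pm$msa[, 2]
  b <- pm$msa[, 10 + 5]
  # recover the majority mapping and count exceptions (binomial over rows)
  tab <- table(a, b)
  mapped <- colnames(tab)[apply(tab, 1, which.max)]
  names(mapped) <- rownames(tab)
  mismatch <- mean(b != mapped[a])
  expect_gte(mismatch, 0.05)
  expect_lte(mismatch, 0.15)
})
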