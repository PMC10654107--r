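# End-to-end orchestration: simulate/load -> orthology -> profiles ->
# screen -> provirus/host -> taxonomy -> cophylo/dca -> annotate -> report.
# Every stage writes its tables plus a manifest (parameters, seed, input
# and output digests) so each summary number is traceable to a file.

#' Default pipeline configuration
#'
#' @param seed Master seed.
#' @param n_decoys Decoy count for profile/search calibration.
#' @return Nested configuration list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1, n_decoys = 1000) {
  list(
    seed = seed,
    community = list(),          # overrides for community_config()
    inputs = NULL,               # or named file paths to skip simulation
    orthology = list(max_evalue = 1e-10, min_query_cover = 0.5,
                     inflation = 2, core_fraction = 0.95,
                     n_decoys = n_decoys),
    search = list(max_evalue = 1e-10, max_iter = 10, n_decoys = n_decoys),
    screen = list(min_len = 2500, motif = "ExDGxxxG", dedup_identity = 0.99),
    provirus = list(host_min_len = 100000, host_penalty = 1,
                    max_evalue = 1e-5),
    taxonomy = list(species_t = 95, genus_t = 70, subfamily_t = 20,
                    n_resamples = 300),
    annotate = list(max_evalue = 1e-5)
  )
}

#' @noRd
merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' @noRd
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    assert_that(file.exists(config),
                paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  merge_config(pipeline_config(), config %||% list())
}

#' @noRd
write_manifest <- function(outdir, stage, params, inputs, outputs, seed) {
  man <- list(stage = stage, seed = seed, params = params,
              inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  jsonlite::write_json(man, file.path(outdir,
                                      sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full mining pipeline
#'
#' Executes all stages on either a freshly generated synthetic community
#' (the default) or user-supplied input files, writing stage tables,
#' per-stage manifests and a `summary.json` into `outdir`. Reruns with the
#' same configuration reproduce identical non-log outputs.
#'
#' @param config A configuration list (see [pipeline_config()]) or the
#'   path of a YAML file of overrides.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the stage results (`community`,
#'   `families`, `flags`, `hallmark_ids`, `hits`, `screen`, `regions`,
#'   `spacer_matches`, `ranks`, `network`, `accumulation`, `srfv`,
#'   `annotations`, `tally`, `lysogeny`, `summary`).
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("run")) {
  cfg <- read_pipeline_config(config)
  seed <- cfg$seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outpath <- function(f) file.path(outdir, f)
  log_line <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), ..., "\n",
        file = outpath("run.log"), append = TRUE)
  }

  # --- stage: simulate / load ---------------------------------------------
  log_line("stage simulate")
  if (is.null(cfg$inputs)) {
    ccfg <- do.call(community_config, c(cfg$community, list(seed = seed)))
    community <- generate_community(ccfg, outdir = outpath("community"))
    ref_proteins <- community$reference_proteins
    references <- community$references
    contig_seqs <- community$contigs
    hosts <- community$hosts
    spacers <- community$spacers
    input_files <- unname(community$paths)
  } else {
    need <- c("reference_proteins_fasta", "contigs_fasta")
    for (k in need) {
      assert_that(!is.null(cfg$inputs[[k]]),
                  paste0("missing config key: inputs$", k))
      assert_that(file.exists(cfg$inputs[[k]]),
                  paste0("input file not found for config key inputs$", k,
                         ": ", cfg$inputs[[k]]))
    }
    community <- NULL
    prot <- read_fasta(cfg$inputs$reference_proteins_fasta, "aa")
    # header convention: <genome>_p<NN> (genome id before the last _p tag)
    ref_proteins <- tibble::tibble(
      protein_id = names(prot),
      genome_id = sub("_p[0-9]+$", "", names(prot)),
      family_id = NA_character_, sequence = unname(prot))
    references <- if (!is.null(cfg$inputs$references_fasta))
      read_fasta(cfg$inputs$references_fasta, "dna") else character(0)
    contig_seqs <- read_fasta(cfg$inputs$contigs_fasta, "dna")
    hosts <- if (!is.null(cfg$inputs$hosts_fasta))
      read_fasta(cfg$inputs$hosts_fasta, "dna") else character(0)
    spacers <- if (!is.null(cfg$inputs$spacers_fasta)) {
      sp <- read_fasta(cfg$inputs$spacers_fasta, "dna")
      tax <- readr::read_tsv(cfg$inputs$spacers_tsv, show_col_types = FALSE)
      tibble::tibble(spacer_id = names(sp), sequence = unname(sp)) |>
        dplyr::left_join(tax, by = "spacer_id")
    } else tibble::tibble(spacer_id = character(), host_taxon = character(),
                          sequence = character())
    input_files <- unlist(cfg$inputs)
  }
  n_genomes <- length(unique(ref_proteins$genome_id))

  # --- stage: orthology ----------------------------------------------------
  log_line("stage orthology")
  oc <- cfg$orthology
  membership <- cluster_families(ref_proteins, oc$max_evalue,
                                 oc$min_query_cover, oc$inflation,
                                 n_decoys = oc$n_decoys,
                                 seed = derive_seed(seed, "orthology"))
  flags <- classify_families(membership, n_genomes, oc$core_fraction)
  hallmark_ids <- flags$family_id[flags$is_hallmark]
  write_families_tsv(membership, flags, outpath("families.tsv"))
  write_manifest(outdir, "orthology", oc, input_files,
                 outpath("families.tsv"), seed)
  assert_that(length(hallmark_ids) > 0,
              "stage orthology: no hallmark family detected")

  # mean member length designates the polymerase-role hallmark family
  fam_len <- membership |>
    dplyr::left_join(ref_proteins[, c("protein_id", "sequence")],
                     by = "protein_id") |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(mean_len = mean(nchar(.data$sequence)))
  pol_family <- fam_len |>
    dplyr::filter(.data$family_id %in% hallmark_ids) |>
    dplyr::arrange(dplyr::desc(.data$mean_len)) |>
    dplyr::slice(1) |>
    dplyr::pull("family_id")

  # --- stage: profiles + iterative search ---------------------------------
  log_line("stage profiles")
  db <- dplyr::bind_rows(lapply(names(contig_seqs), function(cid) {
    extract_orfs(contig_seqs[[cid]], min_len = 50, contig_id = cid)
  }))
  sc <- cfg$search
  profiles <- list()
  hit_rows <- list()
  for (fam in hallmark_ids) {
    members <- membership$protein_id[membership$family_id == fam]
    seeds <- stats::setNames(
      ref_proteins$sequence[match(members, ref_proteins$protein_id)],
      members)
    res <- iterative_search(seeds, db, sc$max_evalue, sc$max_iter,
                            family_id = fam, n_decoys = sc$n_decoys,
                            seed = derive_seed(seed, paste0("search_", fam)))
    profiles[[fam]] <- res$profile
    if (nrow(res$hits) > 0) {
      h <- res$hits
      h$contig_id <- h$genome_id
      h$sequence <- db$sequence[match(h$protein_id, db$protein_id)]
      h$n_iterations <- res$n_iterations
      hit_rows[[fam]] <- h
    }
  }
  hits <- dplyr::bind_rows(hit_rows)
  write_tsv_plain(dplyr::select(hits, -"sequence"), outpath("hits.tsv"))
  write_manifest(outdir, "profiles", sc, input_files, outpath("hits.tsv"),
                 seed)

  # --- stage: screen -------------------------------------------------------
  log_line("stage screen")
  scr <- cfg$screen
  screen <- screen_candidates(hits, contig_seqs,
                              polymerase_family = pol_family,
                              min_len = scr$min_len, motif = scr$motif,
                              dedup_identity = scr$dedup_identity,
                              hallmark_families = hallmark_ids)
  screen_out <- screen |>
    dplyr::mutate(reasons = vapply(.data$reasons, paste, "",
                                   collapse = ";")) |>
    dplyr::select(-"hallmark_counts")
  write_tsv_plain(screen_out, outpath("screen.tsv"))
  write_manifest(outdir, "screen", scr, outpath("hits.tsv"),
                 outpath("screen.tsv"), seed)
  hq_ids <- screen$contig_id[screen$label == "HQ"]

  # --- stage: provirus + host prediction ----------------------------------
  log_line("stage provirus")
  pv <- cfg$provirus
  hosts_kept <- host_contig_filter(hosts, pv$host_min_len)
  # viral gene evidence for segmentation covers the whole reference
  # proteome: hallmark profiles plus profiles of every accessory family,
  # singletons included (hallmark hits are still required per region)
  accessory_profiles <- list()
  if (length(hosts_kept) > 0) {
    acc_ids <- setdiff(unique(membership$family_id), hallmark_ids)
    for (fam in acc_ids) {
      members <- membership$protein_id[membership$family_id == fam]
      seqs <- stats::setNames(
        ref_proteins$sequence[match(members, ref_proteins$protein_id)],
        members)
      aln <- if (length(seqs) >= 2) build_msa(seqs) else msa_from_rows(seqs)
      accessory_profiles[[fam]] <- build_profile(
        aln, family_id = fam, n_decoys = sc$n_decoys,
        seed = derive_seed(seed, paste0("provirus_", fam)))
    }
  }
  regions <- dplyr::bind_rows(lapply(names(hosts_kept), function(hid) {
    genes <- extract_orfs(hosts_kept[[hid]], min_len = 50, contig_id = hid)
    detect_proviral_region(hosts_kept[[hid]], genes,
                           c(profiles, accessory_profiles),
                           host_penalty = pv$host_penalty,
                           max_evalue = pv$max_evalue,
                           hallmark_families = hallmark_ids,
                           contig_id = hid)
  }))
  write_tsv_plain(regions, outpath("proviral_regions.tsv"))
  viral_set <- c(references, contig_seqs[hq_ids])
  spacer_matches <- if (nrow(spacers) > 0 && length(viral_set) > 0) {
    match_spacers(spacers, viral_set)
  } else tibble::tibble()
  write_tsv_plain(spacer_matches, outpath("spacer_matches.tsv"))
  host_predictions <- if (nrow(spacer_matches) > 0)
    predict_hosts(spacer_matches) else tibble::tibble()
  write_tsv_plain(host_predictions, outpath("host_predictions.tsv"))
  write_manifest(outdir, "provirus", pv, input_files,
                 c(outpath("proviral_regions.tsv"),
                   outpath("spacer_matches.tsv"),
                   outpath("host_predictions.tsv")), seed)

  # --- stage: taxonomy -----------------------------------------------------
  log_line("stage taxonomy")
  tx <- cfg$taxonomy
  rank_genomes <- c(references, contig_seqs[hq_ids])
  ranks <- NULL; sim <- NULL
  if (length(rank_genomes) >= 2) {
    sim <- similarity_matrix(rank_genomes)
    write_similarity_tsv(sim, outpath("similarity.tsv"))
    ranks <- cluster_ranks(sim, tx$species_t, tx$genus_t, tx$subfamily_t)
    write_tsv_plain(ranks, outpath("ranks.tsv"))
  }
  pf_presence <- split(membership$family_id, membership$genome_id)
  pf_presence <- lapply(pf_presence, unique)
  network <- content_network(pf_presence,
                             universe_size = nrow(flags))
  write_tsv_plain(network$edges, outpath("network_edges.tsv"))
  accumulation <- accumulation_curve(pf_presence, tx$n_resamples,
                                     seed = derive_seed(seed, "accum"))
  write_tsv_plain(accumulation, outpath("accumulation.tsv"))
  write_manifest(outdir, "taxonomy", tx, input_files,
                 c(outpath("similarity.tsv"), outpath("ranks.tsv"),
                   outpath("network_edges.tsv"),
                   outpath("accumulation.tsv")), seed)

  # --- stage: cophylo / dca ------------------------------------------------
  log_line("stage cophylo")
  trees <- list()
  for (fam in hallmark_ids) {
    members <- membership[membership$family_id == fam, , drop = FALSE]
    if (nrow(members) < 4) next
    seqs <- stats::setNames(
      ref_proteins$sequence[match(members$protein_id,
                                  ref_proteins$protein_id)],
      members$genome_id)
    msa <- build_msa(seqs)
    trees[[fam]] <- build_nj_tree(msa_distances(msa))
  }
  srfv_m <- if (length(trees) >= 2) srfv_matrix(trees) else NULL
  if (!is.null(srfv_m)) {
    write_similarity_tsv(srfv_m, outpath("srfv.tsv"))
  }
  dca_note <- sprintf(
    "skipped: %d paired genomes < 50 rows required for mean-field DCA",
    n_genomes)
  write_manifest(outdir, "cophylo", list(), input_files,
                 outpath("srfv.tsv"), seed)

  # --- stage: annotate -----------------------------------------------------
  log_line("stage annotate")
  an <- cfg$annotate
  annotations <- tibble::tibble()
  tally <- NULL; lysogeny <- NULL
  if (!is.null(community)) {
    lib <- annotation_library_from_truth(
      community, n_decoys = max(200L, an$n_decoys %||% 200L),
      seed = derive_seed(seed, "annotate"))
    targets <- ref_proteins
    annotations <- annotate_profiles(targets, lib, an$max_evalue)
    if (nrow(annotations) > 0) {
      groups <- dplyr::bind_rows(
        tibble::tibble(
          genome_id = names(references),
          group = community$truth$habitat[
            match(names(references), community$truth$contig_id)]),
        tibble::tibble(genome_id = names(references), group = "Isolate"))
      tally <- amg_tally(annotations, groups)
      write_tsv_plain(tally, outpath("amg_tally.tsv"))
      ann_lys <- annotations |>
        dplyr::mutate(label = .data$category,
                      gene_index = as.integer(
                        sub(".*_p", "", .data$protein_id)))
      lysogeny <- flag_lysogeny(ann_lys)
      write_tsv_plain(lysogeny, outpath("lysogeny.tsv"))
    }
    write_tsv_plain(annotations, outpath("annotations.tsv"))
  }
  write_manifest(outdir, "annotate", an, input_files,
                 c(outpath("annotations.tsv"), outpath("amg_tally.tsv"),
                   outpath("lysogeny.tsv")), seed)

  # --- stage: report -------------------------------------------------------
  log_line("stage report")
  summary <- list(
    seed = seed,
    n_reference_genomes = n_genomes,
    n_families = nrow(flags),
    n_core_families = sum(flags$is_core),
    n_hallmark_families = length(hallmark_ids),
    polymerase_family = pol_family,
    n_candidate_contigs = length(contig_seqs),
    n_hq = sum(screen$label == "HQ"),
    hq_contigs = sort(hq_ids),
    n_chimera_flagged = sum(screen$label == "chimera_flagged"),
    n_rejected = sum(screen$label == "rejected"),
    label_counts = as.list(table(screen$label)),
    n_proviral_regions = if (is.null(regions)) 0L else nrow(regions),
    n_spacer_matches = if (is.null(spacer_matches)) 0L else
      nrow(spacer_matches),
    n_species = if (!is.null(ranks))
      length(unique(ranks$species_cluster)) else NA,
    n_genera = if (!is.null(ranks))
      length(unique(ranks$genus_cluster)) else NA,
    n_subfamilies = if (!is.null(ranks))
      length(unique(ranks$subfamily_cluster)) else NA,
    n_network_clusters = length(network$clusters),
    n_annotations = nrow(annotations),
    dca = dca_note)
  jsonlite::write_json(summary, outpath("summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(outdir, "report", list(), input_files,
                 outpath("summary.json"), seed)

  invisible(list(community = community, membership = membership,
                 flags = flags, hallmark_ids = hallmark_ids,
                 polymerase_family = pol_family, hits = hits,
                 screen = screen, regions = regions,
                 spacer_matches = spacer_matches,
                 host_predictions = host_predictions,
                 similarity = sim, ranks = ranks, network = network,
                 accumulation = accumulation, srfv = srfv_m, trees = trees,
                 annotations = annotations, tally = tally,
                 lysogeny = lysogeny, summary = summary, outdir = outdir))
}

# Labeled annotation profile library built from the generator's accessory
# family truth (the synthetic stand-in for an external labeled library).
#' @noRd
annotation_library_from_truth <- function(community, n_decoys = 200,
                                          seed = 1) {
  acc <- community$families[community$families$role == "accessory", ,
                            drop = FALSE]
  prot <- community$reference_proteins
  lib <- list()
  for (k in seq_len(nrow(acc))) {
    fam <- acc$family_id[k]
    members <- prot[prot$family_id == fam, , drop = FALSE]
    if (nrow(members) < 2) next
    seqs <- stats::setNames(members$sequence, members$protein_id)
    # accessory families are generated gapless and equal-length
    msa <- msa_from_rows(seqs)
    profile <- build_profile(msa, family_id = fam, n_decoys = n_decoys,
                             seed = derive_seed(seed, fam))
    lib[[fam]] <- label_profile(profile, category = acc$category[k])
  }
  lib
}
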