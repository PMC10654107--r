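# Synthetic viral/host community generator with full ground truth.
#
# The generator emulates the statistical structure the mining pipeline
# assumes: a reference set of complete genomes sharing seven universal
# single-copy hallmark gene families (one of them a giant virion RNA
# polymerase carrying the conserved E-x-D-G-x-x-x-G motif), metagenome
# contigs of partial completeness (1..7 hallmark types, always anchored on
# the polymerase), decoy contigs carrying a related but motif-free
# polymerase, chimeric contigs with duplicated hallmarks, host contigs
# >100 kbp with an embedded complete provirus, and CRISPR spacers copied
# from viral genomes. Every emitted record is logged in a truth table.

HALLMARK_NAMES <- c("vDNAP", "MCP", "portal", "tail", "TerL", "TerS", "vRNAP")

#' Configuration for the synthetic community generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_community()]. Defaults describe a desk-scale community that
#' preserves the constraints of the real study system: seven hallmark
#' families, a polymerase-role family longer than 2,600 aa carrying the
#' E-x-D-G-x-x-x-G motif, host contigs longer than 100 kbp, and 32-nt
#' spacers.
#'
#' @param n_reference_genomes Number of complete reference genomes.
#' @param n_hallmark_families Number of universal single-copy hallmark
#'   families (the lineage has 7; other values are supported for toys).
#' @param hallmark_lengths Named integer vector of amino-acid lengths, one
#'   per hallmark family. The polymerase-role family (named `vRNAP` by
#'   default) must be at least 2,600 aa.
#' @param within_family_identity Fraction in (0.5, 1]; every planted family
#'   member is generated from the family consensus by substituting exactly
#'   `floor((1 - identity) * n_mutable)` positions, so realized identity to
#'   the consensus is never below this value.
#' @param n_accessory_families Number of accessory (non-hallmark) families,
#'   including one family per AMG category in `amg_plant_rates` plus
#'   dedicated integrase and DGR families.
#' @param n_metagenome_contigs Number of uncultivated candidate contigs.
#' @param completeness_mix Integer vector of length `n_hallmark_families`;
#'   entry `k` is the number of metagenome contigs carrying exactly `k`
#'   hallmark types (the polymerase anchor plus `k - 1` others). Must sum to
#'   `n_metagenome_contigs`.
#' @param n_decoys Number of contigs carrying a related but motif-free
#'   polymerase.
#' @param n_chimeras Number of contigs with all hallmark types but
#'   duplicated copies of at least one family.
#' @param n_host_contigs Number of host (prokaryotic) contigs, each with one
#'   embedded provirus.
#' @param host_contig_length Host contig length in bp; must exceed 100,000.
#' @param provirus_length Upper bound in bp for the embedded provirus donor
#'   genome; must be smaller than `host_contig_length`. The planted provirus
#'   is always a complete donor genome inserted verbatim, and its realized
#'   interval is recorded in the truth table.
#' @param n_spacers_per_host CRISPR spacers sampled per host contig.
#' @param spacer_length Spacer length in bp (default 32).
#' @param habitats Character vector of habitat labels.
#' @param amg_plant_rates Named numeric vector mapping AMG category to the
#'   per-genome Poisson rate at which genes of that category are planted.
#' @param seed Master seed. Every output class draws from its own stream
#'   derived from this seed, so enabling one class never perturbs another.
#'
#' @return A validated `community_config` list.
#' @export
community_config <- function(n_reference_genomes = 10,
                             n_hallmark_families = 7,
                             hallmark_lengths = c(vDNAP = 750, MCP = 380,
                                                  portal = 700, tail = 900,
                                                  TerL = 550, TerS = 180,
                                                  vRNAP = 2850),
                             within_family_identity = 0.85,
                             n_accessory_families = 12,
                             n_metagenome_contigs = 12,
                             completeness_mix = c(2, 1, 1, 2, 1, 2, 3),
                             n_decoys = 3,
                             n_chimeras = 2,
                             n_host_contigs = 2,
                             host_contig_length = 120000,
                             provirus_length = 40000,
                             n_spacers_per_host = 5,
                             spacer_length = 32,
                             habitats = c("marine", "freshwater",
                                          "host_associated", "terrestrial"),
                             amg_plant_rates = c(
                               "Nucleotide metabolism" = 2.5,
                               "Carbohydrate metabolism" = 0.5,
                               "Metabolism of cofactors and vitamins" = 0.4,
                               "Cell circle" = 0.2),
                             seed = 1) {
  cfg <- list(
    n_reference_genomes = n_reference_genomes,
    n_hallmark_families = n_hallmark_families,
    hallmark_lengths = hallmark_lengths,
    within_family_identity = within_family_identity,
    n_accessory_families = n_accessory_families,
    n_metagenome_contigs = n_metagenome_contigs,
    completeness_mix = completeness_mix,
    n_decoys = n_decoys,
    n_chimeras = n_chimeras,
    n_host_contigs = n_host_contigs,
    host_contig_length = host_contig_length,
    provirus_length = provirus_length,
    n_spacers_per_host = n_spacers_per_host,
    spacer_length = spacer_length,
    habitats = habitats,
    amg_plant_rates = amg_plant_rates,
    seed = seed
  )
  validate_community_config(cfg)
  structure(cfg, class = "community_config")
}

#' @noRd
validate_community_config <- function(cfg) {
  counts <- c("n_reference_genomes", "n_accessory_families",
              "n_metagenome_contigs", "n_decoys", "n_chimeras",
              "n_host_contigs", "n_spacers_per_host")
  for (f in counts) {
    assert_that(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 &&
                  cfg[[f]] >= 0 && cfg[[f]] == floor(cfg[[f]]),
                paste0("invalid config field '", f,
                       "': must be a non-negative integer"))
  }
  assert_that(cfg$n_hallmark_families >= 1,
              "invalid config field 'n_hallmark_families': must be >= 1")
  assert_that(length(cfg$hallmark_lengths) == cfg$n_hallmark_families,
              "invalid config field 'hallmark_lengths': one length per hallmark family required")
  assert_that(!is.null(names(cfg$hallmark_lengths)) &&
                "vRNAP" %in% names(cfg$hallmark_lengths),
              "invalid config field 'hallmark_lengths': must be named and include the polymerase-role family 'vRNAP'")
  assert_that(cfg$hallmark_lengths[["vRNAP"]] >= 2600,
              "invalid config field 'hallmark_lengths': polymerase-role family must be >= 2,600 aa")
  assert_that(cfg$within_family_identity > 0.5 && cfg$within_family_identity <= 1,
              "invalid config field 'within_family_identity': must be in (0.5, 1]")
  assert_that(length(cfg$completeness_mix) == cfg$n_hallmark_families &&
                all(cfg$completeness_mix >= 0) &&
                sum(cfg$completeness_mix) == cfg$n_metagenome_contigs,
              "invalid config field 'completeness_mix': counts per 1..n_hallmark_families must sum to n_metagenome_contigs")
  if (cfg$n_host_contigs > 0) {
    assert_that(cfg$host_contig_length > 100000,
                "invalid config field 'host_contig_length': must exceed 100,000 bp")
    assert_that(cfg$provirus_length < cfg$host_contig_length,
                "invalid config field 'provirus_length': must be smaller than host_contig_length")
    assert_that(cfg$provirus_length > 0,
                "invalid config field 'provirus_length': must be positive")
  }
  assert_that(cfg$spacer_length >= 20,
              "invalid config field 'spacer_length': must be >= 20 bp")
  assert_that(length(cfg$habitats) >= 1,
              "invalid config field 'habitats': at least one label required")
  assert_that(length(cfg$amg_plant_rates) == 0 ||
                (!is.null(names(cfg$amg_plant_rates)) &&
                   all(cfg$amg_plant_rates >= 0)),
              "invalid config field 'amg_plant_rates': must be a named non-negative vector")
  assert_that(cfg$n_accessory_families >=
                length(cfg$amg_plant_rates) + 2,
              "invalid config field 'n_accessory_families': need at least one family per AMG category plus integrase and DGR families")
  invisible(cfg)
}

MOTIF_OFFSETS_FIXED <- c(0L, 2L, 3L, 7L)  # E . D G . . . G
MOTIF_RESIDUES <- c("E", "D", "G", "G")

#' @noRd
plant_motif <- function(chars, pos) {
  chars[pos + MOTIF_OFFSETS_FIXED] <- MOTIF_RESIDUES
  chars
}

# Deterministically destroy every E.DG...G occurrence in a sequence.
#' @noRd
scrub_motif <- function(seq) {
  repeat {
    hits <- motif_scan(seq, "ExDGxxxG")
    if (length(hits) == 0) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[hits[1] + 3] <- "P"  # break the first invariant G
    seq <- paste(chars, collapse = "")
  }
}

#' @noRd
make_family_consensuses <- function(cfg) {
  fam <- list()
  # hallmark families; the polymerase carries the motif at a fixed site
  for (i in seq_len(cfg$n_hallmark_families)) {
    name <- names(cfg$hallmark_lengths)[i]
    len <- cfg$hallmark_lengths[[i]]
    chars <- strsplit(random_protein(len), "", fixed = TRUE)[[1]]
    frozen <- 1L
    if (name == "vRNAP") {
      pos <- floor(len * 0.6)
      chars <- plant_motif(chars, pos)
      frozen <- c(1L, pos + MOTIF_OFFSETS_FIXED)
    }
    fam[[name]] <- list(family_id = name, role = "hallmark",
                        category = NA_character_,
                        consensus = paste(chars, collapse = ""),
                        frozen = frozen)
  }
  # accessory families: one per AMG category, dedicated integrase and DGR,
  # remainder structural
  cats <- names(cfg$amg_plant_rates)
  n_struct <- cfg$n_accessory_families - length(cats) - 2
  acc_cats <- c(cats, "integrase", "DGR", rep("structural", n_struct))
  for (j in seq_along(acc_cats)) {
    id <- sprintf("ACC%02d", j)
    len <- sample(150:450, 1)
    fam[[id]] <- list(family_id = id, role = "accessory",
                      category = acc_cats[j],
                      consensus = scrub_motif(random_protein(len)),
                      frozen = 1L)
  }
  fam
}

#' @noRd
draw_member <- function(fam, identity) {
  s <- mutate_protein(fam$consensus, identity, frozen = fam$frozen)
  if (fam$role != "hallmark" || fam$family_id != "vRNAP") s <- scrub_motif(s)
  s
}

# Assemble a genome from an ordered gene plan (tibble: family_id, sequence).
# All genes are placed on the forward strand with 20-120 bp intergenic
# spacers; coordinates are 0-based half-open and include the stop codon.
#' @noRd
assemble_genome <- function(genome_id, plan) {
  pieces <- character(0)
  offset <- 0L
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    spacer <- random_dna(sample(20:120, 1))
    pieces <- c(pieces, spacer)
    offset <- offset + nchar(spacer)
    dna <- protein_to_dna(plan$sequence[i])
    rows[[i]] <- tibble::tibble(
      protein_id = sprintf("%s_p%02d", genome_id, i),
      genome_id = genome_id,
      family_id = plan$family_id[i],
      start = offset, end = offset + nchar(dna), strand = "+",
      sequence = plan$sequence[i])
    pieces <- c(pieces, dna)
    offset <- offset + nchar(dna)
  }
  pieces <- c(pieces, random_dna(sample(20:120, 1)))
  list(dna = paste(pieces, collapse = ""), proteins = dplyr::bind_rows(rows))
}

#' @noRd
plan_viral_genome <- function(cfg, fams, hallmark_types,
                              duplicated_families = character(0),
                              with_lysogeny = FALSE) {
  plan <- list()
  for (h in hallmark_types) {
    plan[[length(plan) + 1]] <- tibble::tibble(
      family_id = h, sequence = draw_member(fams[[h]], cfg$within_family_identity))
  }
  for (d in duplicated_families) {
    plan[[length(plan) + 1]] <- tibble::tibble(
      family_id = d, sequence = draw_member(fams[[d]], cfg$within_family_identity))
  }
  acc_ids <- names(fams)[vapply(fams, function(f) f$role == "accessory",
                                logical(1))]
  # lysogeny markers sit between the hallmark block and the accessory tail
  # (interior placement, like an integration module)
  if (with_lysogeny) {
    for (lys in c("integrase", "DGR")) {
      lid <- acc_ids[vapply(fams[acc_ids],
                            function(f) identical(f$category, lys),
                            logical(1))][1]
      plan[[length(plan) + 1]] <- tibble::tibble(
        family_id = lid,
        sequence = draw_member(fams[[lid]], cfg$within_family_identity))
    }
  }
  struct_ids <- acc_ids[vapply(fams[acc_ids],
                               function(f) f$category == "structural",
                               logical(1))]
  for (sid in struct_ids) {
    if (stats::runif(1) < 0.45) {
      plan[[length(plan) + 1]] <- tibble::tibble(
        family_id = sid,
        sequence = draw_member(fams[[sid]], cfg$within_family_identity))
    }
  }
  amg_cats <- character(0)
  for (cat in names(cfg$amg_plant_rates)) {
    cat_ids <- acc_ids[vapply(fams[acc_ids],
                              function(f) identical(f$category, cat),
                              logical(1))]
    n <- stats::rpois(1, cfg$amg_plant_rates[[cat]])
    if (n > 0 && length(cat_ids) > 0) {
      picks <- sample(cat_ids, n, replace = TRUE)
      for (p in picks) {
        plan[[length(plan) + 1]] <- tibble::tibble(
          family_id = p,
          sequence = draw_member(fams[[p]], cfg$within_family_identity))
        amg_cats <- c(amg_cats, cat)
      }
    }
  }
  list(plan = dplyr::bind_rows(plan), amg_categories = amg_cats)
}

#' Generate a synthetic viral/host community with ground truth
#'
#' Deterministically builds the full community described by `config`:
#' reference genomes, metagenome contigs with controlled hallmark
#' completeness, motif-free decoys, chimeric contigs, host contigs with
#' embedded proviruses, and CRISPR spacers. Identical `config` (including
#' its seed) always reproduces byte-identical outputs.
#'
#' @param config A [community_config()] object.
#' @param outdir Optional directory; when given, FASTA/TSV outputs are
#'   written there (`references.fna`, `reference_proteins.faa`,
#'   `contigs.fna`, `hosts.fna`, `spacers.fna`, `spacers.tsv`,
#'   `metadata.tsv`, `truth.tsv`, `family_truth.tsv`).
#' @return A `community` object: list with `config`, `families` (tibble of
#'   family truth incl. consensus), `reference_proteins` (tibble of planted
#'   ORFs), named character vectors `references`, `contigs`, `hosts`,
#'   `spacers` tibble, `metadata` tibble, `truth` tibble, and `paths` when
#'   `outdir` was given.
#' @export
generate_community <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "community_config"))
  cfg <- config
  fams <- with_stream(cfg$seed, "families", make_family_consensuses(cfg))
  hallmarks <- names(cfg$hallmark_lengths)

  truth <- list(); meta <- list()
  references <- character(0); contigs <- character(0); hosts <- character(0)
  ref_proteins <- list()

  habitat_of <- function(id) cfg$habitats[
    1 + (sum(utf8ToInt(id)) %% length(cfg$habitats))]

  # --- reference genomes ---------------------------------------------------
  with_stream(cfg$seed, "references", {
    for (i in seq_len(cfg$n_reference_genomes)) {
      gid <- sprintf("REF%03d", i)
      # a minority of isolates are temperate and carry the integration
      # module (integrase + DGR), as in real reference collections
      pg <- plan_viral_genome(cfg, fams, hallmarks,
                              with_lysogeny = stats::runif(1) < 0.25)
      g <- assemble_genome(gid, pg$plan)
      references[[gid]] <- g$dna
      ref_proteins[[gid]] <- g$proteins
      truth[[gid]] <- tibble::tibble(
        contig_id = gid, true_class = "reference",
        n_hallmark_types = length(hallmarks),
        planted_hallmark_types = paste(hallmarks, collapse = ","),
        provirus_start = NA_integer_, provirus_end = NA_integer_,
        spacer_sources = NA_character_, habitat = habitat_of(gid),
        amg_categories = paste(pg$amg_categories, collapse = ","),
        duplicated_families = "")
    }
  })
  ref_proteins <- dplyr::bind_rows(ref_proteins)

  # guard: no accessory family may be present in every reference genome,
  # otherwise it would masquerade as an extra hallmark/core family
  if (cfg$n_reference_genomes > 0) {
    pres <- ref_proteins |>
      dplyr::filter(!.data$family_id %in% hallmarks) |>
      dplyr::distinct(.data$family_id, .data$genome_id) |>
      dplyr::count(.data$family_id)
    ubiquitous <- pres$family_id[pres$n >= cfg$n_reference_genomes]
    if (length(ubiquitous) > 0) {
      last_g <- max(names(references))
      drop <- ref_proteins$genome_id == last_g &
        ref_proteins$family_id %in% ubiquitous
      dropped <- ref_proteins[drop, ]
      ref_proteins <- ref_proteins[!drop, ]
      # excise the dropped genes from the emitted genome sequence
      if (nrow(dropped) > 0) {
        seq <- references[[last_g]]
        for (k in order(dropped$start, decreasing = TRUE)) {
          seq <- paste0(substr(seq, 1, dropped$start[k]),
                        substr(seq, dropped$end[k] + 1, nchar(seq)))
        }
        references[[last_g]] <- seq
        # recompute coordinates of the remaining genes by locating each
        # gene's unique fixed-codon DNA in the shortened genome
        keep <- ref_proteins$genome_id == last_g
        for (k in which(keep)) {
          dna <- protein_to_dna(ref_proteins$sequence[k])
          pos <- regexpr(dna, references[[last_g]], fixed = TRUE)[1]
          ref_proteins$start[k] <- pos - 1L
          ref_proteins$end[k] <- pos - 1L + nchar(dna)
        }
      }
    }
  }

  # --- metagenome contigs (partial completeness, anchored on vRNAP) -------
  with_stream(cfg$seed, "metagenome", {
    idx <- 0
    others <- setdiff(hallmarks, "vRNAP")
    for (k in seq_len(cfg$n_hallmark_families)) {
      for (r in seq_len(cfg$completeness_mix[k])) {
        idx <- idx + 1
        gid <- sprintf("MG%03d", idx)
        types <- c("vRNAP", if (k > 1) sample(others, k - 1))
        types <- hallmarks[hallmarks %in% types]  # canonical order
        pg <- plan_viral_genome(cfg, fams, types)
        g <- assemble_genome(gid, pg$plan)
        contigs[[gid]] <- g$dna
        truth[[gid]] <- tibble::tibble(
          contig_id = gid,
          true_class = if (k == cfg$n_hallmark_families) "HQ" else
            sprintf("%d-core", k),
          n_hallmark_types = k,
          planted_hallmark_types = paste(types, collapse = ","),
          provirus_start = NA_integer_, provirus_end = NA_integer_,
          spacer_sources = NA_character_, habitat = habitat_of(gid),
          amg_categories = paste(pg$amg_categories, collapse = ","),
          duplicated_families = "")
      }
    }
  })

  # --- decoys: related, motif-free polymerase ------------------------------
  with_stream(cfg$seed, "decoys", {
    if (cfg$n_decoys > 0) {
      vr <- fams[["vRNAP"]]
      decoy_cons <- mutate_protein(vr$consensus, 0.65, frozen = 1L)
      decoy_cons <- scrub_motif(decoy_cons)
      decoy_fam <- list(family_id = "decoyPol", role = "decoy",
                        category = NA_character_,
                        consensus = decoy_cons, frozen = 1L)
      for (i in seq_len(cfg$n_decoys)) {
        gid <- sprintf("DEC%03d", i)
        plan <- tibble::tibble(family_id = "decoyPol",
                               sequence = draw_member(decoy_fam,
                                                      cfg$within_family_identity))
        g <- assemble_genome(gid, plan)
        contigs[[gid]] <- g$dna
        truth[[gid]] <- tibble::tibble(
          contig_id = gid, true_class = "decoy", n_hallmark_types = 0L,
          planted_hallmark_types = "",
          provirus_start = NA_integer_, provirus_end = NA_integer_,
          spacer_sources = NA_character_, habitat = habitat_of(gid),
          amg_categories = "", duplicated_families = "")
      }
    }
  })

  # --- chimeras: all hallmark types, duplicated copies ---------------------
  with_stream(cfg$seed, "chimeras", {
    for (i in seq_len(cfg$n_chimeras)) {
      gid <- sprintf("CHI%03d", i)
      dup <- sample(hallmarks, sample(1:2, 1))
      pg <- plan_viral_genome(cfg, fams, hallmarks, duplicated_families = dup)
      g <- assemble_genome(gid, pg$plan)
      contigs[[gid]] <- g$dna
      truth[[gid]] <- tibble::tibble(
        contig_id = gid, true_class = "chimera",
        n_hallmark_types = length(hallmarks),
        planted_hallmark_types = paste(hallmarks, collapse = ","),
        provirus_start = NA_integer_, provirus_end = NA_integer_,
        spacer_sources = NA_character_, habitat = habitat_of(gid),
        amg_categories = paste(pg$amg_categories, collapse = ","),
        duplicated_families = paste(dup, collapse = ","))
    }
  })

  # --- host contigs with embedded provirus ---------------------------------
  host_taxa <- character(0)
  provirus_donors <- character(0)
  with_stream(cfg$seed, "hosts", {
    for (i in seq_len(cfg$n_host_contigs)) {
      gid <- sprintf("HOST%03d", i)
      taxon <- sprintf("Bacteria;Pseudomonadota;Host_taxon_%02d", i)
      host_taxa[[gid]] <- taxon
      pg <- plan_viral_genome(cfg, fams, hallmarks, with_lysogeny = TRUE)
      donor <- assemble_genome(sprintf("%s_provirus", gid), pg$plan)
      assert_that(nchar(donor$dna) <= cfg$provirus_length,
                  "invalid config field 'provirus_length': smaller than the generated provirus donor genome; increase it")
      # host backbone: unrelated ~300-aa genes separated by short spacers
      target_backbone <- cfg$host_contig_length - nchar(donor$dna)
      backbone_plan <- list()
      est <- 0
      j <- 0
      while (est < target_backbone) {
        j <- j + 1
        p <- random_protein(sample(220:420, 1))
        backbone_plan[[j]] <- tibble::tibble(
          family_id = sprintf("hostgene_%s_%03d", gid, j), sequence = p)
        est <- est + nchar(p) * 3 + 75
      }
      backbone_plan <- dplyr::bind_rows(backbone_plan)
      insert_after <- sample(seq_len(nrow(backbone_plan) - 1), 1)
      left <- assemble_genome(gid, backbone_plan[seq_len(insert_after), ])
      right <- assemble_genome(gid, backbone_plan[-seq_len(insert_after), ])
      pstart <- nchar(left$dna)
      dna <- paste0(left$dna, donor$dna, right$dna)
      hosts[[gid]] <- dna
      provirus_donors[[gid]] <- donor$dna
      truth[[gid]] <- tibble::tibble(
        contig_id = gid, true_class = "host", n_hallmark_types = 0L,
        planted_hallmark_types = "",
        provirus_start = pstart, provirus_end = pstart + nchar(donor$dna),
        spacer_sources = NA_character_, habitat = "host",
        amg_categories = "", duplicated_families = "")
    }
  })

  # --- CRISPR spacers sampled from emitted viral sequences -----------------
  spacers <- list()
  with_stream(cfg$seed, "spacers", {
    # spacers record infections by complete viruses: sample only from
    # reference genomes and full-completeness metagenome contigs, which are
    # exactly the genomes the host-prediction stage screens against
    hq_ids <- names(truth)[vapply(truth, function(t)
      identical(t$true_class, "HQ"), logical(1))]
    viral_pool <- c(references, contigs[hq_ids])
    if (cfg$n_host_contigs > 0 && cfg$n_spacers_per_host > 0 &&
        length(viral_pool) > 0) {
      s_idx <- 0
      for (gid in names(host_taxa)) {
        src_ids <- sample(names(viral_pool),
                          min(2, length(viral_pool)))
        for (k in seq_len(cfg$n_spacers_per_host)) {
          s_idx <- s_idx + 1
          src <- sample(src_ids, 1)
          seq <- viral_pool[[src]]
          pos <- sample(seq_len(nchar(seq) - cfg$spacer_length + 1), 1)
          sp <- substr(seq, pos, pos + cfg$spacer_length - 1)
          strand <- sample(c("+", "-"), 1)
          emitted <- if (strand == "+") sp else revcomp(sp)
          spacers[[s_idx]] <- tibble::tibble(
            spacer_id = sprintf("SP%04d", s_idx),
            host_taxon = host_taxa[[gid]], host_contig_id = gid,
            sequence = emitted, source_contig = src,
            source_start = pos - 1L, source_strand = strand)
        }
      }
    }
  })
  spacers <- if (length(spacers)) dplyr::bind_rows(spacers) else
    tibble::tibble(spacer_id = character(), host_taxon = character(),
                   host_contig_id = character(), sequence = character(),
                   source_contig = character(), source_start = integer(),
                   source_strand = character())

  # record spacer sources on host truth rows
  truth <- dplyr::bind_rows(truth)
  if (nrow(spacers) > 0) {
    src_by_host <- spacers |>
      dplyr::group_by(.data$host_contig_id) |>
      dplyr::summarise(srcs = paste(unique(.data$source_contig),
                                    collapse = ","))
    truth$spacer_sources[match(src_by_host$host_contig_id,
                               truth$contig_id)] <- src_by_host$srcs
  }

  all_seqs <- c(references, contigs, hosts)
  metadata <- tibble::tibble(
    contig_id = names(all_seqs),
    class = truth$true_class[match(names(all_seqs), truth$contig_id)],
    habitat = truth$habitat[match(names(all_seqs), truth$contig_id)],
    length = nchar(unname(all_seqs)))

  families_tbl <- tibble::tibble(
    family_id = vapply(fams, `[[`, "", "family_id", USE.NAMES = FALSE),
    role = vapply(fams, `[[`, "", "role", USE.NAMES = FALSE),
    category = vapply(fams, function(f) f$category %||% NA_character_,
                      NA_character_, USE.NAMES = FALSE),
    consensus = vapply(fams, `[[`, "", "consensus", USE.NAMES = FALSE))

  out <- structure(list(
    config = cfg, families = families_tbl,
    reference_proteins = ref_proteins,
    references = references, contigs = contigs, hosts = hosts,
    provirus_donors = provirus_donors,
    spacers = spacers, metadata = metadata, truth = truth), class = "community")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    if (length(references)) write_fasta(references, p("references.fna"), "dna")
    if (nrow(ref_proteins)) {
      prot <- ref_proteins$sequence
      names(prot) <- ref_proteins$protein_id
      write_fasta(prot, p("reference_proteins.faa"), "aa")
    }
    if (length(contigs)) write_fasta(contigs, p("contigs.fna"), "dna")
    if (length(hosts)) write_fasta(hosts, p("hosts.fna"), "dna")
    if (nrow(spacers)) {
      sp <- spacers$sequence
      names(sp) <- spacers$spacer_id
      write_fasta(sp, p("spacers.fna"), "dna")
      write_tsv_plain(spacers[, c("spacer_id", "host_taxon")],
                      p("spacers.tsv"))
    }
    write_tsv_plain(metadata, p("metadata.tsv"))
    write_tsv_plain(truth, p("truth.tsv"))
    write_tsv_plain(families_tbl[, c("family_id", "role", "category")],
                    p("family_truth.tsv"))
    out$paths <- vapply(c("references.fna", "reference_proteins.faa",
                          "contigs.fna", "hosts.fna", "spacers.fna",
                          "spacers.tsv", "metadata.tsv", "truth.tsv",
                          "family_truth.tsv"), p, "")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a paired alignment with planted covarying columns
#'
#' Test fixture generator for the inter-protein covariance analysis: two
#' alignment blocks whose rows are paired by genome. Each column draws from
#' its own conserved residue distribution (a random 5-residue subset with
#' Dirichlet weights); planted column pairs covary through a fixed residue
#' bijection, broken independently per row with probability `noise`.
#'
#' @param n_rows Number of rows (paired genomes); must be >= 50.
#' @param len_a,len_b Columns in block A and block B.
#' @param planted_pairs List of `c(col_a, col_b)` pairs (1-based within each
#'   block) that covary.
#' @param noise Per-row probability that a planted pair's coupling is broken
#'   (the B-state is redrawn to a residue different from the mapped one).
#' @param seed Integer seed.
#' @return A `paired_msa` object: list with `msa` (character matrix, rows
#'   named by genome), `block_a_cols`, `block_b_cols`, `planted_pairs`,
#'   `noise`.
#' @export
generate_paired_msa <- function(n_rows, len_a, len_b, planted_pairs = list(),
                                noise = 0, seed = 1) {
  assert_that(n_rows >= 50, "n_rows must be >= 50")
  if (length(planted_pairs) > 0) {
    pa <- vapply(planted_pairs, `[`, 0, 1)
    pb <- vapply(planted_pairs, `[`, 0, 2)
    assert_that(all(pa >= 1 & pa <= len_a) && all(pb >= 1 & pb <= len_b),
                "planted column indices out of bounds")
    assert_that(!anyDuplicated(pa) && !anyDuplicated(pb),
                "duplicate planted columns")
  }
  with_stream(seed, "paired_msa", {
    ncol_total <- len_a + len_b
    msa <- matrix("", nrow = n_rows, ncol = ncol_total)
    col_sets <- vector("list", ncol_total)
    for (j in seq_len(ncol_total)) {
      res <- sample(AA_ALPHABET, 5)
      w <- stats::rgamma(5, 1); w <- w / sum(w)
      col_sets[[j]] <- list(res = res, w = w)
      msa[, j] <- sample(res, n_rows, replace = TRUE, prob = w)
    }
    for (pp in planted_pairs) {
      ja <- pp[1]; jb <- len_a + pp[2]
      res_a <- col_sets[[ja]]$res
      res_b <- col_sets[[jb]]$res
      bij <- stats::setNames(sample(res_b), res_a)
      mapped <- unname(bij[msa[, ja]])
      flip <- stats::runif(n_rows) < noise
      redraw <- vapply(which(flip), function(r) {
        sample(setdiff(res_b, mapped[r]), 1)
      }, "")
      mapped[flip] <- redraw
      msa[, jb] <- mapped
    }
    rownames(msa) <- sprintf("g%04d", seq_len(n_rows))
    structure(list(msa = msa, block_a_cols = seq_len(len_a),
                   block_b_cols = len_a + seq_len(len_b),
                   planted_pairs = planted_pairs, noise = noise),
              class = "paired_msa")
  })
}
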