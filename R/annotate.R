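# Functional annotation against a labeled profile library and the
# habitat-normalized AMG tally.

#' Attach annotation labels to a profile
#'
#' @param profile A `hallmark_profile`.
#' @param category Functional category label (controlled vocabulary of the
#'   annotation library).
#' @param pathway Pathway label (optional).
#' @param amg_class AMG class label, `"I"` or `"II"` (optional; carried
#'   from the library metadata, never recomputed).
#' @return The labeled profile.
#' @export
label_profile <- function(profile, category, pathway = NA_character_,
                          amg_class = NA_character_) {
  profile$category <- category
  profile$pathway <- pathway
  profile$amg_class <- amg_class
  profile
}

#' Annotate proteins against a labeled profile library
#'
#' Reports the best-scoring profile hit per protein at E <=
#' `max_evalue` (default 1e-5, the annotation threshold); category,
#' pathway and AMG class are inherited from the profile's labels.
#'
#' @param proteins Tibble with `protein_id`, `genome_id`, `sequence`.
#' @param profile_library List of labeled, calibrated `hallmark_profile`
#'   objects (unlabeled profiles are an error).
#' @param max_evalue Annotation threshold.
#' @return Tibble: `protein_id`, `genome_id`, `family_id`, `category`,
#'   `pathway`, `amg_class`, `evalue`.
#' @export
annotate_profiles <- function(proteins, profile_library, max_evalue = 1e-5) {
  for (p in profile_library) {
    assert_that(!is.null(p$category),
                paste0("profile '", p$family_id, "' is unlabeled"))
  }
  hits <- lapply(profile_library, function(p) {
    h <- search_profile(p, proteins, max_evalue)
    if (nrow(h) == 0) return(NULL)
    h$category <- p$category
    h$pathway <- p$pathway
    h$amg_class <- p$amg_class
    h
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) {
    return(tibble::tibble(protein_id = character(), genome_id = character(),
                          family_id = character(), category = character(),
                          pathway = character(), amg_class = character(),
                          evalue = double()))
  }
  hits |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::arrange(.data$evalue, .data$family_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("protein_id", "genome_id", "family_id", "category",
                  "pathway", "amg_class", "evalue")
}

#' Habitat-normalized AMG tally
#'
#' For every functional category and genome group, the cell is the total
#' number of annotation detections in that (category, group) divided by
#' the number of genomes in the group — mean detections per genome. A
#' group with genomes but no detections in a category yields 0; a group
#' with no genomes yields NA. Full precision is retained; use
#' `round(x, 2)` for report formatting.
#'
#' @param annotations Tibble from [annotate_profiles()] (or imported with
#'   [read_annotations_tsv()]); needs `genome_id` and `category`.
#' @param genome_groups Tibble with `genome_id` and `group` (one row per
#'   genome-group membership; a genome may belong to several groups, e.g.
#'   a habitat and a source class).
#' @return Tibble: `category`, `group`, `n_detections`, `n_genomes`,
#'   `mean_detections`.
#' @export
amg_tally <- function(annotations, genome_groups) {
  annotations <- tibble::as_tibble(annotations)
  genome_groups <- tibble::as_tibble(genome_groups)
  annotated_genomes <- unique(annotations$genome_id)
  missing <- setdiff(annotated_genomes, genome_groups$genome_id)
  assert_that(length(missing) == 0,
              paste0("annotated genomes without a group label: ",
                     paste(missing, collapse = ", ")))
  group_sizes <- genome_groups |>
    dplyr::distinct(.data$group, .data$genome_id) |>
    dplyr::count(.data$group, name = "n_genomes")
  detections <- annotations |>
    dplyr::inner_join(genome_groups, by = "genome_id",
                      relationship = "many-to-many") |>
    dplyr::count(.data$category, .data$group, name = "n_detections")
  grid <- tidyr::expand_grid(category = unique(annotations$category),
                             group = group_sizes$group)
  grid |>
    dplyr::left_join(detections, by = c("category", "group")) |>
    dplyr::left_join(group_sizes, by = "group") |>
    dplyr::mutate(
      n_detections = dplyr::coalesce(.data$n_detections, 0L),
      mean_detections = ifelse(.data$n_genomes > 0,
                               .data$n_detections / .data$n_genomes,
                               NA_real_))
}

#' Pivot an AMG tally into the report layout (categories x groups)
#'
#' @param tally Tibble from [amg_tally()].
#' @param digits Rounding for display (default 2).
#' @return Wide tibble, one row per category.
#' @export
amg_tally_table <- function(tally, digits = 2) {
  tally |>
    dplyr::mutate(cell = round(.data$mean_detections, digits)) |>
    dplyr::select("category", "group", "cell") |>
    tidyr::pivot_wider(names_from = "group", values_from = "cell")
}

#' Import externally computed annotations
#'
#' Accepts a TSV with at least `protein_id`, `genome_id`, `category`
#' columns (e.g. converted from a study's supplementary annotation
#' tables).
#'
#' @param path TSV file.
#' @return Tibble of annotations.
#' @export
read_annotations_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_that(all(c("protein_id", "genome_id", "category") %in% names(out)),
              "annotation TSV needs protein_id, genome_id, category columns")
  out
}
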