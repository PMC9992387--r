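# Counts-mode analysis: diet-breadth, prey-selection and age-profile
# statistics computed from pre-aggregated per-unit NISP/MNI tables of
# the kind published in site reports, when specimen-level records are
# not available.

#' Bundled Fumane Protoaurignacian count tables
#'
#' Per-unit, per-taxon NISP and MNI counts (with age-class breakdowns
#' and habitat/rank attributes) for the six determined ungulate species
#' of the Fumane Cave Protoaurignacian units A2-A1 and D3, distilled
#' from the published summary tables, together with the published unit
#' subtotals (identified NISP, MNE, MNI and grand record totals).
#'
#' @return A list with tibbles `counts` and `totals`.
#' @export
fumane_counts <- function() {
  read_unit_counts(
    system.file("extdata", "fumane_unit_counts.csv", package = "osteokit"),
    system.file("extdata", "fumane_unit_totals.csv", package = "osteokit")
  )
}

#' Read pre-aggregated unit count tables
#'
#' @param counts_path CSV with columns `unit`, `taxon`, `nisp`, `mni`,
#'   `mni_F` .. `mni_S`, `habitat`, `rank`.
#' @param totals_path Optional CSV with columns `unit`,
#'   `nisp_subtotal`, `mne_subtotal`, `mni_subtotal`, `nr_grand`.
#' @return A list with tibbles `counts` and `totals` (`NULL` when no
#'   totals file is given).
#' @export
read_unit_counts <- function(counts_path, totals_path = NULL) {
  counts <- readr::read_csv(counts_path, col_types = readr::cols(
    unit = readr::col_character(), taxon = readr::col_character(),
    habitat = readr::col_character(), rank = readr::col_character(),
    .default = readr::col_integer()
  ), progress = FALSE)
  bad <- setdiff(unique(counts$habitat), habitats())
  if (length(bad) > 0) stop("unknown habitat: ", bad[1], call. = FALSE)
  bad <- setdiff(unique(counts$rank), prey_ranks())
  if (length(bad) > 0) stop("unknown rank: ", bad[1], call. = FALSE)
  totals <- NULL
  if (!is.null(totals_path) && nzchar(totals_path)) {
    totals <- readr::read_csv(totals_path, col_types = readr::cols(
      unit = readr::col_character(), .default = readr::col_integer()
    ), progress = FALSE)
  }
  list(counts = counts, totals = totals)
}

group_ratio <- function(values, group, a, b) {
  na <- sum(values[group == a]); nb <- sum(values[group == b])
  if (nb == 0) stop("denominator group has zero count", call. = FALSE)
  list(ratio = na / nb, a = na, b = nb, pct_a = 100 * na / (na + nb))
}

#' Summary statistics from pre-aggregated unit counts
#'
#' Computes, for every unit in a counts table: the inverse Simpson
#' diet breadth on both NISP and MNI bases, the juvenile-to-adult
#' ratio and prime-age share from the summed age breakdown, the
#' mountain-versus-plain hunting-preference ratio on both bases, and
#' the mountain share of NISP and MNI. When unit totals are supplied
#' it adds the assemblage-wide identified-to-taxa percentage and the
#' combined MNE and MNI.
#'
#' @param x A list with `counts` and optional `totals`, as returned by
#'   [read_unit_counts()] or [fumane_counts()].
#' @return A list with `by_unit` (tibble, one row per unit) and
#'   `overall` (tibble or `NULL`).
#' @export
counts_summary <- function(x) {
  counts <- x$counts
  rows <- lapply(split(counts, counts$unit), function(d) {
    prof <- age_profile(F = sum(d$mni_F), J = sum(d$mni_J), SAd = sum(d$mni_SAd),
                        Ad = sum(d$mni_Ad), S = sum(d$mni_S))
    hab_nisp <- group_ratio(d$nisp, d$habitat, "mountain", "plain")
    hab_mni <- group_ratio(d$mni, d$habitat, "mountain", "plain")
    rank_nisp <- group_ratio(d$nisp, d$rank, "high", "low")
    tibble::tibble(
      unit = d$unit[1],
      n_taxa = nrow(d),
      inv_simpson_nisp = inverse_simpson(d$nisp),
      inv_simpson_mni = inverse_simpson(d$mni),
      juvenile_adult_ratio = juvenile_adult_ratio(prof),
      prime_age_pct = prime_age_share(prof),
      hunting_pref_nisp = hab_nisp$ratio,
      hunting_pref_mni = hab_mni$ratio,
      mountain_nisp_pct = hab_nisp$pct_a,
      mountain_mni_pct = hab_mni$pct_a,
      rank_ratio_nisp = rank_nisp$ratio
    )
  })
  by_unit <- dplyr::bind_rows(rows)
  overall <- NULL
  if (!is.null(x$totals)) {
    t <- x$totals
    overall <- tibble::tibble(
      combined_nisp = sum(t$nisp_subtotal),
      combined_mne = sum(t$mne_subtotal),
      combined_mni = sum(t$mni_subtotal),
      nr_grand = sum(t$nr_grand)
    )
    overall$identified_pct <- 100 * overall$combined_nisp / overall$nr_grand
  }
  list(by_unit = by_unit, overall = overall)
}
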