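# Taphonomic summaries: butchery marks, burning stages, biostratinomic
# and diagenetic modification tables.

record_has_kind <- function(records, kinds) {
  vapply(records$surface_mods, function(m) any(names(m) %in% kinds), logical(1))
}

# Taxon or size-class row label used by the butchery table.
row_label <- function(records) {
  ifelse(!is.na(records$taxon), records$taxon,
         ifelse(!is.na(records$size_class),
                paste0("size ", records$size_class), "non-identifiable"))
}

#' Butchery-mark summary for one unit
#'
#' Per taxon (or body-size class) row: number of records, counts of
#' records with percussion marks only (PM), cut marks only (CM,
#' including scraping), both (CM+PM), the butchery-mark percentage
#' %BM = 100 (PM + CM + CM+PM) / NR of the row, and retoucher counts.
#' A record counts once: records carrying both mark families fall in
#' CM+PM only.
#'
#' @param records Validated specimen tibble.
#' @param unit Unit label.
#' @return A tibble with one row per taxon/size group present plus a
#'   `Total` row.
#' @export
butchery_summary <- function(records, unit) {
  recs <- unit_records(records, unit)
  if (nrow(recs) == 0) {
    return(tibble::tibble(group = character(0), nr = integer(0), pm = integer(0),
                          cm = integer(0), cm_pm = integer(0), pct_bm = numeric(0),
                          retouchers = integer(0)))
  }
  has_cm <- record_has_kind(recs, cut_mark_kinds())
  has_pm <- record_has_kind(recs, percussion_mark_kinds())
  df <- tibble::tibble(
    group = row_label(recs),
    cm = has_cm & !has_pm,
    pm = has_pm & !has_cm,
    both = has_cm & has_pm,
    ret = recs$is_retoucher
  )
  summarise_rows <- function(d, label) {
    tibble::tibble(
      group = label, nr = nrow(d),
      pm = sum(d$pm), cm = sum(d$cm), cm_pm = sum(d$both),
      pct_bm = 100 * (sum(d$pm) + sum(d$cm) + sum(d$both)) / nrow(d),
      retouchers = sum(d$ret)
    )
  }
  out <- dplyr::bind_rows(lapply(split(df, df$group), function(d) {
    summarise_rows(d, d$group[1])
  }))
  dplyr::bind_rows(out, summarise_rows(df, "Total"))
}

#' Burning-stage histogram for one unit
#'
#' Counts records per thermoalteration colour code 0 (unburned) to 5
#' (calcined). A record with several colourations is counted once under
#' its highest code, so the histogram sums to the unit's record count.
#'
#' @param records Validated specimen tibble.
#' @param unit Unit label.
#' @return A list with `histogram` (tibble: `code`, `nr`, `pct_nr`) and
#'   `burned_fraction` (share of records with highest code > 0).
#' @export
burn_profile <- function(records, unit) {
  recs <- unit_records(records, unit)
  top <- vapply(recs$burn_code, function(b) max(b), integer(1))
  counts <- vapply(burn_codes(), function(k) sum(top == k), integer(1))
  n <- nrow(recs)
  hist <- tibble::tibble(
    code = burn_codes(),
    nr = counts,
    pct_nr = if (n > 0) 100 * counts / n else rep(NA_real_, 6)
  )
  list(histogram = hist,
       burned_fraction = if (n > 0) sum(top > 0) / n else NA_real_)
}

# Grouping of mark kinds into summary categories for the modification
# table; carnivore kinds are reported jointly (detail stays in logs).
modification_category <- function(kind) {
  dplyr::case_when(
    kind %in% carnivore_mark_kinds() ~ "carnivore marks",
    kind == "weathering" ~ "weathering",
    kind == "trampling" ~ "trampling",
    kind == "root_etching" ~ "root marks",
    kind == "manganese" ~ "manganese staining",
    kind == "concretion" ~ "concretions",
    kind == "water_dissolution" ~ "water dissolution",
    kind == "iron_stain" ~ "iron mineral staining",
    .default = NA_character_
  )
}

#' Biostratinomic and diagenetic modification table
#'
#' One row per alteration category present in the unit, with the number
#' of records bearing the alteration and its percentage of the unit's
#' grand total. Carnivore mark kinds (pits, scores, punctures,
#' furrowing, digestion) are pooled as "carnivore marks"; kind-level
#' counts are logged when logging is on.
#'
#' @param records Validated specimen tibble.
#' @param unit Unit label.
#' @return A tibble with columns `category`, `nr`, `pct_nr`; zero rows
#'   when no alteration is present.
#' @export
modification_table <- function(records, unit) {
  recs <- unit_records(records, unit)
  n <- nrow(recs)
  cats <- unique(stats::na.omit(modification_category(mark_kinds())))
  rows <- list()
  for (cat in cats) {
    kinds <- mark_kinds()[modification_category(mark_kinds()) == cat]
    kinds <- kinds[!is.na(kinds)]
    hit <- record_has_kind(recs, kinds)
    if (sum(hit) > 0) {
      for (k in kinds) {
        nk <- sum(record_has_kind(recs, k))
        if (nk > 0) ok_log("modification_table", "%s / %s: %d records", cat, k, nk)
      }
      rows[[cat]] <- tibble::tibble(category = cat, nr = sum(hit),
                                    pct_nr = 100 * sum(hit) / n)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(category = character(0), nr = integer(0),
                          pct_nr = numeric(0)))
  }
  dplyr::bind_rows(rows)
}
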