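# Specimen records: one row per bone fragment, with list-columns for
# anatomical portion codes, surface modifications and burn colourations.

specimen_columns <- c(
  "record_id", "unit", "square", "taxon", "size_class", "element",
  "portion_codes", "side", "age_class", "surface_mods", "burn_code",
  "breakage", "is_retoucher"
)

#' Build a specimen-record tibble
#'
#' Constructs (and validates) the canonical specimen table used by all
#' analysis stages. Each row is one bone fragment. `portion_codes`,
#' `surface_mods` and `burn_code` are list-columns: a fragment may carry
#' several anatomical portion codes (subsets of 1--20), several kinds of
#' surface modification (named integer vectors of counts), and several
#' burn colouration codes (subsets of 0--5).
#'
#' A record is identified either by `taxon` (a Linnean or pooled label)
#' or by `size_class` (1--5 body-size category), never both; records
#' with neither are counted only in assemblage totals.
#'
#' @param record_id Character identifiers, unique within the table.
#' @param unit Archaeological unit label (e.g. `"A2-A1"`).
#' @param square Excavation square, optional (`NA` allowed).
#' @param taxon Taxon label or `NA`.
#' @param size_class Integer 1--5 or `NA`.
#' @param element Skeletal element name or `NA`.
#' @param portion_codes List of integer vectors, each a subset of 1--20.
#' @param side One of `"left"`, `"right"`, `"indeterminate"`.
#' @param age_class One of `F`, `J`, `SAd`, `Ad`, `S`, `indeterminate`.
#' @param surface_mods List of named integer vectors (kind -> count).
#' @param burn_code List of integer vectors, subsets of 0--5.
#' @param breakage One of `"green"`, `"dry"`, `"indeterminate"`.
#' @param is_retoucher Logical.
#' @return A validated tibble with one row per specimen.
#' @export
specimen_records <- function(record_id, unit, square = NA_character_,
                             taxon = NA_character_, size_class = NA_integer_,
                             element = NA_character_,
                             portion_codes = list(integer(0)),
                             side = "indeterminate",
                             age_class = "indeterminate",
                             surface_mods = list(stats::setNames(integer(0), character(0))),
                             burn_code = list(0L),
                             breakage = "indeterminate",
                             is_retoucher = FALSE) {
  x <- tibble::tibble(
    record_id = as.character(record_id),
    unit = as.character(unit),
    square = as.character(square),
    taxon = as.character(taxon),
    size_class = as.integer(size_class),
    element = as.character(element),
    portion_codes = portion_codes,
    side = as.character(side),
    age_class = as.character(age_class),
    surface_mods = surface_mods,
    burn_code = burn_code,
    breakage = as.character(breakage),
    is_retoucher = as.logical(is_retoucher)
  )
  validate_specimens(x)
}

#' Validate a specimen table
#'
#' Checks every type invariant of the specimen schema and fails with a
#' row-numbered diagnostic naming the offending field. Empty-string
#' taxon/element entries are normalised to `NA`.
#'
#' @param x A tibble with the specimen columns.
#' @return `x`, normalised, invisibly valid.
#' @export
validate_specimens <- function(x) {
  missing_cols <- setdiff(specimen_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("specimen table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x$taxon[!is.na(x$taxon) & !nzchar(trimws(x$taxon))] <- NA_character_
  x$element[!is.na(x$element) & !nzchar(trimws(x$element))] <- NA_character_

  for (i in seq_len(nrow(x))) {
    if (is.na(x$unit[i]) || !nzchar(x$unit[i])) {
      stop_field(i, "unit", "must be a non-empty label")
    }
    if (!is.na(x$taxon[i]) && !is.na(x$size_class[i])) {
      stop_field(i, "taxon", "record carries both a taxon and a size_class")
    }
    if (!is.na(x$size_class[i]) && !(x$size_class[i] %in% 1:5)) {
      stop_field(i, "size_class", "must be an integer in 1..5")
    }
    pc <- x$portion_codes[[i]]
    if (length(pc) > 0) {
      if (is.na(x$element[i])) {
        stop_field(i, "portion_codes", "portion codes given without an element")
      }
      if (!all(pc %in% portion_code_range())) {
        stop_field(i, "portion_codes", "codes must lie in 1..20")
      }
      if (anyDuplicated(pc)) {
        stop_field(i, "portion_codes", "codes must be a set (no repeats)")
      }
    }
    if (!(x$side[i] %in% sides())) {
      stop_field(i, "side", sprintf("unknown side '%s'", x$side[i]))
    }
    if (!(x$age_class[i] %in% age_classes())) {
      stop_field(i, "age_class", sprintf("unknown age class '%s'", x$age_class[i]))
    }
    sm <- x$surface_mods[[i]]
    if (length(sm) > 0) {
      bad <- setdiff(names(sm), mark_kinds())
      if (length(bad) > 0) {
        stop_field(i, "surface_mods", sprintf("unknown mark kind '%s'", bad[1]))
      }
      if (any(sm < 1)) stop_field(i, "surface_mods", "mark counts must be >= 1")
    }
    bc <- x$burn_code[[i]]
    if (length(bc) == 0) stop_field(i, "burn_code", "at least one code required")
    if (!all(bc %in% burn_codes())) {
      stop_field(i, "burn_code", "codes must lie in 0..5")
    }
    if (!(x$breakage[i] %in% breakage_states())) {
      stop_field(i, "breakage", sprintf("unknown breakage state '%s'", x$breakage[i]))
    }
    if (is.na(x$is_retoucher[i])) {
      stop_field(i, "is_retoucher", "must be TRUE or FALSE")
    }
  }
  x
}

#' Read specimen records from delimited text
#'
#' Parses a comma-separated specimen file (UTF-8, `.` decimal separator;
#' in-cell lists use `;`, surface modifications use `kind:count` pairs)
#' and validates every row. Row order is preserved.
#'
#' @param path Path to a specimens CSV file.
#' @return A validated specimen tibble (empty if the file holds only a
#'   header).
#' @export
read_specimens <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(specimen_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("specimen file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  if (n == 0) {
    out <- specimen_records(character(0), character(0),
                            portion_codes = list(), surface_mods = list(),
                            burn_code = list())
    return(out)
  }
  pcs <- vector("list", n)
  sms <- vector("list", n)
  bcs <- vector("list", n)
  for (i in seq_len(n)) {
    pc <- parse_int_list(raw$portion_codes[i] %||% NA_character_)
    if (is.null(pc)) stop_field(i, "portion_codes", "not an integer list")
    pcs[[i]] <- pc
    sm <- parse_mark_list(raw$surface_mods[i])
    if (is.null(sm)) stop_field(i, "surface_mods", "not a 'kind:count' list")
    sms[[i]] <- sm
    bc <- parse_int_list(raw$burn_code[i])
    if (is.null(bc)) stop_field(i, "burn_code", "not an integer list")
    if (length(bc) == 0) bc <- 0L
    bcs[[i]] <- bc
  }
  size_class <- suppressWarnings(as.integer(raw$size_class))
  bad_size <- which(!is.na(raw$size_class) & nzchar(trimws(raw$size_class)) & is.na(size_class))
  if (length(bad_size) > 0) stop_field(bad_size[1], "size_class", "not an integer")
  is_ret <- tolower(trimws(raw$is_retoucher)) %in% c("true", "t", "1", "yes")
  is_ret[is.na(raw$is_retoucher) | !nzchar(trimws(raw$is_retoucher))] <- FALSE

  x <- tibble::tibble(
    record_id = raw$record_id,
    unit = raw$unit,
    square = raw$square,
    taxon = raw$taxon,
    size_class = size_class,
    element = raw$element,
    portion_codes = pcs,
    side = ifelse(is.na(raw$side) | !nzchar(trimws(raw$side)),
                  "indeterminate", trimws(raw$side)),
    age_class = ifelse(is.na(raw$age_class) | !nzchar(trimws(raw$age_class)),
                       "indeterminate", trimws(raw$age_class)),
    surface_mods = sms,
    burn_code = bcs,
    breakage = ifelse(is.na(raw$breakage) | !nzchar(trimws(raw$breakage)),
                      "indeterminate", trimws(raw$breakage)),
    is_retoucher = is_ret
  )
  x <- validate_specimens(x)
  ok_log("read_specimens", "%d records from %s", nrow(x), path)
  x
}

#' Write specimen records to delimited text
#'
#' Inverse of [read_specimens()]: `read_specimens(write_specimens(x, f))`
#' returns `x` field-for-field.
#'
#' @param x A validated specimen tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(x, path) {
  x <- validate_specimens(x)
  flat <- tibble::tibble(
    record_id = x$record_id,
    unit = x$unit,
    square = x$square,
    taxon = x$taxon,
    size_class = x$size_class,
    element = x$element,
    portion_codes = vapply(x$portion_codes, format_int_list, character(1)),
    side = x$side,
    age_class = x$age_class,
    surface_mods = vapply(x$surface_mods, format_mark_list, character(1)),
    burn_code = vapply(x$burn_code, format_int_list, character(1)),
    breakage = x$breakage,
    is_retoucher = x$is_retoucher
  )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}
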