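# Skeleton templates: per taxon x element inventory with element counts
# per complete skeleton, skeletal region, maximum bone density, economic
# utility indices and per-age usable meat weights.

template_columns <- c(
  "taxon", "element", "skeleton_count", "region", "density",
  "MGUI", "FUI", "CFUI", "Marrow", "Grease", "UMI",
  "meat_F", "meat_J", "meat_SAd", "meat_Ad", "meat_S",
  "habitat", "rank"
)

#' Build a skeleton template
#'
#' One row per taxon x element. `skeleton_count` is the number of copies
#' of the element in one complete skeleton, `region` classifies it as
#' axial or appendicular, `density` is the element's maximum bone
#' density scaled to (0, 1]. Utility indices and per-age meat weights
#' are optional (`NA` allowed, flagged at read time). `habitat` and
#' `rank` classify the taxon for prey-selection ratios.
#'
#' @param taxon,element Character.
#' @param skeleton_count Integer >= 1.
#' @param region `"axial"` or `"appendicular"`.
#' @param density Real in (0, 1].
#' @param MGUI,FUI,CFUI,Marrow,Grease,UMI Optional utility values (>= 0).
#' @param meat_F,meat_J,meat_SAd,meat_Ad,meat_S Optional usable meat (kg)
#'   for an individual of each age class.
#' @param habitat `"mountain"` or `"plain"` (may be `NA`).
#' @param rank `"high"` or `"low"` (may be `NA`).
#' @return A validated template tibble.
#' @export
skeleton_template <- function(taxon, element, skeleton_count, region, density,
                              MGUI = NA_real_, FUI = NA_real_, CFUI = NA_real_,
                              Marrow = NA_real_, Grease = NA_real_, UMI = NA_real_,
                              meat_F = NA_real_, meat_J = NA_real_,
                              meat_SAd = NA_real_, meat_Ad = NA_real_,
                              meat_S = NA_real_,
                              habitat = NA_character_, rank = NA_character_) {
  x <- tibble::tibble(
    taxon = as.character(taxon), element = as.character(element),
    skeleton_count = as.integer(skeleton_count), region = as.character(region),
    density = as.numeric(density),
    MGUI = as.numeric(MGUI), FUI = as.numeric(FUI), CFUI = as.numeric(CFUI),
    Marrow = as.numeric(Marrow), Grease = as.numeric(Grease), UMI = as.numeric(UMI),
    meat_F = as.numeric(meat_F), meat_J = as.numeric(meat_J),
    meat_SAd = as.numeric(meat_SAd), meat_Ad = as.numeric(meat_Ad),
    meat_S = as.numeric(meat_S),
    habitat = as.character(habitat), rank = as.character(rank)
  )
  validate_template(x)
}

#' Validate a skeleton template
#'
#' Enforces the template invariants: densities in (0, 1], element counts
#' >= 1, a known region for every element, no duplicate taxon x element
#' rows.
#'
#' @param x A template tibble.
#' @return `x` if valid.
#' @export
validate_template <- function(x) {
  missing_cols <- setdiff(template_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("template lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(x[, c("taxon", "element")])
  if (any(dup)) {
    stop("duplicate taxon x element rows: ",
         paste(unique(paste(x$taxon[dup], x$element[dup], sep = "/")), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(x))) {
    if (is.na(x$density[i]) || x$density[i] <= 0 || x$density[i] > 1) {
      stop_field(i, "density", "must lie in (0, 1]")
    }
    if (is.na(x$skeleton_count[i]) || x$skeleton_count[i] < 1) {
      stop_field(i, "skeleton_count", "must be an integer >= 1")
    }
    if (is.na(x$region[i]) || !(x$region[i] %in% regions())) {
      stop_field(i, "region", "must be 'axial' or 'appendicular'")
    }
    if (!is.na(x$habitat[i]) && !(x$habitat[i] %in% habitats())) {
      stop_field(i, "habitat", sprintf("unknown habitat '%s'", x$habitat[i]))
    }
    if (!is.na(x$rank[i]) && !(x$rank[i] %in% prey_ranks())) {
      stop_field(i, "rank", sprintf("unknown rank '%s'", x$rank[i]))
    }
    for (u in utility_indices()) {
      col <- if (u == "Meat") NULL else u
      if (!is.null(col) && !is.na(x[[col]][i]) && x[[col]][i] < 0) {
        stop_field(i, col, "utility values must be >= 0")
      }
    }
  }
  x
}

#' Read a skeleton template from delimited text
#'
#' Missing utility values are allowed; when logging is on the number of
#' incomplete utility cells is reported.
#'
#' @param path Path to a template CSV file.
#' @return A validated template tibble.
#' @export
read_template <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      taxon = readr::col_character(), element = readr::col_character(),
      skeleton_count = readr::col_integer(), region = readr::col_character(),
      habitat = readr::col_character(), rank = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  x <- validate_template(x)
  n_missing <- sum(is.na(x[, c("MGUI", "FUI", "CFUI", "Marrow", "Grease", "UMI")]))
  ok_log("read_template", "%d elements from %s (%d utility cells missing)",
         nrow(x), path, n_missing)
  x
}

#' Write a skeleton template to delimited text
#'
#' @param x A validated template tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_template <- function(x, path) {
  x <- validate_template(x)
  readr::write_csv(x[, template_columns], path, progress = FALSE)
  invisible(path)
}
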