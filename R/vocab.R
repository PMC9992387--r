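# Controlled vocabularies shared by readers, validators and the generator.

#' Controlled vocabularies for specimen records
#'
#' Accessors for the closed sets of values a specimen record may carry:
#' age classes, sides, breakage states, burn codes, surface-modification
#' kinds and skeletal regions. Readers and validators reject values
#' outside these sets.
#'
#' @return A character (or integer, for burn codes and portion codes)
#'   vector of admissible values.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
age_classes <- function() c("F", "J", "SAd", "Ad", "S", "indeterminate")

#' @rdname vocabularies
#' @export
sides <- function() c("left", "right", "indeterminate")

#' @rdname vocabularies
#' @export
breakage_states <- function() c("green", "dry", "indeterminate")

#' @rdname vocabularies
#' @export
burn_codes <- function() 0:5

#' @rdname vocabularies
#' @export
portion_code_range <- function() 1:20

#' @rdname vocabularies
#' @export
mark_kinds <- function() {
  c(
    # anthropogenic
    "cut_skinning", "cut_dismembering", "cut_defleshing", "scrape",
    "percussion_notch", "impact_flake",
    # carnivore
    "carnivore_pit", "carnivore_score", "carnivore_puncture",
    "furrowing", "digestion",
    # biostratinomic / diagenetic
    "trampling", "root_etching", "weathering", "manganese",
    "concretion", "water_dissolution", "iron_stain"
  )
}

#' @rdname vocabularies
#' @export
regions <- function() c("axial", "appendicular")

#' @rdname vocabularies
#' @export
habitats <- function() c("mountain", "plain")

#' @rdname vocabularies
#' @export
prey_ranks <- function() c("high", "low")

#' @rdname vocabularies
#' @export
utility_indices <- function() {
  c("MGUI", "FUI", "CFUI", "Marrow", "Grease", "UMI", "Meat")
}

# Mark kinds grouped by agency; used by the taphonomy summaries.
cut_mark_kinds <- function() {
  c("cut_skinning", "cut_dismembering", "cut_defleshing", "scrape")
}

percussion_mark_kinds <- function() c("percussion_notch", "impact_flake")

carnivore_mark_kinds <- function() {
  c("carnivore_pit", "carnivore_score", "carnivore_puncture",
    "furrowing", "digestion")
}

diagenetic_mark_kinds <- function() {
  c("trampling", "root_etching", "weathering", "manganese",
    "concretion", "water_dissolution", "iron_stain")
}
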