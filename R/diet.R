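# Diet breadth, prey selection, biomass and mortality-profile statistics.

#' Inverse Simpson diversity index
#'
#' With proportions `p_i = n_i / sum(n)`, Simpson's concentration is
#' `D = sum(p_i^2)` and the index returned is `1/D`. Larger values mean
#' a broader diet; `k` equally represented taxa give exactly `k`. The
#' plug-in `sum(p^2)` estimator is used (not the small-sample unbiased
#' variant), which is the convention for NISP/MNI-based diet-breadth
#' work.
#'
#' @param counts Non-negative counts per taxon (named or not).
#' @return `1/D`, a real number in `[1, k]` where `k` is the number of
#'   taxa with non-zero counts.
#' @export
inverse_simpson <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("all counts are zero; diversity undefined", call. = FALSE)
  p <- counts / n
  1 / sum(p^2)
}

#' Age profile of a taxon or assemblage
#'
#' @param F,J,SAd,Ad,S Individual counts per age class
#'   (foetal/neonatal, juvenile, sub-adult, adult, senile).
#' @return A named numeric vector of class counts.
#' @export
age_profile <- function(F = 0, J = 0, SAd = 0, Ad = 0, S = 0) {
  x <- c(F = F, J = J, SAd = SAd, Ad = Ad, S = S)
  if (any(x < 0)) stop("age counts must be non-negative", call. = FALSE)
  x
}

#' Juvenile-to-adult ratio
#'
#' `(F + J + SAd) / (Ad + S)`: the pressure on low-return younger prey.
#' Values near 1 mean juveniles and adults were taken in similar
#' numbers.
#'
#' @param profile An [age_profile()] vector.
#' @return The ratio, a non-negative real.
#' @export
juvenile_adult_ratio <- function(profile) {
  den <- profile[["Ad"]] + profile[["S"]]
  if (den == 0) stop("no adult or senile individuals; ratio undefined", call. = FALSE)
  (profile[["F"]] + profile[["J"]] + profile[["SAd"]]) / den
}

#' Prime-age share of an age profile
#'
#' Fraction (in percent) of individuals that are adult or senile.
#'
#' @param profile An [age_profile()] vector.
#' @return Percentage in `[0, 100]`.
#' @export
prime_age_share <- function(profile) {
  tot <- sum(profile)
  if (tot == 0) stop("empty age profile", call. = FALSE)
  100 * (profile[["Ad"]] + profile[["S"]]) / tot
}

#' Prey-selection ratio
#'
#' The ratio of counts between two prey groups defined by a template
#' attribute: mountain versus plain habitat species, or high- versus
#' low-ranked species. The numerator group is `mountain` (respectively
#' `high`).
#'
#' @param counts Named counts per taxon (NISP or MNI).
#' @param template Skeleton template carrying `habitat` and `rank` per
#'   taxon (any element row works; taxon-level attributes).
#' @param attribute `"habitat"` or `"rank"`.
#' @return A list with `ratio`, plus the group totals `a` (mountain /
#'   high) and `b` (plain / low) and the numerator share `pct_a` in
#'   percent.
#' @export
prey_ratio <- function(counts, template, attribute = c("habitat", "rank")) {
  attribute <- match.arg(attribute)
  groups <- c(habitat = "mountain", rank = "high")[[attribute]]
  other <- c(habitat = "plain", rank = "low")[[attribute]]
  attr_by_taxon <- dplyr::distinct(template[!is.na(template[[attribute]]), ],
                                   .data$taxon, .data[[attribute]])
  lookup <- stats::setNames(attr_by_taxon[[attribute]], attr_by_taxon$taxon)
  known <- names(counts)[names(counts) %in% names(lookup)]
  a <- sum(counts[known][lookup[known] == groups])
  b <- sum(counts[known][lookup[known] == other])
  if (a + b == 0 || length(unique(lookup)) < 2) {
    stop(sprintf("both %s groups must be represented", attribute), call. = FALSE)
  }
  if (b == 0) stop("denominator group has zero count; ratio undefined", call. = FALSE)
  list(ratio = a / b, a = a, b = b, pct_a = 100 * a / (a + b))
}

#' Usable-meat biomass per taxon
#'
#' Multiplies the MNI of each age class by that age class's usable meat
#' weight from the template and sums over ages.
#'
#' @param mni_by_age Named counts per age class (`F`, `J`, `SAd`, `Ad`,
#'   `S`), e.g. an [age_profile()].
#' @param template Skeleton template (meat weights are taxon-level; the
#'   first row of the taxon is used).
#' @param taxon Taxon label.
#' @return Biomass in kg.
#' @export
biomass <- function(mni_by_age, template, taxon) {
  rows <- template[template$taxon == taxon, ]
  if (nrow(rows) == 0) stop(sprintf("taxon '%s' absent from template", taxon),
                            call. = FALSE)
  row <- rows[1, ]
  total <- 0
  for (a in names(mni_by_age)) {
    n <- mni_by_age[[a]]
    if (n == 0) next
    w <- row[[paste0("meat_", a)]]
    if (is.na(w)) {
      stop(sprintf("missing meat weight for %s x %s", taxon, a), call. = FALSE)
    }
    total <- total + n * w
  }
  total
}

#' Ternary mortality coordinates
#'
#' Collapses the five age classes to the (juvenile, prime, old) corners
#' of the mortality triangle: juvenile = F + J + SAd, prime = Ad,
#' old = S, each divided by the total. Taxa represented by four or fewer
#' individuals are conventionally excluded from mortality plots; the
#' result flags them.
#'
#' @param profile An [age_profile()] vector.
#' @return A list with `coords` (named vector summing to 1) and
#'   `plottable` (`FALSE` when total <= 4).
#' @export
ternary_coordinates <- function(profile) {
  tot <- sum(profile)
  if (tot == 0) stop("empty age profile", call. = FALSE)
  coords <- c(
    juvenile = (profile[["F"]] + profile[["J"]] + profile[["SAd"]]) / tot,
    prime = profile[["Ad"]] / tot,
    old = profile[["S"]] / tot
  )
  list(coords = coords, plottable = tot > 4)
}
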