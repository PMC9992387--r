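# Quantification indices: NISP, MNE from anatomical portion codes,
# MNI from element/side/age counts, MAU and %MAU.
#
# MNE is the minimum number of whole elements consistent with the
# observed multiset of portion codes. Fragments of one element cannot
# repeat a portion code, cannot mix determinate left and right sides
# (for paired elements), and cannot mix incompatible age classes.
# Within one side x age bin the minimum element count equals the
# maximum per-code repetition (portion-code runs are intervals on the
# 1..20 axis, so the conflict graph is an interval graph whose chromatic
# number equals its maximum clique). Indeterminate sides and ages are
# assigned to whichever bin minimises the total.

#' Number of identified specimens per taxon
#'
#' Counts taxon-identified records in one unit and expresses each count
#' as a percentage of the unit's identified subtotal (records carrying a
#' taxon label, including family/genus pools). Size-class-only records
#' are excluded from NISP and from the denominator.
#'
#' @param records Validated specimen tibble.
#' @param unit Unit label present in `records`.
#' @return A tibble with columns `taxon`, `nisp`, `pct_nisp`, sorted by
#'   decreasing NISP; zero rows when the unit holds no identified
#'   records.
#' @export
compute_nisp <- function(records, unit) {
  recs <- unit_records(records, unit)
  idd <- recs[!is.na(recs$taxon), ]
  if (nrow(idd) == 0) {
    return(tibble::tibble(taxon = character(0), nisp = integer(0),
                          pct_nisp = numeric(0)))
  }
  out <- dplyr::count(idd, .data$taxon, name = "nisp")
  out$pct_nisp <- 100 * out$nisp / sum(out$nisp)
  ok_log("nisp", "unit %s: %d identified of %d records", unit,
         sum(out$nisp), nrow(recs))
  dplyr::arrange(out, dplyr::desc(.data$nisp))
}

unit_records <- function(records, unit) {
  units <- unique(records$unit)
  if (!(unit %in% units)) {
    stop(sprintf("unknown unit '%s'; available: %s", unit,
                 paste(sort(units), collapse = ", ")), call. = FALSE)
  }
  records[records$unit == unit, ]
}

# Minimum elements for one side x age bin: the largest per-code
# repetition, at least 1 when the bin is non-empty.
bin_mne <- function(code_list) {
  if (length(code_list) == 0) return(0L)
  codes <- unlist(code_list)
  if (length(codes) == 0) return(1L)
  max(max(tabulate(codes, nbins = 20L)), 1L)
}

# Exact-by-search MNE for the specimens of one taxon x element.
# `specs`: tibble with portion_codes (list), side, age_class.
# Paired elements (two per skeleton) distinguish left/right; unpaired
# elements ignore side. Returns list(mne, detail = tibble(side, age, mne)).
mne_assign <- function(specs, paired, combo_limit = 4096L) {
  n <- nrow(specs)
  if (n == 0) {
    return(list(mne = 0L,
                detail = tibble::tibble(side = character(0), age = character(0),
                                        mne = integer(0))))
  }
  det_ages <- setdiff(unique(specs$age_class), "indeterminate")
  age_opts <- lapply(specs$age_class, function(a) {
    if (a == "indeterminate") unique(c(det_ages, "indeterminate")) else a
  })
  side_opts <- if (paired) {
    lapply(specs$side, function(s) if (s == "indeterminate") c("left", "right") else s)
  } else {
    rep(list("pooled"), n)
  }
  opts <- Map(function(s, a) {
    as.matrix(expand.grid(side = s, age = a, stringsAsFactors = FALSE))
  }, side_opts, age_opts)
  n_combo <- prod(vapply(opts, nrow, numeric(1)))

  objective <- function(assign_side, assign_age) {
    key <- paste(assign_side, assign_age, sep = "\r")
    bins <- split(specs$portion_codes, key)
    total <- sum(vapply(bins, bin_mne, integer(1)))
    list(total = total, key = key)
  }

  if (n_combo <= combo_limit) {
    # exhaustive over all side/age assignments of indeterminate specimens
    idx <- lapply(opts, function(o) seq_len(nrow(o)))
    grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      sel <- unlist(grid[g, ])
      a_side <- vapply(seq_len(n), function(i) opts[[i]][sel[i], "side"], character(1))
      a_age <- vapply(seq_len(n), function(i) opts[[i]][sel[i], "age"], character(1))
      res <- objective(a_side, a_age)
      if (is.null(best) || res$total < best$total) {
        best <- c(res, list(side = a_side, age = a_age))
      }
    }
  } else {
    # greedy sequential assignment for large groups; exact for the
    # all-determinate case, heuristic otherwise
    a_side <- vapply(side_opts, `[`, character(1), 1)
    a_age <- vapply(age_opts, `[`, character(1), 1)
    free <- which(vapply(opts, nrow, integer(1)) > 1L)
    for (i in free) {
      o <- opts[[i]]
      scores <- vapply(seq_len(nrow(o)), function(j) {
        a_side[i] <<- o[j, "side"]; a_age[i] <<- o[j, "age"]
        objective(a_side, a_age)$total
      }, integer(1))
      j <- which.min(scores)
      a_side[i] <- o[j, "side"]; a_age[i] <- o[j, "age"]
    }
    best <- c(objective(a_side, a_age), list(side = a_side, age = a_age))
  }

  key <- paste(best$side, best$age, sep = "\r")
  bins <- split(specs$portion_codes, key)
  parts <- strsplit(names(bins), "\r", fixed = TRUE)
  detail <- tibble::tibble(
    side = vapply(parts, `[`, character(1), 1),
    age = vapply(parts, `[`, character(1), 2),
    mne = vapply(bins, bin_mne, integer(1))
  )
  list(mne = sum(detail$mne), detail = detail)
}

template_row <- function(template, taxon, element) {
  row <- template[template$taxon == taxon & template$element == element, ]
  if (nrow(row) == 0) {
    stop(sprintf("element '%s' (taxon '%s') absent from template", element, taxon),
         call. = FALSE)
  }
  row[1, ]
}

is_paired <- function(template, taxon, element) {
  template_row(template, taxon, element)$skeleton_count == 2L
}

#' Minimum number of elements for one taxon and element
#'
#' The smallest number of whole skeletal elements consistent with the
#' observed portion codes, sides and age classes. Indeterminate-side
#' specimens are assigned to whichever side minimises the total
#' (conservative minimum); indeterminate ages are compatible with every
#' age class.
#'
#' @param records Validated specimen tibble (any units).
#' @param taxon,element Which taxon x element to quantify.
#' @param template Skeleton template (decides whether the element is
#'   paired; errors if the element is missing).
#' @param unit Optional unit filter.
#' @return Integer MNE.
#' @export
compute_mne <- function(records, taxon, element, template, unit = NULL) {
  if (!is.null(unit)) records <- unit_records(records, unit)
  paired <- is_paired(template, taxon, element)
  specs <- records[!is.na(records$taxon) & records$taxon == taxon &
                     !is.na(records$element) & records$element == element, ]
  mne_assign(specs, paired)$mne
}

# MNE detail (per side/age bin) for every element of one taxon.
mne_by_element <- function(records, taxon, template, unit = NULL) {
  if (!is.null(unit)) records <- unit_records(records, unit)
  specs <- records[!is.na(records$taxon) & records$taxon == taxon &
                     !is.na(records$element), ]
  if (nrow(specs) == 0) {
    return(tibble::tibble(element = character(0), side = character(0),
                          age = character(0), mne = integer(0)))
  }
  out <- lapply(split(specs, specs$element), function(s) {
    el <- s$element[1]
    res <- mne_assign(s, is_paired(template, taxon, el))
    dplyr::mutate(res$detail, element = el, .before = 1)
  })
  dplyr::bind_rows(out)
}

# Minimum individuals represented by one element's side x age unit
# counts. Paired elements pair lefts with rights within compatible
# ages (max(left, right) individuals per age); unpaired elements need
# ceiling(count / skeleton_count) individuals per age. Units of
# indeterminate side or age are assigned to whichever side / age class
# minimises the total: exhaustively when the assignment space is
# small, greedily otherwise.
element_mni <- function(detail, skeleton_count, combo_limit = 4096L) {
  k <- skeleton_count
  paired <- k == 2L
  # expand bins into units
  units_side <- rep(detail$side, detail$mne)
  units_age <- rep(detail$age, detail$mne)
  n <- length(units_side)
  if (n == 0) {
    return(list(mni = 0L, by_age = stats::setNames(integer(0), character(0)),
                indeterminate = 0L))
  }
  det_ages <- setdiff(unique(units_age), "indeterminate")
  age_opts <- lapply(units_age, function(a) {
    if (a == "indeterminate") unique(c(det_ages, "indeterminate")) else a
  })
  side_opts <- if (paired) {
    lapply(units_side, function(s) if (s %in% c("left", "right")) s
                                   else c("left", "right"))
  } else {
    rep(list("pooled"), n)
  }
  total_for <- function(a_side, a_age) {
    tot <- 0L
    for (a in unique(a_age)) {
      if (paired) {
        tot <- tot + max(sum(a_side == "left" & a_age == a),
                         sum(a_side == "right" & a_age == a))
      } else {
        tot <- tot + as.integer(ceiling(sum(a_age == a) / k))
      }
    }
    tot
  }
  n_opts <- vapply(side_opts, length, integer(1)) * vapply(age_opts, length, integer(1))
  n_combo <- prod(n_opts)
  a_side <- vapply(side_opts, `[`, character(1), 1)
  a_age <- vapply(age_opts, `[`, character(1), 1)
  if (n_combo <= combo_limit && n_combo > 1) {
    opts <- Map(function(s, a) {
      as.matrix(expand.grid(side = s, age = a, stringsAsFactors = FALSE))
    }, side_opts, age_opts)
    grid <- expand.grid(lapply(opts, function(o) seq_len(nrow(o))),
                        KEEP.OUT.ATTRS = FALSE)
    best_total <- Inf
    for (g in seq_len(nrow(grid))) {
      sel <- unlist(grid[g, ])
      s_try <- vapply(seq_len(n), function(i) opts[[i]][sel[i], "side"], character(1))
      a_try <- vapply(seq_len(n), function(i) opts[[i]][sel[i], "age"], character(1))
      tot <- total_for(s_try, a_try)
      if (tot < best_total) {
        best_total <- tot; a_side <- s_try; a_age <- a_try
      }
    }
  } else if (n_combo > combo_limit) {
    free <- which(n_opts > 1L)
    for (i in free) {
      cands <- expand.grid(side = side_opts[[i]], age = age_opts[[i]],
                           stringsAsFactors = FALSE)
      scores <- vapply(seq_len(nrow(cands)), function(j) {
        a_side[i] <<- cands$side[j]; a_age[i] <<- cands$age[j]
        total_for(a_side, a_age)
      }, integer(1))
      j <- which.min(scores)
      a_side[i] <- cands$side[j]; a_age[i] <- cands$age[j]
    }
  }
  by_age <- stats::setNames(integer(length(det_ages)), det_ages)
  extra <- 0L
  for (a in unique(a_age)) {
    m <- if (paired) {
      max(sum(a_side == "left" & a_age == a),
          sum(a_side == "right" & a_age == a))
    } else {
      as.integer(ceiling(sum(a_age == a) / k))
    }
    if (a == "indeterminate") extra <- extra + m else by_age[a] <- m
  }
  list(mni = as.integer(sum(by_age) + extra),
       by_age = by_age, indeterminate = as.integer(extra))
}

#' Minimum number of individuals for one taxon
#'
#' MNI is the maximum, over skeletal elements, of the minimum number of
#' individuals needed to account for that element's side and age
#' representation. The per-age breakdown comes from the element
#' attaining the maximum and always sums to the MNI.
#'
#' @inheritParams compute_mne
#' @return A list with `mni` (integer), `by_age` (named integer vector
#'   over determinate age classes), `indeterminate` (individuals of
#'   unknown age) and `element` (the element attaining the maximum).
#' @export
compute_mni <- function(records, taxon, template, unit = NULL) {
  if (!is.null(unit)) records <- unit_records(records, unit)
  specs <- records[!is.na(records$taxon) & records$taxon == taxon &
                     !is.na(records$element), ]
  if (nrow(specs) == 0) {
    return(list(mni = 0L, by_age = stats::setNames(integer(0), character(0)),
                indeterminate = 0L, element = NA_character_))
  }
  best <- NULL
  for (el in unique(specs$element)) {
    k <- template_row(template, taxon, el)$skeleton_count
    s <- specs[specs$element == el, ]
    # unit counts per original side x age bin, keeping indeterminates
    # flexible for the pairing step
    key <- paste(if (k == 2L) s$side else "pooled", s$age_class, sep = "\r")
    bins <- split(s$portion_codes, key)
    parts <- strsplit(names(bins), "\r", fixed = TRUE)
    raw <- tibble::tibble(
      side = vapply(parts, `[`, character(1), 1),
      age = vapply(parts, `[`, character(1), 2),
      mne = vapply(bins, bin_mne, integer(1))
    )
    res <- element_mni(raw, k)
    if (is.null(best) || res$mni > best$mni) best <- c(res, list(element = el))
  }
  best
}

#' Minimal animal units and percentage MAU
#'
#' MAU divides each element's MNE by the number of copies of that
#' element in one complete skeleton; %MAU rescales so the best
#' represented element reads 100.
#'
#' @param mne A tibble with columns `element` and `mne`.
#' @param template Skeleton template for the taxon.
#' @param taxon Taxon whose template rows to use.
#' @return The input with `mau` and `pct_mau` columns appended.
#' @export
compute_mau <- function(mne, template, taxon) {
  mau <- vapply(seq_len(nrow(mne)), function(i) {
    mne$mne[i] / template_row(template, taxon, mne$element[i])$skeleton_count
  }, numeric(1))
  pct <- if (length(mau) > 0 && max(mau) > 0) 100 * mau / max(mau) else rep(0, length(mau))
  dplyr::mutate(mne, mau = mau, pct_mau = pct)
}

#' Quantify one archaeological unit
#'
#' Runs NISP, MNE, MNI and MAU for every taxon present in the template
#' and returns the per-unit quantification table.
#'
#' @param records Validated specimen tibble.
#' @param unit Unit label.
#' @param template Skeleton template covering the taxa to quantify.
#' @return A list of class `quantification` with elements `unit`, `nr`
#'   (all records in the unit), `nisp`, `mne` (per taxon x element, with
#'   MAU), and `mni` (per taxon, with age breakdown columns).
#' @export
quantify_unit <- function(records, unit, template) {
  recs <- unit_records(records, unit)
  nisp <- compute_nisp(records, unit)
  taxa <- intersect(nisp$taxon, unique(template$taxon))
  mne_tabs <- list(); mni_rows <- list()
  for (tx in taxa) {
    det <- mne_by_element(recs, tx, template)
    if (nrow(det) > 0) {
      by_el <- dplyr::summarise(dplyr::group_by(det, .data$element),
                                mne = sum(.data$mne), .groups = "drop")
      mne_tabs[[tx]] <- dplyr::mutate(compute_mau(by_el, template, tx),
                                      taxon = tx, .before = 1)
    }
    mni_res <- compute_mni(recs, tx, template)
    ages <- age_classes()[1:5]
    by_age <- stats::setNames(integer(5), ages)
    by_age[names(mni_res$by_age)] <- mni_res$by_age
    mni_rows[[tx]] <- tibble::tibble(
      taxon = tx, mni = mni_res$mni,
      mni_F = by_age[["F"]], mni_J = by_age[["J"]], mni_SAd = by_age[["SAd"]],
      mni_Ad = by_age[["Ad"]], mni_S = by_age[["S"]],
      mni_indet_age = mni_res$indeterminate
    )
  }
  structure(list(
    unit = unit,
    nr = nrow(recs),
    nisp = nisp,
    mne = dplyr::bind_rows(mne_tabs),
    mni = dplyr::bind_rows(mni_rows)
  ), class = "quantification")
}

#' @export
print.quantification <- function(x, ...) {
  cat(sprintf("Quantification of unit %s: NR %d, NISP %d, MNE %d, MNI %d\n",
              x$unit, x$nr, sum(x$nisp$nisp),
              if (nrow(x$mne)) sum(x$mne$mne) else 0L,
              if (nrow(x$mni)) sum(x$mni$mni) else 0L))
  invisible(x)
}
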