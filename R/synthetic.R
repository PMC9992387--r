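# Synthetic data with known ground truth: faunal assemblages formed by
# transport + attrition + fragmentation, DEMs of several shapes, and
# NPP series with regime shifts. Every generator is deterministic
# given its seed.

#' Define an assemblage formation scenario
#'
#' The scenario fixes the ground truth a synthetic assemblage is
#' generated from: true individual counts and age structure per taxon,
#' the transport preference `alpha` and attrition `beta` acting on
#' skeletal parts, the fragmentation intensity, and the rates of
#' butchery, carnivore and thermal modification.
#'
#' @param taxa A tibble with columns `taxon` and `n` (individuals).
#' @param template Skeleton template covering the scenario taxa.
#' @param alpha,beta Transport preference in `[-1, 1]` and attrition
#'   exponent >= 0.
#' @param fragmentation Mean fragments per surviving element (>= 1);
#'   fragment counts are 1 plus a Poisson draw with mean
#'   `fragmentation - 1`, and fragments carry contiguous portion-code
#'   runs partitioning 1..20.
#' @param age_probs Named probabilities over `F`, `J`, `SAd`, `Ad`,
#'   `S`.
#' @param p_cut,p_percussion,p_carnivore Per-fragment mark rates.
#' @param burn_probs Probabilities over burn codes 0..5.
#' @param unit Unit label stamped on the records.
#' @param seed Integer seed (mandatory).
#' @return A list of class `assemblage_scenario`.
#' @export
assemblage_scenario <- function(taxa, template, alpha = 0, beta = 0,
                                fragmentation = 1,
                                age_probs = c(F = 0.05, J = 0.25, SAd = 0.10,
                                              Ad = 0.50, S = 0.10),
                                p_cut = 0.15, p_percussion = 0.08,
                                p_carnivore = 0.02,
                                burn_probs = c(0.60, 0.04, 0.01, 0.20, 0.03, 0.12),
                                unit = "SYN", seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(alpha >= -1, alpha <= 1, beta >= 0, fragmentation >= 1)
  probs <- c(age_probs, p_cut, p_percussion, p_carnivore, burn_probs)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  missing_taxa <- setdiff(taxa$taxon, template$taxon)
  if (length(missing_taxa) > 0) {
    stop("taxa absent from template: ", paste(missing_taxa, collapse = ", "),
         call. = FALSE)
  }
  structure(list(taxa = taxa, template = template, alpha = alpha, beta = beta,
                 fragmentation = fragmentation,
                 age_probs = age_probs / sum(age_probs),
                 p_cut = p_cut, p_percussion = p_percussion,
                 p_carnivore = p_carnivore,
                 burn_probs = burn_probs / sum(burn_probs),
                 unit = unit, seed = as.integer(seed)),
            class = "assemblage_scenario")
}

# split 1..20 into n contiguous runs
portion_runs <- function(n_frag) {
  n_frag <- min(n_frag, 20L)
  if (n_frag == 1) return(list(1:20))
  cuts <- sort(sample(1:19, n_frag - 1))
  bounds <- c(0, cuts, 20)
  lapply(seq_len(n_frag), function(i) (bounds[i] + 1):bounds[i + 1])
}

#' Generate a synthetic assemblage
#'
#' Forward-simulates the formation history the analysis stages assume:
#' for each individual, every skeletal element is retained with
#' probability proportional to its transport weight (scaled so the
#' favoured region is always kept), survives attrition with
#' probability `density^beta`, and is then broken into fragments
#' carrying contiguous portion-code runs. Paired elements
#' (`skeleton_count == 2`) get determinate left/right sides; other
#' elements are side-indeterminate. Marks and burn codes are applied
#' per fragment at the scenario rates.
#'
#' At `alpha = 0`, `beta = 0`, `fragmentation = 1` the assemblage is
#' lossless: MNE per element equals `n * skeleton_count` and MNI equals
#' `n`.
#'
#' @param scenario An [assemblage_scenario()].
#' @return A list with `specimens` (validated specimen tibble) and
#'   `truth` (ground-truth ledger: `alpha`, `beta`, per-taxon `n`, and
#'   per-element survivor counts).
#' @export
generate_assemblage <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  ages5 <- names(sc$age_probs)
  rows <- list()
  survivors <- list()
  rid <- 0L
  for (ti in seq_len(nrow(sc$taxa))) {
    tx <- sc$taxa$taxon[ti]
    n_ind <- sc$taxa$n[ti]
    tmpl <- sc$template[sc$template$taxon == tx, ]
    w <- transport_weight(tmpl$region, sc$alpha)
    p_keep <- if (max(w) > 0) w / max(w) else w
    p_surv <- survivorship(tmpl$density, sc$beta)
    surv_count <- stats::setNames(integer(nrow(tmpl)), tmpl$element)
    for (ind in seq_len(n_ind)) {
      age <- sample(ages5, 1, prob = sc$age_probs)
      for (ei in seq_len(nrow(tmpl))) {
        k <- tmpl$skeleton_count[ei]
        paired <- k == 2L
        for (copy in seq_len(k)) {
          if (stats::runif(1) > p_keep[ei]) next
          if (stats::runif(1) > p_surv[ei]) next
          surv_count[ei] <- surv_count[ei] + 1L
          side <- if (paired) c("left", "right")[copy] else "indeterminate"
          n_frag <- 1L + stats::rpois(1, sc$fragmentation - 1)
          for (run in portion_runs(n_frag)) {
            rid <- rid + 1L
            marks <- stats::setNames(integer(0), character(0))
            if (stats::runif(1) < sc$p_cut) {
              marks[sample(cut_mark_kinds(), 1)] <- 1L
            }
            if (stats::runif(1) < sc$p_percussion) {
              marks[sample(percussion_mark_kinds(), 1)] <- 1L
            }
            if (stats::runif(1) < sc$p_carnivore) {
              marks[sample(carnivore_mark_kinds(), 1)] <- 1L
            }
            burn <- sample(0:5, 1, prob = sc$burn_probs)
            rows[[rid]] <- tibble::tibble(
              record_id = sprintf("SYN-%06d", rid),
              unit = sc$unit, square = NA_character_,
              taxon = tx, size_class = NA_integer_,
              element = tmpl$element[ei],
              portion_codes = list(run),
              side = side, age_class = age,
              surface_mods = list(marks),
              burn_code = list(as.integer(burn)),
              breakage = if (n_frag > 1) "green" else "indeterminate",
              is_retoucher = FALSE
            )
          }
        }
      }
    }
    survivors[[tx]] <- tibble::tibble(taxon = tx, element = tmpl$element,
                                      n_surviving = as.integer(surv_count))
  }
  specimens <- if (length(rows) > 0) {
    validate_specimens(dplyr::bind_rows(rows))
  } else {
    specimen_records(character(0), character(0), portion_codes = list(),
                     surface_mods = list(), burn_code = list())
  }
  ok_log("generate_assemblage", "%d fragments from %d individuals",
         nrow(specimens), sum(sc$taxa$n))
  list(specimens = specimens,
       truth = list(alpha = sc$alpha, beta = sc$beta,
                    n_individuals = stats::setNames(sc$taxa$n, sc$taxa$taxon),
                    survivors = dplyr::bind_rows(survivors),
                    seed = sc$seed))
}

#' Generate a synthetic DEM
#'
#' Deterministic given the seed. Kinds: `flat` (constant elevation),
#' `plane` (constant gradient; closed-form slope), `gaussian_hill`
#' (radial bump) and `fractal` (spectral-synthesis random field with a
#' power-law spectrum).
#'
#' @param kind One of `"flat"`, `"plane"`, `"gaussian_hill"`,
#'   `"fractal"`.
#' @param nrow,ncol Grid size.
#' @param cellsize Cell edge (m).
#' @param base Base elevation (m).
#' @param gradient For `plane`: `c(gy, gx)` elevation change per metre
#'   along rows (southward) and columns (eastward); a scalar applies to
#'   columns only.
#' @param height,width For `gaussian_hill`: peak height (m) and
#'   standard deviation (m) of the bump, centred on the grid.
#' @param roughness,exponent For `fractal`: amplitude (m) and spectral
#'   decay exponent.
#' @param seed Integer seed (used by `fractal`; harmless otherwise).
#' @return A [dem()].
#' @export
generate_dem <- function(kind = c("flat", "plane", "gaussian_hill", "fractal"),
                         nrow = 64, ncol = 64, cellsize = 100, base = 350,
                         gradient = 0.1, height = 200, width = 1000,
                         roughness = 50, exponent = 2, seed = 1) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  xs <- (seq_len(ncol) - 1) * cellsize
  ys <- (seq_len(nrow) - 1) * cellsize
  z <- switch(kind,
    flat = matrix(base, nrow, ncol),
    plane = {
      if (length(gradient) == 1) gradient <- c(0, gradient)
      base + outer(ys, xs, function(y, x) gradient[1] * y + gradient[2] * x)
    },
    gaussian_hill = {
      cy <- mean(ys); cx <- mean(xs)
      base + height * outer(ys, xs, function(y, x) {
        exp(-((y - cy)^2 + (x - cx)^2) / (2 * width^2))
      })
    },
    fractal = {
      fy <- stats::fft(matrix(stats::rnorm(nrow * ncol), nrow, ncol))
      ky <- c(0:(nrow %/% 2), -((nrow - nrow %/% 2 - 1):1)) / nrow
      kx <- c(0:(ncol %/% 2), -((ncol - ncol %/% 2 - 1):1)) / ncol
      kk <- sqrt(outer(ky^2, kx^2, `+`))
      kk[1, 1] <- Inf                      # zero out the mean mode
      filt <- kk^(-exponent)
      zz <- Re(stats::fft(fy * filt, inverse = TRUE)) / (nrow * ncol)
      base + roughness * zz / stats::sd(zz)
    }
  )
  dem(z, cellsize = cellsize)
}

#' Generate an NPP series with regime shifts
#'
#' Emulates stadial/interstadial alternation: each regime contributes
#' `duration / step` points of first-order autoregressive noise around
#' its mean, clipped at zero.
#'
#' @param regimes A tibble with columns `duration` (years), `mean` and
#'   `sd` (kg/m^2/year).
#' @param step Sampling step in years.
#' @param start_bp Age of the first (oldest) point, years BP.
#' @param ar Lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param seed Integer seed.
#' @return An [npp_series()] tibble.
#' @export
generate_npp_series <- function(regimes, step = 100, start_bp = 55000,
                                ar = 0.6, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(all(regimes$duration > 0), ar >= 0, ar < 1)
  set.seed(as.integer(seed))
  vals <- numeric(0)
  prev <- NA_real_
  for (i in seq_len(nrow(regimes))) {
    n <- max(1L, round(regimes$duration[i] / step))
    mu <- regimes$mean[i]; s <- regimes$sd[i]
    x <- numeric(n)
    innov_sd <- s * sqrt(1 - ar^2)
    for (t in seq_len(n)) {
      carry <- if (t == 1 && !is.na(prev)) ar * (prev - mu)
               else if (t == 1) 0
               else ar * (x[t - 1] - mu)
      x[t] <- mu + carry + stats::rnorm(1, 0, innov_sd)
    }
    prev <- x[n]
    vals <- c(vals, x)
  }
  vals <- pmax(vals, 0)
  years <- start_bp - step * (seq_along(vals) - 1)
  npp_series(years, vals)
}

#' Reference caprine skeleton template
#'
#' A built-in 20-element skeleton template for a medium-bodied caprine
#' (ibex-like), with element counts per skeleton, axial/appendicular
#' classes and representative maximum bone densities and utility
#' values. The numbers are synthetic but realistic: densities follow
#' the usual ordering (dense limb shafts, fragile vertebrae and ribs)
#' and utility values the usual meat/marrow gradients. Intended for
#' simulation, testing and worked examples, not as a published
#' reference table.
#'
#' @param taxon Taxon label stamped on the rows.
#' @return A validated template tibble with 20 elements.
#' @export
caprine_template <- function(taxon = "Capra ibex") {
  el <- tibble::tribble(
    ~element,        ~skeleton_count, ~region,        ~density,
    "cranium",        1L, "axial",        0.45,
    "mandible",       2L, "axial",        0.61,
    "atlas",          1L, "axial",        0.26,
    "axis",           1L, "axial",        0.30,
    "cervical",       5L, "axial",        0.25,
    "thoracic",      13L, "axial",        0.24,
    "lumbar",         6L, "axial",        0.29,
    "sacrum",         1L, "axial",        0.27,
    "rib",           26L, "axial",        0.40,
    "pelvis",         2L, "axial",        0.49,
    "scapula",        2L, "appendicular", 0.49,
    "humerus",        2L, "appendicular", 0.63,
    "radius",         2L, "appendicular", 0.68,
    "ulna",           2L, "appendicular", 0.45,
    "metacarpal",     2L, "appendicular", 0.72,
    "femur",          2L, "appendicular", 0.57,
    "tibia",          2L, "appendicular", 0.74,
    "metatarsal",     2L, "appendicular", 0.74,
    "astragalus",     2L, "appendicular", 0.61,
    "phalanx",       24L, "appendicular", 0.55
  )
  meat <- c(meat_F = 2, meat_J = 12, meat_SAd = 22, meat_Ad = 30, meat_S = 26)
  skeleton_template(
    taxon = taxon, element = el$element, skeleton_count = el$skeleton_count,
    region = el$region, density = el$density,
    MGUI = round(100 * (1 - el$density) + 5, 1),
    FUI = round(90 * (1 - el$density) + 8, 1),
    CFUI = round(85 * (1 - el$density) + 10, 1),
    Marrow = ifelse(el$element %in% c("humerus", "radius", "femur", "tibia",
                                      "metacarpal", "metatarsal"), 60, 5),
    Grease = ifelse(el$region == "axial", 40, 20),
    UMI = ifelse(el$element %in% c("tibia", "metatarsal", "radius",
                                   "metacarpal"), 70, 25),
    meat_F = meat[["meat_F"]], meat_J = meat[["meat_J"]],
    meat_SAd = meat[["meat_SAd"]], meat_Ad = meat[["meat_Ad"]],
    meat_S = meat[["meat_S"]],
    habitat = "mountain", rank = "high"
  )
}
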