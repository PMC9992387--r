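# Independent brute-force oracles and shared fixtures. These
# deliberately use different algorithms from the package: set-partition
# enumeration for MNE, slot-assignment search for MNI, Bellman-Ford
# relaxation for travel times, and full permutation enumeration for the
# rank tests.

# Minimum number of whole elements by exhaustive partition of specimens
# into blocks with disjoint portion codes, compatible sides (paired
# elements only) and compatible determinate ages.
oracle_mne <- function(specs, paired) {
  n <- nrow(specs)
  if (n == 0) return(0L)
  best <- n
  blocks <- list()
  recurse <- function(i) {
    if (length(blocks) >= best) return(invisible(NULL))
    if (i > n) {
      best <<- min(best, length(blocks))
      return(invisible(NULL))
    }
    codes <- specs$portion_codes[[i]]
    side <- specs$side[i]
    age <- specs$age_class[i]
    for (b in seq_along(blocks)) {
      bl <- blocks[[b]]
      if (length(intersect(bl$codes, codes)) > 0) next
      if (paired && side != "indeterminate" && bl$side != "indeterminate" &&
            bl$side != side) next
      if (age != "indeterminate" && bl$age != "indeterminate" &&
            bl$age != age) next
      blocks[[b]] <<- list(
        codes = c(bl$codes, codes),
        side = if (bl$side == "indeterminate") side else bl$side,
        age = if (bl$age == "indeterminate") age else bl$age
      )
      recurse(i + 1)
      blocks[[b]] <<- bl
    }
    blocks[[length(blocks) + 1]] <<- list(codes = codes, side = side, age = age)
    recurse(i + 1)
    blocks[[length(blocks)]] <<- NULL
    invisible(NULL)
  }
  recurse(1)
  best
}

# Minimal individuals holding element units of one element type.
# units: tibble(side, age); k: copies per skeleton. Paired elements
# (k == 2) have one left and one right slot per individual; unpaired
# elements have k interchangeable slots and no side meaning.
oracle_mni <- function(units, k) {
  paired <- k == 2
  n <- nrow(units)
  if (n == 0) return(0L)
  best <- n
  inds <- list()
  try_place <- function(d, side, age) {
    if (!(age == "indeterminate" || d$age == "indeterminate" || d$age == age)) {
      return(NULL)
    }
    new_age <- if (d$age == "indeterminate") age else d$age
    if (paired) {
      slots <- list()
      if (side %in% c("left", "indeterminate") && !d$left) {
        slots <- c(slots, list(modifyList(d, list(left = TRUE, age = new_age))))
      }
      if (side %in% c("right", "indeterminate") && !d$right) {
        slots <- c(slots, list(modifyList(d, list(right = TRUE, age = new_age))))
      }
      slots
    } else {
      if (d$total >= k) return(NULL)
      list(modifyList(d, list(total = d$total + 1L, age = new_age)))
    }
  }
  recurse <- function(i) {
    if (length(inds) >= best && i <= n) return(invisible(NULL))
    if (i > n) {
      best <<- min(best, length(inds))
      return(invisible(NULL))
    }
    side <- units$side[i]; age <- units$age[i]
    for (d in seq_along(inds)) {
      placements <- try_place(inds[[d]], side, age)
      for (p in placements %||o% list()) {
        old <- inds[[d]]
        inds[[d]] <<- p
        recurse(i + 1)
        inds[[d]] <<- old
      }
    }
    if (length(inds) + 1 <= best) {
      fresh <- list(left = FALSE, right = FALSE, total = 0L, age = "indeterminate")
      placements <- try_place(fresh, side, age)
      for (p in placements %||o% list()) {
        inds[[length(inds) + 1]] <<- p
        recurse(i + 1)
        inds[[length(inds)]] <<- NULL
      }
    }
    invisible(NULL)
  }
  recurse(1)
  best
}

`%||o%` <- function(a, b) if (is.null(a)) b else a

# Travel times by Bellman-Ford relaxation over the same 16-direction
# stencil and hiking function, written independently of the package.
oracle_travel_time <- function(d, origin, v0 = 6, kk = 3.5, c0 = 0.05) {
  z <- d$z; nr <- nrow(z); nc <- ncol(z); cs <- d$cellsize
  offs <- rbind(
    c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
    c(-1, -1), c(-1, 1), c(1, -1), c(1, 1),
    c(-2, -1), c(-2, 1), c(-1, -2), c(-1, 2),
    c(1, -2), c(1, 2), c(2, -1), c(2, 1)
  )
  dist <- matrix(Inf, nr, nc)
  dist[origin[1], origin[2]] <- 0
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cl in seq_len(nc)) {
      if (!is.finite(dist[r, cl])) next
      for (o in seq_len(nrow(offs))) {
        r2 <- r + offs[o, 1]; c2 <- cl + offs[o, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (d$barrier[r2, c2] || d$barrier[r, cl]) next
        len <- cs * sqrt(sum(offs[o, ]^2))
        grad <- (z[r2, c2] - z[r, cl]) / len
        v <- v0 * exp(-kk * abs(grad + c0))
        t_new <- dist[r, cl] + (len / 1000) / v * 60
        if (t_new < dist[r2, c2] - 1e-12) {
          dist[r2, c2] <- t_new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dist
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
    }
  }
  out
}

# Exact two-sided Mann-Whitney p by enumerating every permutation of
# the pooled sample (each split appears equally often).
oracle_mann_whitney <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  u_obs <- u_of(a, b)
  us <- vapply(all_permutations(length(pool)), function(p) {
    u_of(pool[p][seq_len(na)], pool[p][-seq_len(na)])
  }, numeric(1))
  list(statistic = u_obs,
       p.value = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs))))
}

oracle_spearman <- function(x, y) {
  rho_of <- function(a, b) stats::cor(rank(a), rank(b))
  rho <- rho_of(x, y)
  rhos <- vapply(all_permutations(length(x)), function(p) rho_of(x[p], y),
                 numeric(1))
  list(rho = rho, p.value = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# Balanced-density 20-element template for parameter-recovery
# experiments: the same density range in both regions de-confounds
# transport preference from attrition.
recovery_template <- function() {
  skeleton_template(
    taxon = "sim", element = sprintf("el%02d", 1:20),
    skeleton_count = 1L,
    region = rep(c("axial", "appendicular"), each = 10),
    density = rep(seq(0.3, 0.9, length.out = 10), 2)
  )
}

# Random small specimen fixture on one element, with indeterminate
# sides/ages at the given rates; codes are contiguous runs.
random_element_fixture <- function(n, paired, p_indet_side = 0.3,
                                   p_indet_age = 0.3) {
  ages <- c("J", "Ad")
  rows <- lapply(seq_len(n), function(i) {
    a <- b <- sort(sample(1:20, 2))
    side <- if (!paired) "indeterminate"
            else if (stats::runif(1) < p_indet_side) "indeterminate"
            else sample(c("left", "right"), 1)
    age <- if (stats::runif(1) < p_indet_age) "indeterminate" else sample(ages, 1)
    tibble::tibble(side = side, age_class = age,
                   portion_codes = list(a[1]:a[2]))
  })
  dplyr::bind_rows(rows)
}

# wrap a bare element fixture into full specimen records for one taxon
as_specimens <- function(fix, taxon = "Capra ibex", element = "femur",
                         unit = "U") {
  specimen_records(
    record_id = sprintf("f%03d", seq_len(nrow(fix))),
    unit = unit, taxon = taxon, element = element,
    portion_codes = fix$portion_codes,
    side = fix$side, age_class = fix$age_class
  )
}
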