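#' Convert fork length to body mass
#'
#' Standard length-weight allometry \eqn{W = a L^b} with coefficients on an
#' mm-to-kg basis (see [read_attributes_csv()] for unit conversion). Mass is
#' monotone increasing in length.
#'
#' @param fork_length_mm Fork length in mm (positive).
#' @param lw_a Allometric coefficient (kg, mm basis; positive).
#' @param lw_b Allometric exponent (positive, typically near 3).
#' @return Mass in kg.
#' @export
#' @examples
#' to_biomass(100, 1e-8, 3)  # 0.01 kg
to_biomass <- function(fork_length_mm, lw_a, lw_b) {
  if (any(fork_length_mm <= 0, na.rm = TRUE) || any(lw_a <= 0) || any(lw_b <= 0)) {
    abort("to_biomass() requires positive lengths and coefficients.")
  }
  lw_a * fork_length_mm^lw_b
}

#' Attach per-record biomass to catch records
#'
#' @param records Catch-record tibble.
#' @param attributes Species-attributes tibble (mm-to-kg basis).
#' @return `records` with a `biomass_kg` column (`count` x per-fish mass).
#' @export
add_biomass <- function(records, attributes) {
  miss <- setdiff(unique(records$species), attributes$species)
  if (length(miss)) {
    abort(paste0("No attributes for species: ", paste(sort(miss), collapse = ", ")))
  }
  records |>
    left_join(attributes |> select("species", "lw_a", "lw_b"), by = "species") |>
    mutate(biomass_kg = .data$count *
             to_biomass(.data$fork_length_mm, .data$lw_a, .data$lw_b)) |>
    select(-"lw_a", -"lw_b")
}

# Within-class sum of squared deviations for sorted values i..j, via prefix
# sums: ssq - sum^2/n.
class_cost_matrix <- function(x) {
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  cost <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s0 <- if (i > 1) cs[i - 1] else 0
    q0 <- if (i > 1) cs2[i - 1] else 0
    j <- i:n
    m <- j - i + 1
    cost[i, j] <- (cs2[j] - q0) - (cs[j] - s0)^2 / m
  }
  cost
}

#' Optimal natural-breaks classification (Fisher dynamic programming)
#'
#' Partitions one-dimensional values into `k` contiguous classes minimising
#' the total within-class sum of squared deviations — the exact optimum of
#' the Jenks natural-breaks criterion, computed by dynamic programming (no
#' heuristics). Deterministic: among equal-cost optima the partition with the
#' smallest first class (then second, and so on) is returned.
#'
#' @param values Numeric vector (e.g. per-species maximum lengths).
#' @param k Number of classes, `2 <= k`; must not exceed the number of
#'   distinct values.
#' @return An object of class `jenks_breaks`: a list with `classes` (class
#'   index 1..k per input value, 1 = smallest), `breaks` (ascending cut
#'   points: the largest value in each of classes 1..k-1), `gvf`
#'   (goodness of variance fit, `1 - SSD_within / SSD_total`), `ssd_within`,
#'   `ssd_total`, `k`.
#' @export
#' @examples
#' jenks_breaks(c(10, 11, 12, 100, 101, 102), k = 2)
jenks_breaks <- function(values, k) {
  n <- length(values)
  k <- as.integer(k)
  if (n < k || k < 2L) abort("Need at least k values and k >= 2.")
  if (k > length(unique(values))) {
    abort("k exceeds the number of distinct values.")
  }
  ord <- order(values)
  x <- values[ord]
  cost <- class_cost_matrix(x)

  # S[m, i]: minimal cost of partitioning x[i..n] into m classes.
  S <- matrix(Inf, k, n + 1L)
  S[1L, 1:n] <- cost[cbind(1:n, rep(n, n))]
  if (k > 1L) {
    for (m in 2:k) {
      for (i in 1:(n - m + 1L)) {
        j <- i:(n - m + 1L)
        S[m, i] <- min(cost[cbind(i, j)] + S[m - 1L, j + 1L])
      }
    }
  }

  # Forward reconstruction; smallest class first on cost ties.
  tol <- 1e-9 * max(1, S[k, 1L])
  classes_sorted <- integer(n)
  i <- 1L
  for (m in k:1L) {
    if (m == 1L) {
      classes_sorted[i:n] <- k
      break
    }
    j <- i:(n - m + 1L)
    tot <- cost[cbind(i, j)] + S[m - 1L, j + 1L]
    cut <- j[which(tot <= S[m, i] + tol)[1L]]
    classes_sorted[i:cut] <- k - m + 1L
    i <- cut + 1L
  }

  classes <- integer(n)
  classes[ord] <- classes_sorted
  ssd_total <- cost[1L, n]
  ssd_within <- S[k, 1L]
  gvf <- if (ssd_total > 0) 1 - ssd_within / ssd_total else 1
  structure(list(
    classes = classes,
    breaks = vapply(1:(k - 1L), function(cl) max(x[classes_sorted == cl]),
                    numeric(1)),
    gvf = gvf, ssd_within = ssd_within, ssd_total = ssd_total, k = k
  ), class = "jenks_breaks")
}

#' Choose between 2 and 3 body-size classes
#'
#' Three classes are used only when they explain appreciably more variance:
#' `k = 3` is selected iff `gvf(3) - gvf(2) >= increment` (all classes are
#' non-empty by construction of the optimal partition); otherwise `k = 2`.
#'
#' @param values Numeric vector of at least 3 values.
#' @param increment Minimum goodness-of-variance-fit gain for `k = 3`.
#' @return 2L or 3L.
#' @export
choose_k <- function(values, increment = 0.10) {
  if (length(values) < 3L) abort("choose_k() needs at least 3 values.")
  g2 <- jenks_breaks(values, 2L)$gvf
  if (length(unique(values)) < 3L) return(2L)
  g3 <- jenks_breaks(values, 3L)$gvf
  if (g3 - g2 >= increment) 3L else 2L
}

#' Classify species into body-size categories within families
#'
#' Species are grouped within each family by natural breaks on their maximum
#' lengths, into 2 or 3 categories depending on the family's size range
#' (see [choose_k()]). Families with fewer than 3 species cannot be split
#' and are marked `"insufficient"`; they are excluded from large:small ratio
#' analyses.
#'
#' @param attributes Species-attributes tibble.
#' @param increment Passed to [choose_k()].
#' @param k_override Optional named integer vector (family -> k) pinning the
#'   class count for specific families.
#' @return A tibble `family, species, max_length_mm, class_index, n_classes,
#'   gvf, breaks, status` with `class_index = 1` the smallest-bodied class;
#'   `breaks` is a list-column of cut points.
#' @export
classify_sizes <- function(attributes, increment = 0.10, k_override = NULL) {
  attributes |>
    group_by(.data$family) |>
    group_modify(function(df, key) {
      fam <- key$family
      if (nrow(df) < 3L) {
        return(tibble(species = df$species, max_length_mm = df$max_length_mm,
                      class_index = NA_integer_, n_classes = NA_integer_,
                      gvf = NA_real_, breaks = list(numeric()),
                      status = "insufficient"))
      }
      k <- if (!is.null(k_override) && fam %in% names(k_override)) {
        as.integer(k_override[[fam]])
      } else {
        choose_k(df$max_length_mm, increment)
      }
      jb <- jenks_breaks(df$max_length_mm, k)
      tibble(species = df$species, max_length_mm = df$max_length_mm,
             class_index = jb$classes, n_classes = k, gvf = jb$gvf,
             breaks = list(jb$breaks), status = "ok")
    }) |>
    ungroup()
}

#' Write a size classification as CSV
#'
#' @param classification Output of [classify_sizes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_classification_csv <- function(classification, path) {
  classification |>
    mutate(break_points = vapply(.data$breaks, paste, character(1), collapse = ";")) |>
    select(-"breaks") |>
    readr::write_csv(path)
  invisible(path)
}

#' Large-to-small biomass ratios per family and year
#'
#' The biomass landed from the larger body-size classes (class index >= 2)
#' divided by the biomass from the smallest class, per fishery, family and
#' year. Years with no smallest-class fish yield a missing ratio, which is
#' excluded from trend fitting through its weight.
#'
#' @param records Catch records with `biomass_kg`.
#' @param classification Output of [classify_sizes()].
#' @return A tibble `fishery, family, year, small_kg, large_kg, ratio,
#'   weight_kg` where `weight_kg` is the family's total landed kg that year.
#' @export
large_small_ratio <- function(records, classification) {
  cls <- classification |>
    filter(.data$status == "ok") |>
    select("species", "class_index")
  records |>
    inner_join(cls, by = "species") |>
    group_by(.data$fishery, .data$family, .data$year) |>
    summarise(
      small_kg = sum(.data$biomass_kg[.data$class_index == 1L]),
      large_kg = sum(.data$biomass_kg[.data$class_index >= 2L]),
      .groups = "drop"
    ) |>
    mutate(
      ratio = ifelse(.data$small_kg > 0, .data$large_kg / .data$small_kg, NA_real_),
      weight_kg = .data$small_kg + .data$large_kg
    )
}
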