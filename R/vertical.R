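#' Assign stems to relative-height zones
#'
#' Pretzsch's species height profile partitions a stand into three zones
#' relative to its tallest individual (100%): zone I above 80%, zone II
#' from 50% (exclusive) to 80% (inclusive), zone III at or below 50%.
#' Boundary ties fall in the lower zone; the tallest stem is always zone I.
#'
#' @param height_m positive stem heights in metres
#' @param reference_height_m height treated as 100%; defaults to
#'   `max(height_m)` of the scope (normally the plot)
#' @return factor of zones with levels `I`, `II`, `III`
#' @export
#' @examples
#' assign_zones(c(10, 9, 6, 2))  # I, I, II, III
assign_zones <- function(height_m, reference_height_m = max(height_m)) {
  if (length(height_m) == 0) stop("no heights: empty scope")
  if (any(!is.finite(height_m)) || any(height_m <= 0)) {
    stop("heights must be positive")
  }
  if (!is.finite(reference_height_m) || reference_height_m <= 0) {
    stop("reference height must be positive")
  }
  rel <- height_m / reference_height_m
  zone <- ifelse(rel > 0.8, "I", ifelse(rel > 0.5, "II", "III"))
  factor(zone, levels = c("I", "II", "III"))
}

#' Species height profile (A-index) of one scope
#'
#' Shannon entropy over occupied species x height-zone cells:
#' `A = -sum(p_ij * ln(p_ij))` with `p_ij = n_ij / N`, where `n_ij` counts
#' the individuals of species i in zone j and N is the total individual
#' count. The theoretical maximum is `ln(3 * S)` with S species and the
#' fixed three-zone capacity; A is 0 when a single cell holds everything.
#'
#' @param species species label per stem
#' @param height_m height per stem (same length)
#' @param reference_height_m passed to [assign_zones()]
#' @return list of class `vertical_profile`: `zone_counts` (species x zone
#'   table), `a_index`, `a_max` (`log(3 * S)`), `reference_height_m`
#' @export
vertical_profile <- function(species, height_m,
                             reference_height_m = max(height_m)) {
  if (length(species) != length(height_m)) {
    stop("species and height_m lengths differ")
  }
  zones <- assign_zones(height_m, reference_height_m)
  counts <- table(species = as.character(species), zone = zones)
  p <- counts[counts > 0] / sum(counts)
  structure(
    list(zone_counts = counts,
         a_index = -sum(p * log(p)),
         a_max = log(3 * nrow(counts)),
         reference_height_m = reference_height_m),
    class = "vertical_profile"
  )
}

#' @export
print.vertical_profile <- function(x, ...) {
  cat(sprintf("A-index %.4f (max %.4f), reference height %.2f m\n",
              x$a_index, x$a_max, x$reference_height_m))
  print(x$zone_counts)
  invisible(x)
}

#' A-index of a set of stems
#'
#' Convenience wrapper around [vertical_profile()] returning just A.
#'
#' @inheritParams vertical_profile
#' @return A in nats
#' @export
#' @examples
#' a_index(c("A", "A", "B", "B"), c(10, 9, 6, 2))  # ~1.0397
a_index <- function(species, height_m, reference_height_m = max(height_m)) {
  vertical_profile(species, height_m, reference_height_m)$a_index
}

#' Per-site summary of plot-level A-index values
#'
#' Computes A per plot (each plot's own tallest stem defines 100%, the
#' replicated form behind mean +/- SD site reporting) and summarises per
#' site with the sample standard deviation. Site-level pooling — one
#' reference tree per site and all stems scored together — is available
#' via `reference = "site"`.
#'
#' @param chrono a [chronosequence()]
#' @param reference `"plot"` (default) or `"site"`: scope of the 100%
#'   reference height. Per-plot A values are computed in both cases; under
#'   `"site"` the zone thresholds come from the site's tallest stem.
#' @return data.frame with one row per site: `site`, `n_plots` (non-empty),
#'   `mean_a`, `sd_a` (n-1 denominator; `NA` for a single plot). Attribute
#'   `per_plot` holds the plot-level values. Empty plots are skipped with a
#'   warning; a site with no non-empty plot gets `NA` summaries.
#' @export
site_a_summary <- function(chrono, reference = c("plot", "site")) {
  stopifnot(inherits(chrono, "chronosequence"))
  reference <- match.arg(reference)

  per_plot <- chrono$plots[c("site", "plot")]
  per_plot$a_index <- NA_real_
  per_plot$reference_height_m <- NA_real_
  rec_key <- paste(chrono$records$site, chrono$records$plot)
  n_empty <- 0L
  for (i in seq_len(nrow(per_plot))) {
    r <- chrono$records[rec_key == paste(per_plot$site[i], per_plot$plot[i]),
                        , drop = FALSE]
    if (nrow(r) == 0) { n_empty <- n_empty + 1L; next }
    ref <- if (reference == "site") {
      max(chrono$records$height_m[chrono$records$site == per_plot$site[i]])
    } else {
      max(r$height_m)
    }
    per_plot$a_index[i] <- a_index(r$species, r$height_m, ref)
    per_plot$reference_height_m[i] <- ref
  }
  if (n_empty > 0) warning(n_empty, " empty plot(s) skipped in A-index")

  sites <- chrono$site_levels
  out <- data.frame(
    site = sites,
    n_plots = vapply(sites, function(s) {
      sum(!is.na(per_plot$a_index[per_plot$site == s]))
    }, integer(1)),
    mean_a = vapply(sites, function(s) {
      a <- per_plot$a_index[per_plot$site == s]
      if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE)
    }, numeric(1)),
    sd_a = vapply(sites, function(s) {
      a <- per_plot$a_index[per_plot$site == s]
      if (sum(!is.na(a)) < 2) NA_real_ else stats::sd(a, na.rm = TRUE)
    }, numeric(1))
  )
  rownames(out) <- NULL
  attr(out, "per_plot") <- per_plot
  out
}
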