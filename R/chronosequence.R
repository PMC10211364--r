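#' Build a chronosequence inventory object
#'
#' A chronosequence holds stem-level records from fixed-area plots nested in
#' sites that differ only in time since abandonment. Each record is one
#' censused woody individual: its species, basal diameter at 10 cm above
#' ground (`d_0.10`, cm) and total height (m). The census rule of the
#' sampling design — only stems with `d_0.10 >= 1` cm are recorded — is
#' enforced at construction; use [read_inventory()] to load raw exports that
#' may still contain sub-census stems.
#'
#' @param records data.frame with columns `site`, `plot`, `species`,
#'   `basal_diameter_cm`, `height_m`. Sites are treated as ordered
#'   categories in their order of first appearance (or `site_order`).
#' @param plots optional data.frame with columns `site`, `plot`, `area_m2`
#'   listing every plot explicitly (required to represent censused plots
#'   that hold no stems). Defaults to the plots present in `records`, each
#'   with `default_area_m2`.
#' @param default_area_m2 plot area assigned when `plots` is not given;
#'   the sampling design here uses 40 m x 40 m plots (1600 m2).
#' @param site_order optional character vector fixing the site ordering.
#'
#' @details Species names are whitespace-normalised (trimmed, internal runs
#'   of whitespace collapsed) and matched case-insensitively; the first
#'   spelling seen is kept. All plots within a site must share one area and
#'   plot ids must be unique within a site. Plots without records are
#'   allowed and flagged with a message.
#'
#' @return An object of class `chronosequence`: a list with elements
#'   `records` (validated data.frame), `plots` (site, plot, area_m2) and
#'   `site_levels` (ordered site labels).
#' @seealso [read_inventory()], [pooled_abundance()], [simulate_chronosequence()]
#' @export
#' @examples
#' rec <- data.frame(
#'   site = "10", plot = "p1",
#'   species = c("Acacia farnesiana", "Havardia pallens"),
#'   basal_diameter_cm = c(3.2, 1.5), height_m = c(2.1, 1.4)
#' )
#' chronosequence(rec)
chronosequence <- function(records, plots = NULL, default_area_m2 = 1600,
                           site_order = NULL) {
  req <- c("site", "plot", "species", "basal_diameter_cm", "height_m")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) {
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  }
  records <- as.data.frame(records)[req]
  records$site <- as.character(records$site)
  records$plot <- as.character(records$plot)
  records$species <- normalize_species(records$species)

  if (nrow(records) > 0) {
    if (any(!is.finite(records$basal_diameter_cm))) {
      stop("non-finite basal diameter in records")
    }
    if (any(!is.finite(records$height_m))) {
      stop("non-finite height in records")
    }
    if (any(records$basal_diameter_cm < 1)) {
      stop("records violate the census rule (basal diameter < 1 cm); ",
           "use read_inventory() to drop sub-census stems with a warning")
    }
    if (any(records$height_m <= 0)) stop("heights must be positive")
    if (any(is.na(records$species) | !nzchar(records$species))) {
      stop("empty species name in records")
    }
  }

  if (is.null(plots)) {
    plots <- unique(records[c("site", "plot")])
    plots$area_m2 <- default_area_m2
  } else {
    plots <- as.data.frame(plots)[c("site", "plot", "area_m2")]
    plots$site <- as.character(plots$site)
    plots$plot <- as.character(plots$plot)
  }
  if (nrow(plots) == 0) stop("chronosequence has no plots")
  if (any(!is.finite(plots$area_m2)) || any(plots$area_m2 <= 0)) {
    stop("plot areas must be positive")
  }
  if (anyDuplicated(plots[c("site", "plot")]) > 0) {
    stop("plot ids must be unique within a site")
  }
  bad_area <- tapply(plots$area_m2, plots$site,
                     function(a) length(unique(a)) > 1)
  if (any(bad_area)) {
    stop("plots within a site must share one area: site(s) ",
         paste(names(bad_area)[bad_area], collapse = ", "))
  }

  orphan <- !paste(records$site, records$plot) %in%
    paste(plots$site, plots$plot)
  if (any(orphan)) stop("records refer to plots absent from the plot table")

  if (is.null(site_order)) site_order <- unique(plots$site)
  if (anyDuplicated(site_order) > 0) stop("site labels must be unique")
  if (!setequal(site_order, unique(plots$site))) {
    stop("site_order must list exactly the sites present")
  }
  plots <- plots[order(match(plots$site, site_order)), , drop = FALSE]
  rownames(plots) <- NULL

  empties <- sum(!paste(plots$site, plots$plot) %in%
                   paste(records$site, records$plot))
  if (empties > 0) {
    message(empties, " plot(s) hold no records (kept as censused-empty)")
  }

  structure(
    list(records = records, plots = plots, site_levels = site_order),
    class = "chronosequence"
  )
}

# Trim, collapse internal whitespace, and fold case-variants of the same
# binomial onto the first spelling seen.
normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  key <- tolower(x)
  x[match(key, key)]
}

#' @export
print.chronosequence <- function(x, ...) {
  cat("chronosequence:", length(x$site_levels), "site(s),",
      nrow(x$plots), "plot(s),", nrow(x$records), "stem record(s)\n")
  for (s in x$site_levels) {
    p <- x$plots[x$plots$site == s, , drop = FALSE]
    r <- x$records[x$records$site == s, , drop = FALSE]
    cat(sprintf("  site %-6s %d plot(s) x %g m2, %d stems, %d species\n",
                s, nrow(p), p$area_m2[1], nrow(r),
                length(unique(r$species))))
  }
  invisible(x)
}

#' Site labels of a chronosequence, in analysis order
#' @param chrono a [chronosequence()] object
#' @return character vector of site labels
#' @export
site_labels <- function(chrono) {
  stopifnot(inherits(chrono, "chronosequence"))
  chrono$site_levels
}

#' Total sampled area per site
#' @param chrono a [chronosequence()] object
#' @return named numeric vector, summed plot area (m2) per site
#' @export
site_area_m2 <- function(chrono) {
  stopifnot(inherits(chrono, "chronosequence"))
  a <- tapply(chrono$plots$area_m2, chrono$plots$site, sum)
  stats::setNames(as.numeric(a[chrono$site_levels]), chrono$site_levels)
}

# records of one site, erroring on unknown labels
site_records <- function(chrono, site) {
  if (!site %in% chrono$site_levels) stop("unknown site: ", site)
  chrono$records[chrono$records$site == site, , drop = FALSE]
}
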