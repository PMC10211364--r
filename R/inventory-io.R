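#' Read a stem-level inventory table
#'
#' Reads a flat delimited file of censused stems (one row per individual)
#' into a [chronosequence()] object. The expected columns are `site`,
#' `plot`, `species`, `basal_diameter_cm` and `height_m`; other layouts are
#' remapped via `config`. Rows whose basal diameter falls below the 1 cm
#' census threshold are dropped with a warning (field exports often carry
#' sub-census stems); the dropped count is stored in attribute
#' `n_excluded`.
#'
#' @param path path to a comma- or tab-delimited text file with a header.
#'   The delimiter is sniffed from the header line unless `sep` is given.
#' @param config named list mapping the canonical column roles `site`,
#'   `plot`, `species`, `diameter`, `height` (and optionally `area`) to the
#'   column names used in the file.
#' @param sep field delimiter; default `NULL` auto-detects tab vs comma.
#' @param default_area_m2 plot area used when the file has no area column.
#' @return a [chronosequence()]; attribute `n_excluded` counts rows removed
#'   by the census rule.
#' @export
read_inventory <- function(path, config = NULL, sep = NULL,
                           default_area_m2 = 1600) {
  if (!file.exists(path)) stop("inventory file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("empty inventory file: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","

  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  cols <- list(site = "site", plot = "plot", species = "species",
               diameter = "basal_diameter_cm", height = "height_m",
               area = "area_m2")
  if (!is.null(config)) {
    unknown <- setdiff(names(config), names(cols))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cols[names(config)] <- config
  }
  for (role in c("site", "plot", "species", "diameter", "height")) {
    if (!cols[[role]] %in% names(df)) {
      stop("missing column '", cols[[role]], "' (role: ", role, ")")
    }
  }
  if (nrow(df) == 0) stop("inventory file has a header but no records: ", path)

  num <- function(role) {
    raw <- df[[cols[[role]]]]
    x <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(x) & !is.na(raw))
    if (length(bad) > 0) {
      stop("non-numeric ", role, " on line(s) ",
           paste(bad + 1L, collapse = ", "), " of ", path)
    }
    x
  }
  rec <- data.frame(
    site = df[[cols$site]],
    plot = df[[cols$plot]],
    species = df[[cols$species]],
    basal_diameter_cm = num("diameter"),
    height_m = num("height"),
    stringsAsFactors = FALSE
  )

  plots <- NULL
  if (cols$area %in% names(df)) {
    area <- suppressWarnings(as.numeric(df[[cols$area]]))
    plots <- unique(data.frame(site = rec$site, plot = rec$plot,
                               area_m2 = area, stringsAsFactors = FALSE))
  }

  sub <- rec$basal_diameter_cm < 1
  n_excluded <- sum(sub)
  if (n_excluded > 0) {
    warning(n_excluded, " record(s) below the 1 cm census threshold dropped")
    rec <- rec[!sub, , drop = FALSE]
    if (nrow(rec) == 0) stop("no records remain after the census rule")
  }

  chrono <- chronosequence(rec, plots = plots,
                           default_area_m2 = default_area_m2)
  attr(chrono, "n_excluded") <- n_excluded
  chrono
}

#' Write a chronosequence back to the flat inventory format
#'
#' Writes one row per stem with columns `site`, `plot`, `area_m2`,
#' `species`, `basal_diameter_cm`, `height_m`. The round trip
#' `read_inventory(write_inventory(x))` reproduces the record multiset
#' (row order is not guaranteed). Plots without records are not
#' representable in the stem table and are dropped with a warning.
#'
#' @param chrono a [chronosequence()]
#' @param path output file path
#' @param sep field delimiter (default comma)
#' @return `path`, invisibly
#' @export
write_inventory <- function(chrono, path, sep = ",") {
  stopifnot(inherits(chrono, "chronosequence"))
  rec <- chrono$records
  key <- paste(chrono$plots$site, chrono$plots$plot)
  used <- key %in% paste(rec$site, rec$plot)
  if (any(!used) && nrow(rec) > 0) {
    warning(sum(!used), " empty plot(s) cannot be represented in the ",
            "stem table and were dropped on write")
  }
  area <- chrono$plots$area_m2[match(paste(rec$site, rec$plot), key)]
  out <- data.frame(site = rec$site, plot = rec$plot, area_m2 = area,
                    species = rec$species,
                    basal_diameter_cm = rec$basal_diameter_cm,
                    height_m = rec$height_m)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Pool stem records into a per-hectare abundance matrix
#'
#' Aggregates records over each site's plots and rescales counts to
#' densities: `N_ha(site, sp) = count / site area (m2) * 10^4`. The species
#' axis is the union over sites, zero where a species is absent; species
#' recorded nowhere never appear.
#'
#' @param chrono a [chronosequence()]
#' @return a numeric site x species matrix of densities (N ha-1), class
#'   `abundance_matrix`, with attribute `site_area_m2`.
#' @export
#' @examples
#' rec <- data.frame(site = "10", plot = "p1",
#'                   species = rep("Acacia farnesiana", 8),
#'                   basal_diameter_cm = 2, height_m = 1.5)
#' pooled_abundance(chronosequence(rec))  # 8 / 1600 m2 -> 50 N ha-1
pooled_abundance <- function(chrono) {
  stopifnot(inherits(chrono, "chronosequence"))
  sites <- chrono$site_levels
  species <- unique(chrono$records$species)
  m <- matrix(0, nrow = length(sites), ncol = length(species),
              dimnames = list(sites, species))
  if (nrow(chrono$records) > 0) {
    tab <- table(factor(chrono$records$site, levels = sites),
                 factor(chrono$records$species, levels = species))
    m[] <- as.numeric(tab)
  }
  area <- site_area_m2(chrono)
  m <- sweep(m, 1, area[sites], "/") * 1e4
  structure(m, site_area_m2 = area, class = c("abundance_matrix", "matrix"))
}

#' Construct an abundance matrix from site-level density columns
#'
#' For analyses that start from published site x species density tables
#' rather than stem records (e.g. the shipped Tamaulipan thornscrub
#' reference table), this builds the same `abundance_matrix` container that
#' [pooled_abundance()] produces.
#'
#' @param values numeric site x species matrix of densities (N ha-1)
#' @param site_area_m2 optional named vector of sampled areas per site
#' @return an `abundance_matrix`
#' @export
abundance_matrix <- function(values, site_area_m2 = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry site row names and species column names")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("densities must be finite and non-negative")
  }
  structure(values, site_area_m2 = site_area_m2,
            class = c("abundance_matrix", "matrix"))
}
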