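#' Basal area of a stem from its basal diameter
#'
#' Treats the stem section at 10 cm above ground as circular:
#' `g = pi * (d / 200)^2` with d in cm, giving g in m2.
#'
#' @param d_cm basal diameter(s) in cm; must satisfy the 1 cm census rule
#' @return basal area(s) in m2
#' @export
basal_area <- function(d_cm) {
  if (any(!is.finite(d_cm)) || any(d_cm < 1)) {
    stop("basal diameters must be >= 1 cm (census rule)")
  }
  pi * (d_cm / 200)^2
}

#' Stem volume from basal area, height and morphic coefficient
#'
#' `V = g * h * MC`. The morphic coefficient converts the cylinder
#' `g * h` to stem volume; 0.5 is the accepted constant for Tamaulipan
#' thornscrub growth forms.
#'
#' @param g basal area(s), m2 (positive)
#' @param h total height(s), m (positive)
#' @param mc morphic coefficient in (0, 1]
#' @return stem volume(s) in m3
#' @export
stem_volume <- function(g, h, mc = 0.5) {
  if (any(!is.finite(g)) || any(g <= 0)) stop("basal area must be positive")
  if (any(!is.finite(h)) || any(h <= 0)) stop("height must be positive")
  if (!is.finite(mc) || mc <= 0 || mc > 1) stop("mc must be in (0, 1]")
  g * h * mc
}

#' Importance value table for one site
#'
#' Per species of the site: absolute abundance `A_i` (N ha-1), absolute
#' dominance `D_i` (basal area, m2 ha-1), absolute frequency `F_i` (number
#' of the site's plots where the species occurs), their relative forms
#' (each normalised to sum to 100 over species), and
#' `IVI_i = (RA_i + Rd_i + Rf_i) / 3` on the 0-100 scale. Rows are sorted
#' by decreasing IVI.
#'
#' @param chrono a [chronosequence()]
#' @param site site label; must hold at least one record
#' @return data.frame with columns `species`, `abs_abundance`,
#'   `rel_abundance`, `abs_dominance`, `rel_dominance`, `abs_frequency`,
#'   `rel_frequency`, `ivi`; attribute `totals` holds the column sums and
#'   the site label.
#' @export
importance_table <- function(chrono, site) {
  stopifnot(inherits(chrono, "chronosequence"))
  rec <- site_records(chrono, site)
  if (nrow(rec) == 0) stop("site '", site, "' holds no records")
  area <- site_area_m2(chrono)[[site]]

  sp <- sort(unique(rec$species))
  f <- factor(rec$species, levels = sp)
  n_i <- as.numeric(table(f))
  ba_i <- as.numeric(tapply(basal_area(rec$basal_diameter_cm), f, sum,
                            default = 0))
  f_i <- vapply(sp, function(s) {
    length(unique(rec$plot[rec$species == s]))
  }, numeric(1))

  abs_abund <- n_i / area * 1e4
  abs_dom <- ba_i / area * 1e4
  rel <- function(x) x / sum(x) * 100
  out <- data.frame(
    species = sp,
    abs_abundance = abs_abund,
    rel_abundance = rel(abs_abund),
    abs_dominance = abs_dom,
    rel_dominance = rel(abs_dom),
    abs_frequency = f_i,
    rel_frequency = rel(f_i),
    stringsAsFactors = FALSE
  )
  out$ivi <- (out$rel_abundance + out$rel_dominance + out$rel_frequency) / 3
  out <- out[order(-out$ivi, out$species), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "totals") <- c(
    abs_abundance = sum(out$abs_abundance), rel_abundance = 100,
    abs_dominance = sum(out$abs_dominance), rel_dominance = 100,
    abs_frequency = sum(out$abs_frequency), rel_frequency = 100,
    ivi = sum(out$ivi)
  )
  attr(out, "site") <- site
  out
}

#' Importance value tables for every site
#'
#' @param chrono a [chronosequence()]
#' @return named list of [importance_table()] results, one per site
#' @export
importance_tables <- function(chrono) {
  stopifnot(inherits(chrono, "chronosequence"))
  stats::setNames(
    lapply(chrono$site_levels, function(s) importance_table(chrono, s)),
    chrono$site_levels
  )
}

#' Stand volume per hectare
#'
#' Sums [stem_volume()] over every stem of each site and rescales by the
#' sampled area to m3 ha-1.
#'
#' @param chrono a [chronosequence()]
#' @param mc morphic coefficient, default 0.5
#' @return data.frame with columns `site`, `volume_m3_ha`,
#'   `morphic_coefficient`; 0 (with a warning) for a site without stems
#' @export
site_volume <- function(chrono, mc = 0.5) {
  stopifnot(inherits(chrono, "chronosequence"))
  area <- site_area_m2(chrono)
  vol <- vapply(chrono$site_levels, function(s) {
    rec <- site_records(chrono, s)
    if (nrow(rec) == 0) {
      warning("site '", s, "' holds no stems; volume 0")
      return(0)
    }
    v <- stem_volume(basal_area(rec$basal_diameter_cm), rec$height_m, mc)
    sum(v) / area[[s]] * 1e4
  }, numeric(1))
  data.frame(site = chrono$site_levels, volume_m3_ha = unname(vol),
             morphic_coefficient = mc)
}
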