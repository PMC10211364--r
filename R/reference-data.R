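#' Reference site-level density table for a thornscrub chronosequence
#'
#' Per-species stand summaries for four Tamaulipan thornscrub sites
#' differing in time since land abandonment (10, 20, 30 and >30 years;
#' four 40 m x 40 m plots per site): absolute abundance `n_ha` (N ha-1),
#' basal-area dominance `g_ha` (m2 ha-1) and importance value `ivi`
#' (0-100 scale). Species appear under the abbreviated binomials of the
#' source table and only where present; one dominance value originally
#' reported as "<0.01" is encoded as 0.005. This table is the package's
#' worked reference input: the similarity, clustering and effective
#' species analyses of the vignette and acceptance script start from its
#' `n_ha` columns.
#'
#' @return data.frame with columns `species`, `site`, `n_ha`, `g_ha`,
#'   `ivi`, sites ordered 10, 20, 30, >30
#' @seealso [thornscrub_abundance()] for the wide density matrix
#' @export
thornscrub_density <- function() {
  path <- system.file("extdata", "thornscrub_site_density.csv",
                      package = "chronoveg", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df$site <- factor(df$site, levels = c("10", "20", "30", ">30"))
  df[order(df$species, df$site), , drop = FALSE]
}

#' Reference abundance matrix (sites x species, N ha-1)
#'
#' The `n_ha` columns of [thornscrub_density()] spread into the site x
#' species [abundance_matrix()] that the similarity and diversity
#' analyses consume, zeros where a species is absent from a site.
#'
#' @return an [abundance_matrix()] with rows `10`, `20`, `30`, `>30`
#' @export
thornscrub_abundance <- function() {
  df <- thornscrub_density()
  sites <- levels(df$site)
  species <- sort(unique(df$species))
  m <- matrix(0, length(sites), length(species),
              dimnames = list(sites, species))
  m[cbind(match(as.character(df$site), sites),
          match(df$species, species))] <- df$n_ha
  abundance_matrix(m, site_area_m2 = stats::setNames(rep(6400, 4), sites))
}

#' Woody species pool for the inventory simulator
#'
#' Binomials of woody taxa characteristic of Tamaulipan thornscrub
#' (thorny legumes and their associates), used as the default pool the
#' simulator draws stage compositions from.
#'
#' @return character vector of 26 binomials
#' @export
thornscrub_species_pool <- function() {
  c("Cordia boissieri", "Celtis pallida", "Koeberlinia spinosa",
    "Diospyros texana", "Bernardia myricifolia", "Acacia amentacea",
    "Acacia farnesiana", "Acacia rigidula", "Caesalpinia mexicana",
    "Ebenopsis ebano", "Eysenhardtia polystachya", "Havardia pallens",
    "Mimosa monancistra", "Parkinsonia aculeata", "Cercidium texanum",
    "Prosopis laevigata", "Yucca filifera", "Forestiera angustifolia",
    "Condalia hookeri", "Randia obcordata", "Helietta parvifolia",
    "Zanthoxylum fagara", "Sideroxylon celastrinum",
    "Leucophyllum frutescens", "Castela erecta", "Porlieria angustifolia")
}
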