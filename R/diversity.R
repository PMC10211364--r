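#' Species richness of an abundance vector
#'
#' @param abund non-negative per-species abundances (counts or densities).
#' @return number of species with strictly positive abundance
#' @export
species_richness <- function(abund) {
  check_abundance(abund, allow_zero = TRUE)
  sum(abund > 0)
}

#' Shannon diversity index H' (natural log)
#'
#' `H' = -sum(p_i * ln(p_i))` over species with positive abundance, where
#' `p_i` is the proportion of individuals of species i. Proportions are
#' scale-invariant, so densities (N ha-1) and raw counts give identical
#' results.
#'
#' @inheritParams species_richness
#' @return H' in nats; 0 for a single-species vector
#' @export
#' @examples
#' shannon_index(c(1, 1, 1, 1))  # log(4)
shannon_index <- function(abund) {
  check_abundance(abund, allow_zero = FALSE)
  p <- abund[abund > 0] / sum(abund)
  -sum(p * log(p))
}

#' Effective number of species (first-order Hill number)
#'
#' The exponential of Shannon's index: the number of equally common species
#' that would give the same entropy.
#'
#' @param h Shannon index H' in nats (non-negative)
#' @return `exp(h)`
#' @export
effective_species <- function(h) {
  if (any(!is.finite(h)) || any(h < 0)) stop("H' must be finite and >= 0")
  exp(h)
}

check_abundance <- function(abund, allow_zero) {
  if (length(abund) == 0 || any(!is.finite(abund))) {
    stop("abundances must be a non-empty finite numeric vector")
  }
  if (any(abund < 0)) stop("abundances must be non-negative")
  if (!allow_zero && all(abund == 0)) {
    stop("all-zero abundance vector: proportions undefined")
  }
  invisible(abund)
}

#' Diversity per site (pooled) or per plot
#'
#' At `scope = "pooled"` the four plots of each site are summed into one
#' abundance vector before computing H' and the effective number of
#' species; pooled computation is the convention used for site-level
#' reporting here. At `scope = "plot"` each plot is scored separately,
#' which is the replicated form that feeds [compare_metric()].
#'
#' @param chrono a [chronosequence()]
#' @param scope `"pooled"` (one row per site) or `"plot"` (one per plot)
#' @return data.frame with columns `site` (and `plot` when per-plot),
#'   `richness`, `shannon_h`, `effective_species`, `defined`. Empty scopes
#'   get richness 0 and `NA` indices with `defined = FALSE`.
#' @export
site_diversity <- function(chrono, scope = c("pooled", "plot")) {
  stopifnot(inherits(chrono, "chronosequence"))
  scope <- match.arg(scope)

  one <- function(counts) {
    s <- species_richness(counts)
    if (s == 0) {
      data.frame(richness = 0L, shannon_h = NA_real_,
                 effective_species = NA_real_, defined = FALSE)
    } else {
      h <- shannon_index(counts)
      data.frame(richness = s, shannon_h = h,
                 effective_species = effective_species(h), defined = TRUE)
    }
  }

  if (scope == "pooled") {
    m <- pooled_abundance(chrono)
    out <- do.call(rbind, lapply(rownames(m), function(s) one(m[s, ])))
    cbind(data.frame(site = rownames(m)), out)
  } else {
    key <- paste(chrono$plots$site, chrono$plots$plot)
    rows <- lapply(seq_len(nrow(chrono$plots)), function(i) {
      r <- chrono$records[paste(chrono$records$site, chrono$records$plot) ==
                            key[i], , drop = FALSE]
      counts <- as.numeric(table(r$species))
      if (length(counts) == 0) counts <- 0
      cbind(data.frame(site = chrono$plots$site[i],
                       plot = chrono$plots$plot[i]), one(counts))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
}
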