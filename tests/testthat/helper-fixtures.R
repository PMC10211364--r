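# Shared fixtures and independent oracles for the test suite.

make_records <- function(site, plot, species, d = 2, h = 1.5) {
  data.frame(site = site, plot = plot, species = species,
             basal_diameter_cm = d, height_m = h,
             stringsAsFactors = FALSE)
}

# two sites x one plot, three stems each
tiny_chrono <- function() {
  rec <- rbind(
    make_records("10", "p1", c("Acacia farnesiana", "Acacia farnesiana",
                               "Havardia pallens"), d = c(2, 3, 1.5),
                 h = c(1.5, 2.0, 1.2)),
    make_records("20", "p1", c("Cordia boissieri", "Prosopis laevigata",
                               "Prosopis laevigata"), d = c(4, 2.5, 6),
                 h = c(3.0, 2.2, 4.1))
  )
  chronosequence(rec)
}

# random inventory with k sites, p plots, seeded
random_chrono <- function(seed, n_sites = 3, n_plots = 3,
                          n_species = 6, lambda = 30) {
  withr::with_seed(seed, {
    pool <- paste("Species", letters[seq_len(n_species)])
    rec <- do.call(rbind, lapply(seq_len(n_sites), function(s) {
      do.call(rbind, lapply(seq_len(n_plots), function(p) {
        n <- stats::rpois(1, lambda) + 1
        make_records(paste0("s", s), paste0("p", p),
                     sample(pool, n, replace = TRUE),
                     d = stats::runif(n, 1, 12),
                     h = stats::runif(n, 0.5, 8))
      }))
    }))
    chronosequence(rec)
  })
}

# stem-level reconstruction of the shipped reference density table: one
# pseudo-plot per site whose counts recover the published densities
# (counts = density * 6400 m2 / 1e4 are integers up to table rounding)
reference_chrono <- function() {
  df <- thornscrub_density()
  counts <- round(df$n_ha * 6400 / 1e4)
  rec <- do.call(rbind, lapply(which(counts > 0), function(i) {
    make_records(as.character(df$site[i]), "pooled",
                 rep(df$species[i], counts[i]))
  }))
  chronosequence(rec, plots = data.frame(
    site = c("10", "20", "30", ">30"), plot = "pooled", area_m2 = 6400
  ), site_order = c("10", "20", "30", ">30"))
}

# published pairwise similarity values (3 dp) among the four sites
published_similarity <- function() {
  m <- matrix(1, 4, 4, dimnames = list(c("10", "20", "30", ">30"),
                                       c("10", "20", "30", ">30")))
  m["10", "20"] <- m["20", "10"] <- 0.708
  m["10", "30"] <- m["30", "10"] <- 0.410
  m["10", ">30"] <- m[">30", "10"] <- 0.145
  m["20", "30"] <- m["30", "20"] <- 0.599
  m["20", ">30"] <- m[">30", "20"] <- 0.186
  m["30", ">30"] <- m[">30", "30"] <- 0.255
  m
}

# --- independent oracles -------------------------------------------------

# Shannon entropy by explicit elementwise loop
brute_shannon <- function(x) {
  tot <- sum(x)
  h <- 0
  for (xi in x) {
    if (xi > 0) {
      p <- xi / tot
      h <- h - p * log(p)
    }
  }
  h
}

# UPGMA by brute force: recompute every cross-pair mean of the ORIGINAL
# distances at each step; returns the cophenetic matrix implied by the
# merge heights (comparing cophenetic matrices checks merge order and
# heights jointly).
brute_upgma_cophenetic <- function(dmat) {
  n <- nrow(dmat)
  labels <- rownames(dmat)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_len(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        cross <- mean(dmat[clusters[[a]], clusters[[b]]])
        if (is.null(best) || cross < best$d) best <- list(a = a, b = b,
                                                          d = cross)
      }
    }
    coph[clusters[[best$a]], clusters[[best$b]]] <- best$d
    coph[clusters[[best$b]], clusters[[best$a]]] <- best$d
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  coph
}

# effective species of an infinite->truncated geometric rank-abundance
geometric_effective_species <- function(decay, s) {
  p <- decay^(seq_len(s) - 1)
  p <- p / sum(p)
  exp(-sum(p * log(p)))
}
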