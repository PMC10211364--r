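# Group values may arrive as a named list of numeric vectors; coerce and
# validate the shared preconditions of the omnibus tests.
check_groups <- function(groups, min_n = 2, need_var = FALSE) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least two groups")
  }
  groups <- lapply(groups, as.numeric)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  n <- vapply(groups, length, integer(1))
  if (any(n < min_n)) {
    stop("every group needs at least ", min_n, " observations")
  }
  if (any(vapply(groups, function(x) any(!is.finite(x)), logical(1)))) {
    stop("group values must be finite")
  }
  if (need_var && any(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("zero-variance group: Welch weights undefined; ",
         "consider classic one_way_anova()")
  }
  groups
}

groups_to_long <- function(groups) {
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups))
  )
}

#' Classic one-way fixed-effects ANOVA
#'
#' @param groups named list of numeric vectors, one per group (k >= 2,
#'   each n >= 2)
#' @return list with `statistic` (F), `df1` (k - 1), `df2` (N - k),
#'   `p_value`, and `variant = "classic"`
#' @export
one_way_anova <- function(groups) {
  groups <- check_groups(groups)
  d <- groups_to_long(groups)
  fit <- stats::oneway.test(value ~ group, data = d, var.equal = TRUE)
  list(statistic = unname(fit$statistic),
       df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]),
       p_value = unname(fit$p.value), variant = "classic")
}

#' Welch's heteroscedasticity-robust one-way ANOVA
#'
#' Group weights `n_i / s_i^2` with the Welch-Satterthwaite denominator
#' degrees of freedom (generally non-integer). Coincides with the classic
#' F when all group variances and sizes are equal.
#'
#' @inheritParams one_way_anova
#' @return list as [one_way_anova()] with `variant = "welch"`
#' @export
welch_anova <- function(groups) {
  groups <- check_groups(groups, need_var = TRUE)
  d <- groups_to_long(groups)
  fit <- stats::oneway.test(value ~ group, data = d, var.equal = FALSE)
  list(statistic = unname(fit$statistic),
       df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]),
       p_value = unname(fit$p.value), variant = "welch")
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on absolute deviations from the group centre. The default
#' centre is the median (the Brown-Forsythe form, the common default of
#' assumption-checking tooling); mean-centring gives the original test.
#'
#' @inheritParams one_way_anova
#' @param center `"median"` (default) or `"mean"`
#' @return list with `statistic` (F), `df1`, `df2`, `p_value`, `center`
#' @export
levene_test <- function(groups, center = c("median", "mean")) {
  groups <- check_groups(groups)
  center <- match.arg(center)
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("all groups constant: deviations are all zero")
  }
  d <- groups_to_long(groups)
  fit <- car::leveneTest(value ~ group, data = d,
                         center = if (center == "median") stats::median
                                  else mean)
  list(statistic = fit[1, "F value"], df1 = fit[1, "Df"],
       df2 = fit[2, "Df"], p_value = fit[1, "Pr(>F)"], center = center)
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric vector (typically ANOVA residuals), 3 <= n <= 5000
#' @return list with `statistic` (W) and `p_value`
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("values must be finite")
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  fit <- stats::shapiro.test(x)
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}

#' Tukey HSD post hoc comparisons
#'
#' Studentized-range adjusted pairwise comparisons under the classic
#' pooled-variance ANOVA model, with compact-letter display.
#'
#' @inheritParams one_way_anova
#' @param alpha significance level for the letter display
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean of `group1` minus mean of `group2`), `lwr`, `upr`, `p_adj`;
#'   attribute `letters` is the compact letter display (groups sharing a
#'   letter are not separated at `alpha`).
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  d <- groups_to_long(groups)
  tk <- stats::TukeyHSD(stats::aov(value ~ group, data = d))$group
  pr <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    group1 = vapply(pr, `[`, "", 1), group2 = vapply(pr, `[`, "", 2),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"], stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "letters") <- sig_letters(out, names(groups),
                                      vapply(groups, mean, numeric(1)),
                                      alpha)
  out
}

#' Games-Howell post hoc comparisons
#'
#' Pairwise comparisons that do not assume equal variances: for each pair,
#' `t = (m_i - m_j) / sqrt(s_i^2/n_i + s_j^2/n_j)` with Welch-Satterthwaite
#' degrees of freedom, and the adjusted p-value from the studentized range
#' distribution with `q = |t| * sqrt(2)` and k groups. The companion post
#' hoc to [welch_anova()].
#'
#' @inheritParams tukey_hsd
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`,
#'   `se`, `statistic` (t), `df` (non-integer), `p_adj`; attribute
#'   `letters` as in [tukey_hsd()].
#' @export
games_howell <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups, need_var = TRUE)
  k <- length(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  n <- lengths(groups)
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(v[i] / n[i] + v[j] / n[j])
    t_stat <- (m[i] - m[j]) / se
    df <- (v[i] / n[i] + v[j] / n[j])^2 /
      ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(abs(t_stat) * sqrt(2), k, df, lower.tail = FALSE)
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               diff = m[i] - m[j], se = se, statistic = t_stat, df = df,
               p_adj = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "letters") <- sig_letters(out, names(groups), m, alpha)
  out
}

# Compact letter display by insert-and-absorb over maximal sets of
# mutually non-separated groups; letters ordered by decreasing group mean.
sig_letters <- function(pairs, group_names, group_means, alpha) {
  k <- length(group_names)
  sep <- matrix(FALSE, k, k, dimnames = list(group_names, group_names))
  for (r in seq_len(nrow(pairs))) {
    if (pairs$p_adj[r] < alpha) {
      sep[pairs$group1[r], pairs$group2[r]] <- TRUE
      sep[pairs$group2[r], pairs$group1[r]] <- TRUE
    }
  }
  # maximal subsets with no internal separation
  subsets <- list()
  for (size in k:1) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      if (any(sep[idx, idx])) next
      covered <- any(vapply(subsets, function(s) all(idx %in% s),
                            logical(1)))
      if (!covered) subsets <- c(subsets, list(idx))
    }
  }
  ord <- order(vapply(subsets, function(s) -max(group_means[s]), numeric(1)))
  subsets <- subsets[ord]
  letters_out <- stats::setNames(rep("", k), group_names)
  for (i in seq_along(subsets)) {
    letters_out[subsets[[i]]] <- paste0(letters_out[subsets[[i]]],
                                        letters[i])
  }
  letters_out
}

#' Assumption-gated comparison of groups
#'
#' The decision flow used for every per-plot metric: Shapiro-Wilk on the
#' ANOVA residuals and Levene's test are always computed and reported;
#' routing is driven by Levene only (with the small per-site replication
#' of this design, normality tests have almost no power and the analysis
#' never switches methods on them). If Levene's p-value falls below
#' `alpha`, the omnibus test is [welch_anova()] with [games_howell()] post
#' hoc; otherwise the classic [one_way_anova()] with [tukey_hsd()]. When
#' Levene flags unequal spread but some group is constant (possible for
#' discrete per-plot metrics such as richness), Welch weights are
#' undefined and the comparison falls back to the classic path, recording
#' the forced route.
#'
#' @inheritParams one_way_anova
#' @param alpha routing and letter-display significance level
#' @param metric label carried into the result
#' @return object of class `group_comparison`: `metric`, `groups`,
#'   `normality`, `homoscedasticity`, `omnibus`, `posthoc` (all
#'   `k*(k-1)/2` pairs), `letters`, and `route`
#'   (`"classic+tukey"` or `"welch+games-howell"`).
#' @export
route_comparison <- function(groups, alpha = 0.05, metric = "metric") {
  groups <- check_groups(groups)
  resid <- unlist(lapply(groups, function(x) x - mean(x)), use.names = FALSE)
  normality <- shapiro_wilk(resid)
  homo <- levene_test(groups)
  welch_feasible <- all(vapply(groups, stats::var, numeric(1)) > 0)
  if (homo$p_value < alpha && welch_feasible) {
    omnibus <- welch_anova(groups)
    posthoc <- games_howell(groups, alpha)
    route <- "welch+games-howell"
  } else {
    omnibus <- one_way_anova(groups)
    posthoc <- tukey_hsd(groups, alpha)
    route <- if (homo$p_value < alpha) {
      "classic+tukey (welch infeasible: zero-variance group)"
    } else {
      "classic+tukey"
    }
  }
  structure(
    list(metric = metric, groups = groups, alpha = alpha,
         normality = normality, homoscedasticity = homo,
         omnibus = omnibus, posthoc = posthoc,
         letters = attr(posthoc, "letters"), route = route),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Comparison of", x$metric, "across", length(x$groups), "groups\n")
  cat(sprintf("  Shapiro-Wilk on residuals: W = %.3f, p = %.3g\n",
              x$normality$statistic, x$normality$p_value))
  cat(sprintf("  Levene (%s-centred): F = %.3f, p = %.3g -> route %s\n",
              x$homoscedasticity$center, x$homoscedasticity$statistic,
              x$homoscedasticity$p_value, x$route))
  cat(sprintf("  Omnibus %s: F(%.4g, %.4g) = %.3f, p = %.3g\n",
              x$omnibus$variant, x$omnibus$df1, x$omnibus$df2,
              x$omnibus$statistic, x$omnibus$p_value))
  cat("  Letters:", paste(names(x$letters), x$letters, sep = ":",
                          collapse = "  "), "\n")
  invisible(x)
}

#' Per-plot structural metrics of a chronosequence
#'
#' The replicated (per-plot) values of every metric that the
#' chronosequence comparison uses: species richness, Shannon H', effective
#' number of species, A-index, stem density (N ha-1), basal-area dominance
#' (m2 ha-1), and stand volume (m3 ha-1).
#'
#' @param chrono a [chronosequence()]
#' @param mc morphic coefficient for the volume column
#' @return data.frame with one row per plot
#' @export
plot_metrics <- function(chrono, mc = 0.5) {
  stopifnot(inherits(chrono, "chronosequence"))
  div <- site_diversity(chrono, scope = "plot")
  a <- attr(site_a_summary(chrono), "per_plot")
  key <- paste(div$site, div$plot)
  rec_key <- paste(chrono$records$site, chrono$records$plot)
  area <- chrono$plots$area_m2[match(key, paste(chrono$plots$site,
                                                chrono$plots$plot))]
  dens <- dom <- vol <- numeric(length(key))
  for (i in seq_along(key)) {
    r <- chrono$records[rec_key == key[i], , drop = FALSE]
    dens[i] <- nrow(r) / area[i] * 1e4
    if (nrow(r) > 0) {
      g <- basal_area(r$basal_diameter_cm)
      dom[i] <- sum(g) / area[i] * 1e4
      vol[i] <- sum(stem_volume(g, r$height_m, mc)) / area[i] * 1e4
    }
  }
  data.frame(site = div$site, plot = div$plot, richness = div$richness,
             shannon_h = div$shannon_h,
             effective_species = div$effective_species,
             a_index = a$a_index[match(key, paste(a$site, a$plot))],
             abundance = dens, dominance = dom, volume = vol)
}

#' Compare a per-plot metric across chronosequence stages
#'
#' Computes the chosen metric for every plot and runs the assumption-gated
#' [route_comparison()] with sites as groups.
#'
#' @param chrono a [chronosequence()] (the sampling design here has four
#'   plots per site)
#' @param metric one of `"richness"`, `"effective_species"`, `"a_index"`,
#'   `"abundance"`, `"dominance"`, `"volume"`
#' @param alpha routing significance level
#' @param mc morphic coefficient (volume metric only)
#' @return a `group_comparison` (see [route_comparison()])
#' @export
compare_metric <- function(chrono,
                           metric = c("richness", "effective_species",
                                      "a_index", "abundance", "dominance",
                                      "volume"),
                           alpha = 0.05, mc = 0.5) {
  metric <- match.arg(metric)
  pm <- plot_metrics(chrono, mc = mc)
  vals <- pm[[metric]]
  if (any(is.na(vals))) {
    stop("metric '", metric, "' is undefined for some plot ",
         "(empty plots cannot be compared)")
  }
  groups <- split(vals, factor(pm$site, levels = chrono$site_levels))
  route_comparison(groups, alpha = alpha, metric = metric)
}
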