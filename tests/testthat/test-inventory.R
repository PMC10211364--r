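test_that("a small stem table parses into the expected structure", {
  path <- tempfile(fileext = ".csv")
  write_inventory(tiny_chrono(), path)
  ch <- read_inventory(path)
  expect_s3_class(ch, "chronosequence")
  expect_identical(site_labels(ch), c("10", "20"))
  expect_identical(nrow(ch$records), 6L)
  expect_identical(attr(ch, "n_excluded"), 0L)
  expect_equal(unname(site_area_m2(ch)), c(1600, 1600))

  # tab-delimited and remapped column names are accepted
  path2 <- tempfile(fileext = ".tsv")
  df <- utils::read.table(path, header = TRUE, sep = ",")
  names(df)[names(df) == "basal_diameter_cm"] <- "d10"
  utils::write.table(df, path2, sep = "\t", row.names = FALSE)
  ch2 <- read_inventory(path2, config = list(diameter = "d10"))
  expect_equal(sort(ch2$records$basal_diameter_cm),
               sort(ch$records$basal_diameter_cm))
})

test_that("sub-census stems are dropped with a warning and counted", {
  path <- tempfile(fileext = ".csv")
  rec <- make_records("10", "p1", c("Acacia farnesiana", "Celtis pallida"),
                      d = c(0.5, 2), h = c(0.8, 1.5))
  utils::write.table(cbind(rec[1:2], area_m2 = 1600, rec[3:5]), path,
                     sep = ",", row.names = FALSE)
  expect_warning(ch <- read_inventory(path), "census threshold")
  expect_identical(attr(ch, "n_excluded"), 1L)
  expect_identical(ch$records$species, "Celtis pallida")
})

test_that("malformed inventories fail with informative errors", {
  p <- tempfile(fileext = ".csv")
  writeLines("site,plot,species,basal_diameter_cm,height_m", p)
  expect_error(read_inventory(p), "no records")

  writeLines(c("site,plot,species,height_m", "a,p1,X,2"), p)
  expect_error(read_inventory(p), "basal_diameter_cm")

  writeLines(c("site,plot,species,basal_diameter_cm,height_m",
               "a,p1,X,two,1.5"), p)
  expect_error(read_inventory(p), "line\\(s\\) 2")

  expect_error(read_inventory(tempfile()), "not found")
})

test_that("construction enforces census and structural invariants", {
  bad <- make_records("10", "p1", "Acacia farnesiana", d = 0.5)
  expect_error(chronosequence(bad), "census rule")
  bad <- make_records("10", "p1", "Acacia farnesiana", h = -1)
  expect_error(chronosequence(bad), "positive")
  bad <- make_records("10", "p1", "  ")
  expect_error(chronosequence(bad), "species")
  rec <- make_records("10", "p1", "Acacia farnesiana")
  expect_error(
    chronosequence(rec, plots = data.frame(site = "10",
                                           plot = c("p1", "p1"),
                                           area_m2 = 1600)),
    "unique")
  expect_error(
    chronosequence(rec, plots = data.frame(site = "10",
                                           plot = c("p1", "p2"),
                                           area_m2 = c(1600, 400))),
    "share one area")
  # case and whitespace variants of a binomial are folded together
  rec2 <- make_records("10", "p1", c("Acacia  farnesiana",
                                     "ACACIA FARNESIANA "))
  expect_identical(unique(chronosequence(rec2)$records$species),
                   "Acacia farnesiana")
})

test_that("round-tripping preserves the record multiset and abundances", {
  ch <- simulate_chronosequence(paperlike_config(seed = 11))
  path <- tempfile(fileext = ".csv")
  write_inventory(ch, path)
  ch2 <- read_inventory(path)
  key <- function(x) sort(with(x$records, paste(site, plot, species,
                                                round(basal_diameter_cm, 9),
                                                round(height_m, 9))))
  expect_identical(key(ch2), key(ch))

  a1 <- pooled_abundance(ch)
  a2 <- pooled_abundance(ch2)
  sp <- sort(colnames(a1))
  expect_equal(unclass(a1)[, sp], unclass(a2)[site_labels(ch), sp],
               tolerance = 1e-12, ignore_attr = TRUE)

  # second round trip is exact (idempotence)
  path2 <- tempfile(fileext = ".csv")
  write_inventory(ch2, path2)
  expect_identical(key(read_inventory(path2)), key(ch2))
})

test_that("pooled abundance scales counts to per-hectare densities", {
  rec <- make_records("10", "p1", rep("Acacia farnesiana", 8))
  expect_equal(as.numeric(pooled_abundance(chronosequence(rec))), 50)

  # 915 stems over four 1600 m2 plots
  rec <- make_records("10", rep(paste0("p", 1:4), length.out = 915),
                      rep("Acacia farnesiana", 915))
  expect_equal(round(as.numeric(pooled_abundance(chronosequence(rec))), 1),
               1429.7)

  # conservation: row sums equal total records / site area * 1e4, and a
  # species recorded nowhere never appears as a column
  ch <- random_chrono(5)
  m <- pooled_abundance(ch)
  for (s in site_labels(ch)) {
    n_s <- sum(ch$records$site == s)
    expect_equal(sum(m[s, ]), n_s / site_area_m2(ch)[[s]] * 1e4,
                 tolerance = 1e-12)
  }
  expect_true(all(colSums(m) > 0))
  expect_setequal(colnames(m), unique(ch$records$species))
})
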