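pep_rows <- function(peptide_id, forms, intensities, dose = 0, rep = 1) {
  data.frame(peptide_id = peptide_id, modform = forms, marks = forms,
             dose = dose, replicate = rep, intensity = intensities)
}

test_that("stoichiometries are intensity fractions of the peptide group", {
  tab <- rbind(pep_rows("p1", c("K23ac", "unmod"), c(25, 75)),
               pep_rows("p2", c("K9ac"), 500),  # single observed form
               pep_rows("p3", c("a", "b", "c"), c(10, 30, 60)))
  expect_warning(st <- compute_stoichiometries(tab), regexp = NA)
  expect_equal(st$stoichiometry[st$peptide_id == "p1" & st$modform == "K23ac"],
               25)
  expect_equal(st$stoichiometry[st$peptide_id == "p2"], 100)
  expect_true(all(st$no_unmod[st$peptide_id == "p2"]))
  expect_equal(sort(st$stoichiometry[st$peptide_id == "p3"]), c(10, 30, 60))
  expect_error(compute_stoichiometries(
    pep_rows("p", c("x", "unmod"), c(0, 0))), "zero total")
})

test_that("stoichiometries of one peptide group sum to 100% on noisy data", {
  truth <- tiny_truth()
  set.seed(19)
  tab <- generate_histone_dataset(truth, noise_cv = 0.2)
  st <- compute_stoichiometries(tab)
  # modified forms + implied unmodified complement: per-group totals
  totals <- aggregate(stoichiometry ~ peptide_id + dose + replicate,
                      data = st, FUN = sum)
  expect_true(all(totals$stoichiometry <= 100 + 1e-9))
  # recompute including the unmodified rows directly from intensities
  key <- interaction(tab$peptide_id, tab$dose, tab$replicate)
  for (g in split(tab, key)) {
    frac <- 100 * g$intensity / sum(g$intensity)
    got <- st[st$peptide_id == g$peptide_id[1] & st$dose == g$dose[1] &
                st$replicate == g$replicate[1], ]
    expect_equal(sum(got$stoichiometry),
                 sum(frac[g$modform != "unmod"]), tolerance = 1e-9)
  }
})

test_that("reproducibility filter applies the mean and SD rules", {
  st <- rbind(
    stoich_rows("keep",    c(3, 5, 7)),          # mean 5, sd 2 -> kept
    stoich_rows("low",     c(0.4, 0.5, 0.6)),    # mean 0.5 -> dropped
    stoich_rows("noisy",   c(0.1, 1.4, 7.5)))    # mean 3, sd ~4 -> dropped
  kept <- apply_reproducibility_filter(st, min_mean = 1, reference = 0)
  expect_identical(kept$modform, "keep")
  expect_equal(kept$mean, 5)
  expect_equal(kept$sd, 2)
})

test_that("filter in 'all' mode requires the rule at every dose", {
  st <- rbind(stoich_rows("m", c(4, 5, 6), dose = 0),
              stoich_rows("m", c(0.5, 0.6, 0.7), dose = 10))
  expect_identical(nrow(apply_reproducibility_filter(st, reference = "all")),
                   0L)
  expect_identical(
    apply_reproducibility_filter(st, reference = 0)$modform, "m")
})

test_that("responsiveness is a boundary-inclusive fold change with direction", {
  st <- rbind(stoich_rows("down",  c(8, 8, 8),   dose = 0.1),
              stoich_rows("down",  c(2, 2, 2),   dose = 30),
              stoich_rows("flat",  c(5, 5, 5),   dose = 0.1),
              stoich_rows("flat",  c(4, 4, 4),   dose = 30),
              stoich_rows("up",    c(2, 2, 2),   dose = 0.1),
              stoich_rows("up",    c(4, 4, 4),   dose = 30),
              stoich_rows("gone",  c(5, 5, 5),   dose = 0.1),
              stoich_rows("gone",  c(0, 0, 0),   dose = 30))
  resp <- call_responsive_marks(st, 0.1, 30, fc_threshold = 2)
  get <- function(m) resp[resp$modform == m, ]
  expect_true(get("down")$responsive)
  expect_identical(get("down")$direction, "decrease")
  expect_false(get("flat")$responsive)
  expect_true(get("up")$responsive)        # ratio exactly 2, inclusive
  expect_identical(get("up")$direction, "increase")
  expect_true(get("gone")$responsive)      # zero mean -> infinite ratio
  expect_true(get("gone")$infinite_ratio)
  expect_error(call_responsive_marks(st, 0.1, 99), "must be present")
})

test_that("filters commute: reproducibility then responsiveness is an intersection", {
  truth <- tiny_truth()
  set.seed(23)
  tab <- generate_histone_dataset(truth)
  st <- compute_stoichiometries(tab)
  kept <- apply_reproducibility_filter(st)
  st_kept <- merge(st, kept[, c("peptide_id", "modform")],
                   by = c("peptide_id", "modform"))
  a <- call_responsive_marks(st_kept, 0.1, 30)
  b <- call_responsive_marks(st, 0.1, 30)
  b <- merge(b, kept[, c("peptide_id", "modform")],
             by = c("peptide_id", "modform"))
  a <- a[order(a$peptide_id, a$modform), ]
  b <- b[order(b$peptide_id, b$modform), ]
  expect_equal(a$responsive, b$responsive)
  expect_equal(a$fold_change, b$fold_change)
})

test_that("mark aggregation sums stoichiometries of co-modified forms", {
  st <- rbind(stoich_rows("K14ac", 10, peptide_id = "p", marks = "H3K14ac"),
              stoich_rows("K9acK14ac", 3, peptide_id = "p",
                          marks = "H3K9ac;H3K14ac"),
              stoich_rows("K9ac", 7, peptide_id = "p", marks = "H3K9ac"))
  agg <- aggregate_mark_stoichiometry(st)
  expect_equal(agg$stoichiometry[agg$mark == "H3K14ac"], 13)
  expect_equal(agg$stoichiometry[agg$mark == "H3K9ac"], 10)
})

test_that("noiseless 4PL fits are exact and flat responses are flagged", {
  d <- c(0, 0.1, 1, 10, 30)
  y <- four_pl(d, top = 40, bottom = 0, ic50 = 1, hill = 1)
  fit <- fit_inhibition_curve(d, y)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 1, tolerance = 1e-6)
  expect_equal(fit$top, 40, tolerance = 1e-4)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  flat <- fit_inhibition_curve(d, rep(12, 5))
  expect_true(!flat$converged || flat$insensitive)
  expect_error(fit_inhibition_curve(c(0, 1, 10), c(1, 2, 3)), "4 dose")
})

test_that("IC50 recovery from noisy triplicates is within 2-fold almost always", {
  truth <- tiny_truth()  # planted IC50 1 uM on K1ac
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    tab <- generate_histone_dataset(truth, noise_cv = 0.1, n_replicates = 3)
    st <- compute_stoichiometries(tab)
    means <- aggregate(stoichiometry ~ dose, FUN = mean,
                       data = st[st$modform == "K1ac", ])
    fit <- fit_inhibition_curve(means$dose, means$stoichiometry)
    fit$converged && fit$ic50 > 0.5 && fit$ic50 < 2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("biomarker panel orders KATs by their planted IC50 hierarchy", {
  truth <- synthetic_truth()
  set.seed(31)
  tab <- generate_histone_dataset(truth)
  st <- compute_stoichiometries(tab)
  kept <- apply_reproducibility_filter(st)
  st_kept <- merge(st, kept[, c("peptide_id", "modform")],
                   by = c("peptide_id", "modform"))
  panel <- biomarker_panel_report(st_kept)
  ic <- setNames(panel$ic50, panel$kat)
  expect_true(ic[["KAT6A/B"]] < ic[["KAT7"]])
  expect_true(ic[["KAT7"]] < ic[["KAT8"]])
  expect_true(ic[["KAT8"]] < ic[["KAT5"]])
  expect_identical(panel$status[panel$kat == "KAT2A/B"], "insensitive")
  expect_identical(panel$status[panel$kat == "KAT3A/B"], "insensitive")
})

test_that("panel reports missing marks and a selective-compound scenario", {
  # WM-1119-like truth: only the KAT6 biomarker is planted sensitive
  mt <- default_mark_table()
  mt$ic50[mt$marks != "H3K23ac"] <- NA
  truth <- synthetic_truth(mark_table = mt)
  set.seed(37)
  tab <- generate_histone_dataset(truth)
  st <- compute_stoichiometries(tab)
  panel <- biomarker_panel_report(st)
  expect_identical(panel$status[panel$kat == "KAT6A/B"], "sensitive")
  expect_true(all(panel$status[panel$kat != "KAT6A/B"] == "insensitive"))
  # assigned mark absent from the matrix -> "not detected" row
  panel2 <- biomarker_panel_report(
    st[st$marks != "H3K23ac", , drop = FALSE])
  expect_identical(panel2$status[panel2$kat == "KAT6A/B"], "not detected")
})
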