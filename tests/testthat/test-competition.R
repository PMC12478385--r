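make_capture <- function(abund, resin, dose, replicate = NULL) {
  n <- length(resin)
  capture_dataset(abund, data.frame(
    sample_id = paste0("s", seq_len(n)), resin = resin, dose = dose,
    replicate = replicate %||% ave(seq_len(n), resin, dose, FUN = seq_along)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("normalization equalizes the per-sample statistic and 'none' is identity", {
  set.seed(4)
  m <- matrix(rexp(60, 1e-5), 20, 3,
              dimnames = list(paste0("P", 1:20), NULL))
  m[3, 2] <- NA
  cap <- make_capture(m, rep("bisubstrate", 3), c(0, 0, 0))
  norm <- normalize_abundances(cap, "median")
  meds <- apply(norm$abundance, 2, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(meds[[1]], 3))
  expect_identical(which(is.na(norm$abundance)), which(is.na(m)))
  # sample B = 2x sample A elementwise -> scaled back to ratio 1
  m2 <- cbind(A = m[, 1], B = 2 * m[, 1])
  cap2 <- make_capture(m2, rep("bisubstrate", 2), c(0, 0))
  norm2 <- normalize_abundances(cap2, "median")
  expect_equal(unname(norm2$abundance[, 2] / norm2$abundance[, 1]),
               rep(1, 20), tolerance = 1e-12)
  expect_identical(normalize_abundances(cap, "none"), cap)
  norm3 <- normalize_abundances(cap, "total")
  tots <- colSums(norm3$abundance, na.rm = TRUE)
  expect_equal(unname(tots), rep(tots[[1]], 3))
})

test_that("enrichment calls match hand arithmetic and the specificity rule", {
  set.seed(9)
  jit <- function(x) x * exp(rnorm(length(x), 0, 0.01))
  abund <- rbind(
    SPEC = c(jit(rep(200, 3)), jit(rep(100, 3))),  # ~2x over capped
    FLAT = c(rep(150, 3), rep(150, 3)))            # identical vectors
  cap <- make_capture(abund, rep(c("bisubstrate", "capped"), each = 3),
                      rep(0, 6))
  res <- test_enrichment(cap)
  spec <- res[res$protein == "SPEC", ]
  expect_equal(spec$log2fc_vs_capped, 1, tolerance = 0.05)
  expect_true(spec$specific)
  flat <- res[res$protein == "FLAT", ]
  expect_equal(flat$log2fc_vs_capped, 0)
  expect_false(flat$specific)
  # the specific flag is exactly the thresholded rule
  expect_equal(res$specific,
               !is.na(res$p_value) & res$log2fc_vs_capped > 0.6 &
                 res$p_value < 0.05)
})

test_that("enrichment agrees with a brute-force per-protein recomputation", {
  truth <- tiny_truth()
  set.seed(21)
  cap <- generate_capture_dataset(truth, n_background = 10, n_coabinders = 3)
  res <- test_enrichment(cap)
  s <- cap$samples
  bis <- s$resin == "bisubstrate" & s$dose == 0
  capd <- s$resin == "capped"
  floor_val <- 0.5 * min(cap$abundance, na.rm = TRUE)
  for (p in res$protein) {
    xb <- log2(cap$abundance[p, bis])
    xc <- cap$abundance[p, capd]
    xc[is.na(xc)] <- floor_val
    xc <- log2(xc)
    row <- res[res$protein == p, ]
    expect_equal(row$log2fc_vs_capped, mean(xb) - mean(xc))
    expect_equal(row$p_value, t.test(xb, xc)$p.value)
  }
})

test_that("proteins missing from all bisubstrate vehicle samples are dropped with a warning", {
  abund <- rbind(OK = rep(100, 6), GONE = c(NA, NA, NA, 50, 50, 50))
  cap <- make_capture(abund, rep(c("bisubstrate", "capped"), each = 3),
                      rep(0, 6))
  expect_warning(res <- test_enrichment(cap), "excluded")
  expect_identical(res$protein, "OK")
})

test_that("noiseless competition profiles equal the planted curve exactly", {
  truth <- tiny_truth()
  set.seed(2)
  cap <- generate_capture_dataset(truth, n_background = 5, n_coabinders = 2,
                                  doses = c(0, 0.5, 5), noise_cv = 0)
  prof <- compute_competition_profiles(cap, restrict = FALSE)
  # member P1: IC50 0.5, hill 1 -> log2fc = log2(1 - d/(d + 0.5))
  expected <- log2(1 - c(0, 0.5, 5) / (c(0, 0.5, 5) + 0.5))
  expected[1] <- 0
  expect_equal(unname(prof$log2fc["P1", ]), expected)
  # vehicle-vs-vehicle column is identically zero for everyone
  expect_true(all(prof$log2fc[, "d0"] == 0))
  # at dose = IC50 (hill 1) the log2 fold change is exactly -1
  expect_equal(unname(prof$log2fc["P1", "d0.5"]), -1)
  expect_error(compute_competition_profiles(
    make_capture(matrix(1, 1, 2, dimnames = list("P", NULL)),
                 rep("bisubstrate", 2), c(1, 1))),
    "vehicle")
})

test_that("missing treated values are imputed at the floor and read as full occupancy", {
  abund <- rbind(GONE = c(1000, 1000, 1000, NA, NA, NA, 900, 900, 900),
                 REF  = c(10, 11, 10, 10, 11, 10, 10, 10, 10))
  cap <- make_capture(abund,
                      c(rep("bisubstrate", 6), rep("capped", 3)),
                      c(0, 0, 0, 10, 10, 10, 0, 0, 0))
  prof <- compute_competition_profiles(cap, imputation_floor = 0.01,
                                       restrict = FALSE)
  expect_gt(prof$occupancy["GONE", "d10"], 0.99)
})

test_that("occupancy derives from log2fc with clamping to [0, 1]", {
  prof <- structure(list(
    proteins = c("A", "B", "C"), doses = c(0, 1),
    log2fc = rbind(A = c(0, -2), B = c(0, 0.5), C = c(0, 0)),
    p_values = matrix(NA_real_, 3, 2)), class = "competition_profiles")
  prof$occupancy <- pmin(pmax(1 - 2^prof$log2fc, 0), 1)
  occ <- occupancy_matrix(prof)
  expect_equal(unname(occ["A", 2]), 0.75)   # 1 - 2^-2
  expect_equal(unname(occ["B", 2]), 0)      # increased capture clamps to 0
  expect_equal(unname(occ["C", 2]), 0)      # log2fc = 0 -> occupancy 0
  expect_true(all(occ >= 0 & occ <= 1))
})

test_that("occupancy is monotone non-increasing in log2fc", {
  lfc <- seq(-8, 3, by = 0.25)
  occ <- pmin(pmax(1 - 2^lfc, 0), 1)
  expect_true(all(diff(occ) <= 0))
})

test_that("ranking puts the most significantly competed protein first", {
  truth <- tiny_truth()  # P1-P3 (IC50 0.5) sensitive at 0.5 uM, Q1-Q2 not
  set.seed(13)
  cap <- generate_capture_dataset(truth, n_background = 10, n_coabinders = 3,
                                  doses = c(0, 0.5, 5))
  prof <- compute_competition_profiles(cap)
  rk <- rank_competed(prof, 0.5)
  expect_true(rk$protein[1] %in% c("P1", "P2", "P3", "X1"))
  expect_error(rank_competed(prof, 99), "not in the profile ladder")
  # two proteins, one competed: competed first; all-zero ties alphabetical
  prof2 <- structure(list(
    proteins = c("B", "A"), doses = c(0, 1),
    log2fc = rbind(B = c(0, 0), A = c(0, -2)),
    p_values = rbind(B = c(NA, 0.9), A = c(NA, 0.001))),
    class = "competition_profiles")
  prof2$occupancy <- pmin(pmax(1 - 2^prof2$log2fc, 0), 1)
  expect_identical(rank_competed(prof2, 1)$protein, c("A", "B"))
  prof2$log2fc[] <- 0
  prof2$p_values[] <- NA
  expect_identical(rank_competed(prof2, 1)$protein, c("A", "B"))
})

test_that("capture TSV round-trip preserves the dataset", {
  truth <- tiny_truth()
  set.seed(6)
  cap <- generate_capture_dataset(truth, n_background = 4, n_coabinders = 2,
                                  detection_floor = 2e5)
  qf <- tempfile(fileext = ".tsv"); af <- tempfile(fileext = ".tsv")
  write_capture_dataset(cap, qf, af)
  back <- read_capture_dataset(qf, af)
  expect_equal(back$abundance, cap$abundance, tolerance = 1e-6)
  expect_equal(back$samples$dose, cap$samples$dose)
  expect_equal(back$samples$resin, cap$samples$resin)
})
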