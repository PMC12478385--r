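two_chain_bundle <- function(n1 = 20, n2 = 20, offset = 5, seed = 3,
                             pae = NULL, plddt = NULL) {
  set.seed(seed)
  n <- n1 + n2
  chain <- rep(c("A", "B"), c(n1, n2))
  coords <- rbind(cbind(3.8 * seq_len(n1), 0, 0),
                  cbind(3.8 * seq_len(n2), offset, 0))
  pae_bundle(pae = pae %||% matrix(runif(n * n, 0, 30), n, n),
             chain = chain, plddt = plddt %||% runif(n, 50, 95),
             iptm = 0.5, coords = coords,
             resid = sample(c("ALA", "GLY"), n, replace = TRUE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

three_chain_bundle <- function(offsetC = 50) {
  n <- 30
  chain <- rep(c("A", "B", "C"), each = 10)
  coords <- rbind(cbind(3.8 * 1:10, 0, 0),
                  cbind(3.8 * 1:10, 5, 0),
                  cbind(3.8 * 1:10, offsetC, 0))
  pae_bundle(matrix(10, n, n) - diag(10, n), chain, rep(75, n), 0.6,
             coords = coords)
}

test_that("bundle constructor enforces its invariants", {
  expect_error(pae_bundle(matrix(1, 3, 4), rep("A", 3), rep(90, 3), 0.5),
               "square")
  expect_error(pae_bundle(matrix(1, 4, 4), rep("A", 3), rep(90, 3), 0.5),
               "residues")
  expect_error(pae_bundle(matrix(1, 3, 3), rep("A", 3), rep(90, 3), 0.5),
               "2 chains")
  expect_error(pae_bundle(matrix(-1, 2, 2), c("A", "B"), c(90, 90), 0.5),
               "non-negative")
})

test_that("bundle round-trips through PAE-JSON and mmCIF losslessly", {
  b <- two_chain_bundle(n1 = 8, n2 = 6)
  d <- withr::local_tempdir()
  write_af_bundle(b, file.path(d, "pae.json"), file.path(d, "model.cif"))
  b2 <- parse_af_bundle(file.path(d, "pae.json"), file.path(d, "model.cif"),
                        iptm = b$iptm)
  expect_equal(b2$pae, b$pae, tolerance = 1e-5)
  expect_identical(b2$chain, b$chain)
  expect_equal(b2$coords, b$coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(b2$plddt, b$plddt, tolerance = 1e-2)
  # glycine rows carry CA as representative atom, others CB
  atoms <- readLines(file.path(d, "model.cif"))
  gly <- grep(" GLY ", atoms, value = TRUE)
  expect_true(all(grepl(" CA ", gly)))
})

test_that("PAE/structure dimension mismatch errors", {
  b <- two_chain_bundle(n1 = 8, n2 = 6)
  d <- withr::local_tempdir()
  write_af_bundle(b, file.path(d, "pae.json"), file.path(d, "model.cif"))
  jsonlite::write_json(list(predicted_aligned_error = matrix(1, 10, 10)),
                       file.path(d, "bad.json"))
  expect_error(parse_af_bundle(file.path(d, "bad.json"),
                               file.path(d, "model.cif"), iptm = 0.5),
               "does not match")
})

test_that("interface contacts match the brute-force all-pairs oracle", {
  b <- two_chain_bundle(n1 = 20, n2 = 20, offset = 7, seed = 10)
  got <- interface_contacts(b, 8)
  oracle <- contacts_oracle(b$coords, b$chain, 8)
  expect_identical(got$n_contacts, oracle$n_contacts)
  expect_identical(got$interface_residues, oracle$interface_residues)
  # far-apart chains: no contacts at all
  far <- two_chain_bundle(offset = 50)
  expect_equal(interface_contacts(far, 8)$n_contacts, 0)
  # a single pair at 7.9 A is inside the 8 A cutoff
  pair <- pae_bundle(matrix(1, 2, 2) - diag(2), c("A", "B"), c(90, 90), 0.5,
                     coords = rbind(c(0, 0, 0), c(7.9, 0, 0)))
  got2 <- interface_contacts(pair, 8)
  expect_equal(got2$n_contacts, 1L)
  expect_identical(got2$interface_residues, c(1L, 2L))
})

test_that("pDockQ matches an independent scalar evaluation of the sigmoid", {
  # fixed interface: <pLDDT> = 80 over the interface, known contact count
  b <- two_chain_bundle(n1 = 20, n2 = 20, offset = 5, seed = 2,
                        plddt = rep(80, 40))
  ic <- interface_contacts(b, 8)
  expect_gt(ic$n_contacts, 0)
  x <- 80 * log(ic$n_contacts)
  by_hand <- 0.724 / (1 + exp(-0.052 * (x - 152.611))) + 0.018
  expect_equal(compute_pdockq(b), by_hand)
  # no contacts -> exactly the baseline offset
  far <- two_chain_bundle(offset = 50)
  expect_equal(compute_pdockq(far), 0.018)
  # bounded by (b, L + b) even at a saturated interface
  sat <- two_chain_bundle(n1 = 30, n2 = 30, offset = 4, seed = 4,
                          plddt = rep(99, 60))
  k <- dockq_constants()$pdockq
  expect_gt(compute_pdockq(sat), compute_pdockq(b))
  expect_lt(compute_pdockq(sat), k[["L"]] + k[["b"]])
  expect_error(compute_pdockq(three_chain_bundle()), "compute_mpdockq")
})

test_that("mpDockQ handles multimers, zero contacts, and is contact-monotone", {
  b <- three_chain_bundle()
  ic <- interface_contacts(b, 8)
  x <- 75 * log(ic$n_contacts)
  by_hand <- 0.728 / (1 + exp(-0.098 * (x - 309.375))) + 0.262
  expect_equal(compute_mpdockq(b), by_hand)
  none <- three_chain_bundle(offsetC = 120)
  none$coords[11:20, 2] <- 60  # move chain B away too
  expect_equal(compute_mpdockq(none), 0.262)
  expect_error(compute_mpdockq(two_chain_bundle()), "pDockQ")
  # adding contacts at fixed <pLDDT> never decreases the score
  scores <- sapply(c(5, 20, 80, 320), function(k)
    0.728 / (1 + exp(-0.098 * (75 * log(k) - 309.375))) + 0.262)
  expect_true(all(diff(scores) >= 0))
})

test_that("LIS/LIA match hand arithmetic and the brute-force oracle", {
  # single qualifying pair with averaged PAE 6 at cutoff 12
  pae <- matrix(30, 4, 4); diag(pae) <- 0
  pae[1, 3] <- 4; pae[3, 1] <- 8   # mean 6 across directions
  b <- pae_bundle(pae, c("A", "A", "B", "B"), rep(90, 4), 0.5)
  ll <- compute_lis_lia(b)
  expect_equal(ll$lis, 0.5)
  expect_equal(ll$lia, 1L)
  # everything at or above the cutoff -> (0, 0)
  b0 <- pae_bundle(matrix(12, 4, 4) - 12 * diag(4), c("A", "A", "B", "B"),
                   rep(90, 4), 0.5)
  expect_equal(compute_lis_lia(b0), list(lis = 0, lia = 0L))
  # random 30 + 30 instance against the O(n^2) oracle
  set.seed(14)
  n <- 60
  pae_r <- matrix(runif(n * n, 0, 30), n, n)
  chain <- rep(c("A", "B"), each = 30)
  br <- pae_bundle(pae_r, chain, rep(80, n), 0.5)
  got <- compute_lis_lia(br, 12)
  oracle <- lis_lia_oracle(pae_r, chain, 12)
  expect_equal(got$lis, oracle$lis)
  expect_equal(got$lia, oracle$lia)
})

test_that("LIS and LIA are non-increasing as the PAE cutoff shrinks", {
  set.seed(15)
  n <- 40
  b <- pae_bundle(matrix(runif(n * n, 0, 30), n, n),
                  rep(c("A", "B"), each = 20), rep(80, n), 0.5)
  cutoffs <- c(15, 12, 9, 6, 3)
  lia <- sapply(cutoffs, function(ct) compute_lis_lia(b, ct)$lia)
  expect_true(all(diff(lia) <= 0))
})

test_that("confidence coefficient is the fraction of passing filters", {
  rec <- data.frame(iptm = 0.8, lis = 0.5, lia = 2000, dockq_proxy = 0.5)
  thr <- default_af_thresholds()
  expect_equal(confidence_coefficient(rec, thr), 1)
  rec0 <- data.frame(iptm = 0.1, lis = 0, lia = 0, dockq_proxy = 0.01)
  expect_equal(confidence_coefficient(rec0, thr), 0)
  rec2 <- data.frame(iptm = 0.8, lis = 0.5, lia = 0, dockq_proxy = 0.01)
  expect_equal(confidence_coefficient(rec2, thr), 0.5)
  expect_error(confidence_coefficient(rec, numeric(0)), "non-empty")
})

test_that("composite ranking normalizes, weights, bounds and orders", {
  recs <- data.frame(
    pair_id = c("top", "mid", "low"),
    iptm = c(0.9, 0.6, 0.1),
    lis = c(0.6, 0.3, 0),
    lia = c(2000, 1700, 0),
    dockq_proxy = c(0.6, 0.3, 0.018),
    n_contacts = c(50, 20, 0))
  rk <- composite_rank(recs)
  expect_equal(rk$composite[rk$pair_id == "top"], 3)  # maximal in all three
  expect_equal(rk$rank[rk$pair_id == "top"], 1)
  expect_equal(rk$composite[rk$pair_id == "low"], 0)  # coefficient 0
  expect_true(all(rk$composite >= 0 & rk$composite <= 3))
  # constant column maps to 0, not NaN
  recs$lia <- 1700
  rk2 <- composite_rank(recs)
  expect_true(all(rk2$norm_lia == 0))
  expect_error(composite_rank(recs[1, ]), "at least 2")
})
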