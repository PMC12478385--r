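#' Generate a synthetic affinity-capture dataset
#'
#' Emulates a dose-resolved competitive chemoproteomic experiment: nuclear
#' extract is pre-incubated with competitor at each dose, then captured on
#' a bisubstrate CoA resin; an inert capped-bead control measures
#' non-specific binding. For a complex member with capture IC50 `K`, Hill
#' slope `h` and maximal competable fraction `m`, expected abundance at
#' dose `d` is `baseline * (1 - m * d^h / (d^h + K^h))`. Two classes of
#' dose-invariant protein are emitted alongside the complex members:
#' specific CoA binders (enriched over the capped control, like the
#' non-MYST acetyltransferases a CoA resin captures, which populate the
#' insensitive clusters downstream) and non-specific background that binds
#' both resins equally and fails the enrichment test. Specific proteins
#' drop to `capped_floor` of baseline on capped beads. Noise is multiplicative log-normal with
#' coefficient of variation `noise_cv`. Abundances below `detection_floor`
#' are emitted as missing, exercising downstream imputation.
#'
#' @param truth a [synthetic_truth()].
#' @param n_background number of non-specific background proteins.
#' @param n_coabinders number of specific but dose-invariant CoA binders.
#' @param n_replicates replicates per (resin, dose) condition.
#' @param doses competitor dose ladder in uM; must include 0 (vehicle).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param baseline_log10_mean,baseline_log10_sd log10-normal draw of each
#'   protein's vehicle capture abundance.
#' @param capped_floor fraction of baseline retained by specific proteins
#'   on capped beads.
#' @param detection_floor abundances below this are reported missing
#'   (0 disables).
#' @return A [capture_dataset()].
#' @export
generate_capture_dataset <- function(truth,
                                     n_background = 100,
                                     n_coabinders = 65,
                                     n_replicates = 3,
                                     doses = c(0, 0.1, 1, 10),
                                     noise_cv = 0.1,
                                     baseline_log10_mean = 6,
                                     baseline_log10_sd = 0.4,
                                     capped_floor = 0.2,
                                     detection_floor = 0) {
  if (length(doses) == 0L) stop("dose ladder must be non-empty", call. = FALSE)
  if (!any(doses == 0)) stop("doses must include 0 (vehicle)", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)

  members <- unlist(lapply(truth$complex_specs, `[[`, "members"))
  named_binders <- c("NAT10", "ESCO1", "ESCO2", "ATAT1", "KAT2A", "KAT2B",
                     "NAA50", "NAA40")
  coabinders <- c(head(named_binders, n_coabinders),
                  if (n_coabinders > length(named_binders))
                    sprintf("CB%03d",
                            seq_len(n_coabinders - length(named_binders))))
  specific <- c(members, coabinders)
  background <- sprintf("BG%03d", seq_len(n_background))
  proteins <- c(specific, background)
  n <- length(proteins)

  baseline <- 10^rnorm(n, baseline_log10_mean, baseline_log10_sd)
  names(baseline) <- proteins

  # expected competable fraction per protein and dose
  inhib <- matrix(0, n, length(doses), dimnames = list(proteins, NULL))
  for (cs in truth$complex_specs) {
    frac <- cs$max_competition * hill_inhibition(doses, cs$ic50_capture, cs$hill)
    inhib[cs$members, ] <- matrix(frac, length(cs$members), length(doses),
                                  byrow = TRUE)
  }

  samples <- rbind(
    expand.grid(resin = "bisubstrate", dose = doses,
                replicate = seq_len(n_replicates),
                stringsAsFactors = FALSE),
    expand.grid(resin = "capped", dose = 0,
                replicate = seq_len(n_replicates),
                stringsAsFactors = FALSE))
  samples$sample_id <- sprintf("%s_d%g_r%d", substr(samples$resin, 1, 3),
                               samples$dose, samples$replicate)

  abundance <- matrix(NA_real_, n, nrow(samples),
                      dimnames = list(proteins, samples$sample_id))
  is_specific <- proteins %in% specific
  for (j in seq_len(nrow(samples))) {
    if (samples$resin[j] == "bisubstrate") {
      di <- match(samples$dose[j], doses)
      mu <- baseline * (1 - inhib[, di])
    } else {
      mu <- baseline * ifelse(is_specific, capped_floor, 1)
    }
    abundance[, j] <- mu * lognormal_noise(n, noise_cv)
  }
  if (detection_floor > 0) abundance[abundance < detection_floor] <- NA_real_

  capture_dataset(abundance, samples[, c("sample_id", "resin", "dose",
                                         "replicate")])
}

#' Generate a synthetic histone peptidoform intensity table
#'
#' Emulates bottom-up histone PTM profiling of cells treated across a dose
#' ladder. Each modified form's stoichiometry follows a 4PL decay versus
#' dose with its planted IC50 (dose-invariant when `ic50` is NA); the
#' unmodified form of each peptide absorbs the complement so that the
#' expected forms of one peptide sum to 100%. Intensities are the product
#' of a log-normal total peptide intensity and the form's stoichiometric
#' fraction, with multiplicative noise per form.
#'
#' @param truth a [synthetic_truth()].
#' @param doses dose ladder in uM, including 0 (vehicle).
#' @param n_replicates replicates per dose.
#' @param noise_cv coefficient of variation of per-form noise.
#' @param total_log10_mean,total_log10_sd log10-normal draw of each
#'   peptide's total intensity per (dose, replicate).
#' @return A `peptidoform_table` data.frame with columns `peptide_id`,
#'   `modform`, `marks`, `dose`, `replicate`, `intensity`.
#' @export
generate_histone_dataset <- function(truth,
                                     doses = c(0, 0.1, 1, 10, 30),
                                     n_replicates = 3,
                                     noise_cv = 0.1,
                                     total_log10_mean = 7,
                                     total_log10_sd = 0.3) {
  if (length(doses) == 0L) stop("dose ladder must be non-empty", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  mt <- truth$mark_table
  if (any(mt$baseline <= 0 | mt$baseline >= 100))
    stop("baseline stoichiometries must lie in (0, 100)%", call. = FALSE)

  out <- vector("list", length(unique(mt$peptide_id)))
  i <- 0L
  for (pep in unique(mt$peptide_id)) {
    forms <- mt[mt$peptide_id == pep, ]
    # expected stoichiometry (%) of each modified form at each dose
    stoich <- sapply(seq_len(nrow(forms)), function(k) {
      if (is.na(forms$ic50[k])) rep(forms$baseline[k], length(doses))
      else forms$baseline[k] *
        (1 - hill_inhibition(doses, forms$ic50[k], forms$hill[k]))
    })
    stoich <- matrix(stoich, nrow = length(doses))
    unmod <- 100 - rowSums(stoich)
    if (any(unmod < 0))
      stop(sprintf("forms of peptide %s exceed 100%% stoichiometry", pep),
           call. = FALSE)
    frac <- cbind(stoich, unmod) / 100
    labels <- c(forms$modform, "unmod")
    marks <- c(forms$marks, "")
    grid <- expand.grid(dose = doses, replicate = seq_len(n_replicates))
    total <- 10^rnorm(nrow(grid), total_log10_mean, total_log10_sd)
    rows <- do.call(rbind, lapply(seq_along(labels), function(k) {
      mu <- total * frac[match(grid$dose, doses), k]
      data.frame(peptide_id = pep, modform = labels[k], marks = marks[k],
                 dose = grid$dose, replicate = grid$replicate,
                 intensity = mu * lognormal_noise(nrow(grid), noise_cv))
    }))
    i <- i + 1L
    out[[i]] <- rows
  }
  res <- do.call(rbind, out)
  class(res) <- c("peptidoform_table", "data.frame")
  res
}

#' Generate synthetic predicted-structure bundles for a bait-candidate screen
#'
#' Emulates the output of an in-silico pulldown: for each candidate, a
#' two-chain predicted structure (bait + candidate) with a predicted
#' aligned error (PAE) matrix, per-residue pLDDT, chain-labelled
#' representative-atom coordinates and an ipTM scalar. Planted interactors
#' (`truth$af_interactors`) receive a uniformly low inter-chain PAE block
#' (a confidently docked pair has low aligned error across the whole
#' inter-chain region), a patch of inter-chain contacts within
#' `contact_distance`, high interface pLDDT and high ipTM; all other
#' candidates get inter-chain PAE near `pae_max`, chains separated by
#' `apart_distance`, and low ipTM.
#'
#' @param truth a [synthetic_truth()].
#' @param candidates character vector of candidate names; default: all
#'   annotated complex members plus planted candidates, minus the bait.
#' @param chain_lengths length-2 integer: residues in bait and candidate
#'   chains (>= 5 each).
#' @param pae_max PAE ceiling in Angstrom (non-interacting level).
#' @param interface_size residues per chain in the planted interface.
#' @param contact_distance,apart_distance inter-chain representative-atom
#'   distances (Angstrom) for planted contacts / separated chains.
#' @param symmetric emit a symmetric PAE matrix (PAE(i,j) = PAE(j,i)).
#' @return named list of [pae_bundle()] objects, one per candidate.
#' @export
generate_af_candidates <- function(truth,
                                   candidates = NULL,
                                   chain_lengths = c(60, 50),
                                   pae_max = 30,
                                   interface_size = 15,
                                   contact_distance = 6,
                                   apart_distance = 60,
                                   symmetric = TRUE) {
  if (any(chain_lengths < 5))
    stop("chain_lengths must be at least 5 residues", call. = FALSE)
  if (is.null(candidates)) {
    members <- unlist(lapply(truth$complex_specs, `[[`, "members"))
    candidates <- setdiff(members, truth$bait)
  }
  if (length(candidates) < 2L)
    stop("need at least 2 candidates for a screen", call. = FALSE)

  n1 <- chain_lengths[1]; n2 <- chain_lengths[2]; n <- n1 + n2
  chain <- rep(c("A", "B"), c(n1, n2))
  bundles <- lapply(candidates, function(cand) {
    planted <- cand %in% truth$af_interactors
    # intra-chain PAE low, inter-chain at the ceiling unless planted
    pae <- matrix(runif(n * n, 0.8 * pae_max, pae_max), n, n)
    intra <- outer(chain, chain, "==")
    pae[intra] <- runif(sum(intra), 2, 8)
    iface1 <- seq_len(min(interface_size, n1))
    iface2 <- n1 + seq_len(min(interface_size, n2))
    if (planted) pae[!intra] <- runif(sum(!intra), 3, 9)
    if (symmetric) pae <- (pae + t(pae)) / 2
    diag(pae) <- 0

    # chain A along the x axis; chain B parallel, either docked or far away
    offset <- if (planted) contact_distance else apart_distance
    coords <- rbind(
      cbind(3.8 * (seq_len(n1) - 1), 0, 0),
      cbind(3.8 * (seq_len(n2) - 1), offset, 0))
    coords <- coords + matrix(runif(3 * n, -0.3, 0.3), n, 3)

    plddt <- runif(n, 60, 80)
    if (planted) plddt[c(iface1, iface2)] <- runif(2 * length(iface1), 85, 95)
    resid <- sample(c("ALA", "LEU", "SER", "LYS", "GLY"), n, replace = TRUE)
    pae_bundle(pae = pae, chain = chain, plddt = plddt,
               iptm = if (planted) runif(1, 0.75, 0.9) else runif(1, 0.1, 0.3),
               coords = coords, resid = resid,
               pair_id = paste(truth$bait, cand, sep = "_"))
  })
  names(bundles) <- candidates
  bundles
}

#' Generate a synthetic viability dataset
#'
#' Emulates a growth-inhibition assay with time-zero and untreated-control
#' wells. Percent growth follows a logistic in log10(dose) crossing 50 at
#' the planted GI50: `PG(d) = 100 / (1 + (d / GI50)^h)`. Treated signals
#' are reconstructed from percent growth via the NCI-60 convention
#' `Ti = Tz + PG/100 * (C - Tz)` and perturbed with multiplicative
#' log-normal noise.
#'
#' @param truth a [synthetic_truth()].
#' @param doses dose ladder in uM (all > 0).
#' @param n_replicates replicates per dose.
#' @param noise_cv coefficient of variation of signal noise.
#' @param cell_line,compound labels carried into the table.
#' @param tz,control expected time-zero and untreated-control signals.
#' @return A `viability_table` data.frame with treated rows plus rows
#'   tagged `TZERO` and `CONTROL` in the `role` column.
#' @export
generate_viability_dataset <- function(truth,
                                       doses = c(0.01, 0.1, 1, 10, 100),
                                       n_replicates = 4,
                                       noise_cv = 0.05,
                                       cell_line = "BT-549",
                                       compound = "PF-9363",
                                       tz = 2000, control = 10000) {
  if (any(doses <= 0)) stop("viability doses must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  pg <- 100 * (1 - hill_inhibition(doses, truth$planted_gi50, truth$gi50_hill))
  grid <- expand.grid(dose = doses, replicate = seq_len(n_replicates))
  ti <- tz + pg[match(grid$dose, doses)] / 100 * (control - tz)
  treated <- data.frame(cell_line = cell_line, compound = compound,
                        role = "TREATED", dose = grid$dose,
                        replicate = grid$replicate,
                        signal = ti * lognormal_noise(nrow(grid), noise_cv))
  ctrl <- data.frame(cell_line = cell_line, compound = compound,
                     role = rep(c("TZERO", "CONTROL"), each = n_replicates),
                     dose = 0, replicate = rep(seq_len(n_replicates), 2),
                     signal = c(tz * lognormal_noise(n_replicates, noise_cv),
                                control * lognormal_noise(n_replicates, noise_cv)))
  res <- rbind(treated, ctrl)
  class(res) <- c("viability_table", "data.frame")
  res
}
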