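#' Sigmoid constants for pDockQ / mpDockQ
#'
#' Literature constants of the interface-quality sigmoids
#' `L / (1 + exp(-k (x - x0))) + b`, where `x` is the mean interface pLDDT
#' times the natural log of the contact count. Config-exposed rather than
#' hard-coded so alternative calibrations can be swapped in.
#' @return named list with elements `pdockq` and `mpdockq`, each
#'   `c(L, k, x0, b)`.
#' @export
dockq_constants <- function() {
  list(pdockq = c(L = 0.724, k = 0.052, x0 = 152.611, b = 0.018),
       mpdockq = c(L = 0.728, k = 0.098, x0 = 309.375, b = 0.262))
}

#' Inter-chain interface contacts
#'
#' Counts inter-chain representative-atom pairs within `distance_cutoff`
#' Angstrom and returns the interface residues (union of contact
#' participants). Each unordered residue pair counts once.
#'
#' @param bundle a [pae_bundle()] with coordinates.
#' @param distance_cutoff contact distance in Angstrom (default 8).
#' @return list with `n_contacts` (integer) and `interface_residues`
#'   (sorted integer residue indices into the bundle).
#' @export
interface_contacts <- function(bundle, distance_cutoff = 8) {
  if (is.null(bundle$coords))
    stop("bundle has no coordinates", call. = FALSE)
  d <- as.matrix(stats::dist(bundle$coords))
  inter <- outer(bundle$chain, bundle$chain, "!=")
  hit <- inter & d < distance_cutoff & upper.tri(d)
  idx <- which(hit, arr.ind = TRUE)
  list(n_contacts = nrow(idx),
       interface_residues = sort(unique(as.integer(idx))))
}

dockq_sigmoid <- function(mean_plddt, n_contacts, const) {
  if (n_contacts == 0) return(unname(const["b"]))
  x <- mean_plddt * log(n_contacts)
  unname(const["L"] / (1 + exp(-const["k"] * (x - const["x0"]))) + const["b"])
}

#' pDockQ interface-quality score (two chains)
#'
#' Sigmoid of `x = <interface pLDDT> * log(n_contacts)` with the dimer
#' constants of [dockq_constants()]. Returns the baseline offset `b` when
#' there are no inter-chain contacts (log 0 is undefined; no interface
#' means no support for the prediction).
#'
#' @param bundle a two-chain [pae_bundle()] with coordinates.
#' @param distance_cutoff contact distance in Angstrom.
#' @param constants sigmoid constants, `c(L, k, x0, b)`.
#' @return scalar score in `(b, L + b)`.
#' @export
compute_pdockq <- function(bundle, distance_cutoff = 8,
                           constants = dockq_constants()$pdockq) {
  if (length(unique(bundle$chain)) != 2L)
    stop("pDockQ is defined for 2 chains; use compute_mpdockq for multimers",
         call. = FALSE)
  ic <- interface_contacts(bundle, distance_cutoff)
  if (ic$n_contacts == 0) return(unname(constants["b"]))
  dockq_sigmoid(mean(bundle$plddt[ic$interface_residues]), ic$n_contacts,
                constants)
}

#' mpDockQ interface-quality score (more than two chains)
#'
#' Multimer variant: the same sigmoid with multimer constants, on the mean
#' pLDDT over all interface residues (pooled across chain pairs) times the
#' log of the total inter-chain contact count.
#'
#' @inheritParams compute_pdockq
#' @return scalar score in `(b, L + b)`.
#' @export
compute_mpdockq <- function(bundle, distance_cutoff = 8,
                            constants = dockq_constants()$mpdockq) {
  if (length(unique(bundle$chain)) < 3L)
    stop("mpDockQ is defined for >2 chains; use compute_pdockq for dimers",
         call. = FALSE)
  ic <- interface_contacts(bundle, distance_cutoff)
  if (ic$n_contacts == 0) return(unname(constants["b"]))
  dockq_sigmoid(mean(bundle$plddt[ic$interface_residues]), ic$n_contacts,
                constants)
}

#' Local interaction score and area from the PAE matrix
#'
#' Over inter-chain residue pairs whose symmetrized PAE (mean of the two
#' directions) falls below `pae_cutoff`: the per-pair score is
#' `(cutoff - pae) / cutoff`; LIS is the mean per-pair score (0 when no
#' pair qualifies) and LIA is the count of qualifying unordered pairs.
#'
#' @param bundle a [pae_bundle()].
#' @param pae_cutoff PAE threshold in Angstrom (default 12).
#' @return list with `lis` in \[0, 1\] and `lia` (integer count).
#' @export
compute_lis_lia <- function(bundle, pae_cutoff = 12) {
  sym <- (bundle$pae + t(bundle$pae)) / 2
  inter <- outer(bundle$chain, bundle$chain, "!=")
  sel <- inter & upper.tri(sym) & sym < pae_cutoff
  if (!any(sel)) return(list(lis = 0, lia = 0L))
  scores <- (pae_cutoff - sym[sel]) / pae_cutoff
  list(lis = mean(scores), lia = sum(sel))
}

#' Compute all interface metrics for one bundle
#'
#' @param bundle a [pae_bundle()].
#' @param pae_cutoff PAE threshold for LIS/LIA.
#' @param distance_cutoff contact distance for pDockQ/mpDockQ.
#' @return one-row data.frame: `pair_id`, `iptm`, `lis`, `lia`,
#'   `dockq_proxy` (pDockQ for 2 chains, mpDockQ otherwise), `n_contacts`.
#' @export
af_metrics <- function(bundle, pae_cutoff = 12, distance_cutoff = 8) {
  ll <- compute_lis_lia(bundle, pae_cutoff)
  ic <- interface_contacts(bundle, distance_cutoff)
  dockq <- if (length(unique(bundle$chain)) == 2L)
    compute_pdockq(bundle, distance_cutoff)
  else compute_mpdockq(bundle, distance_cutoff)
  data.frame(pair_id = bundle$pair_id, iptm = bundle$iptm, lis = ll$lis,
             lia = ll$lia, dockq_proxy = dockq, n_contacts = ic$n_contacts)
}

#' Default confidence-coefficient thresholds
#'
#' Published working cutoffs of the component metrics: ipTM 0.5, dockq
#' proxy 0.23 (pDockQ's acceptable-model threshold), LIS 0.073, LIA 1610.
#' @return named numeric vector.
#' @export
default_af_thresholds <- function() {
  c(iptm = 0.5, dockq_proxy = 0.23, lis = 0.073, lia = 1610)
}

#' Filter-based confidence coefficient
#'
#' Fraction of thresholded metrics that meet or exceed their cutoff, in
#' \[0, 1\].
#' @param record one-row data.frame (or list) of metrics as from
#'   [af_metrics()].
#' @param thresholds named numeric vector of metric cutoffs (a non-empty
#'   subset of the metric names).
#' @return scalar in \[0, 1\].
#' @export
confidence_coefficient <- function(record, thresholds = default_af_thresholds()) {
  if (length(thresholds) == 0L)
    stop("threshold map must be non-empty", call. = FALSE)
  if (!all(names(thresholds) %in% names(record)))
    stop("thresholds reference unknown metrics", call. = FALSE)
  passes <- vapply(names(thresholds),
                   function(mn) record[[mn]] >= thresholds[[mn]], logical(1))
  mean(passes)
}

#' Composite ranking of a bait-candidate screen
#'
#' For each of LIA, LIS and the dockq proxy, min-max normalizes across the
#' screen to \[0, 1\] (a constant column maps to 0); the composite score is
#' the confidence coefficient times the sum of the three normalized
#' metrics, so it lies in \[0, 3\] and is 0 whenever the coefficient is 0.
#' Records are sorted by composite descending, ties broken by ipTM then
#' pair id.
#'
#' @param records data.frame of metrics, one row per pair (>= 2 rows; rbind
#'   of [af_metrics()] outputs).
#' @param thresholds confidence-coefficient cutoffs.
#' @return the records with `confidence_coefficient`, normalized metric
#'   columns (`norm_lia`, `norm_lis`, `norm_dockq`), `composite` and
#'   `rank`, sorted by rank.
#' @export
composite_rank <- function(records, thresholds = default_af_thresholds()) {
  if (nrow(records) < 2L)
    stop("min-max normalization needs at least 2 records", call. = FALSE)
  minmax <- function(v) {
    rng <- diff(range(v))
    if (rng == 0) rep(0, length(v)) else (v - min(v)) / rng
  }
  records$confidence_coefficient <-
    vapply(seq_len(nrow(records)),
           function(i) confidence_coefficient(records[i, ], thresholds),
           numeric(1))
  records$norm_lia <- minmax(records$lia)
  records$norm_lis <- minmax(records$lis)
  records$norm_dockq <- minmax(records$dockq_proxy)
  records$composite <- records$confidence_coefficient *
    (records$norm_lia + records$norm_lis + records$norm_dockq)
  ord <- order(-records$composite, -records$iptm, records$pair_id)
  records <- records[ord, ]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  records
}
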