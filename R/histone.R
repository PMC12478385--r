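#' Compute mark-level stoichiometries from a peptidoform table
#'
#' Stoichiometry of a peptidoform is its share of the total intensity of
#' all forms of the same backbone peptide in the same (dose, replicate):
#' `100 * intensity(form) / sum(intensities of all forms)`. When the
#' unmodified form of a peptide was not observed the total is the sum of
#' observed forms and the group is flagged (`no_unmod`).
#'
#' @param table data.frame with columns `peptide_id`, `modform`, `dose`,
#'   `replicate`, `intensity` (and optionally `marks`); all observed forms
#'   of a peptide, including the unmodified form (`modform == "unmod"`),
#'   in each (dose, replicate) group.
#' @return A `stoichiometry_matrix` data.frame: one row per modified form
#'   per (dose, replicate), columns `peptide_id`, `modform`, `marks`,
#'   `dose`, `replicate`, `stoichiometry` (percent), `no_unmod`.
#' @export
compute_stoichiometries <- function(table) {
  req <- c("peptide_id", "modform", "dose", "replicate", "intensity")
  if (!all(req %in% names(table)))
    stop("table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (any(table$intensity < 0, na.rm = TRUE))
    stop("intensities must be non-negative", call. = FALSE)
  key <- interaction(table$peptide_id, table$dose, table$replicate,
                     drop = TRUE)
  groups <- split(seq_len(nrow(table)), key)
  rows <- lapply(groups, function(i) {
    tot <- sum(table$intensity[i], na.rm = TRUE)
    if (tot <= 0)
      stop("zero total intensity for a peptide group", call. = FALSE)
    mod <- i[table$modform[i] != "unmod"]
    data.frame(peptide_id = table$peptide_id[mod],
               modform = table$modform[mod],
               marks = if ("marks" %in% names(table)) table$marks[mod]
                       else table$modform[mod],
               dose = table$dose[mod],
               replicate = table$replicate[mod],
               stoichiometry = 100 * table$intensity[mod] / tot,
               no_unmod = !any(table$modform[i] == "unmod"))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("stoichiometry_matrix", "data.frame")
  res
}

#' Per-form mean and SD of stoichiometry by dose
#' @param stoich a [compute_stoichiometries()] result.
#' @return data.frame `peptide_id`, `modform`, `marks`, `dose`, `mean`,
#'   `sd`, `n`.
#' @export
stoichiometry_summary <- function(stoich) {
  agg <- aggregate(stoichiometry ~ peptide_id + modform + marks + dose,
                   data = stoich,
                   FUN = function(v) c(mean = mean(v), sd = sd(v),
                                       n = length(v)))
  out <- cbind(agg[, c("peptide_id", "modform", "marks", "dose")],
               as.data.frame(agg$stoichiometry))
  out$sd[is.na(out$sd)] <- 0
  out
}

#' Reproducibility filter for modified peptidoforms
#'
#' A form is kept when, at the reference condition (vehicle by default),
#' its mean stoichiometry across replicates exceeds `min_mean` percent and
#' its standard deviation does not exceed its mean. With
#' `reference = "all"` the rule must hold at every dose.
#'
#' @param stoich a [compute_stoichiometries()] result.
#' @param min_mean minimum mean stoichiometry, percent (default 1).
#' @param reference the reference dose (default 0, vehicle) or `"all"`.
#' @return data.frame of kept forms (`peptide_id`, `modform`, `marks`,
#'   `mean`, `sd` at the reference condition).
#' @export
apply_reproducibility_filter <- function(stoich, min_mean = 1, reference = 0) {
  summ <- stoichiometry_summary(stoich)
  if (identical(reference, "all")) {
    ok <- aggregate(cbind(pass = mean > min_mean & sd <= mean) ~
                      peptide_id + modform + marks, data = summ, FUN = all)
    ref <- summ[summ$dose == min(summ$dose), ]
    keep <- merge(ref, ok, by = c("peptide_id", "modform", "marks"))
    keep <- keep[keep$pass, ]
  } else {
    if (any(summ$n[summ$dose == reference] < 2))
      warning("fewer than 2 replicates at the reference condition")
    keep <- summ[summ$dose == reference &
                   summ$mean > min_mean & summ$sd <= summ$mean, ]
  }
  rownames(keep) <- NULL
  keep[, c("peptide_id", "modform", "marks", "mean", "sd")]
}

#' Call dose-responsive forms
#'
#' A form is responsive when the ratio of its mean stoichiometries between
#' the low-dose and high-dose conditions (larger over smaller) meets
#' `fc_threshold`; the direction of change is recorded (a decrease is the
#' expected signature of inhibition). A zero mean at one dose gives an
#' infinite ratio: responsive, flagged.
#'
#' @param stoich a [compute_stoichiometries()] result, usually restricted
#'   to forms passing [apply_reproducibility_filter()].
#' @param low_dose,high_dose the two doses compared (uM).
#' @param fc_threshold fold-change cutoff, boundary inclusive (default 2).
#' @return data.frame `peptide_id`, `modform`, `marks`, `mean_low`,
#'   `mean_high`, `fold_change`, `responsive`, `direction`,
#'   `infinite_ratio`.
#' @export
call_responsive_marks <- function(stoich, low_dose = 0.1, high_dose = 30,
                                  fc_threshold = 2) {
  summ <- stoichiometry_summary(stoich)
  if (!all(c(low_dose, high_dose) %in% summ$dose))
    stop("both comparison doses must be present", call. = FALSE)
  lo <- summ[summ$dose == low_dose, c("peptide_id", "modform", "marks", "mean")]
  hi <- summ[summ$dose == high_dose, c("peptide_id", "modform", "marks", "mean")]
  out <- merge(lo, hi, by = c("peptide_id", "modform", "marks"),
               suffixes = c("_low", "_high"))
  names(out)[names(out) == "mean_low"] <- "mean_low"
  lo_v <- out$mean_low; hi_v <- out$mean_high
  fc <- pmax(lo_v, hi_v) / pmin(lo_v, hi_v)
  out$fold_change <- fc
  out$infinite_ratio <- !is.finite(fc)
  out$responsive <- out$infinite_ratio | fc >= fc_threshold
  out$direction <- ifelse(hi_v < lo_v, "decrease", "increase")
  out
}

#' Aggregate stoichiometries to mark level
#'
#' A histone mark measured on several peptidoforms (e.g. co-modified
#' peptides) is quantified by summing the stoichiometries of all forms
#' carrying it, per (dose, replicate).
#'
#' @param stoich a [compute_stoichiometries()] result with a
#'   semicolon-separated `marks` column.
#' @param marks marks to aggregate; default: all observed.
#' @return data.frame `mark`, `dose`, `replicate`, `stoichiometry`.
#' @export
aggregate_mark_stoichiometry <- function(stoich, marks = NULL) {
  tokens <- strsplit(stoich$marks, ";", fixed = TRUE)
  long <- data.frame(mark = unlist(tokens),
                     dose = rep(stoich$dose, lengths(tokens)),
                     replicate = rep(stoich$replicate, lengths(tokens)),
                     stoichiometry = rep(stoich$stoichiometry,
                                         lengths(tokens)))
  if (!is.null(marks)) long <- long[long$mark %in% marks, ]
  out <- aggregate(stoichiometry ~ mark + dose + replicate, data = long,
                   FUN = sum)
  out[order(out$mark, out$dose, out$replicate), ]
}

#' Biomarker panel report
#'
#' One row per KAT in the assignment: its biomarker mark(s), the fitted
#' IC50 of the mark-level stoichiometry (4PL versus dose;
#' `"insensitive"` when the mark does not respond), the maximal observed
#' inhibition relative to vehicle, and the doses with obvious inhibition
#' (mean below `obvious_fraction` of vehicle). Marks assigned but absent
#' from the data are reported `"not detected"`.
#'
#' @param stoich a [compute_stoichiometries()] result (reproducible forms).
#' @param assignment named character vector mark -> KAT; default
#'   [default_kat_assignment()].
#' @param fc_threshold mark-level responsiveness cutoff (low vs high dose,
#'   as in [call_responsive_marks()]).
#' @param obvious_fraction fraction of vehicle below which inhibition at a
#'   dose is called obvious (default 0.5).
#' @return data.frame `kat`, `biomarker`, `ic50`, `status`,
#'   `max_inhibition_pct`, `obvious_doses`.
#' @export
biomarker_panel_report <- function(stoich,
                                   assignment = default_kat_assignment(),
                                   fc_threshold = 2,
                                   obvious_fraction = 0.5) {
  bymark <- aggregate_mark_stoichiometry(stoich)
  doses <- sort(unique(bymark$dose))
  kats <- unique(unname(assignment))
  rows <- lapply(kats, function(kat) {
    marks <- names(assignment)[assignment == kat]
    sub <- bymark[bymark$mark %in% marks, ]
    if (nrow(sub) == 0L)
      return(data.frame(kat = kat, biomarker = paste(marks, collapse = "/"),
                        ic50 = NA_real_, status = "not detected",
                        max_inhibition_pct = NA_real_, obvious_doses = ""))
    agg <- aggregate(stoichiometry ~ dose + replicate, data = sub, FUN = sum)
    means <- aggregate(stoichiometry ~ dose, data = agg, FUN = mean)
    veh <- means$stoichiometry[means$dose == min(doses)]
    max_inh <- 100 * (1 - min(means$stoichiometry) / veh)
    nz <- doses[doses > 0]
    fc_doses <- c(min(nz), max(nz))
    lo <- means$stoichiometry[means$dose == fc_doses[1]]
    hi <- means$stoichiometry[means$dose == fc_doses[2]]
    responsive <- is.finite(lo / hi) && max(lo, hi) / min(lo, hi) >= fc_threshold ||
      hi == 0
    if (!responsive)
      return(data.frame(kat = kat, biomarker = paste(marks, collapse = "/"),
                        ic50 = NA_real_, status = "insensitive",
                        max_inhibition_pct = max_inh, obvious_doses = ""))
    fit <- fit_inhibition_curve(means$dose, means$stoichiometry)
    obvious <- means$dose[means$dose > 0 &
                            means$stoichiometry < obvious_fraction * veh]
    data.frame(kat = kat, biomarker = paste(marks, collapse = "/"),
               ic50 = if (fit$converged) fit$ic50 else NA_real_,
               status = if (fit$converged) "sensitive" else "fit failed",
               max_inhibition_pct = max_inh,
               obvious_doses = paste(obvious, collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
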