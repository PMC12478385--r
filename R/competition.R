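#' Test enrichment specificity against the capped-bead control
#'
#' For each protein, compares log2 abundances on the bisubstrate resin at
#' vehicle (dose 0) against the capped-bead control with a Welch two-sample
#' t-test. A protein is called *specific* when its log2 fold-change exceeds
#' `fc_threshold` and its p-value is below `p_threshold`. Proteins
#' quantified in fewer than 2 replicates in either condition get a fold
#' change from the available values but an undefined p-value (and are not
#' called specific). Missing capped values are imputed at half the global
#' minimum observed abundance (absence from the control is evidence of
#' specificity, not of noise); proteins missing in all bisubstrate vehicle
#' samples are excluded with a warning.
#'
#' @param data a [capture_dataset()] containing both resins.
#' @param fc_threshold log2 fold-change cutoff (default 0.6).
#' @param p_threshold p-value cutoff (default 0.05).
#' @param p_adjust multiple-testing correction passed to [stats::p.adjust()]
#'   (`"none"` by default, matching threshold-on-raw-p usage).
#' @return data.frame with columns `protein`, `log2fc_vs_capped`,
#'   `p_value`, `specific`.
#' @export
test_enrichment <- function(data, fc_threshold = 0.6, p_threshold = 0.05,
                            p_adjust = "none") {
  s <- data$samples
  bis <- s$resin == "bisubstrate" & s$dose == 0
  cap <- s$resin == "capped"
  if (!any(bis) || !any(cap))
    stop("need bisubstrate vehicle and capped control samples", call. = FALSE)
  m <- data$abundance
  floor_val <- 0.5 * min(m, na.rm = TRUE)

  res <- lapply(rownames(m), function(p) {
    xb <- m[p, bis]
    xc <- m[p, cap]
    if (all(is.na(xb))) return(NULL)
    xc[is.na(xc)] <- floor_val
    xb <- log2(xb[!is.na(xb)])
    xc <- log2(xc)
    lfc <- mean(xb) - mean(xc)
    pv <- if (length(xb) >= 2 && length(xc) >= 2 && sd(c(xb, xc)) > 0)
      tryCatch(t.test(xb, xc)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(protein = p, log2fc_vs_capped = lfc, p_value = pv)
  })
  dropped <- vapply(res, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped),
            " protein(s) missing in all bisubstrate vehicle samples; excluded")
  out <- do.call(rbind, res[!dropped])
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$specific <- !is.na(out$p_value) &
    out$log2fc_vs_capped > fc_threshold & out$p_value < p_threshold
  out
}

#' Compute dose-competition profiles
#'
#' For each protein and each competitor dose, the mean log2 capture ratio
#' versus vehicle on the bisubstrate resin, a Welch two-sample t-test
#' p-value (dose vs vehicle, on log2 values), and the implied active-site
#' occupancy `clamp(1 - 2^log2fc, 0, 1)`. Values missing in a treated
#' condition are imputed at `imputation_floor` times the global minimum
#' observed abundance — absence after competition signals complete
#' competition. By default the analysis is restricted to proteins passing
#' [test_enrichment()].
#'
#' @param data a [capture_dataset()] with a vehicle (dose 0) bisubstrate
#'   condition.
#' @param imputation_floor fraction of the global minimum used to impute
#'   missing treated values (default 0.5).
#' @param enrichment optional result of [test_enrichment()]; computed
#'   internally when `NULL` and `restrict = TRUE`.
#' @param restrict restrict to proteins called specific?
#' @return A `competition_profiles` list: `proteins`, `doses`, and
#'   protein x dose matrices `log2fc`, `p_values`, `occupancy`.
#' @export
compute_competition_profiles <- function(data, imputation_floor = 0.5,
                                         enrichment = NULL, restrict = TRUE) {
  s <- data$samples
  if (!any(s$resin == "bisubstrate" & s$dose == 0))
    stop("no vehicle (dose 0) bisubstrate condition", call. = FALSE)
  m <- data$abundance
  if (restrict) {
    if (is.null(enrichment)) enrichment <- test_enrichment(data)
    keep <- enrichment$protein[enrichment$specific]
    m <- m[rownames(m) %in% keep, , drop = FALSE]
  }
  doses <- sort(unique(s$dose[s$resin == "bisubstrate"]))
  floor_val <- imputation_floor * min(data$abundance, na.rm = TRUE)

  veh <- s$resin == "bisubstrate" & s$dose == 0
  log2fc <- pvals <- matrix(NA_real_, nrow(m), length(doses),
                            dimnames = list(rownames(m), paste0("d", doses)))
  for (p in rownames(m)) {
    x0 <- m[p, veh]
    x0 <- log2(x0[!is.na(x0)])
    for (di in seq_along(doses)) {
      d <- doses[di]
      if (d == 0) { log2fc[p, di] <- 0; next }
      xd <- m[p, s$resin == "bisubstrate" & s$dose == d]
      xd[is.na(xd)] <- floor_val
      xd <- log2(xd)
      log2fc[p, di] <- mean(xd) - mean(x0)
      if (length(xd) >= 2 && length(x0) >= 2 && sd(c(xd, x0)) > 0)
        pvals[p, di] <- tryCatch(t.test(xd, x0)$p.value,
                                 error = function(e) NA_real_)
    }
  }
  structure(list(proteins = rownames(m), doses = doses, log2fc = log2fc,
                 p_values = pvals,
                 occupancy = clamp(1 - 2^log2fc, 0, 1)),
            class = "competition_profiles")
}

#' @export
print.competition_profiles <- function(x, ...) {
  cat(sprintf("competition_profiles: %d proteins over doses %s uM\n",
              length(x$proteins), paste(x$doses, collapse = ", ")))
  invisible(x)
}

#' Rank proteins by competition at one dose
#'
#' Orders proteins by a signed significance score, `-log10(p) *
#' sign(log2fc)`, most strongly competed (most negative) first. Undefined
#' p-values score 0. Ties are broken by |log2fc| (larger first) and then
#' by identifier.
#'
#' @param profiles a [compute_competition_profiles()] result.
#' @param dose a dose present in the ladder.
#' @return data.frame `protein`, `log2fc`, `p_value`, `score`, sorted.
#' @export
rank_competed <- function(profiles, dose) {
  di <- match(dose, profiles$doses)
  if (is.na(di)) stop("dose not in the profile ladder", call. = FALSE)
  lfc <- profiles$log2fc[, di]
  p <- profiles$p_values[, di]
  score <- ifelse(is.na(p), 0, -log10(p)) * sign(lfc)
  ord <- order(score, -abs(lfc), profiles$proteins)
  data.frame(protein = profiles$proteins, log2fc = lfc, p_value = p,
             score = score, row.names = NULL)[ord, ]
}

#' Occupancy matrix of competition profiles
#'
#' Active-site occupancy per protein and dose, `clamp(1 - 2^log2fc, 0, 1)`:
#' 0 for unchanged (or increased) capture, approaching 1 for complete
#' competition. Row order follows the profiles (callers may pass profiles
#' pre-ordered, e.g. grouped by complex).
#'
#' @param profiles a [compute_competition_profiles()] result.
#' @return numeric matrix, proteins x doses, in \[0, 1\].
#' @export
occupancy_matrix <- function(profiles) {
  profiles$occupancy
}

#' Write competition results as TSV
#' @param profiles a [compute_competition_profiles()] result.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_competition_profiles <- function(profiles, file) {
  df <- data.frame(protein = profiles$proteins,
                   profiles$log2fc,
                   setNames(as.data.frame(profiles$p_values),
                            paste0("p_", colnames(profiles$p_values))),
                   setNames(as.data.frame(profiles$occupancy),
                            paste0("occ_", colnames(profiles$occupancy))),
                   check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
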