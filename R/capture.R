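#' Construct an affinity-capture dataset
#'
#' Container for a protein-level quantification matrix from competitive
#' affinity-capture experiments, together with its sample annotation. Each
#' sample is one capture: on the bisubstrate CoA resin at a given
#' competitor dose, or on capped (inert) control beads.
#'
#' @param abundance numeric matrix, proteins x samples; `NA` for
#'   missing (not-quantified) values; non-negative where present.
#' @param samples data.frame with columns `sample_id`, `resin`
#'   (`"bisubstrate"` or `"capped"`), `dose` (uM, >= 0), `replicate`.
#' @return A `capture_dataset` list with elements `abundance` and
#'   `samples`.
#' @export
capture_dataset <- function(abundance, samples) {
  abundance <- as.matrix(abundance)
  req <- c("sample_id", "resin", "dose", "replicate")
  if (!all(req %in% names(samples)))
    stop("samples needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (ncol(abundance) != nrow(samples))
    stop("abundance columns must match sample annotation rows", call. = FALSE)
  if (!all(samples$resin %in% c("bisubstrate", "capped")))
    stop("resin must be 'bisubstrate' or 'capped'", call. = FALSE)
  if (any(samples$dose < 0)) stop("doses must be >= 0", call. = FALSE)
  if (any(abundance < 0, na.rm = TRUE))
    stop("abundances must be non-negative", call. = FALSE)
  colnames(abundance) <- samples$sample_id
  structure(list(abundance = abundance,
                 samples = as.data.frame(samples, stringsAsFactors = FALSE)),
            class = "capture_dataset")
}

#' @export
print.capture_dataset <- function(x, ...) {
  cat(sprintf("capture_dataset: %d proteins x %d samples (%d bisubstrate, %d capped); doses: %s uM\n",
              nrow(x$abundance), ncol(x$abundance),
              sum(x$samples$resin == "bisubstrate"),
              sum(x$samples$resin == "capped"),
              paste(sort(unique(x$samples$dose)), collapse = ", ")))
  invisible(x)
}

#' Read / write a capture dataset as TSV
#'
#' The quantification table is wide (first column `protein`, one column per
#' sample); the annotation table has columns `sample_id`, `resin`,
#' `dose_uM`, `replicate`.
#' @param quant_file,annotation_file paths to the two TSVs.
#' @return [read_capture_dataset()] returns a [capture_dataset()].
#' @export
read_capture_dataset <- function(quant_file, annotation_file) {
  quant <- read.table(quant_file, header = TRUE, sep = "\t",
                      check.names = FALSE)
  annot <- read.table(annotation_file, header = TRUE, sep = "\t")
  m <- as.matrix(quant[, -1, drop = FALSE])
  rownames(m) <- quant[[1]]
  annot$dose <- annot$dose_uM
  capture_dataset(m[, annot$sample_id, drop = FALSE], annot)
}

#' @rdname read_capture_dataset
#' @param data a [capture_dataset()].
#' @export
write_capture_dataset <- function(data, quant_file, annotation_file) {
  quant <- data.frame(protein = rownames(data$abundance), data$abundance,
                      check.names = FALSE)
  write.table(quant, quant_file, sep = "\t", quote = FALSE, row.names = FALSE)
  annot <- data$samples
  annot$dose_uM <- annot$dose
  write.table(annot[, c("sample_id", "resin", "dose_uM", "replicate")],
              annotation_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(quant_file, annotation_file))
}

#' Normalize capture abundances across samples
#'
#' Per-sample scaling so that a chosen statistic (median or total of the
#' observed values) is equalized across samples; missing values are left
#' untouched. `"none"` returns the input unchanged.
#'
#' @param data a [capture_dataset()].
#' @param method `"median"`, `"total"`, or `"none"`.
#' @return A normalized [capture_dataset()].
#' @export
normalize_abundances <- function(data, method = c("median", "total", "none")) {
  method <- match.arg(method)
  if (method == "none") return(data)
  m <- data$abundance
  stat <- switch(method,
                 median = apply(m, 2, median, na.rm = TRUE),
                 total = colSums(m, na.rm = TRUE))
  if (any(!is.finite(stat)))
    stop("a sample has no observed values; cannot normalize", call. = FALSE)
  target <- mean(stat)
  data$abundance <- sweep(m, 2, stat / target, "/")
  data
}
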