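#' Build a clustering feature matrix from competition profiles
#'
#' Assembles per-protein dose-response feature vectors from log2
#' fold-change competition profiles. `"log2fc"` uses the raw vectors;
#' `"scaled_log2fc"` applies a per-protein min-max rescale to \[0, 1\]
#' (emphasizing profile shape over magnitude; constant profiles map to 0).
#' Missing values are imputed as 0 (no change).
#'
#' @param profiles a [compute_competition_profiles()] result.
#' @param transform `"log2fc"` or `"scaled_log2fc"`.
#' @return A `feature_matrix` list: `proteins`, `doses`, `features`
#'   (transformed matrix), `log2fc` (raw matrix, retained for cluster
#'   signatures), `transform_tag`.
#' @export
build_feature_matrix <- function(profiles,
                                 transform = c("log2fc", "scaled_log2fc")) {
  transform <- match.arg(transform)
  if (length(profiles$proteins) == 0L)
    stop("no profiles to build features from", call. = FALSE)
  raw <- profiles$log2fc
  raw[is.na(raw)] <- 0
  feat <- raw
  if (transform == "scaled_log2fc") {
    feat <- t(apply(raw, 1, function(v) {
      rng <- diff(range(v))
      if (rng == 0) rep(0, length(v)) else (v - min(v)) / rng
    }))
    dimnames(feat) <- dimnames(raw)
  }
  structure(list(proteins = rownames(raw), doses = profiles$doses,
                 features = feat, log2fc = raw, transform_tag = transform),
            class = "feature_matrix")
}

#' Embed competition features in two dimensions with t-SNE
#'
#' Deterministic for a fixed seed (exact t-SNE, single thread). The default
#' perplexity is 30, reduced to n/4 for small screens; t-SNE requires
#' `3 * perplexity < n - 1`.
#'
#' @param features a [build_feature_matrix()] result.
#' @param seed RNG seed for the embedding initialization.
#' @param perplexity t-SNE perplexity; `NULL` for the default rule.
#' @param max_iter gradient-descent iterations.
#' @return numeric matrix (proteins x 2) of embedding coordinates.
#' @export
embed_2d <- function(features, seed = 0, perplexity = NULL, max_iter = 1000) {
  x <- features$features
  n <- nrow(x)
  if (is.null(perplexity)) perplexity <- min(30, floor(n / 4))
  if (3 * perplexity >= n - 1)
    stop("perplexity too large for ", n, " proteins", call. = FALSE)
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, theta = 0,
                      pca = FALSE, check_duplicates = FALSE,
                      max_iter = max_iter, num_threads = 1)
  coords <- fit$Y
  rownames(coords) <- features$proteins
  colnames(coords) <- c("tsne1", "tsne2")
  coords
}

#' k-means clustering of the 2-D embedding
#'
#' Clusters the embedding coordinates (k-means, 10 restarts, fixed seed)
#' and computes each cluster's dose-response signature as the per-cluster
#' mean of the untransformed log2 fold-change vectors.
#'
#' @param coords embedding from [embed_2d()] (or any numeric matrix with
#'   one row per protein; pass `features$features` to cluster the feature
#'   space directly).
#' @param features the [build_feature_matrix()] used to derive `coords`.
#' @param k number of clusters (default 5).
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return A `cluster_result` list: `embedding`, `labels` (1..k, named by
#'   protein), `k`, `seed`, `signatures` (k x dose matrix), `doses`.
#' @export
cluster_kmeans <- function(coords, features, k = 5, seed = 0, nstart = 10) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > nrow(coords)) stop("k exceeds the number of proteins", call. = FALSE)
  set.seed(seed)
  if (k == nrow(coords)) {
    labels <- seq_len(k)  # degenerate: every protein its own cluster
  } else {
    km <- kmeans(coords, centers = k, nstart = nstart, iter.max = 100)
    labels <- km$cluster
  }
  names(labels) <- rownames(coords)
  sig <- t(sapply(seq_len(k), function(ci) {
    colMeans(features$log2fc[labels == ci, , drop = FALSE])
  }))
  dimnames(sig) <- list(paste0("cluster", seq_len(k)),
                        colnames(features$log2fc))
  structure(list(embedding = coords, labels = labels, k = k, seed = seed,
                 signatures = sig, doses = features$doses),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d proteins in k = %d clusters (sizes: %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Classify dose-sensitive clusters
#'
#' A cluster is *sensitive* when its mean dose-response signature is
#' monotone non-increasing across the dose ladder (within tolerance `tol`)
#' and its total drop (first minus last log2 fold change) is at least
#' `min_drop` log2 units.
#'
#' @param result a [cluster_kmeans()] result.
#' @param min_drop minimum total log2 drop (default 1).
#' @param tol tolerance for the monotonicity check, log2 units.
#' @return integer vector of sensitive cluster indices.
#' @export
classify_sensitive_clusters <- function(result, min_drop = 1, tol = 0.1) {
  sig <- result$signatures
  which(apply(sig, 1, function(v) {
    all(diff(v) <= tol) && (v[1] - v[length(v)]) >= min_drop
  }))
}

#' Read a complex-annotation table
#'
#' Two-column TSV (`protein`, `complex`), one row per membership, as
#' exported from a curated complex catalogue. Lookups for unlisted
#' proteins return the empty set.
#' @param file path to the TSV.
#' @return A `complex_annotation` object.
#' @export
read_complex_annotation <- function(file) {
  complex_annotation(read.table(file, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
}

#' @rdname read_complex_annotation
#' @param df data.frame with columns `protein`, `complex`.
#' @export
complex_annotation <- function(df) {
  stopifnot(all(c("protein", "complex") %in% names(df)))
  structure(split(as.character(df$complex), df$protein),
            class = "complex_annotation")
}

#' Complexes annotated for a protein (empty set when unlisted)
#' @param annotation a [complex_annotation()].
#' @param protein protein identifier.
#' @return character vector of complex names (possibly empty).
#' @export
annotated_complexes <- function(annotation, protein) {
  res <- unclass(annotation)[[protein]]
  if (is.null(res)) character(0) else res
}

#' Flag unannotated proteins co-clustering with complex members
#'
#' Candidates are proteins assigned to a sensitive cluster but absent from
#' the complex annotation. For each candidate the report lists its
#' cluster, the cluster's dose-response signature, and the annotated
#' complex members it co-clusters with.
#'
#' @param result a [cluster_kmeans()] result.
#' @param annotation a [complex_annotation()].
#' @param sensitive sensitive cluster indices; computed with
#'   [classify_sensitive_clusters()] defaults when `NULL`.
#' @return data.frame with columns `protein`, `cluster`, `signature`
#'   (comma-joined log2 fold changes) and `co_annotated` (comma-joined
#'   annotated neighbours), zero rows when every sensitive protein is
#'   annotated.
#' @export
flag_candidate_interactors <- function(result, annotation, sensitive = NULL) {
  if (is.null(sensitive)) sensitive <- classify_sensitive_clusters(result)
  empty <- data.frame(protein = character(), cluster = integer(),
                      signature = character(), co_annotated = character())
  if (length(sensitive) == 0L) return(empty)
  annotated <- vapply(names(result$labels),
                      function(p) length(annotated_complexes(annotation, p)) > 0,
                      logical(1))
  rows <- lapply(sensitive, function(ci) {
    members <- names(result$labels)[result$labels == ci]
    cand <- members[!annotated[members]]
    if (length(cand) == 0L) return(NULL)
    data.frame(protein = cand, cluster = ci,
               signature = paste(round(result$signatures[ci, ], 3),
                                 collapse = ","),
               co_annotated = paste(sort(members[annotated[members]]),
                                    collapse = ","))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}
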