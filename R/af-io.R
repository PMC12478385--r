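#' Construct a predicted-structure bundle
#'
#' Holds everything the interface metrics need for one bait-candidate
#' prediction: the predicted aligned error (PAE) matrix over all residues,
#' the residue-to-chain map, per-residue pLDDT, the ipTM scalar, and
#' chain-labelled representative-atom coordinates (one atom per residue:
#' C-beta, C-alpha for glycine).
#'
#' @param pae square non-negative numeric matrix (total residues).
#' @param chain character vector of chain ids per residue (>= 2 chains).
#' @param plddt numeric per-residue confidence in \[0, 100\].
#' @param iptm interface predicted TM-score in \[0, 1\].
#' @param coords optional n x 3 coordinate matrix (Angstrom).
#' @param resid optional 3-letter residue names (used when writing mmCIF).
#' @param pair_id identifier, e.g. `"BAIT_CANDIDATE"`.
#' @return A `pae_bundle` list.
#' @export
pae_bundle <- function(pae, chain, plddt, iptm, coords = NULL, resid = NULL,
                       pair_id = "pair") {
  pae <- as.matrix(pae)
  n <- length(chain)
  if (nrow(pae) != ncol(pae)) stop("PAE matrix must be square", call. = FALSE)
  if (nrow(pae) != n)
    stop("PAE dimension must equal the number of residues", call. = FALSE)
  if (any(pae < 0)) stop("PAE must be non-negative", call. = FALSE)
  if (length(unique(chain)) < 2L)
    stop("bundle must contain at least 2 chains", call. = FALSE)
  if (length(plddt) != n) stop("plddt length mismatch", call. = FALSE)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3)
      stop("coords must be n x 3", call. = FALSE)
  }
  structure(list(pae = pae, chain = chain, plddt = plddt, iptm = iptm,
                 coords = coords, resid = resid %||% rep("ALA", n),
                 pair_id = pair_id),
            class = "pae_bundle")
}

#' @export
print.pae_bundle <- function(x, ...) {
  cat(sprintf("pae_bundle '%s': %d residues in chains %s; ipTM = %.2f\n",
              x$pair_id, length(x$chain),
              paste(unique(x$chain), collapse = "/"), x$iptm))
  invisible(x)
}

#' Write a predicted-structure bundle to disk
#'
#' Emits the standard on-disk pair: a PAE JSON (square matrix under the
#' `predicted_aligned_error` key, plus `max_predicted_aligned_error`) and a
#' minimal two-chain mmCIF whose `atom_site` loop carries one
#' representative atom per residue (CB; CA for glycine) with pLDDT in the
#' B-factor column.
#'
#' @param bundle a [pae_bundle()] with coordinates.
#' @param pae_file,structure_file output paths.
#' @return the two paths, invisibly.
#' @export
write_af_bundle <- function(bundle, pae_file, structure_file) {
  if (is.null(bundle$coords))
    stop("bundle has no coordinates to write", call. = FALSE)
  jsonlite::write_json(
    list(predicted_aligned_error = bundle$pae,
         max_predicted_aligned_error = max(bundle$pae)),
    pae_file, auto_unbox = TRUE, digits = 6)

  n <- length(bundle$chain)
  seqno <- stats::ave(seq_len(n), bundle$chain, FUN = seq_along)
  atom <- ifelse(bundle$resid == "GLY", "CA", "CB")
  lines <- c(
    sprintf("data_%s", gsub("[^A-Za-z0-9_]", "_", bundle$pair_id)),
    "#", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                            "label_atom_id", "label_alt_id", "label_comp_id",
                            "label_asym_id", "label_entity_id",
                            "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
                            "Cartn_y", "Cartn_z", "occupancy",
                            "B_iso_or_equiv", "auth_seq_id", "auth_asym_id",
                            "pdbx_PDB_model_num")),
    sprintf("ATOM %d C %s . %s %s %d %d ? %.3f %.3f %.3f 1.00 %.2f %d %s 1",
            seq_len(n), atom, bundle$resid, bundle$chain,
            match(bundle$chain, unique(bundle$chain)), seqno,
            bundle$coords[, 1], bundle$coords[, 2], bundle$coords[, 3],
            bundle$plddt, seqno, bundle$chain),
    "#")
  writeLines(lines, structure_file)
  invisible(c(pae_file, structure_file))
}

# Minimal mmCIF atom_site loop reader for the whitespace-delimited files
# this package writes (and AlphaFold-style model CIFs without quoted
# fields). Returns a data.frame with one row per atom.
read_atom_site <- function(file) {
  lines <- readLines(file)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0L)
    stop("no _atom_site loop in ", file, call. = FALSE)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body <- lines[seq(max(hdr_idx) + 1L, length(lines))]
  body <- body[!grepl("^\\s*(#|loop_|_|$)", body)]
  stop_at <- grep("^(ATOM|HETATM)", body, invert = TRUE)
  if (length(stop_at)) body <- body[seq_len(min(stop_at) - 1L)]
  tok <- strsplit(trimws(body), "\\s+")
  bad <- lengths(tok) != length(fields)
  if (any(bad)) stop("malformed atom_site rows in ", file, call. = FALSE)
  df <- as.data.frame(do.call(rbind, tok), stringsAsFactors = FALSE)
  names(df) <- fields
  for (col in intersect(c("Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                          "B_iso_or_equiv", "label_seq_id", "auth_seq_id"),
                        names(df)))
    df[[col]] <- as.numeric(df[[col]])
  df
}

#' Parse a predicted-structure bundle from disk
#'
#' Reads a PAE JSON (either a bare object or the AlphaFold list-of-one
#' layout, keyed `predicted_aligned_error`) and a chain-annotated mmCIF,
#' keeping one representative atom per residue (CB, falling back to CA —
#' glycine has no CB). pLDDT is taken from the B-factor column. Errors if
#' the PAE dimension disagrees with the structure's residue count or the
#' structure has a single chain.
#'
#' @param pae_file path to the PAE JSON.
#' @param structure_file path to the mmCIF.
#' @param iptm ipTM scalar for the pair (from the prediction's ranking
#'   output).
#' @param pair_id identifier; defaults to the structure file name.
#' @return A [pae_bundle()].
#' @export
parse_af_bundle <- function(pae_file, structure_file, iptm,
                            pair_id = NULL) {
  j <- jsonlite::read_json(pae_file, simplifyVector = TRUE)
  if (is.data.frame(j) || (is.list(j) && is.null(names(j)))) j <- j[[1]]
  pae <- j[["predicted_aligned_error"]]
  if (is.null(pae)) stop("no predicted_aligned_error key", call. = FALSE)
  pae <- as.matrix(pae)

  atoms <- read_atom_site(structure_file)
  chain_col <- if ("auth_asym_id" %in% names(atoms)) "auth_asym_id"
               else "label_asym_id"
  key <- paste(atoms[[chain_col]], atoms$label_seq_id)
  rep_rows <- vapply(split(seq_len(nrow(atoms)), factor(key, unique(key))),
                     function(i) {
                       cb <- i[atoms$label_atom_id[i] == "CB"]
                       if (length(cb)) cb[1]
                       else i[atoms$label_atom_id[i] == "CA"][1]
                     }, integer(1))
  if (anyNA(rep_rows))
    stop("residue without CB or CA atom in ", structure_file, call. = FALSE)
  atoms <- atoms[rep_rows, ]
  if (nrow(pae) != nrow(atoms))
    stop(sprintf("PAE dimension (%d) does not match residue count (%d)",
                 nrow(pae), nrow(atoms)), call. = FALSE)
  pae_bundle(pae = pae, chain = atoms[[chain_col]],
             plddt = atoms$B_iso_or_equiv, iptm = iptm,
             coords = as.matrix(atoms[, c("Cartn_x", "Cartn_y", "Cartn_z")]),
             resid = atoms$label_comp_id,
             pair_id = pair_id %||%
               sub("\\.cif$", "", basename(structure_file)))
}
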