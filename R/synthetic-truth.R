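#' Specify a protein complex for the synthetic capture generator
#'
#' A `complex_spec` describes one affinity-captured protein complex: its
#' members, whether each member appears in the complex-annotation reference,
#' and the competition behaviour of the complex's CoA-binding site —
#' the competitor concentration at which resin capture is half-competed
#' (`ic50_capture`), the Hill slope, and the maximal competable fraction
#' (`max_competition`, < 1 for proteins with a resin-bound pool that the
#' competitor cannot reach, e.g. a fraction residing in a non-target
#' complex).
#'
#' @param name complex name.
#' @param members character vector of protein identifiers (non-empty).
#' @param ic50_capture half-competition concentration in uM (> 0).
#' @param hill Hill slope (unitless, > 0).
#' @param annotated logical scalar or vector per member: present in the
#'   complex-annotation reference?
#' @param max_competition fraction of capture that is competable at
#'   saturating competitor, in (0, 1].
#' @return A `complex_spec` list.
#' @export
complex_spec <- function(name, members, ic50_capture, hill = 1,
                         annotated = TRUE, max_competition = 1) {
  if (length(members) == 0L) stop("members must be non-empty", call. = FALSE)
  stop_if_not_scalar_pos(ic50_capture, "ic50_capture")
  stop_if_not_scalar_pos(hill, "hill")
  annotated <- rep_len(annotated, length(members))
  structure(list(name = name, members = members, annotated = annotated,
                 ic50_capture = ic50_capture, hill = hill,
                 max_competition = max_competition),
            class = "complex_spec")
}

#' Default synthetic complex roster
#'
#' Loosely mirrors the MYST KAT complexes recovered by H3K14-CoA capture:
#' a highly sensitive KAT7/JADE complex, a less sensitive BRPF arm, the
#' KAT8-containing MSL and NSL complexes at intermediate sensitivity, and
#' the KAT5-containing NuA4 complex, plus a handful of NuA4-associated
#' proteins whose capture is only partially competable (a non-MYST-complex
#' fraction, e.g. TRRAP in STAGA). The hierarchy of capture IC50s follows
#' KAT7 > KAT8 > KAT5. Two unannotated proteins (FOXK2, H2AZ1) are given
#' complex-like profiles via [synthetic_truth()]'s `planted_candidates`.
#'
#' @return list of [complex_spec()] objects.
#' @export
default_complex_specs <- function() {
  list(
    complex_spec("JADE", c("KAT7", "JADE1", "JADE2", "MEAF6", "ING4", "ING5"),
                 ic50_capture = 0.05),
    complex_spec("BRPF", "BRPF3", ic50_capture = 5),
    complex_spec("MSL", c("KAT8", "MSL1", "MSL2", "MSL3"), ic50_capture = 0.8),
    complex_spec("NSL", c("KANSL1", "KANSL2", "KANSL3", "HCFC1", "MCRS1",
                          "OGT", "PHF20", "PHF20L1", "WDR5"),
                 ic50_capture = 1),
    complex_spec("NuA4", c("KAT5", "EPC1", "EPC2", "DMAP1", "ING3", "MBTD1",
                           "YEATS4", "VPS72", "EP400", "BRD8", "RUVBL1",
                           "RUVBL2", "MORF4L1"),
                 ic50_capture = 2.5),
    complex_spec("NuA4-partial", c("TRRAP", "MORF4L2", "ACTL6A", "MRGBP"),
                 ic50_capture = 2.5, max_competition = 0.3),
    # unannotated proteins with complex-like competition (candidate
    # interactors the discovery stage should flag)
    complex_spec("NSL-candidate", "FOXK2", ic50_capture = 1, annotated = FALSE),
    complex_spec("NuA4-candidate", "H2AZ1", ic50_capture = 2.5,
                 annotated = FALSE)
  )
}

#' Default histone peptidoform roster
#'
#' One row per modified peptidoform: the backbone peptide, the modification
#' set, the marks it carries, its vehicle stoichiometry (percent of the
#' peptide pool), and — for competitor-sensitive forms — the planted IC50
#' (uM) and Hill slope of the 4PL decay of its stoichiometry. `ic50 = NA`
#' marks dose-invariant forms. The roster plants the hierarchical
#' sensitivity H3K23ac (KAT6A/B) << H3K14ac (KAT7) < H4K16ac (KAT8) <
#' H2A.Z acetylation (KAT5); H3K9ac and H3K18ac are dose-invariant, and a
#' set of low-stoichiometry forms below 1% exercises the reproducibility
#' filter.
#'
#' @return data.frame with columns `peptide_id`, `modform`, `marks`
#'   (semicolon-separated), `baseline` (% stoichiometry), `ic50` (uM or
#'   NA), `hill`.
#' @export
default_mark_table <- function() {
  r <- function(peptide_id, modform, marks, baseline, ic50 = NA_real_, hill = 1)
    data.frame(peptide_id = peptide_id, modform = modform, marks = marks,
               baseline = baseline, ic50 = ic50, hill = hill)
  do.call(rbind, list(
    ## competitor-sensitive acetyl forms (8 peptidoforms, 6 acetyl positions)
    r("H3_18_26",  "K23ac",      "H3K23ac",            25,  0.025),
    r("H3_9_17",   "K14ac",      "H3K14ac",            15,  1),
    r("H3_9_17",   "K9acK14ac",  "H3K9ac;H3K14ac",      3,  1),
    r("H4_4_17",   "K16ac",      "H4K16ac",            12, 10),
    r("H4_4_17",   "K12acK16ac", "H4K12ac;H4K16ac",     3, 10),
    r("H2AZ_4_11", "K4ac",       "H2A.ZK4ac",           3, 18),
    r("H2AZ_4_11", "K7ac",       "H2A.ZK7ac",         2.5, 18),
    r("H2AZ_4_11", "K4acK7ac",   "H2A.ZK4ac;H2A.ZK7ac", 1.8, 18),
    ## dose-invariant, reproducibly detected forms (30)
    r("H3_3_8",    "K4me1",      "H3K4me1",            20),
    r("H3_3_8",    "K4me2",      "H3K4me2",             5),
    r("H3_3_8",    "K4me3",      "H3K4me3",             2),
    r("H3_9_17",   "K9ac",       "H3K9ac",             12),
    r("H3_9_17",   "K9me1",      "H3K9me1",            15),
    r("H3_9_17",   "K9me2",      "H3K9me2",            20),
    r("H3_9_17",   "K9me3",      "H3K9me3",             8),
    r("H3_18_26",  "K18ac",      "H3K18ac",            10),
    r("H3_27_40",  "K27ac",      "H3K27ac",             3),
    r("H3_27_40",  "K27me1",     "H3K27me1",           12),
    r("H3_27_40",  "K27me2",     "H3K27me2",           20),
    r("H3_27_40",  "K27me3",     "H3K27me3",           10),
    r("H3_27_40",  "K36me1",     "H3K36me1",            8),
    r("H3_27_40",  "K36me2",     "H3K36me2",           12),
    r("H3_27_40",  "K36me3",     "H3K36me3",            5),
    r("H3_27_40",  "K27me1K36me2", "H3K27me1;H3K36me2", 5),
    r("H3_54_63",  "K56ac",      "H3K56ac",           1.5),
    r("H4_4_17",   "K5ac",       "H4K5ac",              2),
    r("H4_4_17",   "K8ac",       "H4K8ac",              3),
    r("H4_4_17",   "K12ac",      "H4K12ac",             4),
    r("H4_4_17",   "K5acK8ac",   "H4K5ac;H4K8ac",     1.6),
    r("H4_4_17",   "K8acK12ac",  "H4K8ac;H4K12ac",    1.5),
    r("H4_20_23",  "K20me1",     "H4K20me1",           30),
    r("H4_20_23",  "K20me2",     "H4K20me2",           40),
    r("H4_20_23",  "K20me3",     "H4K20me3",            8),
    r("H2A_4_11",  "K5ac",       "H2AK5ac",             2),
    r("H2B_12_20", "K12ac",      "H2BK12ac",          2.5),
    r("H2B_12_20", "K15ac",      "H2BK15ac",            3),
    r("H2B_12_20", "K16ac",      "H2BK16ac",          1.8),
    r("H2B_12_20", "K20ac",      "H2BK20ac",          2.2),
    ## low-stoichiometry forms below the 1% reproducibility cutoff (12)
    r("H3_3_8",    "K4ac",       "H3K4ac",            0.3),
    r("H3_18_26",  "K18me1",     "H3K18me1",          0.6),
    r("H3_18_26",  "K23me1",     "H3K23me1",          0.5),
    r("H3_27_40",  "K37me1",     "H3K37me1",          0.4),
    r("H3_54_63",  "K56me1",     "H3K56me1",          0.3),
    r("H4_24_35",  "K31me1",     "H4K31me1",          0.5),
    r("H4_24_35",  "K31ac",      "H4K31ac",           0.3),
    r("H2A_4_11",  "K9ac",       "H2AK9ac",           0.6),
    r("H2A_4_11",  "K13ac",      "H2AK13ac",          0.4),
    r("H2B_1_11",  "K5ac",       "H2BK5ac",           0.7),
    r("H2B_1_11",  "K11ac",      "H2BK11ac",          0.5),
    r("H2B_21_29", "K23ac",      "H2BK23ac",          0.6)
  ))
}

#' Default mark-to-KAT biomarker assignment
#'
#' The field's standard mapping of histone acetylation biomarkers to the
#' enzymes that write them.
#' @return named character vector, mark -> KAT.
#' @export
default_kat_assignment <- function() {
  c("H3K23ac"   = "KAT6A/B",
    "H3K14ac"   = "KAT7",
    "H4K16ac"   = "KAT8",
    "H2A.ZK4ac" = "KAT5",
    "H2A.ZK7ac" = "KAT5",
    "H3K9ac"    = "KAT2A/B",
    "H3K18ac"   = "KAT3A/B")
}

#' Assemble the ground truth of a synthetic study
#'
#' Bundles everything the generators need: the complex roster with capture
#' IC50s, which unannotated proteins carry a complex-like profile
#' (candidate interactors the discovery stage should recover), the histone
#' peptidoform roster with planted mark IC50s, which candidates are planted
#' as true structural interactors of the bait in the in-silico screen, and
#' the planted GI50 of the viability assay. All generators draw from R's
#' RNG; seed them with [set.seed()] (the pipeline and CLI do this for you).
#'
#' @param complex_specs list of [complex_spec()]; default
#'   [default_complex_specs()].
#' @param mark_table data.frame as returned by [default_mark_table()].
#' @param af_interactors character vector of candidate proteins planted as
#'   true bait interactors in the predicted-structure screen.
#' @param bait bait protein for the in-silico screen.
#' @param planted_gi50 GI50 (uM) planted in the viability generator.
#' @param gi50_hill Hill slope of the planted growth curve.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(complex_specs = default_complex_specs(),
                            mark_table = default_mark_table(),
                            af_interactors = c("OGT", "WDR5"),
                            bait = "FOXK2",
                            planted_gi50 = 7,
                            gi50_hill = 1.3) {
  stopifnot(is.list(complex_specs),
            all(vapply(complex_specs, inherits, logical(1), "complex_spec")))
  stop_if_not_scalar_pos(planted_gi50, "planted_gi50")
  bad <- mark_table$baseline <= 0 | mark_table$baseline >= 100
  if (any(bad))
    stop("baseline stoichiometries must lie in (0, 100)%", call. = FALSE)
  members <- unlist(lapply(complex_specs, `[[`, "members"))
  if (anyDuplicated(members))
    stop("a protein may belong to only one complex_spec profile", call. = FALSE)
  annotated <- unlist(lapply(complex_specs, `[[`, "annotated"))
  structure(
    list(complex_specs = complex_specs,
         planted_candidates = members[!annotated],
         mark_table = mark_table,
         af_interactors = af_interactors,
         bait = bait,
         planted_gi50 = planted_gi50,
         gi50_hill = gi50_hill),
    class = "synthetic_truth")
}

#' Complex-annotation reference implied by a synthetic truth
#'
#' Returns the annotation table a curated complex catalogue would hold for
#' the synthetic study: one row per *annotated* complex member. Planted
#' candidates are deliberately absent.
#' @param truth a [synthetic_truth()].
#' @return data.frame with columns `protein`, `complex`.
#' @export
truth_annotation <- function(truth) {
  rows <- lapply(truth$complex_specs, function(cs) {
    keep <- cs$annotated
    if (!any(keep)) return(NULL)
    data.frame(protein = cs$members[keep],
               complex = sub("-partial$", "", cs$name))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
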