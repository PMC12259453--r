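# Packaged constants: the 48-analyte functional-category map, analyte-name
# canonicalisation, and the gene-segment label tables used by the simulator.

#' Functional categories of the 48-analyte cytokine panel
#'
#' The fixed analyte-to-category map used throughout the package: each of the
#' 48 cytokines, chemokines and growth factors of the multiplex panel is
#' assigned to one of five functional groups (chemokine, growth factor,
#' pro-inflammatory, anti-inflammatory, other). Vendor labels such as
#' `"IL-12 (p70)"`/`"IL-12 (p40)"` are canonicalised to `IL-12`/`IL-12-1`;
#' see [canonicalize_analyte()].
#'
#' @format A tibble with 48 rows and columns `analyte` and `category`.
#' @export
cytokine_categories <- tibble::tibble(
  analyte = c(
    # chemokines
    "CTACK", "Eotaxin", "GRO-a", "IL-8", "IP-10", "MCP-1", "MCP-3", "MIG",
    "MIP-1a", "MIP-1b", "RANTES", "SDF-1a",
    # growth factors
    "FGF2", "G-CSF", "GM-CSF", "HGF", "SCF", "SCGF-b", "VEGF", "b-NGF",
    "PDGF-BB",
    # pro-inflammatory
    "IFN-g", "IL-1a", "IL-1b", "IL-6", "IL-12", "IL-12-1", "IL-17", "IL-18",
    "TNF-a", "TNF-b",
    # anti-inflammatory
    "IL-1RA", "IL-4", "IL-10", "IL-13",
    # other
    "IFN-a2", "IL-2", "IL-2Ra", "IL-3", "IL-5", "IL-7", "IL-9", "IL-15",
    "IL-16", "LIF", "M-CSF", "MIF", "TRAIL"
  ),
  category = c(
    rep("chemokine", 12),
    rep("growth factor", 9),
    rep("pro-inflammatory", 10),
    rep("anti-inflammatory", 4),
    rep("other", 13)
  )
)

# vendor / legacy spellings -> canonical analyte identifiers
analyte_synonyms <- c(
  "IL-12 (p70)" = "IL-12",
  "IL-12p70"    = "IL-12",
  "IL-12 (p40)" = "IL-12-1",
  "IL-12p40"    = "IL-12-1",
  "FGF basic"   = "FGF2",
  "IL-17A"      = "IL-17",
  "MIP-1alpha"  = "MIP-1a",
  "MIP-1beta"   = "MIP-1b",
  "GRO-alpha"   = "GRO-a",
  "SDF-1alpha"  = "SDF-1a",
  "IFN-gamma"   = "IFN-g",
  "IFN-alpha2"  = "IFN-a2",
  "TNF-alpha"   = "TNF-a",
  "TNF-beta"    = "TNF-b",
  "SCGF-beta"   = "SCGF-b",
  "beta-NGF"    = "b-NGF",
  "IL-2Ralpha"  = "IL-2Ra",
  "IL-1alpha"   = "IL-1a",
  "IL-1beta"    = "IL-1b"
)

#' Canonicalise analyte names
#'
#' Maps vendor spellings of panel analytes (e.g. `"IL-12 (p70)"`,
#' `"FGF basic"`, `"IL-17A"`) onto the canonical identifiers used by
#' [cytokine_categories]. Unrecognised names are returned unchanged.
#'
#' @param x Character vector of analyte names.
#' @return Character vector of canonical analyte names.
#' @export
canonicalize_analyte <- function(x) {
  hit <- match(x, names(analyte_synonyms))
  out <- x
  out[!is.na(hit)] <- unname(analyte_synonyms[hit[!is.na(hit)]])
  out
}

# TRB gene-segment label tables for the simulator. The base usage weights are
# a fixed, mildly skewed profile; they are not estimates of human gene usage.
trbv_gene_table <- local({
  genes <- c(
    "TRBV28-1", "TRBV6-5", "TRBV5-6", "TRBV3-1", "TRBV27-1", "TRBV19-1",
    "TRBV7-9", "TRBV12-1", "TRBV20-1", "TRBV7-2", "TRBV2-1", "TRBV4-1",
    "TRBV4-2", "TRBV5-1", "TRBV5-4", "TRBV6-1", "TRBV6-2", "TRBV6-6",
    "TRBV7-3", "TRBV7-6", "TRBV7-8", "TRBV9-1", "TRBV10-3", "TRBV11-2",
    "TRBV13-1", "TRBV14-1", "TRBV15-1", "TRBV16-1", "TRBV18-1", "TRBV24-1",
    "TRBV25-1", "TRBV29-1", "TRBV30-1", "TRBV10-1", "TRBV11-1", "TRBV23-1"
  )
  w <- 1 / (seq_along(genes) + 2)
  tibble::tibble(gene = genes, weight = w / sum(w))
})

trbd_genes <- c("TRBD1-1", "TRBD2-1")
trbj_genes <- c(
  "TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5", "TRBJ1-6",
  "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4", "TRBJ2-5", "TRBJ2-6", "TRBJ2-7"
)
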