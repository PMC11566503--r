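#' Index registry
#'
#' One table enumerating every index the package computes, its category
#' (diversity, biotic, functional) and the exported function implementing
#' it. Flow-T is an instance of [fuzzy_trait_ratio()] over the
#' flow-affinity trait block (see [flow_t()]); the biocontamination entry
#' covers the ACI/RCI/SBCI triple of [bioco()].
#'
#' @return Data frame: name, category, fun, needs (extra input the index
#'   requires beyond the aggregated community).
#' @export
index_registry <- function() {
  e <- function(name, category, fun = name, needs = "") {
    data.frame(name = name, category = category, fun = fun, needs = needs,
               stringsAsFactors = FALSE)
  }
  rbind(
    e("richness", "diversity"), e("shannon", "diversity"),
    e("simpson", "diversity"), e("invsimpson", "diversity"),
    e("esimpson", "diversity"), e("pielou", "diversity"),
    e("berpar", "diversity"), e("invberpar", "diversity"),
    e("margalef", "diversity"), e("menhinick", "diversity"),
    e("brillouin", "diversity"), e("mcintosh", "diversity"),
    e("fisher_alpha", "diversity"),
    e("bmwp", "biotic", needs = "scores"),
    e("aspt", "biotic", needs = "scores"),
    e("whpt", "biotic", needs = "scores"),
    e("life", "biotic", needs = "scores"),
    e("psi", "biotic", needs = "scores"),
    e("epsi", "biotic", needs = "scores"),
    e("dehli", "biotic", needs = "scores"),
    e("ibmr", "biotic", needs = "scores"),
    e("ept", "biotic"),
    e("eptd", "biotic", needs = "scores"),
    e("igold", "biotic"),
    e("bioco", "biotic", needs = "alien"),
    e("flow_t", "biotic", needs = "traits"),
    e("f_rich", "functional", needs = "space"),
    e("f_disp", "functional", needs = "space"),
    e("f_eve", "functional", needs = "space"),
    e("f_divs", "functional", needs = "dist"),
    e("f_red", "functional", needs = "dist"),
    e("cwm", "functional", needs = "traits"),
    e("csi", "functional", needs = "traits"),
    e("tsi", "functional", needs = "traits"),
    e("fuzzy_trait_ratio", "functional", needs = "traits"))
}

#' Plot-data structures available
#'
#' @return Character vector naming the three plot-ready data structures.
#' @export
plot_data_registry <- function() {
  c(sankey = "plot_indicator_taxa_data",
    prevalence = "prevalence_data",
    composition = "composition_barplot_data")
}

#' PCoA corrections and trait-space quality criteria available
#'
#' @return List with \code{corrections} and \code{criteria}.
#' @export
pcoa_registry <- function() {
  list(corrections = c("cailliez", "lingoes", "sqrt", "quasi"),
       criteria = c("corr", "r2", "msd"))
}
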