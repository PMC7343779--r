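#' Canonical cortical parcellation regions
#'
#' The 34 bilateral cortical regions of the Desikan-Killiany parcellation used
#' for regional aggregation, as 68 (34 x 2 hemispheres) entries. Codes 1-34
#' are left-hemisphere regions, 35-68 the corresponding right-hemisphere
#' regions.
#'
#' @return A tibble with columns `region_code`, `hemi` (`"left"`/`"right"`)
#'   and `region` (e.g. `"fusiform left"`).
#' @export
#' @examples
#' dk_regions()
dk_regions <- function() {
  base <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
    "temporalpole", "transversetemporal", "insula"
  )
  tibble(
    region_code = seq_len(68L),
    hemi = rep(c("left", "right"), each = 34L),
    region = paste(rep(base, 2L), rep(c("left", "right"), each = 34L))
  )
}

#' Look up region names for integer parcel codes
#'
#' @param codes Integer parcel codes (1-68), or codes from a custom lookup.
#' @param lookup A region lookup tibble as returned by [dk_regions()], or a
#'   custom one with columns `region_code` and `region` (e.g. the synthetic
#'   phantom's two-region table).
#' @return Character vector of region names (NA for unknown codes).
#' @export
region_name <- function(codes, lookup = dk_regions()) {
  lookup$region[match(codes, lookup$region_code)]
}
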