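#' Desikan-Killiany cortical region names
#'
#' The 34 cortical parcels per hemisphere of the Desikan-Killiany atlas.
#'
#' @return Character vector of 34 region names.
#' @export
dk_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal",
    "temporalpole", "transversetemporal")
}

#' Lobar assignment of Desikan-Killiany regions
#'
#' Standard lobar grouping of the 34 DK parcels into frontal, parietal,
#' temporal, occipital, cingulate and insula lobes.  Any standard grouping
#' leaves the catalog counts unchanged; this one is fixed so that lobar
#' aggregates are reproducible.
#'
#' @return Named character vector mapping region name to lobe.
#' @export
dk_lobe_map <- function() {
  lobes <- list(
    frontal = c("superiorfrontal", "rostralmiddlefrontal",
                "caudalmiddlefrontal", "parsopercularis", "parstriangularis",
                "parsorbitalis", "lateralorbitofrontal", "medialorbitofrontal",
                "precentral", "paracentral", "frontalpole"),
    parietal = c("superiorparietal", "inferiorparietal", "supramarginal",
                 "postcentral", "precuneus"),
    temporal = c("superiortemporal", "middletemporal", "inferiortemporal",
                 "bankssts", "fusiform", "transversetemporal", "entorhinal",
                 "temporalpole", "parahippocampal"),
    occipital = c("lateraloccipital", "lingual", "cuneus", "pericalcarine"),
    cingulate = c("rostralanteriorcingulate", "caudalanteriorcingulate",
                  "posteriorcingulate", "isthmuscingulate"),
    insula = "insula")
  out <- rep(names(lobes), lengths(lobes))
  names(out) <- unlist(lobes, use.names = FALSE)
  out[dk_regions()]
}

#' Subcortical structures with bilateral representation
#' @return Character vector of 8 structure names.
#' @export
subcortical_structures <- function() {
  c("thalamus_proper", "caudate", "putamen", "pallidum", "accumbens_area",
    "hippocampus", "amygdala", "ventral_dc")
}

.som_kinds <- c("volume", "mean_cth", "sd_cth", "asymmetry", "icv")

.catalog_row <- function(name, kind, region, hemisphere, normalizable) {
  data.frame(name = name, kind = kind, region = region,
             hemisphere = hemisphere, normalizable = normalizable,
             stringsAsFactors = FALSE)
}

# one lh/rh pair plus its asymmetry entry, for a region and metric kind
.bilateral_entries <- function(region, kind) {
  rbind(
    .catalog_row(paste("lh", region, kind, sep = "."), kind, region, "lh", TRUE),
    .catalog_row(paste("rh", region, kind, sep = "."), kind, region, "rh", TRUE),
    .catalog_row(paste("asym", region, kind, sep = "."), "asymmetry", region,
                 "bilateral-index", FALSE))
}

#' Build the canonical metric catalog
#'
#' Enumerates the full set of raw regional morphometry metrics: 8 bilateral
#' subcortical volumes with asymmetry indices, 3 midline volumes, 3 metric
#' kinds (GM volume, mean and SD of cortical thickness) for the 34 DK
#' regions per hemisphere with asymmetries, 6 lobar volumes per hemisphere
#' with asymmetries, hemispheric cortex volume and mean thickness with
#' asymmetries, and one intracranial-volume (ICV) entry.  This yields 358
#' raw entries of which 239 (everything except asymmetry indices and ICV)
#' have a brain-size-normalized variant, for 597 metrics in total.
#'
#' Canonical naming is \code{<hemi>.<region>.<kind>} with hemisphere
#' \code{lh}/\code{rh}/\code{mid}, asymmetry entries named
#' \code{asym.<region>.<kind>}, and normalized variants suffixed
#' \code{.norm}.
#'
#' @return A data.frame of class \code{som_catalog} with columns
#'   \code{name}, \code{kind}, \code{region}, \code{hemisphere},
#'   \code{normalizable}.
#' @export
build_metric_catalog <- function() {
  rows <- list()
  for (s in subcortical_structures())
    rows[[length(rows) + 1L]] <- .bilateral_entries(s, "volume")
  for (m in c("brainstem", "ventricle_3rd", "ventricle_4th"))
    rows[[length(rows) + 1L]] <-
      .catalog_row(paste("mid", m, "volume", sep = "."), "volume", m, "midline", TRUE)
  for (r in dk_regions())
    for (k in c("volume", "mean_cth", "sd_cth"))
      rows[[length(rows) + 1L]] <- .bilateral_entries(r, k)
  for (lb in unique(dk_lobe_map()))
    rows[[length(rows) + 1L]] <- .bilateral_entries(paste0(lb, "_lobe"), "volume")
  rows[[length(rows) + 1L]] <- .bilateral_entries("cortex", "volume")
  rows[[length(rows) + 1L]] <- .bilateral_entries("cortex", "mean_cth")
  rows[[length(rows) + 1L]] <-
    .catalog_row("icv", "icv", "whole_brain", "midline", FALSE)
  cat <- do.call(rbind, rows)
  rownames(cat) <- NULL
  class(cat) <- c("som_catalog", "data.frame")
  cat
}

#' Raw metric names of a catalog
#' @param catalog A \code{som_catalog}.
#' @return Character vector of the 358 raw metric names.
#' @export
catalog_raw_names <- function(catalog) catalog$name

#' Normalized metric names of a catalog
#' @param catalog A \code{som_catalog}.
#' @return Character vector of the 239 normalized metric names
#'   (\code{.norm} suffix).
#' @export
catalog_normalized_names <- function(catalog)
  paste0(catalog$name[catalog$normalizable], ".norm")

#' All metric names (raw plus normalized)
#' @param catalog A \code{som_catalog}.
#' @return Character vector of the 597 metric names.
#' @export
catalog_all_names <- function(catalog)
  c(catalog_raw_names(catalog), catalog_normalized_names(catalog))

# left/right partner names for an asymmetry entry
.asym_pair <- function(region, kind) {
  c(left = paste("lh", region, kind, sep = "."),
    right = paste("rh", region, kind, sep = "."))
}

#' Names of cortical DK metrics for one kind
#'
#' @param catalog A \code{som_catalog}.
#' @param kind One of \code{volume}, \code{mean_cth}, \code{sd_cth}.
#' @param normalized Return the \code{.norm} variants?
#' @return Character vector of 68 metric names (34 regions x 2 hemispheres).
#' @export
catalog_dk_names <- function(catalog, kind = "mean_cth", normalized = FALSE) {
  sel <- catalog$kind == kind & catalog$region %in% dk_regions() &
    catalog$hemisphere %in% c("lh", "rh")
  nm <- catalog$name[sel]
  if (normalized) paste0(nm, ".norm") else nm
}

#' Export the catalog as CSV
#' @param catalog A \code{som_catalog}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE)
  invisible(path)
}
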