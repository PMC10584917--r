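#' Electrode montage with region assignments
#'
#' A montage is the ordered set of channel labels together with a map from
#' each channel to a scalp region. The default is the 16-channel motor-imagery
#' montage used throughout this package, grouped into frontal, parietal,
#' temporal and occipital regions.
#'
#' @param labels Character vector of unique channel names.
#' @param region_map Named character vector or list mapping every channel
#'   label to exactly one region tag.
#' @return An object of class `"mst_montage"` with elements `labels` and
#'   `region_map` (named character vector).
#' @examples
#' m <- default_montage()
#' m$labels
#' channels_in_region(m, "temporal")
#' @export
montage_spec <- function(labels, region_map) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("montage labels must be unique", call. = FALSE)
  }
  region_map <- unlist(region_map)
  if (!setequal(names(region_map), labels)) {
    stop("region_map must assign every montage label to exactly one region",
         call. = FALSE)
  }
  structure(
    list(labels = labels, region_map = region_map[labels]),
    class = "mst_montage"
  )
}

#' @rdname montage_spec
#' @export
default_montage <- function() {
  labels <- c("AF3", "AF4", "FC3", "FCz", "FC4", "C3", "Cz", "C4",
              "T7", "T8", "CP3", "CPz", "CP4", "Pz", "O1", "O2")
  regions <- c(
    AF3 = "frontal", AF4 = "frontal", FC3 = "frontal", FCz = "frontal",
    FC4 = "frontal", Cz = "frontal",
    C3 = "parietal", C4 = "parietal", CP3 = "parietal", CPz = "parietal",
    CP4 = "parietal", Pz = "parietal",
    T7 = "temporal", T8 = "temporal",
    O1 = "occipital", O2 = "occipital"
  )
  montage_spec(labels, regions)
}

#' @rdname montage_spec
#' @param montage A `"mst_montage"` object.
#' @param region Region tag to look up.
#' @export
channels_in_region <- function(montage, region) {
  stopifnot(inherits(montage, "mst_montage"))
  if (!region %in% montage$region_map) {
    stop("unknown region: ", region, call. = FALSE)
  }
  montage$labels[montage$region_map[montage$labels] == region]
}

#' @export
print.mst_montage <- function(x, ...) {
  cat("<mst_montage> ", length(x$labels), " channels\n", sep = "")
  for (r in unique(x$region_map)) {
    cat("  ", r, ": ", paste(x$labels[x$region_map == r], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
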