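#' AAL-90 node labels
#'
#' Ordered region labels of the 90-region automated anatomical labeling
#' (AAL) parcellation (cortical and subcortical regions, cerebellum
#' excluded), in the conventional left/right interleaved order. These are
#' the node labels every connectivity matrix in the package carries by
#' default.
#'
#' @param definition_file Optional path to a JSON atlas/subnetwork
#'   definition file overriding the shipped resource. The file must contain
#'   a `node_labels` array and a `subnetworks` object mapping subnetwork
#'   names to region-label arrays.
#' @return Character vector of 90 region labels.
#' @export
aal90_labels <- function(definition_file = NULL) {
  atlas_resource(definition_file)$node_labels
}

#' Canonical subnetwork definitions
#'
#' Returns the fixed 12-region subsets of the AAL-90 atlas used for the
#' default mode (DMN), executive control (ECN), and salience (SAN)
#' networks, each defined by six bilateral region pairs, plus a
#' `whole_brain` definition covering all 90 regions. DMN: superior frontal
#' gyrus (medial), middle temporal gyrus, superior frontal gyrus
#' (dorsolateral), anterior cingulate cortex, precuneus, angular gyrus.
#' ECN: superior frontal gyrus (dorsolateral), middle frontal gyrus,
#' inferior frontal gyrus (triangular part), inferior parietal gyrus,
#' caudate, inferior temporal gyrus. SAN: middle cingulate cortex,
#' supplementary motor area, inferior frontal gyrus (pars orbitalis),
#' superior frontal gyrus (medial), insula, caudate.
#'
#' @inheritParams aal90_labels
#' @return Named list of character vectors of region labels.
#' @examples
#' names(subnetwork_definitions())
#' subnetwork_definitions()$DMN
#' @export
subnetwork_definitions <- function(definition_file = NULL) {
  res <- atlas_resource(definition_file)
  subs <- res$subnetworks
  subs$whole_brain <- res$node_labels
  subs
}

atlas_resource <- function(definition_file = NULL) {
  path <- definition_file %||%
    system.file("extdata", "aal90_subnetworks.json", package = "scfc",
                mustWork = TRUE)
  res <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  stopifnot(is.character(res$node_labels), is.list(res$subnetworks))
  bad <- vapply(res$subnetworks,
                function(r) any(!r %in% res$node_labels), logical(1))
  if (any(bad)) {
    stop("subnetwork regions not in node_labels: ",
         paste(names(res$subnetworks)[bad], collapse = ", "))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
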