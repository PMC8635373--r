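#' Construct a connectivity matrix
#'
#' Wraps a square symmetric matrix of edge values with node labels and a
#' modality tag. Structural (`"SC"`) matrices hold non-negative fiber
#' counts; functional (`"FC"`) matrices hold Fisher-z transformed
#' correlations. The diagonal is forced to zero. Mildly asymmetric input
#' (as raw probabilistic tractography produces, where counts seeded from
#' region i to j need not equal j to i) is symmetrized by the elementwise
#' mean; SC values are then rounded half-up so counts stay integer.
#'
#' @param values Square numeric matrix.
#' @param node_labels Character vector of region names, one per row.
#'   Defaults to existing rownames, else the AAL-90 labels when the matrix
#'   is 90 x 90.
#' @param modality `"SC"` or `"FC"`.
#' @param symmetrize_tol Maximum allowed `max(abs(x - t(x)))` before
#'   symmetrization refuses; defaults to `Inf` (always symmetrize).
#' @return A `connectivity_matrix`: the numeric matrix with `modality`
#'   attribute and label dimnames.
#' @export
connectivity_matrix <- function(values, node_labels = NULL,
                                modality = c("SC", "FC"),
                                symmetrize_tol = Inf) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("connectivity matrix must be square")
  }
  if (!all(is.finite(values))) stop("connectivity matrix has non-finite entries")
  asym <- max(abs(values - t(values)))
  if (asym > symmetrize_tol) {
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g",
                 asym, symmetrize_tol))
  }
  values <- (values + t(values)) / 2
  if (modality == "SC") {
    if (any(values < 0)) stop("SC matrix has negative fiber counts")
    values <- floor(values + 0.5)  # round half-up: counts are integers
  }
  diag(values) <- 0
  n <- nrow(values)
  if (is.null(node_labels)) {
    node_labels <- rownames(values) %||%
      (if (n == 90) aal90_labels() else sprintf("node%03d", seq_len(n)))
  }
  if (length(node_labels) != n) stop("node_labels length != matrix size")
  dimnames(values) <- list(node_labels, node_labels)
  structure(values, modality = modality,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %d x %d nodes\n",
              attr(x, "modality"), nrow(x), ncol(x)))
  cat(sprintf("  nonzero off-diagonal: %d / %d\n",
              sum(x[upper.tri(x)] != 0), sum(upper.tri(x))))
  invisible(x)
}

modality <- function(x) attr(x, "modality")

#' Restrict a matrix or graph to a subnetwork
#'
#' Takes the principal submatrix of a connectivity matrix (or binary
#' graph adjacency) over the regions of a subnetwork definition, in the
#' definition's region order. Because both thresholding and extraction act
#' elementwise, extraction commutes with thresholding.
#'
#' @param x A `connectivity_matrix`, `binary_graph`, or plain labeled
#'   square matrix.
#' @param regions Character vector of region labels (one entry of
#'   [subnetwork_definitions()]), or a subnetwork name to be resolved
#'   against the shipped definitions.
#' @return Object of the same class restricted to the subnetwork regions.
#' @export
extract_subnetwork <- function(x, regions) {
  if (length(regions) == 1 && !regions %in% rownames(x)) {
    defs <- subnetwork_definitions()
    if (!regions %in% names(defs)) stop("unknown subnetwork: ", regions)
    regions <- defs[[regions]]
  }
  missing <- setdiff(regions, rownames(x))
  if (length(missing) > 0) {
    stop("regions not present in matrix: ", paste(missing, collapse = ", "))
  }
  out <- x[regions, regions, drop = FALSE]
  attributes(out)$modality <- attr(x, "modality")
  class(out) <- class(x)
  out
}

#' Write / read a connectivity matrix as delimited text
#'
#' Matrices are stored as tab-separated text, one row per node, no header;
#' node labels travel in a JSON sidecar (`<path>.json`) together with the
#' modality, so the text file stays loadable by any numeric reader.
#'
#' @param x A `connectivity_matrix`.
#' @param path Output path for the matrix text file.
#' @return `write_matrix`: `path`, invisibly. `read_matrix`: a
#'   `connectivity_matrix`.
#' @export
write_matrix <- function(x, path) {
  utils::write.table(unclass(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sidecar <- list(node_labels = rownames(x), modality = modality(x))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @param modality Modality override when no sidecar is present.
#' @export
read_matrix <- function(path, modality = NULL) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  sidecar_path <- paste0(path, ".json")
  labels <- NULL
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::fromJSON(sidecar_path)
    labels <- sidecar$node_labels
    modality <- modality %||% sidecar$modality
  }
  if (is.null(modality)) stop("modality not given and no sidecar found: ", path)
  connectivity_matrix(m, node_labels = labels, modality = modality)
}
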