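#' Point clouds as tibbles
#'
#' A point cloud is a tibble with numeric columns `x`, `y`, `z` (millimetres),
#' optionally unit-normal columns `nx`, `ny`, `nz`, and optionally a character
#' `label` column tagging each point with an anatomical region (see
#' [spinefit_labels()]).
#' `as_point_cloud()` validates these invariants and returns the tibble with
#' class `point_cloud` prepended so plotting and printing can dispatch.
#'
#' @param data A data frame with at least `x`, `y`, `z` columns.
#' @return A `point_cloud` tibble.
#' @examples
#' as_point_cloud(data.frame(x = 0:1, y = 0, z = 0))
#' @export
as_point_cloud <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("x", "y", "z")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("point cloud is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(data) < 1) abort("point cloud must contain at least one point")
  xyz <- as.matrix(data[need])
  if (!is.numeric(xyz) || !all(is.finite(xyz))) {
    abort("point coordinates must be finite numerics")
  }
  if (has_normals(data)) {
    nrm <- as.matrix(data[c("nx", "ny", "nz")])
    if (!all(is.finite(nrm))) abort("normals must be finite")
    len <- sqrt(rowSums(nrm^2))
    if (any(abs(len - 1) > 1e-9)) abort("normals must have unit length")
  }
  if ("label" %in% names(data)) {
    bad <- setdiff(unique(data$label), spinefit_labels())
    if (length(bad) > 0) {
      abort(paste0("unknown region label(s): ", paste(bad, collapse = ", ")))
    }
  }
  class(data) <- unique(c("point_cloud", class(data)))
  data
}

#' Region labels recognised on labelled point clouds
#' @return Character vector of valid `label` values.
#' @export
spinefit_labels <- function() {
  c("left_hemilamina", "right_hemilamina", "sp_base", "sp_tip",
    "facet", "transverse_process", "surface", "outlier")
}

has_normals <- function(data) all(c("nx", "ny", "nz") %in% names(data))

cloud_matrix <- function(cloud) {
  unname(as.matrix(cloud[c("x", "y", "z")]))
}

normal_matrix <- function(cloud) {
  unname(as.matrix(cloud[c("nx", "ny", "nz")]))
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("# A point cloud: %d points%s%s\n", nrow(x),
              if (has_normals(x)) ", with normals" else "",
              if ("label" %in% names(x)) ", labelled" else ""))
  NextMethod()
}
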