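#' Pairwise Euclidean distances between ponds
#'
#' @param ponds a data.frame with columns `pond`, `x`, `y` (coordinates in
#'   metres), or a 2-column coordinate matrix with pond names as row names.
#' @return labelled symmetric distance matrix in metres (zero diagonal).
#' @examples
#' euclidean_distances(data.frame(pond = c("A", "B"), x = c(0, 3), y = c(0, 4)))
#' @export
euclidean_distances <- function(ponds) {
  if (is.data.frame(ponds)) {
    if (!all(c("pond", "x", "y") %in% names(ponds)))
      stopf("ponds data.frame needs columns pond, x, y")
    coords <- as.matrix(ponds[c("x", "y")])
    rownames(coords) <- as.character(ponds$pond)
  } else {
    coords <- as.matrix(ponds)
    if (is.null(rownames(coords))) stopf("coordinate matrix needs pond row names")
  }
  if (nrow(coords) < 2L) stopf("need at least 2 ponds")
  if (any(!is.finite(coords))) stopf("non-finite coordinates")
  if (anyDuplicated(rownames(coords))) stopf("duplicate pond labels")
  m <- as.matrix(stats::dist(coords))
  dimnames(m) <- list(rownames(coords), rownames(coords))
  validate_dist_matrix(m)
  m
}
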