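#' Tanimoto similarity of two binary fingerprints
#'
#' Computes `|u n v| / |u u v|` on the on-bit index sets. On binary vectors
#' this coincides with the Tanimoto kernel
#' `K(u, v) = <u,v> / (<u,u> + <v,v> - <u,v>)`, so one computation serves both
#' as the similarity measure for SAR scoring and as the SVR kernel.
#'
#' @param u,v Non-empty integer vectors of on-bit indices over the same
#'   fingerprint universe.
#' @return Similarity in `[0, 1]`; 1 exactly when `u` and `v` are the same set.
#' @examples
#' tanimoto(c(1L, 2L), c(1L, 3L)) # 1/3
#' @export
tanimoto <- function(u, v) {
  if (length(u) == 0 || length(v) == 0) {
    stop_input("Fingerprints must be non-empty.", class = "sarsvr_empty_fingerprint")
  }
  n_common <- length(intersect(u, v))
  n_u <- length(unique(u))
  n_v <- length(unique(v))
  n_common / (n_u + n_v - n_common)
}

#' Pairwise Tanimoto similarity matrix of a data set
#'
#' Builds the dense n-by-n matrix of all pairwise Tanimoto coefficients, used
#' both as the similarity input to SARI scoring / landscape embedding and as
#' the precomputed SVR kernel. Computed via a binary bit-matrix product, so
#' intersections are exact integer counts and the matrix is exactly symmetric
#' with unit diagonal.
#'
#' @param dataset A [cmpd_dataset()] (or data frame with a `fingerprint`
#'   list-column).
#' @return An n-by-n numeric matrix with `dimnames` set to the compound ids
#'   when available.
#' @export
pairwise_matrix <- function(dataset) {
  dataset <- as_dataset_input(dataset, "dataset")
  fps <- dataset$fingerprint
  n <- length(fps)
  if (n == 0) stop_input("`dataset` is empty.")
  universe <- if (is_cmpd_dataset(dataset)) dataset_attr(dataset, "universe") else max(unlist(fps))
  sizes <- lengths(fps)
  if (any(sizes == 0)) {
    stop_input("Empty fingerprints are not allowed.", class = "sarsvr_empty_fingerprint")
  }
  x <- matrix(0, nrow = n, ncol = universe)
  x[cbind(rep.int(seq_len(n), sizes), unlist(fps))] <- 1
  inter <- tcrossprod(x)
  uni <- outer(sizes, sizes, "+") - inter
  m <- inter / uni
  diag(m) <- 1
  if (!is.null(dataset$compound_id)) {
    dimnames(m) <- list(dataset$compound_id, dataset$compound_id)
  }
  m
}

#' Extract a kernel block from a similarity matrix
#'
#' Convenience slice used to carve train/train and test/train kernel blocks
#' out of a precomputed full-data-set kernel.
#'
#' @param matrix A square similarity/kernel matrix.
#' @param row_indices,col_indices Integer indices into the matrix.
#' @return The sub-matrix `matrix[row_indices, col_indices]`, never dropped to
#'   a vector.
#' @export
kernel_blocks <- function(matrix, row_indices, col_indices) {
  n <- nrow(matrix)
  row_indices <- as.integer(row_indices)
  col_indices <- as.integer(col_indices)
  if (length(row_indices) == 0 || length(col_indices) == 0) {
    stop_input("Index sets must be non-empty.")
  }
  if (any(is.na(row_indices)) || any(is.na(col_indices)) ||
      any(row_indices < 1) || any(row_indices > n) ||
      any(col_indices < 1) || any(col_indices > ncol(matrix))) {
    stop_input("Indices out of range.", class = "sarsvr_index_error")
  }
  matrix[row_indices, col_indices, drop = FALSE]
}
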