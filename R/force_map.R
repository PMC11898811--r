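#' Instance centroids of a label map
#'
#' One centroid per instance id (arithmetic mean of 0-based pixel
#' coordinates), in id order.
#'
#' @param labels H x W integer instance map (0 = background).
#' @return data.frame with columns `instance_id`, `row`, `col` (continuous,
#'   0-based); zero rows for an empty map.
#' @export
compute_centers <- function(labels) {
  n <- max(labels, 0L)
  if (n == 0L)
    return(data.frame(instance_id = integer(0), row = numeric(0),
                      col = numeric(0)))
  idx <- which(labels > 0, arr.ind = TRUE)
  id <- labels[labels > 0]
  data.frame(
    instance_id = seq_len(n),
    row = as.numeric(tapply(idx[, 1] - 1, factor(id, levels = seq_len(n)), mean)),
    col = as.numeric(tapply(idx[, 2] - 1, factor(id, levels = seq_len(n)), mean)))
}

#' Inward-directed force field of an instance label map
#'
#' Every foreground pixel receives a 2-vector pointing from the pixel toward
#' its own instance's centroid: `-alpha * (p - C) / ||p - C||` in `"unit"`
#' mode (all nonzero vectors have magnitude `alpha`), or `-alpha * (p - C)`
#' in `"distance"` mode (magnitude proportional to the centre distance).
#' Pixels within 0.5 px of their centre and all background pixels carry the
#' zero vector. Channel order is (delta-row, delta-col), 0-based coordinates.
#'
#' @param labels H x W integer instance map.
#' @param alpha positive scaling factor (default 1).
#' @param mode `"unit"` or `"distance"`.
#' @return object of class `forceseg_force_field`: list with `field`
#'   (H x W x 2 array), `alpha`, `mode`, `centers`.
#' @export
compute_force_field <- function(labels, alpha = 1, mode = c("unit", "distance")) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0)
  h <- nrow(labels); w <- ncol(labels)
  field <- array(0, c(h, w, 2))
  centers <- compute_centers(labels)
  if (nrow(centers) > 0) {
    rr <- matrix(0:(h - 1), h, w)
    cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
    for (i in centers$instance_id) {
      m <- labels == i
      dr <- rr[m] - centers$row[i]
      dc <- cc[m] - centers$col[i]
      d <- sqrt(dr^2 + dc^2)
      scale <- if (mode == "unit") ifelse(d > 0.5, alpha / d, 0)
               else ifelse(d > 0.5, alpha, 0)
      f1 <- field[, , 1]; f2 <- field[, , 2]
      f1[m] <- -scale * dr
      f2[m] <- -scale * dc
      field[, , 1] <- f1; field[, , 2] <- f2
    }
  }
  structure(list(field = field, alpha = alpha, mode = mode, centers = centers),
            class = "forceseg_force_field")
}

#' Force field derived from a probability map (inference pathway)
#'
#' Thresholds the probability map, labels 8-connected components and
#' delegates to [compute_force_field()]. An empty prediction yields the
#' all-zero field.
#'
#' @param prob_map H x W matrix of probabilities in `[0, 1]`.
#' @param alpha positive scaling factor.
#' @param threshold probability cut (default 0.5).
#' @param mode `"unit"` or `"distance"`.
#' @return a `forceseg_force_field`.
#' @export
force_field_from_prediction <- function(prob_map, alpha = 1, threshold = 0.5,
                                        mode = "unit") {
  stopifnot(all(prob_map >= 0 & prob_map <= 1))
  lab <- .label8(matrix(as.integer(prob_map >= threshold),
                        nrow(prob_map), ncol(prob_map)))
  compute_force_field(lab, alpha = alpha, mode = mode)
}
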