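# 8-connected component labelling of a logical matrix. BFS flood fill with a
# preallocated ring buffer; AFM masks are sparse so this stays cheap.
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  queue <- integer(sum(mask))
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    labels[start] <- lab
    queue[1] <- start
    head_i <- 1L; tail_i <- 1L
    while (head_i <= tail_i) {
      cur <- queue[head_i]; head_i <- head_i + 1L
      r <- ((cur - 1L) %% nr) + 1L
      cl <- ((cur - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- cl + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        nb <- (cc - 1L) * nr + rr
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- lab
          tail_i <- tail_i + 1L
          queue[tail_i] <- nb
        }
      }
    }
  }
  labels
}

#' Roundness of a particle from its pixel footprint
#'
#' The equivalent-ellipse shape metric `4 * area / (pi * L_major^2)`, where
#' `L_major` is the major-axis length of the ellipse with the same second
#' moments as the pixel set (each pixel treated as a unit square, adding
#' 1/12 to each moment). A flat, perfectly round particle scores 1; a 2:1
#' oval (a particle lying on its side) scores 0.5.
#'
#' @param rows,cols Integer pixel coordinates of the particle's footprint
#'   (>= 5 pixels).
#' @return Roundness in (0, 1].
#' @export
particle_roundness <- function(rows, cols) {
  n <- length(rows)
  if (n != length(cols)) abort("`rows` and `cols` must have equal length.")
  if (n < 5L) abort("degenerate particle: roundness needs >= 5 pixels.")
  cov_m <- stats::cov(cbind(rows, cols)) * (n - 1) / n + diag(1 / 12, 2)
  lam_max <- max(eigen(cov_m, symmetric = TRUE, only.values = TRUE)$values)
  l_major <- 4 * sqrt(lam_max)
  min(4 * n / (pi * l_major^2), 1)
}

#' Detect particles on an AFM height image
#'
#' Thresholds the image at `background + height_threshold`, groups the
#' selected pixels by 8-connectivity, and measures each particle: maximum
#' height above background (nm), footprint area (nm^2), equivalent-circle
#' diameter `2 sqrt(area/pi)` (nm), volume as the background-subtracted
#' height integral (nm^3), and roundness ([particle_roundness()]; `NA` for
#' footprints under 5 pixels).
#'
#' @param image A [height_image()].
#' @param height_threshold Detection threshold above background, nm
#'   (default 1.0). If it selects more than 20% of all pixels a warning is
#'   issued (threshold likely below the noise floor) and detection proceeds.
#' @param min_area Minimum particle footprint in nm^2; smaller components
#'   are discarded (default 0).
#'
#' @return A tibble of class `particle_table`: `particle`, `centroid_x_nm`,
#'   `centroid_y_nm`, `height_nm`, `area_nm2`, `diameter_nm`, `volume_nm3`,
#'   `roundness`, `n_pixels`. Image metadata in attributes.
#' @export
detect_particles <- function(image, height_threshold = 1.0, min_area = 0) {
  stopifnot(inherits(image, "height_image"))
  if (height_threshold <= 0) abort("height_threshold must be > 0 nm.")
  g <- image$grid
  px <- image$pixel_size
  bg <- image$background
  mask <- g > bg + height_threshold
  if (mean(mask) > 0.2) {
    warn("height threshold selects more than 20% of pixels; likely below the noise floor.")
  }
  empty <- tibble(
    particle = integer(), centroid_x_nm = double(), centroid_y_nm = double(),
    height_nm = double(), area_nm2 = double(), diameter_nm = double(),
    volume_nm3 = double(), roundness = double(), n_pixels = integer()
  )
  if (!any(mask)) {
    out <- empty
  } else {
    labels <- .label_components(mask)
    pix_area <- px^2
    out <- purrr::map_dfr(seq_len(max(labels)), function(k) {
      idx <- which(labels == k)
      n_pix <- length(idx)
      area <- n_pix * pix_area
      if (area < min_area) return(NULL)
      rows <- ((idx - 1L) %% nrow(g)) + 1L
      cols <- ((idx - 1L) %/% nrow(g)) + 1L
      hts <- g[idx] - bg
      tibble(
        particle = k,
        # pixel centres: (i - 0.5) * pixel_size; x along columns, y along rows
        centroid_x_nm = mean(cols - 0.5) * px,
        centroid_y_nm = mean(rows - 0.5) * px,
        height_nm = max(hts),
        area_nm2 = area,
        diameter_nm = 2 * sqrt(area / pi),
        volume_nm3 = sum(hts) * pix_area,
        roundness = if (n_pix >= 5L) particle_roundness(rows, cols) else NA_real_,
        n_pixels = n_pix
      )
    })
    if (nrow(out) > 0L) out$particle <- seq_len(nrow(out)) else out <- empty
  }
  class(out) <- c("particle_table", class(out))
  attr(out, "pixel_size_nm") <- px
  attr(out, "background_nm") <- bg
  attr(out, "height_threshold_nm") <- height_threshold
  out
}

#' Group particles into clusters by centroid distance
#'
#' Single-linkage agglomeration with a hard distance cutoff: two particles
#' belong to the same cluster when a chain of centroid-to-centroid links,
#' each within `radius_um`, connects them (equivalently, connected
#' components of the distance graph). The alternative `"fixed_disc"` mode
#' instead counts, for each single-linkage group, the particles within
#' `radius_um` of the group centroid.
#'
#' @param particles A [detect_particles()] table (or any data frame with
#'   `centroid_x_nm`, `centroid_y_nm`).
#' @param radius_um Grouping radius in micrometres (default 0.25).
#' @param method `"single_linkage"` (default) or `"fixed_disc"`.
#'
#' @return A tibble of class `cluster_report`: one row per cluster with
#'   `cluster`, `size`, `centroid_x_nm`, `centroid_y_nm`. The particle table
#'   with a `cluster` column is attached as attribute `"particles"`;
#'   `radius_um` and `method` are attributes too.
#' @export
count_clusters <- function(particles, radius_um = 0.25,
                           method = c("single_linkage", "fixed_disc")) {
  method <- match.arg(method)
  if (radius_um <= 0) abort("grouping radius must be > 0.")
  n <- nrow(particles)
  radius_nm <- radius_um * 1000
  if (n == 0L) {
    membership <- integer(0)
  } else if (n == 1L) {
    membership <- 1L
  } else {
    xy <- cbind(particles$centroid_x_nm, particles$centroid_y_nm)
    hc <- hclust(dist(xy), method = "single")
    membership <- cutree(hc, h = radius_nm)
    # relabel clusters in order of first appearance for determinism
    membership <- match(membership, unique(membership))
  }
  parts <- as_tibble(particles)
  parts$cluster <- membership
  clusters <- parts |>
    group_by(.data$cluster) |>
    summarise(
      size = dplyr::n(),
      centroid_x_nm = mean(.data$centroid_x_nm),
      centroid_y_nm = mean(.data$centroid_y_nm),
      .groups = "drop"
    )
  if (method == "fixed_disc" && n > 0L) {
    disc_size <- vapply(seq_len(nrow(clusters)), function(k) {
      dx <- parts$centroid_x_nm - clusters$centroid_x_nm[k]
      dy <- parts$centroid_y_nm - clusters$centroid_y_nm[k]
      sum(sqrt(dx^2 + dy^2) <= radius_nm)
    }, integer(1))
    clusters$size <- disc_size
  }
  class(clusters) <- c("cluster_report", class(clusters))
  attr(clusters, "particles") <- parts
  attr(clusters, "radius_um") <- radius_um
  attr(clusters, "method") <- method
  clusters
}

#' Fraction of particles lying in clusters of at least a given size
#'
#' @param report A [count_clusters()] result.
#' @param min_size Minimum cluster size to count as "clustered" (default 2).
#' @return A single fraction in `[0, 1]` (`NaN` for an empty report).
#' @export
fraction_clustered <- function(report, min_size = 2) {
  parts <- attr(report, "particles")
  sizes <- report$size[match(parts$cluster, report$cluster)]
  mean(sizes >= min_size)
}
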