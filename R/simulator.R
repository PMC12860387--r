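#' Generate a synthetic single-cell RNA reference
#'
#' Cells are drawn from `n_types` cell types with marker-gene structure: each
#' type owns a disjoint block of marker genes whose Poisson mean is
#' `marker_fold * base_rate` in cells of that type and `base_rate` elsewhere;
#' all remaining genes are background at `base_rate`. This emulates the
#' marker-separated cell types of a dissociated single-cell reference at a
#' scale where composition is recoverable, without any platform-specific noise
#' model.
#'
#' @param n_cells,n_genes,n_types problem sizes; `n_types <= n_genes`.
#' @param marker_fold fold change of a marker in its own type (> 1).
#' @param base_rate background Poisson rate per gene per cell.
#' @param markers_per_type marker genes owned by each type (default ~12.5% of
#'   genes split evenly, at least 1).
#' @param seed integer seed; the generator is a pure function of it.
#' @return object of class `synthetic_scrna`: list with `counts` (cells x
#'   genes integer matrix), `cell_types` (integer in `1..n_types`),
#'   `marker_map` (per-type marker gene indices) and `params`.
#' @export
generate_synthetic_scrna <- function(n_cells, n_genes, n_types, marker_fold = 8,
                                     base_rate = 1, markers_per_type = NULL,
                                     seed = 1) {
  if (n_types > n_genes) stop_arg("n_types must not exceed n_genes")
  if (marker_fold <= 1) stop_arg("marker_fold must be > 1")
  if (n_cells < n_types) stop_arg("need at least one cell per type")
  markers_per_type <- markers_per_type %||%
    max(1L, floor(n_genes / (8 * n_types)))
  if (markers_per_type * n_types > n_genes)
    stop_arg("markers_per_type * n_types exceeds n_genes")
  with_seed(seed, {
    cell_types <- sort(rep_len(seq_len(n_types), n_cells))
    marker_map <- lapply(seq_len(n_types), function(t)
      seq.int((t - 1L) * markers_per_type + 1L, t * markers_per_type))
    rate <- matrix(base_rate, n_cells, n_genes)
    for (t in seq_len(n_types))
      rate[cell_types == t, marker_map[[t]]] <- marker_fold * base_rate
    counts <- matrix(stats::rpois(n_cells * n_genes, as.vector(rate)),
                     n_cells, n_genes)
    rownames(counts) <- paste0("cell", seq_len(n_cells))
    colnames(counts) <- paste0("gene", seq_len(n_genes))
    structure(list(counts = counts, cell_types = cell_types,
                   marker_map = marker_map,
                   params = list(n_cells = n_cells, n_genes = n_genes,
                                 n_types = n_types, marker_fold = marker_fold,
                                 base_rate = base_rate,
                                 markers_per_type = markers_per_type,
                                 seed = seed)),
              class = "synthetic_scrna")
  })
}

#' Pseudo-spot simulation configuration
#'
#' The number of cells per spot `N_c` and cell types per spot `N_t` are drawn
#' per spot from normal distributions, rounded, and truncated to `N_c >= 1`
#' and `1 <= N_t <= P1`.
#'
#' @param n_spots number of pseudo-spots.
#' @param mu_cells,sigma_cells mean / sd of the `N_c` draw (default 10 / 3).
#' @param mu_types,sigma_types mean / sd of the `N_t` draw (default 3 / 1).
#' @param downsample_fraction binomial thinning fraction in `(0, 1]` applied
#'   to the aggregated counts (default 0.5) to mimic the shallower depth of
#'   real spot-level data.
#' @param seed integer seed.
#' @return list of class `pseudospot_config`.
#' @export
pseudospot_config <- function(n_spots, mu_cells = 10, sigma_cells = 3,
                              mu_types = 3, sigma_types = 1,
                              downsample_fraction = 0.5, seed = 1) {
  if (n_spots < 1) stop_arg("n_spots must be >= 1")
  if (mu_cells < 1) stop_arg("mu_cells must be >= 1")
  if (sigma_cells < 0 || sigma_types < 0) stop_arg("sigma parameters must be >= 0")
  if (downsample_fraction <= 0 || downsample_fraction > 1)
    stop_arg("downsample_fraction must be in (0, 1]")
  structure(list(n_spots = n_spots, mu_cells = mu_cells, sigma_cells = sigma_cells,
                 mu_types = mu_types, sigma_types = sigma_types,
                 downsample_fraction = downsample_fraction, seed = seed),
            class = "pseudospot_config")
}

# draw the per-spot cell count / type count, rounded + truncated
draw_trunc_normal <- function(n, mu, sigma, lo, hi = Inf) {
  pmin(pmax(round(stats::rnorm(n, mu, sigma)), lo), hi)
}

#' Simulate pseudo-spots from a single-cell reference
#'
#' Per spot: draw `N_c` and `N_t` from the configured normal distributions
#' (rounded and truncated), choose `N_t` cell types uniformly without
#' replacement, sample `N_c` cells of the chosen types with replacement
#' proportionally to their abundance in the reference, and sum their count
#' rows. The proportion label row is the exact ratio of sampled per-type cell
#' counts over `N_c`. Downsampling (if `downsample_fraction < 1`) is applied
#' after aggregation; the sampled cell indices are recorded so the
#' pre-downsampling matrix can be replayed exactly.
#'
#' @param ref a `synthetic_scrna`, or any list with `counts` (cells x genes)
#'   and `cell_types`.
#' @param cfg a [pseudospot_config].
#' @return list of class `pseudospot_set` with `expression` (a [spot_matrix],
#'   counts layer, after downsampling), `proportions` (a
#'   [proportion_matrix]), `sampled_cells` (per-spot integer vectors) and
#'   `pre_downsample` (the aggregated [spot_matrix] before thinning).
#' @export
simulate_pseudospots <- function(ref, cfg) {
  if (!inherits(cfg, "pseudospot_config")) stop_arg("cfg must be a pseudospot_config")
  counts <- ref$counts
  types <- as.integer(ref$cell_types)
  P1 <- max(types)
  if (!all(seq_len(P1) %in% types)) stop_arg("every type needs at least one cell")
  type_cells <- split(seq_along(types), types)
  with_seed(cfg$seed, {
    n <- cfg$n_spots
    Nc <- draw_trunc_normal(n, cfg$mu_cells, cfg$sigma_cells, 1)
    Nt <- draw_trunc_normal(n, cfg$mu_types, cfg$sigma_types, 1, P1)
    expr <- matrix(0, n, ncol(counts))
    prop <- matrix(0, n, P1)
    sampled <- vector("list", n)
    for (i in seq_len(n)) {
      chosen_types <- sample(P1, Nt[i], replace = FALSE)
      pool <- unlist(type_cells[chosen_types], use.names = FALSE)
      idx <- pool[sample.int(length(pool), Nc[i], replace = TRUE)]
      sampled[[i]] <- idx
      expr[i, ] <- colSums(counts[idx, , drop = FALSE])
      tab <- tabulate(types[idx], nbins = P1)
      prop[i, ] <- tab / Nc[i]
    }
    ids <- paste0("pspot", seq_len(n))
    pre <- spot_matrix(expr, ids, colnames(counts), layer = "counts")
    out <- if (cfg$downsample_fraction < 1) {
      downsample_counts(pre, cfg$downsample_fraction,
                        seed = derive_seed(cfg$seed, "downsample"))
    } else pre
    structure(list(expression = out,
                   proportions = proportion_matrix(
                     prop, paste0("type", seq_len(P1)), ids),
                   sampled_cells = sampled,
                   n_cells = Nc, n_types_drawn = Nt,
                   pre_downsample = pre),
              class = "pseudospot_set")
  })
}

#' Binomial downsampling of a count matrix
#'
#' Every entry is replaced by an independent `Binomial(count, fraction)` draw
#' (binomial thinning), the standard semantics of count-matrix downsampling.
#' Unbiased: the expected thinned entry is `fraction * count`.
#'
#' @param m a [spot_matrix] with `layer == "counts"`.
#' @param fraction retention fraction in `(0, 1]`.
#' @param seed integer seed.
#' @return a [spot_matrix] of thinned counts.
#' @export
downsample_counts <- function(m, fraction, seed = 1) {
  stopifnot(inherits(m, "spot_matrix"))
  if (m$layer != "counts") stop_arg("downsample_counts expects layer 'counts'")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop_arg("fraction must be in (0, 1]")
  if (fraction == 1) return(m)
  v <- as_dense(m$values)
  if (any(v != floor(v))) stop_arg("counts must be integers for downsampling")
  with_seed(seed, {
    nz <- which(v > 0)
    out <- v
    out[nz] <- stats::rbinom(length(nz), as.integer(v[nz]), fraction)
    spot_matrix(out, m$spot_ids, m$gene_ids, layer = "counts")
  })
}

#' Generate a synthetic region-structured tissue slide
#'
#' Spots sit on a regular `n_rows x n_cols` grid with the given pixel spacing
#' inside an image with `image_margin_px` of empty margin. Regions are grown
#' from random seed cells into contiguous tiles covering the grid
#' (multi-source randomised flood fill), each spot belongs to exactly one
#' region, and the image is tinted per region (distinct hue and luminance)
#' with mild Gaussian noise so that patches are region-discriminative under a
#' grayscale-based encoder.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param spacing_px centre-to-centre spot spacing in pixels.
#' @param n_regions number of contiguous regions (>= 1).
#' @param image_margin_px margin between the outermost spot centres and the
#'   image border.
#' @param noise_sd pixel noise standard deviation.
#' @param seed integer seed.
#' @return object of class `synthetic_slide`: `coords` ([spot_coords]),
#'   `image` (H x W x 3 array in `[0,1]`), `regions` ([pathology_labels]),
#'   `region_ids` (integer per spot), `region_geometry` (per-region
#'   data.frames of grid-cell rectangles in pixel units; their union is the
#'   region's rectilinear polygon).
#' @export
generate_synthetic_slide <- function(n_rows, n_cols, spacing_px = 60,
                                     n_regions = 4, image_margin_px = 80,
                                     noise_sd = 0.02, seed = 1) {
  if (n_regions < 1) stop_arg("n_regions must be >= 1")
  n_spots <- n_rows * n_cols
  if (n_regions > n_spots) stop_arg("more regions than grid cells")
  width <- 2 * image_margin_px + (n_cols - 1) * spacing_px
  height <- 2 * image_margin_px + (n_rows - 1) * spacing_px
  if (width < 1 || height < 1) stop_arg("grid larger than image")
  with_seed(seed, {
    # spot centres, row-major
    gr <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
    cx <- image_margin_px + (gr$col - 1) * spacing_px
    cy <- image_margin_px + (gr$row - 1) * spacing_px
    ids <- paste0("spot", seq_len(n_spots))
    coords <- spot_coords(ids, cx, cy)
    region <- grow_regions(n_rows, n_cols, n_regions)
    # region colours: distinct hue AND luminance
    vals <- if (n_regions == 1) 0.65 else
      0.30 + 0.60 * (seq_len(n_regions) - 1) / (n_regions - 1)
    cols <- t(sapply(seq_len(n_regions), function(r)
      grDevices::col2rgb(grDevices::hsv((r - 1) / n_regions, 0.45, vals[r])) / 255))
    # pixel -> nearest grid cell -> region tint
    px_col <- pmin(pmax(round((seq_len(width) - image_margin_px) / spacing_px) + 1, 1), n_cols)
    px_row <- pmin(pmax(round((seq_len(height) - image_margin_px) / spacing_px) + 1, 1), n_rows)
    cell_region <- matrix(region, n_rows, n_cols, byrow = TRUE)  # region is row-major
    reg_img <- cell_region[px_row, px_col]                       # height x width
    image <- array(0, c(height, width, 3))
    for (ch in 1:3)
      image[, , ch] <- matrix(cols[reg_img, ch], height, width) +
        stats::rnorm(height * width, 0, noise_sd)
    image <- pmin(pmax(image, 0), 1)
    # rectilinear geometry: one rectangle of pixels per grid cell
    half <- spacing_px / 2
    rects <- data.frame(
      region = region,
      xmin = cx - half, xmax = cx + half,
      ymin = cy - half, ymax = cy + half)
    region_geometry <- split(rects[, -1], rects$region)
    labels <- pathology_labels(paste0("region", region),
                               paste0("region", seq_len(n_regions)), ids)
    structure(list(coords = coords, image = image, regions = labels,
                   region_ids = region, region_geometry = region_geometry,
                   params = list(n_rows = n_rows, n_cols = n_cols,
                                 spacing_px = spacing_px, n_regions = n_regions,
                                 image_margin_px = image_margin_px, seed = seed)),
              class = "synthetic_slide")
  })
}

# multi-source randomised flood fill over the grid; returns a region id per
# spot in row-major order, every region contiguous and non-empty
grow_regions <- function(n_rows, n_cols, n_regions) {
  n <- n_rows * n_cols
  idx <- function(r, c) (r - 1L) * n_cols + c
  region <- integer(n)
  seeds <- sample.int(n, n_regions)
  frontier <- list()
  for (k in seq_len(n_regions)) {
    region[seeds[k]] <- k
    frontier[[k]] <- seeds[k]
  }
  n_assigned <- n_regions
  while (n_assigned < n) {
    for (k in sample(n_regions)) {
      if (length(frontier[[k]]) == 0) next
      # expand one random frontier cell into one random unassigned neighbour
      repeat {
        if (length(frontier[[k]]) == 0) break
        pick <- sample.int(length(frontier[[k]]), 1L)
        cell <- frontier[[k]][pick]
        r <- (cell - 1L) %/% n_cols + 1L
        c <- (cell - 1L) %% n_cols + 1L
        nb <- c(if (r > 1) idx(r - 1L, c), if (r < n_rows) idx(r + 1L, c),
                if (c > 1) idx(r, c - 1L), if (c < n_cols) idx(r, c + 1L))
        nb <- nb[region[nb] == 0L]
        if (length(nb) == 0) {
          frontier[[k]] <- frontier[[k]][-pick]
          next
        }
        new <- nb[sample.int(length(nb), 1L)]
        region[new] <- k
        frontier[[k]] <- c(frontier[[k]], new)
        n_assigned <- n_assigned + 1L
        break
      }
    }
  }
  region
}

#' Simulate region-biased spot expression on a synthetic slide
#'
#' Builds the "real" arm of a fully synthetic benchmark: each slide spot is a
#' pseudo-spot whose cell-type sampling probabilities are biased towards the
#' dominant type of its region (type `r` dominates region `r`, recycled when
#' there are more regions than types). Cells are sampled i.i.d. with
#' probability `dominant_weight` concentrated on the dominant type and the
#' remainder spread uniformly, so the planted truth has one dominant type per
#' region. Counts are aggregated and binomially thinned exactly as in
#' [simulate_pseudospots()].
#'
#' @param ref a `synthetic_scrna` reference.
#' @param slide a `synthetic_slide`.
#' @param dominant_weight extra probability mass on the region's dominant
#'   type (default 0.7).
#' @param mu_cells,sigma_cells per-spot cell count distribution.
#' @param downsample_fraction binomial thinning fraction.
#' @param seed integer seed.
#' @return an [st_dataset] with expression (counts), coords, image, planted
#'   `proportions` and region `pathology` labels.
#' @export
simulate_slide_spots <- function(ref, slide, dominant_weight = 0.7,
                                 mu_cells = 10, sigma_cells = 3,
                                 downsample_fraction = 0.5, seed = 1) {
  stopifnot(inherits(slide, "synthetic_slide"))
  if (dominant_weight < 0 || dominant_weight >= 1)
    stop_arg("dominant_weight must be in [0, 1)")
  counts <- ref$counts
  types <- as.integer(ref$cell_types)
  P1 <- max(types)
  type_cells <- split(seq_along(types), types)
  n <- nrow(slide$coords)
  dom <- ((slide$region_ids - 1L) %% P1) + 1L
  with_seed(seed, {
    Nc <- draw_trunc_normal(n, mu_cells, sigma_cells, 1)
    expr <- matrix(0, n, ncol(counts))
    prop <- matrix(0, n, P1)
    for (i in seq_len(n)) {
      p <- rep((1 - dominant_weight) / P1, P1)
      p[dom[i]] <- p[dom[i]] + dominant_weight
      drawn_types <- sample.int(P1, Nc[i], replace = TRUE, prob = p)
      idx <- vapply(drawn_types, function(t) {
        cells <- type_cells[[t]]
        cells[sample.int(length(cells), 1L)]
      }, integer(1))
      expr[i, ] <- colSums(counts[idx, , drop = FALSE])
      prop[i, ] <- tabulate(types[idx], nbins = P1) / Nc[i]
    }
    ids <- slide$coords$spot_id
    pre <- spot_matrix(expr, ids, colnames(counts), layer = "counts")
    out <- if (downsample_fraction < 1) {
      downsample_counts(pre, downsample_fraction,
                        seed = derive_seed(seed, "slide-downsample"))
    } else pre
    st_dataset(expression = out, coords = slide$coords, image = slide$image,
               proportions = proportion_matrix(prop, paste0("type", seq_len(P1)), ids),
               pathology = slide$regions)
  })
}
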