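#' Read and write two-color localization tables
#'
#' The canonical CSV layout is ThunderSTORM-compatible:
#' `frame,x_nm,y_nm,channel,uncertainty_nm[,true_cluster]`, coordinates in
#' nm. The common bracketed dialects `x [nm]` and `x [um]` are accepted (the
#' um variant is converted to nm); unknown columns are preserved. Missing
#' required columns are listed in the error.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `localization_table`.
#' @export
read_localizations <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(d)
  for (ax in c("x", "y")) {
    um_col <- paste0(ax, " [um]")
    nm_col <- paste0(ax, " [nm]")
    if (um_col %in% nm) {
      d[[paste0(ax, "_nm")]] <- d[[um_col]] * 1000
      d[[um_col]] <- NULL
    } else if (nm_col %in% nm) {
      d[[paste0(ax, "_nm")]] <- d[[nm_col]]
      d[[nm_col]] <- NULL
    }
  }
  if ("uncertainty [nm]" %in% names(d)) {
    d$uncertainty_nm <- d[["uncertainty [nm]"]]
    d[["uncertainty [nm]"]] <- NULL
  }
  required <- c("frame", "x_nm", "y_nm", "channel", "uncertainty_nm")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0)
    stop("localization CSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(d) > 0 && !all(is.finite(d$x_nm) & is.finite(d$y_nm)))
    stop("coordinates must be finite")
  class(d) <- c("localization_table", "data.frame")
  d
}

#' @rdname read_localizations
#' @param table a localization table to write.
#' @export
write_localizations <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Cross-channel nearest-neighbor distances
#'
#' For each localization of the query channel, the Euclidean distance to the
#' nearest localization of the reference channel (excluding the point itself
#' when the two channels are the same). The search is grid-index accelerated
#' but exact: results are identical to an exhaustive pairwise scan. The
#' measure is directional: query->reference generally differs from
#' reference->query.
#'
#' @param table a localization table with `x_nm, y_nm, channel`.
#' @param query_channel,reference_channel channel labels (e.g. `"red"` =
#'   GluN2B/AF647, `"green"` = BK/AF488).
#' @return A list of class `nnd_result`: `distances` (nm, one per query
#'   localization, in table row order), `direction`, `n_query`,
#'   `n_reference`.
#' @export
cross_channel_nnd <- function(table, query_channel, reference_channel) {
  q <- table[table$channel == query_channel, , drop = FALSE]
  r <- table[table$channel == reference_channel, , drop = FALSE]
  if (nrow(q) == 0) stop("query channel '", query_channel, "' is empty")
  if (nrow(r) == 0) stop("reference channel '", reference_channel,
                         "' is empty")
  same <- identical(query_channel, reference_channel)
  if (same && nrow(r) < 2)
    stop("within-channel NND needs >= 2 localizations")
  d <- cpp_nnd(q$x_nm, q$y_nm, r$x_nm, r$y_nm, same)
  structure(list(distances = as.numeric(d),
                 direction = paste(query_channel, "->", reference_channel),
                 n_query = nrow(q), n_reference = nrow(r)),
            class = "nnd_result")
}

#' Histogram, ECDF and summary of an NND distribution
#'
#' Fixed-width bins, left-closed right-open (`[a, b)`); the ECDF is the
#' right-continuous empirical CDF. The summary reports the modal bin and the
#' fraction of distances within the nanodomain range (0-50 nm by default),
#' which equals `ecdf(50)` by construction.
#'
#' @param result an `nnd_result` or a numeric vector of distances (nm).
#' @param bin_width bin width in nm (> 0), default 5 nm.
#' @param range length-2 histogram range; default 0 to the max distance.
#' @param nanodomain_nm upper edge of the "within nanodomain" fraction.
#' @return A list with `breaks`, `counts`, `ecdf` (function), `modal_bin`
#'   (length-2), `fraction_within` and `n`.
#' @export
nnd_distribution <- function(result, bin_width = 5, range = NULL,
                             nanodomain_nm = 50) {
  d <- if (inherits(result, "nnd_result")) result$distances else result
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("no distances")
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (is.null(range)) range <- c(0, max(d))
  breaks <- seq(range[1], range[2] + bin_width, by = bin_width)
  # left-closed, right-open bins
  bin <- findInterval(d, breaks, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  e <- ecdf_step(d)
  modal <- which.max(counts)
  list(breaks = breaks, counts = counts, ecdf = e,
       modal_bin = c(breaks[modal], breaks[modal + 1]),
       fraction_within = e(nanodomain_nm), n = length(d))
}

make_cluster <- function(id, members, table) {
  coords <- cbind(table$x_nm[members], table$y_nm[members])
  ch <- table$channel[members]
  list(id = id, members = members,
       n_red = sum(ch == "red"), n_green = sum(ch == "green"),
       centroid = c(mean(coords[, 1]), mean(coords[, 2])),
       coords = coords)
}

#' Density-based clustering of the merged two-color point set
#'
#' DBSCAN on the union of both channels (channel-blind density,
#' channel-aware classification downstream): a core point has at least
#' `min_count` points (itself included) within `radius`; clusters are the
#' connected components of core points under radius adjacency; border points
#' are attached to the cluster of their nearest core point (ties to the
#' lowest cluster id); everything else is noise. Cluster ids are ordered by
#' lowest member row index, making the result independent of input row
#' order. The defaults mirror the study's density filtering: radius from
#' \{20, 40, 60\} nm with a count of 10 molecules.
#'
#' @param table a localization table.
#' @param radius neighborhood radius in nm (> 0).
#' @param min_count minimum molecules per neighborhood (>= 2), self included.
#' @return A list of class `smlm_clusters`; each element has `id`, `members`
#'   (row indices), `n_red`, `n_green`, `centroid`, `coords`. The full label
#'   vector (0 = noise) is in the `labels` attribute.
#' @export
density_cluster <- function(table, radius = 40, min_count = 10) {
  if (radius <= 0) stop("radius must be > 0")
  if (min_count < 2) stop("min_count must be >= 2")
  if (nrow(table) == 0) {
    out <- list(); class(out) <- "smlm_clusters"
    attr(out, "labels") <- integer(0)
    return(out)
  }
  labels <- cpp_dbscan(table$x_nm, table$y_nm, radius, as.integer(min_count))
  ids <- sort(unique(labels[labels > 0]))
  out <- lapply(ids, function(id)
    make_cluster(id, which(labels == id), table))
  class(out) <- "smlm_clusters"
  attr(out, "labels") <- labels
  attr(out, "radius") <- radius
  attr(out, "min_count") <- min_count
  out
}

#' Classify clusters as homo-red, homo-green or hetero
#'
#' A cluster is a heterocluster when it contains at least `min_minor`
#' molecules of each channel (default 1: any mixed cluster is hetero);
#' otherwise it is a homocluster of the channel it contains. The
#' distribution reports percentages over all clusters, summing to 100.
#'
#' @param clusters an `smlm_clusters` list.
#' @param min_minor minimum molecules of the minority channel required to
#'   call a heterocluster.
#' @return A list with `clusters` (each gains a `composition` field) and
#'   `distribution` (`data.frame`: `composition, n, percentage`).
#' @export
classify_clusters <- function(clusters, min_minor = 1) {
  comp <- vapply(clusters, function(cl) {
    if (cl$n_red >= min_minor && cl$n_green >= min_minor) "hetero"
    else if (cl$n_red >= cl$n_green) "homo_red" else "homo_green"
  }, character(1))
  for (i in seq_along(clusters)) clusters[[i]]$composition <- comp[i]
  lev <- c("homo_red", "homo_green", "hetero")
  n <- as.integer(table(factor(comp, levels = lev)))
  total <- length(comp)
  distribution <- data.frame(
    composition = lev, n = n,
    percentage = if (total > 0) 100 * n / total else rep(NA_real_, 3))
  list(clusters = clusters, distribution = distribution)
}

shoelace_area <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

hull_area <- function(coords) {
  pts <- unique(coords)
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  if (length(h) < 3) return(0)
  shoelace_area(pts[h, , drop = FALSE])
}

#' Convex-hull areas of clusters, per composition class
#'
#' Cluster size is the area of the 2D convex hull of its member
#' localizations (nm^2). Degenerate hulls (fewer than 3 distinct,
#' non-collinear points) get area 0, are flagged, and are excluded from the
#' per-class cumulative probability curves.
#'
#' @param clusters classified clusters (the `clusters` element of
#'   [classify_clusters()], or an `smlm_clusters` list, in which case
#'   classification is applied first).
#' @return A list with `table` (`data.frame`: `cluster_id, composition,
#'   n_red, n_green, area_nm2, degenerate, centroid_x, centroid_y`) and
#'   `ecdf` (named list of per-class ECDFs over non-degenerate areas).
#' @export
cluster_areas <- function(clusters) {
  if (inherits(clusters, "smlm_clusters"))
    clusters <- classify_clusters(clusters)$clusters
  if (length(clusters) == 0) {
    return(list(table = data.frame(cluster_id = integer(0),
                                   composition = character(0),
                                   n_red = integer(0), n_green = integer(0),
                                   area_nm2 = numeric(0),
                                   degenerate = logical(0),
                                   centroid_x = numeric(0),
                                   centroid_y = numeric(0)),
                ecdf = list()))
  }
  areas <- vapply(clusters, function(cl) hull_area(cl$coords), numeric(1))
  tab <- data.frame(
    cluster_id = vapply(clusters, `[[`, numeric(1), "id"),
    composition = vapply(clusters, `[[`, character(1), "composition"),
    n_red = vapply(clusters, `[[`, numeric(1), "n_red"),
    n_green = vapply(clusters, `[[`, numeric(1), "n_green"),
    area_nm2 = areas,
    degenerate = areas == 0,
    centroid_x = vapply(clusters, function(cl) cl$centroid[1], numeric(1)),
    centroid_y = vapply(clusters, function(cl) cl$centroid[2], numeric(1)),
    stringsAsFactors = FALSE)
  ecdfs <- lapply(split(tab, tab$composition), function(g) {
    a <- g$area_nm2[!g$degenerate]
    if (length(a) > 0) ecdf_step(a) else NULL
  })
  list(table = tab, ecdf = Filter(Negate(is.null), ecdfs))
}

#' Run clustering, classification and area analysis over a radius sweep
#'
#' Repeats [density_cluster()] + [classify_clusters()] + [cluster_areas()]
#' for each neighborhood radius (default the study's 20/40/60 nm panel at a
#' count of 10 molecules) and assembles a tidy per-radius table.
#'
#' @param table a localization table.
#' @param radii positive radii in nm, sorted increasing.
#' @param min_count minimum molecules per neighborhood.
#' @return A list of class `radius_sweep` with one entry per radius
#'   (`radius, clusters, distribution, areas, n_clustered`) and a combined
#'   `summary` data.frame.
#' @export
radius_sweep <- function(table, radii = c(20, 40, 60), min_count = 10) {
  if (any(radii <= 0)) stop("radii must be positive")
  if (is.unsorted(radii)) stop("radii must be sorted increasing")
  per <- lapply(radii, function(r) {
    cl <- density_cluster(table, r, min_count)
    cls <- classify_clusters(cl)
    ar <- cluster_areas(cls$clusters)
    labels <- attr(cl, "labels")
    list(radius = r, clusters = cls$clusters,
         distribution = cls$distribution, areas = ar,
         clustered_idx = which(labels > 0),
         n_clustered = sum(labels > 0))
  })
  names(per) <- paste0("r", radii)
  summary <- do.call(rbind, lapply(per, function(p) {
    cbind(radius_nm = p$radius, p$distribution,
          n_clustered_points = p$n_clustered)
  }))
  rownames(summary) <- NULL
  structure(list(results = per, summary = summary, radii = radii,
                 min_count = min_count),
            class = "radius_sweep")
}
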