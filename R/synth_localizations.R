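#' Configuration for the two-color localization simulator
#'
#' Describes a synthetic two-color SMLM scene: a rectangular field holding
#' red-only clusters, green-only clusters and two-color ("hetero") clusters,
#' each cluster a 2D Gaussian spread of molecules, observed through
#' channel-specific Gaussian localization error, over an optional uniform
#' (complete spatial randomness) background per channel.
#'
#' Default localization precisions are 13 nm (red, Alexa Fluor 647-like) and
#' 16 nm (green, Alexa Fluor 488-like), typical lateral accuracies for
#' dual-color dSTORM of membrane proteins.
#'
#' @param field_size numeric length-2, field width and height in nm.
#' @param n_homo_red,n_homo_green,n_hetero number of clusters of each class.
#' @param molecules_per_cluster either a single integer (fixed count per
#'   cluster) or a list `list(lambda =, floor =)` for Poisson counts with a
#'   hard floor.
#' @param cluster_sd spatial SD (nm) of true molecule positions around the
#'   cluster center.
#' @param hetero_fraction_red fraction in (0, 1) of molecules in a
#'   heterocluster assigned to the red channel.
#' @param loc_precision_red,loc_precision_green per-channel Gaussian
#'   localization error SD in nm.
#' @param background_density uniform background localizations per um^2 per
#'   channel (complete spatial randomness).
#' @param seed integer seed; the same seed gives bit-identical scenes.
#' @return A validated list of class `point_sim_config`.
#' @export
point_sim_config <- function(field_size = c(4000, 4000),
                             n_homo_red = 0, n_homo_green = 0, n_hetero = 0,
                             molecules_per_cluster = 20,
                             cluster_sd = 20,
                             hetero_fraction_red = 0.5,
                             loc_precision_red = 13,
                             loc_precision_green = 16,
                             background_density = 0,
                             seed = 1L) {
  stopifnot(length(field_size) == 2, all(field_size > 0))
  counts <- c(n_homo_red, n_homo_green, n_hetero)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cluster counts must be non-negative integers")
  if (hetero_fraction_red < 0 || hetero_fraction_red > 1)
    stop("hetero_fraction_red must be in [0, 1]")
  if (n_hetero > 0 && (hetero_fraction_red <= 0 || hetero_fraction_red >= 1))
    stop("heteroclusters require hetero_fraction_red strictly inside (0, 1)")
  if (loc_precision_red < 0 || loc_precision_green < 0)
    stop("localization precisions must be >= 0")
  if (cluster_sd < 0) stop("cluster_sd must be >= 0")
  if (background_density < 0) stop("background_density must be >= 0")
  if (is.list(molecules_per_cluster)) {
    stopifnot(!is.null(molecules_per_cluster$lambda),
              molecules_per_cluster$lambda > 0)
    molecules_per_cluster$floor <- molecules_per_cluster$floor %||% 1
  } else {
    stopifnot(length(molecules_per_cluster) == 1, molecules_per_cluster >= 1)
  }
  structure(list(field_size = as.numeric(field_size),
                 n_homo_red = as.integer(n_homo_red),
                 n_homo_green = as.integer(n_homo_green),
                 n_hetero = as.integer(n_hetero),
                 molecules_per_cluster = molecules_per_cluster,
                 cluster_sd = as.numeric(cluster_sd),
                 hetero_fraction_red = as.numeric(hetero_fraction_red),
                 loc_precision_red = as.numeric(loc_precision_red),
                 loc_precision_green = as.numeric(loc_precision_green),
                 background_density = as.numeric(background_density),
                 seed = as.integer(seed)),
            class = "point_sim_config")
}

draw_cluster_size <- function(spec) {
  if (is.list(spec)) max(spec$floor, stats::rpois(1, spec$lambda))
  else as.integer(spec)
}

#' Simulate a two-color localization table with known ground truth
#'
#' Cluster centers are drawn uniformly with a margin of `4 * cluster_sd` kept
#' inside the field (avoids edge truncation biasing area statistics); if the
#' field is too small to honor the margin, placement falls back to the full
#' field with a warning that cluster overlap is likely. Heterocluster channel
#' assignment is per-molecule Bernoulli(`hetero_fraction_red`), redrawn if a
#' draw comes out single-channel so the labeled class is always realized.
#'
#' @param cfg a [point_sim_config()].
#' @return A `data.frame` (class `localization_table`) with columns
#'   `frame, x_nm, y_nm, channel, uncertainty_nm, true_cluster` (background
#'   rows have `true_cluster = -1`) and attributes `truth` (per-cluster class,
#'   size and center) and `field_size`. Observed positions are true positions
#'   plus per-channel Gaussian error.
#' @export
simulate_localizations <- function(cfg) {
  stopifnot(inherits(cfg, "point_sim_config"))
  local_seed(cfg$seed, {
    W <- cfg$field_size[1]; H <- cfg$field_size[2]
    n_clusters <- cfg$n_homo_red + cfg$n_homo_green + cfg$n_hetero
    margin <- 4 * cfg$cluster_sd
    if (n_clusters > 0 && (2 * margin >= W || 2 * margin >= H)) {
      warning("field too small for a 4*cluster_sd margin; ",
              "clusters may be truncated/overlapping at the edges")
      margin <- 0
    }
    # crude crowding check: expected cluster footprints vs available area
    if (n_clusters > 0 &&
        n_clusters * (8 * cfg$cluster_sd)^2 > 0.5 * W * H) {
      warning("field too small to hold ", n_clusters,
              " clusters without likely overlap")
    }

    classes <- rep(c("homo_red", "homo_green", "hetero"),
                   times = c(cfg$n_homo_red, cfg$n_homo_green, cfg$n_hetero))
    cx <- stats::runif(n_clusters, margin, W - margin)
    cy <- stats::runif(n_clusters, margin, H - margin)
    m <- vapply(seq_len(n_clusters), function(k)
      as.integer(draw_cluster_size(cfg$molecules_per_cluster)), integer(1))
    M <- sum(m)
    ki <- rep(seq_len(n_clusters), times = m)
    tx <- cx[ki] + stats::rnorm(M, sd = cfg$cluster_sd)
    ty <- cy[ki] + stats::rnorm(M, sd = cfg$cluster_sd)
    channel <- character(M)
    channel[classes[ki] == "homo_red"] <- "red"
    channel[classes[ki] == "homo_green"] <- "green"
    het <- which(classes[ki] == "hetero")
    if (length(het) > 0) {
      channel[het] <- ifelse(stats::runif(length(het)) <
                               cfg$hetero_fraction_red, "red", "green")
      # redraw heteroclusters that came out single-channel: the labeled
      # class must be realized
      for (k in which(classes == "hetero")) {
        idx <- which(ki == k)
        for (try in 1:1000) {
          if (length(unique(channel[idx])) == 2) break
          channel[idx] <- ifelse(stats::runif(length(idx)) <
                                   cfg$hetero_fraction_red, "red", "green")
        }
        if (length(unique(channel[idx])) < 2)
          channel[idx[1]] <- setdiff(c("red", "green"), channel[idx[1]])
      }
    }
    prec <- ifelse(channel == "red",
                   cfg$loc_precision_red, cfg$loc_precision_green)
    ox <- tx + stats::rnorm(M, sd = prec)
    oy <- ty + stats::rnorm(M, sd = prec)

    # CSR background, independent per channel
    area_um2 <- W * H / 1e6
    bg_x <- numeric(0); bg_y <- numeric(0); bg_ch <- character(0)
    for (ch in c("red", "green")) {
      nb <- stats::rpois(1, cfg$background_density * area_um2)
      if (nb > 0) {
        bg_x <- c(bg_x, stats::runif(nb, 0, W))
        bg_y <- c(bg_y, stats::runif(nb, 0, H))
        bg_ch <- c(bg_ch, rep(ch, nb))
      }
    }
    bg_prec <- ifelse(bg_ch == "red",
                      cfg$loc_precision_red, cfg$loc_precision_green)

    all_x <- c(ox, bg_x); all_y <- c(oy, bg_y)
    tab <- data.frame(
      frame = seq_along(all_x),
      x_nm = all_x, y_nm = all_y,
      channel = c(channel, bg_ch),
      uncertainty_nm = c(prec, bg_prec),
      true_cluster = c(ki, rep(-1L, length(bg_x))),
      true_x_nm = c(tx, bg_x), true_y_nm = c(ty, bg_y),
      stringsAsFactors = FALSE)
    truth <- data.frame(cluster = seq_len(n_clusters), class = classes,
                        n_molecules = m, center_x_nm = cx, center_y_nm = cy,
                        stringsAsFactors = FALSE)
    structure(tab,
              truth = truth,
              field_size = cfg$field_size,
              class = c("localization_table", "data.frame"))
  })
}

#' Build cluster objects from ground-truth labels
#'
#' Groups a simulated localization table by its `true_cluster` column,
#' yielding the same cluster structure as [density_cluster()] but defined by
#' the generator's ground truth (background rows are dropped). Useful for
#' computing ground-truth composition and area distributions.
#'
#' @param table a `localization_table` with a `true_cluster` column.
#' @return A list of clusters as in [density_cluster()].
#' @export
clusters_from_truth <- function(table) {
  stopifnot("true_cluster" %in% names(table))
  pos <- which(table$true_cluster > 0)
  groups <- split(pos, table$true_cluster[pos])
  groups <- groups[order(as.integer(names(groups)))]
  out <- lapply(seq_along(groups), function(i)
    make_cluster(i, groups[[i]], table))
  class(out) <- "smlm_clusters"
  out
}
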