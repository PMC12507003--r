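# Daily behavior vectors and phenotype clustering: 23 named parameters per
# individual-day, Box-Cox + z normalization, UMAP embedding, density map and
# watershed segmentation.

#' Names of the 23 daily behavior parameters
#'
#' Sum/N/Mean for each of Rest, Nest, Toilet, Garbage, Other, plus
#' Sum_relative/N_relative (normalized by total active duration) for the
#' four non-Rest categories.
#'
#' @return Character vector of length 23.
#' @export
behavior_parameter_names <- function() {
  cats <- c("Rest", "Nest", "Toilet", "Garbage", "Other")
  c(as.vector(outer(c("Sum", "N", "Mean"), cats, paste, sep = "_")),
    paste0("Sumrel_", cats[-1]), paste0("Nrel_", cats[-1]))
}

#' Extract the daily behavior vector for one individual-day
#'
#' Computes total duration (Sum), event count (N) and mean duration (Mean)
#' for each of the five stay categories over one day, plus Sum and N
#' relative to the total active (non-Rest) duration.  An event is attributed
#' to the day by clipping it to the day window, so stays spanning midnight
#' contribute their within-day part.  Ticks excluded as disturbances should
#' already have been removed from the events.
#'
#' @param events Classified stay events of one individual (or a full table;
#'   filtered by \code{individual}).
#' @param individual Individual id.
#' @param day 1-based day index.
#' @param day_s Day length in seconds (default 86400).
#' @return Named numeric vector of the 23 parameters.
#' @export
extract_daily_parameters <- function(events, individual, day,
                                     day_s = 86400) {
  ev <- events[events$individual == individual &
                 !is.na(events$category), , drop = FALSE]
  daily_params_one(ev$start_s, ev$end_s, ev$category, day, day_s)
}

daily_params_one <- function(start_s, end_s, category, day, day_s) {
  w0 <- (day - 1) * day_s
  w1 <- day * day_s
  s <- pmax(start_s, w0)
  e <- pmin(end_s, w1)
  keep <- e > s
  dur <- (e - s)[keep]
  cat_f <- factor(category[keep],
                  levels = c("Rest", "Nest", "Toilet", "Garbage", "Other"))
  sum_v <- as.numeric(tapply(dur, cat_f, sum, default = 0))
  n_v <- as.numeric(table(cat_f))
  mean_v <- ifelse(n_v > 0, sum_v / pmax(n_v, 1), 0)
  active <- sum(sum_v[-1])
  rel <- function(x) if (active > 0) x / active else rep(0, length(x))
  out <- c(as.vector(rbind(sum_v, n_v, mean_v)), rel(sum_v[-1]),
           rel(n_v[-1]))
  names(out) <- behavior_parameter_names()
  attr(out, "zero_active") <- active <= 0
  out
}

#' Build the full individual-day parameter matrix
#'
#' @param events Classified stay events for a colony.
#' @param days Number of days covered.
#' @param individuals Individual ids (default: those present in the events).
#' @param day_s Day length in seconds.
#' @return Data frame with columns \code{individual}, \code{day} and the 23
#'   parameters.
#' @export
daily_parameter_table <- function(events, days,
                                  individuals = sort(unique(
                                    events$individual)),
                                  day_s = 86400) {
  events <- events[!is.na(events$category), , drop = FALSE]
  by_ind <- split(events, factor(events$individual, levels = individuals))
  rows <- expand.grid(day = seq_len(days), individual = individuals,
                      stringsAsFactors = FALSE)[, 2:1]
  vals <- t(mapply(function(id, d) {
    ev <- by_ind[[id]]
    daily_params_one(ev$start_s, ev$end_s, ev$category, d, day_s)
  }, rows$individual, rows$day))
  rownames(vals) <- NULL
  cbind(rows, as.data.frame(vals))
}

# Univariate Box-Cox / Yeo-Johnson MLE via car::powerTransform, with a
# graceful fallback for degenerate columns.
power_lambda <- function(x, family = "bcPower") {
  if (length(unique(x)) < 2) return(1)
  lam <- tryCatch(
    as.numeric(car::powerTransform(x, family = family)$lambda),
    error = function(e) 1)
  if (!is.finite(lam)) 1 else lam
}

#' Normalize the behavior parameter matrix
#'
#' Per colony, each parameter is shifted by +1 and Box-Cox transformed with
#' its maximum-likelihood lambda; the result is then z-transformed within
#' each colony-day.  Constant columns within a colony-day z-transform to
#' zeros with a warning.
#'
#' @param mat Numeric matrix (samples x parameters).
#' @param colony Colony label per sample (scalar or vector).
#' @param day Day label per sample.
#' @return Normalized matrix of the same shape; per-parameter lambdas are
#'   attached as attribute \code{lambda} (one row per colony).
#' @export
normalize_parameters <- function(mat, colony, day) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  colony <- rep_len(colony, n)
  day <- rep_len(day, n)
  out <- mat
  lambdas <- list()
  for (co in unique(colony)) {
    rows <- which(colony == co)
    lam <- numeric(ncol(mat))
    for (p in seq_len(ncol(mat))) {
      x <- mat[rows, p] + 1
      # behavioral parameters are non-negative; a column that is not is
      # shifted to a minimum of 1 so the Box-Cox transform stays defined
      if (min(x) <= 0) x <- x - min(x) + 1
      lam[p] <- power_lambda(x, "bcPower")
      out[rows, p] <- car::bcPower(x, lam[p])
    }
    lambdas[[co]] <- lam
  }
  warned <- FALSE
  for (g in split(seq_len(n), paste(colony, day))) {
    for (p in seq_len(ncol(mat))) {
      x <- out[g, p]
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) {
        out[g, p] <- 0
        warned <- TRUE
      } else {
        out[g, p] <- (x - mean(x)) / s
      }
    }
  }
  if (warned)
    warning("constant parameter column(s) within a colony-day; ",
            "z-transform returned zeros", call. = FALSE)
  attr(out, "lambda") <- do.call(rbind, lambdas)
  out
}

#' Embed samples and segment the embedding density into clusters
#'
#' UMAP embedding to two coordinates, rasterized to a density map, smoothed
#' with an isotropic Gaussian blur, and partitioned by watershed
#' segmentation with depth-based minima suppression (\code{hmin}, expressed
#' as a fraction of the density maximum).  Each sample is labeled by the
#' watershed compartment containing its embedding point; clusters are
#' renumbered by descending size.
#'
#' @param mat Normalized parameter matrix (samples x parameters), or a
#'   two-column matrix used directly as the embedding when
#'   \code{embedding = NULL} is overridden.
#' @param n_neighbors UMAP neighborhood size (default 5).
#' @param min_dist UMAP minimum distance (default 0.1).
#' @param seed Integer seed pinning the embedding.
#' @param raster Raster side length in pixels (default 512).
#' @param blur_sigma Gaussian blur sigma in pixels; the default
#'   (\code{NULL}) uses \code{raster / sqrt(n)} so that the smoothing scale
#'   tracks the typical inter-point spacing (about 9 px for 3000 samples on
#'   a 512-px raster, about 30 px for 300 samples).
#' @param hmin Watershed minima-suppression depth as a fraction of the
#'   density maximum (default 0.05).
#' @param embedding Optional precomputed two-column embedding; bypasses
#'   UMAP.
#' @return An object of class \code{cluster_map}: list with
#'   \code{embedding} (samples x 2), \code{density} (raster matrix),
#'   \code{labels} (integer cluster per sample), \code{K}.
#' @export
embed_and_segment <- function(mat, n_neighbors = 5, min_dist = 0.1,
                              seed = 20, raster = 512, blur_sigma = NULL,
                              hmin = 0.05, embedding = NULL) {
  if (is.null(embedding)) {
    stopifnot(nrow(mat) >= 2)
    set.seed(seed)
    embedding <- uwot::umap(as.matrix(mat),
                            n_neighbors = min(n_neighbors,
                                              nrow(mat) - 1L),
                            min_dist = min_dist, n_threads = 1,
                            n_sgd_threads = 1, batch = TRUE)
  }
  embedding <- as.matrix(embedding)
  stopifnot(ncol(embedding) == 2)
  n <- nrow(embedding)
  if (is.null(blur_sigma)) blur_sigma <- raster / sqrt(n)
  # the Gaussian brush must fit inside the raster
  blur_sigma <- min(blur_sigma, floor((raster - 1) / 8))

  rngx <- range(embedding[, 1]); rngy <- range(embedding[, 2])
  if (diff(rngx) == 0 && diff(rngy) == 0) {
    warning("degenerate embedding (all points identical): single cluster",
            call. = FALSE)
    return(structure(list(embedding = embedding, density = NULL,
                          labels = rep(1L, n), K = 1L),
                     class = "cluster_map"))
  }
  pad <- 0.05
  padx <- max(diff(rngx), 1e-9) * pad; pady <- max(diff(rngy), 1e-9) * pad
  x0 <- rngx[1] - padx; x1 <- rngx[2] + padx
  y0 <- rngy[1] - pady; y1 <- rngy[2] + pady
  px <- pmin(pmax(ceiling((embedding[, 1] - x0) / (x1 - x0) * raster), 1L),
             raster)
  py <- pmin(pmax(ceiling((embedding[, 2] - y0) / (y1 - y0) * raster), 1L),
             raster)
  dens <- matrix(0, raster, raster)
  for (i in seq_len(n)) dens[px[i], py[i]] <- dens[px[i], py[i]] + 1
  dens <- EBImage::gblur(dens, sigma = blur_sigma)
  dens[dens < 0] <- 0

  labels_img <- EBImage::watershed(EBImage::as.Image(dens),
                                   tolerance = hmin * max(dens), ext = 1)
  lab <- EBImage::imageData(labels_img)
  labels <- lab[cbind(px, py)]
  # samples on unlabeled pixels (possible at blur fringes): nearest labeled
  if (any(labels == 0)) {
    lp <- which(lab > 0, arr.ind = TRUE)
    for (i in which(labels == 0)) {
      d2 <- (lp[, 1] - px[i])^2 + (lp[, 2] - py[i])^2
      labels[i] <- lab[lp[which.min(d2), , drop = FALSE]]
    }
  }
  # renumber by descending cluster size (ties by original id)
  tab <- sort(table(labels), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(tab), names(tab))
  labels <- as.integer(relabel[as.character(labels)])
  structure(list(embedding = embedding, density = dens, labels = labels,
                 K = length(tab)),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("<cluster_map>", nrow(x$embedding), "samples,", x$K, "clusters:",
      paste(utils::head(table(x$labels), 10), collapse = " "), "\n")
  invisible(x)
}

#' Flag embedding outliers and individuals to exclude
#'
#' Flags samples whose distance from the embedding centroid (component-wise
#' median) exceeds \code{k_iqr} times the IQR of distances.  If at least
#' \code{indiv_frac} of one individual's samples are flagged, all samples of
#' that individual are marked for exclusion (the embedding should then be
#' recomputed without them).
#'
#' @param embedding Two-column embedding matrix.
#' @param individual Individual id per sample.
#' @param k_iqr Robust distance threshold in IQR units (default 5).
#' @param indiv_frac Fraction of flagged samples that excludes an individual
#'   (default 0.8).
#' @return List with \code{outliers} (sample indices) and
#'   \code{exclude_individuals} (ids) and \code{exclude_samples} (all sample
#'   indices of excluded individuals).
#' @export
detect_embedding_outliers <- function(embedding, individual,
                                      k_iqr = 5, indiv_frac = 0.8) {
  embedding <- as.matrix(embedding)
  ctr <- apply(embedding, 2, stats::median)
  d <- sqrt(rowSums(sweep(embedding, 2, ctr)^2))
  iqr <- stats::IQR(d)
  thr <- stats::median(d) + k_iqr * max(iqr, 1e-12)
  flagged <- which(d > thr)
  excl <- character(0)
  for (id in unique(individual[flagged])) {
    idx <- which(individual == id)
    if (mean(idx %in% flagged) >= indiv_frac) excl <- c(excl, id)
  }
  list(outliers = flagged, exclude_individuals = excl,
       exclude_samples = which(individual %in% excl))
}

#' Representative cluster of an individual
#'
#' The modal cluster over the individual's assigned days; ties are broken in
#' favor of the cluster with the lowest overall occurrence across all
#' individuals.
#'
#' @param assignments Data frame \code{individual}, \code{day},
#'   \code{cluster}.
#' @param individual Individual id.
#' @return Integer cluster id, or \code{NA} if the individual has no
#'   assignments.
#' @export
assign_representative_cluster <- function(assignments, individual) {
  own <- assignments$cluster[assignments$individual == individual &
                               !is.na(assignments$cluster)]
  if (length(own) == 0) return(NA_integer_)
  tab <- table(own)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) == 1) return(top)
  overall <- table(factor(assignments$cluster, levels = top))
  top[which.min(as.integer(overall))]
}
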