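# Significance-thresholded weighted social networks and strength centrality.

#' Build a social network from classified dyad results
#'
#' Nodes are all individuals; edges are the dyads classified
#' \code{significant_high}, weighted by their index.
#'
#' @param results A [dyad_index_table()] (or equivalent data frame with
#'   columns \code{a}, \code{b}, \code{index}, \code{class}).
#' @param directed Whether the relationship is directed (follow); for
#'   follow, edges point from the follower to the followee.
#' @param ids Node ids (default: all individuals appearing in
#'   \code{results}).
#' @return An \pkg{igraph} graph with edge attribute \code{weight}.
#' @export
build_network <- function(results, directed = isTRUE(attr(results,
                                                          "directed")),
                          ids = sort(unique(c(results$a, results$b)))) {
  sig <- results[results$class == "significant_high" &
                   is.finite(results$index), , drop = FALSE]
  edges <- data.frame(from = sig$a, to = sig$b, weight = sig$index,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = directed,
                                vertices = data.frame(name = ids))
}

#' Strength centrality
#'
#' The sum of the weights of all edges incident to each node; for directed
#' networks, in-strength sums the weights of incoming edges (being followed)
#' and out-strength those of outgoing edges (following others).  Isolated
#' nodes have strength 0.
#'
#' @param net An \pkg{igraph} graph with a \code{weight} edge attribute.
#' @param mode \code{"all"} (undirected), \code{"in"} or \code{"out"}.
#' @return Named numeric vector of node strengths.
#' @export
strength_centrality <- function(net, mode = c("all", "in", "out")) {
  mode <- match.arg(mode)
  if (mode != "all" && !igraph::is_directed(net))
    stop("parameter error: in/out strength requested on an undirected ",
         "network", call. = FALSE)
  w <- if (igraph::ecount(net) > 0) igraph::E(net)$weight else numeric(0)
  igraph::strength(net, mode = mode, weights = w, loops = FALSE)
}

#' Recompute networks and centralities over consecutive time subsets
#'
#' Partitions the recording into consecutive day blocks, re-runs the full
#' dyadic pipeline (counts, surrogates, significance, network) within each
#' block, and tabulates strength centralities.  Significance thresholds are
#' re-derived per subset from that subset's own surrogate distribution.
#'
#' @param data As in [dyad_index_table()] for the chosen type, covering the
#'   full recording.
#' @param type \code{"synchrony"}, \code{"proximity"} or \code{"follow"}.
#' @param n_days Number of recorded days.
#' @param n_subsets Number of consecutive blocks (default 6).
#' @param n_surrogates Surrogates per dyad within each subset.
#' @param seed Integer base seed; subset k uses \code{seed + (k - 1) * 1000}
#'   so that \code{n_subsets = 1} reproduces the full-period analysis.
#' @param day_s Day length in seconds.
#' @param interval_s Sampling interval of sample-based data (default 10 s).
#' @param window_s Follow window (follow only).
#' @return List with \code{centrality} (data frame \code{individual},
#'   \code{subset}, \code{mode}, \code{value}), \code{tables} and
#'   \code{networks} (per subset).
#' @export
time_split_recompute <- function(data, type = c("synchrony", "proximity",
                                                "follow"),
                                 n_days, n_subsets = 6, n_surrogates = 999,
                                 seed = 1, day_s = 86400, interval_s = 10,
                                 window_s = 3) {
  type <- match.arg(type)
  len <- n_days / n_subsets
  if (len != round(len)) {
    len <- ceiling(len)
    warning("recording length not divisible into ", n_subsets,
            " equal subsets; final subset is shorter", call. = FALSE)
  }
  ids <- if (type == "follow") names(data) else colnames(
    if (type == "proximity") data$act else data)
  samples_per_day <- day_s / interval_s

  slice <- function(k) {
    d0 <- (k - 1) * len
    d1 <- min(k * len, n_days)
    if (type == "follow") {
      lapply(data, function(mv)
        mv[mv$time_s >= d0 * day_s & mv$time_s < d1 * day_s, ,
           drop = FALSE])
    } else {
      r0 <- d0 * samples_per_day + 1
      r1 <- d1 * samples_per_day
      if (type == "synchrony") data[r0:r1, , drop = FALSE]
      else list(loc = data$loc[r0:r1, , drop = FALSE],
                act = data$act[r0:r1, , drop = FALSE],
                nest = rep_len(data$nest, nrow(data$act))[r0:r1])
    }
  }

  tables <- networks <- vector("list", n_subsets)
  cent <- list()
  for (k in seq_len(n_subsets)) {
    tbl <- dyad_index_table(slice(k), type, n_surrogates,
                            seed + (k - 1L) * 1000L, window_s)
    net <- build_network(tbl, directed = type == "follow", ids = ids)
    tables[[k]] <- tbl
    networks[[k]] <- net
    modes <- if (type == "follow") c("in", "out") else "all"
    for (m in modes) {
      v <- strength_centrality(net, m)
      cent[[length(cent) + 1L]] <- data.frame(
        individual = names(v), subset = k, mode = m, value = as.numeric(v),
        stringsAsFactors = FALSE)
    }
  }
  centrality <- do.call(rbind, cent)
  rownames(centrality) <- NULL
  list(centrality = centrality, tables = tables, networks = networks)
}
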