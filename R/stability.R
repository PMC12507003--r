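# Within-individual phenotype consistency (entropy index + Monte-Carlo
# null), colony-level day-to-day cluster stability, cluster co-assignment,
# and nest-transition leadership ranks.

#' Cluster assignment frequencies of one individual
#'
#' @param assignments Data frame \code{individual}, \code{day},
#'   \code{cluster}.
#' @param individual Individual id.
#' @param K Number of clusters.
#' @return Numeric vector of length \code{K} summing to 1 over assigned
#'   days, with attribute \code{n_days}.
#' @export
cluster_frequencies <- function(assignments, individual, K) {
  own <- assignments$cluster[assignments$individual == individual &
                               !is.na(assignments$cluster)]
  p <- tabulate(own, nbins = K)
  if (sum(p) == 0) stop("no assignments for individual ", individual,
                        call. = FALSE)
  structure(p / sum(p), n_days = length(own))
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Behavioral consistency index
#'
#' One minus the Shannon entropy of an individual's cluster-assignment
#' frequencies, normalized by \code{log(K)}: 1 when all days fall in a
#' single cluster, 0 when the assignment is uniform over all K clusters.
#'
#' @param p Frequency vector over clusters (sums to 1).
#' @param K Number of clusters (>= 2).
#' @return List with \code{H} (entropy, nats) and \code{index} in
#'   \code{[0, 1]}.
#' @export
consistency_index <- function(p, K = length(p)) {
  if (K < 2) stop("parameter error: K must be >= 2", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("parameter error: frequencies must sum to 1", call. = FALSE)
  H <- shannon_entropy(p)
  list(H = H, index = 1 - H / log(K))
}

#' Monte-Carlo null for the consistency index
#'
#' Simulates individuals whose daily cluster labels are drawn i.i.d. from
#' the pooled mean assignment probabilities, and computes the consistency
#' index of each simulated individual.  The p-value of an observed index is
#' the (add-one) proportion of simulated indices at least as large.
#'
#' @param mean_probs Pooled cluster probabilities (sums to 1).
#' @param n_days Days per simulated individual (default 30).
#' @param n_sims Number of simulated individuals (default 10000).
#' @param seed Integer seed.
#' @param observed Optional vector of observed indices for which p-values
#'   are returned.
#' @return List with \code{sim_indices} and, when \code{observed} is given,
#'   \code{p_values} (add-one convention) and \code{significant} at
#'   alpha = 0.05.
#' @export
consistency_null <- function(mean_probs, n_days = 30, n_sims = 10000,
                             seed = 1, observed = NULL) {
  stopifnot(abs(sum(mean_probs) - 1) < 1e-8)
  K <- length(mean_probs)
  set.seed(seed)
  counts <- stats::rmultinom(n_sims, n_days, mean_probs)
  p <- counts / n_days
  # columnwise entropy with 0 log 0 = 0
  lp <- ifelse(p > 0, log(p), 0)
  H <- -colSums(p * lp)
  sim <- 1 - H / log(K)
  out <- list(sim_indices = sim)
  if (!is.null(observed)) {
    sorted <- sort(sim)
    n_ge <- n_sims - findInterval(observed - 1e-12, sorted)
    out$p_values <- (1 + n_ge) / (1 + n_sims)
    out$significant <- out$p_values < 0.05
  }
  out
}

#' Day-to-day cluster stability by cosine similarity
#'
#' For one colony and cluster, builds the daily binary membership vectors
#' (individual in cluster or not), computes the cosine similarity of each
#' consecutive-day pair, and builds a null by shuffling the elements within
#' each daily vector.
#'
#' @param assignments Data frame \code{individual}, \code{day},
#'   \code{cluster} (one colony).
#' @param cluster Cluster id.
#' @param n_shuffles Shuffled vector sets (default 100).
#' @param seed Integer seed.
#' @return List with \code{observed} (one cosine per consecutive-day pair)
#'   and \code{null} (length \code{(days-1) * n_shuffles}).
#' @export
cluster_stability_cosine <- function(assignments, cluster,
                                     n_shuffles = 100, seed = 1) {
  ids <- sort(unique(assignments$individual))
  days <- sort(unique(assignments$day))
  stopifnot(length(days) >= 2)
  memb <- vapply(days, function(d) {
    as.integer(ids %in% assignments$individual[
      assignments$day == d & !is.na(assignments$cluster) &
        assignments$cluster == cluster])
  }, integer(length(ids)))
  cos_sim <- function(a, b) {
    denom2 <- sum(a^2) * sum(b^2)
    if (denom2 == 0) return(structure(0, flagged = TRUE))
    sum(a * b) / sqrt(denom2)
  }
  nd <- length(days)
  observed <- vapply(seq_len(nd - 1), function(k)
    as.numeric(cos_sim(memb[, k], memb[, k + 1])), numeric(1))
  set.seed(seed)
  null <- numeric((nd - 1) * n_shuffles)
  idx <- 0
  for (s in seq_len(n_shuffles)) {
    shuf <- apply(memb, 2, sample)
    for (k in seq_len(nd - 1)) {
      idx <- idx + 1
      null[idx] <- as.numeric(cos_sim(shuf[, k], shuf[, k + 1]))
    }
  }
  list(observed = observed, null = null)
}

#' Within-individual cluster co-assignment index
#'
#' For each cluster pair (k, l), compares the mean within-individual product
#' of assignment frequencies against the product of pooled mean frequencies.
#' Values above 1 indicate that the two clusters co-occur within the same
#' individuals more often than expected under independence.
#'
#' @param assignments Data frame \code{individual}, \code{day},
#'   \code{cluster}.
#' @param K Number of clusters (default: maximum observed).
#' @return List with matrices \code{C_emp}, \code{C_ref}, \code{index}
#'   (NA where \code{C_ref} is 0) and \code{N}.
#' @export
co_assignment <- function(assignments,
                          K = max(assignments$cluster, na.rm = TRUE)) {
  ids <- unique(assignments$individual)
  stopifnot(length(ids) >= 1)
  P <- t(vapply(ids, function(id) cluster_frequencies(assignments, id, K),
                numeric(K)))
  N <- length(ids)
  C_emp <- crossprod(P) / N
  pbar <- colMeans(P)
  C_ref <- outer(pbar, pbar)
  index <- ifelse(C_ref > 0, C_emp / C_ref, NA_real_)
  dimnames(C_emp) <- dimnames(C_ref) <- dimnames(index) <-
    list(seq_len(K), seq_len(K))
  list(C_emp = C_emp, C_ref = C_ref, index = index, N = N)
}

#' Nest transitions of an annotation
#'
#' @param nest Data frame \code{time_s}, \code{cell} (nest per sample).
#' @return Data frame \code{time_s}, \code{from}, \code{to}, one row per
#'   change of the annotated nest.
#' @export
nest_transitions <- function(nest) {
  ch <- which(nest$cell[-1] != nest$cell[-nrow(nest)]) + 1L
  data.frame(time_s = nest$time_s[ch],
             from = nest$cell[ch - 1L], to = nest$cell[ch])
}

#' Rest-initiation leadership ranks at nest transitions
#'
#' For each nest transition, individuals are ranked by the start of their
#' first Rest event in the new nest within a window from \code{pre_s} before
#' to \code{post_s} after the transition; tied onsets receive averaged
#' ranks.  Transitions in which at most \code{inclusion} of the colony
#' participates are excluded.
#'
#' @param events Classified stay events (colony-wide).
#' @param transitions Output of [nest_transitions()].
#' @param individuals Colony member ids.
#' @param pre_s Window start before the transition (default 7200 s).
#' @param post_s Window end after the transition (default 43200 s).
#' @param inclusion Minimum participating fraction, exclusive (default 0.8).
#' @return Data frame \code{event}, \code{individual}, \code{onset_s},
#'   \code{rank}; only included transitions appear.
#' @export
leadership_ranks <- function(events, transitions, individuals,
                             pre_s = 7200, post_s = 43200,
                             inclusion = 0.8) {
  if (nrow(transitions) == 0)
    return(data.frame(event = integer(0), individual = character(0),
                      onset_s = numeric(0), rank = numeric(0)))
  rest <- events[!is.na(events$category) & events$category == "Rest", ,
                 drop = FALSE]
  out <- list()
  for (ev in seq_len(nrow(transitions))) {
    t0 <- transitions$time_s[ev]
    new_nest <- transitions$to[ev]
    w0 <- t0 - pre_s; w1 <- t0 + post_s
    cand <- rest[rest$cell == new_nest & rest$start_s >= w0 &
                   rest$start_s <= w1, , drop = FALSE]
    onset <- vapply(individuals, function(id) {
      s <- cand$start_s[cand$individual == id]
      if (length(s)) min(s) else NA_real_
    }, numeric(1))
    part <- !is.na(onset)
    if (mean(part) <= inclusion) next
    out[[length(out) + 1L]] <- data.frame(
      event = ev, individual = individuals[part],
      onset_s = onset[part],
      rank = rank(onset[part], ties.method = "average"),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(event = integer(0), individual = character(0),
               onset_s = numeric(0), rank = numeric(0))
  rownames(res) <- NULL
  res
}
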