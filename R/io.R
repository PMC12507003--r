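# Readers/writers for the pipeline artifacts and the end-to-end driver.

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df[, cols, drop = FALSE]
}

read_csv_checked <- function(path, cols, what, col_classes = NA) {
  empty <- stats::setNames(as.data.frame(replicate(length(cols),
                                                   logical(0),
                                                   simplify = FALSE)),
                           cols)
  if (file.size(path) == 0) return(empty)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = col_classes)
  if (nrow(df) == 0 && ncol(df) == 0) return(empty)
  check_columns(df, cols, what)
}

#' Read and write pipeline artifacts
#'
#' Plain-CSV round-trip readers and writers for the tables the pipeline
#' produces: detection logs (\code{time_s,tag,reader}), stay events
#' (\code{individual,start_s,end_s,row,col,category}), daily parameter
#' tables, cluster assignments (\code{individual,day,cluster}) and dyad
#' index tables.  Missing header columns raise a schema error naming the
#' column; an empty file yields an empty table.
#'
#' @param x Table to write.
#' @param path File path.
#' @return Readers return a data frame; writers return \code{path}
#'   invisibly.
#' @name artifact_io
NULL

#' @rdname artifact_io
#' @export
write_detections <- function(x, path) {
  utils::write.csv(check_columns(x, c("time_s", "tag", "reader"),
                                 "detection log"),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_detections <- function(path) {
  df <- read_csv_checked(path, c("time_s", "tag", "reader"),
                         "detection log")
  df$time_s <- as.numeric(df$time_s)
  df$tag <- as.character(df$tag)
  df$reader <- as.character(df$reader)
  df
}

#' @rdname artifact_io
#' @export
write_events <- function(x, path) {
  rc <- cell_rc(ifelse(is.na(x$cell), 1L, x$cell))
  out <- data.frame(individual = x$individual, start_s = x$start_s,
                    end_s = x$end_s,
                    row = ifelse(is.na(x$cell), NA_integer_, rc[, "row"]),
                    col = ifelse(is.na(x$cell), NA_integer_, rc[, "col"]),
                    category = if ("category" %in% names(x)) x$category
                               else NA_character_)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_events <- function(path) {
  df <- read_csv_checked(path, c("individual", "start_s", "end_s", "row",
                                 "col", "category"), "events table")
  if (nrow(df) == 0)
    return(data.frame(individual = character(0), start_s = numeric(0),
                      end_s = numeric(0), cell = integer(0),
                      category = character(0), stringsAsFactors = FALSE))
  data.frame(individual = as.character(df$individual),
             start_s = as.numeric(df$start_s),
             end_s = as.numeric(df$end_s),
             cell = ifelse(is.na(df$row), NA_integer_,
                           cell_id(ifelse(is.na(df$row), 0L, df$row),
                                   ifelse(is.na(df$col), 0L, df$col))),
             category = as.character(df$category),
             stringsAsFactors = FALSE)
}

#' @rdname artifact_io
#' @export
write_location_series <- function(x, path) {
  stopifnot(inherits(x, "location_series"))
  rc <- cell_rc(ifelse(is.na(x), 1L, x))
  n <- nrow(x)
  out <- data.frame(
    tick = rep(seq_len(n) - 1L, ncol(x)),
    individual = rep(colnames(x), each = n),
    cell_row = ifelse(is.na(as.vector(x)), NA_integer_, rc[, "row"]),
    cell_col = ifelse(is.na(as.vector(x)), NA_integer_, rc[, "col"]))
  utils::write.csv(out, path, row.names = FALSE)
  attr_path <- paste0(path, ".json")
  jsonlite::write_json(list(tick_s = attr(x, "tick_s"), n_ticks = n),
                       attr_path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_location_series <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read_csv_checked(path, c("tick", "individual", "cell_row",
                                 "cell_col"), "location series")
  ids <- unique(df$individual)
  cells <- matrix(NA_integer_, meta$n_ticks, length(ids),
                  dimnames = list(NULL, ids))
  ok <- !is.na(df$cell_row)
  cells[cbind(df$tick[ok] + 1L, match(df$individual[ok], ids))] <-
    cell_id(df$cell_row[ok], df$cell_col[ok])
  location_series(cells, meta$tick_s)
}

#' @rdname artifact_io
#' @export
write_assignments <- function(x, path) {
  utils::write.csv(check_columns(x, c("individual", "day", "cluster"),
                                 "assignments"), path, row.names = FALSE)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_assignments <- function(path) {
  read_csv_checked(path, c("individual", "day", "cluster"), "assignments")
}

#' @rdname artifact_io
#' @export
write_dyad_table <- function(x, path) {
  utils::write.csv(check_columns(x, c("a", "b", "n_actual",
                                      "surrogate_mean", "surrogate_sd",
                                      "index", "p_value", "class")),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_dyad_table <- function(path) {
  read_csv_checked(path, c("a", "b", "n_actual", "surrogate_mean",
                           "surrogate_sd", "index", "p_value", "class"),
                   "dyad table")
}

#' @rdname artifact_io
#' @export
write_network_graphml <- function(x, path) {
  igraph::write_graph(x, path, format = "graphml")
  invisible(path)
}

#' Run the end-to-end pipeline on a simulated colony
#'
#' Simulates a colony, reconstructs locations from the detection log,
#' builds and corrects stay events, excludes disturbance phases, extracts
#' daily behavior vectors, clusters phenotypes, computes consistency and
#' co-assignment metrics, dyadic indices for all three relationship types,
#' and the derived social networks.  All artifacts are written as CSV (plus
#' GraphML networks) under \code{out_dir}, together with a JSON manifest of
#' seeds, parameters and per-stage record counts.
#'
#' @param config A [colony_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_surrogates Surrogates per dyad (default 199 for a desk-scale
#'   demonstration; a full-scale analysis uses 9999 for synchrony/proximity
#'   and 999 for follow).
#' @param interval_s Activity/proximity sampling interval (default 10 s).
#' @param layout A \code{grid_layout}.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, out_dir, n_surrogates = 199,
                         interval_s = 10, layout = build_layout()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
    res
  }

  sim <- stage("simulate", simulate_colony(config, layout))
  write_detections(sim$detections, file.path(out_dir, "detections.csv"))
  counts$detections <- nrow(sim$detections)

  series <- stage("track", reconstruct_locations(
    sim$detections, layout, tick_s = config$tick_s,
    duration_s = config$duration_s, tags = config$ids))
  counts$ticks <- nrow(series)

  nest <- stage("events", annotate_nest(series, layout = layout))
  ann <- chamber_annotation(nest, config$toilet_cell, config$garbage_cell)
  events <- segment_stays(series)
  events <- classify_stays(events, ann)
  events <- apply_corrections(events, ann, config$duration_s, layout)
  rf <- rest_fraction_series(events, config$n_individuals,
                             config$duration_s, interval_s)
  disturb <- detect_disturbances(rf)
  write_events(events, file.path(out_dir, "events.csv"))
  utils::write.csv(as.data.frame(disturb),
                   file.path(out_dir, "disturbances.csv"),
                   row.names = FALSE)
  counts$events <- nrow(events)
  counts$disturbances <- nrow(disturb)

  n_days <- max(1L, floor(config$duration_s / 86400))
  params <- stage("phenotype", daily_parameter_table(
    events, n_days, individuals = config$ids,
    day_s = config$duration_s / n_days))
  norm <- normalize_parameters(as.matrix(params[, -(1:2)]), "colony",
                               params$day)
  cm <- embed_and_segment(norm, seed = config$seed)
  assignments <- data.frame(individual = params$individual,
                            day = params$day, cluster = cm$labels)
  utils::write.csv(cbind(params[, 1:2], as.data.frame(norm)),
                   file.path(out_dir, "parameters.csv"), row.names = FALSE)
  write_assignments(assignments, file.path(out_dir, "assignments.csv"))
  counts$samples <- nrow(assignments)
  counts$clusters <- cm$K

  consistency <- NULL
  if (cm$K >= 2) {
    consistency <- stage("stability", {
      mp <- as.numeric(table(factor(assignments$cluster,
                                    levels = seq_len(cm$K)))) /
        nrow(assignments)
      null <- consistency_null(mp, n_days = n_days, n_sims = 1000,
                               seed = config$seed)
      do.call(rbind, lapply(config$ids, function(id) {
        fr <- cluster_frequencies(assignments, id, cm$K)
        ci <- consistency_index(fr, cm$K)
        p <- (1 + sum(null$sim_indices >= ci$index - 1e-12)) /
          (1 + length(null$sim_indices))
        data.frame(individual = id, H = ci$H, index = ci$index,
                   p_value = p, stringsAsFactors = FALSE)
      }))
    })
    utils::write.csv(consistency, file.path(out_dir, "consistency.csv"),
                     row.names = FALSE)
    coa <- co_assignment(assignments, cm$K)
    utils::write.csv(as.data.frame(as.table(coa$index)),
                     file.path(out_dir, "co_assignment.csv"),
                     row.names = FALSE)
  }

  act <- stage("dyads", vapply(config$ids, function(id)
    binarize_activity(events, id, config$duration_s, interval_s, disturb),
    integer(floor(config$duration_s / interval_s))))
  step <- round(interval_s / config$tick_s)
  samp_rows <- seq(1L, nrow(series), by = step)
  loc <- unclass(series)[samp_rows, , drop = FALSE]
  nest_sam <- nest_at(ann, (samp_rows - 1L) * config$tick_s)
  tables <- list(
    synchrony = dyad_index_table(act, "synchrony", n_surrogates,
                                 config$seed),
    proximity = dyad_index_table(list(loc = loc, act = act,
                                      nest = nest_sam),
                                 "proximity", n_surrogates, config$seed),
    follow = dyad_index_table(
      lapply(config$ids, function(id) {
        mv <- extract_movements(series[, id], config$tick_s, layout)
        mv
      }) |> stats::setNames(config$ids),
      "follow", n_surrogates, config$seed))
  networks <- stage("networks", lapply(names(tables), function(ty) {
    write_dyad_table(tables[[ty]], file.path(out_dir,
                                             paste0("dyads_", ty, ".csv")))
    net <- build_network(tables[[ty]], directed = ty == "follow",
                         ids = config$ids)
    write_network_graphml(net, file.path(out_dir,
                                         paste0("network_", ty,
                                                ".graphml")))
    net
  }) |> stats::setNames(names(tables)))
  counts$significant_dyads <- vapply(tables, function(t)
    sum(t$class == "significant_high"), numeric(1))

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config),
                                              c("coupling", "co_location",
                                                "follow"))],
                               auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "burrowtrack",
    version = as.character(utils::packageVersion("burrowtrack")),
    seed = config$seed,
    n_surrogates = n_surrogates,
    interval_s = interval_s,
    config_md5 = unname(tools::md5sum(tmp)),
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(sim = sim, series = series, events = events,
                 disturbances = disturb, assignments = assignments,
                 cluster_map = cm, consistency = consistency,
                 dyads = tables, networks = networks))
}
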