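# Cell coordinates are 0-based (row, col) on a 5x5 grid; the scalar cell id
# used internally is row * 5 + col + 1 (1..25).

#' Convert between (row, col) coordinates and scalar cell ids
#'
#' Cells of the 5x5 burrow grid are addressed either by 0-based
#' \code{(row, col)} coordinates or by a scalar id in \code{1:25}.
#'
#' @param row,col Integer vectors of 0-based coordinates.
#' @param id Integer vector of cell ids.
#' @return \code{cell_id} returns integer ids; \code{cell_rc} returns a
#'   two-column matrix with columns \code{row} and \code{col}.
#' @export
cell_id <- function(row, col) {
  stopifnot(all(row >= 0 & row <= 4), all(col >= 0 & col <= 4))
  as.integer(row * 5L + col + 1L)
}

#' @rdname cell_id
#' @export
cell_rc <- function(id) {
  stopifnot(all(id >= 1 & id <= 25))
  id <- as.integer(id) - 1L
  cbind(row = id %/% 5L, col = id %% 5L)
}

#' Canonical burrow layout description
#'
#' Describes the standard housing system: nine boxes arranged three-by-three,
#' connected by twelve pipes, with one RFID reader at each pipe end (24
#' readers).  On the 5x5 grid model, boxes occupy the positions with both
#' coordinates even, pipes the positions between adjacent boxes, and the four
#' remaining diagonal positions are void.
#'
#' @return A list with data frames \code{boxes} (\code{row}, \code{col}),
#'   \code{pipes} (\code{row}, \code{col}) and \code{readers}
#'   (\code{reader}, \code{row}, \code{col}, \code{end_row}, \code{end_col});
#'   reader positions name the pipe cell, end positions the box at that
#'   reader's end of the pipe.
#' @export
burrow_layout_spec <- function() {
  boxes <- expand.grid(col = c(0L, 2L, 4L), row = c(0L, 2L, 4L))[, 2:1]
  pipe_rc <- cell_rc(which(grid_cell_kinds() == "pipe"))
  pipes <- data.frame(row = pipe_rc[, "row"], col = pipe_rc[, "col"])
  readers <- do.call(rbind, lapply(seq_len(nrow(pipes)), function(i) {
    pr <- pipes$row[i]; pc <- pipes$col[i]
    if (pr %% 2L == 1L) {             # vertical pipe: boxes above and below
      ends <- cbind(c(pr - 1L, pr + 1L), c(pc, pc))
    } else {                          # horizontal pipe: boxes left and right
      ends <- cbind(c(pr, pr), c(pc - 1L, pc + 1L))
    }
    data.frame(row = pr, col = pc, end_row = ends[, 1], end_col = ends[, 2])
  }))
  readers$reader <- sprintf("R%02d", seq_len(nrow(readers)))
  rownames(boxes) <- rownames(readers) <- NULL
  list(boxes = boxes, pipes = pipes,
       readers = readers[, c("reader", "row", "col", "end_row", "end_col")])
}

grid_cell_kinds <- function() {
  rc <- cell_rc(1:25)
  kind <- rep("void", 25)
  kind[rc[, "row"] %% 2L == 0L & rc[, "col"] %% 2L == 0L] <- "box"
  kind[xor(rc[, "row"] %% 2L == 1L, rc[, "col"] %% 2L == 1L)] <- "pipe"
  kind
}

#' Build a validated burrow grid layout
#'
#' Validates a layout description (see [burrow_layout_spec()]) against the
#' 5x5 grid model and precomputes adjacency and box-to-box shortest paths.
#'
#' @param spec A layout description; defaults to the canonical nine-box,
#'   twelve-pipe, 24-reader layout.
#' @return An object of class \code{grid_layout}: a list with elements
#'   \code{kind} (character vector of length 25: box/pipe/void),
#'   \code{boxes}, \code{pipes} (integer cell ids), \code{readers}
#'   (data frame \code{reader}, \code{pipe}, \code{end_box}),
#'   \code{adjacency} (list of neighboring cell ids per cell) and
#'   \code{paths} (list matrix of box-to-box cell-id paths).
#' @export
build_layout <- function(spec = burrow_layout_spec()) {
  kind <- grid_cell_kinds()
  box_ids <- which(kind == "box")
  pipe_ids <- which(kind == "pipe")

  spec_boxes <- sort(cell_id(spec$boxes$row, spec$boxes$col))
  if (!identical(spec_boxes, box_ids))
    stop("layout error: boxes must occupy the nine odd-index (3x3) positions",
         call. = FALSE)
  spec_pipes <- sort(cell_id(spec$pipes$row, spec$pipes$col))
  if (!identical(spec_pipes, pipe_ids))
    stop("layout error: expected the 12 pipe cells between adjacent boxes; ",
         "got ", length(spec_pipes), call. = FALSE)

  rd <- spec$readers
  if (anyDuplicated(rd$reader))
    stop("layout error: duplicated reader ids", call. = FALSE)
  rd_pipe <- cell_id(rd$row, rd$col)
  if (any(kind[rd_pipe] != "pipe"))
    stop("layout error: reader assigned to a non-pipe cell: ",
         paste(rd$reader[kind[rd_pipe] != "pipe"], collapse = ", "),
         call. = FALSE)
  rd_end <- cell_id(rd$end_row, rd$end_col)
  if (any(kind[rd_end] != "box"))
    stop("layout error: reader end must be a box cell", call. = FALSE)
  if (nrow(rd) != 24L || any(table(rd_pipe) > 2L))
    stop("layout error: expected 24 readers, at most two per pipe cell",
         call. = FALSE)

  # adjacency: 4-neighborhood restricted to non-void cells
  rc <- cell_rc(1:25)
  adjacency <- lapply(1:25, function(i) {
    if (kind[i] == "void") return(integer(0))
    r <- rc[i, 1]; cc <- rc[i, 2]
    nb <- rbind(c(r - 1L, cc), c(r + 1L, cc), c(r, cc - 1L), c(r, cc + 1L))
    nb <- nb[nb[, 1] >= 0 & nb[, 1] <= 4 & nb[, 2] >= 0 & nb[, 2] <= 4, ,
             drop = FALSE]
    ids <- cell_id(nb[, 1], nb[, 2])
    sort(ids[kind[ids] != "void"])
  })

  layout <- structure(
    list(kind = kind, boxes = box_ids, pipes = pipe_ids,
         readers = data.frame(reader = rd$reader, pipe = rd_pipe,
                              end_box = rd_end, stringsAsFactors = FALSE),
         adjacency = adjacency),
    class = "grid_layout")
  layout$paths <- precompute_box_paths(layout)
  layout
}

# BFS shortest path between two cells over non-void cells; ties broken by
# visiting neighbors in ascending cell-id order.
shortest_cell_path <- function(layout, from, to) {
  if (from == to) return(from)
  prev <- rep(NA_integer_, 25)
  prev[from] <- 0L
  frontier <- from
  while (length(frontier) > 0 && is.na(prev[to])) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in layout$adjacency[[v]]) {
        if (is.na(prev[w])) {
          prev[w] <- v
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- sort(nxt)
  }
  if (is.na(prev[to])) stop("no path between cells ", from, " and ", to)
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

precompute_box_paths <- function(layout) {
  b <- layout$boxes
  paths <- vector("list", 25L * 25L)
  dim(paths) <- c(25L, 25L)
  for (i in b) for (j in b) paths[[i, j]] <- shortest_cell_path(layout, i, j)
  paths
}

#' @export
print.grid_layout <- function(x, ...) {
  cat("<grid_layout> 5x5 burrow grid:",
      sum(x$kind == "box"), "boxes,",
      sum(x$kind == "pipe"), "pipes,",
      nrow(x$readers), "readers\n")
  invisible(x)
}

# Cell "between" two readers: the shared pipe if both flank one pipe, else
# the shared box if their pipes meet at a box, else NA (unlocatable).
between_cell <- function(layout, reader_a, reader_b) {
  rd <- layout$readers
  ia <- match(reader_a, rd$reader); ib <- match(reader_b, rd$reader)
  if (is.na(ia) || is.na(ib))
    stop("input error: unknown reader id: ",
         paste(c(reader_a, reader_b)[is.na(c(ia, ib))], collapse = ", "),
         call. = FALSE)
  if (rd$pipe[ia] == rd$pipe[ib]) return(rd$pipe[ia])
  shared <- intersect(pipe_end_boxes(layout, rd$pipe[ia]),
                      pipe_end_boxes(layout, rd$pipe[ib]))
  if (length(shared) == 1L) shared else NA_integer_
}

pipe_end_boxes <- function(layout, pipe) {
  nb <- layout$adjacency[[pipe]]
  nb[layout$kind[nb] == "box"]
}

#' Spatial class of a box cell
#'
#' Classifies a box cell of the three-by-three box lattice as a corner,
#' edge or center chamber.
#'
#' @param cell Integer cell id (must be a box cell).
#' @param layout A \code{grid_layout}.
#' @return One of \code{"corner"}, \code{"edge"}, \code{"center"}.
#' @export
classify_spatial_position <- function(cell, layout = build_layout()) {
  if (layout$kind[cell] != "box")
    stop("input error: cell ", cell, " is not a box cell", call. = FALSE)
  rc <- cell_rc(cell)
  n_center <- sum(rc == 2L)  # box coords are 0, 2 or 4; 2 is central
  c("corner", "edge", "center")[n_center + 1L]
}
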