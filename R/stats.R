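#' Torus-aware cell centroid
#'
#' On bounded axes the centroid is the arithmetic mean of pixel coordinates.
#' On torus axes it is the circular mean: each coordinate is mapped to an
#' angle on the circle, the mean resultant angle is mapped back, and the
#' result is wrapped into `[0, L)`. Cells straddling the wrap therefore get
#' the geometrically correct centroid; for compact cells away from the seam
#' the two estimators agree to numerical precision.
#'
#' @param state A `cpm_state`.
#' @param cell_id Cell id with at least one pixel.
#' @return Numeric `c(x, y)`.
#' @export
centroid <- function(state, cell_id) {
  w <- which(state$identity == cell_id)
  if (!length(w)) stop("cell ", cell_id, " has no pixels", call. = FALSE)
  W <- state$spec$width; H <- state$spec$height
  x <- (w - 1L) %% W
  y <- (w - 1L) %/% W
  c(axis_mean(x, W, state$spec$torus_x), axis_mean(y, H, state$spec$torus_y))
}

axis_mean <- function(v, n, torus) {
  if (!torus) return(mean(v))
  th <- v * (2 * pi / n)
  ang <- atan2(mean(sin(th)), mean(cos(th)))
  (ang * n / (2 * pi)) %% n
}

#' Centroids of all live cells
#'
#' @param state A `cpm_state`.
#' @return A data.frame with columns `cell`, `kind`, `x`, `y`, `volume`.
#' @export
centroids <- function(state) {
  ids <- which(state$volume_of > 0) - 1L
  ids <- ids[ids > 0L]
  out <- lapply(ids, function(id) {
    cen <- centroid(state, id)
    data.frame(cell = id, kind = state$kind_of[id + 1L],
               x = cen[1], y = cen[2], volume = state$volume_of[id + 1L])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Heterotypic interface length
#'
#' Number of unordered kernel-neighbor pixel pairs whose identities belong
#' to two different non-background kinds. Decreases as differential-adhesion
#' cell sorting proceeds; invariant under global kind relabelling.
#'
#' @param state A `cpm_state`.
#' @param kernel Neighborhood kernel.
#' @return A count.
#' @export
heterotypic_interface <- function(state, kernel = moore_kernel()) {
  cpp_heterotypic_interface(state$identity, as.integer(state$kind_of),
                            kernel, state$spec$torus_x, state$spec$torus_y)
}

#' Is a cell a single connected component?
#'
#' Breadth-first search over the cell's pixel set with kernel adjacency,
#' torus-aware. Useful for detecting cell-breaking artefacts.
#'
#' @param state A `cpm_state`.
#' @param cell_id Non-empty cell id.
#' @param kernel Neighborhood kernel (defaults to the dynamics kernel).
#' @return Logical.
#' @export
is_connected <- function(state, cell_id, kernel = moore_kernel()) {
  w <- which(state$identity == cell_id)
  if (!length(w)) stop("cell ", cell_id, " has no pixels", call. = FALSE)
  if (length(w) == 1L) return(TRUE)
  W <- state$spec$width
  member <- logical(length(state$identity))
  member[w] <- TRUE
  seen <- logical(length(state$identity))
  queue <- w[1]; seen[w[1]] <- TRUE; found <- 1L
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    x <- (cur - 1L) %% W; y <- (cur - 1L) %/% W
    nb <- neighbors(state$spec, c(x, y), kernel)
    ni <- nb[, 1] + 1L + W * nb[, 2]
    ni <- ni[member[ni] & !seen[ni]]
    if (length(ni)) {
      seen[ni] <- TRUE
      found <- found + length(ni)
      queue <- c(queue, ni)
    }
  }
  found == length(w)
}

#' One logged observation of a running simulation
#'
#' Collects the per-cell table (centroids, volumes, kinds) and global
#' summaries (cell count, background pixels, heterotypic interface) for one
#' MCS index.
#'
#' @param state A `cpm_state`.
#' @param mcs MCS index of the observation.
#' @param kernel Kernel for the interface count.
#' @return A list of class `cpm_stat_record` with elements `mcs`, `per_cell`
#'   (data.frame) and `global` (named numeric vector).
#' @export
stat_record <- function(state, mcs, kernel = moore_kernel()) {
  pc <- centroids(state)
  if (is.null(pc))
    pc <- data.frame(cell = integer(), kind = integer(),
                     x = numeric(), y = numeric(), volume = integer())
  structure(list(
    mcs = as.integer(mcs),
    per_cell = cbind(mcs = as.integer(mcs), pc),
    global = c(mcs = as.integer(mcs),
               cell_count = nrow(pc),
               background = state$volume_of[1],
               heterotypic_interface = heterotypic_interface(state, kernel))
  ), class = "cpm_stat_record")
}

#' Write / read statistics logs as tidy CSV
#'
#' `write_stat_log()` writes two CSVs: `<prefix>_cells.csv`, one row per
#' (mcs, cell) with columns `mcs, cell, kind, x, y, volume`; and
#' `<prefix>_global.csv`, one row per mcs with columns
#' `mcs, cell_count, background, heterotypic_interface`.
#' `read_stat_log()` parses them back losslessly.
#'
#' @param records List of `cpm_stat_record`s.
#' @param prefix Output path prefix.
#' @return `write_stat_log`: the two file paths, invisibly.
#'   `read_stat_log`: a list with data.frames `cells` and `global`.
#' @export
write_stat_log <- function(records, prefix) {
  cells <- do.call(rbind, lapply(records, `[[`, "per_cell"))
  glob <- as.data.frame(do.call(rbind, lapply(records, `[[`, "global")))
  fc <- paste0(prefix, "_cells.csv")
  fg <- paste0(prefix, "_global.csv")
  utils::write.csv(cells, fc, row.names = FALSE)
  utils::write.csv(glob, fg, row.names = FALSE)
  invisible(c(fc, fg))
}

#' @rdname write_stat_log
#' @export
read_stat_log <- function(prefix) {
  list(cells = utils::read.csv(paste0(prefix, "_cells.csv")),
       global = utils::read.csv(paste0(prefix, "_global.csv")))
}
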