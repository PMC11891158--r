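# 3-D discretizing mesh and morphological (second-scan) rules.
#
# Occupied GCs are columns of a shared compartment matrix; `map` is a 3-D
# integer array giving the column index of each lattice site (0 = empty).
# Coordinates are 0-based, x fastest. The morphological rules move cells
# between columns but never create or destroy them.

.nb26 <- local({
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d[rowSums(abs(d)) > 0, , drop = FALSE]
})
.nb6 <- .nb26[rowSums(abs(.nb26)) == 1, , drop = FALSE]

#' Create a tumor mesh
#'
#' A 3-D cubic lattice of geometrical cells (GCs). Each occupied GC holds a
#' compartment column; at nominal density a GC carries `NBC = cell_density *
#' voxel_edge^3` biological cells and its total is kept within
#' `[(1 - margin) NBC, (1 + margin) NBC]` by the second-scan rules.
#'
#' @param geometry A [build_geometry()] result (or a [tumor_geometry()],
#'   rasterized internally).
#' @param params An [model_params()] object.
#' @return An object of class `oncosim_mesh`.
#' @export
tumor_mesh <- function(geometry, params) {
  if (inherits(geometry, "tumor_geometry"))
    geometry <- build_geometry(geometry, voxel_edge = params$voxel_edge)
  dims <- geometry$dims
  occ <- geometry$occupied
  n <- nrow(occ)
  if (n == 0L) stop("geometry rasterizes to zero occupied GCs", call. = FALSE)
  map <- array(0L, dim = dims)
  map[occ + 1L] <- seq_len(n)
  region <- rep("proliferating", n)
  if (nrow(geometry$necrotic)) {
    ni <- map[geometry$necrotic + 1L]
    region[ni[ni > 0]] <- "necrotic"
  }
  mesh <- list(dims = dims, voxel_edge = params$voxel_edge,
               NBC = params$cell_density * params$voxel_edge^3,
               margin = params$margin_percent,
               params = params, map = map,
               coords = occ, region = region,
               state = new_compartment_state(params, n),
               events = list(chain_expansions = 0L, chain_fills = 0L,
                             isolated_moves = 0L, holes_filled = 0L))
  class(mesh) <- "oncosim_mesh"
  mesh
}

#' @export
print.oncosim_mesh <- function(x, ...) {
  cat(sprintf("Tumor mesh %dx%dx%d GCs (edge %g mm), %d occupied, volume %g mm^3\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_edge,
              nrow(x$coords), tumor_volume(x)))
  invisible(x)
}

#' Tumor volume
#'
#' Occupied-GC count times the voxel volume.
#'
#' @param mesh An `oncosim_mesh`.
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(mesh) {
  if (!nrow(mesh$coords)) return(0)
  sum(colSums(mesh$state$M) > 0) * mesh$voxel_edge^3
}

.occupy <- function(mesh, coord) {
  mesh$map[coord[1] + 1L, coord[2] + 1L, coord[3] + 1L] <-
    ncol(mesh$state$M) + 1L
  mesh$state$M <- cbind(mesh$state$M, 0)
  mesh$coords <- rbind(mesh$coords, coord)
  mesh$region <- c(mesh$region, "proliferating")
  mesh
}

.vacate <- function(mesh, j) {
  co <- mesh$coords[j, ]
  mesh$map[co[1] + 1L, co[2] + 1L, co[3] + 1L] <- 0L
  mesh$state$M <- mesh$state$M[, -j, drop = FALSE]
  mesh$coords <- mesh$coords[-j, , drop = FALSE]
  mesh$region <- mesh$region[-j]
  sel <- mesh$map > j
  mesh$map[sel] <- mesh$map[sel] - 1L
  mesh
}

.move_column <- function(mesh, from, to_coord) {
  # relocate the whole content of column `from` to lattice site `to_coord`
  k <- mesh$map[to_coord[1] + 1L, to_coord[2] + 1L, to_coord[3] + 1L]
  if (k > 0L) {                      # merge into an occupied site
    mesh$state$M[, k] <- mesh$state$M[, k] + mesh$state$M[, from]
    mesh <- .vacate(mesh, from)
  } else {
    co <- mesh$coords[from, ]
    mesh$map[co[1] + 1L, co[2] + 1L, co[3] + 1L] <- 0L
    mesh$map[to_coord[1] + 1L, to_coord[2] + 1L, to_coord[3] + 1L] <- from
    mesh$coords[from, ] <- to_coord
  }
  mesh
}

.neighbor_ids <- function(mesh, coord, offsets) {
  nb <- offsets + rep(as.integer(coord), each = nrow(offsets))
  ok <- nb[, 1] >= 0L & nb[, 2] >= 0L & nb[, 3] >= 0L &
    nb[, 1] < mesh$dims[1] & nb[, 2] < mesh$dims[2] & nb[, 3] < mesh$dims[3]
  nb <- nb[ok, , drop = FALSE]
  list(coords = nb, ids = mesh$map[nb + 1L])
}

# occupied 6-neighbor count for every row of a coordinate matrix (vectorized)
.occupied_nb6_counts <- function(mesh, coords) {
  n <- nrow(coords)
  cnt <- integer(n)
  for (k in seq_len(6)) {
    nb <- coords + rep(.nb6[k, ], each = n)
    ok <- nb[, 1] >= 0L & nb[, 2] >= 0L & nb[, 3] >= 0L &
      nb[, 1] < mesh$dims[1] & nb[, 2] < mesh$dims[2] & nb[, 3] < mesh$dims[3]
    if (any(ok))
      cnt[ok] <- cnt[ok] + (mesh$map[nb[ok, , drop = FALSE] + 1L] > 0L)
  }
  cnt
}

.transfer <- function(mesh, from, to, amount) {
  tot <- sum(mesh$state$M[, from])
  if (tot <= 0 || amount <= 0) return(mesh)
  frac <- min(amount / tot, 1)
  v <- mesh$state$M[, from] * frac    # drawn proportionally from all subclasses
  mesh$state$M[, from] <- mesh$state$M[, from] - v
  mesh$state$M[, to] <- mesh$state$M[, to] + v
  mesh
}

#' Unload an overloaded GC (differential expansion)
#'
#' When a GC exceeds `(1 + margin) NBC` its population minus NBC is unloaded
#' to occupied 26-neighbors with free space (total < NBC), visiting receivers
#' from the one with maximum free space (ties broken by the seeded RNG) to
#' exhaustion. If excess remains, a randomly directed chain of GC contents is
#' shifted one step outwards to free the adjacent GC, which then receives the
#' excess (when the adjacent site is already empty the chain is trivial and
#' the tumor simply expands into it); if the chain reaches the lattice
#' boundary the simulation domain is exceeded and an error is raised.
#'
#' @param mesh An `oncosim_mesh`.
#' @param j Column index of the overloaded GC.
#' @return The rebalanced mesh.
#' @export
rebalance_overloaded <- function(mesh, j) {
  NBC <- mesh$NBC
  tot <- sum(mesh$state$M[, j])
  if (tot <= (1 + mesh$margin) * NBC) return(mesh)
  excess <- tot - NBC
  nb <- .neighbor_ids(mesh, mesh$coords[j, ], .nb26)
  ids <- nb$ids[nb$ids > 0L]
  if (length(ids)) {
    free <- NBC - colSums(mesh$state$M[, ids, drop = FALSE])
    for (k in order(-free, stats::runif(length(ids)))) {
      if (excess <= 1e-9) break
      if (free[k] <= 0) next
      amt <- min(excess, free[k])
      mesh <- .transfer(mesh, j, ids[k], amt)
      excess <- excess - amt
    }
  }
  if (excess > 1e-9) {
    dirs <- .nb26[sample.int(26), , drop = FALSE]
    done <- FALSE
    for (di in seq_len(26)) {
      d <- dirs[di, ]
      # find the first empty site outward along d
      co <- mesh$coords[j, ]; k <- 0L; path <- list()
      repeat {
        k <- k + 1L
        p <- co + k * d
        if (any(p < 0) || any(p >= mesh$dims)) { k <- -1L; break }
        if (mesh$map[p[1] + 1L, p[2] + 1L, p[3] + 1L] == 0L) break
        path[[k]] <- p
      }
      if (k < 0L) next
      # shift contents outward from the far end, freeing the adjacent GC
      if (length(path))
        for (i in rev(seq_along(path))) {
          from_id <- mesh$map[path[[i]][1] + 1L, path[[i]][2] + 1L,
                              path[[i]][3] + 1L]
          mesh <- .move_column(mesh, from_id, co + (i + 1L) * d)
        }
      mesh <- .occupy(mesh, co + d)
      mesh <- .transfer(mesh, j, ncol(mesh$state$M), excess)
      mesh$events$chain_expansions <- mesh$events$chain_expansions + 1L
      done <- TRUE
      break
    }
    if (!done)
      stop("tumor reached the simulation domain boundary; enlarge the mesh dims",
           call. = FALSE)
  }
  mesh
}

.chain_fill_direction <- function(mesh, coord) {
  # sample six of the 26 directions; along each ray find the outermost
  # occupied GC and count its occupied 6-neighbors (NGCT); pick the max.
  dirs <- .nb26[sample.int(26, 6), , drop = FALSE]
  best <- NULL; best_score <- -1
  for (i in seq_len(6)) {
    d <- dirs[i, ]
    outer <- NULL; k <- 0L
    repeat {
      k <- k + 1L
      p <- coord + k * d
      if (any(p < 0) || any(p >= mesh$dims)) break
      if (mesh$map[p[1] + 1L, p[2] + 1L, p[3] + 1L] > 0L) outer <- p
    }
    if (is.null(outer)) next
    ngct <- sum(.neighbor_ids(mesh, outer, .nb6)$ids > 0L)
    score <- ngct + stats::runif(1) * 1e-6      # seeded tie-break
    if (score > best_score) { best_score <- score; best <- d }
  }
  best
}

.chain_fill <- function(mesh, coord) {
  # fill the empty site `coord` by shifting a chain of GC contents inward
  d <- .chain_fill_direction(mesh, coord)
  if (is.null(d)) return(mesh)
  positions <- list(); k <- 0L; last_occ <- 0L
  repeat {
    k <- k + 1L
    p <- coord + k * d
    if (any(p < 0) || any(p >= mesh$dims)) break
    positions[[k]] <- p
    if (mesh$map[p[1] + 1L, p[2] + 1L, p[3] + 1L] > 0L) last_occ <- k
  }
  if (last_occ == 0L) return(mesh)
  for (i in seq_len(last_occ)) {
    id <- mesh$map[positions[[i]][1] + 1L, positions[[i]][2] + 1L,
                   positions[[i]][3] + 1L]
    if (id > 0L)
      mesh <- .move_column(mesh, id,
                           if (i == 1L) coord else positions[[i - 1L]])
  }
  mesh$events$chain_fills <- mesh$events$chain_fills + 1L
  mesh
}

#' Unload an underloaded GC (differential shrinkage)
#'
#' When a GC falls below `(1 - margin) NBC` its contents are pushed to
#' occupied 26-neighbors with free space, starting from the one with maximum
#' free space. If the GC empties it is removed and the vacuum is filled by
#' shifting a chain of GC contents towards it; the chain direction is chosen
#' by sampling six random directions, locating the outermost non-empty GC on
#' each and selecting the direction whose outermost GC has the largest count
#' of tumor 6-neighbors.
#'
#' @inheritParams rebalance_overloaded
#' @return The rebalanced mesh.
#' @export
rebalance_underloaded <- function(mesh, j) {
  NBC <- mesh$NBC
  tot <- sum(mesh$state$M[, j])
  if (tot >= (1 - mesh$margin) * NBC) return(mesh)
  nb <- .neighbor_ids(mesh, mesh$coords[j, ], .nb26)
  ids <- nb$ids[nb$ids > 0L & nb$ids != j]
  if (length(ids)) {
    free <- NBC - colSums(mesh$state$M[, ids, drop = FALSE])
    ord <- order(-free, stats::runif(length(ids)))
    for (k in ord) {
      if (tot <= 1e-9) break
      if (free[k] <= 0) next
      amt <- min(tot, free[k])
      mesh <- .transfer(mesh, j, ids[k], amt)
      tot <- tot - amt
    }
  }
  if (tot <= 1e-9) {
    coord <- mesh$coords[j, ]
    mesh <- .vacate(mesh, j)
    if (nrow(mesh$coords)) mesh <- .chain_fill(mesh, coord)
  }
  mesh
}

#' Repair tumor fragmentation and internal holes
#'
#' Detects occupied GCs whose 6-neighborhood is entirely empty and moves
#' their contents one GC per call towards the tumor center of mass, along the
#' coordinate axis with the smallest non-zero absolute offset from the center
#' (ties broken by the seeded RNG). Detects empty GCs fully surrounded by
#' occupied 6-neighbors and fills them with the shrinkage chain procedure.
#' Iterates to a fixpoint.
#'
#' @param mesh An `oncosim_mesh`.
#' @return The repaired mesh.
#' @export
repair_fragmentation <- function(mesh) {
  for (pass in 1:100) {
    changed <- FALSE
    ## stray GCs drift towards the center of mass
    if (nrow(mesh$coords) > 1L) {
      stray <- .occupied_nb6_counts(mesh, mesh$coords) == 0L
      j <- 1L
      while (j <= nrow(mesh$coords)) {
        if (j <= length(stray) && stray[j] &&
            all(.neighbor_ids(mesh, mesh$coords[j, ], .nb6)$ids == 0L)) {
          w <- colSums(mesh$state$M)
          com <- colSums(mesh$coords * w) / sum(w)
          off <- com - mesh$coords[j, ]
          ax <- which(round(off) != 0)
          if (length(ax)) {
            pick <- ax[order(abs(off[ax]), stats::runif(length(ax)))][1]
            tgt <- mesh$coords[j, ]
            tgt[pick] <- tgt[pick] + sign(off[pick])
            mesh <- .move_column(mesh, j, tgt)
            mesh$events$isolated_moves <- mesh$events$isolated_moves + 1L
            changed <- TRUE
          }
        }
        j <- j + 1L
      }
    }
    ## interior holes: empty sites with all six neighbors occupied
    if (nrow(mesh$coords) >= 6L) {
      box_lo <- pmax(apply(mesh$coords, 2, min), 1)
      box_hi <- pmin(apply(mesh$coords, 2, max), mesh$dims - 2)
      if (all(box_lo <= box_hi)) {
        cand <- as.matrix(expand.grid(x = box_lo[1]:box_hi[1],
                                      y = box_lo[2]:box_hi[2],
                                      z = box_lo[3]:box_hi[3]))
        empty <- cand[mesh$map[cand + 1L] == 0L, , drop = FALSE]
        holes <- empty[.occupied_nb6_counts(mesh, empty) == 6L, , drop = FALSE]
        for (r in seq_len(nrow(holes))) {
          co <- holes[r, ]
          if (mesh$map[co[1] + 1L, co[2] + 1L, co[3] + 1L] != 0L) next
          nb <- .neighbor_ids(mesh, co, .nb6)
          if (nrow(nb$coords) == 6L && all(nb$ids > 0L)) {
            mesh <- .chain_fill(mesh, co)
            mesh$events$holes_filled <- mesh$events$holes_filled + 1L
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  mesh
}

#' Second mesh scan: morphological rules
#'
#' Visits occupied GCs in lexicographic order from a random starting offset
#' (avoiding directional drift), rebalances any GC outside the occupancy
#' band, and repairs fragmentation and holes. Up to six band passes are made
#' because a repair or a spillover can leave a GC out of band again. Freshly
#' occupied growth-front GCs legitimately start below the band and fill up
#' as the tumor grows.
#'
#' @param mesh An `oncosim_mesh`.
#' @return The updated mesh.
#' @export
second_scan <- function(mesh) {
  NBC <- mesh$NBC
  for (pass in 1:6) {
    tots <- colSums(mesh$state$M)
    out_of_band <- which(tots > (1 + mesh$margin) * NBC |
                         (tots < (1 - mesh$margin) * NBC & tots > 0))
    if (!length(out_of_band)) break
    keys <- mesh$coords[, 1] + mesh$dims[1] * (mesh$coords[, 2] +
              mesh$dims[2] * mesh$coords[, 3])
    offset <- sample.int(prod(mesh$dims), 1)      # random scan origin
    visit <- order((keys + offset) %% prod(mesh$dims))
    for (j in visit) {
      if (j > ncol(mesh$state$M)) next    # columns may have been removed
      tot <- sum(mesh$state$M[, j])
      if (tot > (1 + mesh$margin) * NBC) mesh <- rebalance_overloaded(mesh, j)
      else if (tot > 0 && tot < (1 - mesh$margin) * NBC)
        mesh <- rebalance_underloaded(mesh, j)
    }
    mesh <- repair_fragmentation(mesh)
  }
  mesh
}

#' Paint necrotic GCs
#'
#' A GC is labeled necrotic when its dead-cell (apoptotic + necrotic)
#' fraction reaches the coloring criterion.
#'
#' @param mesh An `oncosim_mesh`.
#' @param color_criterion Threshold in `[0.9, 0.999]`.
#' @return A 3-D integer array over the lattice: 0 background, 1 tumor,
#'   2 necrotic.
#' @export
color_necrotic <- function(mesh, color_criterion = mesh$params$color_criterion) {
  if (color_criterion < 0.9 || color_criterion > 0.999)
    stop("color_criterion must be in [0.9, 0.999]", call. = FALSE)
  L <- mesh$state$layout
  dead <- colSums(mesh$state$M[c(L$apo_rows, L$nec_rows), , drop = FALSE])
  tot <- colSums(mesh$state$M)
  lab <- array(0L, dim = mesh$dims)
  occ <- tot > 0
  lab[mesh$coords[occ, , drop = FALSE] + 1L] <- 1L
  nec <- occ & dead / pmax(tot, 1e-12) >= color_criterion
  lab[mesh$coords[nec, , drop = FALSE] + 1L] <- 2L
  lab
}

#' Read / write voxel-list masks
#'
#' Plain CSV dialect with columns `x`, `y`, `z` (0-based integer indices)
#' and `label` (1 tumor, 2 necrotic). [write_nifti_mask()] and
#' [read_nifti_mask()] handle the same label volumes as NIfTI (requires the
#' RNifti package).
#'
#' @param path File path.
#' @return `read_voxel_mask()` returns a data.frame with `x`, `y`, `z`,
#'   `label`.
#' @export
read_voxel_mask <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("x", "y", "z", "label") %in% names(x)))
    stop("mask CSV needs columns x, y, z, label", call. = FALSE)
  x
}

#' @rdname read_voxel_mask
#' @param mask A data.frame with columns `x`, `y`, `z`, `label`.
#' @export
write_voxel_mask <- function(mask, path) {
  utils::write.csv(mask[, c("x", "y", "z", "label")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_voxel_mask
#' @param volume A 3-D label array (e.g. from [color_necrotic()]).
#' @export
write_nifti_mask <- function(volume, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI masks", call. = FALSE)
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' @rdname read_voxel_mask
#' @export
read_nifti_mask <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI masks", call. = FALSE)
  v <- RNifti::readNifti(path)
  array(as.integer(round(v)), dim = dim(v))
}
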