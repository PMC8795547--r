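#' Build the target-structure geometry
#'
#' Defines the lattice of species sites that a complete structure occupies:
#' a periodic ring of `S = L` species in 1D, or an open-boundary square
#' (cubic) lattice of `S = L^d` species in 2D/3D. Each lattice site hosts one
#' dedicated species; binding is specific, so the compatible partners of a
#' species are exactly the species on neighbouring sites.
#'
#' Sites are indexed 1..S in row-major order (first axis fastest), so in 1D
#' species `1` and `S` are ring neighbours. Internally coordinates are
#' 0-based integer tuples in `[0, L)^d`.
#'
#' @param d Dimension of the target structure: 1, 2 or 3.
#' @param L Edge length (integer, at least 2). The structure holds `S = L^d`
#'   distinct species.
#' @return An object of class `"assembly_geometry"`: a list with elements
#'   `d`, `L`, `S`, `boundary` (`"periodic"` for 1D, `"open"` otherwise),
#'   `coords` (S x d matrix of 0-based coordinates), `adjacency` (list of
#'   integer vectors of compatible partner species, 1-based) and `bonds`
#'   (two-column matrix of unique compatible pairs).
#' @examples
#' g <- build_geometry(2, 10)
#' g$S                       # 100
#' neighbors(g, 45)          # an interior site has 4 partners
#' @export
build_geometry <- function(d, L) {
  if (length(d) != 1L || !d %in% c(1L, 2L, 3L))
    stop("`d` must be 1, 2 or 3 (got ", deparse(d), ")")
  if (length(L) != 1L || !is.finite(L) || L != as.integer(L) || L < 2)
    stop("`L` must be an integer edge length >= 2 (got ", deparse(L), ")")
  d <- as.integer(d)
  L <- as.integer(L)
  S <- L^d

  coords <- as.matrix(do.call(expand.grid, rep(list(0:(L - 1L)), d)))
  dimnames(coords) <- NULL
  storage.mode(coords) <- "integer"

  site_of <- function(x) 1L + as.integer(x %*% L^(0:(d - 1L)))

  adjacency <- vector("list", S)
  for (s in seq_len(S)) {
    x <- coords[s, ]
    nb <- integer(0)
    for (ax in seq_len(d)) {
      for (dir in c(-1L, 1L)) {
        y <- x
        y[ax] <- y[ax] + dir
        if (d == 1L) {
          y[ax] <- y[ax] %% L  # periodic ring
        } else if (y[ax] < 0L || y[ax] >= L) {
          next                 # open boundary
        }
        nb <- c(nb, site_of(y))
      }
    }
    adjacency[[s]] <- sort(unique(nb[nb != s]))
  }

  bonds <- do.call(rbind, lapply(seq_len(S), function(s) {
    p <- adjacency[[s]]
    p <- p[p > s]
    if (length(p)) cbind(s, p) else NULL
  }))
  colnames(bonds) <- c("i", "j")

  structure(
    list(d = d, L = L, S = S,
         boundary = if (d == 1L) "periodic" else "open",
         coords = coords, adjacency = adjacency, bonds = bonds),
    class = "assembly_geometry")
}

#' @export
print.assembly_geometry <- function(x, ...) {
  cat(sprintf("assembly geometry: d = %d, L = %d, S = %d species (%s boundary)\n",
              x$d, x$L, x$S, x$boundary))
  cat(sprintf("  lattice bonds: %d\n", nrow(x$bonds)))
  invisible(x)
}

#' Compatible binding partners of a species
#'
#' @param geometry An [build_geometry()] object.
#' @param site Species/site index in `1..S`.
#' @return Integer vector of partner species indices.
#' @export
neighbors <- function(geometry, site) {
  stopifnot(inherits(geometry, "assembly_geometry"))
  if (length(site) != 1L || !is.finite(site) || site != as.integer(site) ||
      site < 1L || site > geometry$S)
    stop("`site` must be a single index in 1..", geometry$S)
  geometry$adjacency[[as.integer(site)]]
}

#' Onion-shell supply decomposition of a geometry
#'
#' Partitions the S sites into ordered batches for just-in-sequence supply.
#' In 1D the batches are the singleton species in ring order `1, 2, ..., S`
#' (unidirectional growth from species 1). For d >= 2 the sites are grouped
#' into concentric Chebyshev shells around the central site (odd `L`) or
#' around the central `2^d` block (even `L`), and every shell is split into
#' sub-batches that contain no pair of mutual binding partners: the square
#' lattice is bipartite, so each shell splits into its two coordinate-parity
#' classes (the even-`L` seed block is graded more finely, by Hamming
#' distance from one block corner, giving `d + 1` independent sub-batches).
#' Within a shell the parity class holding the shell's corner sites is
#' supplied second, so its members can attach via their already-supplied
#' same-shell neighbours.
#'
#' The no-partner property is essential, not cosmetic: a batch containing
#' two compatible species nucleates competing dimers the moment it is
#' supplied, at a rate that no batch spacing `delta_T` can suppress, and
#' those off-pathway structures parasitize the remaining supply.
#'
#' @param geometry An [build_geometry()] object.
#' @return A list of integer vectors (ordered batches) that partition `1..S`.
#' @examples
#' lengths(onion_shells(build_geometry(2, 5)))  # 1, 4, 4, 4, 8, 4
#' @export
onion_shells <- function(geometry) {
  stopifnot(inherits(geometry, "assembly_geometry"))
  d <- geometry$d
  L <- geometry$L
  S <- geometry$S
  if (d == 1L) return(as.list(seq_len(S)))

  coords <- geometry$coords
  parity <- rowSums(coords) %% 2L
  if (L %% 2L == 1L) {
    ctr <- (L - 1L) %/% 2L
    cheb <- apply(abs(coords - ctr), 1L, max)
    seed_batches <- list(which(cheb == 0L))
  } else {
    lo <- L %/% 2L - 1L
    hi <- L %/% 2L
    ax_dist <- pmax(lo - coords, coords - hi, 0L)
    cheb <- apply(ax_dist, 1L, max)
    seed <- which(cheb == 0L)
    # grade the 2^d seed block by Hamming distance from its low corner:
    # sites within one grade differ in >= 2 axes, hence are not partners
    ham <- rowSums(coords[seed, , drop = FALSE] == hi)
    seed_batches <- lapply(0:d, function(m) seed[ham == m])
  }

  if (L %% 2L == 1L) {
    ax <- abs(coords - (L - 1L) %/% 2L)
  } else {
    ax <- pmax(L %/% 2L - 1L - coords, coords - L %/% 2L, 0L)
  }
  shells <- seed_batches
  for (k in seq_len(max(cheb))) {
    ring <- which(cheb == k)
    # grade by the number m of axes at the maximal distance (faces, then
    # edges, then corners): a grade-m site's partners are all of grade m-1
    # or inward, hence already bound when the site arrives; splitting each
    # grade by parity removes the remaining same-grade adjacencies
    m <- rowSums(ax[ring, , drop = FALSE] == k)
    for (mi in sort(unique(m))) {
      grade <- ring[m == mi]
      cls <- split(grade, parity[grade])
      shells <- c(shells, unname(cls))
    }
  }
  shells <- Filter(length, shells)
  lapply(shells, as.integer)
}

# 0-based CSR adjacency + 0-based bond endpoints for the compiled engine
geometry_csr <- function(geometry) {
  lens <- lengths(geometry$adjacency)
  list(adj = as.integer(unlist(geometry$adjacency, use.names = FALSE) - 1L),
       ptr = as.integer(c(0L, cumsum(lens))),
       bond_i = as.integer(geometry$bonds[, 1L] - 1L),
       bond_j = as.integer(geometry$bonds[, 2L] - 1L))
}
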