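#' Create a fresh system state
#'
#' Holds the instantaneous configuration of the well-mixed assembly system:
#' free monomer pools (active and not-yet-supplied), the growing clusters,
#' and the count of completed structures. This plain-R representation backs
#' the reference propensity calculations and the event-level bookkeeping
#' tests; production simulations run through the compiled engine in
#' [run_simulation()].
#'
#' @param geometry An [build_geometry()] object.
#' @param active Integer vector (length S, or scalar recycled) of free,
#'   assembly-competent monomers per species.
#' @param unsupplied Integer vector (length S, or scalar) of monomers not yet
#'   injected (activation / just-in-sequence supply).
#' @return An object of class `"assembly_state"`.
#' @export
new_assembly_state <- function(geometry, active, unsupplied = 0L) {
  stopifnot(inherits(geometry, "assembly_geometry"))
  S <- geometry$S
  active <- as.integer(rep_len(active, S))
  unsupplied <- as.integer(rep_len(unsupplied, S))
  if (any(active < 0L) || any(unsupplied < 0L))
    stop("monomer counts must be nonnegative")
  structure(
    list(geometry = geometry, t = 0, active = active, unsupplied = unsupplied,
         clusters = list(), completed = 0L,
         allotment = active + unsupplied),
    class = "assembly_state")
}

#' @export
print.assembly_state <- function(x, ...) {
  cat(sprintf(
    "assembly state: t = %.4g, %d free monomers, %d clusters, %d completed\n",
    x$t, sum(x$active), length(x$clusters), x$completed))
  invisible(x)
}

as_members <- function(cluster) {
  m <- if (is.list(cluster)) cluster$members else cluster
  as.integer(m)
}

#' Number of bonds a monomer would form at a vacancy
#'
#' Counts the cluster members adjacent to an unoccupied site; this is the
#' bond count `b` entering the attachment propensity `b * nu * a / V` and,
#' after attachment, the `n` of the detachment rate `delta_n`.
#'
#' @param geometry An [build_geometry()] object.
#' @param cluster A cluster: an integer vector of member sites (or a list
#'   with element `members`).
#' @param site An unoccupied site index.
#' @return Integer in `0..2d`.
#' @export
bond_count <- function(geometry, cluster, site) {
  members <- as_members(cluster)
  if (site %in% members) stop("site ", site, " is occupied in this cluster")
  sum(neighbors(geometry, site) %in% members)
}

# all vacancies adjacent to the cluster, with their bond counts
cluster_frontier <- function(geometry, cluster) {
  members <- as_members(cluster)
  cand <- setdiff(unique(unlist(geometry$adjacency[members])), members)
  if (!length(cand)) return(data.frame(site = integer(0), b = integer(0)))
  b <- vapply(cand, function(s) bond_count(geometry, members, s), integer(1))
  data.frame(site = as.integer(cand), b = b)[order(cand), , drop = FALSE]
}

#' Members of a cluster that may detach
#'
#' A member may detach only if the remaining members stay connected
#' (articulation members are excluded), so clusters never fragment; in 1D
#' this reduces to the two chain ends. Each removable member is returned
#' with the number `n` of bonds its removal breaks.
#'
#' @inheritParams bond_count
#' @return A data frame with columns `site` and `n`.
#' @export
removable_members <- function(geometry, cluster) {
  members <- as_members(cluster)
  if (length(members) < 2L)
    stop("a cluster has at least 2 members")
  if (length(members) == 2L)
    return(data.frame(site = sort(members), n = c(1L, 1L)))
  sub <- geometry$bonds[geometry$bonds[, 1L] %in% members &
                          geometry$bonds[, 2L] %in% members, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(match(sub[, 1L], members),
                                         match(sub[, 2L], members)),
                                   directed = FALSE)
  art <- members[as.integer(igraph::articulation_points(g))]
  rem <- setdiff(members, art)
  n <- vapply(rem, function(v) sum(neighbors(geometry, v) %in% members),
              integer(1))
  out <- data.frame(site = as.integer(rem), n = n)
  out[order(out$site), , drop = FALSE]
}

#' Reaction event constructors
#'
#' Build the event lists consumed by [apply_event()]: dimerization of two
#' compatible free monomers, attachment of a free monomer at a cluster
#' vacancy, detachment of a removable cluster member, and influx (supply)
#' of unsupplied monomers.
#'
#' @param i,j Species indices of the dimerizing pair.
#' @param cluster Index of the cluster in `state$clusters`.
#' @param site Site/species index at which to attach or detach.
#' @param species Species to supply.
#' @param amount Number of copies to supply.
#' @return An event list with a `type` field.
#' @export
ev_dimerize <- function(i, j) list(type = "dimerize", i = i, j = j)

#' @rdname ev_dimerize
#' @export
ev_attach <- function(cluster, site) list(type = "attach", cluster = cluster, site = site)

#' @rdname ev_dimerize
#' @export
ev_detach <- function(cluster, site) list(type = "detach", cluster = cluster, site = site)

#' @rdname ev_dimerize
#' @export
ev_influx <- function(species, amount = 1L) list(type = "influx", species = species, amount = amount)

#' Apply a single reaction event to a state
#'
#' Events are lists with a `type` field: `dimerize` (fields `i`, `j`),
#' `attach` (`cluster`, `site`), `detach` (`cluster`, `site`) or `influx`
#' (`species`, `amount`). Infeasible events are rejected with an error
#' naming the violated precondition. A cluster reaching all `S` species is
#' complete: it is removed from the reactive set and counted in
#' `state$completed`. A detach from a 2-member cluster dissolves it into two
#' free monomers. Mass is conserved exactly (integer arithmetic).
#'
#' @param state An [new_assembly_state()] object.
#' @param event An event list (see Details).
#' @return The updated state.
#' @export
apply_event <- function(state, event) {
  stopifnot(inherits(state, "assembly_state"))
  g <- state$geometry
  S <- g$S
  switch(
    event$type,
    dimerize = {
      i <- event$i; j <- event$j
      if (!(j %in% neighbors(g, i)))
        stop("species ", i, " and ", j, " are not compatible partners")
      if (state$active[i] < 1L || state$active[j] < 1L)
        stop("no free active monomer of species ", if (state$active[i] < 1L) i else j)
      state$active[c(i, j)] <- state$active[c(i, j)] - 1L
      if (S == 2L) {
        state$completed <- state$completed + 1L
      } else {
        state$clusters[[length(state$clusters) + 1L]] <-
          list(members = sort(c(i, j)))
      }
    },
    attach = {
      k <- event$cluster
      if (k < 1L || k > length(state$clusters)) stop("no such cluster: ", k)
      members <- state$clusters[[k]]$members
      s <- event$site
      if (s %in% members) stop("site ", s, " is already occupied")
      if (bond_count(g, members, s) < 1L)
        stop("site ", s, " is not adjacent to cluster ", k)
      if (state$active[s] < 1L)
        stop("no free active monomer of species ", s)
      state$active[s] <- state$active[s] - 1L
      members <- sort(c(members, s))
      if (length(members) == S) {
        state$completed <- state$completed + 1L
        state$clusters[[k]] <- NULL
      } else {
        state$clusters[[k]]$members <- members
      }
    },
    detach = {
      k <- event$cluster
      if (k < 1L || k > length(state$clusters)) stop("no such cluster: ", k)
      members <- state$clusters[[k]]$members
      s <- event$site
      if (length(members) == 2L) {
        state$active[members] <- state$active[members] + 1L
        state$clusters[[k]] <- NULL
      } else {
        if (!s %in% removable_members(g, members)$site)
          stop("site ", s, " is not a removable member of cluster ", k)
        state$active[s] <- state$active[s] + 1L
        state$clusters[[k]]$members <- setdiff(members, s)
      }
    },
    influx = {
      s <- event$species
      amt <- as.integer(event$amount)
      if (state$unsupplied[s] < amt)
        stop("only ", state$unsupplied[s], " unsupplied monomers of species ", s)
      state$unsupplied[s] <- state$unsupplied[s] - amt
      state$active[s] <- state$active[s] + amt
    },
    stop("unknown event type: ", event$type)
  )
  state
}

#' Assembly yield of a state
#'
#' The number of completed structures relative to `reference_count`, the
#' maximum possible number of structures. Under stoichiometric supply the
#' reference is `N`; under a nonstoichiometric ramp the natural reference is
#' the minimum over species of the supplied copy numbers.
#'
#' @param state An [new_assembly_state()] object.
#' @param reference_count Positive integer.
#' @return Fraction in `[0, 1]`.
#' @export
yield_of <- function(state, reference_count) {
  if (length(reference_count) != 1L || !is.finite(reference_count) ||
      reference_count <= 0)
    stop("`reference_count` must be a positive number")
  state$completed / reference_count
}

#' Per-species mass balance of a state
#'
#' Returns `active + unsupplied + bound-in-clusters + completed - allotment`
#' per species; exact zeros certify that event bookkeeping conserved mass.
#'
#' @param state An [new_assembly_state()] object.
#' @return Integer vector of length S (all zero when mass is conserved).
#' @export
mass_balance <- function(state) {
  S <- state$geometry$S
  bound <- integer(S)
  for (cl in state$clusters) bound[cl$members] <- bound[cl$members] + 1L
  state$active + state$unsupplied + bound + state$completed - state$allotment
}
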