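# shared in-code fixtures; everything is generated, nothing is stored

geo1d <- function(S) build_geometry(1, S)
geo2d <- function(L) build_geometry(2, L)

# site index of 0-based coordinates in row-major order
site_at <- function(geometry, ...) {
  x <- c(...)
  as.integer(1L + sum(x * geometry$L^(seq_along(x) - 1L)))
}

# random feasible event drawn uniformly from the enumerated feasible set
random_feasible_event <- function(state, rates, supply = NULL) {
  tab <- compute_propensities(state, rates, supply)
  n <- c(nrow(tab$dimerization), nrow(tab$attachment), nrow(tab$detachment),
         nrow(tab$influx))
  if (sum(n) == 0L) return(NULL)
  idx <- sample.int(sum(n), 1L)
  if (idx <= n[1]) {
    ev_dimerize(tab$dimerization$i[idx], tab$dimerization$j[idx])
  } else if (idx <= n[1] + n[2]) {
    r <- tab$attachment[idx - n[1], ]
    ev_attach(r$cluster, r$site)
  } else if (idx <= n[1] + n[2] + n[3]) {
    r <- tab$detachment[idx - n[1] - n[2], ]
    ev_detach(r$cluster, r$site)
  } else {
    ev_influx(tab$influx$species[idx - n[1] - n[2] - n[3]])
  }
}

# connectivity check by flood fill over the member-induced subgraph
cluster_connected <- function(geometry, members) {
  if (length(members) <= 1L) return(TRUE)
  seen <- members[1L]
  frontier <- members[1L]
  while (length(frontier)) {
    nxt <- setdiff(intersect(unlist(geometry$adjacency[frontier]), members), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(members)
}
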