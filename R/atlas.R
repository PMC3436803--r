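# Package-level cache: the atlas is a pure function of nothing, so build it
# once per session.
.egdv_cache <- new.env(parent = emptyenv())

# All permutations of 1..n as a matrix (n! rows).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep.int(i, rows), matrix(setdiff(seq_len(n), i)[sub], rows))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

# Unordered pairs of 1..k in combn order; pair index lookup matrix.
.pairs_of <- function(k) utils::combn(k, 2L)

.pair_index_matrix <- function(k) {
  prs <- .pairs_of(k)
  idx <- matrix(0L, k, k)
  for (t in seq_len(ncol(prs))) {
    idx[prs[1L, t], prs[2L, t]] <- t
    idx[prs[2L, t], prs[1L, t]] <- t
  }
  idx
}

# Is the graph encoded by `bits` (over .pairs_of(k)) connected on k nodes?
.bits_connected <- function(bits, prs, k) {
  if (k == 1L) return(TRUE)
  adj <- matrix(FALSE, k, k)
  on <- which(bits == 1L)
  if (length(on) == 0L) return(FALSE)
  adj[cbind(prs[1L, on], prs[2L, on])] <- TRUE
  adj[cbind(prs[2L, on], prs[1L, on])] <- TRUE
  seen <- logical(k)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Enumerate all 2-5-node graphlets and their automorphism orbits
#'
#' Builds the canonical atlas of the 30 connected simple graphs on 2 to 5
#' nodes ("graphlets") and derives, for each graphlet, the partition of its
#' nodes and of its edges into automorphism orbits: two nodes (edges) share
#' an orbit exactly when some automorphism of the graphlet maps one onto the
#' other.  Across the atlas there are 73 node orbits and 69 edge orbits (68
#' excluding the single edge of the 2-node graphlet).  Automorphism groups
#' are computed by exhaustive permutation, which is exact at this size.
#'
#' Graphlets are ordered by node count, then edge count, then decreasing
#' degree sequence, so that the conventional anchors hold: the 2-node edge
#' is graphlet 0, the 3-node path graphlet 1, the triangle graphlet 2 and
#' the 4-node path graphlet 3.  Orbits are numbered along that order, and
#' within a graphlet by decreasing orbit size; hence the 3-node path's edges
#' form edge orbit 1, the triangle's edges edge orbit 2, and the 4-node
#' path's outer and middle edges edge orbits 3 and 4.
#'
#' The atlas also carries, for every labelled graph on up to 5 nodes, lookup
#' tables mapping each node and each edge position directly to its global
#' orbit id; [count_node_gdv()] and [count_edge_gdv()] use these to classify
#' enumerated induced subgraphs in constant time.
#'
#' @param force Rebuild even if a cached atlas exists in the session.
#' @return An object of class `egdv_atlas`: a list with elements
#'   `graphlets` (data frame: `id`, `n`, `m`, canonical `code`), `reps`
#'   (edge lists of the canonical representatives), `node_orbits` /
#'   `edge_orbits` (per-graphlet global orbit ids), `n_node_orbits` (73),
#'   `n_edge_orbits` (69), and internal lookup tables.
#' @seealso [edge_orbit_weights()], [node_orbit_weights()], [atlas_table()]
#' @examples
#' atl <- graphlet_atlas()
#' nrow(atl$graphlets)   # 30
#' atl$n_node_orbits    # 73
#' atl$n_edge_orbits    # 69
#' @export
graphlet_atlas <- function(force = FALSE) {
  if (!force && !is.null(.egdv_cache$atlas)) return(.egdv_cache$atlas)

  perms <- lapply(1:5, .permutations)
  pairs <- lapply(1:5, function(k) if (k >= 2) .pairs_of(k) else matrix(0L, 2, 0))
  pidx <- lapply(1:5, function(k) if (k >= 2) .pair_index_matrix(k) else matrix(0L, 1, 1))

  # Per k: bit matrix of all codes, code image under every permutation
  # (CP, ncodes x nperm), canonical code (row minimum), connectivity.
  bits_of <- list()
  canon_of <- list()
  conn_of <- list()
  CP_of <- list()
  # PI[[k]]: nperm x npairs matrix, image pair index under each permutation.
  PI <- list()
  for (k in 2:5) {
    np <- ncol(pairs[[k]])
    codes <- 0:(2^np - 1)
    B <- vapply(seq_len(np), function(t) as.integer(codes %/% 2^(t - 1)) %% 2L,
                integer(length(codes)))
    P <- perms[[k]]
    pim <- matrix(0L, nrow(P), np)
    for (p in seq_len(nrow(P))) {
      pp <- P[p, ]
      pim[p, ] <- pidx[[k]][cbind(pp[pairs[[k]][1L, ]], pp[pairs[[k]][2L, ]])]
    }
    W <- matrix(0, np, nrow(P))
    W[cbind(as.vector(t(pim)), rep(seq_len(nrow(P)), each = np))] <-
      rep(2^(seq_len(np) - 1), nrow(P))
    CP <- B %*% W
    bits_of[[k]] <- B
    canon_of[[k]] <- as.integer(apply(CP, 1L, min))
    conn_of[[k]] <- vapply(seq_along(codes), function(i)
      .bits_connected(B[i, ], pairs[[k]], k), logical(1))
    CP_of[[k]] <- CP
    PI[[k]] <- pim
  }

  # Collect graphlets: unique canonical codes of connected graphs, ordered.
  glist <- list()
  for (k in 2:5) {
    reps <- sort(unique(canon_of[[k]][conn_of[[k]]]))
    for (code in reps) {
      bits <- bits_of[[k]][code + 1L, ]
      on <- which(bits == 1L)
      deg <- tabulate(c(pairs[[k]][1L, on], pairs[[k]][2L, on]), k)
      glist[[length(glist) + 1L]] <- list(
        n = k, m = length(on), code = code,
        degkey = paste(sort(deg, decreasing = TRUE), collapse = ""))
    }
  }
  ord <- order(vapply(glist, `[[`, 0L, "n"),
               vapply(glist, `[[`, 0L, "m"),
               vapply(glist, `[[`, "", "degkey"),
               vapply(glist, `[[`, 0L, "code"))
  glist <- glist[ord]

  n_g <- length(glist)
  node_orbits <- vector("list", n_g)
  edge_orbits <- vector("list", n_g)   # per pair index; NA where no edge
  reps <- vector("list", n_g)
  next_norb <- 0L
  next_eorb <- 0L
  for (g in seq_len(n_g)) {
    k <- glist[[g]]$n
    code <- glist[[g]]$code
    bits <- bits_of[[k]][code + 1L, ]
    on <- which(bits == 1L)
    prs <- pairs[[k]]
    # automorphisms: permutations fixing the code
    auts <- which(CP_of[[k]][code + 1L, ] == code)
    # node orbit classes via union over automorphism images
    nrep <- seq_len(k)
    for (p in auts) {
      img <- perms[[k]][p, ]
      for (v in seq_len(k)) {
        a <- min(nrep[v], nrep[img[v]]); b <- max(nrep[v], nrep[img[v]])
        nrep[nrep == b] <- a
      }
    }
    # edge orbit classes
    erep <- rep(NA_integer_, ncol(prs)); erep[on] <- on
    for (p in auts) {
      for (t in on) {
        ti <- PI[[k]][p, t]
        a <- min(erep[t], erep[ti]); b <- max(erep[t], erep[ti])
        erep[!is.na(erep) & erep == b] <- a
      }
    }
    # number orbits: larger classes first, then smallest member
    assign_ids <- function(classrep, members, start) {
      cls <- unique(classrep[members])
      size <- vapply(cls, function(cc) sum(classrep[members] == cc), 0L)
      cls <- cls[order(-size, cls)]
      ids <- rep(NA_integer_, length(classrep))
      for (i in seq_along(cls))
        ids[!is.na(classrep) & classrep == cls[i]] <- start + i - 1L
      list(ids = ids, nxt = start + length(cls))
    }
    an <- assign_ids(nrep, seq_len(k), next_norb)
    node_orbits[[g]] <- an$ids; next_norb <- an$nxt
    ae <- assign_ids(erep, on, next_eorb)
    edge_orbits[[g]] <- ae$ids; next_eorb <- ae$nxt
    reps[[g]] <- list(n = k, m = glist[[g]]$m, code = code,
                      edges = prs[, on, drop = FALSE], pair_on = on)
  }

  # Lookup tables: labelled code -> graphlet id and per-position orbit ids.
  canon2g <- new.env(parent = emptyenv())
  for (g in seq_len(n_g))
    assign(sprintf("%d_%d", glist[[g]]$n, glist[[g]]$code), g, envir = canon2g)
  node_lut <- vector("list", 5)
  edge_lut <- vector("list", 5)
  g_lut <- vector("list", 5)
  for (k in 2:5) {
    nc <- nrow(bits_of[[k]])
    np <- ncol(bits_of[[k]])
    nl <- matrix(NA_integer_, nc, k)
    el <- matrix(NA_integer_, nc, np)
    gl <- rep(NA_integer_, nc)
    for (code in which(conn_of[[k]]) - 1L) {
      cn <- canon_of[[k]][code + 1L]
      g <- get(sprintf("%d_%d", k, cn), envir = canon2g)
      # CP[, p] is the image under the inverse of perms[[k]][p, ], so a hit
      # means perms[[k]][p, ] carries the canonical labelling onto this one:
      # canonical node u sits at labelled position perms[p, u], canonical
      # pair slot s at labelled slot PI[p, s].
      p <- which(CP_of[[k]][code + 1L, ] == cn)[1L]
      nl[code + 1L, perms[[k]][p, ]] <- node_orbits[[g]]
      el[code + 1L, PI[[k]][p, ]] <- edge_orbits[[g]]
      gl[code + 1L] <- g - 1L
    }
    node_lut[[k]] <- nl
    edge_lut[[k]] <- el
    g_lut[[k]] <- gl
  }

  atlas <- structure(list(
    graphlets = data.frame(
      id = seq_len(n_g) - 1L,
      n = vapply(glist, `[[`, 0L, "n"),
      m = vapply(glist, `[[`, 0L, "m"),
      code = vapply(glist, `[[`, 0L, "code")),
    reps = reps,
    node_orbits = node_orbits,
    edge_orbits = edge_orbits,
    n_node_orbits = next_norb,
    n_edge_orbits = next_eorb,
    node_lut = node_lut,
    edge_lut = edge_lut,
    graphlet_lut = g_lut,
    pairs = pairs
  ), class = "egdv_atlas")
  .egdv_cache$atlas <- atlas
  atlas
}

#' @export
print.egdv_atlas <- function(x, ...) {
  cat(sprintf("Graphlet atlas: %d graphlets (2-5 nodes), %d node orbits, %d edge orbits\n",
              nrow(x$graphlets), x$n_node_orbits, x$n_edge_orbits))
  invisible(x)
}

# All ordered injections of `m` slots into `pool` (matrix, one row per map).
.arrangements <- function(m, pool) {
  if (m == 0L) return(matrix(integer(0), 1L, 0L))
  if (length(pool) < m) return(matrix(integer(0), 0L, m))
  out <- NULL
  for (i in seq_along(pool)) {
    sub <- .arrangements(m - 1L, pool[-i])
    out <- rbind(out, cbind(rep.int(pool[i], nrow(sub)), sub))
  }
  out
}

# Does graphlet j occur as an induced subgraph of graphlet i under a map
# carrying edge (x, y) of j onto edge (p, q) of i?  Induced occurrence is
# what makes one orbit's count imply another's: every copy of graphlet i
# touching an edge at orbit i contains, on a node subset, exactly the
# graphlets induced within i.
.occurs_through_edge <- function(adj_j, nj, x, y, adj_i, ni, p, q) {
  rest_j <- setdiff(seq_len(nj), c(x, y))
  rest_i <- setdiff(seq_len(ni), c(p, q))
  maps <- .arrangements(length(rest_j), rest_i)
  for (orient in 1:2) {
    phi <- integer(nj)
    phi[x] <- if (orient == 1L) p else q
    phi[y] <- if (orient == 1L) q else p
    for (r in seq_len(nrow(maps))) {
      phi[rest_j] <- maps[r, ]
      ok <- TRUE
      for (a in seq_len(nj - 1L)) {
        for (b in (a + 1L):nj) {
          if (adj_j[a, b] != adj_i[phi[a], phi[b]]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) return(TRUE)
    }
  }
  FALSE
}

# As above but carrying node x of j onto node p of i.
.occurs_through_node <- function(adj_j, nj, x, adj_i, ni, p) {
  rest_j <- setdiff(seq_len(nj), x)
  rest_i <- setdiff(seq_len(ni), p)
  phi <- integer(nj)
  phi[x] <- p
  maps <- .arrangements(length(rest_j), rest_i)
  for (r in seq_len(nrow(maps))) {
    phi[rest_j] <- maps[r, ]
    ok <- TRUE
    for (a in seq_len(nj - 1L)) {
      for (b in (a + 1L):nj) {
        if (adj_j[a, b] != adj_i[phi[a], phi[b]]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) return(TRUE)
  }
  FALSE
}

.rep_adj <- function(atlas, g) {
  rp <- atlas$reps[[g]]
  adj <- matrix(FALSE, rp$n, rp$n)
  adj[t(rp$edges)] <- TRUE
  adj[t(rp$edges)[, 2:1, drop = FALSE]] <- TRUE
  adj
}

# Representative (graphlet index, member) for every node / edge orbit.
.orbit_reps <- function(atlas, kind = c("node", "edge")) {
  kind <- match.arg(kind)
  n_orb <- if (kind == "node") atlas$n_node_orbits else atlas$n_edge_orbits
  out <- vector("list", n_orb)
  for (g in seq_along(atlas$reps)) {
    if (kind == "node") {
      ids <- atlas$node_orbits[[g]]
      for (v in seq_along(ids)) {
        o <- ids[v] + 1L
        if (is.null(out[[o]])) out[[o]] <- list(g = g, member = v)
      }
    } else {
      ids <- atlas$edge_orbits[[g]]
      for (t in which(!is.na(ids))) {
        o <- ids[t] + 1L
        if (is.null(out[[o]]))
          out[[o]] <- list(g = g, member = atlas$pairs[[atlas$reps[[g]]$n]][, t])
      }
    }
  }
  out
}

#' Edge-orbit dependency counts and weights
#'
#' For each edge orbit \eqn{i} (orbits 1-68, spanning the 3-5-node
#' graphlets), counts the number \eqn{o_i} of edge orbits that affect orbit
#' \eqn{i}, including itself: orbit \eqn{j} affects orbit \eqn{i} when the
#' graphlet housing \eqn{j} occurs as an induced subgraph of the graphlet
#' housing \eqn{i} under an injection that carries an edge of orbit \eqn{j}
#' onto the focal edge of orbit \eqn{i}.  (Every network copy of orbit
#' \eqn{i}'s graphlet then necessarily contributes to orbit \eqn{j}'s count
#' of the focal edge, so differences in nested orbits propagate outward;
#' the triangle orbit, for instance, affects exactly the orbits whose
#' graphlet places the focal edge inside an induced triangle.)  Dependent
#' orbits are down-weighted:
#' \deqn{w_i = 1 - \log(o_i)/\log(68).}
#' Weights lie in (0, 1]; \eqn{w_i = 1} exactly when \eqn{o_i = 1}.
#'
#' @param atlas An atlas from [graphlet_atlas()] (built if missing).
#' @return A list with integer vector `o` and numeric vector `w`, each of
#'   length 68, indexed by edge orbit id (element `i` is orbit `i`).
#' @examples
#' w <- edge_orbit_weights()
#' w$o[1]   # 1: nothing but itself affects the 3-node path edge orbit
#' w$w[1]   # 1
#' @export
edge_orbit_weights <- function(atlas = graphlet_atlas()) {
  if (!is.null(.egdv_cache$edge_w) && !is.null(.egdv_cache$atlas) &&
      identical(atlas, .egdv_cache$atlas)) return(.egdv_cache$edge_w)
  reps <- .orbit_reps(atlas, "edge")
  adjs <- lapply(seq_along(atlas$reps), function(g) .rep_adj(atlas, g))
  n_orb <- atlas$n_edge_orbits
  o <- integer(n_orb - 1L)  # orbits 1..68; orbit 0 excluded from the vector
  for (i in 2:n_orb) {
    gi <- reps[[i]]$g; ei <- reps[[i]]$member
    ni <- atlas$reps[[gi]]$n
    cnt <- 0L
    for (j in 2:n_orb) {
      gj <- reps[[j]]$g; ej <- reps[[j]]$member
      nj <- atlas$reps[[gj]]$n
      if (nj > ni) next
      if (.occurs_through_edge(adjs[[gj]], nj, ej[1L], ej[2L],
                               adjs[[gi]], ni, ei[1L], ei[2L]))
        cnt <- cnt + 1L
    }
    o[i - 1L] <- cnt
  }
  res <- list(o = o, w = 1 - log(o) / log(n_orb - 1L))
  .egdv_cache$edge_w <- res
  res
}

#' Node-orbit dependency counts and weights
#'
#' The node analogue of [edge_orbit_weights()]: for each of the 73 node
#' orbits, \eqn{o_i} counts the node orbits whose graphlet occurs as an
#' induced subgraph of orbit \eqn{i}'s graphlet with a node of orbit \eqn{j}
#' carried onto the focal node, and \eqn{w_i = 1 - \log(o_i)/\log(73)}.
#' Orbit 0 (the degree) depends only on itself.
#'
#' @inheritParams edge_orbit_weights
#' @return A list with integer vector `o` and numeric vector `w` of length
#'   73; element `i` corresponds to node orbit `i - 1`.
#' @export
node_orbit_weights <- function(atlas = graphlet_atlas()) {
  if (!is.null(.egdv_cache$node_w) && !is.null(.egdv_cache$atlas) &&
      identical(atlas, .egdv_cache$atlas)) return(.egdv_cache$node_w)
  reps <- .orbit_reps(atlas, "node")
  adjs <- lapply(seq_along(atlas$reps), function(g) .rep_adj(atlas, g))
  n_orb <- atlas$n_node_orbits
  o <- integer(n_orb)
  for (i in seq_len(n_orb)) {
    gi <- reps[[i]]$g; vi <- reps[[i]]$member
    ni <- atlas$reps[[gi]]$n
    cnt <- 0L
    for (j in seq_len(n_orb)) {
      gj <- reps[[j]]$g; vj <- reps[[j]]$member
      nj <- atlas$reps[[gj]]$n
      if (nj > ni) next
      if (.occurs_through_node(adjs[[gj]], nj, vj, adjs[[gi]], ni, vi))
        cnt <- cnt + 1L
    }
    o[i] <- cnt
  }
  res <- list(o = o, w = 1 - log(o) / log(n_orb))
  .egdv_cache$node_w <- res
  res
}

#' Reference table of all orbits
#'
#' One row per orbit across the atlas: orbit kind, global orbit id, housing
#' graphlet, member nodes or edges of the canonical representative, and (for
#' edge orbits 1-68 and all node orbits) the dependency count `o` and weight
#' `w`.
#'
#' @inheritParams edge_orbit_weights
#' @return A data frame with columns `kind`, `orbit`, `graphlet`, `members`,
#'   `o`, `w`.
#' @export
atlas_table <- function(atlas = graphlet_atlas()) {
  ew <- edge_orbit_weights(atlas)
  nw <- node_orbit_weights(atlas)
  rows <- list()
  for (g in seq_along(atlas$reps)) {
    k <- atlas$reps[[g]]$n
    ids <- atlas$node_orbits[[g]]
    for (o in sort(unique(ids))) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "node", orbit = o, graphlet = g - 1L,
        members = paste(which(ids == o), collapse = ","),
        o = nw$o[o + 1L], w = nw$w[o + 1L])
    }
    eids <- atlas$edge_orbits[[g]]
    prs <- atlas$pairs[[k]]
    for (o in sort(unique(eids[!is.na(eids)]))) {
      ts <- which(!is.na(eids) & eids == o)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "edge", orbit = o, graphlet = g - 1L,
        members = paste(vapply(ts, function(t)
          paste(prs[, t], collapse = "-"), ""), collapse = ","),
        o = if (o == 0L) NA_integer_ else ew$o[o],
        w = if (o == 0L) NA_real_ else ew$w[o])
    }
  }
  do.call(rbind, rows)
}
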